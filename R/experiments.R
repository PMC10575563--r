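# Scripted replications of the simulated behavioral experiments. Each
# function runs a Monte-Carlo protocol on top of run_batch / the decoding
# engine and returns a tidy table plus, where applicable, a least-squares
# fit summary.

#' Least-squares curve fit summary
#'
#' Ordinary least squares on (optionally log-transformed) coordinates:
#' `"log-linear"` fits `y ~ log2(x)` (Hick-style), `"log-log"` fits
#' `log(y) ~ log(x)` (power law), `"linear"` fits `y ~ x`.
#'
#' @param x predictor vector (positive where a log transform applies).
#' @param y response vector.
#' @param model_kind one of `"log-linear"`, `"log-log"`, `"linear"`.
#' @return a list of class `fit_summary` with `model_kind`, `intercept`,
#'   `slope`, `r_squared`.
#' @export
fit_curve <- function(x, y, model_kind = c("log-linear", "log-log", "linear")) {
  model_kind <- match.arg(model_kind)
  if (length(x) < 3L || length(y) != length(x)) {
    stop("fit_curve needs at least 3 (x, y) points", call. = FALSE)
  }
  if (model_kind != "linear" && any(x <= 0)) {
    stop("x must be positive for log transforms", call. = FALSE)
  }
  if (model_kind == "log-log" && any(y <= 0)) {
    stop("y must be positive for a log-log fit", call. = FALSE)
  }
  tx <- switch(model_kind,
               "log-linear" = log2(x),
               "log-log" = log(x),
               "linear" = x)
  ty <- switch(model_kind,
               "log-log" = log(y),
               y)
  if (stats::sd(tx) == 0) stop("degenerate fit: x is constant", call. = FALSE)
  fit <- stats::lm(ty ~ tx)
  ss_tot <- sum((ty - mean(ty))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(model_kind = model_kind,
         intercept = unname(stats::coef(fit)[1L]),
         slope = unname(stats::coef(fit)[2L]),
         r_squared = r2),
    class = "fit_summary"
  )
}

#' @export
print.fit_summary <- function(x, ...) {
  cat(sprintf("<fit_summary> %s: intercept %.4g, slope %.4g, R^2 %.4f\n",
              x$model_kind, x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Renormalized halving source distribution
#'
#' The non-uniform source used in the surprisal and prior-sweep protocols:
#' probabilities proportional to `0.5^exponents`, renormalized to sum to 1.
#' The default exponent sequence `c(1, 2, 5, 4, 5)` is non-monotone in its
#' middle entries; pass `1:5` for the strictly geometric variant.
#'
#' @param exponents positive exponents applied to 0.5.
#' @return probability vector.
#' @export
halving_source_probs <- function(exponents = c(1, 2, 5, 4, 5)) {
  p <- 0.5^exponents
  p / sum(p)
}

#' Set-size (Hick) experiment
#'
#' Mean decoding time as a function of codebook size K under a uniform prior.
#' For each K a one-hot codebook is built and `n_trials` transmissions are
#' decoded; the per-K mean times are fitted against `log2(K)`. Decoding time
#' grows linearly with the logarithm of the number of possible symbols.
#'
#' @param K_values integer vector of codebook sizes (each >= 2).
#' @param noise baseline noise rate (spikes/second).
#' @param signal signal power (spikes/second).
#' @param threshold entropy stopping threshold in bits.
#' @param n_trials transmissions per K.
#' @param dt bin width in seconds.
#' @param max_time censoring horizon in seconds.
#' @param seed optional integer seed.
#' @return list with `table` (columns `K`, `mean_time`, `se_time`, `n`) and
#'   `fit` (a log-linear [fit_curve()] summary).
#' @export
hick_experiment <- function(K_values = c(2, 4, 6, 8, 10), noise = 10,
                            signal = 18, threshold = 0.5, n_trials = 2000,
                            dt = 0.1, max_time = 60, seed = NULL) {
  if (any(K_values < 2)) stop("every K must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(K_values, function(K) {
    cb <- make_onehot_codebook(K, K, signal_power = signal, noise_rate = noise)
    sched <- transmission_schedule(uniform_prior(K), n_trials,
                                   threshold = threshold, dt = dt,
                                   max_time = max_time)
    res <- run_batch(sched, cb)
    data.frame(K = K, mean_time = mean(res$decode_time),
               se_time = stats::sd(res$decode_time) / sqrt(n_trials),
               n = n_trials)
  })
  tab <- do.call(rbind, rows)
  fit <- if (nrow(tab) >= 3L) fit_curve(tab$K, tab$mean_time, "log-linear")
  list(table = tab, fit = fit)
}

#' Surprisal (Hyman) experiment
#'
#' Transmits symbols from a non-uniform source while the decoder holds a
#' matching (or supplied) prior, and relates each symbol's mean information
#' gain at decision time — the KL divergence from prior to posterior — to its
#' mean decoding time. Rarer-believed symbols require more evidence to
#' overwhelm the skeptical prior, yielding both larger information gain and
#' longer decoding time; across symbols the relation is linear.
#'
#' @param source_probabilities true symbol distribution.
#' @param decoder_prior decoder's prior; default equal to the source.
#' @param threshold entropy stopping threshold in bits.
#' @param noise baseline noise rate.
#' @param signal signal power.
#' @param n_trials total transmissions.
#' @param dt bin width in seconds.
#' @param max_time censoring horizon.
#' @param seed optional integer seed.
#' @return list with `table` (per symbol: `symbol`, `source_prob`,
#'   `mean_info_gain`, `mean_time`, `se_time`, `n`), `fit` (linear fit of
#'   mean time on mean info gain) and `pearson_r`.
#' @export
hyman_experiment <- function(source_probabilities = halving_source_probs(),
                             decoder_prior = NULL, threshold = 0.7,
                             noise = 10, signal = 12, n_trials = 50000,
                             dt = 0.1, max_time = 60, seed = NULL) {
  if (is.null(decoder_prior)) decoder_prior <- source_probabilities
  K <- length(source_probabilities)
  cb <- make_onehot_codebook(K, K, signal_power = signal, noise_rate = noise)
  sched <- transmission_schedule(source_probabilities, n_trials,
                                 decoder_prior = decoder_prior,
                                 threshold = threshold, dt = dt,
                                 max_time = max_time, seed = seed)
  res <- run_batch(sched, cb)
  tab <- do.call(rbind, lapply(seq_len(K), function(s) {
    r <- res[res$true_symbol == s, ]
    data.frame(symbol = s, source_prob = source_probabilities[s],
               mean_info_gain = mean(r$info_gain),
               mean_time = mean(r$decode_time),
               se_time = stats::sd(r$decode_time) / sqrt(nrow(r)),
               n = nrow(r))
  }))
  fit <- if (nrow(tab) >= 3L) {
    fit_curve(tab$mean_info_gain, tab$mean_time, "linear")
  }
  list(table = tab, fit = fit,
       pearson_r = stats::cor(tab$mean_info_gain, tab$mean_time))
}

#' Prior-sweep experiment
#'
#' Decodes the same non-uniform source under several decoder priors. A
#' uniform prior yields equivalent decoding times for all symbols despite
#' their unequal frequencies; as the prior approaches the true source
#' distribution, frequent symbols speed up, rare ones slow down, and the
#' source-weighted expected decoding time falls.
#'
#' @param source_probabilities true symbol distribution.
#' @param priors named list of decoder priors (each strictly positive).
#' @param threshold entropy stopping threshold in bits.
#' @param noise baseline noise rate.
#' @param signal signal power.
#' @param n_trials transmissions per prior condition.
#' @param dt bin width in seconds.
#' @param max_time censoring horizon.
#' @param seed optional integer seed.
#' @return list with `table` (per prior x symbol: `prior`, `symbol`,
#'   `mean_time`, `se_time`, `n`) and `expected_time` (per prior:
#'   source-weighted mean decoding time with its standard error).
#' @export
prior_sweep_experiment <- function(source_probabilities = halving_source_probs(),
                                   priors = NULL, threshold = 0.7, noise = 10,
                                   signal = 12, n_trials = 50000, dt = 0.1,
                                   max_time = 60, seed = NULL) {
  K <- length(source_probabilities)
  if (is.null(priors)) {
    approx_prior <- c(0.360, 0.228, 0.168, 0.065, 0.032)
    approx_prior <- approx_prior / sum(approx_prior)
    if (K != 5L) stop("default priors assume a 5-symbol source", call. = FALSE)
    priors <- list(uniform = uniform_prior(K),
                   approximate = approx_prior,
                   exact = source_probabilities)
  }
  if (is.null(names(priors)) || any(names(priors) == "")) {
    stop("`priors` must be a named list", call. = FALSE)
  }
  for (p in priors) {
    validate_prior(p, K = K)
    if (any(p[source_probabilities > 0] == 0)) {
      stop("a prior places zero mass on a transmitted symbol: decoding would ",
           "never terminate", call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  cb <- make_onehot_codebook(K, K, signal_power = signal, noise_rate = noise)
  per_cell <- list()
  expected <- list()
  for (label in names(priors)) {
    sched <- transmission_schedule(source_probabilities, n_trials,
                                   decoder_prior = priors[[label]],
                                   threshold = threshold, dt = dt,
                                   max_time = max_time)
    res <- run_batch(sched, cb)
    per_cell[[label]] <- do.call(rbind, lapply(seq_len(K), function(s) {
      r <- res[res$true_symbol == s, ]
      data.frame(prior = label, symbol = s,
                 mean_time = mean(r$decode_time),
                 se_time = stats::sd(r$decode_time) / sqrt(nrow(r)),
                 n = nrow(r))
    }))
    expected[[label]] <- data.frame(
      prior = label,
      expected_time = mean(res$decode_time),
      se = stats::sd(res$decode_time) / sqrt(nrow(res)))
  }
  list(table = do.call(rbind, unname(per_cell)),
       expected_time = do.call(rbind, unname(expected)))
}

#' Speed-accuracy trade-off experiment
#'
#' Sweeps the entropy stopping threshold at one or more signal powers and
#' records mean decoding time and accuracy per cell. Lower thresholds demand
#' more confidence: decodes get slower and more accurate. Higher signal
#' power shifts the whole curve toward faster, at-least-as-accurate decodes.
#'
#' @param thresholds vector of entropy thresholds in bits.
#' @param signal_powers vector of signal powers (spikes/second).
#' @param noise baseline noise rate.
#' @param K codebook size.
#' @param n_trials transmissions per (threshold, signal) cell.
#' @param dt bin width in seconds.
#' @param max_time censoring horizon.
#' @param seed optional integer seed.
#' @return data.frame with columns `threshold`, `signal`, `mean_time`,
#'   `se_time`, `accuracy`, `n`.
#' @export
sat_experiment <- function(thresholds = seq(0.2, 2.5, length.out = 10),
                           signal_powers = c(18, 20), noise = 8, K = 10,
                           n_trials = 1000, dt = 0.1, max_time = 60,
                           seed = NULL) {
  if (any(thresholds <= 0)) stop("thresholds must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(threshold = thresholds, signal = signal_powers)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cb <- make_onehot_codebook(K, K, signal_power = grid$signal[i],
                               noise_rate = noise)
    sched <- transmission_schedule(uniform_prior(K), n_trials,
                                   threshold = grid$threshold[i], dt = dt,
                                   max_time = max_time)
    res <- run_batch(sched, cb)
    data.frame(threshold = grid$threshold[i], signal = grid$signal[i],
               mean_time = mean(res$decode_time),
               se_time = stats::sd(res$decode_time) / sqrt(n_trials),
               accuracy = mean(res$correct), n = n_trials)
  })
  do.call(rbind, rows)
}

#' Congruence/conflict (Stroop) experiment
#'
#' Transmits multiplexed stimuli — weighted superpositions of codebook rate
#' vectors — while the decoder keeps the unmodified codebook. Relative to a
#' neutral single-symbol transmission, a congruent addition (extra rate on
#' the target's own neuron) speeds decoding, while an incongruent addition
#' (extra rate on a competing neuron) slows it and lowers accuracy.
#'
#' @param conditions named list; each element is a list with `symbols` and
#'   `weights` passed to [multiplex_rates()]. Defaults to the two-symbol
#'   neutral / congruent / incongruent setup at signal 12, noise 12 (rate
#'   vectors `[24, 12]`, `[27, 12]`, `[24, 17]`).
#' @param target_symbol 1-based index decoding is scored against.
#' @param threshold entropy stopping threshold in bits.
#' @param noise baseline noise rate.
#' @param signal signal power.
#' @param n_trials transmissions per condition.
#' @param dt bin width in seconds.
#' @param max_time censoring horizon.
#' @param seed optional integer seed.
#' @return list with `results` (per trial: `condition`, `decode_time`,
#'   `decoded_symbol`, `correct`, `censored`) and `summary` (per condition:
#'   `mean_time`, `se_time`, `accuracy`, `n`).
#' @export
stroop_experiment <- function(conditions = NULL, target_symbol = 1,
                              threshold = 0.1, noise = 12, signal = 12,
                              n_trials = 5000, dt = 0.1, max_time = 60,
                              seed = NULL) {
  if (is.null(conditions)) {
    conditions <- list(
      neutral = list(symbols = 1, weights = 1),
      congruent = list(symbols = c(1, 1), weights = c(1, 0.25)),
      incongruent = list(symbols = c(1, 2), weights = c(1, 5 / 12))
    )
  }
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    stop("`conditions` must be a named list", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cb <- make_onehot_codebook(2, 2, signal_power = signal, noise_rate = noise)
  prior <- uniform_prior(2)
  results <- list()
  summary_rows <- list()
  for (label in names(conditions)) {
    spec <- conditions[[label]]
    rates <- multiplex_rates(cb, spec$symbols, spec$weights)
    res <- .decode_engine(
      rate_matrix = matrix(rates, nrow = n_trials, ncol = length(rates),
                           byrow = TRUE),
      codebook = cb,
      log_prior = matrix(log(prior), nrow = 1L),
      threshold = threshold, dt = dt, max_time = max_time
    )
    results[[label]] <- data.frame(
      condition = label, trial = seq_len(n_trials),
      decode_time = res$decode_time, decoded_symbol = res$decoded,
      correct = res$decoded == target_symbol, censored = res$censored)
    summary_rows[[label]] <- data.frame(
      condition = label, mean_time = mean(res$decode_time),
      se_time = stats::sd(res$decode_time) / sqrt(n_trials),
      accuracy = mean(res$decoded == target_symbol), n = n_trials)
  }
  list(results = do.call(rbind, unname(results)),
       summary = do.call(rbind, unname(summary_rows)))
}
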