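# Vectorized decoding engine.
#
# Decodes M transmissions bin-synchronously: all still-active trials draw one
# bin of Poisson counts, fold it into their log posterior, and trials whose
# posterior entropy has reached the threshold are retired. Per-trial rate
# vectors and per-trial priors are supported (needed for practice curves,
# where every decoder carries its own prior). Equivalent trial-by-trial to
# the streaming decoder; the batching only changes the RNG interleaving.

.decode_engine <- function(rate_matrix, codebook, log_prior, threshold, dt,
                           max_time, keep_history = FALSE) {
  M <- nrow(rate_matrix)
  n <- ncol(rate_matrix)
  if (n != n_neurons(codebook)) {
    stop("rate vectors do not match the codebook's neuron count", call. = FALSE)
  }
  K <- n_symbols(codebook)
  terms <- .decoder_terms(codebook)
  if (nrow(log_prior) == 1L && M > 1L) {
    log_prior <- matrix(log_prior, nrow = M, ncol = K, byrow = TRUE)
  }
  prior <- exp(log_prior)

  decode_time <- numeric(M)
  decoded <- integer(M)
  stop_entropy <- numeric(M)
  total_spikes <- numeric(M)
  censored <- logical(M)
  posterior <- matrix(NA_real_, M, K)
  E <- matrix(0, M, n)
  log_post <- log_prior

  # immediate decode when the prior is already confident enough
  H0 <- .row_entropy_bits(prior)
  instant <- H0 <= threshold
  if (any(instant)) {
    decoded[instant] <- max.col(prior[instant, , drop = FALSE],
                                ties.method = "first")
    stop_entropy[instant] <- H0[instant]
    posterior[instant, ] <- prior[instant, , drop = FALSE]
  }
  idx_active <- which(!instant)

  n_bins <- floor(max_time / dt + 1e-9)
  if (n_bins < 1L) stop("`max_time` must be >= dt", call. = FALSE)
  history <- if (keep_history) vector("list", 0L) else NULL
  entropy_traj <- if (keep_history) numeric(0L) else NULL

  bin <- 0L
  while (length(idx_active) > 0L && bin < n_bins) {
    bin <- bin + 1L
    mA <- length(idx_active)
    lam <- rate_matrix[idx_active, , drop = FALSE] * dt
    C <- matrix(stats::rpois(mA * n, lambda = as.vector(lam)), mA, n)
    E[idx_active, ] <- E[idx_active, , drop = FALSE] + C

    inc <- C %*% terms$log_lambda_t
    inc <- sweep(inc, 2L, dt * terms$sum_rates, "-")
    if (any(terms$any_zero)) {
      inc[(C %*% terms$zero_t) > 0] <- -Inf
    }
    lp <- log_post[idx_active, , drop = FALSE] + inc
    mx <- apply(lp, 1L, max)
    if (any(mx == -Inf)) {
      stop("degenerate evidence: observed counts are impossible under every ",
           "symbol in the codebook", call. = FALSE)
    }
    lp <- lp - mx
    log_post[idx_active, ] <- lp
    P <- exp(lp)
    P <- P / rowSums(P)
    H <- .row_entropy_bits(P)

    if (keep_history) {
      history[[bin]] <- C[1L, ]
      entropy_traj <- c(entropy_traj, H[[1L]])
    }

    hit <- H <= threshold
    if (any(hit)) {
      ids <- idx_active[hit]
      decode_time[ids] <- bin * dt
      decoded[ids] <- max.col(P[hit, , drop = FALSE], ties.method = "first")
      stop_entropy[ids] <- H[hit]
      posterior[ids, ] <- P[hit, , drop = FALSE]
      total_spikes[ids] <- rowSums(E[ids, , drop = FALSE])
      idx_active <- idx_active[!hit]
    }
  }

  if (length(idx_active) > 0L) {  # horizon reached without crossing
    P <- .normalize_rows(log_post[idx_active, , drop = FALSE])
    decode_time[idx_active] <- n_bins * dt
    decoded[idx_active] <- max.col(P, ties.method = "first")
    stop_entropy[idx_active] <- .row_entropy_bits(P)
    posterior[idx_active, ] <- P
    total_spikes[idx_active] <- rowSums(E[idx_active, , drop = FALSE])
    censored[idx_active] <- TRUE
  }

  ratio <- posterior / prior
  lg <- posterior * log2(ratio)
  lg[posterior == 0] <- 0
  info_gain <- rowSums(lg)

  out <- list(decode_time = decode_time, decoded = decoded,
              stop_entropy = stop_entropy, info_gain = info_gain,
              total_spikes = total_spikes, censored = censored,
              posterior = posterior)
  if (keep_history) {
    out$history <- do.call(rbind, history)
    out$entropy_trajectory <- entropy_traj
  }
  out
}

#' Transmission schedule
#'
#' Bundles the parameters of a simulated block of transmissions: the true
#' source distribution `p(s)` over symbols (which may differ from the
#' decoder's subjective prior `q(s)`), the number of trials, the decoder's
#' prior, the entropy stopping threshold, and timing.
#'
#' @param source_probabilities probability vector `p(s)` the environment draws
#'   symbols from.
#' @param n_trials number of transmissions (>= 1).
#' @param decoder_prior the decoder's prior `q(s)`; default uniform.
#' @param threshold entropy stopping threshold in bits.
#' @param dt bin width in seconds, default 0.1.
#' @param max_time censoring horizon in seconds, default 60.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return a list of class `transmission_schedule`.
#' @export
transmission_schedule <- function(source_probabilities, n_trials,
                                  decoder_prior = NULL, threshold,
                                  dt = 0.1, max_time = 60, seed = NULL) {
  validate_prior(source_probabilities)
  n_trials <- stop_if_not_count(n_trials, "n_trials", min = 1L)
  if (is.null(decoder_prior)) {
    decoder_prior <- uniform_prior(length(source_probabilities))
  }
  validate_prior(decoder_prior, K = length(source_probabilities))
  stop_if_not_scalar(threshold, "threshold", min = 0)
  if (threshold <= 0) stop("`threshold` must be > 0 bits", call. = FALSE)
  structure(
    list(source_probabilities = source_probabilities, n_trials = n_trials,
         decoder_prior = decoder_prior, threshold = threshold, dt = dt,
         max_time = max_time, seed = seed),
    class = "transmission_schedule"
  )
}

#' Run a batch of independent transmissions
#'
#' Draws `n_trials` true symbols from the schedule's source distribution,
#' transmits each with the codebook's total rates, and decodes with the
#' schedule's prior and threshold. Bit-identical output under the same seed.
#'
#' @param schedule a [transmission_schedule()].
#' @param codebook a `codebook` whose K matches the schedule.
#' @return data.frame with one row per trial: `trial`, `true_symbol`,
#'   `decoded_symbol`, `correct`, `decode_time`, `stop_entropy`, `info_gain`,
#'   `total_spikes`, `censored`.
#' @export
run_batch <- function(schedule, codebook) {
  stopifnot(inherits(schedule, "transmission_schedule"))
  K <- n_symbols(codebook)
  validate_prior(schedule$source_probabilities, K = K)
  if (!is.null(schedule$seed)) set.seed(schedule$seed)
  true_sym <- sample.int(K, schedule$n_trials, replace = TRUE,
                         prob = schedule$source_probabilities)
  lambda <- codebook$noise_rate + codebook$signal_rates
  res <- .decode_engine(
    rate_matrix = lambda[true_sym, , drop = FALSE],
    codebook = codebook,
    log_prior = matrix(log(schedule$decoder_prior), nrow = 1L),
    threshold = schedule$threshold, dt = schedule$dt,
    max_time = schedule$max_time
  )
  data.frame(
    trial = seq_len(schedule$n_trials),
    true_symbol = true_sym,
    decoded_symbol = res$decoded,
    correct = res$decoded == true_sym,
    decode_time = res$decode_time,
    stop_entropy = res$stop_entropy,
    info_gain = res$info_gain,
    total_spikes = res$total_spikes,
    censored = res$censored
  )
}

#' Bin-averaged posterior entropy trajectory
#'
#' Runs `n_trials` transmissions of each requested symbol to a fixed horizon
#' (no stopping) and returns the posterior entropy averaged across trials at
#' each time step — the expected information-accumulation curve. The mean
#' entropy decreases over time with diminishing marginal drops.
#'
#' @param codebook a `codebook`.
#' @param prior decoder prior; default uniform.
#' @param symbols symbols to transmit (recycled over trials); default all.
#' @param n_trials trials per curve.
#' @param horizon duration in seconds to track.
#' @param dt bin width in seconds.
#' @param seed optional integer seed.
#' @return data.frame with columns `t` and `mean_entropy` (bits).
#' @export
mean_entropy_trajectory <- function(codebook, prior = NULL, symbols = NULL,
                                    n_trials = 1000, horizon = 3, dt = 0.1,
                                    seed = NULL) {
  K <- n_symbols(codebook)
  if (is.null(prior)) prior <- uniform_prior(K)
  validate_prior(prior, K = K)
  if (is.null(symbols)) symbols <- seq_len(K)
  if (!is.null(seed)) set.seed(seed)
  n_trials <- stop_if_not_count(n_trials, "n_trials", min = 1L)
  true_sym <- rep_len(symbols, n_trials)
  lambda <- codebook$noise_rate + codebook$signal_rates
  rate_matrix <- lambda[true_sym, , drop = FALSE]
  terms <- .decoder_terms(codebook)
  n <- n_neurons(codebook)
  n_bins <- floor(horizon / dt + 1e-9)
  log_post <- matrix(log(prior), nrow = n_trials, ncol = K, byrow = TRUE)
  mean_H <- numeric(n_bins)
  for (bin in seq_len(n_bins)) {
    C <- matrix(stats::rpois(n_trials * n, lambda = as.vector(rate_matrix * dt)),
                n_trials, n)
    inc <- C %*% terms$log_lambda_t
    inc <- sweep(inc, 2L, dt * terms$sum_rates, "-")
    if (any(terms$any_zero)) inc[(C %*% terms$zero_t) > 0] <- -Inf
    log_post <- log_post + inc
    log_post <- log_post - apply(log_post, 1L, max)
    P <- exp(log_post)
    P <- P / rowSums(P)
    mean_H[bin] <- mean(.row_entropy_bits(P))
  }
  data.frame(t = seq_len(n_bins) * dt, mean_entropy = mean_H)
}
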