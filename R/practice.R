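# Practice effects: the decoder tracks observed symbol frequencies as a
# Dirichlet belief whose mode supplies the decoding prior. As observations
# accumulate the prior approaches the true source distribution, transmitted
# symbols carry less subjective surprisal, and decoding times fall — in
# aggregate, as a power law of practice.

#' Dirichlet belief over symbol frequencies
#'
#' @param alphas length-K vector of positive concentration parameters. Large
#'   equal alphas encode a strong belief in a uniform source.
#' @param increment amount added to a symbol's alpha per observation
#'   (default 1; values below 1 slow the apparent learning rate).
#' @return an object of class `dirichlet_state`.
#' @export
dirichlet_state <- function(alphas, increment = 1) {
  if (!is.numeric(alphas) || length(alphas) < 2L || anyNA(alphas) ||
      any(alphas <= 0)) {
    stop("alphas must be a length >= 2 vector of positive values", call. = FALSE)
  }
  stop_if_not_scalar(increment, "increment", min = 0)
  if (increment <= 0) stop("`increment` must be > 0", call. = FALSE)
  structure(list(alphas = as.double(alphas), increment = as.double(increment)),
            class = "dirichlet_state")
}

#' @export
print.dirichlet_state <- function(x, ...) {
  cat(sprintf("<dirichlet_state> K = %d, increment = %g\n",
              length(x$alphas), x$increment))
  print(x$alphas)
  invisible(x)
}

#' Record one observed transmission
#'
#' Adds the state's increment to the observed symbol's concentration
#' parameter, leaving the others untouched.
#'
#' @param state a [dirichlet_state()].
#' @param symbol 1-based index of the observed symbol.
#' @return the updated `dirichlet_state`.
#' @export
dirichlet_observe <- function(state, symbol) {
  stopifnot(inherits(state, "dirichlet_state"))
  symbol <- stop_if_not_count(symbol, "symbol", min = 1L)
  if (symbol > length(state$alphas)) {
    stop("symbol index out of range", call. = FALSE)
  }
  state$alphas[symbol] <- state$alphas[symbol] + state$increment
  state
}

#' Decoding prior from a Dirichlet belief
#'
#' Uses the mode of the Dirichlet, `(alpha - 1) / (sum(alpha) - K)`, when all
#' alphas exceed 1 (the mode lies in the simplex interior). When any alpha is
#' <= 1 the mode sits on the boundary, so the mean `alpha / sum(alpha)` is
#' used instead; with the large starting alphas typical of practice runs the
#' two are nearly identical.
#'
#' @param state a [dirichlet_state()].
#' @return probability vector over symbols.
#' @export
dirichlet_prior <- function(state) {
  stopifnot(inherits(state, "dirichlet_state"))
  a <- state$alphas
  if (all(a > 1)) {
    p <- (a - 1) / (sum(a) - length(a))
  } else {
    p <- a / sum(a)
  }
  p / sum(p)
}

# rowwise mode-or-mean prior for a matrix of alpha vectors (decoders x K)
.dirichlet_prior_rows <- function(alphas) {
  K <- ncol(alphas)
  p <- alphas / rowSums(alphas)
  interior <- rowSums(alphas > 1) == K
  if (any(interior)) {
    a <- alphas[interior, , drop = FALSE] - 1
    p[interior, ] <- a / rowSums(a)
  }
  p
}

#' Simulate a practice curve
#'
#' Reproduces the practice protocol: a population of naive decoders, each
#' holding its own Dirichlet belief (all alphas equal to `alpha0`), receives
#' blocks of transmissions whose symbols are drawn from the true source
#' distribution. After each block every decoder increments its alphas by its
#' observed symbol counts and re-derives its prior from the Dirichlet mode;
#' decoding performance is then measured with `eval_trials` transmissions per
#' decoder under the frozen prior (evaluation trials do not update the
#' belief). The grand-mean decoding time per block, plotted against
#' cumulative practice trials, is linear in log-log coordinates — the power
#' law of practice.
#'
#' @param codebook a `codebook`.
#' @param source_probabilities true symbol distribution `p(s)`.
#' @param n_decoders number of independent decoders to aggregate over.
#' @param block_size practice transmissions per decoder per block.
#' @param n_blocks number of practice blocks; 0 gives only the initial
#'   (naive-prior) point.
#' @param eval_trials evaluation transmissions per decoder per block.
#' @param threshold entropy stopping threshold in bits.
#' @param alpha0 initial concentration of every alpha (default 1000, a strong
#'   uniform belief).
#' @param increment alpha increment per observed transmission (default 1).
#' @param dt bin width in seconds.
#' @param max_time censoring horizon in seconds.
#' @param seed optional integer seed.
#' @return data.frame with one row per evaluation point: `cumulative_trials`,
#'   `mean_decode_time`, `sd_decode_time`, `n_decoders`, `n_eval`.
#' @export
practice_schedule <- function(codebook, source_probabilities, n_decoders,
                              block_size, n_blocks, eval_trials, threshold,
                              alpha0 = 1000, increment = 1, dt = 0.1,
                              max_time = 60, seed = NULL) {
  K <- n_symbols(codebook)
  validate_prior(source_probabilities, K = K)
  n_decoders <- stop_if_not_count(n_decoders, "n_decoders", min = 1L)
  if (n_blocks > 0L) block_size <- stop_if_not_count(block_size, "block_size")
  eval_trials <- stop_if_not_count(eval_trials, "eval_trials", min = 1L)
  if (!is.null(seed)) set.seed(seed)

  lambda <- codebook$noise_rate + codebook$signal_rates
  alphas <- matrix(alpha0, nrow = n_decoders, ncol = K)

  eval_block <- function(priors) {
    # pool all decoders' evaluation trials into one vectorized decode
    M <- n_decoders * eval_trials
    dec_id <- rep(seq_len(n_decoders), each = eval_trials)
    true_sym <- sample.int(K, M, replace = TRUE, prob = source_probabilities)
    res <- .decode_engine(
      rate_matrix = lambda[true_sym, , drop = FALSE],
      codebook = codebook,
      log_prior = log(priors[dec_id, , drop = FALSE]),
      threshold = threshold, dt = dt, max_time = max_time
    )
    c(mean = mean(res$decode_time), sd = stats::sd(res$decode_time))
  }

  rows <- vector("list", n_blocks + 1L)
  s0 <- eval_block(.dirichlet_prior_rows(alphas))
  rows[[1L]] <- data.frame(cumulative_trials = 0, mean_decode_time = s0[["mean"]],
                           sd_decode_time = s0[["sd"]], n_decoders = n_decoders,
                           n_eval = n_decoders * eval_trials)
  if (n_blocks > 0L) {
    for (b in seq_len(n_blocks)) {
      obs <- t(stats::rmultinom(n_decoders, size = block_size,
                                prob = source_probabilities))
      alphas <- alphas + obs * increment
      s <- eval_block(.dirichlet_prior_rows(alphas))
      rows[[b + 1L]] <- data.frame(
        cumulative_trials = b * block_size,
        mean_decode_time = s[["mean"]], sd_decode_time = s[["sd"]],
        n_decoders = n_decoders, n_eval = n_decoders * eval_trials)
    }
  }
  do.call(rbind, rows)
}
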