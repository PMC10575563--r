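# Ideal-observer decoding.
#
# All likelihood arithmetic is in the log domain. For cumulative counts e at
# elapsed time t, the per-symbol log-likelihood (dropping terms constant
# across symbols: e_i * log dt and log e_i!) is
#   sum_i e_i * log(lambda_{s,i}) - t * sum_i lambda_{s,i}
# with lambda_{s,i} = noise_rate + signal_rates[s, i]. A symbol with rate 0 on
# a neuron that has fired is impossible and gets posterior exactly 0.

# precompute decoder-side quantities for a codebook
.decoder_terms <- function(codebook) {
  lambda <- codebook$noise_rate + codebook$signal_rates  # K x n
  zero <- lambda == 0
  log_lambda <- lambda
  log_lambda[!zero] <- log(lambda[!zero])
  log_lambda[zero] <- 0  # placeholder; impossible symbols masked separately
  list(lambda = lambda,
       log_lambda_t = t(log_lambda),          # n x K, for counts %*% .
       zero_t = t(zero) * 1,                  # n x K indicator
       any_zero = rowSums(zero) > 0,          # length K
       sum_rates = rowSums(lambda))           # length K
}

# unnormalized log posterior matrix (M x K) from cumulative counts (M x n)
.log_posterior_unnorm <- function(counts, elapsed, terms, log_prior) {
  ll <- counts %*% terms$log_lambda_t
  ll <- ll - outer(elapsed, terms$sum_rates)
  if (any(terms$any_zero)) {
    impossible <- (counts %*% terms$zero_t) > 0
    ll[impossible] <- -Inf
  }
  sweep(ll, 2L, log_prior, "+")
}

# normalize rows of a log-probability matrix to probabilities (max-shift)
.normalize_rows <- function(log_p) {
  m <- apply(log_p, 1L, max)
  if (any(m == -Inf)) {
    stop("degenerate evidence: observed counts are impossible under every ",
         "symbol in the codebook", call. = FALSE)
  }
  p <- exp(log_p - m)
  p / rowSums(p)
}

# rowwise entropy in bits of a probability matrix (no validation; 0 log 0 = 0)
.row_entropy_bits <- function(p) {
  plogp <- p * log2(p)
  plogp[p == 0] <- 0
  -rowSums(plogp)
}

#' Shannon entropy in bits
#'
#' `H = -sum(p * log2(p))` with the convention `0 * log 0 = 0`. The result
#' lies in `[0, log2(K)]` for a length-K probability vector.
#'
#' @param p probability vector (non-negative, summing to 1 within 1e-8).
#' @return entropy in bits.
#' @examples
#' entropy_bits(rep(0.1, 10))  # log2(10) = 3.3219...
#' @export
entropy_bits <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0)) {
    stop("p must be a vector of non-negative probabilities", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-8) {
    stop("p must sum to 1 (within 1e-8)", call. = FALSE)
  }
  .row_entropy_bits(matrix(p, nrow = 1L))[[1L]]
}

#' Information gain (KL divergence) in bits
#'
#' The decoder's information gain at decision time is the Kullback-Leibler
#' divergence from its prior to its posterior,
#' `sum(post * log2(post / prior))`, in bits. Always >= 0; equals the prior's
#' surprisal scale when the posterior is degenerate.
#'
#' @param posterior probability vector.
#' @param prior probability vector, strictly positive wherever `posterior` is
#'   positive.
#' @return KL divergence in bits.
#' @export
info_gain_bits <- function(posterior, prior) {
  validate_prior(posterior)
  validate_prior(prior, K = length(posterior))
  pos <- posterior > 0
  if (any(pos & prior == 0)) {
    stop("posterior places mass on a zero-prior symbol: divergence is infinite",
         call. = FALSE)
  }
  sum(posterior[pos] * log2(posterior[pos] / prior[pos]))
}

#' Posterior over symbols from a cumulative count record
#'
#' Bayes' rule with independent Poisson likelihoods: the posterior is
#' proportional to `prior(s) * prod_i Pois(e_i; (noise + signal[s,i]) * t)`,
#' computed in the log domain and normalized. A symbol with rate 0 on a neuron
#' that has fired receives posterior exactly 0. With zero elapsed time (no
#' evidence) the posterior equals the prior.
#'
#' @param record a [count_record()] (or a list with `counts` and
#'   `elapsed_time`).
#' @param codebook a `codebook` with n matching `length(record$counts)`.
#' @param prior probability vector over the codebook's symbols.
#' @return probability vector of length K.
#' @export
log_posterior <- function(record, codebook, prior) {
  prior <- validate_prior(prior, K = n_symbols(codebook))
  counts <- record$counts
  if (length(counts) != n_neurons(codebook)) {
    stop("count record length does not match the codebook's neuron count",
         call. = FALSE)
  }
  if (record$elapsed_time == 0 && any(counts > 0)) {
    stop("positive counts at zero elapsed time are impossible", call. = FALSE)
  }
  terms <- .decoder_terms(codebook)
  lp <- .log_posterior_unnorm(matrix(as.double(counts), nrow = 1L),
                              record$elapsed_time, terms, log(prior))
  as.vector(.normalize_rows(lp))
}

#' Streaming decoder state
#'
#' `decoder_state()` initializes the ideal observer from a prior;
#' `decoder_update()` folds in one (or more) new bins of counts. After any
#' number of updates the posterior equals [log_posterior()] applied to the
#' cumulative counts (the running tally is a sufficient statistic), which is
#' the correctness oracle for the streaming form.
#'
#' @param codebook a `codebook`.
#' @param prior probability vector over symbols.
#' @return a list of class `decoder_state` with the current `posterior()`
#'   available via [decoder_posterior()].
#' @export
decoder_state <- function(codebook, prior) {
  prior <- validate_prior(prior, K = n_symbols(codebook))
  structure(
    list(terms = .decoder_terms(codebook),
         log_prior = log(prior),
         log_post = log(prior),  # unnormalized log posterior
         counts = rep(0L, n_neurons(codebook)),
         elapsed_time = 0,
         n = n_neurons(codebook)),
    class = "decoder_state"
  )
}

#' @rdname decoder_state
#' @param state a `decoder_state`.
#' @param bin_counts integer vector of spike counts in the new bin(s).
#' @param dt elapsed seconds the counts cover.
#' @export
decoder_update <- function(state, bin_counts, dt) {
  if (length(bin_counts) != state$n) {
    stop("bin_counts length does not match the decoder's neuron count",
         call. = FALSE)
  }
  stop_if_not_scalar(dt, "dt", min = 0)
  terms <- state$terms
  c_row <- matrix(as.double(bin_counts), nrow = 1L)
  inc <- c_row %*% terms$log_lambda_t - dt * terms$sum_rates
  if (any(terms$any_zero)) {
    inc[(c_row %*% terms$zero_t) > 0] <- -Inf
  }
  state$log_post <- state$log_post + as.vector(inc)
  # max-shift to keep the unnormalized log posterior in range at large t
  finite <- is.finite(state$log_post)
  if (any(finite)) state$log_post <- state$log_post - max(state$log_post[finite])
  state$counts <- state$counts + as.integer(bin_counts)
  state$elapsed_time <- state$elapsed_time + dt
  state
}

#' @rdname decoder_state
#' @export
decoder_posterior <- function(state) {
  as.vector(.normalize_rows(matrix(state$log_post, nrow = 1L)))
}

#' Decode a single transmission
#'
#' Runs the full ideal-observer loop for one transmission: spikes are drawn
#' from `true_rates` in bins of `dt` seconds, the posterior over codebook
#' symbols is updated after each bin, and the decoder commits to the most
#' probable symbol (ties broken by lowest index) as soon as posterior entropy
#' drops to `threshold` bits or below. If the prior's entropy is already at or
#' below the threshold, the decoder answers immediately at time 0. If
#' `max_time` elapses without crossing, the trial is marked censored and the
#' current argmax is reported.
#'
#' @param true_rates length-n rate vector actually generating spikes (usually
#'   `total_rates(codebook, s)`, or a [multiplex_rates()] vector).
#' @param codebook the decoder's `codebook`.
#' @param prior probability vector over symbols.
#' @param threshold entropy stopping threshold in bits (> 0).
#' @param dt bin width in seconds, default 0.1.
#' @param max_time censoring horizon in seconds, default 60.
#' @param true_symbol 1-based index used to score correctness; `NA` leaves
#'   `correct` as `NA` (e.g. multiplexed stimuli scored externally).
#' @param keep_history if `TRUE`, attach the per-bin count matrix as attribute
#'   `"bin_counts"` and the entropy trajectory as `"entropy_trajectory"`.
#' @return one-row data.frame with columns `true_symbol`, `decoded_symbol`,
#'   `correct`, `decode_time`, `stop_entropy`, `info_gain`, `total_spikes`,
#'   `censored`; attribute `"posterior"` holds the posterior at stop.
#' @export
decode <- function(true_rates, codebook, prior, threshold, dt = 0.1,
                   max_time = 60, true_symbol = NA_integer_,
                   keep_history = FALSE) {
  prior <- validate_prior(prior, K = n_symbols(codebook))
  if (length(true_rates) != n_neurons(codebook)) {
    stop("true_rates length does not match the codebook", call. = FALSE)
  }
  stop_if_not_scalar(threshold, "threshold", min = 0)
  if (threshold <= 0) stop("`threshold` must be > 0 bits", call. = FALSE)

  res <- .decode_engine(
    rate_matrix = matrix(true_rates, nrow = 1L),
    codebook = codebook,
    log_prior = matrix(log(prior), nrow = 1L),
    threshold = threshold, dt = dt, max_time = max_time,
    keep_history = keep_history
  )
  out <- data.frame(
    true_symbol = as.integer(true_symbol),
    decoded_symbol = res$decoded,
    correct = if (is.na(true_symbol)) NA else res$decoded == true_symbol,
    decode_time = res$decode_time,
    stop_entropy = res$stop_entropy,
    info_gain = res$info_gain,
    total_spikes = res$total_spikes,
    censored = res$censored
  )
  attr(out, "posterior") <- res$posterior[1L, ]
  if (keep_history) {
    attr(out, "bin_counts") <- res$history
    attr(out, "entropy_trajectory") <- res$entropy_trajectory
  }
  out
}
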