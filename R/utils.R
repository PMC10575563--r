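# internal validation helpers

stop_if_not_scalar <- function(x, name, min = -Inf, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x)) || x < min) {
    stop(sprintf("`%s` must be a single finite numeric value >= %s", name, min),
         call. = FALSE)
  }
  invisible(x)
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

#' Validate a prior belief vector
#'
#' A prior belief is a plain numeric probability vector over the `K` symbols of
#' a codebook: non-negative entries summing to 1 (within 1e-9).
#'
#' @param prior numeric vector of symbol probabilities.
#' @param K expected length (number of symbols), or `NULL` to skip the check.
#' @return the prior, invisibly, if valid; otherwise an error.
#' @export
validate_prior <- function(prior, K = NULL) {
  if (!is.numeric(prior) || anyNA(prior) || any(prior < 0)) {
    stop("prior must be a numeric vector of non-negative probabilities",
         call. = FALSE)
  }
  if (abs(sum(prior) - 1) > 1e-9) {
    stop("prior probabilities must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (!is.null(K) && length(prior) != K) {
    stop(sprintf("prior has length %d but the codebook has %d symbols",
                 length(prior), K), call. = FALSE)
  }
  invisible(prior)
}

#' Uniform prior over K symbols
#'
#' @param K number of symbols.
#' @return numeric vector of length `K`, each entry `1/K`.
#' @export
uniform_prior <- function(K) {
  K <- stop_if_not_count(K, "K", min = 1L)
  rep(1 / K, K)
}
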