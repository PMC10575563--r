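#' Construct a codebook
#'
#' A codebook defines the channel: it maps each of `K` symbols to an n-length
#' vector of signal firing rates (spikes/second) and stores the baseline noise
#' rate shared by all neurons. During a transmission of symbol `s`, neuron `i`
#' fires as a Poisson process with total rate `noise_rate + signal_rates[s, i]`.
#'
#' @param signal_rates K x n numeric matrix of non-negative signal rates; row
#'   `s` is the rate vector added to the baseline when symbol `s` is sent.
#' @param noise_rate single non-negative baseline rate (spikes/second) common
#'   to every neuron regardless of the symbol.
#' @param symbols optional character vector of K symbol labels; defaults to
#'   `"s1" ... "sK"`. Symbols are referenced by 1-based index throughout;
#'   labels are for reporting only.
#' @return an object of class `codebook` with fields `symbols`,
#'   `signal_rates`, and `noise_rate`.
#' @examples
#' cb <- codebook(rbind(c(0, 4, 0), c(4, 0, 0), c(0, 0, 4)), noise_rate = 6)
#' total_rates(cb, 1)  # [6, 10, 6]
#' @export
codebook <- function(signal_rates, noise_rate, symbols = NULL) {
  signal_rates <- as.matrix(signal_rates)
  storage.mode(signal_rates) <- "double"
  K <- nrow(signal_rates)
  n <- ncol(signal_rates)
  if (K < 2L) stop("a codebook needs at least 2 symbols (K >= 2)", call. = FALSE)
  if (n < 1L) stop("a codebook needs at least 1 neuron (n >= 1)", call. = FALSE)
  if (anyNA(signal_rates) || any(!is.finite(signal_rates))) {
    stop("signal rates must be finite", call. = FALSE)
  }
  if (any(signal_rates < 0)) stop("signal rates must be >= 0", call. = FALSE)
  stop_if_not_scalar(noise_rate, "noise_rate", min = 0)
  if (is.null(symbols)) symbols <- paste0("s", seq_len(K))
  symbols <- as.character(symbols)
  if (length(symbols) != K) {
    stop("`symbols` must have one label per row of `signal_rates`", call. = FALSE)
  }
  rownames(signal_rates) <- symbols
  cb <- structure(
    list(symbols = symbols,
         signal_rates = signal_rates,
         noise_rate = as.double(noise_rate)),
    class = "codebook"
  )
  if (anyDuplicated.matrix(signal_rates) > 0L) {
    warning("codebook contains duplicate signal-rate rows; ",
            "the decoder cannot distinguish those symbols beyond chance",
            call. = FALSE)
  }
  cb
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook> %d symbols x %d neurons, noise rate %g spikes/s\n",
              n_symbols(x), n_neurons(x), x$noise_rate))
  rates <- x$signal_rates
  if (nrow(rates) > 8L) {
    print(utils::head(rates, 8L))
    cat(sprintf("... (%d more rows)\n", nrow(rates) - 8L))
  } else {
    print(rates)
  }
  invisible(x)
}

#' @rdname codebook
#' @param x a `codebook`.
#' @export
n_symbols <- function(x) nrow(x$signal_rates)

#' @rdname codebook
#' @export
n_neurons <- function(x) ncol(x$signal_rates)

#' One-hot codebook
#'
#' Builds the sparse encoding used throughout the simulated experiments: each
#' symbol elevates exactly one neuron's rate by `signal_power` above the
#' shared baseline. For example with K = n = 3, `signal_power = 4` and
#' `noise_rate = 6`, the total rate vector for symbol 1 is `[6, 10, 6]`.
#'
#' @param K number of symbols (>= 2).
#' @param n number of neurons; must satisfy `n >= K` so each symbol gets its
#'   own neuron.
#' @param signal_power rate increment (spikes/second) on the symbol's neuron.
#' @param noise_rate shared baseline rate (spikes/second).
#' @return a `codebook`.
#' @export
make_onehot_codebook <- function(K, n = K, signal_power, noise_rate) {
  K <- stop_if_not_count(K, "K", min = 2L)
  n <- stop_if_not_count(n, "n", min = 1L)
  if (K > n) {
    stop("one-hot coding requires n >= K (one neuron per symbol)",
         call. = FALSE)
  }
  stop_if_not_scalar(signal_power, "signal_power", min = 0)
  stop_if_not_scalar(noise_rate, "noise_rate", min = 0)
  if (signal_power == 0) {
    warning("signal_power = 0: all symbols are identical and undecodable ",
            "beyond chance", call. = FALSE)
  }
  rates <- matrix(0, nrow = K, ncol = n)
  rates[cbind(seq_len(K), seq_len(K))] <- signal_power
  suppressWarnings(cb <- codebook(rates, noise_rate))
  cb
}

#' Total firing rates for a symbol
#'
#' @param codebook a `codebook`.
#' @param symbol 1-based symbol index.
#' @return length-n numeric vector `noise_rate + signal_rates[symbol, ]`.
#' @export
total_rates <- function(codebook, symbol) {
  symbol <- stop_if_not_count(symbol, "symbol", min = 1L)
  if (symbol > n_symbols(codebook)) {
    stop(sprintf("symbol index %d out of range (K = %d)", symbol,
                 n_symbols(codebook)), call. = FALSE)
  }
  unname(codebook$noise_rate + codebook$signal_rates[symbol, ])
}

#' Multiplexed (superimposed) rate vector
#'
#' Builds the rate vector for the simultaneous transmission of several symbols
#' as a weighted sum of their signal rows plus the baseline:
#' `noise_rate + sum_j weights[j] * signal_rates[symbols[j], ]`.
#' This is the generating process for Stroop-style congruent / incongruent
#' stimuli: fractional additions of a second symbol's rate vector onto the
#' target's. With a 2-symbol one-hot codebook at signal 12 and noise 12,
#' weights `c(1, 0.25)` on symbols `c(1, 1)` give `[27, 12]` (congruent, +3 on
#' the target's own neuron) and weights `c(1, 5/12)` on symbols `c(1, 2)` give
#' `[24, 17]` (incongruent, +5 on the competing neuron).
#'
#' @param codebook a `codebook`.
#' @param symbols integer vector of 1-based symbol indices (>= 1 entry).
#' @param weights non-negative finite weights, one per symbol; default all 1.
#' @return length-n numeric rate vector.
#' @export
multiplex_rates <- function(codebook, symbols, weights = rep(1, length(symbols))) {
  if (length(symbols) < 1L) {
    stop("multiplex spec needs at least one component", call. = FALSE)
  }
  symbols <- as.integer(symbols)
  if (anyNA(symbols) || any(symbols < 1L) || any(symbols > n_symbols(codebook))) {
    stop("multiplex symbol indices out of range", call. = FALSE)
  }
  if (length(weights) != length(symbols) || anyNA(weights) ||
      any(!is.finite(weights)) || any(weights < 0)) {
    stop("multiplex weights must be non-negative finite, one per symbol",
         call. = FALSE)
  }
  sig <- colSums(codebook$signal_rates[symbols, , drop = FALSE] * weights)
  unname(codebook$noise_rate + sig)
}

#' Random codebook
#'
#' Each signal rate is drawn i.i.d. uniform on `[0, max_rate]` — the randomly
#' initialized starting point of codebook learning, and the baseline the
#' learned codebooks are compared against.
#'
#' @param K number of symbols.
#' @param n number of neurons.
#' @param max_rate maximum firing rate (the power constraint), > 0 except for
#'   the degenerate all-zero limit which is permitted with a warning.
#' @param noise_rate shared baseline rate; default 0.
#' @return a `codebook`.
#' @export
random_codebook <- function(K, n, max_rate, noise_rate = 0) {
  K <- stop_if_not_count(K, "K", min = 2L)
  n <- stop_if_not_count(n, "n", min = 1L)
  stop_if_not_scalar(max_rate, "max_rate", min = 0)
  if (max_rate == 0) {
    warning("max_rate = 0 gives an all-zero (undecodable) codebook",
            call. = FALSE)
  }
  rates <- matrix(stats::runif(K * n, min = 0, max = max_rate), nrow = K)
  suppressWarnings(codebook(rates, noise_rate))
}
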