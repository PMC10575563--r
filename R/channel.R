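#' Poisson spike counts for one time bin
#'
#' Draws one count per neuron from independent Poisson distributions with mean
#' `rates * dt`. Uses R's global RNG stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param rates non-negative firing-rate vector (spikes/second).
#' @param dt bin width in seconds (> 0).
#' @return integer vector of spike counts, one per neuron.
#' @export
generate_bin_counts <- function(rates, dt) {
  if (!is.numeric(rates) || anyNA(rates) || any(!is.finite(rates)) ||
      any(rates < 0)) {
    stop("rates must be finite and >= 0", call. = FALSE)
  }
  stop_if_not_scalar(dt, "dt", min = 0)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  stats::rpois(length(rates), lambda = rates * dt)
}

#' Stream a transmission as cumulative count records
#'
#' Simulates a transmission of duration `max_time`: every `dt` seconds the
#' cumulative spike tally of each neuron is recorded. The cumulative counts at
#' elapsed time `t` are the decoder's sufficient statistic; per-bin counts are
#' returned as well for spike-level inspection.
#'
#' @param rates non-negative firing-rate vector (spikes/second).
#' @param dt bin width in seconds, default 0.1.
#' @param max_time total duration in seconds (>= dt).
#' @return a list with `times` (elapsed seconds, multiples of `dt`),
#'   `bin_counts` (bins x n matrix of per-bin counts) and `cumulative`
#'   (bins x n matrix of running tallies).
#' @export
stream_transmission <- function(rates, dt = 0.1, max_time) {
  stop_if_not_scalar(max_time, "max_time", min = 0)
  if (max_time < dt) stop("`max_time` must be >= dt", call. = FALSE)
  n_bins <- floor(max_time / dt + 1e-9)
  n <- length(rates)
  bin_counts <- matrix(
    generate_bin_counts(rep(rates, n_bins), dt),
    nrow = n_bins, ncol = n, byrow = TRUE
  )
  cumulative <- apply(bin_counts, 2L, cumsum)
  if (n_bins == 1L) cumulative <- matrix(cumulative, nrow = 1L)
  list(times = seq_len(n_bins) * dt,
       bin_counts = bin_counts,
       cumulative = cumulative)
}

#' Write a spike log CSV
#'
#' Debug output for a streamed transmission: one row per (bin, neuron) with
#' the per-bin spike count.
#'
#' @param stream result of [stream_transmission()].
#' @param path output CSV path.
#' @param trial trial identifier recorded in the first column.
#' @return `path`, invisibly.
#' @export
write_spike_log <- function(stream, path, trial = 1L) {
  n_bins <- nrow(stream$bin_counts)
  n <- ncol(stream$bin_counts)
  log_df <- data.frame(
    trial = trial,
    bin = rep(seq_len(n_bins), times = n),
    neuron = rep(seq_len(n), each = n_bins),
    count = as.vector(stream$bin_counts)
  )
  log_df <- log_df[order(log_df$bin, log_df$neuron), ]
  utils::write.csv(log_df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cumulative count record
#'
#' Bundles the decoder's sufficient statistic: cumulative per-neuron spike
#' counts and the elapsed time they cover.
#'
#' @param counts non-negative integer vector of cumulative counts per neuron.
#' @param elapsed_time elapsed seconds since transmission onset (>= 0).
#' @return a list of class `count_record`.
#' @export
count_record <- function(counts, elapsed_time) {
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  stop_if_not_scalar(elapsed_time, "elapsed_time", min = 0)
  structure(list(counts = as.integer(counts),
                 elapsed_time = as.double(elapsed_time)),
            class = "count_record")
}
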