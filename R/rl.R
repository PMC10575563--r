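# Codebook learning by reinforcement. The agent is both transmitter and
# decoder: each episode it observes a symbol (the state), emits an n-length
# vector of firing rates (a continuous action, capped at max_rate — a power
# constraint), the transmission is decoded with the agent's current mean
# codebook, and the reward combines decoding accuracy, decoding time, and
# the number of spikes emitted. The learner is a Gaussian-policy REINFORCE:
# states are discrete, so the policy is a table of mean rate vectors. Three
# standard variance-reduction/conditioning devices make it converge on one
# CPU: antithetic (mirrored) exploration pairs, whose reward difference
# cancels both the baseline term and the clipping bias at the zero-rate
# boundary; action repeats, which average away Poisson spike-count noise in
# the reward; and Adam-style per-coordinate step normalization, which keeps
# the descent velocity uniform across population sizes. Learned codes
# concentrate signal power on few neurons: spike cost prunes uninformative
# neurons while time and accuracy costs preserve discriminability.

#' Codebook learning task specification
#'
#' @param K number of messages to encode (>= 2).
#' @param n_neurons population size available to the encoder.
#' @param max_rate firing-rate cap per neuron (spikes/second); the power
#'   constraint.
#' @param reward_weights named vector with elements `accuracy`, `time`,
#'   `spike`: reward = `accuracy * correct - time * decode_time -
#'   spike * total_spikes`.
#' @param training_budget total episodes (single transmissions) of training.
#' @param noise_rate baseline channel noise during training and evaluation.
#' @param threshold entropy stopping threshold during decoding (bits).
#' @param dt bin width in seconds.
#' @param max_time censoring horizon per episode in seconds.
#' @param batch_size actions (sampled symbol/rate-vector pairs) per policy
#'   update; drawn as `batch_size / 2` antithetic pairs.
#' @param action_repeats transmissions decoded per action; the action's
#'   reward is their mean. Averaging tames the Poisson spike-count noise in
#'   the reward without changing its expectation.
#' @param sigma exploration noise s.d. (spikes/second).
#' @param learning_rate Adam step size in rate units (spikes/second per
#'   update); decays linearly to a tenth over training.
#' @param seed optional integer seed.
#' @return a list of class `codebook_learning_task`.
#' @export
codebook_learning_task <- function(K, n_neurons, max_rate = 60,
                                   reward_weights = c(accuracy = 1, time = 1,
                                                      spike = 0.05),
                                   training_budget = 480000, noise_rate = 10,
                                   threshold = 0.5, dt = 0.1, max_time = 10,
                                   batch_size = 32, action_repeats = 8,
                                   sigma = 6, learning_rate = 0.6,
                                   seed = NULL) {
  K <- stop_if_not_count(K, "K", min = 2L)
  n_neurons <- stop_if_not_count(n_neurons, "n_neurons", min = 1L)
  stop_if_not_scalar(max_rate, "max_rate", min = 0)
  if (max_rate <= 0) stop("`max_rate` must be > 0", call. = FALSE)
  needed <- c("accuracy", "time", "spike")
  if (!all(needed %in% names(reward_weights)) ||
      any(!is.finite(reward_weights[needed]))) {
    stop("reward_weights needs finite elements named accuracy, time, spike",
         call. = FALSE)
  }
  training_budget <- stop_if_not_count(training_budget, "training_budget")
  structure(
    list(K = K, n_neurons = n_neurons, max_rate = max_rate,
         reward_weights = reward_weights[needed],
         training_budget = training_budget, noise_rate = noise_rate,
         threshold = threshold, dt = dt, max_time = max_time,
         batch_size = stop_if_not_count(batch_size, "batch_size"),
         action_repeats = stop_if_not_count(action_repeats, "action_repeats"),
         sigma = sigma, learning_rate = learning_rate, seed = seed),
    class = "codebook_learning_task"
  )
}

#' Reward for one decoding episode
#'
#' `accuracy_weight * correct - time_weight * decode_time -
#'  spike_weight * spike_count`. Monotone increasing in correctness,
#' decreasing in time and in spikes.
#'
#' @param result a transmission result row (needs `correct` and
#'   `decode_time`).
#' @param spike_count total spikes across neurons at stop time.
#' @param weights named vector with `accuracy`, `time`, `spike` elements.
#' @return scalar reward.
#' @export
episode_reward <- function(result, spike_count,
                           weights = c(accuracy = 1, time = 1, spike = 0.01)) {
  weights[["accuracy"]] * as.numeric(result$correct) -
    weights[["time"]] * result$decode_time -
    weights[["spike"]] * spike_count
}

#' Learn a codebook by policy optimization
#'
#' Trains the Gaussian policy described in [codebook_learning_task()] and
#' returns the learned codebook (the policy's mean rate vectors, clipped to
#' `[0, max_rate]`) together with a per-update training log. The learned
#' mapping is available to the decoder during decoding: each episode is
#' decoded against the current mean codebook.
#'
#' @param task a [codebook_learning_task()].
#' @return list with `codebook` (a `codebook` with the task's noise rate) and
#'   `log` (data.frame: `update`, `episodes`, `mean_reward`, `mean_time`,
#'   `accuracy`, `mean_spikes`).
#' @export
learn_codebook <- function(task) {
  stopifnot(inherits(task, "codebook_learning_task"))
  if (!is.null(task$seed)) set.seed(task$seed)
  K <- task$K
  n <- task$n_neurons
  w <- task$reward_weights
  mu <- matrix(stats::runif(K * n, 0, task$max_rate), K, n)
  P <- max(2L, task$batch_size %/% 2L)  # antithetic pairs per update
  m <- task$action_repeats
  n_updates <- max(1L, ceiling(task$training_budget / (2L * P * m)))
  log_rows <- vector("list", n_updates)
  adam_m1 <- matrix(0, K, n)
  adam_m2 <- matrix(0, K, n)
  b1 <- 0.9
  b2 <- 0.999

  for (u in seq_len(n_updates)) {
    lr <- task$learning_rate *
      (1 - 0.9 * (u - 1) / max(1L, n_updates - 1L))
    sym <- sample.int(K, P, replace = TRUE)
    eps <- matrix(stats::rnorm(P * n, sd = task$sigma), P, n)
    a_plus <- pmin(pmax(mu[sym, , drop = FALSE] + eps, 0), task$max_rate)
    a_minus <- pmin(pmax(mu[sym, , drop = FALSE] - eps, 0), task$max_rate)
    actions <- rbind(a_plus, a_minus)
    if (any(!is.finite(actions))) {
      stop("training failure: non-finite policy outputs", call. = FALSE)
    }
    cb <- suppressWarnings(codebook(mu, task$noise_rate))
    rep_idx <- rep(seq_len(2L * P), each = m)
    sym_all <- c(sym, sym)
    res <- .decode_engine(
      rate_matrix = task$noise_rate + actions[rep_idx, , drop = FALSE],
      codebook = cb,
      log_prior = matrix(log(uniform_prior(K)), nrow = 1L),
      threshold = task$threshold, dt = task$dt, max_time = task$max_time
    )
    ep_correct <- res$decoded == sym_all[rep_idx]
    ep_rewards <- w[["accuracy"]] * ep_correct -
      w[["time"]] * res$decode_time - w[["spike"]] * res$total_spikes
    # per-action mean reward over its repeated transmissions
    rewards <- as.vector(tapply(ep_rewards, rep_idx, mean))

    # antithetic REINFORCE gradient: reward difference of each mirrored pair
    dr <- (rewards[seq_len(P)] - rewards[P + seq_len(P)]) / 2
    grad <- matrix(0, K, n)
    counts <- tabulate(sym, nbins = K)
    scaled <- dr * eps / task$sigma^2
    for (j in seq_len(P)) {
      grad[sym[j], ] <- grad[sym[j], ] + scaled[j, ]
    }
    upd <- counts > 0
    grad[upd, ] <- grad[upd, , drop = FALSE] / counts[upd]

    adam_m1 <- b1 * adam_m1 + (1 - b1) * grad
    adam_m2 <- b2 * adam_m2 + (1 - b2) * grad^2
    step <- (adam_m1 / (1 - b1^u)) /
      (sqrt(adam_m2 / (1 - b2^u)) + 1e-8)
    mu <- pmin(pmax(mu + lr * step, 0), task$max_rate)

    log_rows[[u]] <- data.frame(
      update = u, episodes = u * 2L * P * m, mean_reward = mean(rewards),
      mean_time = mean(res$decode_time), accuracy = mean(ep_correct),
      mean_spikes = mean(res$total_spikes))
  }
  list(codebook = suppressWarnings(codebook(mu, task$noise_rate)),
       log = do.call(rbind, log_rows))
}

#' Sparsity of a set of codebooks
#'
#' Thresholds each signal rate at `threshold_fraction * max_rate` and reports
#' the fraction of 'active' neurons per message, averaged over messages and
#' then over codebooks.
#'
#' @param codebooks a list of `codebook` objects (>= 1).
#' @param max_rate the rate cap the threshold is relative to.
#' @param threshold_fraction activation threshold as a fraction of `max_rate`
#'   (default 0.05).
#' @return list of class `sparsity_report` with `n_neurons`,
#'   `mean_active_fraction`, `threshold_fraction`, `per_codebook`.
#' @export
sparsity_report <- function(codebooks, max_rate, threshold_fraction = 0.05) {
  if (!is.list(codebooks) || length(codebooks) == 0L) {
    stop("`codebooks` must be a non-empty list", call. = FALSE)
  }
  if (inherits(codebooks, "codebook")) codebooks <- list(codebooks)
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("`threshold_fraction` must lie in (0, 1)", call. = FALSE)
  }
  thr <- threshold_fraction * max_rate
  fracs <- vapply(codebooks, function(cb) {
    mean(rowMeans(cb$signal_rates > thr))
  }, numeric(1))
  structure(
    list(n_neurons = n_neurons(codebooks[[1L]]),
         mean_active_fraction = mean(fracs),
         threshold_fraction = threshold_fraction,
         per_codebook = fracs),
    class = "sparsity_report"
  )
}

#' @export
print.sparsity_report <- function(x, ...) {
  cat(sprintf(
    "<sparsity_report> n = %d neurons: %.1f%% active (> %.0f%% of max rate)\n",
    x$n_neurons, 100 * x$mean_active_fraction, 100 * x$threshold_fraction))
  invisible(x)
}

#' Sparsity of learned codes versus population size
#'
#' Trains replicate codebooks at each population size `n` and reports the
#' mean active fraction (at the 5% activation threshold) per `n`, with a
#' log-linear fit. Learned codes use a smaller proportion of the available
#' neurons as the population grows; the active fraction falls roughly
#' linearly with log n.
#'
#' @param n_values population sizes to train at.
#' @param K number of messages (default 12).
#' @param replicates codebooks trained per population size.
#' @param training_budget episodes per training run.
#' @param threshold_fraction activation threshold fraction (default 0.05).
#' @param ... further arguments to [codebook_learning_task()] (e.g.
#'   `max_rate`, `noise_rate`, `reward_weights`).
#' @param seed optional integer seed.
#' @return list with `table` (columns `n_neurons`, `mean_active_fraction`,
#'   `sd_active_fraction`, `replicates`), `fit` (log-linear fit of active
#'   fraction on n) and `codebooks` (list of lists of learned codebooks).
#' @export
sparsity_scaling_experiment <- function(n_values, K = 12, replicates = 8,
                                        training_budget = 480000,
                                        threshold_fraction = 0.05, ...,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  all_cbs <- list()
  rows <- lapply(n_values, function(n) {
    cbs <- lapply(seq_len(replicates), function(r) {
      task <- codebook_learning_task(K = K, n_neurons = n,
                                     training_budget = training_budget, ...)
      learn_codebook(task)$codebook
    })
    all_cbs[[as.character(n)]] <<- cbs
    task <- codebook_learning_task(K = K, n_neurons = n, ...)
    rep_frac <- sparsity_report(cbs, max_rate = task$max_rate,
                                threshold_fraction = threshold_fraction)
    data.frame(n_neurons = n,
               mean_active_fraction = rep_frac$mean_active_fraction,
               sd_active_fraction = stats::sd(rep_frac$per_codebook),
               replicates = replicates)
  })
  tab <- do.call(rbind, rows)
  fit <- if (nrow(tab) >= 3L) {
    fit_curve(tab$n_neurons, tab$mean_active_fraction, "log-linear")
  } else NULL
  list(table = tab, fit = fit, codebooks = all_cbs)
}

#' Evaluate a codebook's decoding performance
#'
#' Decodes `n_trials` uniform transmissions with the given codebook and
#' returns mean decoding time, accuracy and mean spike count — the evaluation
#' used to compare learned codebooks against random-rate baselines.
#'
#' @param codebook a `codebook`.
#' @param n_trials evaluation transmissions.
#' @param threshold entropy stopping threshold (bits).
#' @param dt bin width in seconds.
#' @param max_time censoring horizon in seconds.
#' @param seed optional integer seed.
#' @return one-row data.frame: `mean_time`, `se_time`, `accuracy`,
#'   `mean_spikes`, `n`.
#' @export
evaluate_codebook <- function(codebook, n_trials = 1000, threshold = 0.5,
                              dt = 0.1, max_time = 10, seed = NULL) {
  sched <- transmission_schedule(uniform_prior(n_symbols(codebook)), n_trials,
                                 threshold = threshold, dt = dt,
                                 max_time = max_time, seed = seed)
  res <- run_batch(sched, codebook)
  data.frame(mean_time = mean(res$decode_time),
             se_time = stats::sd(res$decode_time) / sqrt(n_trials),
             accuracy = mean(res$correct),
             mean_spikes = mean(res$total_spikes),
             n = n_trials)
}
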