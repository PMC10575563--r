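test_that("curve fitting recovers exact and noisy generating parameters", {
  x <- c(2, 4, 8, 16, 32)
  f <- fit_curve(x, 2 + 3 * log2(x), "log-linear")
  expect_equal(f$slope, 3)
  expect_equal(f$intercept, 2)
  expect_equal(f$r_squared, 1)

  g <- fit_curve(x, x, "log-log")
  expect_equal(g$slope, 1)
  expect_equal(g$r_squared, 1)

  set.seed(18)
  y <- 1.5 + 0.8 * log2(x) + stats::rnorm(5, sd = 0.05)
  h <- fit_curve(x, y, "log-linear")
  lmfit <- stats::lm(y ~ log2(x))
  se_slope <- summary(lmfit)$coefficients[2, 2]
  expect_lt(abs(h$slope - 0.8), 3 * se_slope)

  expect_error(fit_curve(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_curve(rep(2, 4), 1:4, "linear"), "constant")
  expect_error(fit_curve(c(-1, 1, 2), 1:3, "log-linear"), "positive")
})

test_that("batches are tidy, sized, and bit-reproducible under a seed", {
  cb <- make_onehot_codebook(10, 10, signal_power = 15, noise_rate = 10)
  one <- run_batch(transmission_schedule(uniform_prior(10), 1,
                                         threshold = 0.5, seed = 1), cb)
  expect_identical(nrow(one), 1L)
  expect_named(one, c("trial", "true_symbol", "decoded_symbol", "correct",
                      "decode_time", "stop_entropy", "info_gain",
                      "total_spikes", "censored"))

  sched <- transmission_schedule(uniform_prior(10), 300, threshold = 0.5,
                                 seed = 123)
  expect_identical(run_batch(sched, cb), run_batch(sched, cb))
})

test_that("a two-symbol task at a 1-bit threshold decodes instantly", {
  ex <- hick_experiment(K_values = 2, noise = 10, signal = 18, threshold = 1,
                        n_trials = 50, seed = 2)
  expect_identical(ex$table$mean_time, 0)
  expect_error(hick_experiment(K_values = c(1, 4)), ">= 2")
})

test_that("raising signal power speeds decoding at every set size", {
  lo <- hick_experiment(K_values = c(4, 8), signal = 9, n_trials = 600,
                        seed = 19)$table
  hi <- hick_experiment(K_values = c(4, 8), signal = 18, n_trials = 600,
                        seed = 20)$table
  expect_true(all(hi$mean_time < lo$mean_time))
})

test_that("a uniform matched source yields symmetric times and gains", {
  ex <- hyman_experiment(source_probabilities = uniform_prior(4),
                         threshold = 0.7, noise = 10, signal = 12,
                         n_trials = 8000, seed = 22)
  tab <- ex$table
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lt(abs(tab$mean_time[i] - tab$mean_time[j]),
              3 * sqrt(tab$se_time[i]^2 + tab$se_time[j]^2))
  }
  expect_lt(diff(range(tab$mean_info_gain)), 0.1)
})

test_that("symbols believed rare are decoded more slowly", {
  # threshold below the prior's 0.469-bit entropy so decoding needs evidence
  ex <- hyman_experiment(source_probabilities = c(0.5, 0.5),
                         decoder_prior = c(0.9, 0.1), threshold = 0.3,
                         noise = 10, signal = 12, n_trials = 6000, seed = 23)
  tab <- ex$table
  expect_gt(tab$mean_time[2] - tab$mean_time[1],
            2 * sqrt(tab$se_time[1]^2 + tab$se_time[2]^2))
  expect_gt(tab$mean_info_gain[2], tab$mean_info_gain[1])
})

test_that("prior sweep rejects zero-mass priors on transmitted symbols", {
  expect_error(
    prior_sweep_experiment(priors = list(bad = c(0.5, 0.5, 0, 0, 0)),
                           n_trials = 10, seed = 1),
    "zero mass")
})

test_that("decoding at a threshold above the prior entropy is chance", {
  tab <- sat_experiment(thresholds = 3.5, signal_powers = 18, noise = 8,
                        K = 10, n_trials = 2000, seed = 24)
  expect_identical(tab$mean_time, 0)
  se <- sqrt(0.1 * 0.9 / 2000)
  expect_lt(abs(tab$accuracy - 0.1), 3 * se)
})

test_that("zero-weight multiplex additions leave the channel unchanged", {
  conds <- list(
    a = list(symbols = 1, weights = 1),
    b = list(symbols = c(1, 1), weights = c(1, 0)),
    c = list(symbols = c(1, 2), weights = c(1, 0))
  )
  ex <- stroop_experiment(conditions = conds, n_trials = 4000, seed = 25)
  s <- ex$summary
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(abs(s$mean_time[i] - s$mean_time[j]),
              3 * sqrt(s$se_time[i]^2 + s$se_time[j]^2))
  }
})
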