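test_that("episode reward combines accuracy, time and spike costs", {
  res_ok <- data.frame(correct = TRUE, decode_time = 0)
  res_bad <- data.frame(correct = FALSE, decode_time = 2)

  expect_equal(episode_reward(res_ok, 100,
                              c(accuracy = 0, time = 0, spike = 0)), 0)
  expect_equal(episode_reward(res_ok, 0,
                              c(accuracy = 1, time = 1, spike = 1)), 1)
  # direct arithmetic: 0 - 1 * 2.0 - 0.01 * 40
  expect_equal(episode_reward(res_bad, 40,
                              c(accuracy = 5, time = 1, spike = 0.01)),
               -2.0 - 0.4)

  # monotone in each argument
  w <- c(accuracy = 1, time = 1, spike = 0.01)
  expect_gt(episode_reward(res_ok, 10, w),
            episode_reward(data.frame(correct = FALSE, decode_time = 0), 10, w))
  expect_gt(episode_reward(res_ok, 10, w),
            episode_reward(data.frame(correct = TRUE, decode_time = 1), 10, w))
  expect_gt(episode_reward(res_ok, 10, w), episode_reward(res_ok, 20, w))
})

test_that("sparsity reports match analytic activation fractions", {
  onehot <- make_onehot_codebook(4, 8, signal_power = 50, noise_rate = 0)
  expect_equal(sparsity_report(list(onehot), 60)$mean_active_fraction, 1 / 8)

  flat <- suppressWarnings(codebook(matrix(0, 3, 5), 1))
  expect_equal(sparsity_report(list(flat), 60)$mean_active_fraction, 0)

  # uniform rates exceed the 5% threshold with probability 0.95
  set.seed(26)
  rnd <- random_codebook(20, 200, max_rate = 60)
  sp <- sparsity_report(list(rnd), 60, threshold_fraction = 0.05)
  se <- sqrt(0.95 * 0.05 / 4000)
  expect_lt(abs(sp$mean_active_fraction - 0.95), 3 * se)

  expect_error(sparsity_report(list(), 60), "non-empty")
  expect_error(sparsity_report(list(onehot), 60, threshold_fraction = 1.2),
               "\\(0, 1\\)")
})

test_that("tiny-budget training still returns a valid, reproducible codebook", {
  task <- codebook_learning_task(K = 2, n_neurons = 2, training_budget = 256,
                                 seed = 27)
  fit <- learn_codebook(task)
  expect_s3_class(fit$codebook, "codebook")
  expect_true(all(fit$codebook$signal_rates >= 0 &
                    fit$codebook$signal_rates <= task$max_rate))
  expect_true(all(is.finite(fit$log$mean_reward)))

  fit2 <- learn_codebook(task)
  expect_identical(fit$log, fit2$log)
  expect_identical(fit$codebook$signal_rates, fit2$codebook$signal_rates)
})

test_that("a briefly trained codebook decodes above chance", {
  task <- codebook_learning_task(K = 4, n_neurons = 4,
                                 training_budget = 30000, seed = 28)
  fit <- learn_codebook(task)
  ev <- evaluate_codebook(fit$codebook, n_trials = 800, threshold = 0.5,
                          seed = 29)
  se <- sqrt(0.25 * 0.75 / 800)
  expect_gt(ev$accuracy, 0.25 + 2 * se)
  # power constraint respected throughout
  expect_true(all(fit$codebook$signal_rates <= task$max_rate))
})

test_that("learned codes use fewer neurons than random ones and shrink with n", {
  ex <- sparsity_scaling_experiment(n_values = c(4, 16, 64), K = 12,
                                    replicates = 2,
                                    training_budget = 320000, seed = 30)
  tab <- ex$table
  expect_identical(tab$n_neurons, c(4, 16, 64))
  expect_true(all(diff(tab$mean_active_fraction) < 0))
  expect_lt(ex$fit$slope, 0)

  # learned vs random at n = 64: far sparser than the ~0.95 uniform tail
  set.seed(31)
  rnd <- lapply(1:4, function(i) random_codebook(12, 64, 60))
  sp_rnd <- sparsity_report(rnd, 60)
  learned_frac <- tab$mean_active_fraction[tab$n_neurons == 64]
  se_rnd <- stats::sd(sp_rnd$per_codebook) / 2
  expect_lt(learned_frac, sp_rnd$mean_active_fraction - 2 * se_rnd)
})
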