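test_that("entropy matches closed forms and stays within bounds", {
  expect_equal(entropy_bits(rep(0.1, 10)), log2(10), tolerance = 1e-12)
  expect_identical(entropy_bits(c(1, 0, 0)), 0)
  expect_equal(entropy_bits(c(0.5, 0.5)), 1)
  expect_error(entropy_bits(c(0.5, 0.4)), "sum to 1")
  expect_error(entropy_bits(c(-0.5, 1.5)), "non-negative")

  set.seed(9)
  for (i in 1:50) {
    K <- sample(2:12, 1)
    p <- stats::rgamma(K, 1)
    p <- p / sum(p)
    h <- entropy_bits(p)
    expect_gte(h, 0)
    expect_lte(h, log2(K) + 1e-12)
  }
})

test_that("information gain is the prior-to-posterior KL divergence", {
  p <- rep(0.1, 10)
  expect_equal(info_gain_bits(p, p), 0)
  expect_equal(info_gain_bits(c(1, rep(0, 9)), p), log2(10))
  # direct arithmetic: 0.25 log2(1/3) + 0.75 log2(3)
  expect_equal(info_gain_bits(c(0.25, 0.75), c(0.75, 0.25)),
               0.25 * log2(0.25 / 0.75) + 0.75 * log2(0.75 / 0.25))
  expect_error(info_gain_bits(c(0.5, 0.5), c(1, 0)), "zero-prior")
})

test_that("posterior matches a brute-force Poisson-product oracle", {
  cb <- codebook(rbind(c(4, 0), c(0, 4)), noise_rate = 6)
  rec <- count_record(c(10, 6), elapsed_time = 1)
  post <- log_posterior(rec, cb, c(0.5, 0.5))
  # oracle: explicit Poisson pmfs with factorials, then normalize
  lik <- c(prod(stats::dpois(c(10, 6), c(10, 6))),
           prod(stats::dpois(c(10, 6), c(6, 10))))
  expect_equal(post, lik / sum(lik), tolerance = 1e-12)
  # the stated ratio: (10/6)^10 * (6/10)^6
  expect_equal(post[1] / post[2], (10 / 6)^10 * (6 / 10)^6, tolerance = 1e-9)

  # non-uniform prior folds in multiplicatively
  prior <- c(0.9, 0.1)
  post2 <- log_posterior(rec, cb, prior)
  expect_equal(post2[1] / post2[2], (lik[1] * 0.9) / (lik[2] * 0.1),
               tolerance = 1e-9)
})

test_that("posterior degenerates correctly with and without evidence", {
  cb <- example_codebook()
  prior <- c(0.2, 0.3, 0.5)
  # no evidence: posterior equals prior
  expect_equal(log_posterior(count_record(c(0, 0, 0), 0), cb, prior), prior)
  # symmetric codebook, uniform prior, equal counts: uniform posterior
  expect_equal(log_posterior(count_record(c(4, 4, 4), 1), cb, uniform_prior(3)),
               rep(1 / 3, 3))
  # zero-rate neuron with a spike rules a symbol out exactly
  zn <- make_onehot_codebook(2, 2, signal_power = 5, noise_rate = 0)
  post <- log_posterior(count_record(c(3, 0), 0.5), zn, uniform_prior(2))
  expect_identical(post, c(1, 0))
  # counts impossible under every symbol raise a degeneracy error
  cb3 <- codebook(rbind(c(4, 0, 0), c(0, 4, 0)), noise_rate = 0)
  expect_error(log_posterior(count_record(c(0, 0, 2), 1), cb3,
                             uniform_prior(2)),
               "degenerate")
  expect_error(log_posterior(count_record(c(1, 1, 1), 0), cb3,
                             uniform_prior(2)),
               "zero elapsed")
})

test_that("streaming updates match the batch posterior (sufficiency)", {
  set.seed(11)
  for (i in 1:100) {
    K <- sample(2:5, 1)
    n <- sample(2:5, 1)
    cb <- suppressWarnings(
      codebook(matrix(stats::runif(K * n, 0, 20), K, n),
               noise_rate = stats::runif(1, 0.5, 10)))
    prior <- stats::rgamma(K, 1) + 0.05
    prior <- prior / sum(prior)
    dt <- 0.1
    n_bins <- sample(1:50, 1)
    lam <- total_rates(cb, sample(K, 1))
    state <- decoder_state(cb, prior)
    cum <- rep(0L, n)
    for (b in seq_len(n_bins)) {
      counts <- generate_bin_counts(lam, dt)
      cum <- cum + counts
      state <- decoder_update(state, counts, dt)
    }
    batch <- log_posterior(count_record(cum, n_bins * dt), cb, prior)
    inc <- decoder_posterior(state)
    expect_equal(inc, batch, tolerance = 1e-10)
    expect_lt(abs(sum(inc) - 1), 1e-9)
  }

  # zero updates: posterior is the prior
  cb <- example_codebook()
  st <- decoder_state(cb, c(0.2, 0.3, 0.5))
  expect_equal(decoder_posterior(st), c(0.2, 0.3, 0.5))

  # splitting a stream in two halves gives the same posterior as one pass
  set.seed(12)
  lam <- total_rates(cb, 2)
  c1 <- generate_bin_counts(lam * 10, 0.1)  # 10 bins' worth at once
  c2 <- generate_bin_counts(lam * 10, 0.1)
  one_pass <- decoder_update(decoder_state(cb, uniform_prior(3)),
                             c1 + c2, 2)
  two_pass <- decoder_update(decoder_update(decoder_state(cb, uniform_prior(3)),
                                            c1, 1), c2, 1)
  expect_equal(decoder_posterior(one_pass), decoder_posterior(two_pass),
               tolerance = 1e-12)
})

test_that("decoding stops at the entropy threshold with the argmax symbol", {
  cb <- make_onehot_codebook(10, 10, signal_power = 15, noise_rate = 10)
  # confident prior already below threshold: immediate decode at time 0
  prior <- c(0.99, rep(0.01 / 9, 9))
  stopifnot(entropy_bits(prior) < 0.2)
  set.seed(3)
  res <- decode(total_rates(cb, 2), cb, prior, threshold = 0.2,
                true_symbol = 2)
  expect_identical(res$decode_time, 0)
  expect_identical(res$decoded_symbol, 1L)
  expect_false(res$correct)
  expect_identical(res$info_gain, 0)

  # normal decode: stop entropy at or below threshold, time a multiple of dt
  set.seed(4)
  res <- decode(total_rates(cb, 5), cb, uniform_prior(10), threshold = 0.5,
                true_symbol = 5)
  expect_lte(res$stop_entropy, 0.5)
  expect_false(res$censored)
  expect_equal(res$decode_time / 0.1, round(res$decode_time / 0.1),
               tolerance = 1e-9)
  expect_gte(res$info_gain, 0)
  post <- attr(res, "posterior")
  expect_equal(sum(post), 1, tolerance = 1e-9)
  expect_identical(res$decoded_symbol, which.max(post))

  # unreachable threshold on an uninformative channel: censored at max_time
  flat <- suppressWarnings(make_onehot_codebook(2, 2, 0, noise_rate = 5))
  set.seed(6)
  res <- decode(total_rates(flat, 1), flat, uniform_prior(2), threshold = 0.1,
                dt = 0.1, max_time = 1, true_symbol = 1)
  expect_true(res$censored)
  expect_equal(res$decode_time, 1)

  # exact posterior tie: lowest index wins (duplicate-row codebook)
  set.seed(8)
  res <- decode(total_rates(flat, 2), flat, c(0.5, 0.5), threshold = 1.1,
                true_symbol = 2)
  expect_identical(res$decoded_symbol, 1L)
})

test_that("with zero noise the first spike decides (one-hot limit)", {
  cb <- make_onehot_codebook(4, 4, signal_power = 6, noise_rate = 0)
  set.seed(21)
  for (i in 1:100) {
    s <- sample(4, 1)
    res <- decode(total_rates(cb, s), cb, uniform_prior(4), threshold = 0.5,
                  dt = 0.1, max_time = 30, true_symbol = s,
                  keep_history = TRUE)
    hist <- attr(res, "bin_counts")
    first_spike_bin <- which(rowSums(hist) > 0)[1]
    expect_equal(res$decode_time, first_spike_bin * 0.1)
    expect_identical(res$decoded_symbol, s)
    expect_identical(res$stop_entropy, 0)
  }
})

test_that("accuracy rises as the entropy threshold is lowered", {
  cb <- make_onehot_codebook(5, 5, signal_power = 8, noise_rate = 8)
  acc <- vapply(c(1.6, 0.8, 0.2), function(thr) {
    sched <- transmission_schedule(uniform_prior(5), 800, threshold = thr,
                                   seed = 300 + round(10 * thr))
    mean(run_batch(sched, cb)$correct)
  }, numeric(1))
  se <- sqrt(acc * (1 - acc) / 800)
  # monotone within 2 SE at each adjacent pair
  expect_gt(acc[2] - acc[1], -2 * sqrt(se[1]^2 + se[2]^2))
  expect_gt(acc[3] - acc[2], -2 * sqrt(se[2]^2 + se[3]^2))
  expect_gt(acc[3], acc[1])
})
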