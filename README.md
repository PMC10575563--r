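# ratechannel

Simulation of information transmission over a neural rate code, with an
ideal-observer decoder whose decoding times reproduce classic regularities of
human response times.

## The problem

Human response times follow robust empirical laws: they are right-skewed,
they grow with the logarithm of the number of response alternatives
(Hick-Hyman), they fall as a power law with practice, they trade speed for
accuracy, and they slow under conflicting stimulus attributes (Stroop). This
package implements a single generative mechanism that produces all of these
patterns: the time it takes a Bayesian ideal observer to decode a symbol
encoded as firing rates in an array of Poisson processes.

It is aimed at computational cognitive scientists and students of
information-theoretic models of behavior who want a fast, reproducible
simulator of the mechanism, not a fit to any particular dataset.

## The model

A **codebook** C maps each of K symbols to a signal-rate vector
rho_s = (rho_s1, ..., rho_sn) over n neurons; all neurons share a baseline
noise rate rho_b. While symbol s is transmitted, neuron i fires as a Poisson
process with rate lambda_si = rho_b + rho_si. The decoder knows C and rho_b,
keeps a running spike tally e_t per neuron (updated every dt = 0.1 s), and
computes the posterior

    q(s | e_t)  ∝  q(s) * prod_i Pois(e_it ; lambda_si * t)

from its prior belief q(s), which may differ from the true source
distribution p(s). It tracks the posterior entropy H(Q_t | e_t) =
−sum_s q(s|e_t) log2 q(s|e_t) and commits to the most probable symbol the
moment H falls to a threshold (in bits). Decoding time is the model's
response time:

- more symbols → higher initial entropy → log-linear set-size effect;
- symbols believed rare need more evidence → time is linear in the
  information gained, D_KL(q(s|e_t) || q(s));
- tracking symbol frequencies as a Dirichlet belief whose mode supplies q(s)
  turns trial-by-trial practice into a log-log (power-law) speedup;
- the entropy threshold is the speed-accuracy dial;
- superimposing (multiplexing) rate vectors yields congruence and conflict
  effects.

A reinforcement-learning module (`learn_codebook()`) learns codebooks that
minimize decoding time and spike cost under a maximum-rate power constraint,
and `sparsity_scaling_experiment()` shows the learned codes use a shrinking
fraction of the population as more neurons become available.

## Worked example

```r
library(ratechannel)

# 10 symbols, one-hot code, signal 15 spikes/s over a 10 spikes/s baseline
cb <- make_onehot_codebook(10, 10, signal_power = 15, noise_rate = 10)
sched <- transmission_schedule(uniform_prior(10), n_trials = 2000,
                               threshold = 0.5, seed = 42)
res <- run_batch(sched, cb)
round(c(mean_time_s = mean(res$decode_time),
        accuracy   = mean(res$correct),
        skewness   = mean(((res$decode_time - mean(res$decode_time)) /
                             sd(res$decode_time))^3)), 4)
#> mean_time_s    accuracy    skewness
#>      0.5582      0.9665      1.0902
```

Mean decoding time is about 0.56 s, 97% of transmissions are decoded
correctly at the 0.5-bit threshold, and the time distribution is
right-skewed (sample skewness ≈ 1.1), as in human data.

The set-size law:

```r
hick <- hick_experiment(seed = 7)
hick$table
#>    K mean_time se_time    n
#> 1  2     0.224 0.00315 2000
#> 2  4     0.305 0.00402 2000
#> 3  6     0.357 0.00430 2000
#> 4  8     0.393 0.00442 2000
#> 5 10     0.420 0.00481 2000
hick$fit
#> <fit_summary> log-linear: intercept 0.1381, slope 0.0847, R^2 0.9997
```

Mean decoding time grows almost perfectly linearly in log2(K): each extra
bit of set-size entropy costs about 85 ms at these channel parameters.

A command-line interface covering every experiment is installed at
`inst/scripts/ratechannel`, e.g.

```sh
Rscript inst/scripts/ratechannel hick --noise 10 --signal 18 \
    --threshold-bits 0.5 --n-trials 2000 --seed 7 --out hick.csv
```

writes the per-K table to `hick.csv` and the fit plus full parameter set to
`hick.csv.json`.

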