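---
title: "Decoding times in a Poisson rate code: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding times in a Poisson rate code: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ratechannel)
```

## The model

The package simulates the transmission of discrete symbols over a noisy
channel built from an array of `n` Poisson processes ("neurons"). A codebook
`C` assigns each symbol `s` of `K` a signal-rate vector
`rho_s = (rho_s1, ..., rho_sn)` in spikes/second; a baseline noise rate
`rho_b` is common to every neuron. During a transmission of `s`, neuron `i`
fires with rate `lambda_si = rho_b + rho_si`, independently across neurons
and over time.

The decoder is an ideal observer. It knows `C` and `rho_b`, it knows when
the transmission began, and it has perfect memory: its sufficient statistic
is the cumulative spike tally `e_t = (e_1t, ..., e_nt)` at elapsed time `t`.
Its belief about the transmitted symbol is the Bayes posterior

    q(s | e_t)  proportional to  q(s) * prod_i Pois(e_it; lambda_si * t)

where `q(s)` is its subjective prior, which may differ from the true source
distribution `p(s)`. The decoder tracks the posterior's Shannon entropy in
bits, `H = -sum_s q(s|e_t) log2 q(s|e_t)`, and commits to the most probable
symbol at the first time step where `H` is at or below a fixed threshold.
Decoding time — the model's response time — is that elapsed time; accuracy
is whether the argmax symbol equals the transmitted one; the information
gained is the KL divergence from prior to posterior at the stop,
`D_KL(q(s|e_t) || q(s))` in bits.

Two conventions deserve note. First, entropy is implemented with the
standard negative sum, so that it is non-negative and decreases toward the
threshold as evidence accumulates. Second, the stopping comparison is
inclusive (`H <= threshold`); at the 0.1 s bin resolution an exclusive
comparison is observationally indistinguishable.

## Parameters

| parameter | units | typical value | role |
|---|---|---|---|
| `K` | symbols | 2–10 | codebook size; uniform initial entropy `log2 K` |
| `n` | neurons | `>= K` for one-hot codes | population size |
| `signal_power` | spikes/s | 8–20 | per-symbol rate elevation |
| `noise_rate` (`rho_b`) | spikes/s | 8–12 | shared baseline; makes decoding nontrivial and times skewed |
| `threshold` | bits | 0.1–2.5 | decision caution; the speed-accuracy dial |
| `dt` | s | 0.1 | update interval; smaller values only refine time resolution |
| `max_time` | s | 60 | censoring horizon (see below) |

With zero baseline noise a one-hot code is decoded by its first spike — the
posterior collapses to certainty because every other symbol has likelihood
zero — and decoding times become exponential rather than right-skewed
unimodal. The baseline is therefore essential to the model's behavioral
realism, not a nuisance parameter.

## Numerical choices

* All likelihood arithmetic is in the log domain. Terms constant across
  symbols (`e_i log dt`, `log e_i!`) are dropped before normalization, and a
  max-shift is applied at every update so the unnormalized log posterior
  never under- or overflows even at long elapsed times.
* A symbol whose rate is exactly zero on a neuron that has spiked receives
  posterior exactly 0 (not a small number). If every symbol is ruled out —
  possible only when some neuron has rate zero under all symbols yet spiked,
  which cannot happen for counts generated from the codebook itself — a
  degenerate-evidence error is raised rather than returning garbage.
* Argmax ties are broken toward the lowest symbol index. Ties occur only in
  measure-zero situations or with duplicate codebook rows (permitted, but
  flagged with a warning at construction).
* If the prior's entropy is already at or below the threshold the decoder
  answers at time 0 with the prior's argmax. This convention is what makes
  very lax thresholds produce instant, chance-level decodes at the fast end
  of the speed-accuracy curve.
* Decoding runs have a `max_time` horizon (default 60 s). A trial that has
  not crossed the threshold by then is returned with `censored = TRUE` and
  the current argmax, rather than looping forever on an uninformative
  channel.
* Decoding is simulated by drawing Poisson bin counts directly; explicit
  spike times are never needed because the cumulative count is a sufficient
  statistic. The streaming update (`decoder_update()`) is tested to agree
  with the batch posterior to 1e-10, which licenses the vectorized engine
  used by every experiment: all trials of a batch advance bin-synchronously
  and retire as they cross the threshold.
* All experiment functions consume one seeded RNG stream and are
  bit-reproducible under a fixed seed. Trials in a vectorized batch
  interleave their draws; this changes no distribution, only the mapping
  from seed to individual trials.

## The experiment protocols

`run_batch()` draws true symbols from `p(s)` and decodes each transmission.
On top of it:

* `hick_experiment()` sweeps codebook size with a uniform prior (defaults:
  noise 10, signal 18, threshold 0.5 bits, K in {2, 4, 6, 8, 10}) and fits
  mean time against `log2 K`. The exact K grid is a package default; any
  set of at least three sizes supports the fit.
* `hyman_experiment()` transmits a five-symbol source with probabilities
  proportional to `0.5^(1, 2, 5, 4, 5)`, renormalized, at threshold 0.7,
  noise 10, signal 12, with the decoder's prior matched to the source, and
  relates per-symbol mean information gain to mean time. The default
  exponent sequence is non-monotone in its middle entries;
  `halving_source_probs(1:5)` gives the strictly geometric variant. Neither
  variant changes the qualitative result, and the package asserts nothing
  about which is preferable.
* `prior_sweep_experiment()` decodes the same source under uniform,
  approximate and exact priors. The default approximate prior
  `(0.360, 0.228, 0.168, 0.065, 0.032)` sums to 0.853 and is renormalized
  to a valid probability vector before use.
* `sat_experiment()` sweeps the entropy threshold (0.2–2.5 bits) at two
  signal powers (18, 20) over noise 8, tracing speed-accuracy curves.
* `stroop_experiment()` transmits multiplexed rate vectors through an
  unmodified two-symbol codebook (signal 12, noise 12, threshold 0.1). The
  congruent condition adds a 0.25-weighted copy of the target's own row
  (+3 spikes/s on its neuron); the incongruent condition adds a
  5/12-weighted copy of the competitor's row (+5 spikes/s on the competing
  neuron). Representing the additions as weights on codebook rows, rather
  than hard-coded vectors, lets the mechanism generalize beyond the
  two-symbol example; the weights are free parameters of the stimulus, not
  of the model.

Symbols are 1-based indices throughout, with arbitrary string labels for
reporting.

## Practice

`practice_schedule()` tracks task statistics as a Dirichlet belief: one
concentration parameter per symbol, all starting at `alpha0` (default 1000,
a strong belief in a uniform source), incremented by 1 per observed
transmission. The decoding prior is the Dirichlet mode
`(alpha - 1) / (sum(alpha) - K)` whenever all alphas exceed 1; on the
boundary the mode is undefined and the mean `alpha / sum(alpha)` is used
instead. At the large alphas of the practice protocol the two are nearly
identical, so the fallback is a numerical guard, not a modeling change.

Each block draws its practice symbols from the true source (a multinomial
per decoder), updates every decoder's alphas, re-derives the priors, and
then measures decoding time with a batch of evaluation transmissions under
the frozen prior. Evaluation transmissions do not update the belief; the
protocol freezes the prior within a measurement block by construction, and
whether the original measurement trials also updated the belief is
immaterial at these alpha magnitudes. Aggregating over many decoders
mirrors the fact that the power law describes aggregate behavior.

## Learning a codebook

`learn_codebook()` treats encoding as a reinforcement-learning problem: the
state is the symbol to transmit, the action is an n-length rate vector
capped at `max_rate` (a power constraint), and the reward of an episode
(one transmission decoded with the agent's current mean codebook, which the
decoder knows) is

    accuracy_weight * correct - time_weight * decode_time - spike_weight * spikes

with defaults (1, 1, 0.05): a correct decode is worth one unit, a second of
decoding costs one unit, and a spike costs 0.05. The spike weight is set so
that, at the rate scales involved (tens of spikes per transmission), the
spike term is comparable to the accuracy term — strong enough to prune
uninformative neurons, weak enough that discriminability survives. The
weights, like every training hyperparameter, are documented package
defaults.

Because the states are discrete the policy is simply a `K x n` table of
mean rate vectors with Gaussian exploration noise (sd 6 spikes/s). Three
standard devices make plain REINFORCE converge on one CPU:

* **antithetic pairs** — each update evaluates mirrored actions
  `mu + eps` and `mu - eps`; the gradient uses their reward difference,
  which cancels the baseline term and, importantly, the bias that clipping
  at the zero-rate boundary would otherwise induce (without it, near-zero
  rates are systematically pushed back up and the learned codes stop
  getting sparser with population size);
* **action repeats** — each action's reward is averaged over 8
  transmissions, taming Poisson spike-count noise;
* **Adam-style step normalization** (step size 0.6 spikes/s per update,
  decaying linearly to a tenth) — keeps the descent velocity uniform across
  coordinates and population sizes, which would otherwise differ by orders
  of magnitude in gradient scale.

Training decodes at threshold 0.5 bits with a 10 s episode horizon over a
baseline noise of 10 spikes/s, consistent with the other experiments. The
default budget is 480,000 transmissions, a few seconds of CPU; the
comparison baseline is the random codebook the policy is initialized from
(i.i.d. uniform rates on `[0, max_rate]`).

`sparsity_report()` thresholds signal rates at 5% of `max_rate` and reports
the fraction of "active" neurons per message, averaged over messages and
then codebooks; `sparsity_scaling_experiment()` repeats training across
population sizes. The full-scale scan (n from 2 to 2048, 8 replicates)
is hours of CPU; the package's tests use n in {4, 16, 64} with 2
replicates, which preserves the direction of the trend.

## Problem sizes

Tests and the acceptance script run reduced Monte-Carlo scales chosen for
statistical power on the qualitative claims: 1,200–2,000 transmissions per
decoding-time distribution, 2,000 per set size, 20,000–50,000 for the
surprisal and prior-sweep protocols, 25 decoders x 1,000 evaluation
transmissions per practice point with 12 blocks of 6,250 practice trials
(the same 75,000-trial range as the full protocol, in fewer, wider blocks
whose Dirichlet arithmetic is identical for equal totals), 1,500 per
speed-accuracy cell, and 5,000 per congruence condition. Full-scale
defaults (50,000 transmissions, 1,000 decoders, blocks of 1,500) remain
available through the function arguments and the CLI.

## What the generator does and does not emulate

All inputs are synthetic: the package's claims are about the mechanism, not
about any dataset. The channel assumes constant rates within a
transmission, no refractory periods, no bursting, and no inter-neuron
correlations; the decoder knows the codebook, the noise rate, and the
transmission onset. Passing tests therefore demonstrate that the
decoding-time mechanism produces the behavioral patterns under these
idealized conditions — they do not show that human response times arise
this way, nor do they fit Wald or shifted-log-normal distributions to human
data, reproduce re-plotted human panels, or calibrate parameters against
experiments. Decoding with unknown onset and codebook learning by the
decoder from observations alone are out of scope.
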