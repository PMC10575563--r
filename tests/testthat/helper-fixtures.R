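# shared fixtures built in code

# the 3-neuron worked example: noise 6, one-hot signal 4
example_codebook <- function() {
  make_onehot_codebook(3, 3, signal_power = 4, noise_rate = 6)
}

# two-symbol channel used by the congruence protocols: signal 12, noise 12
stroop_codebook <- function() {
  make_onehot_codebook(2, 2, signal_power = 12, noise_rate = 12)
}

# sample skewness
skewness <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  mean(((x - m) / s)^3)
}

# standard error of a mean
se_mean <- function(x) stats::sd(x) / sqrt(length(x))
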