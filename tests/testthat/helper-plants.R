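# Shared test fixtures, built in code.
#
# Most controller-level tests run the plant at a scaled acquisition
# (10 MHz sampling, 2 ms pulses -> 20,000 samples instead of the default
# 40 MHz x 10 ms = 400,000) so a full 185-pulse session takes ~1.5 s.
# The SC (2 MHz) and IC (2.1 MHz) bands and all 8 harmonics stay far
# below the scaled Nyquist (5 MHz), and every emitted tone still falls
# on an exact FFT bin (resolution 500 Hz).

scaled_plant <- function(...) {
  plant_params(fs = 1e7, pulse_len = 2e-3, ...)
}

# Noiseless deterministic plant: harmonics only, no onsets in reach.
quiet_plant <- function(gamma = 1.5, ...) {
  scaled_plant(noise_sigma = 0, gamma = gamma, p_uh = 10, p_ic = 10,
               bb_gain = 0, ...)
}

# Closed-form reference plant: a pure 4th-harmonic tone with amplitude
# proportional to p, so that sc_db(p) = 20*log10(p / dummy_pressure)
# exactly (the hand-derivable plant of the convergence analysis). A tiny
# deterministic tone is placed in the IC band so the baseline IC level
# is nonzero and dB values are defined.
tone_plant <- function(fs = 1e7, pulse_len = 2e-3) {
  n <- round(fs * pulse_len)
  t <- (0:(n - 1)) / fs
  f <- function(p) p * sin(2 * pi * 2e6 * t) + 1e-6 * sin(2 * pi * 2.1e6 * t)
  attr(f, "fs") <- fs
  f
}

# Direct O(N^2) DFT: the independent oracle for compute_spectrum.
dft_oracle <- function(x, fs) {
  n <- length(x)
  half <- n %/% 2 + 1
  k <- 0:(half - 1)
  mag <- vapply(k, function(kk) {
    Mod(sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n)))
  }, numeric(1))
  data.frame(freq = k * fs / n, mag = mag)
}

# Brute-force band sum: the independent oracle for band_level.
band_sum_oracle <- function(spectrum, center, half_width) {
  s <- 0
  for (i in seq_len(nrow(spectrum))) {
    f <- spectrum$freq[i]
    if (f >= center - half_width && f <= center + half_width)
      s <- s + spectrum$mag[i]
  }
  s
}

# Least-squares sinusoid fit: amplitude of a tone at frequency f in x.
fit_tone_amplitude <- function(x, fs, f) {
  t <- (seq_along(x) - 1) / fs
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  co <- stats::coef(stats::lm.fit(X, x))
  sqrt(sum(co^2))
}

# A synthetic records data.frame for counting-statistic oracles.
random_records <- function(n, seed) {
  withr::with_seed(seed, {
    data.frame(
      index = seq_len(n),
      phase = sample(c("dummy", "ramp", "maintain"), n, replace = TRUE,
                     prob = c(0.1, 0.2, 0.7)),
      pressure_MPa = runif(n, 0.25, 0.4),
      sc_linear = runif(n, 1, 2), ic_linear = runif(n, 1, 2),
      sc_db = rnorm(n, 0.5, 0.4), ic_db = rnorm(n, 0, 0.6),
      in_band = sample(c(TRUE, FALSE), n, replace = TRUE),
      ic_event = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.1, 0.9)),
      stringsAsFactors = FALSE)
  })
}
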