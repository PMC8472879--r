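# Shared fixtures. Heavy end-to-end experiments are cached per seed so that
# the leakage, tail-error and personalization checks reuse the same trained
# models within a session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

get_leakage_experiment <- function(seed) {
  cached(paste0("leakage", seed),
         run_leakage_experiment(n_subjects = 50, seed = seed))
}

quiet_profile <- function(id = "T1", record_duration = 30, ..., seed = 1) {
  subject_profile(id, bp_drift_amplitude = 0, hr_jitter_sd = 0,
                  noise_sd = 0, record_duration = record_duration,
                  seed = seed, ...)
}

# Independent brute-force SNR oracle: direct periodogram band summation,
# with its own peak search, sharing only the definition with compute_snr().
snr_oracle <- function(x, fs, peak_hw = 0.2, band = c(0.5, 8),
                       hr_band = c(0.5, 3)) {
  xc <- x - mean(x)
  nfft <- 2^ceiling(log2(max(length(xc), fs / 0.02)))
  mag <- abs(stats::fft(c(xc, rep(0, nfft - length(xc)))))[1:(nfft / 2 + 1)]
  fr <- (0:(nfft / 2)) * fs / nfft
  sel <- fr >= hr_band[1] & fr <= hr_band[2]
  fp <- fr[sel][which.max(mag[sel])]
  n <- length(xc)
  p <- abs(stats::fft(xc))^2
  k <- 0:(n %/% 2)
  f2 <- k * fs / n
  p <- p[seq_along(k)]
  pm <- (abs(f2 - fp) <= peak_hw) | (abs(f2 - 2 * fp) <= peak_hw)
  inb <- f2 >= band[1] & f2 <= band[2]
  es <- sum(p[inb & !pm])
  if (es == 0) return(Inf)
  10 * log10(sum(p[inb & pm]) / es)
}

# A small pulse-like window: sinusoid at `f` Hz plus white noise.
noisy_pulse_window <- function(dur_s = 7, fs = 125, f = 1.2, amp = 1,
                               noise_sd = 0.5) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * f * t) + rnorm(length(t), sd = noise_sd)
}
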