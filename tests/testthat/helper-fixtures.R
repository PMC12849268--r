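# Shared fixtures: a reduced cohort design and signal builders kept small
# enough that every file's tests run in seconds.

small_design <- function(...) {
  cohort_design(n_blocks = 6, trials_per_block = 10, rest_dur_s = 2,
                channels = c("Fz", "Cz", "POz", "Oz"), srate = 250, ...)
}

quiet_spec <- function(theta_slope = 0, alpha_slope = 0) {
  list(theta_base = 2, theta_slope = theta_slope,
       alpha_base = 3, alpha_slope = alpha_slope,
       noise_sd = 0, blink_rate_per_min = 0)
}

sinusoid_rec <- function(freq, amp = 1, dur_s = 10, srate = 500,
                         channel = "Cz") {
  t <- (0:(dur_s * srate - 1)) / srate
  eeg_recording(matrix(amp * sin(2 * pi * freq * t), 1), srate, channel)
}

# brute-force BH step-up used as the independent multiple-testing oracle
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
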