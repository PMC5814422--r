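# Shared fixtures and independent oracles for the test suite.

# Tone generator: amplitude * sin(2 pi f t + phase), sampled at fs.
make_tone <- function(f, fs = 10, duration = 600, amplitude = 1, phase = 0,
                      label = "tone", id = "S01") {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  time_series(amplitude * sin(2 * pi * f * t + phase), fs = fs,
              channel_label = label, subject_id = id)
}

# Direct trapezoid-rule evaluation of the wavelet integral over the record,
# no FFT: the brute-force oracle the fast path must reproduce.
direct_cwt <- function(ts, freqs) {
  t <- sample_times(ts)
  dt <- 1 / ts$fs
  n <- length(ts$samples)
  w <- rep(1, n); w[c(1L, n)] <- 0.5
  gw <- ts$samples * w
  out <- matrix(0i, nrow = length(freqs), ncol = n)
  for (k in seq_along(freqs)) {
    s <- 1 / freqs[k]
    K <- outer(t, t, function(u, tt) morlet_mother((u - tt) / s))  # [u, t]
    out[k, ] <- as.vector(crossprod(K, gw)) * dt / sqrt(s)
  }
  out
}

# Coefficient field with iid uniform phases (complex white noise per cell):
# the regime in which E|mean phasor| = sqrt(pi) / (2 sqrt(n)) holds exactly.
iid_phase_field <- function(grid, nt, fs, label = "noise", id = "S01") {
  nf <- length(grid$frequencies)
  coef <- matrix(complex(real = rnorm(nf * nt), imaginary = rnorm(nf * nt)),
                 nrow = nf)
  wavelet_transform(coef, grid, times = (0:(nt - 1)) / fs, fs = fs,
                    channel_label = label, subject_id = id)
}

# Exact two-sided rank-sum p by full enumeration of rank assignments,
# independent of stats::wilcox.test.
enumerate_ranksum_p <- function(a, b) {
  m <- length(a)
  N <- m + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  splits <- utils::combn(N, m)
  u_all <- colSums(matrix(seq_len(N)[splits], nrow = m)) - m * (m + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Exact U-statistic null distribution for group sizes (m, n), by enumeration.
enumerate_u_distribution <- function(m, n) {
  splits <- utils::combn(m + n, m)
  u <- colSums(matrix(seq_len(m + n)[splits], nrow = m)) - m * (m + 1) / 2
  table(u) / ncol(splits)
}

# Two coupled noisy tones: shared random-walk phase, independent noise,
# second channel leading by lead_deg.
coupled_tone_pair <- function(f, fs = 10, duration = 900, amplitude = 1,
                              wander_sd = 0.2, noise_sd = 0.1, lead_deg = 0) {
  n <- as.integer(duration * fs)
  t <- (0:(n - 1)) / fs
  b <- cumsum(rnorm(n, 0, wander_sd * sqrt(1 / fs)))
  x <- amplitude * sin(2 * pi * f * t + b) + rnorm(n, 0, noise_sd)
  y <- amplitude * sin(2 * pi * f * t + lead_deg * pi / 180 + b) +
    rnorm(n, 0, noise_sd)
  list(x = time_series(x, fs, channel_label = "x"),
       y = time_series(y, fs, channel_label = "y"))
}

# Build a spectrum object directly from values (for interval/peak tests).
make_spectrum <- function(grid, values, id = "S01", label = "synthetic") {
  structure(list(grid = grid, mean_amplitude = values, subject_id = id,
                 channel_label = label), class = "sas_spectrum")
}
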