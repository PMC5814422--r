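test_that("the logarithmic frequency grid covers the requested range with constant ratio", {
  g <- frequency_grid(0.5, 2, 1)
  expect_equal(g$frequencies, c(0.5, 1, 2))

  g <- frequency_grid(0.005, 2, 16)
  expect_equal(g$frequencies[1], 0.005)
  expect_gte(max(g$frequencies), 2)
  expect_length(g$frequencies, ceiling(16 * log2(2 / 0.005)) + 1)
  ratios <- diff(log2(g$frequencies))
  expect_equal(ratios, rep(1 / 16, length(ratios)), tolerance = 1e-12)

  expect_error(frequency_grid(2, 0.5), "bounds")
  expect_error(frequency_grid(0.1, 1, 0), "voices")
})

test_that("the reliable frequency range is bounded by Nyquist", {
  expect_equal(max_reliable_frequency(100), 50)
  expect_error(morlet_cwt(time_series(rnorm(6000), fs = 10),
                          frequency_grid(0.1, 8, 8)), "Nyquist")
})

test_that("the Morlet mother wavelet matches its closed form", {
  expect_equal(morlet_mother(0), pi^(-1 / 4) + 0i)
  expect_equal(Mod(morlet_mother(0.25)), pi^(-1 / 4) * exp(-0.03125))
  u <- seq(-3, 3, by = 0.1)
  expect_equal(Mod(morlet_mother(u)), Mod(morlet_mother(-u)))
})

test_that("the FFT-accelerated transform equals direct trapezoid integration", {
  set.seed(11)
  ts <- time_series(rnorm(1000), fs = 10)
  g <- frequency_grid(0.05, 2, 4)
  wt <- morlet_cwt(ts, g)
  oracle <- direct_cwt(ts, g$frequencies)
  rel_err <- max(Mod(wt$coefficients - oracle)) / max(Mod(oracle))
  expect_lt(rel_err, 1e-6)
})

test_that("the transform is linear and phase-shift invariant in modulus", {
  set.seed(12)
  x <- rnorm(1500)
  g <- frequency_grid(0.1, 2, 6)
  w1 <- morlet_cwt(time_series(x, 10), g)
  w2 <- morlet_cwt(time_series(2 * x, 10), g)
  expect_equal(w2$coefficients, 2 * w1$coefficients, tolerance = 1e-12)

  a <- morlet_cwt(make_tone(0.5, duration = 150, phase = 0), g)
  b <- morlet_cwt(make_tone(0.5, duration = 150, phase = 1.1), g)
  valid <- !a$coi_mask
  expect_equal(Mod(a$coefficients)[valid], Mod(b$coefficients)[valid],
               tolerance = 0.02)
})

test_that("a pure tone is localised at its grid frequency with phase advancing at 2 pi f", {
  g <- frequency_grid(0.125, 2, 16)      # 1 Hz is exactly on this grid
  wt <- morlet_cwt(make_tone(1, duration = 600), g)
  spec <- time_averaged_amplitude(wt)
  expect_equal(spec$grid$frequencies[which.max(spec$mean_amplitude)], 1)

  row <- which(g$frequencies == 1)
  ph <- Arg(wt$coefficients[row, 2000:2200])
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi      # unwrap one-step increments
  expect_equal(mean(dph) * wt$fs, 2 * pi * 1, tolerance = 1e-3)
})

test_that("amplitude and phase come from the complex coefficients with full quadrant handling", {
  g <- frequency_grid(0.5, 2, 1)
  coef <- matrix(c(3 + 4i, -1 + 0i, 1i, -2i, 1 + 0i, -3 - 4i), nrow = 3)
  wt <- wavelet_transform(coef, g, times = c(0, 0.1), fs = 10,
                          coi_mask = matrix(FALSE, 3, 2))
  ap <- amplitude_phase(wt)
  expect_equal(ap$amplitude[1, 1], 5)
  expect_equal(ap$phase[1, 1], atan2(4, 3))
  expect_equal(ap$phase[2, 1], pi)        # -1 + 0i maps to pi, not 0
  expect_equal(ap$phase[3, 1], pi / 2)
})

test_that("the cone of influence widens towards low frequencies and edge cells bias averages down", {
  g <- frequency_grid(0.01, 1, 8)
  wt <- morlet_cwt(make_tone(0.1, duration = 600), g)
  frac <- rowMeans(wt$coi_mask)
  expect_true(all(diff(frac) <= 1e-12))   # decreasing with increasing f

  # including the attenuated edges lowers the average where there is signal:
  # a slow tone on a short record loses amplitude inside the cone
  wt_slow <- morlet_cwt(make_tone(0.02, duration = 600), g)
  sp_in <- time_averaged_amplitude(wt_slow, exclude_coi = TRUE)
  sp_all <- time_averaged_amplitude(wt_slow, exclude_coi = FALSE)
  near <- sp_in$mean_amplitude >= 0.8 * max(sp_in$mean_amplitude)
  expect_true(all(sp_all$mean_amplitude[near] < sp_in$mean_amplitude[near]))

  # constant-amplitude tone: interior column equals the time average within 1%
  sp_tone <- time_averaged_amplitude(wt)
  row <- which.min(abs(g$frequencies - 0.1))
  mid <- Mod(wt$coefficients[row, 3000])
  expect_equal(sp_tone$mean_amplitude[row], mid, tolerance = 0.01)
})

test_that("spectra of stationary noise are stable across disjoint halves", {
  set.seed(21)
  x <- rnorm(12000)
  g <- frequency_grid(0.05, 2, 6)
  s1 <- time_averaged_amplitude(morlet_cwt(time_series(x[1:6000], 10), g))
  s2 <- time_averaged_amplitude(morlet_cwt(time_series(x[6001:12000], 10), g))
  expect_equal(mean(s1$mean_amplitude), mean(s2$mean_amplitude),
               tolerance = 0.1)
})

test_that("interval summaries are interval-local means and additive", {
  g <- frequency_grid(0.005, 2, 16)
  flat <- make_spectrum(g, rep(1.5, length(g$frequencies)))
  expect_equal(unname(interval_summary(flat)), rep(1.5, 6))

  # mass only in interval V -> zero in I-IV and VI
  iv <- sas_intervals()
  inV <- g$frequencies > iv$low[iv$interval == "V"] &
    g$frequencies <= iv$high[iv$interval == "V"]
  spec_v <- make_spectrum(g, ifelse(inV, 2, 0))
  s <- interval_summary(spec_v)
  expect_gt(s[["V"]], 0)
  expect_equal(unname(s[c("I", "II", "III", "IV", "VI")]), rep(0, 5))

  set.seed(3)
  v1 <- runif(length(g$frequencies)); v2 <- runif(length(g$frequencies))
  expect_equal(interval_summary(make_spectrum(g, v1 + v2)),
               interval_summary(make_spectrum(g, v1)) +
                 interval_summary(make_spectrum(g, v2)))

  expect_error(interval_summary(make_spectrum(frequency_grid(0.1, 2, 8),
                                              rep(1, 70))),
               "no grid frequencies")
})

test_that("peak detection returns prominent local maxima in increasing order", {
  g <- frequency_grid(0.005, 2, 16)
  lf <- log(g$frequencies)
  bump <- function(f0, height, width = 0.3) height * exp(-(lf - log(f0))^2 /
                                                           (2 * width^2))
  one <- make_spectrum(g, bump(1, 1))
  expect_equal(detect_peaks(one), 1, tolerance = 0.05)

  two <- make_spectrum(g, bump(0.01, 1) + bump(1, 1))
  pks <- detect_peaks(two)
  expect_length(pks, 2)
  expect_equal(pks, c(0.01, 1), tolerance = 0.05)
  expect_true(all(diff(pks) > 0))

  monotone <- make_spectrum(g, seq_along(g$frequencies) / 10)
  expect_length(detect_peaks(monotone), 0)

  # sub-threshold prominence is discarded
  tiny <- make_spectrum(g, bump(1, 1) + bump(0.01, 0.02))
  expect_length(detect_peaks(tiny, min_prominence_fraction = 0.05), 1)
})
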