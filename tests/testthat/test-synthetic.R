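test_that("a single deterministic mode yields exactly the stated sinusoid", {
  m <- mode_spec("I", amplitude = c(BP = 2), freq_range = c(1, 1),
                 phase_wander_sd = 0)
  spec <- cohort_spec(2, list(m), duration_s = 60, fs = 10, noise_sd = 0,
                      seed = 5)
  rec <- generate_subject(spec, 1)
  t <- (0:599) / 10
  expect_equal(rec$channels$BP$samples, 2 * sin(2 * pi * 1 * t),
               tolerance = 1e-12)
})

test_that("generation is deterministic per (seed, subject) and varies across both", {
  spec <- default_resting_spec(3, seed = 9)
  spec$duration_s <- 120
  r1 <- generate_subject(spec, 1)
  r2 <- generate_subject(spec, 1)
  expect_identical(r1$channels$BP$samples, r2$channels$BP$samples)
  r_other <- generate_subject(spec, 2)
  expect_false(identical(r1$channels$BP$samples, r_other$channels$BP$samples))
  spec2 <- default_resting_spec(3, seed = 10)
  spec2$duration_s <- 120
  expect_false(identical(generate_subject(spec2, 1)$channels$BP$samples,
                         r1$channels$BP$samples))
  # the generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_subject(spec, 1)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("the default resting-state spec encodes the stated amplitude orderings and couplings", {
  spec <- default_resting_spec(12, seed = 1)
  amp <- sapply(spec$modes, `[[`, "amplitude")
  colnames(amp) <- sapply(spec$modes, `[[`, "interval")
  # BP cardiac-dominant: interval I at least 3x every other BP amplitude
  expect_true(all(amp["BP", "I"] >= 3 * amp["BP", -1]))
  # SAS endothelial-dominant: V and VI at least 3x I and II
  for (ch in c("TQ_LEFT", "TQ_RIGHT"))
    expect_true(all(amp[ch, c("V", "VI")] >= 3 * max(amp[ch, c("I", "II")])))
  # couplings: BP with SAS in I-III only; SAS pair through I-V
  groups <- lapply(spec$modes, `[[`, "coupling_group")
  names(groups) <- colnames(amp)
  expect_true(all(sapply(groups[c("I", "II", "III")], function(g) "BP" %in% g)))
  expect_false(any(sapply(groups[c("IV", "V", "VI")], function(g) "BP" %in% g)))
  expect_true(all(sapply(groups[c("I", "II", "III", "IV", "V")], function(g)
    all(c("TQ_LEFT", "TQ_RIGHT") %in% g))))
  expect_length(groups[["VI"]], 0)
  # myogenic SAS lead is positive
  expect_equal(spec$modes[[3]]$offset_deg[["TQ_LEFT"]], 30)
})

test_that("cohort metadata straddles 25 years, alternates sex, and records round-trip", {
  spec <- default_resting_spec(6, seed = 2)
  spec$duration_s <- 60
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(spec, dir = dir)
  expect_length(cohort$records, 6)
  expect_equal(nrow(cohort$meta), 6)
  expect_true(any(cohort$meta$age < 25) && any(cohort$meta$age >= 25))
  expect_equal(sum(cohort$meta$sex == "male"), 3)
  expect_true(file.exists(file.path(dir, "metadata.csv")))

  # file round trip is bit-exact
  id <- cohort$meta$subject_id[1]
  sc <- read_sidecar(file.path(dir, paste0(id, ".json")))
  back <- read_signal_table(file.path(dir, paste0(id, ".csv")), fs = sc$fs,
                            subject_id = id)
  expect_identical(back$channels$BP$samples,
                   cohort$records[[1]]$channels$BP$samples)
  # same seed reproduces the identical cohort; a different seed does not
  again <- generate_cohort(spec)
  expect_identical(again$records[[1]]$channels$TQ_LEFT$samples,
                   cohort$records[[1]]$channels$TQ_LEFT$samples)
})

test_that("generated spectra have the endothelial-dominant SAS / cardiac-dominant BP structure", {
  spec <- default_resting_spec(2, seed = 3)
  spec$duration_s <- 900
  rec <- preprocess_record(generate_subject(spec, 1))
  g <- frequency_grid(0.005, 2, 16)
  iv <- sas_intervals()

  sp_bp <- time_averaged_amplitude(morlet_cwt(rec$channels$BP, g))
  f_peak <- g$frequencies[which.max(sp_bp$mean_amplitude)]
  expect_gt(f_peak, 0.6)
  expect_lte(f_peak, 2)

  sp_sas <- time_averaged_amplitude(morlet_cwt(rec$channels$TQ_LEFT, g))
  s <- interval_summary(sp_sas, iv)
  expect_gt(s[["V"]], s[["I"]])
  expect_gt(s[["VI"]], s[["II"]])
})

test_that("mode frequencies in intervals I-IV are recovered by peak detection within one grid step", {
  spec <- default_resting_spec(2, seed = 6)
  raw <- generate_subject(spec, 1)
  drawn <- raw$mode_frequencies     # mode x channel ground truth
  rec <- preprocess_record(raw)
  g <- frequency_grid(0.005, 2, 16)
  step <- 1 / g$voices_per_octave

  for (ch in c("BP", "TQ_LEFT")) {
    sp <- time_averaged_amplitude(morlet_cwt(rec$channels[[ch]], g))
    pks <- detect_peaks(sp, min_prominence_fraction = 0.01)
    for (lab in c("I", "II", "III", "IV")) {
      gap <- min(abs(log2(pks / drawn[lab, ch])))
      expect_lt(gap, step * 1.01)
    }
  }
})

test_that("the 1/f noise option shifts noise mass to low frequencies at equal variance", {
  m <- mode_spec("I", amplitude = c(BP = 0.001))
  white <- cohort_spec(2, list(m), duration_s = 600, fs = 10, noise_sd = 1,
                       seed = 8)
  pink <- cohort_spec(2, list(m), duration_s = 600, fs = 10, noise_sd = 1,
                      noise_model = "one_over_f", seed = 8)
  xw <- generate_subject(white, 1)$channels$BP$samples
  xp <- generate_subject(pink, 1)$channels$BP$samples
  expect_equal(sd(xp), sd(xw), tolerance = 0.05)
  g <- frequency_grid(0.02, 2, 6)
  sw <- time_averaged_amplitude(morlet_cwt(time_series(xw, 10), g))
  sp <- time_averaged_amplitude(morlet_cwt(time_series(xp, 10), g))
  low <- g$frequencies <= 0.1
  expect_gt(mean(sp$mean_amplitude[low]), 1.5 * mean(sw$mean_amplitude[low]))
})

test_that("with couplings removed the cohort coherence stays below the surrogate threshold almost everywhere", {
  spec <- default_resting_spec(8, seed = 7)
  spec$duration_s <- 900
  for (i in seq_along(spec$modes)) spec$modes[[i]]$coupling_group <- character()
  cohort <- generate_cohort(spec)
  g <- frequency_grid(0.005, 2, 8)
  fields <- lapply(cohort$records, function(rec) {
    rec <- preprocess_record(rec)
    list(BP = phase_field(morlet_cwt(rec$channels$BP, g)),
         TQ = phase_field(morlet_cwt(rec$channels$TQ_LEFT, g)))
  })
  curves <- lapply(fields, function(f) wpco(f$BP, f$TQ))
  med <- median_coherence(curves)
  thr <- threshold_curve(surrogate_distribution(
    lapply(fields, `[[`, "BP"), lapply(fields, `[[`, "TQ")))
  mask <- significant_mask(med, thr)
  iv <- sas_intervals()
  for (lab in iv$interval) {
    sel <- g$frequencies > iv$low[iv$interval == lab] &
      g$frequencies <= iv$high[iv$interval == lab]
    expect_lte(mean(mask[sel]), 0.10)
  }
})
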