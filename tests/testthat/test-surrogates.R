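test_that("intersubject pairing enumerates all ordered pairs exactly once", {
  expect_equal(nrow(intersubject_pairs(2)), 2)
  expect_equal(nrow(intersubject_pairs(36)), 1260)
  p5 <- intersubject_pairs(5)
  expect_equal(nrow(p5), 20)
  expect_true(all(p5[, "i"] != p5[, "j"]))
  expect_equal(nrow(unique(p5)), 20)
  # brute-force enumeration oracle
  all_pairs <- expand.grid(i = 1:5, j = 1:5)
  all_pairs <- all_pairs[all_pairs$i != all_pairs$j, ]
  expect_setequal(paste(p5[, 1], p5[, 2]), paste(all_pairs$i, all_pairs$j))
  expect_error(intersubject_pairs(1), "at least 2")
})

test_that("the surrogate distribution holds one coherence curve per ordered pair", {
  set.seed(41)
  g <- frequency_grid(0.1, 2, 6)
  wa <- lapply(1:3, function(i) iid_phase_field(g, 300, 10, id = paste0("S", i)))
  wb <- lapply(1:3, function(i) iid_phase_field(g, 300, 10, id = paste0("S", i)))
  dist <- surrogate_distribution(wa, wb)
  expect_equal(nrow(dist$coherences), 6)
  expect_equal(dist$pairs, intersubject_pairs(3))
  expect_true(all(dist$coherences >= 0 & dist$coherences <= 1))
  # row 1 is pair (1, 2): must equal a direct wpco call
  expect_equal(dist$coherences[1, ], wpco(wa[[1]], wb[[2]])$coherence)
})

test_that("records of unequal length are truncated to the shortest before pairing", {
  set.seed(42)
  g <- frequency_grid(0.2, 2, 6)
  wa <- list(iid_phase_field(g, 300, 10), iid_phase_field(g, 260, 10))
  wb <- list(iid_phase_field(g, 280, 10), iid_phase_field(g, 300, 10))
  dist <- surrogate_distribution(wa, wb)
  expect_equal(nrow(dist$coherences), 2)
  expect_true(all(is.finite(dist$coherences)))
})

test_that("threshold curves follow the linear-interpolation percentile convention", {
  g <- frequency_grid(0.5, 2, 4)
  nf <- length(g$frequencies)
  same <- structure(list(grid = g,
                         coherences = matrix(0.37, nrow = 25, ncol = nf),
                         pairs = intersubject_pairs(6)[1:25, ]),
                    class = "sas_surrogates")
  expect_equal(threshold_curve(same)$threshold, rep(0.37, nf))

  vals <- seq(0, 1, length.out = 21)
  dist <- structure(list(grid = g,
                         coherences = matrix(vals, nrow = 21, ncol = nf),
                         pairs = NULL), class = "sas_surrogates")
  expect_equal(threshold_curve(dist, 100)$threshold, rep(1, nf))
  # type-7 percentile by hand: order statistic at 1 + 0.95 * (n - 1)
  h <- 1 + 0.95 * 20
  expected <- vals[floor(h)] + (h - floor(h)) * (vals[floor(h) + 1] - vals[floor(h)])
  expect_equal(threshold_curve(dist, 95)$threshold, rep(expected, nf))

  # Monte-Carlo vs analytic percentile of a known distribution
  set.seed(43)
  u <- matrix(runif(1260 * nf)^2, nrow = 1260)   # P(X <= x) = sqrt(x)
  dist_u <- structure(list(grid = g, coherences = u, pairs = NULL),
                      class = "sas_surrogates")
  expect_equal(mean(threshold_curve(dist_u, 95)$threshold), 0.95^2,
               tolerance = 0.02)

  small <- structure(list(grid = g, coherences = matrix(0.5, 5, nf),
                          pairs = NULL), class = "sas_surrogates")
  expect_error(threshold_curve(small), "fewer than 20")
})

test_that("significance requires the median to strictly exceed the threshold", {
  g <- frequency_grid(0.5, 2, 4)
  nf <- length(g$frequencies)
  thr <- structure(list(grid = g, threshold = rep(0.3, nf), percentile = 95),
                   class = "sas_threshold")
  med <- structure(list(grid = g, coherence = c(0.2, rep(0.3, nf - 2), 0.5),
                        n_valid = rep(50L, nf), pair_label = "a~b"),
                   class = "sas_coherence")
  m <- significant_mask(med, thr)
  expect_false(m[1])                      # below
  expect_false(m[2])                      # tie is not significant
  expect_true(m[nf])                      # above
})

test_that("white-noise cohorts show the low-frequency coherence bias and a null-consistent threshold", {
  set.seed(44)
  g <- frequency_grid(0.005, 2, 8)
  n_sub <- 5
  mk <- function(id) {
    rec <- time_series(rnorm(4500), fs = 5, subject_id = id)
    phase_field(morlet_cwt(rec, g))
  }
  wa <- lapply(sprintf("A%d", 1:n_sub), mk)
  wb <- lapply(sprintf("B%d", 1:n_sub), mk)
  dist <- surrogate_distribution(wa, wb)
  thr <- threshold_curve(dist)

  # bias: mean surrogate coherence rises towards low frequencies, and so
  # does the surrogate threshold that corrects for it
  iv <- sas_intervals()
  band <- function(v, lab) mean(v[g$frequencies > iv$low[iv$interval == lab] &
                                    g$frequencies <= iv$high[iv$interval == lab]])
  expect_gt(band(colMeans(dist$coherences), "VI"),
            band(colMeans(dist$coherences), "I"))
  expect_gt(band(thr$threshold, "VI"), band(thr$threshold, "I"))

  # null-on-null: genuine (same-index) white-noise pairs are statistically
  # indistinguishable from surrogate pairs in every interval
  genuine <- t(sapply(1:n_sub, function(i)
    wpco(wa[[i]], wb[[i]])$coherence))
  for (lab in iv$interval) {
    sel <- g$frequencies > iv$low[iv$interval == lab] &
      g$frequencies <= iv$high[iv$interval == lab]
    p <- wilcoxon_rank_sum(rowMeans(genuine[, sel, drop = FALSE]),
                           rowMeans(dist$coherences[, sel, drop = FALSE]))$p_value
    expect_gt(p, 0.05)
  }
})
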