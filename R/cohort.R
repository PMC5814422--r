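#' Correlation between left and right SAS signals
#'
#' Product-moment correlation of the two preprocessed interhemispheric
#' signals; used both as a subject characteristic and as a grouping variable
#' (high vs low interhemispheric synchrony).
#'
#' @param left,right [time_series()] objects of equal length.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
sas_correlation <- function(left, right) {
  stopifnot(inherits(left, "sas_ts"), inherits(right, "sas_ts"))
  if (length(left$samples) != length(right$samples))
    stop("signals must have equal length")
  if (stats::sd(left$samples) == 0 || stats::sd(right$samples) == 0)
    stop("zero-variance signal")
  stats::cor(left$samples, right$samples)
}

#' Assemble a cohort table
#'
#' Bundles per-subject metadata with the per-subject spectral and coherence
#' summaries the group comparisons consume.
#'
#' @param meta Data frame with columns `subject_id`, `age`, `sex`, and
#'   optionally `sas_correlation`.
#' @param amplitude Long data frame (`subject_id`, `channel`, `interval`,
#'   `mean_amplitude`) of interval summaries, or NULL.
#' @param coherence_bands Long data frame (`subject_id`, `pair`, `interval`,
#'   `coherence`) of band-averaged coherences, or NULL.
#' @return An object of class `sas_cohort`.
#' @export
cohort_table <- function(meta, amplitude = NULL, coherence_bands = NULL) {
  if (anyDuplicated(meta$subject_id)) stop("subject ids must be unique")
  if (any(meta$age <= 0)) stop("ages must be positive")
  structure(list(meta = meta, amplitude = amplitude,
                 coherence_bands = coherence_bands),
            class = "sas_cohort")
}

#' @export
print.sas_cohort <- function(x, ...) {
  cat(sprintf("<sas_cohort> %d subjects (%d male, %d female), ages %g-%g\n",
              nrow(x$meta), sum(x$meta$sex == "male"),
              sum(x$meta$sex == "female"), min(x$meta$age), max(x$meta$age)))
  invisible(x)
}

#' Split a cohort into two groups
#'
#' Grouping criteria: `"age_25"` puts subjects younger than 25 in group 1 and
#' those aged 25 or more in group 2; `"sex"` splits male vs female;
#' `"sas_correlation_median"` splits at the cohort median interhemispheric
#' correlation, with subjects at or above the median (including the median
#' subject itself) in the high group.
#'
#' @param cohort A [cohort_table()].
#' @param criterion One of `"age_25"`, `"sex"`, `"sas_correlation_median"`.
#' @return List with character vectors `group1`, `group2` of subject ids and
#'   a `label` describing the split. Errors if either group is empty.
#' @export
split_cohort <- function(cohort,
                         criterion = c("age_25", "sex",
                                       "sas_correlation_median")) {
  stopifnot(inherits(cohort, "sas_cohort"))
  criterion <- match.arg(criterion)
  meta <- cohort$meta
  g <- switch(criterion,
    age_25 = list(group1 = meta$subject_id[meta$age < 25],
                  group2 = meta$subject_id[meta$age >= 25],
                  label = "age < 25 vs age >= 25"),
    sex = list(group1 = meta$subject_id[meta$sex == "male"],
               group2 = meta$subject_id[meta$sex == "female"],
               label = "male vs female"),
    sas_correlation_median = {
      if (is.null(meta$sas_correlation) || any(!is.finite(meta$sas_correlation)))
        stop("sas_correlation is not populated for this cohort")
      med <- stats::median(meta$sas_correlation)
      list(group1 = meta$subject_id[meta$sas_correlation < med],
           group2 = meta$subject_id[meta$sas_correlation >= med],
           label = "low vs high SAS correlation (median split)")
    })
  if (length(g$group1) == 0L || length(g$group2) == 0L)
    stop(sprintf("criterion '%s' produces an empty group", criterion))
  g
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test. For combined sample sizes
#' up to 12 with no ties the exact null distribution is used; otherwise the
#' continuity-corrected normal approximation with tie correction.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact path; the
#'   default `NULL` applies the size/tie rule above. Forcing `FALSE` exposes
#'   the approximation for accuracy studies.
#' @return List with `statistic` (Mann-Whitney U for the first group),
#'   `p_value`, `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
wilcoxon_rank_sum <- function(a, b, exact = NULL) {
  if (length(a) == 0L || length(b) == 0L) stop("empty input group")
  no_ties <- !anyDuplicated(c(a, b))
  if (is.null(exact)) exact <- no_ties && (length(a) + length(b)) <= 12L
  else if (exact && !no_ties) stop("exact enumeration requires tie-free data")
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact enumeration" else
         "normal approximation (continuity + tie correction)")
}

# Paired signed-rank analogue. Zero differences are dropped (Wilcoxon
# convention); tied magnitudes take midranks. For up to 15 informative pairs
# the null is enumerated over all 2^n sign assignments -- unlike the
# wilcox.test exact path this stays exact under ties, and tied differences
# are the norm for interval contrasts with a common offset. Larger samples
# use the continuity-corrected normal approximation.
.wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  dn <- d[d != 0]
  n <- length(dn)
  if (n == 0L) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(dn))
  v_obs <- sum(r[dn > 0])
  if (n <= 15L) {
    v_all <- as.matrix(expand.grid(rep(list(c(0, 1)), n))) %*% r
    p <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, alternative = "two.sided",
                         exact = FALSE, correct = TRUE))$p.value
  }
  list(statistic = v_obs, p_value = p)
}

#' Standardized mean difference (Cohen's d, pooled)
#'
#' @param a,b Numeric vectors.
#' @return Absolute standardized difference of group means, using the
#'   pooled standard deviation.
#' @export
effect_size_d <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) return(if (mean(a) == mean(b)) 0 else Inf)
  abs(mean(a) - mean(b)) / sqrt(sp2)
}

#' Effect-size / power reporting gate
#'
#' A group difference is only reported as significant when the observed
#' standardized effect is at least as large as the minimal effect detectable
#' with the requested power. The minimal detectable effect comes from the
#' two-sample normal-approximation power formula,
#' `d_min = (z_{1 - alpha/2} + z_{power}) * sqrt(1/n1 + 1/n2)`.
#'
#' @param effect_size Observed standardized mean difference.
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Required power (default 0.8, i.e. beta = 0.2).
#' @return List with `pass` (logical) and `min_detectable_effect`.
#' @examples
#' power_gate(1.0, 18, 18)$min_detectable_effect  # ~0.934
#' @export
power_gate <- function(effect_size, n1, n2, alpha = 0.05, power = 0.8) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie strictly between 0 and 1")
  d_min <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) *
    sqrt(1 / n1 + 1 / n2)
  list(pass = effect_size >= d_min, min_detectable_effect = d_min)
}

#' Paired interval-vs-interval amplitude comparisons
#'
#' Within-channel contrasts of the interval mean amplitudes (by default
#' the endothelial-vs-cardiac/respiratory contrasts I vs V, I vs VI, II vs V,
#' II vs VI). The same subjects contribute both intervals of a contrast, so
#' the paired signed-rank test is applied to the per-subject differences; the
#' effect size is the standardized mean of those differences and feeds the
#' power gate with `n1 = n2 = n` subjects.
#'
#' @param cohort A [cohort_table()] with `amplitude` populated.
#' @param channel Channel whose interval summaries are compared.
#' @param pairs List of 2-element character vectors of interval names.
#' @param alpha,power Gate parameters (defaults 0.05 and 0.8).
#' @return Data frame with one row per contrast: `comparison`, `statistic`,
#'   `p`, `effect_size`, `gate_pass`, `significant` (p < alpha and gate
#'   passed).
#' @export
interval_amplitude_compare <- function(cohort, channel,
                                       pairs = list(c("I", "V"), c("I", "VI"),
                                                    c("II", "V"), c("II", "VI")),
                                       alpha = 0.05, power = 0.8) {
  stopifnot(inherits(cohort, "sas_cohort"), !is.null(cohort$amplitude))
  amp <- cohort$amplitude[cohort$amplitude$channel == channel, ]
  if (nrow(amp) == 0L) stop("no amplitude summaries for channel ", channel)
  rows <- lapply(pairs, function(pr) {
    x <- amp$mean_amplitude[amp$interval == pr[1L]]
    y <- amp$mean_amplitude[amp$interval == pr[2L]]
    if (length(x) == 0L || length(y) == 0L || length(x) != length(y))
      stop(sprintf("missing interval summaries for contrast %s vs %s",
                   pr[1L], pr[2L]))
    ht <- .wilcoxon_signed_rank(x, y)
    d <- x - y
    es <- if (stats::sd(d) == 0) {
      if (all(d == 0)) 0 else Inf
    } else abs(mean(d)) / stats::sd(d)
    gate <- power_gate(es, length(x), length(x), alpha = alpha, power = power)
    data.frame(comparison = paste(pr[1L], "vs", pr[2L]),
               statistic = ht$statistic, p = ht$p_value, effect_size = es,
               gate_pass = gate$pass,
               significant = ht$p_value < alpha && gate$pass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Between-group comparison of a per-subject measure
#'
#' Compares two subject groups interval by interval with the rank-sum test,
#' attaching the standardized effect size and the power-gate flag; a
#' difference is labelled significant only when p < alpha AND the gate
#' passes, so underpowered contrasts are never reported as findings.
#'
#' @param values Long data frame with columns `subject_id`, `interval`, and
#'   the measure named by `value_col`.
#' @param split A [split_cohort()] result.
#' @param value_col Name of the measure column (e.g. `"coherence"`).
#' @param alpha,power Gate parameters.
#' @return Data frame with one row per interval: `interval`, `n1`, `n2`,
#'   `statistic`, `p`, `effect_size`, `gate_pass`, `significant`.
#' @export
group_compare <- function(values, split, value_col = "coherence",
                          alpha = 0.05, power = 0.8) {
  stopifnot(all(c("subject_id", "interval", value_col) %in% names(values)))
  rows <- lapply(unique(values$interval), function(iv) {
    v <- values[values$interval == iv, ]
    a <- v[[value_col]][v$subject_id %in% split$group1]
    b <- v[[value_col]][v$subject_id %in% split$group2]
    ht <- wilcoxon_rank_sum(a, b)
    es <- effect_size_d(a, b)
    gate <- power_gate(es, length(a), length(b), alpha = alpha, power = power)
    data.frame(interval = iv, n1 = length(a), n2 = length(b),
               statistic = ht$statistic, p = ht$p_value, effect_size = es,
               gate_pass = gate$pass,
               significant = ht$p_value < alpha && gate$pass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
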