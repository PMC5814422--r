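#' All ordered intersubject pairs
#'
#' Enumerates the ordered pairs `(i, j)` with `i != j` used to build
#' intersubject surrogates: channel A of subject i matched with channel B of
#' subject j. For `n` subjects there are exactly `n * (n - 1)` such pairs
#' (1260 for a 36-subject cohort).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @return Integer matrix with columns `i`, `j`, one row per ordered pair.
#' @examples
#' nrow(intersubject_pairs(36))  # 1260
#' @export
intersubject_pairs <- function(n_subjects) {
  if (!is.finite(n_subjects) || n_subjects < 2)
    stop("need at least 2 subjects to form intersubject pairs")
  n <- as.integer(n_subjects)
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), times = n)
  keep <- i != j
  cbind(i = i[keep], j = j[keep])
}

#' Intersubject-surrogate coherence distribution
#'
#' Builds the null distribution of wavelet phase coherence under "no genuine
#' coupling" by pairing channel A of subject i with channel B of subject j
#' for every ordered pair `i != j`: mismatched signals from different people
#' share the physiological spectral structure but cannot be phase-locked.
#' The construction is exhaustive (no sampling), so it is deterministic given
#' the cohort ordering. Records of unequal length are truncated to the
#' shortest before pairing, with edge masks recomputed for the truncated
#' length.
#'
#' @param wts_a,wts_b Lists (one element per subject, same order) of
#'   [wavelet_transform()] or [phase_field()] objects on a common grid.
#' @return An object of class `sas_surrogates` with fields `grid`,
#'   `coherences` (matrix, one row per ordered pair, ordered as
#'   [intersubject_pairs()]), `pairs`.
#' @export
surrogate_distribution <- function(wts_a, wts_b) {
  if (length(wts_a) != length(wts_b))
    stop("channel lists must have one entry per subject")
  n <- length(wts_a)
  if (n < 2) stop("need at least 2 subjects")
  pa <- lapply(wts_a, .as_phasors)
  pb <- lapply(wts_b, .as_phasors)
  all_p <- c(pa, pb)
  for (p in all_p[-1L]) {
    if (!isTRUE(all.equal(all_p[[1L]]$grid$frequencies, p$grid$frequencies)))
      stop("all transforms must share the same frequency grid")
  }
  nt <- min(vapply(all_p, function(p) length(p$times), integer(1)))
  truncate_p <- function(p) {
    if (length(p$times) == nt) return(p)
    p$phasors <- p$phasors[, seq_len(nt), drop = FALSE]
    p$times <- p$times[seq_len(nt)]
    mask <- .coi_mask(p$grid$frequencies, p$times)
    p$phasors[mask] <- 0i
    p$n_valid <- rowSums(p$phasors != 0i)
    p
  }
  pa <- lapply(pa, truncate_p)
  pb <- lapply(pb, truncate_p)
  pairs <- intersubject_pairs(n)
  nf <- length(pa[[1L]]$grid$frequencies)
  coh <- matrix(NA_real_, nrow = nrow(pairs), ncol = nf)
  for (r in seq_len(nrow(pairs))) {
    res <- .pair_resultant(pa[[pairs[r, 1L]]], pb[[pairs[r, 2L]]])
    coh[r, ] <- pmin(Mod(res$resultant), 1)
  }
  structure(list(grid = pa[[1L]]$grid, coherences = coh, pairs = pairs),
            class = "sas_surrogates")
}

#' @export
print.sas_surrogates <- function(x, ...) {
  cat(sprintf("<sas_surrogates> %d surrogate pairs x %d frequencies\n",
              nrow(x$coherences), ncol(x$coherences)))
  invisible(x)
}

#' Surrogate significance threshold curve
#'
#' Per-frequency empirical percentile (linear interpolation between order
#' statistics, the type-7 convention) of the surrogate coherences. The
#' threshold rises towards low frequencies on null data, mirroring -- and
#' thereby correcting for -- the intrinsic low-frequency bias of phase
#' coherence.
#'
#' @param dist A [surrogate_distribution()].
#' @param percentile Percentile to extract (default 95).
#' @return An object of class `sas_threshold` with fields `grid`,
#'   `threshold`, `percentile`.
#' @export
threshold_curve <- function(dist, percentile = 95) {
  stopifnot(inherits(dist, "sas_surrogates"))
  if (nrow(dist$coherences) < 20)
    stop("fewer than 20 surrogate pairs: the 95th percentile is meaningless")
  if (percentile <= 0 || percentile > 100) stop("invalid percentile")
  thr <- apply(dist$coherences, 2L, stats::quantile, probs = percentile / 100,
               type = 7, names = FALSE)
  structure(list(grid = dist$grid, threshold = thr, percentile = percentile),
            class = "sas_threshold")
}

#' Median coherence curve across a cohort
#'
#' @param curves List of [wpco()] results on a common grid, one per subject.
#' @return A `sas_coherence` whose `coherence` is the per-frequency median
#'   across subjects.
#' @export
median_coherence <- function(curves) {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, logical(1), "sas_coherence")))
  g <- curves[[1L]]$grid
  for (cu in curves[-1L])
    if (!isTRUE(all.equal(g$frequencies, cu$grid$frequencies)))
      stop("coherence curves are not on the same grid")
  m <- apply(vapply(curves, `[[`, numeric(length(g$frequencies)), "coherence"),
             1L, stats::median)
  structure(
    list(grid = g, coherence = m,
         n_valid = do.call(pmin, lapply(curves, `[[`, "n_valid")),
         pair_label = curves[[1L]]$pair_label),
    class = "sas_coherence"
  )
}

#' Frequencies where cohort coherence is significant
#'
#' A frequency is significant when the group-median coherence strictly
#' exceeds the surrogate threshold; ties are not significant.
#'
#' @param median_curve A [median_coherence()] (or any `sas_coherence`).
#' @param threshold A [threshold_curve()] on the same grid.
#' @return Logical vector, one element per grid frequency.
#' @export
significant_mask <- function(median_curve, threshold) {
  stopifnot(inherits(median_curve, "sas_coherence"),
            inherits(threshold, "sas_threshold"))
  if (!isTRUE(all.equal(median_curve$grid$frequencies,
                        threshold$grid$frequencies)))
    stop("coherence and threshold are not on the same grid")
  median_curve$coherence > threshold$threshold
}

#' Which intervals contain significant coherence
#'
#' Convenience reduction of a per-frequency significance mask to the six
#' physiological intervals: an interval is flagged when any of its grid
#' frequencies is significant.
#'
#' @param mask Logical vector from [significant_mask()].
#' @param grid The matching [frequency_grid()].
#' @param intervals An interval table as from [sas_intervals()].
#' @return Named logical vector, one element per interval.
#' @export
interval_significance <- function(mask, grid, intervals = sas_intervals()) {
  stopifnot(length(mask) == length(grid$frequencies))
  f <- grid$frequencies
  out <- vapply(seq_len(nrow(intervals)), function(i)
    any(mask[f > intervals$low[i] & f <= intervals$high[i]]), logical(1))
  names(out) <- intervals$interval
  out
}
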