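#' Extract the unit-phasor field of a wavelet transform
#'
#' Reduces a wavelet transform to `exp(i * theta)` per time-frequency cell,
#' with cells inside the cone of influence set to zero so they drop out of
#' all phase averages. This is the minimal object phase-coherence analysis
#' needs, at half the bookkeeping of a full transform, and is the natural
#' input for surrogate computations over many subjects.
#'
#' @param wt A [wavelet_transform()].
#' @return An object of class `sas_phasors` with fields `phasors` (complex
#'   matrix, COI cells zero), `n_valid` (per-frequency count of usable time
#'   samples), `grid`, `times`, `fs`, `channel_label`, `subject_id`.
#' @export
phase_field <- function(wt) {
  stopifnot(inherits(wt, "sas_wt"))
  ph <- exp(1i * Arg(wt$coefficients))
  ph[wt$coi_mask] <- 0i
  structure(
    list(phasors = ph, n_valid = rowSums(!wt$coi_mask), grid = wt$grid,
         times = wt$times, fs = wt$fs, channel_label = wt$channel_label,
         subject_id = wt$subject_id),
    class = "sas_phasors"
  )
}

.as_phasors <- function(x) {
  if (inherits(x, "sas_phasors")) return(x)
  if (inherits(x, "sas_wt")) return(phase_field(x))
  stop("expected a wavelet transform ('sas_wt') or phase field ('sas_phasors')")
}

.check_pair_base <- function(p1, p2) {
  if (!isTRUE(all.equal(p1$grid$frequencies, p2$grid$frequencies)))
    stop("the two transforms are not on the same frequency grid")
  if (length(p1$times) != length(p2$times) ||
      !isTRUE(all.equal(p1$times, p2$times)))
    stop("the two transforms are not on the same time base")
}

# Per-frequency circular resultant of the phase difference theta2 - theta1:
# mean over jointly valid times of exp(i (theta2 - theta1)). COI cells are
# zero phasors, so they vanish from the sum automatically.
.pair_resultant <- function(p1, p2) {
  num <- rowSums(Conj(p1$phasors) * p2$phasors)
  nv <- rowSums(p1$phasors != 0i & p2$phasors != 0i)
  if (any(nv == 0L))
    stop("no jointly valid time samples at some frequency (record too short)")
  list(resultant = num / nv, n_valid = nv)
}

#' Wavelet phase coherence between two channels
#'
#' `C(f) = | mean over time of exp(i (theta2 - theta1)) |` per frequency,
#' averaging over the time samples outside the cone of influence of both
#' transforms. Coherence near 1 means the two channels keep an almost
#' constant phase relation at that frequency; for unrelated oscillations the
#' phase difference drifts and the mean phasor shrinks towards zero (up to
#' the finite-sample floor of order `sqrt(pi)/(2 sqrt(n))`). Only phase
#' enters: the statistic is invariant to amplitude rescaling of either input.
#'
#' @param wt1,wt2 [wavelet_transform()] or [phase_field()] objects on the
#'   same grid and time base. By convention signal 1 is the reference (BP, or
#'   TQ_RIGHT for the interhemispheric pair).
#' @return An object of class `sas_coherence` with fields `grid`,
#'   `coherence` (in `[0, 1]`), `n_valid`, `pair_label`.
#' @examples
#' ts <- time_series(sin(2 * pi * (0:5999) / 10), fs = 10)
#' wt <- morlet_cwt(ts, frequency_grid(0.1, 2, 8))
#' all(wpco(wt, wt)$coherence > 1 - 1e-9)  # identical inputs
#' @export
wpco <- function(wt1, wt2) {
  p1 <- .as_phasors(wt1); p2 <- .as_phasors(wt2)
  .check_pair_base(p1, p2)
  r <- .pair_resultant(p1, p2)
  structure(
    list(grid = p1$grid, coherence = pmin(Mod(r$resultant), 1),
         n_valid = r$n_valid,
         pair_label = paste0(p1$channel_label, "~", p2$channel_label)),
    class = "sas_coherence"
  )
}

#' @export
print.sas_coherence <- function(x, ...) {
  cat(sprintf("<sas_coherence> %s: %d frequencies, max %.3f at %.4g Hz\n",
              x$pair_label, length(x$coherence), max(x$coherence),
              x$grid$frequencies[which.max(x$coherence)]))
  invisible(x)
}

#' Circular-mean phase difference between two channels
#'
#' `delta_theta(f) = atan2(mean sin(theta2 - theta1), mean cos(theta2 -
#' theta1))`, reported in degrees in `(-180, 180]`. Positive values mean
#' signal 2 leads signal 1 (with signal 1 = BP and signal 2 = SAS, positive
#' means the SAS signal leads). Where the mean phasor is degenerate
#' (coherence below 1e-12) the direction is meaningless and is reported as
#' `NA` rather than as an arbitrary angle.
#'
#' @inheritParams wpco
#' @return An object of class `sas_phasediff` with fields `grid`,
#'   `delta_theta_deg` (`NA` where undefined), `coherence`, `pair_label`.
#' @export
phase_difference <- function(wt1, wt2) {
  p1 <- .as_phasors(wt1); p2 <- .as_phasors(wt2)
  .check_pair_base(p1, p2)
  r <- .pair_resultant(p1, p2)
  coh <- Mod(r$resultant)
  delta <- Arg(r$resultant) * 180 / pi
  delta[coh < 1e-12] <- NA_real_
  structure(
    list(grid = p1$grid, delta_theta_deg = delta, coherence = pmin(coh, 1),
         pair_label = paste0(p1$channel_label, "~", p2$channel_label)),
    class = "sas_phasediff"
  )
}

#' Band-averaged coherence per physiological interval
#'
#' Unweighted mean of the per-frequency coherence over the grid points in
#' each half-open interval `(low, high]`; used for the interval-wise group
#' comparisons.
#'
#' @param curve A [wpco()] coherence curve.
#' @param intervals An interval table as from [sas_intervals()].
#' @return Named numeric vector, one value per interval.
#' @export
band_average_coherence <- function(curve, intervals = sas_intervals()) {
  stopifnot(inherits(curve, "sas_coherence"))
  f <- curve$grid$frequencies
  out <- vapply(seq_len(nrow(intervals)), function(i) {
    sel <- f > intervals$low[i] & f <= intervals$high[i]
    if (!any(sel))
      stop(sprintf("no grid frequencies inside interval %s",
                   intervals$interval[i]))
    mean(curve$coherence[sel])
  }, numeric(1))
  names(out) <- intervals$interval
  out
}
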