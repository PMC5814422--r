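#' Logarithmic frequency grid for wavelet analysis
#'
#' Frequencies are geometrically spaced with ratio `2^(1/voices_per_octave)`,
#' starting exactly at `fmin` and ending at the first grid point at or above
#' `fmax`. The default range 0.005-2 Hz spans the six physiological frequency
#' intervals of cardiovascular oscillations (cardiac down to NO-independent
#' endothelial activity).
#'
#' @param fmin,fmax Frequency range bounds in Hz, `0 < fmin < fmax`.
#' @param voices_per_octave Number of grid points per octave (>= 1,
#'   default 16; the default resolves the narrowest interval, VI, which
#'   spans about 0.93 octave, with ~15 points).
#' @return An object of class `sas_grid` with fields `frequencies`,
#'   `voices_per_octave`, `fmin`, `fmax`.
#' @examples
#' frequency_grid(0.5, 2, 1)$frequencies  # 0.5 1 2
#' @export
frequency_grid <- function(fmin = 0.005, fmax = 2, voices_per_octave = 16) {
  if (!is.finite(fmin) || !is.finite(fmax) || fmin <= 0 || fmin >= fmax)
    stop("invalid bounds: need 0 < fmin < fmax")
  if (voices_per_octave < 1) stop("voices_per_octave must be >= 1")
  k <- 0:ceiling(voices_per_octave * log2(fmax / fmin))
  structure(
    list(frequencies = fmin * 2^(k / voices_per_octave),
         voices_per_octave = voices_per_octave, fmin = fmin, fmax = fmax),
    class = "sas_grid"
  )
}

#' @export
print.sas_grid <- function(x, ...) {
  cat(sprintf("<sas_grid> %d frequencies, %g-%g Hz, %d voices/octave\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$voices_per_octave))
  invisible(x)
}

#' Highest reliably resolvable frequency at a given sampling rate
#'
#' The Nyquist bound: spectral content is only resolvable up to half the
#' sampling rate, e.g. 50 Hz for a 100 Hz recording.
#'
#' @param fs Sampling rate in Hz.
#' @return `fs / 2`, in Hz.
#' @export
max_reliable_frequency <- function(fs) {
  stopifnot(is.finite(fs), fs > 0)
  fs / 2
}

#' The six physiological frequency intervals
#'
#' Cardiovascular oscillations are conventionally partitioned into six
#' contiguous bands: I cardiac (0.6-2 Hz), II respiratory (0.145-0.6),
#' III myogenic (0.052-0.145), IV neurogenic (0.021-0.052), V NO-dependent
#' endothelial (0.0095-0.021), VI NO-independent endothelial (0.005-0.0095).
#' Each interval is the half-open band (low, high].
#'
#' @return A data frame with columns `interval`, `low`, `high`, ordered
#'   from highest (I) to lowest (VI) frequency.
#' @export
sas_intervals <- function() {
  data.frame(
    interval = c("I", "II", "III", "IV", "V", "VI"),
    low  = c(0.6, 0.145, 0.052, 0.021, 0.0095, 0.005),
    high = c(2, 0.6, 0.145, 0.052, 0.021, 0.0095),
    stringsAsFactors = FALSE
  )
}

#' Morlet mother wavelet
#'
#' `phi(u) = pi^(-1/4) * exp(-i 2 pi u) * exp(-u^2 / 2)`: a complex
#' exponential of unit frequency under a Gaussian envelope. With this
#' normalisation the scale-to-frequency mapping of the transform is exactly
#' `f = 1/s`.
#'
#' @param u Dimensionless time (numeric vector).
#' @return Complex vector of wavelet values.
#' @examples
#' morlet_mother(0)  # pi^(-1/4) ~ 0.7511
#' @export
morlet_mother <- function(u) {
  pi^(-0.25) * exp(-1i * 2 * pi * u) * exp(-0.5 * u^2)
}

# COI mask (TRUE = edge-affected): times within sqrt(2) * s of either record
# edge, the e-folding time of the Gaussian envelope at scale s.
.coi_mask <- function(frequencies, times) {
  t_end <- times[length(times)]
  outer(sqrt(2) / frequencies, times, function(w, tt) tt < w) |
    outer(sqrt(2) / frequencies, times, function(w, tt) tt > t_end - w)
}

#' Construct a wavelet-transform object
#'
#' Low-level constructor used by [morlet_cwt()] and useful for building
#' synthetic coefficient fields in calibration studies.
#'
#' @param coefficients Complex matrix, frequencies in rows, times in columns.
#' @param grid A [frequency_grid()] whose length matches `nrow(coefficients)`.
#' @param times Sample times in seconds, length `ncol(coefficients)`.
#' @param fs Sampling rate in Hz.
#' @param coi_mask Logical matrix of the same shape marking edge-affected
#'   cells; computed from the envelope e-folding time when omitted.
#' @param channel_label,subject_id Provenance labels.
#' @return An object of class `sas_wt`.
#' @export
wavelet_transform <- function(coefficients, grid, times, fs, coi_mask = NULL,
                              channel_label = "signal", subject_id = "subject") {
  stopifnot(inherits(grid, "sas_grid"), is.matrix(coefficients))
  if (nrow(coefficients) != length(grid$frequencies))
    stop("coefficient rows must match grid frequencies")
  if (ncol(coefficients) != length(times))
    stop("coefficient columns must match times")
  if (is.null(coi_mask)) coi_mask <- .coi_mask(grid$frequencies, times)
  stopifnot(identical(dim(coi_mask), dim(coefficients)))
  structure(
    list(coefficients = coefficients, grid = grid, times = times, fs = fs,
         coi_mask = coi_mask, channel_label = as.character(channel_label),
         subject_id = as.character(subject_id)),
    class = "sas_wt"
  )
}

#' @export
print.sas_wt <- function(x, ...) {
  cat(sprintf("<sas_wt> %s / %s: %d frequencies x %d times (%g-%g Hz)\n",
              x$subject_id, x$channel_label, nrow(x$coefficients),
              ncol(x$coefficients), min(x$grid$frequencies),
              max(x$grid$frequencies)))
  invisible(x)
}

#' Continuous Morlet wavelet transform
#'
#' Computes `W(s, t) = s^(-1/2) * integral phi((u - t)/s) g(u) du` for every
#' scale `s = 1/f` on the grid, discretising the integral by the trapezoid
#' rule at the sampling interval. The implementation evaluates the resulting
#' linear convolution exactly via zero-padded FFTs (the Gaussian kernel is
#' truncated at eight envelope standard deviations, below 1e-13 relative
#' amplitude), so it agrees with direct numerical integration to rounding
#' error. Cells within `sqrt(2) * s` of either record edge -- the cone of
#' influence, where the finite record attenuates the coefficients -- are
#' flagged in `coi_mask`.
#'
#' @param ts A preprocessed [time_series()].
#' @param grid A [frequency_grid()]; `max(frequencies)` must not exceed the
#'   Nyquist frequency `fs/2`, and the record must be longer than one full
#'   cone of influence (`2 * sqrt(2) / fmin` seconds) at the lowest frequency.
#' @return A [wavelet_transform()] (`sas_wt`).
#' @examples
#' ts <- time_series(sin(2 * pi * 1 * (0:5999) / 10), fs = 10)
#' wt <- morlet_cwt(ts, frequency_grid(0.1, 2, 8))
#' @export
morlet_cwt <- function(ts, grid) {
  stopifnot(inherits(ts, "sas_ts"), inherits(grid, "sas_grid"))
  fs <- ts$fs
  freqs <- grid$frequencies
  if (max(freqs) > max_reliable_frequency(fs))
    stop(sprintf("grid maximum %g Hz exceeds the Nyquist frequency %g Hz",
                 max(freqs), max_reliable_frequency(fs)))
  n <- length(ts$samples)
  smax <- 1 / min(freqs)
  if (n <= 2 * sqrt(2) * smax * fs)
    stop(sprintf(paste0("record too short for the lowest frequency: need more ",
                        "than %.0f samples (2*sqrt(2)*s*fs at s = %.0f s), have %d"),
                 2 * sqrt(2) * smax * fs, smax, n))
  dt <- 1 / fs
  # trapezoid weights on the integration variable u
  g <- ts$samples
  g[1L] <- g[1L] / 2
  g[n] <- g[n] / 2
  half_max <- min(ceiling(8 * smax * fs), n - 1L)
  m <- stats::nextn(n + 2L * half_max + 1L, c(2, 3, 5))
  G <- stats::fft(c(g, rep(0, m - n)))
  coef <- matrix(0i, nrow = length(freqs), ncol = n)
  for (k in seq_along(freqs)) {
    s <- 1 / freqs[k]
    half <- min(ceiling(8 * s * fs), n - 1L)
    j <- 1:half
    # circular layout of the reversed kernel phi(-j dt / s): W is then the
    # linear convolution g * rev(kernel), i.e. the cross-correlation with phi
    kr <- complex(length.out = m)
    kr[1L] <- morlet_mother(0)
    kr[1L + j] <- morlet_mother(-j * dt / s)
    kr[m + 1L - j] <- morlet_mother(j * dt / s)
    w <- stats::fft(G * stats::fft(kr), inverse = TRUE) / m
    coef[k, ] <- w[seq_len(n)] * (dt / sqrt(s))
  }
  wavelet_transform(coef, grid, sample_times(ts), fs,
                    channel_label = ts$channel_label,
                    subject_id = ts$subject_id)
}

#' Amplitude and phase fields of a wavelet transform
#'
#' Amplitude is the coefficient modulus `sqrt(a^2 + b^2)`; phase is the
#' two-argument arctangent `atan2(b, a)` in `(-pi, pi]`.
#'
#' @param wt A [wavelet_transform()].
#' @return A list with matrices `amplitude` and `phase`.
#' @export
amplitude_phase <- function(wt) {
  stopifnot(inherits(wt, "sas_wt"))
  list(amplitude = Mod(wt$coefficients), phase = Arg(wt$coefficients))
}

#' Time-averaged wavelet amplitude spectrum
#'
#' Averages the coefficient amplitude over time at each frequency, by default
#' excluding cells inside the cone of influence so that edge attenuation does
#' not bias the low-frequency end of the spectrum.
#'
#' @param wt A [wavelet_transform()].
#' @param exclude_coi Exclude edge-affected cells from the average
#'   (default TRUE).
#' @param squared Average `|W|^2` (wavelet power) instead of `|W|`
#'   (default FALSE: all interval comparisons use amplitude).
#' @return An object of class `sas_spectrum` with fields `grid`,
#'   `mean_amplitude`, `subject_id`, `channel_label`.
#' @export
time_averaged_amplitude <- function(wt, exclude_coi = TRUE, squared = FALSE) {
  stopifnot(inherits(wt, "sas_wt"))
  amp <- Mod(wt$coefficients)
  if (squared) amp <- amp^2
  if (exclude_coi) {
    amp[wt$coi_mask] <- NA_real_
    nv <- rowSums(!wt$coi_mask)
    if (any(nv == 0L))
      stop(sprintf(paste0("cone of influence covers the whole record at %g Hz; ",
                          "the record is too short for this frequency"),
                   wt$grid$frequencies[which(nv == 0L)[1L]]))
    ma <- rowMeans(amp, na.rm = TRUE)
  } else {
    ma <- rowMeans(amp)
  }
  structure(
    list(grid = wt$grid, mean_amplitude = ma, subject_id = wt$subject_id,
         channel_label = wt$channel_label),
    class = "sas_spectrum"
  )
}

#' @export
print.sas_spectrum <- function(x, ...) {
  cat(sprintf("<sas_spectrum> %s / %s: %d frequencies, peak %.3g AU at %.4g Hz\n",
              x$subject_id, x$channel_label, length(x$mean_amplitude),
              max(x$mean_amplitude),
              x$grid$frequencies[which.max(x$mean_amplitude)]))
  invisible(x)
}

#' @export
as.data.frame.sas_spectrum <- function(x, ...) {
  data.frame(subject_id = x$subject_id, channel = x$channel_label,
             frequency = x$grid$frequencies, mean_amplitude = x$mean_amplitude,
             stringsAsFactors = FALSE)
}

#' Mean spectral amplitude per physiological interval
#'
#' Unweighted mean of the time-averaged amplitude over the grid frequencies
#' falling inside each half-open interval `(low, high]`.
#'
#' @param spec A [time_averaged_amplitude()] spectrum.
#' @param intervals An interval table as from [sas_intervals()].
#' @return Named numeric vector, one value per interval.
#' @export
interval_summary <- function(spec, intervals = sas_intervals()) {
  stopifnot(inherits(spec, "sas_spectrum"))
  f <- spec$grid$frequencies
  out <- vapply(seq_len(nrow(intervals)), function(i) {
    sel <- f > intervals$low[i] & f <= intervals$high[i]
    if (!any(sel))
      stop(sprintf("no grid frequencies inside interval %s (%g-%g Hz)",
                   intervals$interval[i], intervals$low[i], intervals$high[i]))
    mean(spec$mean_amplitude[sel])
  }, numeric(1))
  names(out) <- intervals$interval
  out
}

# Topographic prominence of local maxima of y; returns indices and
# prominences. A local maximum must be strictly above both neighbours.
.peak_prominence <- function(y) {
  n <- length(y)
  if (n < 3L) return(list(idx = integer(0), prom = numeric(0)))
  idx <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] > y[3:n]) + 1L
  prom <- vapply(idx, function(i) {
    left <- y[1:(i - 1L)]
    higher_l <- which(left > y[i])
    base_l <- if (length(higher_l)) min(y[(max(higher_l) + 1L):(i - 1L)]) else
      min(left)
    right <- y[(i + 1L):n]
    higher_r <- which(right > y[i])
    base_r <- if (length(higher_r)) min(y[(i + 1L):(i + min(higher_r) - 1L)]) else
      min(right)
    y[i] - max(base_l, base_r)
  }, numeric(1))
  list(idx = idx, prom = prom)
}

#' Locate spectral peaks
#'
#' Finds local maxima of the time-averaged amplitude on the logarithmic
#' frequency grid whose topographic prominence is at least
#' `min_prominence_fraction` of the global maximum.
#'
#' @param spec A [time_averaged_amplitude()] spectrum.
#' @param min_prominence_fraction Prominence threshold as a fraction of the
#'   global maximum (default 0.05).
#' @return Numeric vector of peak frequencies in Hz, increasing; may be empty.
#' @export
detect_peaks <- function(spec, min_prominence_fraction = 0.05) {
  stopifnot(inherits(spec, "sas_spectrum"))
  pk <- .peak_prominence(spec$mean_amplitude)
  keep <- pk$prom >= min_prominence_fraction * max(spec$mean_amplitude)
  sort(spec$grid$frequencies[pk$idx[keep]])
}
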