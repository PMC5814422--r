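#' Specify one oscillatory mode of the synthetic generator
#'
#' Each mode is a frequency-wandering sinusoid living in one physiological
#' interval. Per subject, a centre frequency is drawn log-uniformly inside
#' the interval bounds (mimicking inter-subject peak scatter) and the mode's
#' instantaneous phase performs a random walk around the linear ramp, giving
#' the band-limited, time-varying oscillations wavelet analysis is built
#' for. Channels listed in `coupling_group` share one phase process --
#' centre frequency and wander realisation -- plus their fixed offsets, and
#' are therefore phase-locked; every other channel carrying the mode draws
#' its own centre frequency and its own wander, so uncoupled channels are
#' mismatched in exactly the way intersubject surrogate pairs are and
#' decohere over the record.
#'
#' @param interval Interval label ("I".."VI").
#' @param freq_range Length-2 numeric, (low, high) bounds in Hz for the
#'   per-subject centre-frequency draw; defaults to the interval's bounds.
#' @param amplitude Named numeric vector: oscillation amplitude (AU) per
#'   channel; channels absent (or 0) do not carry the mode.
#' @param phase_wander_sd Random-walk intensity in rad per sqrt(second).
#'   Defaults to `0.3 * sqrt(f_c)` with `f_c` the geometric centre of
#'   `freq_range`: phase diffusion per cycle is then frequency-independent,
#'   giving every mode the same fractional linewidth (about 1.5%, well
#'   inside one grid step at 16 voices per octave).
#' @param coupling_group Character vector of channels sharing the phase
#'   process (empty = no coupling).
#' @param offset_deg Named numeric vector of fixed phase offsets in degrees,
#'   in `(-180, 180]`, added per channel within the coupling group. A
#'   positive offset makes that channel lead.
#' @return An object of class `sas_mode`.
#' @export
mode_spec <- function(interval, amplitude, freq_range = NULL,
                      phase_wander_sd = NULL, coupling_group = character(),
                      offset_deg = numeric()) {
  iv <- sas_intervals()
  if (is.null(freq_range)) {
    row <- match(interval, iv$interval)
    if (is.na(row)) stop("unknown interval label: ", interval)
    freq_range <- c(iv$low[row], iv$high[row])
  }
  if (length(freq_range) != 2L || freq_range[1L] <= 0 ||
      freq_range[1L] > freq_range[2L])
    stop("freq_range must be (low, high) with 0 < low <= high")
  if (is.null(names(amplitude)) || any(amplitude < 0))
    stop("'amplitude' must be a named vector of non-negative values")
  if (length(offset_deg) &&
      (any(offset_deg <= -180) || any(offset_deg > 180)))
    stop("offsets must lie in (-180, 180] degrees")
  if (!all(coupling_group %in% names(amplitude)))
    stop("coupling_group contains channels with no amplitude entry")
  if (is.null(phase_wander_sd))
    phase_wander_sd <- 0.3 * sqrt(sqrt(prod(freq_range)))
  structure(
    list(interval = interval, freq_range = freq_range, amplitude = amplitude,
         phase_wander_sd = phase_wander_sd, coupling_group = coupling_group,
         offset_deg = offset_deg),
    class = "sas_mode"
  )
}

#' Specify a synthetic cohort
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param modes List of [mode_spec()] objects.
#' @param duration_s Record duration in seconds (default 1800: 30-minute
#'   resting-state recordings).
#' @param fs Sampling rate in Hz (default 10, the analysis rate).
#' @param noise_sd Standard deviation of the additive measurement noise, AU.
#' @param noise_model `"white"` (default: the simplest null consistent with
#'   the analysis assumptions) or `"one_over_f"` (power spectral density
#'   proportional to 1/f, same total variance).
#' @param seed Master seed; every subject derives an independent sub-seed
#'   from it, so the whole cohort is reproducible from this one integer.
#' @param age_range Cohort age span in years (default 18-42).
#' @return An object of class `sas_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, modes, duration_s = 1800, fs = 10,
                        noise_sd = 0.1, noise_model = c("white", "one_over_f"),
                        seed = 1, age_range = c(18, 42)) {
  noise_model <- match.arg(noise_model)
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  if (abs(duration_s * fs - round(duration_s * fs)) > 1e-9)
    stop("duration_s * fs must be an integer number of samples")
  if (!all(vapply(modes, inherits, logical(1), "sas_mode")))
    stop("'modes' must be a list of mode_spec() objects")
  channels <- unique(unlist(lapply(modes, function(m) names(m$amplitude))))
  structure(
    list(n_subjects = as.integer(n_subjects), modes = modes,
         duration_s = duration_s, fs = fs, noise_sd = noise_sd,
         noise_model = noise_model, seed = as.integer(seed),
         age_range = age_range, channels = channels),
    class = "sas_cohort_spec"
  )
}

# Spectrally shape a white-noise vector to power ~ 1/f (amplitude ~
# 1/sqrt(f)), preserving total variance; DC keeps the lowest-bin weight.
.shape_one_over_f <- function(x) {
  n <- length(x)
  f <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1))
  w <- 1 / sqrt(pmax(f, 1))
  y <- Re(stats::fft(stats::fft(x) * w, inverse = TRUE)) / n
  y * stats::sd(x) / stats::sd(y)
}

# Independent per-subject RNG stream, reproducible from the master seed.
.subject_seed <- function(seed, subject_index, salt = 0L) {
  as.integer((as.numeric(seed) * 1009 + subject_index * 7919 + salt * 104729)
             %% 2147483629)
}

#' A cohort specification mimicking resting-state BP/SAS structure
#'
#' Six modes, one per interval, with the qualitative amplitude ordering seen
#' in resting recordings: the BP channel is cardiac-dominant (interval-I
#' amplitude at least 3x every other BP mode), while the SAS channels
#' (TQ_LEFT, TQ_RIGHT) are endothelial-dominant (interval V-VI amplitudes at
#' least 3x their cardiac/respiratory amplitudes). Couplings: BP and both
#' SAS channels share phase in intervals I-III, with a +30 degree SAS lead
#' in the myogenic interval (III); the two SAS channels are additionally
#' phase-locked at zero lag through intervals IV and V; interval VI is
#' uncoupled everywhere.
#'
#' @param n_subjects Number of subjects (default 12).
#' @param seed Master seed.
#' @return A [cohort_spec()].
#' @export
default_resting_spec <- function(n_subjects = 12, seed = 1) {
  all3 <- c("BP", "TQ_LEFT", "TQ_RIGHT")
  sas2 <- c("TQ_LEFT", "TQ_RIGHT")
  amp <- function(bp, sas) c(BP = bp, TQ_LEFT = sas, TQ_RIGHT = sas)
  modes <- list(
    mode_spec("I",   amp(3.0, 0.3), coupling_group = all3),
    mode_spec("II",  amp(0.5, 0.3), coupling_group = all3),
    mode_spec("III", amp(0.3, 0.5), coupling_group = all3,
              offset_deg = c(TQ_LEFT = 30, TQ_RIGHT = 30)),
    mode_spec("IV",  amp(0.2, 0.6), coupling_group = sas2),
    mode_spec("V",   amp(0.15, 1.2), coupling_group = sas2),
    mode_spec("VI",  amp(0.1, 1.0))
  )
  cohort_spec(n_subjects, modes, seed = seed)
}

#' Generate one synthetic subject
#'
#' Each channel is the sum over modes of
#' `A * sin(2 pi f t + offset + B(t))` plus white noise, where `B(t)` is a
#' cumulative random-walk phase shared across the mode's coupling group and
#' drawn independently for every other channel. Fully deterministic given
#' `(spec$seed, subject_index)`; the global RNG state is left untouched.
#'
#' @param spec A [cohort_spec()].
#' @param subject_index Subject number, 1-based.
#' @return A [multi_channel_record()] with subject id `S01`, `S02`, ..., plus
#'   a `mode_frequencies` field (mode x channel matrix) recording the drawn
#'   centre frequencies (generator ground truth for recovery studies).
#' @export
generate_subject <- function(spec, subject_index) {
  stopifnot(inherits(spec, "sas_cohort_spec"))
  if (subject_index < 1 || subject_index > spec$n_subjects)
    stop("subject_index out of range")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(.subject_seed(spec$seed, subject_index))

  n <- as.integer(round(spec$duration_s * spec$fs))
  dt <- 1 / spec$fs
  t <- (0:(n - 1L)) * dt
  sig <- matrix(0, nrow = n, ncol = length(spec$channels),
                dimnames = list(NULL, spec$channels))
  mode_freqs <- matrix(
    NA_real_, nrow = length(spec$modes), ncol = length(spec$channels),
    dimnames = list(vapply(spec$modes, `[[`, character(1), "interval"),
                    spec$channels))
  for (mi in seq_along(spec$modes)) {
    m <- spec$modes[[mi]]
    draw_fc <- function()
      exp(stats::runif(1, log(m$freq_range[1L]), log(m$freq_range[2L])))
    wander_scale <- m$phase_wander_sd * sqrt(dt)
    # the shared phase process of the coupling group: 2 pi fc t + B(t);
    # channels outside the group get their own frequency AND their own walk,
    # so "uncoupled" means mismatched the way intersubject pairs are
    fc_group <- draw_fc()
    b_group <- cumsum(stats::rnorm(n, 0, wander_scale))
    for (ch in names(m$amplitude)) {
      a <- m$amplitude[[ch]]
      if (a <= 0) next
      if (ch %in% m$coupling_group) {
        fc <- fc_group
        b <- b_group
      } else {
        fc <- draw_fc()
        b <- cumsum(stats::rnorm(n, 0, wander_scale))
      }
      mode_freqs[mi, ch] <- fc
      off <- if (ch %in% names(m$offset_deg))
        m$offset_deg[[ch]] * pi / 180 else 0
      sig[, ch] <- sig[, ch] + a * sin(2 * pi * fc * t + off + b)
    }
  }
  if (spec$noise_sd > 0) {
    noise <- matrix(stats::rnorm(n * ncol(sig), 0, spec$noise_sd), nrow = n)
    if (identical(spec$noise_model, "one_over_f"))
      noise <- apply(noise, 2L, .shape_one_over_f)
    sig <- sig + noise
  }
  subject_id <- sprintf("S%02d", subject_index)
  channels <- lapply(colnames(sig), function(ch)
    time_series(sig[, ch], fs = spec$fs, channel_label = ch,
                subject_id = subject_id))
  names(channels) <- colnames(sig)
  rec <- multi_channel_record(channels, subject_id = subject_id)
  rec$mode_frequencies <- mode_freqs   # generator ground truth, for validation
  rec
}

#' Generate a full synthetic cohort
#'
#' Generates all subject records plus a metadata table. Ages are drawn to
#' straddle 25 years (half the cohort below, half at or above, shuffled);
#' sexes alternate male/female. When `dir` is given, each record is written
#' as `<subject_id>.csv` with a JSON sidecar carrying the sampling rate, and
#' the metadata as `metadata.csv`, in the same formats the readers consume.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory.
#' @return List with `records` (list of [multi_channel_record()]), `meta`
#'   (data frame: subject_id, age, sex), and `spec`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "sas_cohort_spec"))
  n <- spec$n_subjects
  records <- lapply(seq_len(n), function(i) generate_subject(spec, i))
  ids <- vapply(records, `[[`, character(1), "subject_id")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(.subject_seed(spec$seed, 0L, salt = 1L))
  n_young <- ceiling(n / 2)
  ages <- sample(c(
    sample(seq(spec$age_range[1L], 24), n_young, replace = TRUE),
    sample(seq(25, spec$age_range[2L]), n - n_young, replace = TRUE)))
  meta <- data.frame(
    subject_id = ids, age = ages,
    sex = rep_len(c("male", "female"), n), stringsAsFactors = FALSE)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (rec in records) {
      write_signal_table(rec, file.path(dir, paste0(rec$subject_id, ".csv")))
      write_sidecar(file.path(dir, paste0(rec$subject_id, ".json")),
                    fs = spec$fs, subject_id = rec$subject_id,
                    channels = names(rec$channels))
    }
    utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  }
  list(records = records, meta = meta, spec = spec)
}
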