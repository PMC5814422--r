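#' Assemble a pipeline configuration
#'
#' Collects every tunable of the analysis chain in one validated object:
#' preprocessing (detrend window, target rate), the frequency grid, the
#' surrogate percentile, the statistics gate, and the channel pairs with
#' their sign conventions (first channel = reference, so a positive phase
#' difference means the second channel leads).
#'
#' @param output_dir Directory for the result tables.
#' @param input_dir Directory holding `metadata.csv` plus per-subject
#'   `<subject_id>.csv` / `.json` sidecars; ignored when `simulate = TRUE`.
#' @param simulate Generate a synthetic cohort instead of reading records.
#' @param n_subjects Cohort size for simulation.
#' @param seed Master seed for simulation.
#' @param cohort Optional [cohort_spec()] overriding the default
#'   default resting-state generator spec.
#' @param window_s,target_fs Preprocessing parameters.
#' @param fmin,fmax,voices_per_octave Frequency-grid parameters.
#' @param exclude_coi Exclude cone-of-influence cells from time averages.
#' @param percentile Surrogate percentile for the significance threshold.
#' @param alpha,power Statistics gate parameters.
#' @param pairs List of 2-element character vectors (signal 1, signal 2).
#' @return An object of class `sas_config`.
#' @export
pipeline_config <- function(output_dir, input_dir = NULL, simulate = TRUE,
                            n_subjects = 12, seed = 1, cohort = NULL,
                            window_s = 120, target_fs = 10,
                            fmin = 0.005, fmax = 2, voices_per_octave = 16,
                            exclude_coi = TRUE, percentile = 95,
                            alpha = 0.05, power = 0.8,
                            pairs = list(c("BP", "TQ_LEFT"),
                                         c("BP", "TQ_RIGHT"),
                                         c("TQ_RIGHT", "TQ_LEFT"))) {
  if (!simulate && is.null(input_dir))
    stop("either set simulate = TRUE or provide input_dir")
  if (!all(vapply(pairs, length, integer(1)) == 2L))
    stop("each pair must name exactly two channels")
  structure(
    list(output_dir = output_dir, input_dir = input_dir, simulate = simulate,
         n_subjects = n_subjects, seed = seed, cohort = cohort,
         window_s = window_s, target_fs = target_fs, fmin = fmin, fmax = fmax,
         voices_per_octave = voices_per_octave, exclude_coi = exclude_coi,
         percentile = percentile, alpha = alpha, power = power, pairs = pairs),
    class = "sas_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the [pipeline_config()] arguments
#'   (`pairs` as a list of 2-element lists).
#' @return An `sas_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$pairs))
    cfg$pairs <- lapply(cfg$pairs, function(p) as.character(unlist(p)))
  do.call(pipeline_config, cfg)
}

.config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$cohort <- if (is.null(cfg$cohort)) "default_resting_spec" else
    "custom cohort_spec"
  yaml::as.yaml(cfg)
}

.config_hash <- function(echo) {
  b <- as.integer(charToRaw(echo))
  sprintf("%08x", sum(b * (seq_along(b) %% 251 + 1)) %% 2147483647)
}

.read_cohort_records <- function(input_dir) {
  meta <- read_cohort_metadata(file.path(input_dir, "metadata.csv"))
  records <- lapply(meta$subject_id, function(id) {
    sidecar <- file.path(input_dir, paste0(id, ".json"))
    if (!file.exists(sidecar)) stop("missing sidecar for subject ", id)
    sc <- read_sidecar(sidecar)
    read_signal_table(file.path(input_dir, paste0(id, ".csv")), fs = sc$fs,
                      subject_id = id)
  })
  list(records = records, meta = meta)
}

#' Run the full resting-state analysis pipeline
#'
#' Orchestrates simulate/load -> preprocess -> wavelet spectra -> interval
#' summaries -> phase coherence -> intersubject surrogates -> cohort
#' statistics, writing every stage as a tidy delimited table under
#' `config$output_dir` along with a run log echoing the configuration (the
#' echo plus the package version is sufficient to reproduce the bundle
#' byte-for-byte). A failure in any subject aborts with an error naming that
#' subject rather than silently dropping it.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a result bundle (class `sas_bundle`): per-subject
#'   spectra and interval summaries, per-pair coherence/phase-difference
#'   curves, surrogate thresholds and significance masks, cohort comparison
#'   tables, and the cohort table itself.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sas_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # ---- records -------------------------------------------------------------
  if (config$simulate) {
    spec <- if (!is.null(config$cohort)) config$cohort else
      default_resting_spec(config$n_subjects, seed = config$seed)
    sim <- generate_cohort(spec)
    records <- sim$records
    meta <- sim$meta
  } else {
    loaded <- .read_cohort_records(config$input_dir)
    records <- loaded$records
    meta <- loaded$meta
  }
  ids <- vapply(records, `[[`, character(1), "subject_id")
  channel_names <- names(records[[1L]]$channels)
  for (pr in config$pairs)
    if (!all(pr %in% channel_names))
      stop(sprintf("pair %s~%s references a channel absent from the records",
                   pr[1L], pr[2L]))

  # ---- preprocess ----------------------------------------------------------
  records <- lapply(records, function(rec)
    tryCatch(preprocess_record(rec, window_s = config$window_s,
                               target_fs = config$target_fs),
             error = function(e) stop(sprintf("subject %s: %s",
                                              rec$subject_id,
                                              conditionMessage(e)),
                                      call. = FALSE)))

  # ---- wavelet spectra & phase fields -------------------------------------
  grid <- frequency_grid(config$fmin, config$fmax, config$voices_per_octave)
  intervals <- sas_intervals()
  covered <- vapply(seq_len(nrow(intervals)), function(i)
    any(grid$frequencies > intervals$low[i] &
          grid$frequencies <= intervals$high[i]), logical(1))
  intervals <- intervals[covered, , drop = FALSE]
  fields <- list()
  spectra <- list()
  summaries <- list()
  for (rec in records) {
    id <- rec$subject_id
    for (ch in names(rec$channels)) {
      wt <- tryCatch(morlet_cwt(rec$channels[[ch]], grid),
                     error = function(e)
                       stop(sprintf("subject %s: %s", id, conditionMessage(e)),
                            call. = FALSE))
      spec <- time_averaged_amplitude(wt, exclude_coi = config$exclude_coi)
      spectra[[paste(id, ch)]] <- as.data.frame(spec)
      summaries[[paste(id, ch)]] <- data.frame(
        subject_id = id, channel = ch, interval = intervals$interval,
        mean_amplitude = unname(interval_summary(spec, intervals)),
        stringsAsFactors = FALSE)
      fields[[id]][[ch]] <- phase_field(wt)
    }
  }
  spectra <- do.call(rbind, c(spectra, make.row.names = FALSE))
  summaries <- do.call(rbind, c(summaries, make.row.names = FALSE))

  # ---- coherence, surrogates, significance --------------------------------
  coh_rows <- list()
  median_rows <- list()
  band_rows <- list()
  pair_results <- list()
  for (pr in config$pairs) {
    label <- paste0(pr[1L], "~", pr[2L])
    curves <- lapply(ids, function(id)
      wpco(fields[[id]][[pr[1L]]], fields[[id]][[pr[2L]]]))
    deltas <- lapply(ids, function(id)
      phase_difference(fields[[id]][[pr[1L]]], fields[[id]][[pr[2L]]]))
    med <- median_coherence(curves)
    surr <- surrogate_distribution(lapply(ids, function(id)
      fields[[id]][[pr[1L]]]), lapply(ids, function(id)
      fields[[id]][[pr[2L]]]))
    thr <- threshold_curve(surr, percentile = config$percentile)
    mask <- significant_mask(med, thr)
    # circular mean of the per-subject phase differences, cohort level
    delta_mat <- vapply(deltas, `[[`, numeric(length(grid$frequencies)),
                        "delta_theta_deg")
    z <- rowMeans(exp(1i * delta_mat * pi / 180), na.rm = TRUE)
    delta_med <- Arg(z) * 180 / pi

    for (k in seq_along(ids)) {
      coh_rows[[paste(label, ids[k])]] <- data.frame(
        subject_id = ids[k], pair = label,
        frequency = grid$frequencies, coherence = curves[[k]]$coherence,
        delta_theta_deg = deltas[[k]]$delta_theta_deg,
        n_valid = curves[[k]]$n_valid, stringsAsFactors = FALSE)
      band_rows[[paste(label, ids[k])]] <- data.frame(
        subject_id = ids[k], pair = label, interval = intervals$interval,
        coherence = unname(band_average_coherence(curves[[k]], intervals)),
        stringsAsFactors = FALSE)
    }
    median_rows[[label]] <- data.frame(
      pair = label, frequency = grid$frequencies,
      median_coherence = med$coherence, threshold = thr$threshold,
      significant = mask, delta_theta_deg = delta_med,
      stringsAsFactors = FALSE)
    pair_results[[label]] <- list(
      median = med, threshold = thr, mask = mask,
      interval_significant = interval_significance(mask, grid, intervals))
  }
  coherence <- do.call(rbind, c(coh_rows, make.row.names = FALSE))
  median_tbl <- do.call(rbind, c(median_rows, make.row.names = FALSE))
  bands <- do.call(rbind, c(band_rows, make.row.names = FALSE))

  # ---- cohort statistics ---------------------------------------------------
  sas_ch <- intersect(c("TQ_LEFT", "TQ_RIGHT"), channel_names)
  if (length(sas_ch) == 2L)
    meta$sas_correlation <- vapply(records, function(rec)
      sas_correlation(rec$channels[["TQ_LEFT"]], rec$channels[["TQ_RIGHT"]]),
      numeric(1))
  cohort <- cohort_table(meta, amplitude = summaries, coherence_bands = bands)

  contrasts <- Filter(function(pr) all(pr %in% intervals$interval),
                      list(c("I", "V"), c("I", "VI"),
                           c("II", "V"), c("II", "VI")))
  amp_cmp <- if (length(contrasts)) do.call(rbind, lapply(sas_ch, function(ch) {
    tab <- interval_amplitude_compare(cohort, ch, pairs = contrasts,
                                      alpha = config$alpha,
                                      power = config$power)
    cbind(channel = ch, tab, stringsAsFactors = FALSE)
  })) else NULL

  criteria <- c("age_25", "sex",
                if (!is.null(meta$sas_correlation)) "sas_correlation_median")
  grp_cmp <- list()
  for (crit in criteria) {
    split <- tryCatch(split_cohort(cohort, crit), error = function(e) NULL)
    if (is.null(split)) next
    for (label in unique(bands$pair)) {
      v <- bands[bands$pair == label, ]
      tab <- group_compare(v, split, "coherence", alpha = config$alpha,
                           power = config$power)
      grp_cmp[[paste(crit, label)]] <- cbind(
        criterion = crit, pair = label, tab, stringsAsFactors = FALSE)
    }
  }
  grp_cmp <- if (length(grp_cmp)) do.call(rbind, c(grp_cmp,
                                                   make.row.names = FALSE))
  else NULL

  # ---- outputs -------------------------------------------------------------
  wr <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(out, name), row.names = FALSE)
  wr(meta, "metadata.csv")
  wr(spectra, "spectra.csv")
  wr(summaries, "interval_summaries.csv")
  wr(coherence, "coherence.csv")
  wr(median_tbl, "median_coherence.csv")
  wr(bands, "coherence_bands.csv")
  wr(amp_cmp, "amplitude_comparisons.csv")
  wr(grp_cmp, "group_comparisons.csv")
  echo <- .config_echo(config)
  writeLines(c(
    sprintf("saswave %s | R %s.%s", as.character(utils::packageVersion("saswave")),
            R.version$major, R.version$minor),
    sprintf("config hash: %s", .config_hash(echo)),
    "config:", echo), file.path(out, "run_log.txt"))

  invisible(structure(
    list(config = config, grid = grid, meta = meta, spectra = spectra,
         interval_summaries = summaries, coherence = coherence,
         median_coherence = median_tbl, coherence_bands = bands,
         pair_results = pair_results, amplitude_comparisons = amp_cmp,
         group_comparisons = grp_cmp, cohort = cohort, output_dir = out),
    class = "sas_bundle"))
}

#' @export
print.sas_bundle <- function(x, ...) {
  cat(sprintf("<sas_bundle> %d subjects, %d pairs, outputs in %s\n",
              nrow(x$meta), length(x$pair_results), x$output_dir))
  for (label in names(x$pair_results)) {
    sig <- x$pair_results[[label]]$interval_significant
    cat(sprintf("  %s significant in: %s\n", label,
                if (any(sig)) paste(names(sig)[sig], collapse = ", ") else
                  "none"))
  }
  invisible(x)
}
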