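#' Study analysis configuration
#'
#' All constants of the end-to-end analysis in one place, with the
#' standard values as defaults: 600 s trailing analysis window, 10 Hz
#' analysis rate, 1200-point Welch segments with 60 s overlap and Hanning
#' taper, VLF/LF/HF bands, coherence validity threshold 0.4, and a 240 s
#' trailing mean for steady-state MCAv/MAP levels.
#'
#' @param welch A [welch_config()].
#' @param bands Band definitions, see [default_bands()].
#' @param coherence_threshold Band-coherence validity threshold
#'   (default 0.4).
#' @param window_s Trailing spectral-analysis window in seconds
#'   (default 600).
#' @param mean_window_s Trailing averaging window for steady-state levels
#'   in seconds (default 240).
#' @param target_rate Spectral analysis sampling rate in Hz (default 10).
#' @param exclusion_band Band whose coherence drives subject exclusion
#'   (default `"LF"`).
#' @return A list of class `study_config`.
#' @export
study_config <- function(welch = welch_config(), bands = default_bands(),
                         coherence_threshold = 0.4, window_s = 600,
                         mean_window_s = 240, target_rate = 10,
                         exclusion_band = "LF") {
  stopifnot(inherits(welch, "welch_config"))
  structure(
    list(welch = welch, bands = bands,
         coherence_threshold = coherence_threshold, window_s = window_s,
         mean_window_s = mean_window_s, target_rate = target_rate,
         exclusion_band = exclusion_band),
    class = "study_config"
  )
}

#' Analyse a single recording
#'
#' Runs the per-recording pipeline: trailing-window extraction,
#' resampling to the analysis rate, Welch cross-spectral estimation,
#' transfer function, and band averaging with the coherence validity
#' flag. Steady-state MCAv and MAP levels are taken as trailing means of
#' the unresampled recording.
#'
#' @param rec A [hemodynamic_recording()].
#' @param config A [study_config()].
#' @return A tibble with one row per band: recording metadata, `map_sp`,
#'   `mcav_sp`, `gain`, `normalised_gain`, `phase`, `coherence`, `valid`,
#'   plus `mcav_mean` and `map_mean`.
#' @export
analyze_recording <- function(rec, config = study_config()) {
  windowed <- extract_analysis_window(rec, config$window_s)
  analysed <- resample_to_analysis_rate(windowed, config$target_rate)
  est <- welch_cross_spectra(analysed$map, analysed$mcav, config$welch)
  bands <- band_average(est, bands = config$bands,
                        coherence_threshold = config$coherence_threshold)
  dplyr::mutate(
    dplyr::rename(bands, map_sp = "map_power", mcav_sp = "mcav_power"),
    subject_id = rec$subject_id, condition = rec$condition,
    intervention = rec$intervention,
    mcav_mean = segment_mean(rec, config$mean_window_s, channel = "mcav"),
    map_mean = segment_mean(rec, config$mean_window_s, channel = "map"),
    .before = 1L
  )
}

tfa_metrics <- c("map_sp", "mcav_sp", "gain", "normalised_gain", "phase",
                 "coherence")

paired_wilcoxon_row <- function(df, metric, key, value_a, value_b) {
  ia <- df[[key]] == value_a
  ib <- df[[key]] == value_b
  m <- match(df$subject_id[ia], df$subject_id[ib])
  keep <- !is.na(m)
  if (!any(keep)) return(NULL)
  a <- df[[metric]][ia][keep]
  b <- df[[metric]][ib][m[keep]]
  res <- tryCatch(
    wilcoxon_signed_rank(a, b),
    dcar_degenerate_sample = function(e) NULL
  )
  if (is.null(res)) {
    return(tibble::tibble(n = length(a), statistic = NA_real_,
                          p_raw = NA_real_))
  }
  tibble::tibble(n = res$n_effective + res$n_zero_dropped,
                 statistic = res$statistic, p_raw = res$p_value)
}

#' Run the full study analysis
#'
#' Orchestrates the whole pipeline over a cohort: per recording, the
#' trailing analysis window is extracted, resampled, Welch-analysed and
#' band-averaged; per subject and condition, oxygen vasoreactivity slopes
#' are computed from trailing four-minute means against the same-condition
#' normoxic reference; at cohort level, median-IQR summaries and paired
#' Wilcoxon comparisons (each intervention against its normoxic reference
#' within condition, and each intervention across conditions) are
#' assembled, with Holm adjustment applied within each comparison family
#' per band and metric.
#'
#' Any subject whose low-frequency band coherence falls below the
#' validity threshold in any recording is excluded from the
#' autoregulation summaries and comparisons (and logged), but retained in
#' the vasoreactivity analysis.
#'
#' @param x A `car_cohort` from [simulate_cohort()] or a layout from
#'   [read_study_layout()].
#' @param config A [study_config()].
#' @return An object of class `cohort_table`: list with `band_results`,
#'   `tfa_summary`, `comparisons`, `covr`, `covr_summary`,
#'   `covr_comparisons`, `exclusions`, `config` and `log`.
#' @export
run_study <- function(x, config = study_config()) {
  if (!inherits(x, c("car_cohort", "car_layout"))) {
    stop_dcar("`x` must be a simulated cohort or a study layout.",
              "dcar_invalid_config")
  }
  recordings <- x$recordings
  panels <- x$panels
  if (length(recordings) == 0L) {
    stop_dcar("The study layout contains no recordings.", "dcar_invalid_config")
  }

  band_results <- dplyr::bind_rows(
    lapply(recordings, analyze_recording, config = config)
  )

  # ---- exclusion on the coherence validity criterion (LF by default) ----
  excl_rows <- band_results[
    band_results$band == config$exclusion_band & !band_results$valid,
    c("subject_id", "condition", "intervention", "coherence")
  ]
  exclusions <- dplyr::mutate(
    excl_rows,
    reason = sprintf(
      "%s-band coherence %.2f below validity threshold %.2f",
      config$exclusion_band, .data$coherence, config$coherence_threshold
    )
  )
  excluded_subjects <- unique(exclusions$subject_id)
  band_results$included <- !(band_results$subject_id %in% excluded_subjects)
  included <- band_results[band_results$included, , drop = FALSE]

  # ---- cohort summaries (median + IQR over included subjects) ----
  tfa_summary <- if (nrow(included) > 0L) {
    long <- tidyr::pivot_longer(
      included[, c("band", "condition", "intervention", "subject_id",
                   tfa_metrics)],
      cols = dplyr::all_of(tfa_metrics),
      names_to = "metric", values_to = "value"
    )
    dplyr::summarise(
      dplyr::group_by(long, .data$band, .data$condition, .data$intervention,
                      .data$metric),
      n = dplyr::n(),
      median = median_iqr(.data$value)[["median"]],
      q1 = median_iqr(.data$value)[["q1"]],
      q3 = median_iqr(.data$value)[["q3"]],
      .groups = "drop"
    )
  } else {
    tibble::tibble(
      band = character(), condition = character(), intervention = character(),
      metric = character(), n = integer(), median = double(), q1 = double(),
      q3 = double()
    )
  }

  # ---- paired comparisons with Holm adjustment within each family ----
  interventions <- unique(band_results$intervention)
  comparisons <- list()
  for (b in unique(band_results$band)) {
    for (metric in tfa_metrics) {
      sub <- included[included$band == b, , drop = FALSE]
      if (nrow(sub) == 0L) next
      fam_within <- list()
      for (cond in c("baseline", "LPS")) {
        for (iv in setdiff(interventions, "normoxia")) {
          row <- paired_wilcoxon_row(
            sub[sub$condition == cond, , drop = FALSE], metric,
            "intervention", iv, "normoxia"
          )
          if (!is.null(row)) {
            fam_within[[paste(cond, iv)]] <- dplyr::mutate(
              row, band = b, metric = metric,
              family = "intervention_vs_normoxia",
              comparison = sprintf("%s: %s vs normoxia", cond, iv),
              .before = 1L
            )
          }
        }
      }
      fam_across <- list()
      for (iv in interventions) {
        row <- paired_wilcoxon_row(
          sub[sub$intervention == iv, , drop = FALSE], metric,
          "condition", "LPS", "baseline"
        )
        if (!is.null(row)) {
          fam_across[[iv]] <- dplyr::mutate(
            row, band = b, metric = metric, family = "lps_vs_baseline",
            comparison = sprintf("%s: LPS vs baseline", iv), .before = 1L
          )
        }
      }
      for (fam in list(fam_within, fam_across)) {
        if (length(fam) == 0L) next
        tab <- dplyr::bind_rows(fam)
        ok <- !is.na(tab$p_raw)
        tab$p_holm <- NA_real_
        if (any(ok)) tab$p_holm[ok] <- holm_adjust(tab$p_raw[ok])
        comparisons[[length(comparisons) + 1L]] <- tab
      }
    }
  }
  comparisons <- dplyr::bind_rows(comparisons)

  # ---- oxygen vasoreactivity (all subjects, including TFA exclusions) ----
  covr <- list()
  if (!is.null(panels) && nrow(panels) > 0L &&
      length(setdiff(interventions, "normoxia")) > 0L) {
    lf <- band_results[band_results$band == config$exclusion_band, , drop = FALSE]
    for (sid in unique(lf$subject_id)) {
      for (cond in c("baseline", "LPS")) {
        ref <- lf[lf$subject_id == sid & lf$condition == cond &
                    lf$intervention == "normoxia", , drop = FALSE]
        pref <- panels[panels$subject_id == sid & panels$condition == cond &
                         panels$intervention == "normoxia", , drop = FALSE]
        if (nrow(ref) != 1L || nrow(pref) != 1L) next
        for (iv in intersect(c("hyperoxia", "hypoxia"), interventions)) {
          test <- lf[lf$subject_id == sid & lf$condition == cond &
                       lf$intervention == iv, , drop = FALSE]
          ptest <- panels[panels$subject_id == sid & panels$condition == cond &
                            panels$intervention == iv, , drop = FALSE]
          if (nrow(test) != 1L || nrow(ptest) != 1L) next
          s_pao2 <- compute_covr(ref$mcav_mean, test$mcav_mean,
                                 pref$paO2_kPa, ptest$paO2_kPa,
                                 direction = iv)
          s_cao2 <- compute_covr_cao2(ref$mcav_mean, test$mcav_mean,
                                      pref$caO2_mM, ptest$caO2_mM,
                                      direction = iv)
          covr[[length(covr) + 1L]] <- tibble::tibble(
            subject_id = sid, condition = cond, direction = iv,
            slope_pao2 = s_pao2$slope, slope_cao2 = s_cao2$slope,
            mcav_ref = ref$mcav_mean, mcav_test = test$mcav_mean,
            pao2_ref = pref$paO2_kPa, pao2_test = ptest$paO2_kPa
          )
        }
      }
    }
  }
  covr <- dplyr::bind_rows(covr)

  covr_summary <- covr_comparisons <- tibble::tibble()
  if (nrow(covr) > 0L) {
    covr_summary <- dplyr::summarise(
      dplyr::group_by(covr, .data$condition, .data$direction),
      n = dplyr::n(),
      slope_pao2_median = median_iqr(.data$slope_pao2)[["median"]],
      slope_pao2_q1 = median_iqr(.data$slope_pao2)[["q1"]],
      slope_pao2_q3 = median_iqr(.data$slope_pao2)[["q3"]],
      slope_cao2_median = median_iqr(.data$slope_cao2)[["median"]],
      slope_cao2_q1 = median_iqr(.data$slope_cao2)[["q1"]],
      slope_cao2_q3 = median_iqr(.data$slope_cao2)[["q3"]],
      .groups = "drop"
    )
    rows <- list()
    for (slope_col in c("slope_pao2", "slope_cao2")) {
      fam <- list()
      for (iv in unique(covr$direction)) {
        row <- paired_wilcoxon_row(
          covr[covr$direction == iv, , drop = FALSE], slope_col,
          "condition", "LPS", "baseline"
        )
        if (!is.null(row)) {
          fam[[iv]] <- dplyr::mutate(
            row, metric = slope_col, family = "lps_vs_baseline",
            comparison = sprintf("%s COVR: LPS vs baseline", iv), .before = 1L
          )
        }
      }
      if (length(fam) > 0L) {
        tab <- dplyr::bind_rows(fam)
        ok <- !is.na(tab$p_raw)
        tab$p_holm <- NA_real_
        if (any(ok)) tab$p_holm[ok] <- holm_adjust(tab$p_raw[ok])
        rows[[slope_col]] <- tab
      }
    }
    covr_comparisons <- dplyr::bind_rows(rows)
  }

  log <- c(
    sprintf("n recordings: %d", length(recordings)),
    sprintf("welch: %d-point segments, %.0f s overlap, %s window, %g Hz",
            config$welch$segment_length, config$welch$overlap_s,
            config$welch$window, config$welch$sampling_rate),
    sprintf("analysis window: %g s; mean window: %g s", config$window_s,
            config$mean_window_s),
    sprintf("coherence threshold: %.2f on %s band", config$coherence_threshold,
            config$exclusion_band),
    sprintf("excluded subjects: %s",
            if (length(excluded_subjects) == 0L) "none" else
              paste(excluded_subjects, collapse = ", "))
  )

  structure(
    list(
      band_results = tibble::as_tibble(band_results),
      tfa_summary = tfa_summary, comparisons = comparisons,
      covr = covr, covr_summary = covr_summary,
      covr_comparisons = covr_comparisons,
      exclusions = tibble::as_tibble(exclusions),
      config = config, log = log
    ),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table>\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}

#' Write cohort result tables to disk
#'
#' Renders the components of a [run_study()] result as delimited tables
#' with a fixed column order: the band summaries (one block per requested
#' band, VLF/LF/HF order) with both machine-readable columns and a
#' formatted `median (q1-q3)` column, the per-recording band results, the
#' paired comparisons, the vasoreactivity tables and the exclusion log.
#' No value is recomputed here; every number is taken from the
#' `cohort_table`.
#'
#' @param table A `cohort_table` from [run_study()].
#' @param dir Output directory (created if missing).
#' @param bands Bands to render, in output order (default
#'   `c("VLF", "LF", "HF")`).
#' @param format Output format; only `"csv"` is provided.
#' @return Invisibly, the paths of the written files.
#' @export
render_tables <- function(table, dir, bands = c("VLF", "LF", "HF"),
                          format = "csv") {
  stopifnot(inherits(table, "cohort_table"))
  if (!identical(format, "csv")) {
    stop_dcar(sprintf("Unknown output format '%s'.", format),
              "dcar_invalid_config")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    paths[[name]] <<- path
  }

  summ <- table$tfa_summary[table$tfa_summary$band %in% bands, , drop = FALSE]
  summ$band <- factor(summ$band, levels = bands)
  summ <- summ[order(summ$band, summ$condition, summ$intervention,
                     summ$metric), , drop = FALSE]
  summ$band <- as.character(summ$band)
  summ$formatted <- sprintf("%.2f (%.2f-%.2f)", summ$median, summ$q1, summ$q3)
  emit(summ, "tfa_summary")

  br <- table$band_results[table$band_results$band %in% bands, , drop = FALSE]
  emit(br[, c("subject_id", "condition", "intervention", "band", "map_sp",
              "mcav_sp", "gain", "normalised_gain", "phase", "coherence",
              "valid", "included")], "band_results")

  if (nrow(table$comparisons) > 0L) {
    emit(table$comparisons[table$comparisons$band %in% bands, , drop = FALSE],
         "comparisons")
  }
  if (nrow(table$covr) > 0L) emit(table$covr, "covr")
  if (nrow(table$covr_summary) > 0L) emit(table$covr_summary, "covr_summary")
  if (nrow(table$covr_comparisons) > 0L) {
    emit(table$covr_comparisons, "covr_comparisons")
  }
  emit(table$exclusions, "exclusions")
  invisible(paths)
}
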