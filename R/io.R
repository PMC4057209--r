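#' Write a recording as delimited text
#'
#' Columns `time_s`, `map_mmHg`, `mcav_cm_s`.
#'
#' @param rec A [hemodynamic_recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path) {
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Expects a header `time_s,map_mmHg,mcav_cm_s`. The sampling rate is
#' inferred from the time column, which must be a uniform grid; gaps or
#' missing samples are an ingest error.
#'
#' @param path File path.
#' @param subject_id,condition,intervention Metadata attached to the
#'   recording.
#' @return A [hemodynamic_recording()].
#' @export
read_recording <- function(path, subject_id = NA_character_,
                           condition = NA_character_,
                           intervention = NA_character_) {
  df <- tryCatch(
    utils::read.csv(path),
    error = function(e) {
      stop_dcar(sprintf("Cannot parse recording file '%s': %s", path,
                        conditionMessage(e)), "dcar_ingest_error")
    }
  )
  required <- c("time_s", "map_mmHg", "mcav_cm_s")
  if (!all(required %in% names(df))) {
    stop_dcar(
      sprintf("Recording file '%s' must have columns %s.", path,
              paste(required, collapse = ", ")),
      "dcar_ingest_error"
    )
  }
  if (nrow(df) < 2L) {
    stop_dcar(sprintf("Recording file '%s' has fewer than 2 samples.", path),
              "dcar_ingest_error")
  }
  dt <- stats::median(diff(df$time_s))
  hemodynamic_recording(
    map = df$map_mmHg, mcav = df$mcav_cm_s, sampling_rate = 1 / dt,
    time = df$time_s, subject_id = subject_id, condition = condition,
    intervention = intervention
  )
}

#' Write a blood-gas panel as delimited text
#'
#' @param panel One-row tibble with columns `paO2_kPa`, `saO2_frac`,
#'   `paCO2_kPa`, `hb_mM`, `caO2_mM` (metadata columns are preserved).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_blood_gas_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' Read a blood-gas panel from delimited text
#'
#' @param path File path with header `paO2_kPa,saO2_frac,paCO2_kPa,hb_mM,caO2_mM`.
#' @return A tibble.
#' @export
read_blood_gas_panel <- function(path) {
  df <- tryCatch(
    utils::read.csv(path),
    error = function(e) {
      stop_dcar(sprintf("Cannot parse blood-gas file '%s': %s", path,
                        conditionMessage(e)), "dcar_ingest_error")
    }
  )
  required <- c("paO2_kPa", "saO2_frac", "paCO2_kPa", "hb_mM", "caO2_mM")
  if (!all(required %in% names(df))) {
    stop_dcar(
      sprintf("Blood-gas file '%s' must have columns %s.", path,
              paste(required, collapse = ", ")),
      "dcar_ingest_error"
    )
  }
  tibble::as_tibble(df)
}

#' Write a simulated cohort to a study directory
#'
#' Writes one recording file and one blood-gas file per study cell, a
#' `layout.yaml` describing the subject x condition x intervention grid,
#' and a `truth.yaml` sidecar holding the simulator's ground-truth
#' parameters (so recovery tests read, never re-derive, the truth).
#'
#' @param cohort A `car_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path of the layout file.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "car_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- list()
  for (key in names(cohort$recordings)) {
    rec <- cohort$recordings[[key]]
    rec_file <- paste0(key, ".csv")
    gas_file <- paste0(key, ".gases.csv")
    write_recording(rec, file.path(dir, rec_file))
    panel <- cohort$panels[
      cohort$panels$subject_id == rec$subject_id &
        cohort$panels$condition == rec$condition &
        cohort$panels$intervention == rec$intervention, , drop = FALSE
    ]
    write_blood_gas_panel(panel, file.path(dir, gas_file))
    cells[[length(cells) + 1L]] <- list(
      subject_id = rec$subject_id, condition = rec$condition,
      intervention = rec$intervention, recording = rec_file,
      blood_gas = gas_file
    )
  }
  layout_path <- file.path(dir, "layout.yaml")
  yaml::write_yaml(list(cells = cells), layout_path)
  yaml::write_yaml(
    lapply(seq_len(nrow(cohort$truth)), function(i) as.list(cohort$truth[i, ])),
    file.path(dir, "truth.yaml")
  )
  invisible(layout_path)
}

#' Read a study layout from disk
#'
#' Reads a `layout.yaml` (or the directory containing one) written by
#' [write_cohort()] or assembled by hand, loads every referenced
#' recording and blood-gas file, and returns an object accepted by
#' [run_study()]. Every referenced file must exist and parse.
#'
#' @param path Path to `layout.yaml` or its directory.
#' @return A list of class `car_layout` with `recordings` and `panels`.
#' @export
read_study_layout <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "layout.yaml")
  if (!file.exists(path)) {
    stop_dcar(sprintf("Layout file '%s' does not exist.", path),
              "dcar_ingest_error")
  }
  layout <- yaml::read_yaml(path)
  base <- dirname(path)
  if (length(layout$cells) == 0L) {
    stop_dcar("Layout contains no cells.", "dcar_ingest_error")
  }
  recordings <- list()
  panels <- list()
  for (cell in layout$cells) {
    rec_path <- file.path(base, cell$recording)
    gas_path <- file.path(base, cell$blood_gas)
    for (p in c(rec_path, gas_path)) {
      if (!file.exists(p)) {
        stop_dcar(sprintf("Referenced file '%s' does not exist.", p),
                  "dcar_ingest_error")
      }
    }
    key <- paste(cell$subject_id, cell$condition, cell$intervention, sep = ".")
    recordings[[key]] <- read_recording(
      rec_path, subject_id = cell$subject_id, condition = cell$condition,
      intervention = cell$intervention
    )
    panel <- read_blood_gas_panel(gas_path)
    panel$subject_id <- cell$subject_id
    panel$condition <- cell$condition
    panel$intervention <- cell$intervention
    panels[[key]] <- panel
  }
  structure(
    list(recordings = recordings, panels = dplyr::bind_rows(panels)),
    class = "car_layout"
  )
}
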