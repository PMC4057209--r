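#' Arterial oxygen content
#'
#' CaO2 (mM) = SaO2 (fraction) x haemoglobin (mM) + 0.01 x PaO2 (kPa):
#' haemoglobin-bound oxygen plus the small physically dissolved fraction.
#' Vectorised and linear in each argument.
#'
#' @param saO2 Arterial oxygen saturation as a fraction in \[0, 1\].
#' @param hb Haemoglobin concentration in mM (>= 0).
#' @param paO2 Arterial oxygen tension in kPa (>= 0).
#' @return Arterial oxygen content in mM.
#' @export
compute_cao2 <- function(saO2, hb, paO2) {
  if (any(!is.finite(saO2)) || any(saO2 < 0) || any(saO2 > 1)) {
    stop_dcar("`saO2` must be a fraction in [0, 1].", "dcar_validation_error")
  }
  if (any(!is.finite(hb)) || any(hb < 0) ||
      any(!is.finite(paO2)) || any(paO2 < 0)) {
    stop_dcar("`hb` and `paO2` must be finite and >= 0.", "dcar_validation_error")
  }
  saO2 * hb + 0.01 * paO2
}

covr_result <- function(slope, unit, predictor, direction) {
  delta_sign <- if (direction == "hyperoxia") 1 else -1
  pct <- slope * delta_sign # % MCAv change per unit *in the applied direction*
  reported <- sprintf(
    "%.2f%% %s in MCAv per %s %s in %s",
    abs(pct), if (pct > 0) "increase" else "decrease",
    sub("^%/", "", unit),
    if (delta_sign > 0) "increase" else "decrease", predictor
  )
  structure(
    list(direction = direction, slope = slope, unit = unit,
         predictor = predictor, reported_magnitude = reported),
    class = "covr_result"
  )
}

#' @export
print.covr_result <- function(x, ...) {
  cat(sprintf("<covr_result> %s: slope %.4f %s (%s)\n",
              x$direction, x$slope, x$unit, x$reported_magnitude))
  invisible(x)
}

covr_slope <- function(mcav_ref, mcav_test, pred_ref, pred_test, predictor,
                       unit, direction) {
  if (!is.finite(mcav_ref) || mcav_ref <= 0) {
    stop_dcar("Reference MCAv must be positive.", "dcar_validation_error")
  }
  d_pred <- pred_test - pred_ref
  if (!is.finite(d_pred) || d_pred == 0) {
    stop_dcar(
      sprintf("Zero %s change: the vasoreactivity slope is undefined.", predictor),
      "dcar_undefined_slope"
    )
  }
  if (is.null(direction)) {
    direction <- if (d_pred > 0) "hyperoxia" else "hypoxia"
  }
  slope <- 100 * (mcav_test - mcav_ref) / mcav_ref / d_pred
  covr_result(slope, unit, predictor, direction)
}

#' Cerebral oxygen vasoreactivity (PaO2 based)
#'
#' Percent change in MCAv (relative to the same-condition normoxic
#' reference, typically a trailing four-minute mean from
#' [segment_mean()]) per kPa change in PaO2. The slope is stored signed
#' (`100 * dMCAv / MCAv_ref / dPaO2`); because cerebral blood flow falls
#' when oxygen rises and vice versa, both the hyperoxic and the hypoxic
#' slope of a healthy subject are negative. The verbal rendering
#' (`reported_magnitude`) phrases the hypoxic response as a percent
#' increase per kPa decrease. Hyperoxic and hypoxic challenges are
#' assessed separately because the MCAv-PaO2 relation is nonlinear.
#'
#' @param mcav_ref Normoxic reference MCAv (cm/s, > 0).
#' @param mcav_test MCAv during the challenge (cm/s).
#' @param pao2_ref,pao2_test PaO2 at reference and during the challenge
#'   (kPa); must differ.
#' @param direction `"hyperoxia"` or `"hypoxia"`; inferred from the sign
#'   of the PaO2 change when `NULL`.
#' @return An object of class `covr_result` with elements `direction`,
#'   `slope` (%/kPa, signed), `unit`, `reported_magnitude`.
#' @export
compute_covr <- function(mcav_ref, mcav_test, pao2_ref, pao2_test,
                         direction = NULL) {
  covr_slope(mcav_ref, mcav_test, pao2_ref, pao2_test,
             predictor = "PaO2", unit = "%/kPa", direction = direction)
}

#' Cerebral oxygen vasoreactivity (CaO2 based)
#'
#' As [compute_covr()], but with arterial oxygen content (mM) as the
#' predictor: percent change in MCAv per mM change in CaO2.
#'
#' @param mcav_ref,mcav_test As in [compute_covr()].
#' @param cao2_ref,cao2_test Arterial oxygen content at reference and
#'   during the challenge (mM); must differ.
#' @param direction `"hyperoxia"` or `"hypoxia"`; inferred from the sign
#'   of the CaO2 change when `NULL`.
#' @return An object of class `covr_result` (slope in %/mM).
#' @export
compute_covr_cao2 <- function(mcav_ref, mcav_test, cao2_ref, cao2_test,
                              direction = NULL) {
  covr_slope(mcav_ref, mcav_test, cao2_ref, cao2_test,
             predictor = "CaO2", unit = "%/mM", direction = direction)
}
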