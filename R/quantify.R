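#' Tc-99m physical half-life, hours
#'
#' The scanner software's decay correction uses the physical half-life of the
#' radionuclide. The value is a physical constant, kept as an explicit,
#' overridable default on every function that needs it.
#' @export
TC99M_HALF_LIFE_H <- 6.0067

#' Radionuclide decay rate
#'
#' `lambda = 0.693 / half-life`, in inverse hours. The conventional clinical
#' formula uses the rounded constant 0.693 rather than `log(2)` (a relative
#' difference below 0.03%); pass `ln2 = TRUE` for the exact constant.
#'
#' @param half_life_h Half-life in hours, > 0.
#' @param ln2 Use `log(2)` instead of 0.693.
#' @return Decay rate in 1/h.
#' @export
#' @examples
#' decay_rate(6.0067)
decay_rate <- function(half_life_h, ln2 = FALSE) {
  if (!is.numeric(half_life_h) || length(half_life_h) != 1L ||
      !is.finite(half_life_h) || half_life_h <= 0)
    stop("half-life must be a positive finite number of hours")
  (if (ln2) log(2) else 0.693) / half_life_h
}

#' Lean body mass (James formula)
#'
#' `LBM = 1.07 W - 148 (W/H)^2` for females and `1.10 W - 120 (W/H)^2` for
#' males, with weight W in kg and height H in cm; result in kg.
#'
#' @param weight_kg Weight in kg, > 0.
#' @param height_cm Height in cm, > 0.
#' @param sex `"female"` or `"male"`.
#' @return Lean body mass in kg.
#' @export
#' @examples
#' lean_body_mass(70, 170, "female")  # 49.81 kg
lean_body_mass <- function(weight_kg, height_cm, sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    stop("weight and height must be strictly positive")
  r2 <- (weight_kg / height_cm)^2
  lbm <- if (sex == "female") 1.07 * weight_kg - 148 * r2
         else                 1.10 * weight_kg - 120 * r2
  if (any(lbm <= 0))
    stop(sprintf(
      "lean body mass is non-positive (%.2f kg) for weight %.1f kg, height %.1f cm, sex %s",
      min(lbm), weight_kg[which.min(lbm)], height_cm[which.min(lbm)], sex))
  lbm
}

#' Decay-corrected net injected activity
#'
#' Reconstructs the activity actually delivered to the patient, decayed to
#' scan time, from the syringe assays and the injection chronology:
#' \deqn{decay1 = e^{\lambda (t_{measured} - t_{administered})}}
#' \deqn{decay2 = e^{\lambda (t_{post} - t_{measured})}}
#' \deqn{decay_{scan} = e^{\lambda (t_{administered} - t_{scan})}}
#' \deqn{actual = decay_{scan} \cdot decay1 \cdot
#'   (A_{pre} - decay2 \cdot A_{post})}
#' with time differences in hours. `decay1` forward-decays the pre-injection
#' assay to injection time, `decay2` back-decays the residual assay to the
#' assay time of the full syringe (so `decay1 * decay2 * A_post` is the
#' residual at injection time), and `decay_scan` carries the net activity to
#' scan time. Algebraically this equals
#' `(A_pre e^{-lambda dt_pre} - A_post e^{+lambda dt_post}) e^{-lambda dt_scan}`
#' with the three intervals measured from injection.
#'
#' @param patient A [patient_record].
#' @param half_life_h Radionuclide half-life in hours.
#' @param ln2 Passed to [decay_rate()].
#' @return A list of class `decay_correction` with elements `lam`, `decay1`,
#'   `decay2`, `decay_scan` and `actual_activity_mbq`.
#' @export
decay_correction <- function(patient, half_life_h = TC99M_HALF_LIFE_H,
                             ln2 = FALSE) {
  stopifnot(inherits(patient, "patient_record"))
  lam <- decay_rate(half_life_h, ln2 = ln2)
  decay1 <- exp(lam * hours_between(patient$administered_time,
                                    patient$measured_time))
  decay2 <- exp(lam * hours_between(patient$measured_time,
                                    patient$post_injection_time))
  decay_scan <- exp(lam * hours_between(patient$scan_time,
                                        patient$administered_time))
  actual <- decay_scan * decay1 *
    (patient$pre_injection_activity_mbq -
       decay2 * patient$post_injection_activity_mbq)
  if (!is.finite(actual) || actual <= 0)
    stop("patient ", patient$patient_id,
         ": decay-corrected net activity is not positive ",
         "(residual exceeds the measured activity after correction)")
  structure(list(lam = lam, decay1 = decay1, decay2 = decay2,
                 decay_scan = decay_scan, actual_activity_mbq = actual),
            class = "decay_correction")
}

#' Convert an activity concentration to SUVlbm
#'
#' `SUV = C * LBM * 1000 / A` with the concentration C in Bq/mL, lean body
#' mass in kg (the factor 1000 converts it to g) and the decay-corrected
#' actual activity A in Bq. Units g/mL.
#'
#' @param conc_bq_ml Activity concentration(s), Bq/mL, >= 0.
#' @param lbm_kg Lean body mass, kg, > 0.
#' @param actual_activity_mbq Decay-corrected net injected activity, MBq, > 0.
#' @return SUVlbm value(s), g/mL.
#' @export
#' @examples
#' suv_from_concentration(30000, 49.81, 476.6)
suv_from_concentration <- function(conc_bq_ml, lbm_kg, actual_activity_mbq) {
  if (actual_activity_mbq <= 0) stop("actual activity must be > 0 MBq")
  if (lbm_kg <= 0) stop("lean body mass must be > 0 kg")
  if (any(conc_bq_ml < 0)) stop("activity concentrations must be >= 0")
  conc_bq_ml * lbm_kg * 1000 / (actual_activity_mbq * 1e6)
}

#' Voxelwise SUVlbm volume from an activity volume
#'
#' Applies [suv_from_concentration()] to every voxel, with the lean body mass
#' and decay-corrected activity of the given patient. Shape, spacing and
#' origin are preserved.
#'
#' @param vol An [activity_volume()] (grid in Bq/mL).
#' @param patient A [patient_record].
#' @param half_life_h Radionuclide half-life in hours.
#' @param ln2 Passed to [decay_rate()].
#' @return An object of class `suv_volume` (grid in g/mL) carrying
#'   `patient_id`.
#' @export
suv_volume <- function(vol, patient, half_life_h = TC99M_HALF_LIFE_H,
                       ln2 = FALSE) {
  stopifnot(inherits(vol, "activity_volume"), inherits(patient, "patient_record"))
  dc <- decay_correction(patient, half_life_h = half_life_h, ln2 = ln2)
  lbm <- lean_body_mass(patient$weight_kg, patient$height_cm, patient$sex)
  grid <- suv_from_concentration(vol$grid, lbm, dc$actual_activity_mbq)
  dim(grid) <- dim(vol$grid)
  structure(list(grid = grid, spacing_mm = vol$spacing_mm,
                 origin_mm = vol$origin_mm, patient_id = patient$patient_id),
            class = "suv_volume")
}
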