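#' Patient record for SUV quantification
#'
#' Bundles the per-patient inputs needed to decay-correct the injected
#' activity and normalize uptake by lean body mass: body metrics, the syringe
#' activities measured before and after injection, and the four timestamps of
#' the injection/measurement chronology.
#'
#' Timestamps are wall-clock (single time zone, minute resolution) and must
#' satisfy `measured_time <= administered_time <= post_injection_time <=
#' scan_time`: the full syringe is assayed first, the residual afterwards,
#' and the scan comes last.
#'
#' @param patient_id Identifier string.
#' @param sex `"female"` or `"male"` (selects the lean-body-mass formula).
#' @param weight_kg Body weight in kg, > 0.
#' @param height_cm Body height in cm, > 0.
#' @param pre_injection_activity_mbq Activity assayed in the full syringe
#'   ("measure activity"), MBq.
#' @param post_injection_activity_mbq Residual activity left in the syringe
#'   after injection, MBq; must be below the pre-injection activity.
#' @param measured_time,administered_time,post_injection_time,scan_time
#'   Timestamps, either `POSIXct` or ISO-8601 strings `"YYYY-MM-DDThh:mm"`.
#' @param age_years Optional age in years (metadata only, not used in any
#'   computation).
#'
#' @return An object of class `patient_record`.
#' @export
#' @examples
#' patient_record("P01", "female", 70, 170,
#'   pre_injection_activity_mbq = 700, post_injection_activity_mbq = 20,
#'   measured_time = "2021-03-01T09:00", administered_time = "2021-03-01T09:05",
#'   post_injection_time = "2021-03-01T09:10", scan_time = "2021-03-01T12:05")
patient_record <- function(patient_id, sex, weight_kg, height_cm,
                           pre_injection_activity_mbq,
                           post_injection_activity_mbq,
                           measured_time, administered_time,
                           post_injection_time, scan_time,
                           age_years = NA_real_) {
  sex <- match.arg(sex, c("female", "male"))
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  if (!is.numeric(weight_kg) || weight_kg <= 0)
    stop("patient ", patient_id, ": weight must be > 0 kg")
  if (!is.numeric(height_cm) || height_cm <= 0)
    stop("patient ", patient_id, ": height must be > 0 cm")
  if (pre_injection_activity_mbq <= post_injection_activity_mbq)
    stop("patient ", patient_id,
         ": pre-injection activity must exceed the residual")
  if (post_injection_activity_mbq < 0)
    stop("patient ", patient_id, ": residual activity must be >= 0")

  tm <- parse_suv_time(measured_time)
  ta <- parse_suv_time(administered_time)
  tp <- parse_suv_time(post_injection_time)
  ts <- parse_suv_time(scan_time)
  if (!(tm <= ta && ta <= tp && tp <= ts))
    stop("patient ", patient_id, ": timestamps must be ordered ",
         "measured <= administered <= post-injection <= scan")

  structure(
    list(patient_id = patient_id, sex = sex,
         weight_kg = as.numeric(weight_kg),
         height_cm = as.numeric(height_cm),
         age_years = as.numeric(age_years),
         pre_injection_activity_mbq = as.numeric(pre_injection_activity_mbq),
         post_injection_activity_mbq = as.numeric(post_injection_activity_mbq),
         measured_time = tm, administered_time = ta,
         post_injection_time = tp, scan_time = ts),
    class = "patient_record")
}

parse_suv_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M", tz = "UTC")
  if (any(is.na(out)))
    stop("timestamp not in ISO-8601 'YYYY-MM-DDThh:mm' format: ",
         paste(x[is.na(out)], collapse = ", "))
  out
}

hours_between <- function(from, to) {
  as.numeric(difftime(to, from, units = "hours"))
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s: %s, %.1f kg, %.1f cm>\n",
              x$patient_id, x$sex, x$weight_kg, x$height_cm))
  cat(sprintf("  activity %.1f MBq (residual %.1f), injected %s, scan %s\n",
              x$pre_injection_activity_mbq, x$post_injection_activity_mbq,
              format(x$administered_time, "%H:%M"),
              format(x$scan_time, "%H:%M")))
  invisible(x)
}

#' Read patient records from CSV or YAML
#'
#' The CSV has one row per patient with columns `patient_id, sex, weight_kg,
#' height_cm, age_years, pre_injection_activity_mbq,
#' post_injection_activity_mbq, measured_time, administered_time,
#' post_injection_time, scan_time` (timestamps ISO-8601
#' `"YYYY-MM-DDThh:mm"`). A YAML file holds a list of records with the same
#' field names.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` vs CSV).
#' @return A named list of [patient_record] objects.
#' @export
read_patients <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rows <- if (ext %in% c("yaml", "yml")) {
    lapply(yaml::read_yaml(path), as.data.frame)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    split(df, seq_len(nrow(df)))
  }
  recs <- lapply(rows, function(r) {
    patient_record(r$patient_id, r$sex, r$weight_kg, r$height_cm,
                   r$pre_injection_activity_mbq, r$post_injection_activity_mbq,
                   r$measured_time, r$administered_time,
                   r$post_injection_time, r$scan_time,
                   age_years = if (!is.null(r$age_years)) r$age_years else NA_real_)
  })
  names(recs) <- vapply(recs, `[[`, "", "patient_id")
  recs
}

#' Write patient records to CSV
#'
#' @param patients List of [patient_record] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patients_csv <- function(patients, path) {
  df <- do.call(rbind, lapply(patients, function(p) {
    data.frame(patient_id = p$patient_id, sex = p$sex,
               weight_kg = p$weight_kg, height_cm = p$height_cm,
               age_years = p$age_years,
               pre_injection_activity_mbq = p$pre_injection_activity_mbq,
               post_injection_activity_mbq = p$post_injection_activity_mbq,
               measured_time = format(p$measured_time, "%Y-%m-%dT%H:%M"),
               administered_time = format(p$administered_time, "%Y-%m-%dT%H:%M"),
               post_injection_time = format(p$post_injection_time, "%Y-%m-%dT%H:%M"),
               scan_time = format(p$scan_time, "%Y-%m-%dT%H:%M"))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
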