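#' Quantify lesions from activity volumes
#'
#' Chains the voxel pipeline per patient: activity volume -> SUVlbm volume ->
#' iterative global-maximum lesion extraction -> cohort lesion table rows.
#' Category and region labels are taken from a sidecar label table matched by
#' patient and per-patient lesion rank (lesions are ranked by decreasing
#' SUVmax, as they are extracted); lesions with no label row are emitted with
#' category `"unlabeled"` and a warning.
#'
#' @param volumes Named list of [activity_volume()] objects, names =
#'   patient IDs.
#' @param patients Named list of [patient_record()] objects.
#' @param labels Optional data frame `patient_id, rank, category, region`
#'   assigning a label to the rank-th hottest lesion of a patient.
#' @param k_max,frac,radius_mm,exclusion_radius_mm,floor_suv Passed to
#'   [extract_lesions()].
#' @param half_life_h Radionuclide half-life, hours.
#' @return Cohort lesion table (data frame: `patient_id, lesion_id, category,
#'   region, suv_max, seed_i, seed_j, seed_k`; seed indices 0-based).
#' @export
run_quantify <- function(volumes, patients, labels = NULL, k_max = 5,
                         frac = 0.40, radius_mm = 15,
                         exclusion_radius_mm = 15, floor_suv = NULL,
                         half_life_h = TC99M_HALF_LIFE_H) {
  if (length(volumes) == 0) {
    warning("no volumes supplied; returning an empty lesion table")
    return(empty_lesion_table())
  }
  stopifnot(!is.null(names(volumes)))
  rows <- lapply(names(volumes), function(pid) {
    if (is.null(patients[[pid]]))
      stop("no patient record for volume '", pid, "'")
    sv <- suv_volume(volumes[[pid]], patients[[pid]],
                     half_life_h = half_life_h)
    vois <- extract_lesions(sv, k_max = k_max, frac = frac,
                            radius_mm = radius_mm,
                            exclusion_radius_mm = exclusion_radius_mm,
                            floor_suv = floor_suv)
    if (length(vois) == 0) return(empty_lesion_table())
    df <- data.frame(
      patient_id = pid,
      lesion_id = sprintf("%s_V%02d", pid, seq_along(vois)),
      category = "unlabeled", region = "O",
      suv_max = vapply(vois, `[[`, 0, "suv_max"),
      seed_i = vapply(vois, function(v) v$seed[1], 0L) - 1L,
      seed_j = vapply(vois, function(v) v$seed[2], 0L) - 1L,
      seed_k = vapply(vois, function(v) v$seed[3], 0L) - 1L,
      stringsAsFactors = FALSE)
    if (!is.null(labels)) {
      lab <- labels[labels$patient_id == pid, , drop = FALSE]
      m <- match(seq_len(nrow(df)), lab$rank)
      df$category <- ifelse(is.na(m), "unlabeled", lab$category[m])
      df$region <- ifelse(is.na(m), "O", lab$region[m])
    }
    df
  })
  out <- do.call(rbind, rows)
  if (any(out$category == "unlabeled"))
    warning(sum(out$category == "unlabeled"),
            " extracted lesion(s) have no label; category set to 'unlabeled'")
  rownames(out) <- NULL
  out
}

empty_lesion_table <- function() {
  data.frame(patient_id = character(), lesion_id = character(),
             category = character(), region = character(),
             suv_max = numeric(), seed_i = integer(), seed_j = integer(),
             seed_k = integer(), stringsAsFactors = FALSE)
}

#' Full cohort statistical analysis
#'
#' Runs the analysis stages in order on a cohort lesion table: per-category
#' summaries, region distribution, Shapiro-Wilk normality per category,
#' Mann-Whitney comparison, empirical ROC with DeLong interval, the
#' Youden-optimal SUVmax cut-off, per-category bin breakdowns and the
#' overlap range. Rows with category `"unlabeled"` are dropped (with a
#' message stating how many).
#'
#' @param lesions Cohort lesion table with `category` in
#'   \{"metastatic", "degenerative"\} (plus optional `"unlabeled"`),
#'   `region`, `suv_max`.
#' @param seed Provenance only: the seed the table was generated under, if
#'   any.
#' @return List of class `analysis_report` (see the JSON schema shipped in
#'   `inst/extdata/report-schema.json`).
#' @export
run_analyze <- function(lesions, seed = NULL) {
  n_unlab <- sum(lesions$category == "unlabeled")
  if (n_unlab > 0) {
    message("dropping ", n_unlab, " unlabeled lesion(s)")
    lesions <- lesions[lesions$category != "unlabeled", , drop = FALSE]
  }
  met <- lesions$suv_max[lesions$category == "metastatic"]
  deg <- lesions$suv_max[lesions$category == "degenerative"]
  if (length(met) == 0 || length(deg) == 0)
    stop("analysis needs both metastatic and degenerative lesions")

  scores <- c(met, deg)
  labs <- rep(c(TRUE, FALSE), c(length(met), length(deg)))
  roc <- empirical_roc(scores, labs)
  ci <- auc_ci(scores, labs)
  mw <- mann_whitney(met, deg)
  cut <- youden_cutoff(roc)
  ov <- overlap_range(met, deg)

  structure(list(
    summaries = list(metastatic = suv_summary(met),
                     degenerative = suv_summary(deg)),
    regions = region_distribution(lesions),
    normality = list(
      metastatic = if (length(met) >= 3) shapiro_wilk(met) else NULL,
      degenerative = if (length(deg) >= 3) shapiro_wilk(deg) else NULL),
    mann_whitney = mw,
    roc = list(auc = roc$auc, ci_low = ci$ci_low, ci_high = ci$ci_high,
               n_pos = roc$n_pos, n_neg = roc$n_neg,
               points = roc$points),
    cutoff = unclass(cut),
    bins = list(metastatic = bin_breakdown(met),
                degenerative = bin_breakdown(deg)),
    overlap = ov,
    provenance = list(
      seed = seed, n_unlabeled_dropped = n_unlab,
      package = "spectsuv",
      version = as.character(utils::packageVersion("spectsuv")))),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  s <- x$summaries
  cat(sprintf("Cohort analysis: %d metastatic, %d degenerative lesions\n",
              s$metastatic$n, s$degenerative$n))
  cat(sprintf("  SUVmax metastatic   %.2f +/- %.2f [%.2f, %.2f]\n",
              s$metastatic$mean, s$metastatic$sd, s$metastatic$min,
              s$metastatic$max))
  cat(sprintf("  SUVmax degenerative %.2f +/- %.2f [%.2f, %.2f]\n",
              s$degenerative$mean, s$degenerative$sd, s$degenerative$min,
              s$degenerative$max))
  cat(sprintf("  Mann-Whitney U = %.1f, p = %.3g\n",
              x$mann_whitney$U, x$mann_whitney$p_value))
  cat(sprintf("  AUC = %.3f (95%% CI %.3f-%.3f)\n",
              x$roc$auc, x$roc$ci_low, x$roc$ci_high))
  cat(sprintf("  Cut-off SUVmax > %.2f g/mL: sens %.1f%%, spec %.1f%%\n",
              x$cutoff$threshold, 100 * x$cutoff$sensitivity,
              100 * x$cutoff$specificity))
  cat(sprintf("  Overlap range [%.2f, %.2f]: %.1f%% of lesions inside\n",
              x$overlap$low, x$overlap$high, 100 * x$overlap$fraction_inside))
  invisible(x)
}

#' Write / read an analysis report as JSON
#'
#' The written report validates against the schema shipped in
#' `inst/extdata/report-schema.json` (checked by [check_report()]).
#'
#' @param report An [run_analyze()] result.
#' @param path Output JSON path.
#' @return `write_report_json` returns `path` invisibly; `read_report_json`
#'   returns the report list.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(rep, class = "analysis_report")
}

#' Validate an analysis report against the shipped schema
#'
#' Checks the presence and JSON type of every required field declared in
#' `inst/extdata/report-schema.json`.
#'
#' @param report An `analysis_report` (or a list read from JSON).
#' @return `TRUE` invisibly; errors name the first violated field.
#' @export
check_report <- function(report) {
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "spectsuv"))
  for (field in unlist(schema$required)) {
    if (is.null(report[[field]]))
      stop("report is missing required field '", field, "'")
  }
  num_leaves <- c(report$roc$auc, report$roc$ci_low, report$roc$ci_high,
                  report$mann_whitney$U, report$mann_whitney$p_value,
                  report$cutoff$threshold, report$cutoff$sensitivity,
                  report$cutoff$specificity,
                  unlist(report$summaries, use.names = FALSE))
  if (!all(is.finite(num_leaves)))
    stop("report contains non-finite numeric fields")
  invisible(TRUE)
}

#' Write ROC coordinates to CSV
#'
#' @param report An `analysis_report`.
#' @param path Output CSV path.
#' @export
write_roc_csv <- function(report, path) {
  utils::write.csv(report$roc$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
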