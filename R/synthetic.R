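#' Moments of a truncated lognormal distribution
#'
#' Mean and sd of a lognormal(`mu`, `sigma`) restricted to `[lo, hi]`,
#' evaluated in closed form through the normal CDF:
#' \deqn{E[X^k] = e^{k\mu + k^2\sigma^2/2}
#'   \frac{\Phi(b - k\sigma) - \Phi(a - k\sigma)}{\Phi(b) - \Phi(a)}}
#' with `a = (log lo - mu)/sigma`, `b = (log hi - mu)/sigma`.
#'
#' @param mu,sigma Log-space location and scale (`sigma > 0`).
#' @param lo,hi Truncation bounds, `0 < lo < hi`.
#' @return Named vector `c(mean, sd)`.
#' @export
trunc_lnorm_moments <- function(mu, sigma, lo, hi) {
  stopifnot(sigma > 0, lo > 0, lo < hi)
  a <- (log(lo) - mu) / sigma
  b <- (log(hi) - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  m1 <- exp(mu + sigma^2 / 2) *
    (stats::pnorm(b - sigma) - stats::pnorm(a - sigma)) / z
  m2 <- exp(2 * mu + 2 * sigma^2) *
    (stats::pnorm(b - 2 * sigma) - stats::pnorm(a - 2 * sigma)) / z
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

#' Calibrate a truncated lognormal to target moments
#'
#' Finds log-space parameters (`mu`, `sigma`) such that the lognormal
#' truncated to `[lo, hi]` has the requested mean and sd, to 1e-6 relative.
#' Initialized from the closed-form untruncated moment match
#' `sigma^2 = log(1 + (s/m)^2)`, `mu = log(m) - sigma^2/2`, then refined by
#' Nelder-Mead on the squared relative moment residuals.
#'
#' The lesion SUVmax generator for each category is calibrated this way to
#' the published cohort summary (mean, sd, min, max); a right-skewed,
#' range-bounded family is used because the clinical SUVmax samples are
#' non-normal and right-skewed with hard observed ranges.
#'
#' @param target_mean,target_sd Target moments on the truncated scale, g/mL.
#' @param lo,hi Truncation bounds, g/mL (`lo < target_mean < hi`).
#' @return Object of class `trunc_lnorm_params`: `mu`, `sigma`, `lo`, `hi`,
#'   plus the achieved `mean` and `sd`.
#' @export
#' @examples
#' fit_truncated_lognormal(32.56, 16.39, 10.90, 130.70)
fit_truncated_lognormal <- function(target_mean, target_sd, lo, hi) {
  stopifnot(target_sd > 0, lo > 0, lo < hi)
  if (target_mean <= lo || target_mean >= hi)
    stop("target mean must lie strictly inside the truncation bounds")
  s2 <- log(1 + (target_sd / target_mean)^2)
  init <- c(log(target_mean) - s2 / 2, log(sqrt(s2)))
  obj <- function(p) {
    m <- trunc_lnorm_moments(p[1], exp(p[2]), lo, hi)
    (m[["mean"]] / target_mean - 1)^2 + (m[["sd"]] / target_sd - 1)^2
  }
  opt <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 5000))
  mu <- opt$par[1]; sigma <- exp(opt$par[2])
  got <- trunc_lnorm_moments(mu, sigma, lo, hi)
  rel <- c(got[["mean"]] / target_mean - 1, got[["sd"]] / target_sd - 1)
  if (any(abs(rel) > 1e-6))
    stop(sprintf(paste0("truncated-lognormal calibration did not converge: ",
                        "relative residuals %.3g (mean), %.3g (sd)"),
                 rel[1], rel[2]))
  structure(list(mu = mu, sigma = sigma, lo = lo, hi = hi,
                 mean = got[["mean"]], sd = got[["sd"]]),
            class = "trunc_lnorm_params")
}

#' @export
print.trunc_lnorm_params <- function(x, ...) {
  cat(sprintf(
    "<trunc_lnorm mu %.4f sigma %.4f on [%.2f, %.2f]: mean %.2f, sd %.2f>\n",
    x$mu, x$sigma, x$lo, x$hi, x$mean, x$sd))
  invisible(x)
}

#' Sample SUVmax values from a calibrated generator
#'
#' Inverse-CDF sampling on the truncated interval: uniforms on
#' `[F(lo), F(hi)]` mapped through the lognormal quantile function, so every
#' draw lies in `[lo, hi]` and the stream is reproducible under `seed`.
#'
#' @param params A [fit_truncated_lognormal()] result.
#' @param n Number of draws.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Numeric vector of length `n` in `[lo, hi]`.
#' @export
sample_suv <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "trunc_lnorm_params"), n >= 1)
  draw <- function() {
    u <- stats::runif(n, stats::plnorm(params$lo, params$mu, params$sigma),
                      stats::plnorm(params$hi, params$mu, params$sigma))
    stats::qlnorm(u, params$mu, params$sigma)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Default calibrated generators for the two lesion categories
#'
#' Metastatic: mean 32.56, sd 16.39 on [10.90, 130.70] g/mL; degenerative:
#' mean 10.26, sd 4.67 on [3.50, 27.00] g/mL — the published cohort summary
#' rows this package's simulations are calibrated to.
#'
#' @return Named list with `metastatic` and `degenerative`
#'   [fit_truncated_lognormal()] parameter objects.
#' @export
default_suv_generators <- function() {
  list(metastatic = fit_truncated_lognormal(32.56, 16.39, 10.90, 130.70),
       degenerative = fit_truncated_lognormal(10.26, 4.67, 3.50, 27.00))
}

#' Cohort simulation configuration
#'
#' Defaults reproduce the study conditions: 70 patients, 236 metastatic and
#' 179 degenerative lesions in total (1 to 5 per patient per category),
#' per-category region probabilities from the published localization table,
#' and patient-level injection parameters (activity 673.61 +/- 56.64 MBq,
#' injection-to-scan delay 176.32 +/- 34.47 min, age 59.36 +/- 11.45 yr).
#' Weight and height distributions are plausibility plumbing for the
#' quantification stage only (the cohort is female; they are never used in
#' the statistics).
#'
#' @param n_patients Number of patients.
#' @param n_met,n_deg Total lesion counts per category.
#' @param region_probs_met,region_probs_deg Named probabilities over regions
#'   L, T, P, O per category.
#' @param age_mean,age_sd Age distribution, years.
#' @param activity_mean,activity_sd Injected activity, MBq.
#' @param delay_mean,delay_sd Injection-to-scan delay, minutes.
#' @param weight_mean,weight_sd,height_mean,height_sd Body metrics (kg, cm),
#'   truncated to plausible ranges at sampling time.
#' @param seed Integer seed for [sample_cohort()].
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 70, n_met = 236, n_deg = 179,
                          region_probs_met = c(L = 50, T = 50, P = 61, O = 75) / 236,
                          region_probs_deg = c(L = 74, T = 54, P = 16, O = 35) / 179,
                          age_mean = 59.36, age_sd = 11.45,
                          activity_mean = 673.61, activity_sd = 56.64,
                          delay_mean = 176.32, delay_sd = 34.47,
                          weight_mean = 70, weight_sd = 12,
                          height_mean = 163, height_sd = 7,
                          seed = 1L) {
  stopifnot(n_patients >= 1, n_met >= n_patients, n_deg >= n_patients)
  if (n_met > 5 * n_patients || n_deg > 5 * n_patients)
    stop("infeasible totals: at most 5 lesions per patient per category")
  for (p in list(region_probs_met, region_probs_deg)) {
    stopifnot(setequal(names(p), c("L", "T", "P", "O")))
    if (abs(sum(p) - 1) > 1e-8) stop("region probabilities must sum to 1")
  }
  structure(
    list(n_patients = n_patients, n_met = n_met, n_deg = n_deg,
         region_probs_met = region_probs_met,
         region_probs_deg = region_probs_deg,
         age_mean = age_mean, age_sd = age_sd,
         activity_mean = activity_mean, activity_sd = activity_sd,
         delay_mean = delay_mean, delay_sd = delay_sd,
         weight_mean = weight_mean, weight_sd = weight_sd,
         height_mean = height_mean, height_sd = height_sd,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Simulate a patient cohort with per-lesion SUVmax values
#'
#' Draws a full synthetic cohort matching the configured study conditions:
#' exact per-category lesion totals allocated across patients (each patient
#' gets 1-5 lesions of each category; a multinomial allocation is clipped
#' and rebalanced to hit the totals exactly), regions drawn per category
#' from the configured probabilities, SUVmax values i.i.d. from the
#' calibrated truncated-lognormal generators, and patient metadata
#' (age, injected activity, scan delay, body metrics) from the configured
#' normal distributions. Deterministic under `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param generators Output of [default_suv_generators()] (or recalibrated
#'   parameters of the same shape).
#' @return List with `patients` (list of [patient_record]) and `lesions`
#'   (data frame: `patient_id`, `lesion_id`, `category`, `region`,
#'   `suv_max`).
#' @export
sample_cohort <- function(config = cohort_config(),
                          generators = default_suv_generators()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    n_per <- list(
      metastatic = allocate_lesions(config$n_met, config$n_patients),
      degenerative = allocate_lesions(config$n_deg, config$n_patients))

    ids <- sprintf("P%03d", seq_len(config$n_patients))
    patients <- lapply(seq_len(config$n_patients), function(i) {
      w <- rnorm_trunc(1, config$weight_mean, config$weight_sd, 40, 130)
      h <- rnorm_trunc(1, config$height_mean, config$height_sd, 140, 190)
      act <- rnorm_trunc(1, config$activity_mean, config$activity_sd,
                         400, 1000)
      delay_min <- rnorm_trunc(1, config$delay_mean, config$delay_sd, 60, 360)
      age <- rnorm_trunc(1, config$age_mean, config$age_sd, 18, 95)
      resid_frac <- rnorm_trunc(1, 0.02, 0.005, 0.001, 0.10)
      t0 <- as.POSIXct("2021-03-01T08:00", format = "%Y-%m-%dT%H:%M",
                       tz = "UTC") + (i - 1) * 300
      patient_record(
        patient_id = ids[i], sex = "female", weight_kg = round(w, 1),
        height_cm = round(h, 1), age_years = round(age),
        pre_injection_activity_mbq = round(act, 2),
        post_injection_activity_mbq = round(act * resid_frac, 2),
        measured_time = t0, administered_time = t0 + 5 * 60,
        post_injection_time = t0 + 10 * 60,
        scan_time = t0 + 5 * 60 + round(delay_min) * 60)
    })
    names(patients) <- ids

    one_cat <- function(category, counts, probs, params) {
      pid <- rep(ids, counts)
      n <- length(pid)
      data.frame(
        patient_id = pid,
        category = category,
        region = sample(names(probs), n, replace = TRUE, prob = probs),
        suv_max = sample_suv(params, n),
        stringsAsFactors = FALSE)
    }
    lesions <- rbind(
      one_cat("metastatic", n_per$metastatic, config$region_probs_met,
              generators$metastatic),
      one_cat("degenerative", n_per$degenerative, config$region_probs_deg,
              generators$degenerative))
    lesions <- lesions[order(lesions$patient_id, lesions$category,
                             -lesions$suv_max), ]
    lesions$lesion_id <- sprintf("%s_%s%02d", lesions$patient_id,
                                 toupper(substr(lesions$category, 1, 1)),
                                 stats::ave(seq_len(nrow(lesions)),
                                            lesions$patient_id,
                                            lesions$category,
                                            FUN = seq_along))
    rownames(lesions) <- NULL
    lesions <- lesions[, c("patient_id", "lesion_id", "category", "region",
                           "suv_max")]
    list(patients = patients, lesions = lesions)
  })
}

# Allocate `total` lesions over `n` patients with 1-5 each, exactly.
allocate_lesions <- function(total, n, k_min = 1L, k_max = 5L) {
  if (total < k_min * n || total > k_max * n)
    stop("infeasible lesion total ", total, " for ", n, " patients")
  counts <- k_min + stats::rmultinom(1, total - k_min * n,
                                     rep(1, n))[, 1]
  # clip at k_max and push the excess onto patients with headroom
  repeat {
    over <- counts > k_max
    if (!any(over)) break
    excess <- sum(counts[over] - k_max)
    counts[over] <- k_max
    room <- which(counts < k_max)
    add <- utils::head(rep(room, k_max - counts[room]), excess)
    counts[as.integer(names(table(add)))] <-
      counts[as.integer(names(table(add)))] + as.integer(table(add))
  }
  stopifnot(sum(counts) == total, all(counts >= k_min), all(counts <= k_max))
  counts
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Write a simulated cohort to CSV with provenance
#'
#' Emits `patients.csv`, `lesions.csv` (schema: `patient_id, lesion_id,
#' category, region, suv_max, seed_i, seed_j, seed_k`, seed columns blank
#' for table-only cohorts) and `provenance.json` (seed and configuration).
#' Identical seeds give byte-identical files.
#'
#' @param cohort A [sample_cohort()] result.
#' @param config The [cohort_config()] used.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_patients_csv(cohort$patients, file.path(dir, "patients.csv"))
  les <- cohort$lesions
  les$suv_max <- sprintf("%.6f", les$suv_max)
  les$seed_i <- les$seed_j <- les$seed_k <- ""
  utils::write.csv(les, file.path(dir, "lesions.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- unclass(config)
  prov <- list(seed = config$seed,
               config = cfg[order(names(cfg))],
               package = "spectsuv",
               version = as.character(utils::packageVersion("spectsuv")))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a lesion table from CSV
#'
#' @param path CSV path with at least `patient_id, lesion_id, category,
#'   region, suv_max`.
#' @return Data frame.
#' @export
read_lesions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "lesion_id", "category", "region", "suv_max")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("lesion table is missing columns: ", paste(miss, collapse = ", "))
  df$suv_max <- as.numeric(df$suv_max)
  df
}
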