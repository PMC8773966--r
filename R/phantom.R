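#' Digital sphere phantom in activity-concentration units
#'
#' Builds a 3D activity volume containing spheres of prescribed true SUVlbm
#' on a low uniform background, by inverting the SUV mapping for the given
#' patient: each true SUV is converted to the concentration
#' `C = suv * A_actual(Bq) / (LBM * 1000)` that would quantify back to it.
#' An optional isotropic Gaussian blur emulates reconstruction resolution
#' loss, and optional Poisson noise emulates count statistics:
#' with `gain` counts per SUV unit per voxel, each voxel is replaced by
#' `Poisson(gain * SUV) / gain` (back in concentration units), so the
#' relative error of a voxel at SUV v is about `1/sqrt(gain * v)`.
#'
#' Quantifying the result with [suv_volume()] and the same patient recovers
#' the prescribed SUVs exactly when `blur_fwhm_mm = 0` and `gain = 0`
#' (noise-free).
#'
#' @param patient A [patient_record()] used for the inverse SUV mapping.
#' @param spheres Data frame with columns `cx, cy, cz` (center, mm),
#'   `radius_mm`, `true_suv`.
#' @param shape Grid dimensions (length 3).
#' @param spacing_mm Voxel spacing, mm.
#' @param background_suv Background level, g/mL (default 1).
#' @param blur_fwhm_mm Isotropic Gaussian blur FWHM, mm (0 = none).
#' @param gain Poisson gain in counts per SUV unit per voxel (0 = noise
#'   free).
#' @param seed Seed for the Poisson draw.
#' @param half_life_h Radionuclide half-life, hours.
#' @return List with `volume` (an [activity_volume()]) and `truth` (the
#'   sphere table with the concentration each sphere was painted at).
#' @export
build_phantom <- function(patient, spheres, shape = c(64, 64, 64),
                          spacing_mm = c(2, 2, 2), background_suv = 1,
                          blur_fwhm_mm = 0, gain = 0, seed = NULL,
                          half_life_h = TC99M_HALF_LIFE_H) {
  stopifnot(inherits(patient, "patient_record"),
            all(c("cx", "cy", "cz", "radius_mm", "true_suv") %in%
                  names(spheres)),
            gain >= 0, background_suv >= 0)
  spacing_mm <- rep_len(spacing_mm, 3L)
  extent <- shape * spacing_mm
  ctr <- as.matrix(spheres[, c("cx", "cy", "cz")])
  if (nrow(spheres) > 0 &&
      (any(ctr - spheres$radius_mm < 0) ||
       any(ctr + spheres$radius_mm > matrix(extent, nrow(spheres), 3,
                                            byrow = TRUE))))
    stop("sphere extends outside the grid")
  if (nrow(spheres) > 1) {
    d <- as.matrix(stats::dist(ctr))
    rsum <- outer(spheres$radius_mm, spheres$radius_mm, "+")
    diag(d) <- Inf
    if (any(d < rsum)) stop("spheres overlap; prescribe disjoint lesions")
  }

  dc <- decay_correction(patient, half_life_h = half_life_h)
  lbm <- lean_body_mass(patient$weight_kg, patient$height_cm, patient$sex)
  conc_per_suv <- dc$actual_activity_mbq * 1e6 / (lbm * 1000)  # Bq/mL per g/mL

  suv <- array(background_suv, shape)
  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - 1) + 0.5) * spacing_mm[a])
  for (s in seq_len(nrow(spheres))) {
    d2 <- outer(outer((ax[[1]] - spheres$cx[s])^2,
                      (ax[[2]] - spheres$cy[s])^2, "+"),
                (ax[[3]] - spheres$cz[s])^2, "+")
    suv[d2 <= spheres$radius_mm[s]^2] <- spheres$true_suv[s]
  }
  if (blur_fwhm_mm > 0)
    suv <- gaussian_blur3d(suv, blur_fwhm_mm / 2.354820045 / spacing_mm)
  if (gain > 0) {
    noisy <- function() array(stats::rpois(length(suv), gain * suv) / gain,
                              dim(suv))
    suv <- if (is.null(seed)) noisy() else withr::with_seed(seed, noisy())
  }
  truth <- spheres
  truth$conc_bq_ml <- spheres$true_suv * conc_per_suv
  list(volume = activity_volume(suv * conc_per_suv, spacing_mm = spacing_mm),
       truth = truth)
}

# Separable Gaussian blur; sigma per axis in voxel units.
gaussian_blur3d <- function(x, sigma_vox) {
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-half:half, sd = s)
    k <- k / sum(k)
    x <- apply(x, setdiff(1:3, a), function(v) {
      n <- length(v)
      vp <- c(rep(v[1], half), v, rep(v[n], half))  # replicate edges
      stats::convolve(vp, rev(k), type = "filter")
    })
    x <- aperm(x, order(c(a, setdiff(1:3, a))))
  }
  x
}
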