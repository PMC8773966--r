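#' Global-maximum voxel of an SUV volume
#'
#' Finds the voxel with the highest uptake outside an exclusion set. This is
#' the seed-selection step of the iterative "global maximum" lesion
#' enumeration: repeatedly take the hottest remaining voxel, delineate a VOI
#' around it, exclude it, and repeat. Ties are broken by the smallest voxel
#' index in lexicographic (i, j, k) order, i.e. smallest linear index in
#' column-major storage.
#'
#' @param vol An `suv_volume`.
#' @param excluded Logical array of the same shape marking voxels already
#'   claimed, or `NULL`.
#' @return List with `voxel` (1-based index triple) and `value` (g/mL).
#' @export
global_maximum <- function(vol, excluded = NULL) {
  g <- vol$grid
  if (!is.null(excluded)) {
    stopifnot(identical(dim(excluded), dim(g)))
    if (all(excluded)) stop("all voxels are excluded; no maximum available")
    g[excluded] <- -Inf
  }
  lin <- which(g == max(g))
  cand <- arrayInd(lin, dim(g))
  first <- order(cand[, 1], cand[, 2], cand[, 3])[1]
  list(voxel = as.integer(cand[first, ]), value = vol$grid[lin[first]])
}

#' Threshold region growing around a seed voxel
#'
#' Delineates a VOI as the 26-connected component, containing the seed, of
#' voxels whose SUV is at least `frac` times the seed SUV, intersected with a
#' ball of physical radius `radius_mm` around the seed. The default 40%
#' threshold is the common fixed-threshold VOI rule in skeletal uptake
#' quantification; the radius cap keeps a VOI from leaking along contiguous
#' high-uptake bone into a neighbouring lesion.
#'
#' @param vol An `suv_volume`.
#' @param seed 1-based voxel index triple inside the grid.
#' @param frac Threshold as a fraction of the seed SUV, in (0, 1).
#' @param radius_mm Maximum distance from the seed, mm.
#' @return Object of class `voi`: `seed` (index triple), `voxels` (n x 3
#'   matrix of 1-based indices), `suv_max` (the seed SUV), `centroid_mm`,
#'   `n_voxels`, and `dim` (grid shape).
#' @export
grow_voi <- function(vol, seed, frac = 0.40, radius_mm = 15) {
  g <- vol$grid
  dims <- dim(g)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > dims))
    stop("seed voxel ", paste(seed, collapse = ","), " is outside the grid")
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)")
  if (radius_mm <= 0) stop("radius_mm must be > 0")

  thr <- frac * g[seed[1], seed[2], seed[3]]
  sp <- vol$spacing_mm

  # candidate = above threshold and inside the ball (checked in mm)
  candidate <- array(FALSE, dims)
  ri <- pmax(1L, ceiling(seed - radius_mm / sp))
  ra <- pmin(dims, floor(seed + radius_mm / sp))
  idx <- as.matrix(expand.grid(i = ri[1]:ra[1], j = ri[2]:ra[2], k = ri[3]:ra[3]))
  d2 <- ((idx[, 1] - seed[1]) * sp[1])^2 + ((idx[, 2] - seed[2]) * sp[2])^2 +
    ((idx[, 3] - seed[3]) * sp[3])^2
  keep <- idx[d2 <= radius_mm^2 & g[idx] >= thr, , drop = FALSE]
  candidate[keep] <- TRUE

  # 26-connected flood fill from the seed over the candidate set
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  in_voi <- array(FALSE, dims)
  in_voi[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- matrix(seed, nrow = 1)
  while (nrow(frontier) > 0) {
    nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offsets)), , drop = FALSE] +
      offsets[rep(seq_len(nrow(offsets)), times = nrow(frontier)), , drop = FALSE]
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb <- nb[ok, , drop = FALSE]
    nb <- nb[candidate[nb] & !in_voi[nb], , drop = FALSE]
    nb <- unique(nb)
    if (nrow(nb) == 0) break
    in_voi[nb] <- TRUE
    frontier <- nb
  }

  voxels <- which(in_voi, arr.ind = TRUE)
  dimnames(voxels) <- NULL
  centroid <- vol$origin_mm + (colMeans(voxels) - 1) * sp
  structure(list(seed = seed, voxels = voxels,
                 suv_max = g[seed[1], seed[2], seed[3]],
                 centroid_mm = centroid, n_voxels = nrow(voxels), dim = dims),
            class = "voi")
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("<voi seed (%s), %d voxels, SUVmax %.3f g/mL>\n",
              paste(x$seed, collapse = ","), x$n_voxels, x$suv_max))
  invisible(x)
}

#' Iterative global-maximum lesion extraction
#'
#' Enumerates up to `k_max` lesions from an SUV volume by repeating: find the
#' global-maximum voxel outside everything claimed so far, grow a VOI around
#' it, then exclude that VOI plus an exclusion ball around its seed. The loop
#' stops early when the next maximum falls below `floor_suv`, by default
#' twice the median of the nonzero voxels (a background proxy), which makes
#' the otherwise operator-terminated procedure deterministic.
#'
#' @inheritParams grow_voi
#' @param k_max Maximum number of lesions, >= 1 (clinical protocol: <= 5).
#' @param exclusion_radius_mm Radius of the ball around each accepted seed
#'   that is also removed from the search, mm.
#' @param floor_suv Stop threshold in g/mL, or `NULL` for the automatic
#'   2 x median(nonzero) rule.
#' @return List of [grow_voi()] objects, sorted by decreasing `suv_max`,
#'   with pairwise disjoint voxel sets. Empty list if the volume has no
#'   voxel above the floor.
#' @export
extract_lesions <- function(vol, k_max = 5, frac = 0.40, radius_mm = 15,
                            exclusion_radius_mm = 15, floor_suv = NULL) {
  stopifnot(k_max >= 1)
  g <- vol$grid
  nz <- g[g > 0]
  if (length(nz) == 0) return(list())
  if (is.null(floor_suv)) floor_suv <- 2 * stats::median(nz)

  dims <- dim(g)
  excluded <- array(FALSE, dims)
  vois <- list()
  while (length(vois) < k_max && !all(excluded)) {
    gm <- global_maximum(vol, excluded)
    if (gm$value < floor_suv) break
    voi <- grow_voi(vol, gm$voxel, frac = frac, radius_mm = radius_mm)
    vois[[length(vois) + 1L]] <- voi
    excluded[voi$voxels] <- TRUE
    excluded <- excluded | ball_mask(dims, vol$spacing_mm, gm$voxel,
                                     exclusion_radius_mm)
  }
  vois[order(vapply(vois, `[[`, 0, "suv_max"), decreasing = TRUE)]
}

ball_mask <- function(dims, spacing_mm, center, radius_mm) {
  m <- array(FALSE, dims)
  ri <- pmax(1L, ceiling(center - radius_mm / spacing_mm))
  ra <- pmin(dims, floor(center + radius_mm / spacing_mm))
  idx <- as.matrix(expand.grid(ri[1]:ra[1], ri[2]:ra[2], ri[3]:ra[3]))
  d2 <- ((idx[, 1] - center[1]) * spacing_mm[1])^2 +
    ((idx[, 2] - center[2]) * spacing_mm[2])^2 +
    ((idx[, 3] - center[3]) * spacing_mm[3])^2
  m[idx[d2 <= radius_mm^2, , drop = FALSE]] <- TRUE
  m
}

#' Keep the top-k distinct SUVmax lesions per patient and category
#'
#' Reproduces the clinical selection rule: per patient and lesion category,
#' lesions with duplicated SUVmax are deduplicated (first by `lesion_id`
#' kept), the rest sorted by decreasing SUVmax, and at most `k` retained —
#' so each patient contributes between one and `k` lesions per category
#' present, each with a different SUVmax.
#'
#' @param table Data frame with columns `patient_id`, `lesion_id`,
#'   `category`, `suv_max` (a cohort lesion table).
#' @param k Maximum lesions kept per patient x category (default 5).
#' @return The filtered table, ordered by patient, category, then decreasing
#'   SUVmax.
#' @export
top_k_per_category <- function(table, k = 5) {
  stopifnot(all(c("patient_id", "lesion_id", "category", "suv_max") %in%
                  names(table)), k >= 1)
  parts <- split(table, interaction(table$patient_id, table$category,
                                    drop = TRUE))
  kept <- lapply(parts, function(d) {
    d <- d[order(d$lesion_id), , drop = FALSE]
    d <- d[!duplicated(d$suv_max), , drop = FALSE]
    d <- d[order(-d$suv_max), , drop = FALSE]
    utils::head(d, k)
  })
  out <- do.call(rbind, kept)
  out <- out[order(out$patient_id, out$category, -out$suv_max), , drop = FALSE]
  rownames(out) <- NULL
  out
}
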