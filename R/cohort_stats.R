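#' Summary statistics of a set of SUVmax values
#'
#' @param values Numeric vector of SUVmax values, g/mL.
#' @return List with `n`, `min`, `max`, `mean`, `sd` (sample sd, n-1
#'   denominator; defined as 0 with a warning for n = 1).
#' @export
suv_summary <- function(values) {
  if (length(values) < 1) stop("cannot summarize an empty sample")
  s <- if (length(values) == 1L) {
    warning("single observation: sd reported as 0")
    0
  } else stats::sd(values)
  list(n = length(values), min = min(values), max = max(values),
       mean = mean(values), sd = s)
}

#' Anatomical region distribution
#'
#' Counts lesions per anatomical region (L = lumbar vertebrae, T = thoracic
#' vertebrae, P = pelvic bones, O = other bone sites) and reports percentages
#' of the total, rounded to 2 decimals.
#'
#' @param table Data frame with a `region` column of codes in
#'   \{"L","T","P","O"\}.
#' @return Data frame with columns `region`, `count`, `pct`.
#' @export
region_distribution <- function(table) {
  regions <- c("L", "T", "P", "O")
  bad <- which(!table$region %in% regions)
  if (length(bad))
    stop("unknown region code '", table$region[bad[1]], "' in row ", bad[1])
  counts <- vapply(regions, function(r) sum(table$region == r), 0L)
  data.frame(region = regions, count = as.integer(counts),
             pct = round(100 * counts / sum(counts), 2),
             row.names = NULL)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the Royston-algorithm implementation in
#' [stats::shapiro.test()]; a constant sample is reported as degenerate
#' rather than an opaque failure.
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @return List with `W` and `p_value`; for a constant sample, both `NA`
#'   with `degenerate = TRUE`.
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (diff(range(values)) == 0)
    return(list(W = NA_real_, p_value = NA_real_, degenerate = TRUE))
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p_value = ht$p.value, degenerate = FALSE)
}

#' Mann-Whitney U test
#'
#' Computes the U statistic for sample `x` with midranks for ties, and a
#' two-sided p-value. For small samples (`n_x + n_y <= 12`) the p-value is by
#' exact enumeration over all label assignments of the pooled values (tie
#' safe); otherwise by the normal approximation with tie-corrected variance
#' and continuity correction.
#'
#' @param x,y Numeric vectors (x is the "positive" sample; AUC relates to
#'   its U as `AUC = U / (n_x * n_y)`).
#' @param method `"auto"` (exact when feasible), `"exact"`, or `"normal"`.
#' @return List with `U`, `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 1, ny >= 1)
  r <- rank(c(x, y))  # midranks
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (method == "auto") method <- if (nx + ny <= 12) "exact" else "normal"

  p <- if (method == "exact") {
    pooled <- c(x, y)
    n <- nx + ny
    combos <- utils::combn(n, nx)
    rr <- rank(pooled)
    us <- apply(combos, 2, function(ix) sum(rr[ix]) - nx * (nx + 1) / 2)
    mu <- nx * ny / 2
    mean(abs(us - mu) >= abs(U - mu) - 1e-12)
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1))
    sigma2 <- nx * ny / 12 * ((nx + ny + 1) - tie_term)
    if (sigma2 <= 0) 1 else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)  # continuity correction
      min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
  }
  list(U = U, p_value = p, method = method)
}

#' Empirical ROC curve
#'
#' Builds the empirical ROC for discriminating positives (metastatic) from
#' negatives (degenerative) with the strict decision rule "positive if score
#' > threshold". Thresholds are the distinct observed scores plus a -Inf
#' endpoint (everything positive). The AUC is the trapezoidal area, which for
#' this construction equals the Mann-Whitney `U / (n_pos * n_neg)` including
#' the midrank tie convention.
#'
#' @param scores Numeric vector of SUVmax values.
#' @param labels Logical or 0/1 vector, `TRUE`/1 = positive (metastatic).
#' @return Object of class `roc_curve`: data frame `points` (threshold,
#'   sensitivity, specificity), `auc`, `n_pos`, `n_neg`.
#' @export
empirical_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  pos <- scores[labels]; neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes must be present to build a ROC curve")
  thr <- c(-Inf, sort(unique(scores)))
  sens <- vapply(thr, function(t) mean(pos > t), 0)
  spec <- vapply(thr, function(t) mean(neg <= t), 0)
  # trapezoid over (FPR, TPR), ordered by decreasing threshold
  fpr <- rev(1 - spec); tpr <- rev(sens)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spec),
                 auc = auc, n_pos = length(pos), n_neg = length(neg)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: %d pos / %d neg, AUC %.4f>\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' DeLong confidence interval for the AUC
#'
#' Normal-theory interval on the empirical AUC with the DeLong placement
#' variance estimate, clipped to [0, 1]. With perfect separation the
#' placement variance is zero and a degenerate point interval is returned
#' with a warning.
#'
#' @inheritParams empirical_roc
#' @param level Confidence level (default 0.95).
#' @return List with `auc`, `ci_low`, `ci_high`, `se`, `level`.
#' @export
auc_ci <- function(scores, labels, level = 0.95) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  if (length(pos) < 2 || length(neg) < 2)
    stop("DeLong interval needs at least 2 observations per class")
  # placements: P(pos_i > neg) and P(pos > neg_j) with 1/2 for ties
  v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)), 0)
  v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)), 0)
  auc <- mean(v10)
  var_auc <- stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
  if (var_auc <= 0) {
    warning("degenerate AUC variance (perfect separation); point interval")
    return(list(auc = auc, ci_low = auc, ci_high = auc, se = 0, level = level))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(var_auc)
  list(auc = auc, ci_low = max(0, auc - z * se),
       ci_high = min(1, auc + z * se), se = se, level = level)
}

#' Youden-optimal cut-off
#'
#' Scans the observed thresholds of an empirical ROC for the one maximizing
#' Youden's J = sensitivity + specificity - 1 under the strict rule
#' "positive if score > threshold". Ties are broken by the smallest
#' threshold.
#'
#' @param roc A [empirical_roc()] result.
#' @return List of class `cutoff_result`: `threshold` (g/mL), `sensitivity`,
#'   `specificity`, `youden_j`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  pts <- roc$points[is.finite(roc$points$threshold), , drop = FALSE]
  j <- pts$sensitivity + pts$specificity - 1
  best <- which(j >= max(j) - 1e-12)[1]  # thresholds ascending: smallest wins
  structure(list(threshold = pts$threshold[best],
                 sensitivity = pts$sensitivity[best],
                 specificity = pts$specificity[best],
                 youden_j = j[best]),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff SUVmax > %.2f g/mL: sens %.1f%%, spec %.1f%%, J = %.3f>\n",
              x$threshold, 100 * x$sensitivity, 100 * x$specificity,
              x$youden_j))
  invisible(x)
}

#' SUVmax bin breakdown
#'
#' Counts values in the three clinically reported bins: below 20.00, from
#' 20.00 to just under 27.00, and 27.00 or above (a value of exactly 27.00
#' falls in the top bin). Percentages are rounded to 1 decimal.
#'
#' @param values Numeric vector of SUVmax values, > 0.
#' @param breaks Two inner bin edges (defaults 20 and 27, g/mL).
#' @return Data frame with columns `bin`, `count`, `pct`.
#' @export
bin_breakdown <- function(values, breaks = c(20, 27)) {
  stopifnot(length(breaks) == 2, breaks[1] < breaks[2], all(values > 0))
  counts <- c(sum(values < breaks[1]),
              sum(values >= breaks[1] & values < breaks[2]),
              sum(values >= breaks[2]))
  labs <- c(sprintf("<%.2f", breaks[1]),
            sprintf("[%.2f,%.2f)", breaks[1], breaks[2]),
            sprintf(">=%.2f", breaks[2]))
  data.frame(bin = labs, count = as.integer(counts),
             pct = round(100 * counts / length(values), 1))
}

#' Overlap range of the two categories
#'
#' The interval in which metastatic and degenerative SUVmax values coexist:
#' from the metastatic minimum up to the degenerative maximum (values above
#' the degenerative maximum are always metastatic; values below the
#' metastatic minimum always degenerative). Empty when the classes separate.
#'
#' @param met_values,deg_values SUVmax vectors for the two categories.
#' @return List with `low`, `high`, `empty`, `n_inside` (count of all values
#'   in the closed interval) and `fraction_inside`.
#' @export
overlap_range <- function(met_values, deg_values) {
  stopifnot(length(met_values) > 0, length(deg_values) > 0)
  lo <- min(met_values); hi <- max(deg_values)
  all_v <- c(met_values, deg_values)
  if (lo > hi)
    return(list(low = lo, high = hi, empty = TRUE, n_inside = 0L,
                fraction_inside = 0))
  inside <- sum(all_v >= lo & all_v <= hi)
  list(low = lo, high = hi, empty = FALSE, n_inside = as.integer(inside),
       fraction_inside = inside / length(all_v))
}
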