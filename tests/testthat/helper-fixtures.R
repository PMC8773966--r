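# Shared fixtures and independent oracles used across test files.

# Worked patient: 700 MBq assayed 09:00, injected 09:05, 20 MBq residual
# assayed 09:10, scan 12:05.
worked_patient <- function() {
  patient_record("P01", "female", 70, 170,
                 pre_injection_activity_mbq = 700,
                 post_injection_activity_mbq = 20,
                 measured_time = "2021-03-01T09:00",
                 administered_time = "2021-03-01T09:05",
                 post_injection_time = "2021-03-01T09:10",
                 scan_time = "2021-03-01T12:05")
}

# Independent decay oracle: net activity at administration time (forward
# decay of the full-syringe assay, backward decay of the residual assay),
# then a single exponential to scan time.
oracle_actual_activity <- function(patient, half_life_h = 6.0067) {
  lam <- 0.693 / half_life_h
  h <- function(a, b) as.numeric(difftime(b, a, units = "hours"))
  net <- patient$pre_injection_activity_mbq *
    exp(-lam * h(patient$measured_time, patient$administered_time)) -
    patient$post_injection_activity_mbq *
    exp(lam * h(patient$administered_time, patient$post_injection_time))
  net * exp(-lam * h(patient$administered_time, patient$scan_time))
}

# Exact Mann-Whitney two-sided p by full enumeration of label assignments.
oracle_mw_exact_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  rr <- rank(pooled)
  u_obs <- sum(rr[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  us <- apply(combos, 2, function(ix) sum(rr[ix]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Brute-force AUC: pairwise P(pos > neg) with half credit for ties.
oracle_auc <- function(pos, neg) {
  mean(outer(pos, neg, ">")) + 0.5 * mean(outer(pos, neg, "=="))
}

# Brute-force Youden search over all observed thresholds.
oracle_youden <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg)))
  j <- vapply(thr, function(t) mean(pos > t) + mean(neg <= t) - 1, 0)
  list(threshold = thr[which(j >= max(j) - 1e-12)[1]], j = max(j))
}

# Quadrature oracle for truncated-lognormal moments.
oracle_trunc_lnorm_moments <- function(mu, sigma, lo, hi) {
  z <- stats::integrate(function(x) dlnorm(x, mu, sigma), lo, hi,
                        rel.tol = 1e-10)$value
  m1 <- stats::integrate(function(x) x * dlnorm(x, mu, sigma), lo, hi,
                         rel.tol = 1e-10)$value / z
  m2 <- stats::integrate(function(x) x^2 * dlnorm(x, mu, sigma), lo, hi,
                         rel.tol = 1e-10)$value / z
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

# Small phantom helper: spheres sized so each fits inside the VOI radius cap.
toy_spheres <- function() {
  data.frame(cx = c(24, 64, 100), cy = c(30, 80, 40), cz = c(64, 64, 64),
             radius_mm = c(7, 6, 7), true_suv = c(40, 25, 12))
}
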