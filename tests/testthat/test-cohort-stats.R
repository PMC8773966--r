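test_that("suv_summary computes sample moments with n-1 sd", {
  s <- suv_summary(c(10, 20, 30))
  expect_identical(s[c("n", "min", "max", "mean", "sd")],
                   list(n = 3L, min = 10, max = 30, mean = 20, sd = 10))
  expect_warning(s1 <- suv_summary(7), "single observation")
  expect_identical(s1$sd, 0)
  expect_error(suv_summary(numeric()), "empty")
})

test_that("region distribution reproduces the published localization table", {
  counts <- c(L = 124, T = 104, P = 77, O = 110)
  tb <- data.frame(region = rep(names(counts), counts))
  rd <- region_distribution(tb)
  expect_identical(sum(rd$count), 415L)
  # 77/415 = 18.55%; the published report misprints this one as 18.51
  # (its four percentages sum to 99.96) -- the counts are authoritative
  expect_identical(rd$pct, c(29.88, 25.06, 18.55, 26.51))

  met <- data.frame(region = rep(c("L", "T", "P", "O"), c(50, 50, 61, 75)))
  expect_identical(sum(region_distribution(met)$count), 236L)

  single <- data.frame(region = rep("L", 9))
  expect_identical(region_distribution(single)$pct, c(100, 0, 0, 0))
  expect_error(region_distribution(data.frame(region = c("L", "Z"))),
               "unknown region code 'Z' in row 2")
})

test_that("Shapiro-Wilk rejects the right-skewed generator at cohort size", {
  gen <- fit_truncated_lognormal(10.26, 4.67, 3.50, 27.00)
  rejections <- vapply(1:20, function(s) {
    shapiro_wilk(sample_suv(gen, 179, seed = s))$p_value < 0.05
  }, TRUE)
  expect_gte(sum(rejections), 18)

  sw <- shapiro_wilk(sample_suv(gen, 179, seed = 1))
  expect_lt(sw$p_value, 0.05)
  expect_true(sw$W > 0 && sw$W < 1)

  expect_true(shapiro_wilk(rep(3.3, 10))$degenerate)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("Mann-Whitney U and exact p match hand enumeration", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_identical(mw$U, 0)
  expect_equal(mw$p_value, 1 / 3)  # 2 of the 6 rank splits are as extreme
  expect_identical(mw$method, "exact")

  x <- c(5, 5, 7)
  same <- mann_whitney(x, x)
  expect_identical(same$U, length(x)^2 / 2)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
})

test_that("auto mode returns the exact enumerated p for small samples", {
  set.seed(7)
  for (rep in 1:40) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- round(rnorm(nx, 5, 2), 1)  # rounding induces occasional ties
    y <- round(rnorm(ny, 6, 2), 1)
    mw <- mann_whitney(x, y)
    expect_identical(mw$method, "exact")
    expect_equal(mw$p_value, oracle_mw_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("normal-approximation path matches the reference implementation", {
  set.seed(8)
  for (rep in 1:20) {
    nx <- sample(8:30, 1); ny <- sample(8:30, 1)
    x <- round(rlnorm(nx, 3, 0.5), 1)
    y <- round(rlnorm(ny, 2.5, 0.5), 1)
    mw <- mann_whitney(x, y, method = "normal")
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(mw$U, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mw$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("calibrated cohort comparison is significant at study size", {
  gens <- default_suv_generators()
  met <- sample_suv(gens$metastatic, 236, seed = 1)
  deg <- sample_suv(gens$degenerative, 179, seed = 2)
  expect_lt(mann_whitney(met, deg)$p_value, 0.001)
})

test_that("empirical ROC matches brute-force AUC and the U identity", {
  r <- empirical_roc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(r$auc, 1)
  expect_equal(empirical_roc(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE))$auc,
               0.25)
  expect_equal(empirical_roc(rep(5, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)

  # AUC = U / (n_pos * n_neg) on random tied instances
  set.seed(11)
  for (i in 1:50) {
    np <- sample(2:20, 1); nn <- sample(2:20, 1)
    pos <- round(rlnorm(np, 3, 0.5), 1)
    neg <- round(rlnorm(nn, 2.2, 0.5), 1)
    r <- empirical_roc(c(pos, neg), rep(c(TRUE, FALSE), c(np, nn)))
    u <- mann_whitney(pos, neg, method = "normal")$U
    expect_equal(r$auc, u / (np * nn), tolerance = 1e-12)
    expect_equal(r$auc, oracle_auc(pos, neg), tolerance = 1e-12)
    # monotone sens/spec along ascending thresholds
    expect_true(all(diff(r$points$sensitivity) <= 0))
    expect_true(all(diff(r$points$specificity) >= 0))
    # label reversal maps AUC to 1 - AUC
    rflip <- empirical_roc(c(pos, neg), rep(c(FALSE, TRUE), c(np, nn)))
    expect_equal(rflip$auc, 1 - r$auc, tolerance = 1e-12)
  }
  expect_error(empirical_roc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("DeLong interval brackets the AUC and matches a bootstrap oracle", {
  gens <- default_suv_generators()
  met <- sample_suv(gens$metastatic, 236, seed = 1)
  deg <- sample_suv(gens$degenerative, 179, seed = 1)
  scores <- c(met, deg); labs <- rep(c(TRUE, FALSE), c(236, 179))
  ci <- auc_ci(scores, labs)
  expect_true(ci$ci_low <= ci$auc && ci$auc <= ci$ci_high)
  expect_true(ci$ci_low >= 0 && ci$ci_high <= 1)

  # bootstrap oracle on the same fixed draw
  set.seed(99)
  boot <- replicate(2000, {
    oracle_auc(sample(met, replace = TRUE), sample(deg, replace = TRUE))
  })
  expect_equal(ci$ci_low, unname(quantile(boot, 0.025)), tolerance = 0.01)
  expect_equal(ci$ci_high, unname(quantile(boot, 0.975)), tolerance = 0.01)

  expect_warning(pt <- auc_ci(c(10, 11, 1, 2), c(TRUE, TRUE, FALSE, FALSE)),
                 "degenerate")
  expect_identical(c(pt$ci_low, pt$ci_high), c(1, 1))
})

test_that("DeLong interval agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  gens <- default_suv_generators()
  met <- sample_suv(gens$metastatic, 100, seed = 3)
  deg <- sample_suv(gens$degenerative, 80, seed = 4)
  ci <- auc_ci(c(met, deg), rep(c(TRUE, FALSE), c(100, 80)))
  ref <- suppressMessages(pROC::ci.auc(
    pROC::roc(rep(c(1, 0), c(100, 80)), c(met, deg), direction = "<",
              quiet = TRUE), method = "delong"))
  expect_equal(ci$auc, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(ci$ci_low, as.numeric(ref[1]), tolerance = 1e-9)
  expect_equal(ci$ci_high, as.numeric(ref[3]), tolerance = 1e-9)
})

test_that("Youden cut-off equals the brute-force threshold search", {
  r <- empirical_roc(c(20, 30, 5, 10), c(TRUE, TRUE, FALSE, FALSE))
  cut <- youden_cutoff(r)
  expect_identical(cut$threshold, 10)
  expect_identical(cut$youden_j, 1)
  expect_identical(cut$youden_j, cut$sensitivity + cut$specificity - 1)

  flat <- youden_cutoff(empirical_roc(rep(4.2, 5), c(TRUE, TRUE, FALSE,
                                                     FALSE, FALSE)))
  expect_identical(flat$threshold, 4.2)
  expect_identical(flat$youden_j, 0)

  set.seed(21)
  for (i in 1:40) {
    np <- sample(3:25, 1); nn <- sample(3:25, 1)
    pos <- round(rlnorm(np, 3, 0.6), 1)
    neg <- round(rlnorm(nn, 2.2, 0.6), 1)
    got <- youden_cutoff(empirical_roc(c(pos, neg),
                                       rep(c(TRUE, FALSE), c(np, nn))))
    want <- oracle_youden(pos, neg)
    expect_identical(got$threshold, want$threshold)
    expect_equal(got$youden_j, want$j, tolerance = 1e-12)
  }
})

test_that("bin breakdown uses the 20/27 edges with 27.00 in the top bin", {
  deg <- c(runif(172, 4, 19.9), runif(5, 20.5, 26.9), 27, 27)
  bb <- bin_breakdown(deg)
  expect_identical(bb$count, c(172L, 5L, 2L))
  expect_identical(bb$pct, c(96.1, 2.8, 1.1))

  edge <- bin_breakdown(c(19.99, 20.00, 27.00))
  expect_identical(edge$count, c(1L, 1L, 1L))
  expect_identical(bin_breakdown(c(1, 2, 3))$pct[3], 0)
})

test_that("overlap range spans metastatic minimum to degenerative maximum", {
  ov <- overlap_range(c(10.90, 40, 130.70), c(3.50, 12, 27.00))
  expect_identical(c(ov$low, ov$high), c(10.90, 27.00))
  expect_false(ov$empty)

  sep <- overlap_range(c(30, 40), c(1, 2))
  expect_true(sep$empty)
  expect_identical(sep$fraction_inside, 0)

  ov2 <- overlap_range(c(5, 15), c(10, 20))
  expect_identical(c(ov2$low, ov2$high), c(5, 20))
  expect_identical(ov2$n_inside, 4L)
  expect_identical(ov2$fraction_inside, 1)
})
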