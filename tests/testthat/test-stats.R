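test_that("R_day_n hits its boundary values and exact integrals", {
  # no transient source: R = 0 at every horizon
  p1 <- canonical_params_m1()
  expect_equal(compute_rday(p1, c(20, 30, 40, 50))$r_day_n, rep(0, 4))
  # no persistent source: R = 100 at every horizon
  p2 <- canonical_params(); p2$x2_0 <- 0
  expect_equal(compute_rday(p2, c(20, 30, 40, 50))$r_day_n, rep(100, 4))
  # undefined when both donor sources are absent
  p0 <- canonical_params_m1(); p0$x2_0 <- 0
  expect_error(compute_rday(p0, 30), "undefined")
  expect_error(compute_rday(canonical_params(), 0), "> 0")
})

test_that("R_day_n integrals match a dense trapezoid oracle", {
  set.seed(17)
  for (i in 1:5) {
    p <- random_params()
    if (p$lam == 0 && p$x2_0 == 0) next
    grid <- seq(0, 30, length.out = 10001)
    tr <- solve_trajectories(p, grid)
    trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(grid))
    rd <- compute_rday(p, 30)
    expect_equal(rd$auc_x1, trapz(tr$x1),
                 tolerance = 1e-4)
    expect_equal(rd$auc_x2, trapz(tr$x2), tolerance = 1e-4)
    expect_equal(rd$r_day_n,
                 100 * trapz(tr$x1) / (trapz(tr$x1) + trapz(tr$x2)),
                 tolerance = 1e-4)
  }
})

test_that("R_day_n is invariant under joint amplitude rescaling", {
  p <- canonical_params()
  r0 <- compute_rday(p, c(20, 30, 40, 50))$r_day_n
  for (c_scale in c(0.2, 3, 50)) {
    ps <- sdnam_params(p$lam * c_scale, p$k, p$theta, p$mu, p$r,
                       p$N * c_scale, p$x2_0 * c_scale, p$x3_0 * c_scale)
    expect_equal(compute_rday(ps, c(20, 30, 40, 50))$r_day_n, r0,
                 tolerance = 1e-10)
  }
})

test_that("half-life is ln(2) over the clearance rate", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(log(2) / 12.5), 12.5)
  mu <- c(0.03, 0.2, 1.1)
  expect_equal(half_life(mu / 2), 2 * half_life(mu))
  expect_error(half_life(0), "> 0")
})

test_that("group comparison handles identity, separation, and bad input", {
  v <- c(1, 2, 3, 1, 2, 3)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  gc <- compare_groups(v, lab)
  expect_equal(gc$diff_mean, 0)
  expect_equal(gc$p_t, 1)
  expect_true(gc$ci_low <= 0 && gc$ci_high >= 0)
  # near-degenerate separation: a clean constant shift
  set.seed(3)
  a <- rnorm(10, 0, 1e-6); b <- a + 10
  gs <- compare_groups(c(b, a), rep(c(TRUE, FALSE), each = 10))
  expect_lt(gs$p_t, 1e-10)
  expect_gt(gs$ci_low, 0)
  expect_equal(gs$diff_mean, 10, tolerance = 1e-6)
  expect_error(compare_groups(1:5, rep(TRUE, 5)), "nonempty")
  expect_error(compare_groups(1:5, c(TRUE, rep(FALSE, 4))), ">= 2")
})

test_that("binomial preference test matches exact enumeration", {
  # central value
  expect_equal(binomial_preference_test(6, 12)$p_value, 1)
  # brute-force two-sided convention: sum outcome probabilities that do
  # not exceed the observed one
  brute <- function(k, n) {
    pk <- stats::dbinom(k, n, 0.5)
    sum(stats::dbinom(0:n, n, 0.5)[stats::dbinom(0:n, n, 0.5) <= pk * (1 + 1e-7)])
  }
  expect_equal(binomial_preference_test(4, 5)$p_value, brute(4, 5))
  for (n in c(3, 7, 12)) {
    for (k in 0:n) {
      expect_equal(binomial_preference_test(k, n)$p_value, brute(k, n),
                   tolerance = 1e-12)
    }
  }
  # Clopper-Pearson CI brackets the observed proportion
  bt <- binomial_preference_test(47, 67)
  expect_lt(bt$ci_low, bt$proportion)
  expect_gt(bt$ci_high, bt$proportion)
})

test_that("Fisher test matches hypergeometric enumeration on small tables", {
  brute_fisher <- function(m) {
    s1 <- sum(m[1, ]); s2 <- sum(m[2, ]); c1 <- sum(m[, 1])
    xs <- max(0, c1 - s2):min(c1, s1)
    ps <- stats::dhyper(xs, s1, s2, c1)
    sum(ps[ps <= stats::dhyper(m[1, 1], s1, s2, c1) * (1 + 1e-7)])
  }
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(stats::rpois(4, 3), 2, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_2x2(m)$p_value, brute_fisher(m), tolerance = 1e-12)
  }
  expect_warning(res <- fisher_2x2(matrix(c(2, 5, 0, 0), 2, 2)), "degenerate")
  expect_equal(res$p_value, 1)
})

test_that("ROC machinery matches brute-force enumeration on a toy set", {
  values <- 1:6
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  roc <- roc_analysis(values, labels)
  # perfectly separated values
  expect_equal(roc$auc, 1)
  expect_equal(roc$sensitivity, 1)
  expect_equal(roc$specificity, 1)
  expect_equal(roc$accuracy, 1)
  expect_equal(roc$cutoff, 4)  # smallest positive value, >= convention
  # overlapping toy set: enumerate every threshold by hand
  v2 <- c(1, 2, 3, 4, 2.5, 3.5, 5, 6)
  l2 <- c(rep(FALSE, 4), rep(TRUE, 4))
  roc2 <- roc_analysis(v2, l2)
  cuts <- sort(unique(c(v2, max(v2) + 1)))
  sens <- vapply(cuts, function(ct) mean(v2[l2] >= ct), numeric(1))
  spec <- vapply(cuts, function(ct) mean(v2[!l2] < ct), numeric(1))
  d <- sqrt((1 - sens)^2 + (1 - spec)^2)
  expect_equal(roc2$cutoff, cuts[which.min(d)])
  expect_equal(roc2$sensitivity, sens[which.min(d)])
  expect_equal(roc2$specificity, spec[which.min(d)])
  cm <- roc2$confusion
  expect_identical(sum(cm), 8L)
  expect_equal(roc2$accuracy, (cm[["tp"]] + cm[["tn"]]) / 8)
})

test_that("ROC AUC equals the Mann-Whitney statistic and survives
           monotone transforms", {
  set.seed(12)
  for (i in 1:10) {
    n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
    v <- c(rnorm(n1, 1), rnorm(n0))
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    roc <- roc_analysis(v, lab)
    w <- suppressWarnings(
      stats::wilcox.test(v[lab], v[!lab])$statistic)
    expect_equal(roc$auc, unname(w) / (n1 * n0), tolerance = 1e-12)
    # strictly increasing transform leaves the AUC unchanged
    expect_equal(roc_analysis(exp(v / 3), lab)$auc, roc$auc)
  }
  expect_error(roc_analysis(1:4, rep(TRUE, 4)), "both classes")
})

test_that("ROC AUC, DeLong CI and operating point agree with pROC", {
  set.seed(99)
  v <- c(rnorm(25, 1.2), rnorm(18))
  lab <- rep(c(TRUE, FALSE), c(25, 18))
  ours <- roc_analysis(v, lab)
  ref <- pROC::roc(lab, v, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(ref$auc), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(c(ours$ci_low, ours$ci_high), ci[c(1, 3)], tolerance = 1e-10)
  best <- pROC::coords(ref, "best", best.method = "closest.topleft",
                       transpose = FALSE)
  expect_equal(ours$sensitivity, best$sensitivity[1], tolerance = 1e-12)
  expect_equal(ours$specificity, best$specificity[1], tolerance = 1e-12)
})
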