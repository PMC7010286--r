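#' @importFrom stats binom.test fisher.test t.test wilcox.test qnorm sd var
NULL

#' R_day_n: transient share of donor-derived sDNAM-1 exposure
#'
#' For each horizon `day_n`, integrates the transient (`x1`) and
#' persistent (`x2`) components over `[0, day_n]` and returns the
#' percentage of the donor-derived area under the curve attributable to
#' the transient source,
#' `100 * AUC(x1) / (AUC(x1) + AUC(x2))`. The recipient-derived residual
#' `x3` is excluded by construction: the statistic isolates donor
#' lymphocyte activity. Both integrals are exact (mass-balance identity
#' for `x1`, closed-form logistic integral for `x2`).
#'
#' @param params An [sdnam_params] object (typically a fitted
#'   three-source model).
#' @param day_n Integration horizon(s) in days, all > 0. The cohort
#'   analysis uses 20, 30, 40 and 50.
#' @param patient_id Optional identifier carried into the result.
#' @return A tibble with one row per horizon: `patient_id`, `day_n`,
#'   `auc_x1`, `auc_x2` (pM day) and `r_day_n` (percent, in \[0, 100\]).
#' @examples
#' p <- sdnam_params(lam = 300, k = 3, theta = 4, mu = 0.06,
#'                   r = 0.15, N = 20, x2_0 = 3, x3_0 = 8)
#' compute_rday(p, day_n = c(20, 30, 40, 50))
#' @export
compute_rday <- function(params, day_n, patient_id = NA_character_) {
  params <- as_sdnam_params(params)
  if (any(day_n <= 0)) stop("`day_n` must be > 0", call. = FALSE)
  a1 <- vapply(day_n, function(d) auc_transient(params, d), numeric(1))
  a2 <- vapply(day_n, function(d) auc_persistent(params, d), numeric(1))
  if (any(a1 + a2 == 0)) {
    stop("R_day_n undefined: both donor-derived AUCs are zero ",
         "(lam = 0 and x2_0 = 0)", call. = FALSE)
  }
  tibble::tibble(patient_id = patient_id, day_n = day_n,
                 auc_x1 = a1, auc_x2 = a2,
                 r_day_n = 100 * a1 / (a1 + a2))
}

#' Serum half-life implied by the clearance rate
#'
#' `log(2) / mu` for first-order clearance at rate `mu` per day.
#'
#' @param mu Clearance rate(s), per day, > 0.
#' @return Half-life in days.
#' @export
half_life <- function(mu) {
  if (any(mu <= 0)) stop("`mu` must be > 0", call. = FALSE)
  log(2) / mu
}

#' Compare R_day_n between GVHD-positive and GVHD-negative groups
#'
#' Welch two-sample t-test (unequal variances) with its 95% CI for the
#' mean difference (positive minus negative), and the Wilcoxon rank-sum
#' test (exact for small tie-free samples, normal approximation with
#' continuity correction otherwise, as in [stats::wilcox.test]).
#'
#' @param values Numeric vector of per-patient statistics (e.g.
#'   R_day_n in percent).
#' @param labels Logical (or coercible) vector, `TRUE` = GVHD-positive.
#' @param horizon Optional horizon annotation carried into the result.
#' @param conf_level Confidence level for the mean-difference CI.
#' @return One-row tibble: group sizes, means and SDs, `diff_mean` with
#'   `ci_low`/`ci_high`, `p_t` (Welch) and `p_w` (Wilcoxon).
#' @export
compare_groups <- function(values, labels, horizon = NA_real_,
                           conf_level = 0.95) {
  stopifnot(length(values) == length(labels))
  labels <- as.logical(labels)
  pos <- values[labels]
  neg <- values[!labels]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("each group needs >= 2 observations for the t-test and CI",
         call. = FALSE)
  }
  tt <- t.test(pos, neg, var.equal = FALSE, conf.level = conf_level)
  wt <- suppressWarnings(wilcox.test(pos, neg))
  tibble::tibble(
    horizon = horizon, n_neg = length(neg), n_pos = length(pos),
    mean_neg = mean(neg), mean_pos = mean(pos),
    sd_neg = sd(neg), sd_pos = sd(pos),
    diff_mean = mean(pos) - mean(neg),
    ci_low = tt$conf.int[[1L]], ci_high = tt$conf.int[[2L]],
    p_t = tt$p.value, p_w = wt$p.value)
}

#' Exact binomial test of model preference
#'
#' Two-sided exact binomial test of `k` three-source preferences out of
#' `n` patients against an even split, with the Clopper-Pearson exact
#' 95% CI. Percentages are reported on the 0-100 scale.
#'
#' @param k Number of patients whose data prefer the three-source model.
#' @param n Total number of fitted patients.
#' @return One-row tibble: `k`, `n`, `proportion` (percent), `ci_low`,
#'   `ci_high` (percent) and the two-sided `p_value`.
#' @export
binomial_preference_test <- function(k, n) {
  stopifnot(n >= 1, k >= 0, k <= n)
  bt <- binom.test(k, n, p = 0.5)
  tibble::tibble(k = k, n = n,
                 proportion = 100 * k / n,
                 ci_low = 100 * bt$conf.int[[1L]],
                 ci_high = 100 * bt$conf.int[[2L]],
                 p_value = bt$p.value)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided exact p-value by the minimum-likelihood convention
#' (summing hypergeometric probabilities not exceeding the observed
#' table's), as in [stats::fisher.test]. A table with an empty row or
#' column margin carries no information about association and returns
#' p = 1 with a warning.
#'
#' @param table A 2x2 matrix of nonnegative counts.
#' @return One-row tibble with `p_value` and the conditional MLE
#'   `odds_ratio` (`NA` for degenerate tables).
#' @export
fisher_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("degenerate margin: no association to test, p = 1", call. = FALSE)
    return(tibble::tibble(p_value = 1, odds_ratio = NA_real_))
  }
  ft <- fisher.test(table)
  tibble::tibble(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}

# Mann-Whitney AUC with midrank tie handling
mann_whitney_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# DeLong variance of the empirical AUC via placement values
delong_ci <- function(pos, neg, auc, conf_level = 0.95) {
  m <- length(pos); n <- length(neg)
  if (m < 2L || n < 2L) return(c(NA_real_, NA_real_))
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), numeric(1))
  s <- var(v10) / m + var(v01) / n
  z <- qnorm(1 - (1 - conf_level) / 2)
  pmin(pmax(auc + c(-1, 1) * z * sqrt(s), 0), 1)
}

#' ROC analysis of a biomarker with the closest-to-(0,1) cutoff
#'
#' Builds the empirical ROC over all distinct thresholds with the
#' `value >= cutoff` convention for calling a patient positive
#' (GVHD-positive patients have the higher R_day_n). The AUC is the
#' Mann-Whitney statistic normalized by the product of group sizes
#' (identical to the trapezoidal area under the empirical curve), with a
#' DeLong 95% CI. The operating cutoff minimizes the Euclidean distance
#' `sqrt((1 - sens)^2 + (1 - spec)^2)` to the ideal point (0, 1);
#' distance ties are broken toward higher specificity.
#'
#' @inheritParams compare_groups
#' @return An object of class `sdnam_roc` with the AUC and CI, cutoff,
#'   sensitivity/specificity/accuracy and confusion counts at the
#'   cutoff, and the full curve. Use [glance()] for a one-row tibble.
#' @export
roc_analysis <- function(values, labels, horizon = NA_real_) {
  stopifnot(length(values) == length(labels))
  labels <- as.logical(labels)
  pos <- values[labels]
  neg <- values[!labels]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  auc <- mann_whitney_auc(pos, neg)
  ci <- delong_ci(pos, neg, auc)
  # candidate cutoffs: every distinct observed value plus one above all,
  # descending so the curve runs from (0,0) to (1,1)
  cuts <- sort(unique(values), decreasing = TRUE)
  cuts <- c(max(values) + 1, cuts)
  sens <- vapply(cuts, function(ct) mean(pos >= ct), numeric(1))
  spec <- vapply(cuts, function(ct) mean(neg < ct), numeric(1))
  dist <- sqrt((1 - sens)^2 + (1 - spec)^2)
  # minimal distance; ties toward higher specificity (then higher cutoff)
  cand <- which(dist <= min(dist) + 1e-12)
  best <- cand[order(-spec[cand], -cuts[cand])][1L]
  cutoff <- cuts[[best]]
  tp <- sum(pos >= cutoff); fn <- sum(pos < cutoff)
  tn <- sum(neg < cutoff); fp <- sum(neg >= cutoff)
  structure(list(
    horizon = horizon, auc = auc, ci_low = ci[[1L]], ci_high = ci[[2L]],
    cutoff = cutoff,
    sensitivity = sens[[best]], specificity = spec[[best]],
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
    curve = tibble::tibble(threshold = cuts, sensitivity = sens,
                           specificity = spec)
  ), class = "sdnam_roc")
}

#' @export
print.sdnam_roc <- function(x, ...) {
  cat(sprintf("<sdnam_roc>%s AUC = %.3f (%.3f-%.3f)\n",
              if (is.na(x$horizon)) "" else paste0(" day ", x$horizon, ":"),
              x$auc, x$ci_low, x$ci_high))
  cat(sprintf("  cutoff %.3g: sens %.1f%%, spec %.1f%%, acc %.1f%% (TP %d TN %d FP %d FN %d)\n",
              x$cutoff, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$accuracy, x$confusion[["tp"]], x$confusion[["tn"]],
              x$confusion[["fp"]], x$confusion[["fn"]]))
  invisible(x)
}

#' @rdname roc_analysis
#' @param x An `sdnam_roc` object.
#' @param ... Unused.
#' @export
glance.sdnam_roc <- function(x, ...) {
  tibble::tibble(horizon = x$horizon, auc = x$auc,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 cutoff = x$cutoff, sensitivity = x$sensitivity,
                 specificity = x$specificity, accuracy = x$accuracy,
                 tp = x$confusion[["tp"]], tn = x$confusion[["tn"]],
                 fp = x$confusion[["fp"]], fn = x$confusion[["fn"]])
}

#' @rdname roc_analysis
#' @export
tidy.sdnam_roc <- function(x, ...) x$curve

#' Per-patient R_day_n from fitted cohort comparisons
#'
#' Computes R_day_n at each horizon from each patient's AIC-preferred
#' fit. A patient whose data prefer the two-source model has no
#' transient source (`lam = 0`), so their transient share is exactly
#' zero; patients preferring the three-source model get the share
#' implied by its fitted `x1` and `x2`. Using the preferred variant
#' keeps the share from being driven by the spurious transient mass an
#' over-parameterised fit can assign to burst-free series.
#'
#' @param comparisons Output of [fit_cohort].
#' @param horizons Integration horizons in days.
#' @return A tibble with one row per patient x horizon.
#' @export
rday_cohort <- function(comparisons, horizons = c(20, 30, 40, 50)) {
  ok <- comparisons[!is.na(comparisons$preferred), , drop = FALSE]
  purrr::map_dfr(ok$selection, function(sel) {
    fit <- if (sel$preferred == "model2") sel$fit2 else sel$fit1
    compute_rday(fit$params, horizons, patient_id = sel$patient_id)
  })
}
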