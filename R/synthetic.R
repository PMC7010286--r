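#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the study design the analysis assumes: a
#' cohort of allo-HSCT patients (default 67, of whom 48 develop acute
#' GVHD), sparse irregular serum sampling from about a week before
#' transplant to day ~249, multiplicative lognormal measurement noise,
#' and per-group parameter priors for the three-source model. Patients
#' are drawn either from the full three-source model or, with
#' probability `model1_fraction`, from its two-source restriction
#' (`lam = 0`, no transient burst). For three-source patients the
#' transient mass `lam` is solved analytically so that the true
#' `R_day_30` equals a Beta-distributed per-patient target, which pins
#' the group-level means of the transient share among transient-bearing
#' patients at `rday_target`.
#'
#' @param n_patients Cohort size.
#' @param n_pos Number of GVHD-positive patients.
#' @param noise_sigma Lognormal sigma of the multiplicative measurement
#'   error (0.10 is a typical ELISA-scale coefficient of variation).
#' @param model1_fraction Named vector `c(pos = , neg = )`: probability
#'   that a patient of that group is generated without a transient
#'   source (defaults echo the observed per-group preference counts,
#'   13/48 and 7/19).
#' @param rday_target Named vector `c(pos = , neg = )`: target mean true
#'   `R_day_30` in percent among transient-bearing patients (defaults
#'   74 and 33, the cohort group means).
#' @param rday_kappa Beta concentration (shape sum) of the per-patient
#'   target draw; larger = tighter around the group mean.
#' @param half_life_mean Mean clearance half-life in days used to center
#'   the `mu` prior (12.5 days).
#' @param compliant_fraction Fraction of patients whose sampling
#'   schedule is guaranteed to satisfy the inclusion rule (>= 8
#'   observations in days 0-100 and >= 1 in days 0-7).
#' @param pre_transplant Add one pre-transplant observation (days -7 to
#'   -1) per patient, reflecting the residual recipient-derived pool.
#' @param seed Random seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return A list of class `sdnam_cohort_config`.
#' @export
cohort_config <- function(n_patients = 67L, n_pos = 48L,
                          noise_sigma = 0.10,
                          model1_fraction = c(pos = 13 / 48, neg = 7 / 19),
                          rday_target = c(pos = 74, neg = 33),
                          rday_kappa = 8,
                          half_life_mean = 12.5,
                          compliant_fraction = 1,
                          pre_transplant = TRUE,
                          seed = 1L) {
  stopifnot(n_patients >= 2L, n_pos >= 1L, n_pos < n_patients,
            noise_sigma >= 0, all(model1_fraction >= 0 & model1_fraction <= 1),
            all(rday_target > 0 & rday_target < 100), rday_kappa > 0,
            half_life_mean > 0, compliant_fraction >= 0,
            compliant_fraction <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 n_pos = as.integer(n_pos),
                 noise_sigma = noise_sigma,
                 model1_fraction = model1_fraction,
                 rday_target = rday_target,
                 rday_kappa = rday_kappa,
                 half_life_mean = half_life_mean,
                 compliant_fraction = compliant_fraction,
                 pre_transplant = pre_transplant,
                 seed = as.integer(seed)),
            class = "sdnam_cohort_config")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# observation days: one optional pre-transplant draw, a first sample in
# days 0-7, then every 3-10 days to day 100 and every 15-30 days to ~249;
# non-compliant schedules sample too sparsely to pass inclusion
sample_schedule <- function(compliant, pre_transplant) {
  days <- integer(0)
  if (pre_transplant) days <- -sample(1:7, 1)
  if (compliant) {
    d <- sample(0:7, 1)
    while (d <= 100) {
      days <- c(days, d)
      d <- d + sample(3:10, 1)
    }
  } else {
    d <- sample(8:20, 1)  # misses the day 0-7 window
    while (d <= 100) {
      days <- c(days, d)
      d <- d + sample(15:30, 1)
    }
  }
  while (d <= 249) {
    days <- c(days, d)
    d <- d + sample(15:30, 1)
  }
  sort(unique(days))
}

# group prior over everything except lam (solved from the R target)
draw_base_params <- function(config) {
  mu <- clip(stats::rlnorm(1, log(log(2) / config$half_life_mean), 0.4),
             2e-3, 1.5)
  N <- clip(stats::rlnorm(1, log(15), 0.4), 1, 80)
  # kernel timed by its mode (k - 1) * theta: the alloreactive burst
  # peaks within the first weeks after engraftment
  k <- stats::runif(1, 2, 6)
  mode_day <- stats::runif(1, 4, 18)
  sdnam_params(
    lam = 0,
    k = k,
    theta = clip(mode_day / (k - 1), 0.5, 60),
    mu = mu,
    r = stats::runif(1, 0.08, 0.25),
    N = N,
    x2_0 = stats::runif(1, 0.05, 0.30) * N,
    x3_0 = clip(stats::rlnorm(1, log(8), 0.5), 0.5, 40))
}

# lam making the true transient share at day 30 equal the target
solve_lam <- function(params, target_frac, anchor = 30) {
  unit <- params; unit$lam <- 1
  u1 <- auc_transient(unit, anchor)
  a2 <- auc_persistent(params, anchor)
  target_frac / (1 - target_frac) * a2 / u1
}

#' Draw one synthetic patient
#'
#' @param group `"pos"` (develops acute GVHD) or `"neg"`.
#' @param config An [cohort_config] object.
#' @param patient_id Identifier for the generated patient.
#' @param compliant Whether the sampling schedule must pass the
#'   inclusion rule.
#' @return A list with `params` (true [sdnam_params]), `variant`
#'   (`"model1"` or `"model2"`), `series` (tibble `day`, `sdnam1_pm`),
#'   `truth` (one-row tibble of parameters and true R_day_n) and
#'   `metadata` (one-row tibble). Consumes the current RNG stream; wrap
#'   in a seed for reproducibility (as [generate_cohort] does).
#' @export
sample_patient <- function(group = c("pos", "neg"), config = cohort_config(),
                           patient_id = "P1", compliant = TRUE) {
  group <- match.arg(group)
  params <- draw_base_params(config)
  use_model1 <- stats::runif(1) < config$model1_fraction[[group]]
  if (!use_model1) {
    m <- config$rday_target[[group]] / 100
    a <- m * config$rday_kappa; b <- (1 - m) * config$rday_kappa
    # cap the transient share: lam grows like R/(1-R), and shares much
    # above 95% would push peaks far beyond the observed tens-of-pM scale
    target <- clip(stats::rbeta(1, a, b), 0.02, 0.95)
    params$lam <- solve_lam(params, target)
  }
  days <- sample_schedule(compliant, config$pre_transplant)
  post <- days[days >= 0]
  true_conc <- c(rep(params$x3_0, sum(days < 0)), model_total(post, params))
  noisy <- true_conc * stats::rlnorm(length(days), 0, config$noise_sigma)
  series <- tibble::tibble(day = days, sdnam1_pm = noisy)
  rd <- compute_rday(params, c(20, 30, 40, 50), patient_id = patient_id)
  truth <- tibble::tibble(
    patient_id = patient_id, group = group,
    variant = if (use_model1) "model1" else "model2",
    !!!as.list(unlist(params[param_names()])),
    r_day_20 = rd$r_day_n[[1L]], r_day_30 = rd$r_day_n[[2L]],
    r_day_40 = rd$r_day_n[[3L]], r_day_50 = rd$r_day_n[[4L]])
  metadata <- tibble::tibble(
    patient_id = patient_id,
    gvhd_status = group == "pos",
    gvhd_grade = if (group == "pos") {
      sample(1:4, 1, prob = c(17, 22, 8, 1))
    } else 0L,
    onset_day = if (group == "pos") {
      as.integer(clip(round(stats::rnorm(1, 23, 8)), 5, 50))
    } else NA_integer_,
    tbi = stats::runif(1) < 39 / 67,
    graft = sample(c("BMT", "Other"), 1, prob = c(53, 14)),
    donor = sample(c("RD", "URD"), 1, prob = c(12, 55)),
    conditioning = sample(c("MA", "RIC"), 1, prob = c(45, 22)),
    allele = sample(c("full_match", "mismatch"), 1, prob = c(44, 23)),
    prophylaxis = sample(c("tacrolimus", "csa"), 1, prob = c(43, 24)),
    diagnosis = sample(c("AML", "ALL", "MDS", "Other"), 1,
                       prob = c(28, 13, 9, 17)))
  list(params = params, variant = truth$variant, series = series,
       truth = truth, metadata = metadata)
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param config An [cohort_config] object.
#' @return A list of class `sdnam_cohort`: `measurements` (long tibble
#'   `patient_id`, `day`, `sdnam1_pm`), `metadata` (one row per patient)
#'   and `truth` (generating parameters and true R_day_n per patient;
#'   for validation only, never an input to the analysis), plus the
#'   `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 6, n_pos = 4, seed = 7))
#' cohort$measurements
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "sdnam_cohort_config"))
  with_seed(config$seed, {
    groups <- c(rep("pos", config$n_pos),
                rep("neg", config$n_patients - config$n_pos))
    # the first `compliant_fraction` of each group gets an
    # inclusion-guaranteed sampling schedule
    compliant <- logical(length(groups))
    for (idx in split(seq_along(groups), groups)) {
      compliant[idx] <- seq_along(idx) <=
        round(config$compliant_fraction * length(idx))
    }
    ids <- sprintf("P%03d", seq_along(groups))
    patients <- purrr::pmap(
      list(groups, ids, compliant),
      function(g, id, cp) sample_patient(g, config, id, compliant = cp))
    structure(list(
      measurements = purrr::map_dfr(patients, function(p) {
        dplyr::mutate(p$series, patient_id = p$truth$patient_id,
                      .before = 1L)
      }),
      metadata = purrr::map_dfr(patients, "metadata"),
      truth = purrr::map_dfr(patients, "truth"),
      config = config
    ), class = "sdnam_cohort")
  })
}

#' @export
print.sdnam_cohort <- function(x, ...) {
  cat(sprintf("<sdnam_cohort> %d patients (%d GVHD+), %d measurements, seed %d\n",
              nrow(x$metadata), sum(x$metadata$gvhd_status),
              nrow(x$measurements), x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `measurements.csv`, `metadata.csv` and `truth.csv` in the same
#' dialect [read_measurements] and [read_metadata] expect.
#'
#' @param cohort An `sdnam_cohort` from [generate_cohort].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sdnam_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("measurements.csv", "metadata.csv", "truth.csv"))
  readr::write_csv(cohort$measurements, paths[[1L]])
  readr::write_csv(cohort$metadata, paths[[2L]])
  readr::write_csv(cohort$truth, paths[[3L]])
  invisible(paths)
}
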