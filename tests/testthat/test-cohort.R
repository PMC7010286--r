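test_that("measurement tables round-trip through CSV unchanged", {
  co <- generate_cohort(cohort_config(n_patients = 4, n_pos = 2, seed = 5))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_measurements(file.path(dir, "measurements.csv"))
  expect_equal(back, co$measurements)
  meta <- read_metadata(file.path(dir, "metadata.csv"))
  expect_identical(meta$patient_id, co$metadata$patient_id)
  expect_identical(meta$gvhd_status, co$metadata$gvhd_status)
})

test_that("measurement validation sorts, averages duplicates, rejects bad rows", {
  raw <- tibble::tibble(patient_id = c("a", "a", "a", "b"),
                        day = c(10, 2, 10, 5),
                        sdnam1_pm = c(4, 6, 8, 3))
  expect_warning(out <- validate_measurements(raw), "duplicate")
  expect_equal(out$day[out$patient_id == "a"], c(2, 10))
  expect_equal(out$sdnam1_pm[out$patient_id == "a"], c(6, 6))
  # out-of-order input sorts to identical content
  shuffled <- tibble::tibble(patient_id = "c", day = c(30, 1, 10),
                             sdnam1_pm = c(3, 1, 2))
  expect_equal(validate_measurements(shuffled)$day, c(1, 10, 30))
  expect_error(validate_measurements(tibble::tibble(patient_id = "a", day = 1)),
               "missing columns")
  expect_error(validate_measurements(
    tibble::tibble(patient_id = "a", day = 1, sdnam1_pm = -2)), "negative")
  expect_error(validate_measurements(
    tibble::tibble(patient_id = "a", day = "x", sdnam1_pm = 1)), "non-numeric")
})

test_that("metadata validation enforces the grade/onset coherence rules", {
  dir <- withr::local_tempdir()
  good <- tibble::tibble(patient_id = c("a", "b"), gvhd_status = c(1, 0),
                         gvhd_grade = c(2, 0), onset_day = c(20, NA))
  readr::write_csv(good, file.path(dir, "m.csv"))
  expect_identical(read_metadata(file.path(dir, "m.csv"))$gvhd_status,
                   c(TRUE, FALSE))
  bad <- good; bad$gvhd_grade <- c(0, 0)
  readr::write_csv(bad, file.path(dir, "bad.csv"))
  expect_error(read_metadata(file.path(dir, "bad.csv")), "gvhd_grade")
  bad2 <- good; bad2$onset_day <- c(NA, NA)
  readr::write_csv(bad2, file.path(dir, "bad2.csv"))
  expect_error(read_metadata(file.path(dir, "bad2.csv")), "onset_day")
})

test_that("inclusion rule: eight observations in 0-100 and one in 0-7", {
  mk <- function(id, days) tibble::tibble(patient_id = id, day = days,
                                          sdnam1_pm = 10)
  meas <- dplyr::bind_rows(
    mk("in8", seq(1, 90, length.out = 8)),       # exactly 8, first within 7
    mk("few", seq(1, 90, length.out = 7)),       # only 7 in the window
    mk("late", seq(10, 100, length.out = 10)),   # none within day 7
    mk("pre", c(-7, seq(1, 90, length.out = 8))))# pre-transplant ignored
  res <- inclusion_filter(meas)
  expect_identical(res$included[match(c("in8", "few", "late", "pre"),
                                      res$patient_id)],
                   c(TRUE, FALSE, FALSE, TRUE))
  expect_match(res$reason[res$patient_id == "few"], "fewer than 8")
  expect_match(res$reason[res$patient_id == "late"], "0-7")
  # disposition conservation
  expect_identical(sum(res$included) + sum(!res$included), 4L)
})

test_that("non-compliant synthetic schedules are excluded, compliant pass", {
  co <- generate_cohort(cohort_config(n_patients = 8, n_pos = 5, seed = 13,
                                      compliant_fraction = 0.5))
  res <- inclusion_filter(co$measurements)
  # round() halves go to even: round(.5*5) + round(.5*3) = 2 + 2
  expect_identical(sum(res$included), 4L)
  expect_identical(nrow(res), 8L)
})

test_that("pipeline honours horizons, writes outputs, and reruns identically", {
  co <- generate_cohort(cohort_config(n_patients = 6, n_pos = 4, seed = 31,
                                      noise_sigma = 0.05))
  opts <- fit_options(n_starts = 6, n_hops = 3, seed = 9)
  dir <- withr::local_tempdir()
  res <- run_pipeline(co$measurements, co$metadata, horizons = 30,
                      options = opts, out_dir = dir)
  expect_identical(nrow(res$group_comparisons), 1L)
  expect_identical(nrow(res$roc), 1L)
  expect_identical(res$preference$n_fit, 6L)
  expect_true(file.exists(file.path(dir, "rday.csv")))
  expect_true(file.exists(file.path(dir, "run_log.txt")))
  # per-patient report carries both variants for every patient
  expect_identical(nrow(res$fits), 12L)
  # determinism: a rerun reproduces every result table exactly
  res2 <- run_pipeline(co$measurements, co$metadata, horizons = 30,
                       options = opts)
  expect_identical(res$rday, res2$rday)
  expect_identical(res$group_comparisons, res2$group_comparisons)
  expect_identical(res$roc, res2$roc)
})
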