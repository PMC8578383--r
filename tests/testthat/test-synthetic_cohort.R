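# Small cohorts keep these tests fast; study-scale behavior is exercised in
# test-acceptance.R.
small_config <- function(seed = 1, ...) {
  cohort_config(n_candidates = 24, seed = seed, duration = 60, fps = 30,
                n_rated = 20, gender_counts = c(female = 9, male = 9,
                                                other = 6), ...)
}

test_that("configs validate planted effects against the feature vocabulary", {
  expect_s3_class(default_study_config(), "cohort_config")
  expect_error(cohort_config(planted_effects = list(
    bogus_feature = list(slope = 1, base = 0))), "unknown feature")
  expect_error(cohort_config(planted_effects = list(
    AU12_trend = list(slope = 1, base = 0))), "not generatively controllable")
  expect_error(cohort_config(planted_effects = list(
    happiness_rate = list(slope = 1, base = 0))), "AU")
  expect_error(cohort_config(n_candidates = 1), "n_candidates")
})

test_that("equal seeds give byte-identical cohorts and written files", {
  c1 <- generate_cohort(small_config(seed = 5))
  c2 <- generate_cohort(small_config(seed = 5))
  expect_identical(c1$recordings[[3]]$traces, c2$recordings[[3]]$traces)
  expect_identical(c1$recruiter_matrix$values, c2$recruiter_matrix$values)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1); write_cohort(c2, d2)
  f1 <- file.path(d1, "recordings", "cand003.csv")
  f2 <- file.path(d2, "recordings", "cand003.csv")
  expect_identical(readLines(f1), readLines(f2))

  c3 <- generate_cohort(small_config(seed = 6))
  expect_false(identical(c1$recordings[[3]]$traces$AU12,
                         c3$recordings[[3]]$traces$AU12))
})

test_that("generated recordings parse through the OpenFace reader with zero warnings", {
  co <- generate_cohort(small_config(seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_no_warning({
    rec <- read_openface_csv(file.path(dir, "recordings", "cand001.csv"))
  })
  expect_length(rec$traces, 17)
  # fps is inferred from timestamps printed at 4 decimals
  expect_equal(rec$fps, 30, tolerance = 1e-2)
  expect_equal(rec$n_interpolated, 0L)
  # written trace values match the in-memory cohort to print precision
  expect_equal(rec$traces$AU12, co$recordings[[1]]$traces$AU12,
               tolerance = 1e-5)
  # ratings and ground truth parse back too
  rm_ <- read_ratings_table(file.path(dir, "recruiter_ratings.csv"))
  expect_equal(rm_$values, co$recruiter_matrix$values)
})

test_that("self-reports are rounded, clipped, and carry the configured demographics", {
  co <- generate_cohort(small_config(seed = 2))
  sr <- co$self_reports
  expect_true(all(sr$self_report == round(sr$self_report)))
  expect_true(all(sr$self_report >= 1 & sr$self_report <= 10))
  expect_equal(sr$self_report,
               pmin(10, pmax(1, round(co$ground_truth$m_latent))))
  expect_equal(unname(table(sr$gender)[c("female", "male", "other")]),
               c(9L, 9L, 6L), ignore_attr = TRUE)
  expect_true(all(sr$age >= 18 & sr$age <= 26))
})

test_that("zero-noise rate planting round-trips through the extractor within 10%", {
  cfg <- cohort_config(
    n_candidates = 12, seed = 4, duration = 120, n_rated = 10,
    trace_noise_sd = 0, candidate_sd = 0,
    planted_effects = list(AU12_rate = list(slope = 0.5, base = 2.5,
                                            noise = 0)))
  co <- generate_cohort(cfg)
  got <- co$feature_matrix$values[, "AU12_rate"]
  want <- co$ground_truth[, "AU12_rate"]
  expect_true(all(abs(got - want) / want <= 0.10))
})

test_that("mean-level planting is recovered in expectation at zero noise", {
  cfg <- cohort_config(
    n_candidates = 12, seed = 8, duration = 60, trace_noise_sd = 0,
    candidate_sd = 0, n_rated = 10,
    planted_effects = list(AU04_mean_raw = list(slope = -0.1, base = 1.3,
                                                noise = 0)))
  co <- generate_cohort(cfg)
  got <- co$feature_matrix$values[, "AU04_mean_raw"]
  want <- co$ground_truth[, "AU04_mean_raw"]
  # background episodes add a small positive mass on top of the level
  expect_true(all(got >= want - 1e-9))
  expect_lt(max(got - want), 0.25)
  expect_gt(cor(got, want), 0.99)
})

test_that("negative validity weight produces anticorrelated recruiter means", {
  cfg <- cohort_config(n_candidates = 200, seed = 10, duration = 60,
                       fps = 25, n_rated = 200,
                       gender_counts = c(female = 70, male = 70, other = 60))
  co <- generate_cohort(cfg)
  rec_mean <- colMeans(co$recruiter_matrix$values, na.rm = TRUE)
  rho <- cor(rec_mean, co$self_reports$self_report, method = "spearman")
  expect_lt(rho, 0)
})

test_that("the latent motivation distribution hits the configured observed moments", {
  # accumulate over several seeds at study scale
  ms <- unlist(lapply(1:3, function(s) {
    generate_cohort(cohort_config(n_candidates = 154, seed = s,
                                  duration = 20, fps = 15,
                                  n_rated = 100))$self_reports$self_report
  }))
  expect_lt(abs(mean(ms) - 4.6), 0.5)
  expect_lt(abs(sd(ms) - 2.5), 0.4)
})
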