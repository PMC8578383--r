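test_that("emotion composition averages constituent AUs and derives valence", {
  n <- 10
  traces <- setNames(lapply(au_channels(), function(a) rep(0, n)),
                     au_channels())
  rec <- make_recording(traces = traces)
  emo <- compose_emotions(rec)
  expect_setequal(names(emo),
                  c(names(default_emotion_mapping()), "valence"))
  for (e in emo) expect_equal(e, rep(0, n))

  # frame with AU06 = AU12 = 2 -> happiness 2 there; valence = happiness
  # when all negative emotions are silent
  traces$AU06[3] <- 2; traces$AU12[3] <- 2
  rec <- make_recording(traces = traces)
  emo <- compose_emotions(rec)
  expect_equal(emo$happiness[3], 2)
  expect_equal(emo$valence, emo$happiness - (emo$anger + emo$disgust +
                                               emo$fear + emo$sadness) / 4)

  bad <- default_emotion_mapping()
  bad$happiness <- c("AU06", "AU99")
  expect_error(compose_emotions(rec, bad), "AU99")
})

test_that("episode detection matches hand-computed toy cases", {
  # constant trace: SD = 0, nothing strictly above threshold
  expect_equal(nrow(detect_episodes(c(1, 1, 1, 1), fps = 1)), 0)

  # [0,0,5,5,0,0,5,0] at fps 1: median 0, population SD 2.4206,
  # threshold 2.4206 -> runs {3,4} and {7}
  eps <- detect_episodes(c(0, 0, 5, 5, 0, 0, 5, 0), fps = 1)
  expect_equal(nrow(eps), 2)
  expect_equal(eps$start, c(3, 7))
  expect_equal(eps$duration, c(2, 1))
  expect_equal(eps$amplitude, c(5, 5))
  expect_equal(attr(eps, "threshold"), median(c(0,0,5,5,0,0,5,0)) +
                 sqrt(mean((c(0,0,5,5,0,0,5,0) - 15/8)^2)))
  expect_equal(eps$area, (5 - attr(eps, "threshold")) * c(2, 1))
})

test_that("episode detection equals the brute-force scan on random traces", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(2:200, 1)
    v <- switch(sample(3, 1),
                rnorm(n),
                round(runif(n) * 4) / 2,      # plateaus and exact ties
                abs(rnorm(n)) * rbinom(n, 1, 0.3))
    got <- detect_episodes(v, fps = 25)
    want <- brute_force_episodes(v, fps = 25)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$area, want$area, tolerance = 1e-12)
      expect_equal(got$amplitude, want$amplitude)
      # invariants: nonnegative area/duration, amplitude above threshold
      expect_true(all(got$area >= 0))
      expect_true(all(got$duration > 0))
      expect_true(all(got$amplitude > attr(got, "threshold")))
    }
  }
})

test_that("feature extraction has the documented closed forms and conventions", {
  # constant trace: mean_raw = c, everything else zero
  f <- extract_features(rep(2.5, 100), fps = 10, label = "x")
  expect_equal(unname(f), c(2.5, 0, 0, 0, 0, 0, 0))

  # pure ramp 0.5 * t over 10 s: OLS slope exactly 0.5 units/s
  t10 <- seq(0, 10, by = 0.1)
  f <- extract_features(0.5 * t10, fps = 10, label = "ramp")
  expect_equal(f[["ramp_trend"]], 0.5, tolerance = 1e-9)

  # trend equals an independent two-pass covariance/variance slope
  set.seed(7)
  v <- cumsum(rnorm(500)) / 10 + 3
  f <- extract_features(v, fps = 20, label = "w")
  tt <- (seq_along(v) - 1) / 20
  slope_oracle <- sum((tt - mean(tt)) * (v - mean(v))) /
    sum((tt - mean(tt))^2)
  expect_equal(f[["w_trend"]], slope_oracle, tolerance = 1e-9)

  expect_error(extract_features(c(1, NA, 3), fps = 1), "non-finite")
})

test_that("extraction is shift-invariant except mean_raw, and fps-doubling invariant", {
  set.seed(11)
  v <- abs(rnorm(400)) + 2 * (runif(400) < 0.1)
  f0 <- extract_features(v, fps = 20, label = "t")
  f1 <- extract_features(v + 3.7, fps = 20, label = "t")
  expect_equal(f1[["t_mean_raw"]], f0[["t_mean_raw"]] + 3.7)
  expect_equal(f1[["t_mean_highpass"]], f0[["t_mean_highpass"]])
  expect_equal(f1[["t_trend"]], f0[["t_trend"]])
  expect_equal(f1[["t_rate"]], f0[["t_rate"]])
  expect_equal(f1[["t_mean_duration"]], f0[["t_mean_duration"]])
  expect_equal(f1[["t_mean_area"]], f0[["t_mean_area"]])
  # amplitude shifts with the trace, like the threshold
  expect_equal(f1[["t_mean_amplitude"]], f0[["t_mean_amplitude"]] + 3.7)

  # duplicating every sample at doubled fps leaves duration-based features
  v2 <- rep(v, each = 2)
  f2 <- extract_features(v2, fps = 40, label = "t")
  for (s in c("t_rate", "t_mean_duration", "t_mean_area")) {
    expect_equal(f2[[s]], f0[[s]], tolerance = 1e-6)
  }
})

test_that("high-pass statistic can be signed via config and is ~0 then", {
  set.seed(3)
  v <- rnorm(2000) + 5
  f <- extract_features(v, fps = 20, label = "x", rectify = FALSE)
  expect_lt(abs(f[["x_mean_highpass"]]), 0.05)
  f2 <- extract_features(v, fps = 20, label = "x", rectify = TRUE)
  expect_gt(f2[["x_mean_highpass"]], 0.5)
})

test_that("the feature matrix has 168 deterministic columns and row-order invariance", {
  expect_length(feature_vocabulary(), 7 * (17 + 6 + 1))
  set.seed(5)
  recs <- lapply(1:4, function(i) {
    traces <- setNames(lapply(au_channels(), function(a) abs(rnorm(150))),
                       au_channels())
    make_recording(id = paste0("c", i), n_frames = 150, traces = traces)
  })
  fm <- build_feature_matrix(recs)
  expect_equal(dim(fm$values), c(4, 168))
  expect_equal(fm$feature_names, feature_vocabulary())

  fm_perm <- build_feature_matrix(recs[c(3, 1, 4, 2)])
  expect_equal(fm_perm$values[fm$candidate_ids, ], fm$values)

  expect_error(build_feature_matrix(recs[c(1, 1)]), "duplicate")

  # single constant-trace recording: means and zeros per convention
  const <- make_recording(id = "k", n_frames = 60)
  row <- build_feature_matrix(list(const))$values[1, ]
  expect_equal(unname(row["AU01_mean_raw"]), 0.5)
  expect_equal(unname(row["AU01_rate"]), 0)
  expect_equal(unname(row["valence_mean_raw"]), 0.5 - 0.5)
})
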