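# Helper: wrap a plain matrix as a feature_matrix.
fm_of <- function(X, ids = sprintf("c%03d", seq_len(nrow(X))),
                  feats = sprintf("f%02d", seq_len(ncol(X)))) {
  dimnames(X) <- list(ids, feats)
  feature_matrix(X)
}

test_that("screening ranks by |Spearman| and keeps the stated fraction", {
  set.seed(1)
  n <- 80
  target <- rnorm(n)
  X <- cbind(target + rnorm(n, 0, 0.01),
             -target + rnorm(n, 0, 0.01),
             target + rnorm(n, 0, 0.02),
             matrix(rnorm(n * 7), n, 7))
  fm <- fm_of(X)
  rep_ <- screen_by_correlation(fm, target, fraction = 0.3)
  expect_setequal(rep_$selected, c("f01", "f02", "f03"))

  # brute-force ranking oracle
  oracle <- abs(apply(X, 2, function(x)
    cor(x, target, method = "spearman")))
  expect_equal(rep_$ranked$abs_cor,
               sort(oracle, decreasing = TRUE), tolerance = 1e-12,
               ignore_attr = TRUE)

  # fraction 1 keeps everything
  expect_length(screen_by_correlation(fm, target, 1)$selected, 10)
  # default fraction on the full vocabulary: round(0.3 * 168) = 50
  expect_equal(max(1, round(0.3 * length(feature_vocabulary()))), 50)
  expect_error(screen_by_correlation(fm, rep(2, n)), "constant target")
})

test_that("VIF pruning removes collinear features and logs replacements", {
  set.seed(2)
  n <- 100
  X <- matrix(rnorm(n * 8), n, 8)
  X[, 2] <- X[, 1]  # exact duplicate pair
  target <- X[, 1] + 0.5 * X[, 3] + rnorm(n, 0, 0.2)
  fm <- fm_of(X)
  rep_ <- screen_by_correlation(fm, target, fraction = 0.5)
  expect_true(all(c("f01", "f02") %in% rep_$selected))
  pruned <- prune_by_vif(fm, rep_, vif_max = 10)
  # exactly one of the duplicated pair survives, with a logged replacement
  expect_equal(sum(c("f01", "f02") %in% pruned$selected), 1)
  expect_gte(nrow(pruned$vif_history), 1)
  expect_true(pruned$vif_history$removed[1] %in% c("f01", "f02"))
  expect_false(is.na(pruned$vif_history$replacement[1]))
  # final set satisfies the ceiling
  vif_final <- motivAU:::vif_values(
    fm$values[, pruned$selected, drop = FALSE])
  expect_true(all(vif_final <= 10))
})

test_that("VIF values agree with the car::vif oracle and orthogonal sets pass untouched", {
  skip_if_not_installed("car")
  set.seed(3)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5)
  X[, 5] <- X[, 1] + X[, 2] + rnorm(n, 0, 0.3)
  y <- rnorm(n)
  df <- data.frame(y = y, X)
  oracle <- unname(car::vif(lm(y ~ ., data = df)))
  expect_equal(unname(motivAU:::vif_values(X)), oracle, tolerance = 1e-8)

  # orthogonal columns: all VIF 1, report unchanged
  Q <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  fmq <- fm_of(Q * sqrt(n))
  repq <- screen_by_correlation(fmq, rnorm(n), fraction = 1)
  pruned <- prune_by_vif(fmq, repq, vif_max = 10)
  expect_equal(sort(pruned$selected), sort(repq$selected))
  expect_equal(nrow(pruned$vif_history), 0)
})

test_that("lasso solutions match the separable closed form on an orthonormal design", {
  set.seed(4)
  n <- 400
  A <- scale(matrix(rnorm(n * 2), n, 2), scale = FALSE)
  Q <- qr.Q(qr(A))           # orthonormal, columns mean ~0
  X <- Q * sqrt(n - 1)       # sample SD exactly 1, X'X = (n-1) I
  y <- 2 * X[, 1] - 1 * X[, 2]
  lam <- c(0.1, 1000)
  fit <- lasso_fit(X, y, lam)
  # objective (1/2n)RSS + lambda |b| with (1/n) X'X = ((n-1)/n) I gives
  # b_j = S(x_j' y / n, lambda) / ((n-1)/n)
  cc <- (n - 1) / n
  oracle <- function(l) {
    b <- drop(crossprod(X, y)) / n
    sign(b) * pmax(0, abs(b) - l) / cc
  }
  expect_equal(unname(fit$coefficients[, 1]), oracle(0.1), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients[, 2]), c(0, 0))
  # smallest-penalty residual: each coefficient shrunk by lambda/cc on
  # columns with second moment cc, so RMSE = lambda * sqrt(2/cc)
  pred <- drop(X %*% fit$coefficients[, 1]) + fit$intercepts[1]
  expect_equal(sqrt(mean((y - pred)^2)), 0.1 * sqrt(2 / cc),
               tolerance = 1e-4)
})

test_that("repeated CV is deterministic, grid-complete, and picks minimal mean RMSE", {
  set.seed(5)
  n <- 60
  X <- matrix(rnorm(n * 6), n, 6)
  y <- X[, 1] - 2 * X[, 2] + rnorm(n, 0, 0.5)
  fm <- fm_of(X)
  cv1 <- fit_lasso_cv(fm, y, fm$feature_names, n_iterations = 30, seed = 99)
  cv2 <- fit_lasso_cv(fm, y, fm$feature_names, n_iterations = 30, seed = 99)
  expect_identical(cv1, cv2)  # bit-identical under the same seed

  expect_length(cv1$alphas, 20)
  expect_equal(range(cv1$alphas), c(0.1, 1000))
  expect_true(all(diff(cv1$alphas) > 0))
  expect_true(all(cv1$rmse >= 0))
  expect_true(cv1$chosen_alpha %in% cv1$alphas)
  # chosen alpha attains the minimal mean test RMSE
  expect_equal(cv1$mean_rmse[cv1$alphas == cv1$chosen_alpha],
               min(cv1$mean_rmse), tolerance = 1e-12)
  # extreme regularization suppresses all weights to zero
  expect_equal(unname(cv1$weight_paths[, 20]), rep(0, 6))
  # L1 norm of the mean coefficient path shrinks along the grid
  l1 <- colSums(abs(cv1$weight_paths))
  expect_true(all(diff(l1) <= 1e-6))

  expect_error(fit_lasso_cv(fm, y, fm$feature_names, n_iterations = 5,
                            test_fraction = 0.01, seed = 1),
               "configuration error")
})

test_that("simplification drops features iff their p-value exceeds the ceiling", {
  set.seed(6)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5)
  y <- 1.5 * X[, 1] - X[, 2] + rnorm(n, 0, 0.5)
  fm <- fm_of(X)
  cv <- fit_lasso_cv(fm, y, fm$feature_names, n_iterations = 20, seed = 7)
  model <- simplify_and_finalize(fm, y, cv, p_max = 0.75)
  expect_true(all(model$pvalues <= 0.75))
  expect_true(all(c("f01", "f02") %in% names(model$coefficients)))
  expect_equal(sign(model$coefficients[["f01"]]), 1)
  expect_equal(sign(model$coefficients[["f02"]]), -1)

  # stepwise removal equals an oracle replay: repeatedly drop current max p
  Xz <- scale(fm$values[, cv$selected])
  support_oracle <- cv$selected[
    lasso_fit(Xz, y, cv$chosen_alpha)$coefficients[, 1] != 0]
  repeat {
    d <- data.frame(Xz[, support_oracle, drop = FALSE], check.names = FALSE)
    d$.y <- y
    pv <- summary(lm(.y ~ ., data = d))$coefficients[-1, 4]
    names(pv) <- support_oracle
    if (all(pv <= 0.75)) break
    support_oracle <- setdiff(support_oracle, names(which.max(pv)))
  }
  expect_setequal(names(model$coefficients), support_oracle)
})

test_that("a pure-noise column is dropped exactly when its refit p exceeds 0.75", {
  # a vanishing penalty keeps the whole support, isolating the stepwise
  # p-filter; across seeds the drop frequency tracks P(p > 0.75) = 0.25
  set.seed(8)
  dropped <- logical(0)
  for (i in 1:60) {
    n <- 200
    X <- cbind(rnorm(n), rnorm(n), rnorm(n))
    y <- 2 * X[, 1] - X[, 2] + rnorm(n, 0, 0.5)
    fm <- fm_of(X)
    if (any(lasso_fit(scale(X), y, 1e-6)$coefficients[, 1] == 0)) next
    cv <- structure(list(alphas = default_alpha_grid(),
                         chosen_alpha = 1e-6, selected = fm$feature_names),
                    class = "cv_result")
    model <- simplify_and_finalize(fm, y, cv, p_max = 0.75)
    p_noise <- summary(lm(y ~ scale(X)))$coefficients[4, 4]
    got <- !("f03" %in% names(model$coefficients))
    expect_equal(got, p_noise > 0.75)
    dropped <- c(dropped, got)
  }
  expect_gt(mean(dropped), 0.05)
  expect_lt(mean(dropped), 0.5)
})

test_that("degenerate supports raise the advisory error", {
  set.seed(9)
  X <- matrix(rnorm(50 * 3), 50, 3)
  y <- rnorm(50)
  fm <- fm_of(X)
  cv <- structure(list(alphas = default_alpha_grid(),
                       chosen_alpha = 1000, selected = fm$feature_names),
                  class = "cv_result")
  expect_error(simplify_and_finalize(fm, y, cv), "smaller regularization")
})

test_that("prediction applies stored standardization, clips to scale, and names missing features", {
  set.seed(10)
  n <- 120
  X <- matrix(rnorm(n * 4, mean = 5, sd = 2), n, 4)
  y <- pmin(10, pmax(1, 5 + X[, 1] - 0.8 * X[, 2] + rnorm(n, 0, 0.3)))
  fm <- fm_of(X)
  cv <- fit_lasso_cv(fm, y, fm$feature_names, n_iterations = 20, seed = 11)
  model <- simplify_and_finalize(fm, y, cv)
  pred <- predict(model, fm)
  expect_true(all(pred >= 1 & pred <= 10))
  expect_named(pred, fm$candidate_ids)
  # in-sample fit at least as good as the best single included predictor
  singles <- apply(fm$values, 2, function(x)
    abs(cor(x, y, method = "spearman")))
  expect_gte(abs(cor(pred, y, method = "spearman")), max(singles) - 0.02)

  fm_missing <- fm_of(X[, 1:2, drop = FALSE],
                      feats = names(model$coefficients)[1:2])
  missing_feats <- setdiff(names(model$coefficients),
                           names(model$coefficients)[1:2])
  if (length(missing_feats) > 0) {
    expect_error(predict(model, fm_missing), missing_feats[1], fixed = TRUE)
  }

  # all-zero coefficient model predicts the intercept everywhere
  m0 <- model
  m0$coefficients <- setNames(numeric(0), character(0))
  m0$standardization <- list(mean = numeric(0), sd = numeric(0))
  expect_equal(unname(predict(m0, fm, clip = FALSE)),
               rep(m0$intercept, n))
})

test_that("models serialize to text and round-trip exactly", {
  set.seed(12)
  n <- 80
  X <- matrix(rnorm(n * 3, 2, 1.5), n, 3)
  y <- 4 + X[, 1] - X[, 3] + rnorm(n, 0, 0.4)
  fm <- fm_of(X)
  cv <- fit_lasso_cv(fm, y, fm$feature_names, n_iterations = 10, seed = 13)
  model <- simplify_and_finalize(fm, y, cv, target_label = "recruiter_mean")
  path <- withr::local_tempfile(fileext = ".txt")
  write_motivation_model(model, path, header_lines = "provenance demo")
  back <- read_motivation_model(path)
  expect_equal(back$intercept, model$intercept)
  expect_equal(back$coefficients, model$coefficients)
  expect_equal(back$standardization$mean,
               model$standardization$mean[names(back$coefficients)])
  expect_equal(back$target_label, "recruiter_mean")
  expect_equal(predict(back, fm), predict(model, fm))
})

test_that("CBMM and RBMM are the same code path with different targets", {
  set.seed(13)
  n <- 90
  X <- matrix(rnorm(n * 6), n, 6)
  y1 <- X[, 1] + rnorm(n, 0, 0.4)
  fm <- fm_of(X)
  a <- fit_motivation_model(fm, y1, target_label = "candidate_self_report",
                            n_iterations = 15, seed = 3)
  b <- fit_motivation_model(fm, y1, target_label = "recruiter_mean",
                            n_iterations = 15, seed = 3)
  expect_equal(a$model$coefficients, b$model$coefficients)
  expect_equal(a$model$intercept, b$model$intercept)
  expect_equal(a$model$target_label, "candidate_self_report")
  expect_equal(b$model$target_label, "recruiter_mean")
})
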