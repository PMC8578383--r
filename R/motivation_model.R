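# Sparse linear motivation models: correlation screening, VIF pruning,
# repeated cross-validated Lasso over an alpha grid, stepwise simplification.

#' Default Lasso regularization grid
#'
#' 20 log-spaced penalty strengths from 10^-1 (negligible regularization,
#' coefficients near the least-squares solution) to 10^3 (extreme
#' regularization, all weights suppressed to zero).
#'
#' @return Strictly increasing numeric vector of length 20.
#' @export
default_alpha_grid <- function() 10^seq(-1, 3, length.out = 20)

#' Screen features by rank correlation with the target
#'
#' Ranks all features by the absolute Spearman correlation with the target
#' and keeps the top `round(fraction * n_features)` (at least one). Ties are
#' broken deterministically by feature name; features with undefined
#' correlation (constant columns) rank last with correlation 0.
#'
#' @param matrix A [feature_matrix()].
#' @param target Numeric target scores, one per candidate.
#' @param fraction Fraction of features to keep, in `(0, 1]`. Default 0.3.
#' @return A `screening_report`: list with `ranked` (data.frame of `feature`,
#'   `abs_cor` in rank order), `selected` (kept feature names) and an empty
#'   `vif_history` to be filled by [prune_by_vif()].
#' @export
screen_by_correlation <- function(matrix, target, fraction = 0.3) {
  stopifnot(inherits(matrix, "feature_matrix"))
  stopifnot(length(target) == nrow(matrix$values))
  stopifnot(fraction > 0, fraction <= 1)
  if (stats::sd(target) == 0) {
    stop("constant target: correlation undefined", call. = FALSE)
  }
  abs_cor <- abs(suppressWarnings(
    stats::cor(matrix$values, target, method = "spearman")
  ))[, 1]
  abs_cor[is.na(abs_cor)] <- 0
  ord <- order(-abs_cor, matrix$feature_names)
  ranked <- data.frame(feature = matrix$feature_names[ord],
                       abs_cor = abs_cor[ord], row.names = NULL,
                       stringsAsFactors = FALSE)
  n_keep <- max(1L, round(fraction * nrow(ranked)))
  structure(
    list(ranked = ranked,
         selected = ranked$feature[seq_len(min(n_keep, nrow(ranked)))],
         vif_history = data.frame(removed = character(), vif = numeric(),
                                  replacement = character(),
                                  stringsAsFactors = FALSE)),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %d features ranked, %d selected, %d VIF replacement(s)\n",
              nrow(x$ranked), length(x$selected), nrow(x$vif_history)))
  invisible(x)
}

# VIF_j = 1/(1 - R^2) of standardized feature j regressed on the others.
vif_values <- function(X) {
  Xs <- scale(X)
  Xs[, apply(X, 2, stats::sd) == 0] <- 0
  p <- ncol(Xs)
  vapply(seq_len(p), function(j) {
    others <- Xs[, -j, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, others), Xs[, j])
    tss <- sum(Xs[, j]^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Prune multicollinear features by variance inflation factor
#'
#' Iteratively computes the VIF of every selected feature (1/(1 - R^2) from
#' regressing it on the other selected features). While the maximum VIF
#' exceeds `vif_max`, the offending feature is removed and replaced by the
#' highest-ranked unused feature from the screening ranking; VIFs are
#' recomputed after every replacement. When the reserve pool is exhausted,
#' offenders are dropped without replacement. Every removal is logged.
#'
#' @param matrix A [feature_matrix()].
#' @param report A `screening_report` from [screen_by_correlation()].
#' @param vif_max Maximum tolerated VIF. Default 10.
#' @param victim How to choose which offender (VIF > `vif_max`) to remove at
#'   each step: `"lowest_ranked"` (default) discards the offender that
#'   correlates least with the target, so redundant derived features give
#'   way to the stronger direct predictors they duplicate; `"max_vif"`
#'   removes the feature with the largest VIF.
#' @return The updated `screening_report` (fewer-or-replaced `selected`,
#'   populated `vif_history`). With fewer than two selected features the
#'   report is returned unchanged (VIF undefined).
#' @export
prune_by_vif <- function(matrix, report, vif_max = 10,
                         victim = c("lowest_ranked", "max_vif")) {
  stopifnot(inherits(matrix, "feature_matrix"),
            inherits(report, "screening_report"))
  victim <- match.arg(victim)
  selected <- report$selected
  if (length(selected) < 2) return(report)
  rank_of <- setNames(seq_len(nrow(report$ranked)), report$ranked$feature)
  reserve <- setdiff(report$ranked$feature, selected)
  history <- report$vif_history
  repeat {
    if (length(selected) < 2) break
    vifs <- vif_values(matrix$values[, selected, drop = FALSE])
    worst <- max(vifs)
    if (worst <= vif_max) break
    offenders <- selected[vifs > vif_max]
    out <- if (victim == "lowest_ranked") {
      offenders[which.max(rank_of[offenders])]
    } else {
      # largest VIF, ties by name
      sort(selected[vifs == worst])[1]
    }
    worst <- vifs[selected == out]
    selected <- setdiff(selected, out)
    if (length(reserve) > 0) {
      replacement <- reserve[1]
      reserve <- reserve[-1]
      selected <- c(selected, replacement)
    } else {
      replacement <- NA_character_
    }
    history <- rbind(history, data.frame(removed = out, vif = worst,
                                         replacement = replacement,
                                         stringsAsFactors = FALSE))
  }
  report$selected <- selected
  report$vif_history <- history
  report
}

# Lasso solutions at the given penalties. X is expected already centered /
# standardized by the caller; glmnet's internal standardization is disabled.
# Objective: (1/2n) * RSS + lambda * sum(|beta|).

#' Fit the Lasso at given penalty strengths
#'
#' Low-level solver used by [fit_lasso_cv()] and [simplify_and_finalize()]:
#' minimizes `(1/(2n)) * RSS + lambda * ||beta||_1` with an unpenalized
#' intercept. Predictors are used as passed — callers standardize first.
#'
#' @param X Numeric predictor matrix (n x p).
#' @param y Numeric response.
#' @param lambdas Penalty strengths (any order).
#' @return List with `intercepts` (one per lambda) and `coefficients`
#'   (p x n_lambda matrix), columns in the order of `lambdas`.
#' @export
lasso_fit <- function(X, y, lambdas) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, all(lambdas >= 0))
  ord <- order(lambdas, decreasing = TRUE)
  lam_dec <- lambdas[ord]
  if (p == 1) {
    # closed form: single-coordinate soft threshold
    xc <- X[, 1] - mean(X[, 1]); yc <- y - mean(y)
    r <- mean(xc * yc); v <- mean(xc^2)
    beta <- vapply(lam_dec, function(l) {
      if (v == 0) 0 else sign(r) * max(0, abs(r) - l) / v
    }, numeric(1))
    coefs <- matrix(beta, nrow = 1)
    ints <- mean(y) - beta * mean(X[, 1])
  } else {
    fit <- glmnet::glmnet(X, y, alpha = 1, lambda = lam_dec,
                          standardize = FALSE, intercept = TRUE,
                          thresh = 1e-12, maxit = 1e7)
    cf <- as.matrix(stats::coef(fit))
    # glmnet may drop lambdas it considers redundant; realign by value
    got <- fit$lambda
    idx <- vapply(lam_dec, function(l) which.min(abs(got - l)), integer(1))
    ints <- cf[1, idx]
    coefs <- cf[-1, idx, drop = FALSE]
  }
  inv <- order(ord)
  list(intercepts = unname(ints[inv]),
       coefficients = coefs[, inv, drop = FALSE])
}

standardize_columns <- function(X, center = NULL, scale_ = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale_)) {
    scale_ <- apply(X, 2, stats::sd)
    scale_[scale_ == 0] <- 1
  }
  list(values = sweep(sweep(X, 2, center, "-"), 2, scale_, "/"),
       mean = center, sd = scale_)
}

#' Repeated cross-validated Lasso over the regularization grid
#'
#' For each of `n_iterations` fresh random train/test divisions, predictors
#' are z-scored with training-split statistics, the Lasso is fitted on the
#' training part at every grid penalty, and the test RMSE is recorded per
#' penalty. The chosen penalty minimizes the mean test RMSE, with ties
#' broken toward the larger (more parsimonious) value; `rule = "1se"`
#' instead picks the largest penalty within one standard error of the
#' minimum.
#'
#' @param matrix A [feature_matrix()].
#' @param target Numeric target, one per candidate.
#' @param selected Feature names to use (e.g. from [prune_by_vif()]).
#' @param n_iterations Number of repeated splits. Default 1000.
#' @param test_fraction Fraction of candidates held out per split. Default 0.2.
#' @param seed Integer seed driving all splits; identical seeds give
#'   bit-identical results.
#' @param alphas Penalty grid; see [default_alpha_grid()].
#' @param rule `"min"` (default) or `"1se"`.
#' @return A `cv_result`: list with `alphas`, `rmse` (iterations x alphas),
#'   `mean_rmse`, `weight_paths` (features x alphas, mean standardized
#'   coefficients), `chosen_alpha`, `n_iterations`, `test_fraction`, `seed`,
#'   `selected`.
#' @export
fit_lasso_cv <- function(matrix, target, selected, n_iterations = 1000,
                         test_fraction = 0.2, seed = 1,
                         alphas = default_alpha_grid(), rule = c("min", "1se")) {
  stopifnot(inherits(matrix, "feature_matrix"))
  rule <- match.arg(rule)
  stopifnot(length(selected) >= 1, n_iterations >= 1)
  stopifnot(all(selected %in% matrix$feature_names))
  n <- nrow(matrix$values)
  stopifnot(length(target) == n)
  n_test <- round(test_fraction * n)
  if (n_test < 2 || n - n_test < 2) {
    stop("configuration error: train and test splits need at least 2 ",
         "candidates each", call. = FALSE)
  }
  X <- matrix$values[, selected, drop = FALSE]
  k <- length(alphas)
  set.seed(seed)
  splits <- replicate(n_iterations, sample.int(n, n_test), simplify = FALSE)

  rmse <- base::matrix(NA_real_, n_iterations, k)
  wsum <- base::matrix(0, length(selected), k,
                       dimnames = list(selected, NULL))
  for (i in seq_len(n_iterations)) {
    test <- splits[[i]]
    std <- standardize_columns(X[-test, , drop = FALSE])
    Xte <- sweep(sweep(X[test, , drop = FALSE], 2, std$mean, "-"),
                 2, std$sd, "/")
    fit <- lasso_fit(std$values, target[-test], alphas)
    pred <- sweep(Xte %*% fit$coefficients, 2, fit$intercepts, "+")
    rmse[i, ] <- sqrt(colMeans((pred - target[test])^2))
    wsum <- wsum + fit$coefficients
  }
  mean_rmse <- colMeans(rmse)
  best <- min(mean_rmse)
  if (rule == "min") {
    chosen <- max(alphas[mean_rmse <= best + 1e-12])
  } else {
    se <- stats::sd(rmse[, which.min(mean_rmse)]) / sqrt(n_iterations)
    chosen <- max(alphas[mean_rmse <= best + se])
  }
  structure(
    list(alphas = alphas, rmse = rmse, mean_rmse = mean_rmse,
         weight_paths = wsum / n_iterations, chosen_alpha = chosen,
         n_iterations = n_iterations, test_fraction = test_fraction,
         seed = seed, selected = selected, rule = rule),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d iterations x %d alphas in [%.3g, %.3g]; chosen alpha = %.4g (rule: %s)\n",
              x$n_iterations, length(x$alphas), min(x$alphas), max(x$alphas),
              x$chosen_alpha, x$rule))
  invisible(x)
}

#' Simplify the Lasso support and finalize the model
#'
#' Fits the Lasso at the chosen penalty on the full data (z-scored
#' predictors), takes the nonzero-coefficient support, refits it by ordinary
#' least squares, and then, while any coefficient's p-value exceeds `p_max`,
#' drops the largest-p feature and refits. The final model stores the OLS
#' coefficients (standardized-predictor scale), intercept, p-values, and the
#' full-data standardization constants used by [predict.motivation_model()].
#'
#' @param matrix A [feature_matrix()].
#' @param target Numeric target, one per candidate.
#' @param cv A `cv_result` from [fit_lasso_cv()].
#' @param p_max Maximum tolerated coefficient p-value. Default 0.75.
#' @param target_label Label recorded on the model, e.g.
#'   `"candidate_self_report"` or `"recruiter_mean"`.
#' @param scale_bounds Rating-scale bounds predictions are clipped to.
#' @return A `motivation_model`.
#' @export
simplify_and_finalize <- function(matrix, target, cv, p_max = 0.75,
                                  target_label = "candidate_self_report",
                                  scale_bounds = c(1, 10)) {
  stopifnot(inherits(matrix, "feature_matrix"), inherits(cv, "cv_result"))
  selected <- cv$selected
  X <- matrix$values[, selected, drop = FALSE]
  std <- standardize_columns(X)
  fit <- lasso_fit(std$values, target, cv$chosen_alpha)
  beta <- fit$coefficients[, 1]
  support <- selected[beta != 0]
  if (length(support) == 0) {
    stop("degenerate model: Lasso support empty at alpha = ",
         format(cv$chosen_alpha),
         "; consider a smaller regularization strength", call. = FALSE)
  }
  repeat {
    df <- data.frame(std$values[, support, drop = FALSE], check.names = FALSE)
    df$.target <- target
    ols <- stats::lm(.target ~ ., data = df)
    cf <- summary(ols)$coefficients
    pv <- rep(Inf, length(support))
    names(pv) <- support
    rn <- rownames(cf)[-1]
    # lm backtick-quotes nonsyntactic names
    rn <- gsub("^`|`$", "", rn)
    pv[rn] <- cf[-1, 4]
    pv[is.na(pv)] <- Inf
    if (all(pv <= p_max) || length(support) == 1 && pv[1] > p_max) {
      if (length(support) == 1 && pv[1] > p_max) support <- character(0)
      break
    }
    support <- support[-which.max(pv)]
  }
  if (length(support) == 0) {
    intercept <- mean(target)
    coefficients <- setNames(numeric(0), character(0))
    pvalues <- coefficients
  } else {
    co <- stats::coef(ols)
    intercept <- unname(co[1])
    coefficients <- setNames(unname(co[-1]), support)
    pvalues <- pv[support]
  }
  structure(
    list(intercept = intercept, coefficients = coefficients,
         pvalues = pvalues, chosen_alpha = cv$chosen_alpha,
         standardization = list(mean = std$mean[support],
                                sd = std$sd[support]),
         target_label = target_label,
         scale_min = scale_bounds[1], scale_max = scale_bounds[2]),
    class = "motivation_model"
  )
}

#' @export
print.motivation_model <- function(x, ...) {
  cat(sprintf("<motivation_model> target: %s; alpha = %.4g; %d feature(s)\n",
              x$target_label, x$chosen_alpha, length(x$coefficients)))
  if (length(x$coefficients) > 0) {
    tab <- data.frame(coefficient = round(x$coefficients, 4),
                      p = signif(x$pvalues, 3))
    print(tab)
  }
  cat(sprintf("intercept: %.4f\n", x$intercept))
  invisible(x)
}

#' Predict motivation scores
#'
#' Applies the model's stored standardization to the named feature columns
#' and returns `intercept + sum(coefficient * z-scored feature)`, clipped to
#' the rating scale by default.
#'
#' @param object A `motivation_model`.
#' @param matrix A [feature_matrix()] containing every model feature.
#' @param clip Clip predictions to the model's rating scale. Default `TRUE`.
#' @param ... Unused.
#' @return Named numeric vector of predicted scores, one per candidate.
#' @export
predict.motivation_model <- function(object, matrix, clip = TRUE, ...) {
  stopifnot(inherits(matrix, "feature_matrix"))
  feats <- names(object$coefficients)
  absent <- setdiff(feats, matrix$feature_names)
  if (length(absent) > 0) {
    stop("feature matrix is missing model feature(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (length(feats) == 0) {
    out <- rep(object$intercept, nrow(matrix$values))
  } else {
    Xz <- sweep(sweep(matrix$values[, feats, drop = FALSE], 2,
                      object$standardization$mean, "-"),
                2, object$standardization$sd, "/")
    out <- drop(object$intercept + Xz %*% object$coefficients)
  }
  if (clip) out <- pmin(object$scale_max, pmax(object$scale_min, out))
  setNames(out, matrix$candidate_ids)
}

#' Fit a motivation model end to end
#'
#' Chains [screen_by_correlation()], [prune_by_vif()], [fit_lasso_cv()] and
#' [simplify_and_finalize()]. The candidate-based and recruiter-based models
#' are the identical code path with different targets.
#'
#' @param matrix A [feature_matrix()].
#' @param target Numeric target scores, one per candidate.
#' @param target_label Stored on the model (`"candidate_self_report"` or
#'   `"recruiter_mean"`).
#' @param fraction Screening fraction; default 0.3.
#' @param vif_max VIF ceiling; default 10.
#' @param vif_victim Offender-removal rule, see [prune_by_vif()].
#' @param n_iterations Repeated CV splits; default 1000.
#' @param test_fraction Held-out fraction per split; default 0.2.
#' @param p_max Simplification p ceiling; default 0.75.
#' @param seed Integer seed.
#' @param alphas Regularization grid.
#' @param rule Penalty choice rule, `"min"` or `"1se"`.
#' @return A `motivation_fit`: list with `model`, `screening`, `cv`.
#' @export
fit_motivation_model <- function(matrix, target,
                                 target_label = "candidate_self_report",
                                 fraction = 0.3, vif_max = 10,
                                 vif_victim = "lowest_ranked",
                                 n_iterations = 1000, test_fraction = 0.2,
                                 p_max = 0.75, seed = 1,
                                 alphas = default_alpha_grid(),
                                 rule = "min") {
  screening <- screen_by_correlation(matrix, target, fraction)
  screening <- prune_by_vif(matrix, screening, vif_max, victim = vif_victim)
  cv <- fit_lasso_cv(matrix, target, screening$selected,
                     n_iterations = n_iterations,
                     test_fraction = test_fraction, seed = seed,
                     alphas = alphas, rule = rule)
  model <- simplify_and_finalize(matrix, target, cv, p_max = p_max,
                                 target_label = target_label)
  structure(list(model = model, screening = screening, cv = cv),
            class = "motivation_fit")
}

#' @export
print.motivation_fit <- function(x, ...) {
  print(x$screening); print(x$cv); print(x$model)
  invisible(x)
}

#' Serialize a motivation model as structured text
#'
#' Tab-separated key/value lines plus one `feature` line per coefficient
#' (name, weight, standardization mean/SD, p-value). Round-trips through
#' [read_motivation_model()].
#'
#' @param model A `motivation_model`.
#' @param path Output file path.
#' @param header_lines Optional provenance comment lines.
#' @export
write_motivation_model <- function(model, path, header_lines = character()) {
  stopifnot(inherits(model, "motivation_model"))
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    if (length(header_lines)) paste0("# ", header_lines),
    paste("format", "motivAU-model-v1", sep = "\t"),
    paste("target_label", model$target_label, sep = "\t"),
    paste("chosen_alpha", num(model$chosen_alpha), sep = "\t"),
    paste("intercept", num(model$intercept), sep = "\t"),
    paste("scale_min", num(model$scale_min), sep = "\t"),
    paste("scale_max", num(model$scale_max), sep = "\t"),
    vapply(seq_along(model$coefficients), function(i) {
      f <- names(model$coefficients)[i]
      paste("feature", f, num(model$coefficients[[i]]),
            num(model$standardization$mean[[f]]),
            num(model$standardization$sd[[f]]),
            num(model$pvalues[[f]]), sep = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a motivation model written by [write_motivation_model()]
#'
#' @param path Path to the serialized model.
#' @return A `motivation_model`.
#' @export
read_motivation_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keyed <- function(key) {
    hit <- Filter(function(p) p[1] == key, parts)
    if (length(hit) == 0) stop("model file missing key: ", key, call. = FALSE)
    hit[[1]][2]
  }
  feats <- Filter(function(p) p[1] == "feature", parts)
  fnames <- vapply(feats, `[`, character(1), 2)
  structure(
    list(intercept = as.numeric(keyed("intercept")),
         coefficients = setNames(vapply(feats, function(p) as.numeric(p[3]),
                                        numeric(1)), fnames),
         pvalues = setNames(vapply(feats, function(p) as.numeric(p[6]),
                                   numeric(1)), fnames),
         chosen_alpha = as.numeric(keyed("chosen_alpha")),
         standardization = list(
           mean = setNames(vapply(feats, function(p) as.numeric(p[4]),
                                  numeric(1)), fnames),
           sd = setNames(vapply(feats, function(p) as.numeric(p[5]),
                                numeric(1)), fnames)),
         target_label = keyed("target_label"),
         scale_min = as.numeric(keyed("scale_min")),
         scale_max = as.numeric(keyed("scale_max"))),
    class = "motivation_model"
  )
}
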