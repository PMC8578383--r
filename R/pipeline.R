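# End-to-end orchestration: extract -> fit -> evaluate, with reproducible
# seeds and provenance headers on every output file.

pkg_version <- function() {
  as.character(utils::packageVersion("motivAU"))
}

config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(x), tf)
  unname(tools::md5sum(tf))
}

provenance <- function(seed, config) {
  sprintf("motivAU %s | seed=%s | config=%s", pkg_version(), seed,
          config_hash(config))
}

#' Extract features from a directory of recordings
#'
#' Reads every `*.csv` under `recordings` (or accepts a list of
#' `candidate_recording` objects), builds the feature matrix, and writes the
#' feature table plus an extraction log (per candidate: frames, interpolated
#' frames, episode count summed over traces). Unreadable recordings are
#' reported per file; the run continues and fails at the end if any file
#' failed.
#'
#' @param recordings Directory path, or list of `candidate_recording`s.
#' @param features_path Output path for the feature table.
#' @param log_path Optional output path for the extraction log.
#' @param min_confidence Passed to [read_openface_csv()].
#' @param mapping,lowpass_window Passed to [build_feature_matrix()].
#' @param demographics Optional data.frame (`candidate_id`, `gender`, `age`)
#'   attached to recordings read from disk.
#' @param header_lines Provenance lines for the output files.
#' @return The [feature_matrix()], invisibly.
#' @export
run_extract <- function(recordings, features_path, log_path = NULL,
                        min_confidence = 0.75,
                        mapping = default_emotion_mapping(),
                        lowpass_window = 10, demographics = NULL,
                        header_lines = character()) {
  if (is.character(recordings)) {
    files <- sort(list.files(recordings, pattern = "\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0) {
      stop("no recordings found in ", recordings, call. = FALSE)
    }
    failures <- character()
    recs <- list()
    for (f in files) {
      rec <- tryCatch(read_openface_csv(f, min_confidence = min_confidence),
                      error = function(e) {
                        failures <<- c(failures,
                                       paste0(basename(f), ": ",
                                              conditionMessage(e)))
                        NULL
                      })
      if (!is.null(rec)) {
        if (!is.null(demographics)) {
          hit <- match(rec$candidate_id, demographics$candidate_id)
          if (!is.na(hit)) {
            rec$gender <- demographics$gender[hit]
            rec$age <- demographics$age[hit]
          }
        }
        recs[[length(recs) + 1]] <- rec
      }
    }
    if (length(failures) > 0) {
      stop("failed to read ", length(failures), " recording(s):\n",
           paste(failures, collapse = "\n"), call. = FALSE)
    }
    recordings <- recs
  }
  fm <- build_feature_matrix(recordings, mapping = mapping,
                             lowpass_window = lowpass_window)
  write_feature_table(fm, features_path, header_lines = header_lines)
  if (!is.null(log_path)) {
    log_df <- data.frame(
      candidate_id = vapply(recordings, `[[`, character(1), "candidate_id"),
      n_frames = vapply(recordings, `[[`, integer(1), "n_frames"),
      n_interpolated = vapply(recordings, `[[`, integer(1), "n_interpolated"),
      total_episode_rate = rowSums(
        fm$values[, grepl("_rate$", fm$feature_names), drop = FALSE]),
      stringsAsFactors = FALSE
    )
    lines <- c(if (length(header_lines)) paste0("# ", header_lines),
               paste(names(log_df), collapse = ","),
               apply(log_df, 1, function(r) paste(trimws(r), collapse = ",")))
    writeLines(lines, log_path)
  }
  invisible(fm)
}

join_target <- function(fm, targets, score_col) {
  hit <- match(fm$candidate_ids, targets$candidate_id)
  orphans_f <- fm$candidate_ids[is.na(hit)]
  orphans_t <- setdiff(targets$candidate_id, fm$candidate_ids)
  if (length(orphans_f) > 0 || length(orphans_t) > 0) {
    stop("candidate-id mismatch between features and targets; ",
         "features-only: [", paste(orphans_f, collapse = ", "),
         "]; targets-only: [", paste(orphans_t, collapse = ", "), "]",
         call. = FALSE)
  }
  setNames(targets[[score_col]][hit], fm$candidate_ids)
}

#' Fit a motivation model from files or in-memory objects
#'
#' Joins the feature table with the target table on `candidate_id`, runs the
#' full modeling chain ([fit_motivation_model()]) with
#' `target_label = "candidate_self_report"` (CBMM) or `"recruiter_mean"`
#' (RBMM, trained on each candidate's mean recruiter rating), and serializes
#' the model, the RMSE-versus-alpha diagnostics and the screening/VIF log.
#'
#' @param features A [feature_matrix()] or path readable by
#'   [read_feature_table()].
#' @param targets For the CBMM: data.frame with `candidate_id` and
#'   `self_report` (or a CSV path). For the RBMM: a [ratings_matrix()] or
#'   ratings-table path, whose per-candidate mean becomes the target.
#' @param target_label `"candidate_self_report"` or `"recruiter_mean"`.
#' @param outdir If not `NULL`, writes `model_<label>.txt`,
#'   `cv_rmse_<label>.csv` and `screening_<label>.csv` there.
#' @param seed,n_iterations,fraction,vif_max,test_fraction,p_max,alphas,rule
#'   Passed to [fit_motivation_model()].
#' @return The `motivation_fit`, invisibly.
#' @export
run_fit <- function(features, targets,
                    target_label = c("candidate_self_report",
                                     "recruiter_mean"),
                    outdir = NULL, seed = 1, n_iterations = 1000,
                    fraction = 0.3, vif_max = 10, test_fraction = 0.2,
                    p_max = 0.75, alphas = default_alpha_grid(),
                    rule = "min") {
  target_label <- match.arg(target_label)
  if (is.character(features)) features <- read_feature_table(features)
  if (target_label == "candidate_self_report") {
    if (is.character(targets)) {
      targets <- utils::read.csv(targets, comment.char = "#")
    }
    target <- join_target(features, targets, "self_report")
  } else {
    if (is.character(targets)) targets <- read_ratings_table(targets)
    stopifnot(inherits(targets, "ratings_matrix"))
    means <- colMeans(targets$values, na.rm = TRUE)
    rated <- names(means)[!is.nan(means)]
    target <- join_target(features,
                          data.frame(candidate_id = rated,
                                     score = means[rated]), "score")
  }
  fit <- fit_motivation_model(features, target, target_label = target_label,
                              fraction = fraction, vif_max = vif_max,
                              n_iterations = n_iterations,
                              test_fraction = test_fraction, p_max = p_max,
                              seed = seed, alphas = alphas, rule = rule)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    tag <- if (target_label == "candidate_self_report") "cbmm" else "rbmm"
    hdr <- provenance(seed, list(target_label, n_iterations, fraction,
                                 vif_max, test_fraction, p_max, alphas))
    write_motivation_model(fit$model,
                           file.path(outdir, paste0("model_", tag, ".txt")),
                           header_lines = hdr)
    cv_df <- data.frame(alpha = fit$cv$alphas,
                        mean_rmse = fit$cv$mean_rmse)
    writeLines(c(paste0("# ", hdr),
                 paste(names(cv_df), collapse = ","),
                 apply(cv_df, 1, function(r) {
                   paste(sprintf("%.17g", as.numeric(r)), collapse = ",")
                 })),
               file.path(outdir, paste0("cv_rmse_", tag, ".csv")))
    sc <- fit$screening
    writeLines(c(paste0("# ", hdr),
                 "feature,abs_cor,selected",
                 paste(sc$ranked$feature,
                       sprintf("%.17g", sc$ranked$abs_cor),
                       as.integer(sc$ranked$feature %in% sc$selected),
                       sep = ",")),
               file.path(outdir, paste0("screening_", tag, ".csv")))
  }
  invisible(fit)
}

#' Evaluate a motivation model against candidates and recruiters
#'
#' Produces the full evaluation bundle: the Spearman validity triad
#' (candidate vs model, candidate vs recruiter mean, recruiter mean vs
#' model), the recruiter reliability report, pooled-t gender-bias tests per
#' recruiter and for the model's own predictions, an age-bias rank
#' correlation for the model, and the matched-threshold ROC and confusion
#' curves of the model against the self-reports.
#'
#' @param model A `motivation_model` or serialized model path.
#' @param features A [feature_matrix()] or feature-table path.
#' @param self_reports Data.frame with `candidate_id`, `gender`, `age`,
#'   `self_report` (or CSV path).
#' @param recruiter_matrix A [ratings_matrix()] or ratings-table path.
#' @param outdir If not `NULL`, writes the report, ROC and confusion tables.
#' @param grid Percentile grid for the curves.
#' @param reliability_level Passed to [krippendorff_alpha()].
#' @param seed Recorded in provenance headers only; evaluation is
#'   deterministic.
#' @return An `evaluation_report` list, invisibly.
#' @export
run_evaluate <- function(model, features, self_reports, recruiter_matrix,
                         outdir = NULL, grid = 1:99,
                         reliability_level = "interval", seed = 1) {
  if (is.character(model)) model <- read_motivation_model(model)
  if (is.character(features)) features <- read_feature_table(features)
  if (is.character(self_reports)) {
    self_reports <- utils::read.csv(self_reports, comment.char = "#")
  }
  if (is.character(recruiter_matrix)) {
    recruiter_matrix <- read_ratings_table(recruiter_matrix)
  }
  target <- join_target(features, self_reports, "self_report")
  if (length(target) < 3) stop("fewer than 3 paired observations",
                               call. = FALSE)
  predicted <- predict(model, features)

  rec_mean <- colMeans(recruiter_matrix$values, na.rm = TRUE)
  rec_mean <- rec_mean[!is.nan(rec_mean)]
  shared <- intersect(names(rec_mean), features$candidate_ids)

  validity <- list(
    candidate_vs_model = spearman_validity(target, predicted),
    candidate_vs_recruiter = spearman_validity(target[shared],
                                               rec_mean[shared]),
    recruiter_vs_model = spearman_validity(rec_mean[shared],
                                           predicted[shared])
  )
  reliability <- krippendorff_alpha(recruiter_matrix,
                                    level = reliability_level)

  gender <- setNames(self_reports$gender,
                     self_reports$candidate_id)[features$candidate_ids]
  binary <- gender %in% c("female", "male")
  rater_bias <- lapply(seq_len(nrow(recruiter_matrix$values)), function(j) {
    sc <- recruiter_matrix$values[j, ]
    g <- gender[match(recruiter_matrix$candidate_ids,
                      features$candidate_ids)]
    keep <- !is.na(sc) & g %in% c("female", "male")
    tryCatch(group_bias_ttest(sc[keep], g[keep]), error = function(e) NULL)
  })
  names(rater_bias) <- recruiter_matrix$rater_ids
  model_bias <- if (sum(binary) >= 4) {
    group_bias_ttest(predicted[binary], gender[binary])
  }
  age <- setNames(self_reports$age,
                  self_reports$candidate_id)[features$candidate_ids]
  age_bias <- if (!all(is.na(age)) && stats::sd(age, na.rm = TRUE) > 0) {
    spearman_validity(age, predicted)
  }

  roc <- suppressWarnings(matched_threshold_roc(target, predicted,
                                                grid = grid))
  confusion <- suppressWarnings(confusion_curve(target, predicted,
                                                grid = grid))

  report <- structure(
    list(validity = validity, reliability = reliability,
         rater_bias = rater_bias, model_bias = model_bias,
         age_bias = age_bias, roc = roc, confusion = confusion,
         predicted = predicted,
         model_summary = rating_summary(predicted, model$scale_min,
                                        model$scale_max),
         candidate_summary = rating_summary(target, model$scale_min,
                                            model$scale_max),
         recruiter_summary = rating_summary(
           recruiter_matrix$values[!is.na(recruiter_matrix$values)],
           model$scale_min, model$scale_max)),
    class = "evaluation_report"
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    hdr <- provenance(seed, list(grid, reliability_level))
    write_curve_table(roc, file.path(outdir, "roc_curve.csv"),
                      header_lines = hdr)
    write_curve_table(confusion, file.path(outdir, "confusion_curve.csv"),
                      header_lines = hdr)
    writeLines(c(paste0("# ", hdr), format_evaluation_report(report)),
               file.path(outdir, "evaluation_report.txt"))
  }
  invisible(report)
}

format_evaluation_report <- function(report) {
  v <- report$validity
  lines <- c(
    sprintf("candidate_vs_model_rho\t%.17g\t%.17g\t%d",
            v$candidate_vs_model$rho, v$candidate_vs_model$p,
            v$candidate_vs_model$n),
    sprintf("candidate_vs_recruiter_rho\t%.17g\t%.17g\t%d",
            v$candidate_vs_recruiter$rho, v$candidate_vs_recruiter$p,
            v$candidate_vs_recruiter$n),
    sprintf("recruiter_vs_model_rho\t%.17g\t%.17g\t%d",
            v$recruiter_vs_model$rho, v$recruiter_vs_model$p,
            v$recruiter_vs_model$n),
    sprintf("krippendorff_alpha\t%.17g\t%s\t%d", report$reliability$alpha,
            report$reliability$level, report$reliability$n_pairable)
  )
  for (nm in names(report$rater_bias)) {
    b <- report$rater_bias[[nm]]
    if (!is.null(b)) {
      lines <- c(lines, sprintf("rater_gender_bias\t%s\t%.17g\t%d\t%.17g",
                                nm, b$t, b$df, b$p))
    }
  }
  if (!is.null(report$model_bias)) {
    b <- report$model_bias
    lines <- c(lines, sprintf("model_gender_bias\tmodel\t%.17g\t%d\t%.17g",
                              b$t, b$df, b$p))
  }
  if (!is.null(report$age_bias)) {
    lines <- c(lines, sprintf("model_age_bias_rho\t%.17g\t%.17g",
                              report$age_bias$rho, report$age_bias$p))
  }
  lines
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  candidate vs model:     rho = %+.3f (p = %.3g, n = %d)\n",
              x$validity$candidate_vs_model$rho,
              x$validity$candidate_vs_model$p, x$validity$candidate_vs_model$n))
  cat(sprintf("  candidate vs recruiter: rho = %+.3f (p = %.3g, n = %d)\n",
              x$validity$candidate_vs_recruiter$rho,
              x$validity$candidate_vs_recruiter$p,
              x$validity$candidate_vs_recruiter$n))
  cat(sprintf("  recruiter vs model:     rho = %+.3f (p = %.3g, n = %d)\n",
              x$validity$recruiter_vs_model$rho,
              x$validity$recruiter_vs_model$p, x$validity$recruiter_vs_model$n))
  cat(sprintf("  recruiter reliability:  Krippendorff's alpha = %.3f (%s)\n",
              x$reliability$alpha, x$reliability$level))
  cat(sprintf("  ROC AUC (matched thresholds): %.3f\n", attr(x$roc, "auc")))
  invisible(x)
}

#' Run the full synthetic pipeline: simulate, extract, fit, evaluate
#'
#' Generates a cohort from `config`, writes it to `outdir`, extracts the
#' feature table, fits the candidate-based model, and evaluates it against
#' the self-reports and recruiter ratings. A single seed makes the whole
#' chain bit-reproducible: two runs with the same seed and config produce
#' byte-identical output files.
#'
#' @param outdir Output directory.
#' @param seed Integer seed for cohort generation and CV splits.
#' @param config A [cohort_config()]; defaults to the study-scale config
#'   under `profile = "full"` or a reduced one under `"smoke"`.
#' @param profile `"full"` (154 candidates, 1000 CV iterations) or
#'   `"smoke"` (60 candidates, 60 s recordings, 50 iterations) for quick
#'   end-to-end runs.
#' @param n_iterations Overrides the profile's CV iteration count.
#' @return List with `cohort`, `features`, `fit`, `report`, invisibly.
#' @export
run_pipeline <- function(outdir, seed = 1, config = NULL,
                         profile = c("full", "smoke"), n_iterations = NULL) {
  profile <- match.arg(profile)
  if (is.null(config)) {
    config <- if (profile == "full") {
      default_study_config(seed = seed)
    } else {
      cohort_config(n_candidates = 60, seed = seed, duration = 60,
                    n_rated = 40)
    }
  }
  if (is.null(n_iterations)) {
    n_iterations <- if (profile == "full") 1000 else 50
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config)
  write_cohort(cohort, outdir)
  hdr <- provenance(seed, config)
  features <- run_extract(cohort$recordings,
                          file.path(outdir, "features.csv"),
                          log_path = file.path(outdir, "extraction_log.csv"),
                          header_lines = hdr)
  fit <- run_fit(features, cohort$self_reports,
                 target_label = "candidate_self_report", outdir = outdir,
                 seed = seed, n_iterations = n_iterations)
  report <- run_evaluate(fit$model, features, cohort$self_reports,
                         cohort$recruiter_matrix, outdir = outdir,
                         seed = seed)
  invisible(list(cohort = cohort, features = features, fit = fit,
                 report = report))
}
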