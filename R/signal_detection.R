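# Matched-threshold ROC and confusion-probability curves for model-based
# candidate selection versus chance.

#' Matched-threshold ROC curve
#'
#' For every percentile `t` in the grid, the positive class is the set of
#' candidates whose true score is strictly above the `t`-th percentile of
#' the true scores, and the selection is the set whose predicted score is
#' strictly above the `t`-th percentile of the predictions — i.e. truth and
#' prediction thresholds are matched at the same percentile. Hit rate is the
#' selected fraction of positives; false-alarm rate the selected fraction of
#' negatives. Percentiles use linear interpolation between order statistics
#' (R quantile type 7). Grid points leaving an empty class are skipped with
#' a warning. AUC is the trapezoidal area over the swept curve (sorted by
#' false-alarm rate, closed with the (0,0) and (1,1) endpoints).
#'
#' @param truth Numeric reference scores.
#' @param predicted Numeric predicted scores, same length.
#' @param grid Percentile cut points in (0, 100). Default `1:99`.
#' @param fixed_positive_class If not `NULL`, a single percentile: the
#'   positive class is fixed at that truth percentile and only the
#'   prediction threshold sweeps the grid (classical ROC), for
#'   comparability with standard tooling.
#' @return A `roc_curve`: data.frame with `threshold`, `hit_rate`,
#'   `false_alarm_rate`; AUC attached as attribute `"auc"`.
#' @export
matched_threshold_roc <- function(truth, predicted, grid = 1:99,
                                  fixed_positive_class = NULL) {
  stopifnot(length(truth) == length(predicted), length(truth) >= 4)
  if (stats::sd(truth) == 0) stop("constant truth scores", call. = FALSE)
  stopifnot(all(grid > 0 & grid < 100))
  rows <- lapply(grid, function(t) {
    tq <- if (is.null(fixed_positive_class)) t else fixed_positive_class
    pos <- truth > stats::quantile(truth, tq / 100, type = 7, names = FALSE)
    sel <- predicted > stats::quantile(predicted, t / 100, type = 7,
                                       names = FALSE)
    if (!any(pos) || all(pos)) {
      warning("skipping percentile ", t, ": empty positive or negative class",
              call. = FALSE)
      return(NULL)
    }
    data.frame(threshold = t,
               hit_rate = sum(sel & pos) / sum(pos),
               false_alarm_rate = sum(sel & !pos) / sum(!pos))
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    stop("no valid grid point", call. = FALSE)
  }
  fa <- c(0, sort(out$false_alarm_rate), 1)
  hr <- c(0, out$hit_rate[order(out$false_alarm_rate)], 1)
  auc <- sum(diff(fa) * (utils::head(hr, -1) + utils::tail(hr, -1)) / 2)
  attr(out, "auc") <- min(1, max(0, auc))
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Confusion-probability curve versus chance selection
#'
#' For each selection percentile `q`, the model selects the candidates whose
#' predicted score is at or above the `(100 - q)`-th percentile of the
#' predictions (the top q%); the model confusion probability is the fraction
#' of those selected whose true score falls strictly below the `q`-th truth
#' percentile (the bottom q%). Random selection confuses the two tails with
#' probability `q/100` analytically, which is reported as the chance
#' baseline.
#'
#' @param truth Numeric reference scores.
#' @param predicted Numeric predicted scores, same length.
#' @param grid Percentiles in (0, 100). Default `1:99`.
#' @return A `confusion_curve`: data.frame with `percentile`,
#'   `model_confusion`, `chance_confusion`.
#' @export
confusion_curve <- function(truth, predicted, grid = 1:99) {
  stopifnot(length(truth) == length(predicted), length(truth) >= 4)
  stopifnot(all(grid > 0 & grid < 100))
  rows <- lapply(grid, function(q) {
    sel <- predicted >= stats::quantile(predicted, (100 - q) / 100, type = 7,
                                        names = FALSE)
    if (!any(sel)) {
      warning("skipping percentile ", q, ": empty selection", call. = FALSE)
      return(NULL)
    }
    low <- stats::quantile(truth, q / 100, type = 7, names = FALSE)
    data.frame(percentile = q,
               model_confusion = mean(truth[sel] < low),
               chance_confusion = q / 100)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("confusion_curve", "data.frame")
  out
}

#' Write a curve (ROC or confusion) as delimited text
#'
#' @param curve A `roc_curve` or `confusion_curve` data.frame.
#' @param path Output file path.
#' @param header_lines Optional provenance comment lines.
#' @export
write_curve_table <- function(curve, path, header_lines = character()) {
  df <- as.data.frame(curve)
  rows <- vapply(seq_len(nrow(df)), function(i) {
    paste(sprintf("%.17g", as.numeric(df[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(if (length(header_lines)) paste0("# ", header_lines),
               paste(names(df), collapse = ","), rows), path)
  invisible(path)
}
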