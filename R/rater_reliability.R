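# Interrater reliability, validity correlations, rating summaries, and
# demographic bias tests.

#' Krippendorff's alpha for a ratings matrix
#'
#' Chance-corrected agreement for any number of raters with missing data,
#' via the coincidence-matrix formulation: `alpha = 1 - D_o / D_e`, where
#' `D_o` is the observed within-unit disagreement and `D_e` the disagreement
#' expected by chance over all pairable values. Candidates (units) with a
#' single rating contribute no coincidences and are excluded. The interval
#' difference function `(v - v')^2` is the default; `level = "ordinal"` uses
#' the rank-based metric built from cumulative value frequencies.
#'
#' @param matrix A [ratings_matrix()].
#' @param level Measurement level: `"interval"` (default) or `"ordinal"`.
#' @return A `reliability_report`: list with `alpha`, `level`, `n_pairable`
#'   (number of values in multiply-rated units), and `n_units`.
#' @export
krippendorff_alpha <- function(matrix, level = c("interval", "ordinal")) {
  stopifnot(inherits(matrix, "ratings_matrix"))
  level <- match.arg(level)
  vals <- matrix$values
  if (nrow(vals) < 2) stop("need at least 2 raters", call. = FALSE)
  m_u <- colSums(!is.na(vals))
  pairable_units <- which(m_u >= 2)
  if (length(pairable_units) == 0) {
    stop("undefined reliability: no candidate has two or more ratings",
         call. = FALSE)
  }
  uvals <- sort(unique(vals[, pairable_units][!is.na(vals[, pairable_units])]))
  k <- length(uvals)
  o <- base::matrix(0, k, k)
  for (u in pairable_units) {
    vu <- vals[, u]; vu <- vu[!is.na(vu)]
    m <- length(vu)
    counts <- tabulate(match(vu, uvals), nbins = k)
    # ordered pairs of distinct ratings within the unit, weighted 1/(m-1)
    pair <- outer(counts, counts) - diag(counts, k)
    o <- o + pair / (m - 1)
  }
  n_c <- rowSums(o)
  n_tot <- sum(n_c)
  delta2 <- switch(level,
    interval = outer(uvals, uvals, function(a, b) (a - b)^2),
    ordinal = {
      d <- base::matrix(0, k, k)
      for (a in seq_len(k)) for (b in seq_len(k)) {
        lo <- min(a, b); hi <- max(a, b)
        d[a, b] <- (sum(n_c[lo:hi]) - (n_c[a] + n_c[b]) / 2)^2
      }
      d
    })
  d_o <- sum(o * delta2) / n_tot
  d_e <- sum(outer(n_c, n_c) * delta2) / (n_tot * (n_tot - 1))
  alpha <- if (d_e == 0) 1 else 1 - d_o / d_e
  structure(list(alpha = alpha, level = level,
                 n_pairable = as.integer(round(n_tot)),
                 n_units = length(pairable_units)),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> Krippendorff's alpha = %.4f (%s level; %d pairable values in %d units)\n",
              x$alpha, x$level, x$n_pairable, x$n_units))
  invisible(x)
}

#' Two-sample pooled-variance t-test for group bias
#'
#' Student's pooled t comparing mean scores between two groups (e.g. scores
#' given to women versus men), with `df = n1 + n2 - 2` — the convention that
#' yields df of n - 2 for n rated candidates. The sign of `t` refers to
#' `mean(first group) - mean(second group)` with groups in sorted label
#' order; both group means are reported explicitly.
#'
#' @param scores Numeric per-candidate scores.
#' @param groups Two-level factor or character/logical vector of group
#'   labels, same length as `scores`; pairs with missing score or label are
#'   dropped.
#' @return A `bias_test_result`: list with `group_means` (named), `group_n`,
#'   `t`, `df`, `p` (two-sided).
#' @export
group_bias_ttest <- function(scores, groups) {
  keep <- !is.na(scores) & !is.na(groups)
  scores <- scores[keep]; groups <- as.character(groups)[keep]
  levs <- sort(unique(groups))
  if (length(levs) != 2) {
    stop("groups must have exactly two levels, got: ",
         paste(levs, collapse = ", "), call. = FALSE)
  }
  x1 <- scores[groups == levs[1]]; x2 <- scores[groups == levs[2]]
  if (length(x1) < 2 || length(x2) < 2) {
    stop("both groups need at least 2 members", call. = FALSE)
  }
  pooled_var <- ((length(x1) - 1) * stats::var(x1) +
                 (length(x2) - 1) * stats::var(x2)) /
    (length(x1) + length(x2) - 2)
  df <- length(x1) + length(x2) - 2
  if (pooled_var == 0) {
    if (mean(x1) == mean(x2)) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      stop("zero pooled variance with unequal means: t is infinite",
           call. = FALSE)
    }
  } else {
    ht <- stats::t.test(x1, x2, var.equal = TRUE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  structure(list(group_means = setNames(c(mean(x1), mean(x2)), levs),
                 group_n = setNames(c(length(x1), length(x2)), levs),
                 t = tt$statistic, df = df, p = tt$p.value),
            class = "bias_test_result")
}

#' @export
print.bias_test_result <- function(x, ...) {
  cat(sprintf("<bias_test_result> %s: M = %.2f (n=%d); %s: M = %.2f (n=%d); t(%d) = %.3f, p = %.4g\n",
              names(x$group_means)[1], x$group_means[1], x$group_n[1],
              names(x$group_means)[2], x$group_means[2], x$group_n[2],
              x$df, x$t, x$p))
  invisible(x)
}

#' Spearman validity correlation
#'
#' Rank correlation (average ranks for ties) between two score vectors after
#' pairwise-complete filtering, with a two-sided p-value from the
#' t-approximation. Used for candidate-vs-recruiter, candidate-vs-model and
#' recruiter-vs-model validity, and for age-bias checks (age vs score).
#'
#' @param a,b Numeric score vectors of equal length; `NA`s dropped pairwise.
#' @return List with `rho`, `p`, `n` (pairs used).
#' @export
spearman_validity <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) {
    stop("need at least 3 complete pairs", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Summary statistics of a score distribution
#'
#' Mean, sample standard deviation (n - 1), and histogram counts per integer
#' scale point (scores rounded to the nearest point and clipped into the
#' scale before counting).
#'
#' @param scores Numeric scores; `NA`s dropped.
#' @param scale_min,scale_max Integer scale bounds for the histogram.
#' @return List with `mean`, `sd`, `n`, `histogram` (named integer vector,
#'   counts summing to `n`).
#' @export
rating_summary <- function(scores, scale_min = 1, scale_max = 10) {
  scores <- scores[!is.na(scores)]
  stopifnot(length(scores) >= 1)
  bins <- seq(scale_min, scale_max)
  binned <- pmin(scale_max, pmax(scale_min, round(scores)))
  list(mean = mean(scores),
       sd = if (length(scores) > 1) stats::sd(scores) else 0,
       n = length(scores),
       histogram = setNames(tabulate(match(binned, bins), nbins = length(bins)),
                            bins))
}
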