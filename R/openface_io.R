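# Reading/writing: OpenFace-dialect CSV recordings, ratings tables, feature tables.

#' The 17 action-unit intensity channels
#'
#' Labels of the AU intensity channels an OpenFace 2.x run reports
#' (`AU01_r` ... `AU45_r`). A successfully read recording carries exactly
#' these 17 traces.
#'
#' @return Character vector of 17 AU labels (without the `_r` suffix).
#' @export
#' @examples
#' au_channels()
au_channels <- function() {
  c("AU01", "AU02", "AU04", "AU05", "AU06", "AU07", "AU09", "AU10", "AU12",
    "AU14", "AU15", "AU17", "AU20", "AU23", "AU25", "AU26", "AU45")
}

#' Read an OpenFace 2.x CSV recording
#'
#' Parses one candidate's per-frame AU intensity output. Frames with
#' `success = 0` or `confidence < min_confidence` are replaced by linear
#' interpolation from neighboring valid frames (edge frames take the nearest
#' valid value), so traces stay uniformly sampled. The frame rate is inferred
#' from the median timestamp spacing. Column-name whitespace is trimmed and
#' matching is case-insensitive; presence (`_c`) and landmark columns are
#' ignored. Tiny negative intensities, which OpenFace occasionally emits, are
#' clamped to zero.
#'
#' @param path Path to a CSV file with a header row naming at least `frame`,
#'   `timestamp`, `confidence`, `success` and the 17 `AU*_r` columns.
#' @param min_confidence Frames below this tracking confidence (in `[0, 1]`)
#'   are treated as invalid and interpolated. Default 0.75.
#' @param candidate_id Identifier for the candidate; defaults to the file
#'   name without extension.
#' @param gender Optional; one of `"female"`, `"male"`, `"other"`.
#' @param age Optional age in years.
#' @return A `candidate_recording`: a list with `candidate_id`, `gender`,
#'   `age`, `fps`, `timestamps`, `confidence`, `success`, `n_frames`,
#'   `n_interpolated`, and `traces` (named list of 17 numeric AU intensity
#'   vectors).
#' @export
read_openface_csv <- function(path, min_confidence = 0.75, candidate_id = NULL,
                              gender = NA_character_, age = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(is.numeric(min_confidence), min_confidence >= 0, min_confidence <= 1)
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  names(df) <- trimws(names(df))
  lower <- tolower(names(df))

  au_cols <- paste0(au_channels(), "_r")
  required <- c("frame", "timestamp", "confidence", "success", au_cols)
  missing <- required[!(tolower(required) %in% lower)]
  if (length(missing) > 0) {
    stop("OpenFace CSV format error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  col <- function(name) df[[which(lower == tolower(name))[1]]]

  n <- nrow(df)
  if (n == 0) stop("empty recording: no frames in ", path, call. = FALSE)
  timestamps <- as.numeric(col("timestamp"))
  if (any(diff(timestamps) < 0)) {
    stop("OpenFace CSV format error: non-monotonic timestamps in ", path,
         call. = FALSE)
  }
  confidence <- as.numeric(col("confidence"))
  success <- as.integer(col("success")) != 0L
  valid <- success & confidence >= min_confidence
  if (!any(valid)) {
    stop("empty recording: no frame passes success/confidence filtering in ",
         path, call. = FALSE)
  }

  idx <- seq_len(n)
  traces <- lapply(au_cols, function(cn) {
    v <- as.numeric(col(cn))
    if (any(!is.finite(v[valid]))) {
      stop("non-finite AU intensity in column ", cn, call. = FALSE)
    }
    if (any(!valid)) {
      if (sum(valid) == 1L) {
        v[] <- v[valid]
      } else {
        v[!valid] <- stats::approx(idx[valid], v[valid], xout = idx[!valid],
                                   rule = 2)$y
      }
    }
    pmax(v, 0)
  })
  names(traces) <- au_channels()

  spacing <- stats::median(diff(timestamps))
  if (!is.finite(spacing) || spacing <= 0) {
    stop("OpenFace CSV format error: cannot infer fps (median timestamp ",
         "spacing not positive)", call. = FALSE)
  }

  new_candidate_recording(
    candidate_id = candidate_id %||% sub("\\.[^.]*$", "", basename(path)),
    gender = gender, age = age, fps = 1 / spacing,
    timestamps = timestamps, confidence = confidence, success = success,
    traces = traces, n_interpolated = sum(!valid)
  )
}

new_candidate_recording <- function(candidate_id, gender, age, fps, timestamps,
                                    confidence, success, traces,
                                    n_interpolated = 0L) {
  stopifnot(fps > 0)
  lens <- lengths(traces)
  if (length(unique(lens)) != 1L || lens[1] != length(timestamps)) {
    stop("all traces must have one value per frame", call. = FALSE)
  }
  structure(
    list(candidate_id = candidate_id, gender = gender, age = age, fps = fps,
         timestamps = timestamps, confidence = confidence, success = success,
         n_frames = length(timestamps), n_interpolated = as.integer(n_interpolated),
         traces = traces),
    class = "candidate_recording"
  )
}

#' @export
print.candidate_recording <- function(x, ...) {
  cat(sprintf("<candidate_recording> %s: %d frames @ %.3g fps (%.1f s), %d traces, %d interpolated frame(s)\n",
              x$candidate_id, x$n_frames, x$fps, x$n_frames / x$fps,
              length(x$traces), x$n_interpolated))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a ratings matrix
#'
#' Container for rater-by-candidate motivation scores on a bounded scale,
#' with missing entries allowed (raters typically view only a subset of
#' candidates).
#'
#' @param values Numeric matrix, raters in rows, candidates in columns;
#'   `NA` marks unrated cells.
#' @param rater_ids,candidate_ids Row/column identifiers; default to
#'   dimnames or generated labels.
#' @param scale_min,scale_max Inclusive scale bounds (default 1-10 Likert).
#' @return A `ratings_matrix` object.
#' @export
ratings_matrix <- function(values, rater_ids = rownames(values),
                           candidate_ids = colnames(values),
                           scale_min = 1, scale_max = 10) {
  values <- as.matrix(values)
  if (nrow(values) == 0 || ncol(values) == 0) {
    stop("ratings matrix dimension error: no raters or no candidates",
         call. = FALSE)
  }
  if (is.null(rater_ids)) rater_ids <- paste0("rater", seq_len(nrow(values)))
  if (is.null(candidate_ids)) candidate_ids <- paste0("cand", seq_len(ncol(values)))
  present <- values[!is.na(values)]
  if (any(present < scale_min | present > scale_max)) {
    bad <- which(!is.na(values) & (values < scale_min | values > scale_max),
                 arr.ind = TRUE)[1, ]
    stop(sprintf("rating out of range [%s, %s] at rater '%s', candidate '%s': %s",
                 scale_min, scale_max, rater_ids[bad[1]], candidate_ids[bad[2]],
                 values[bad[1], bad[2]]), call. = FALSE)
  }
  dimnames(values) <- list(rater_ids, candidate_ids)
  structure(list(values = values, rater_ids = rater_ids,
                 candidate_ids = candidate_ids,
                 scale_min = scale_min, scale_max = scale_max),
            class = "ratings_matrix")
}

#' @export
print.ratings_matrix <- function(x, ...) {
  cat(sprintf("<ratings_matrix> %d raters x %d candidates on [%s, %s], %d missing\n",
              nrow(x$values), ncol(x$values), x$scale_min, x$scale_max,
              sum(is.na(x$values))))
  invisible(x)
}

#' Read a rater-by-candidate ratings table
#'
#' Delimited text: one row per rater, first column the rater id, remaining
#' columns one per candidate. Blank cells are missing ratings.
#'
#' @param path Path to a CSV (or tab-delimited) file.
#' @param scale_min,scale_max Inclusive bounds every present value must obey.
#' @param sep Field separator; `","` by default.
#' @return A [ratings_matrix()].
#' @export
read_ratings_table <- function(path, scale_min = 1, scale_max = 10, sep = ",") {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#", sep = sep)
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("ratings table dimension error: need at least one rater row and ",
         "one candidate column", call. = FALSE)
  }
  rater_ids <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  ratings_matrix(values, rater_ids = rater_ids,
                 candidate_ids = colnames(df)[-1],
                 scale_min = scale_min, scale_max = scale_max)
}

#' Write a ratings matrix as delimited text
#'
#' @param x A [ratings_matrix()].
#' @param path Output file path.
#' @param header_lines Optional provenance comment lines (prefixed `#`).
#' @export
write_ratings_table <- function(x, path, header_lines = character()) {
  stopifnot(inherits(x, "ratings_matrix"))
  vals <- x$values
  rows <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(x$rater_ids[i],
            ifelse(is.na(vals[i, ]), "", format_num(vals[i, ]))),
          collapse = ",")
  }, character(1))
  lines <- c(if (length(header_lines)) paste0("# ", header_lines),
             paste(c("rater_id", x$candidate_ids), collapse = ","), rows)
  writeLines(lines, path)
  invisible(path)
}

#' Construct a feature matrix
#'
#' Candidates-by-features container for trace statistics; the predictor set
#' for motivation modeling. All values must be finite.
#'
#' @param values Numeric matrix, candidates in rows.
#' @param candidate_ids,feature_names Row/column identifiers.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, candidate_ids = rownames(values),
                           feature_names = colnames(values)) {
  values <- as.matrix(values)
  if (nrow(values) == 0 || ncol(values) == 0) {
    stop("feature matrix must be nonempty", call. = FALSE)
  }
  if (is.null(candidate_ids) || is.null(feature_names)) {
    stop("feature matrix needs candidate ids and feature names", call. = FALSE)
  }
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature names", call. = FALSE)
  }
  if (anyDuplicated(candidate_ids)) {
    stop("duplicate candidate ids", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("feature matrix contains non-finite values", call. = FALSE)
  }
  dimnames(values) <- list(candidate_ids, feature_names)
  structure(list(values = values, candidate_ids = as.character(candidate_ids),
                 feature_names = as.character(feature_names)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d candidates x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

format_num <- function(x) {
  out <- sprintf("%.17g", x)
  whole <- !is.na(x) & x == round(x) & abs(x) < 1e15
  out[whole] <- sprintf("%d", as.integer(round(x[whole])))
  out[is.na(x)] <- ""
  out
}

#' Write a feature matrix as delimited text
#'
#' One row per candidate, header row of feature names; values printed with
#' 17 significant digits so the table round-trips through
#' [read_feature_table()] well within 1e-9.
#'
#' @param x A [feature_matrix()].
#' @param path Output file path.
#' @param header_lines Optional provenance comment lines (prefixed `#`).
#' @export
write_feature_table <- function(x, path, header_lines = character()) {
  stopifnot(inherits(x, "feature_matrix"))
  rows <- vapply(seq_len(nrow(x$values)), function(i) {
    paste(c(x$candidate_ids[i], sprintf("%.17g", x$values[i, ])), collapse = ",")
  }, character(1))
  lines <- c(if (length(header_lines)) paste0("# ", header_lines),
             paste(c("candidate_id", x$feature_names), collapse = ","), rows)
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write feature table to ", path, call. = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_table()]
#'
#' @param path Path to the delimited file.
#' @return A [feature_matrix()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("feature table dimension error", call. = FALSE)
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  feature_matrix(values, candidate_ids = as.character(df[[1]]),
                 feature_names = colnames(df)[-1])
}
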