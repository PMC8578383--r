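# Emotion composition (EMFACS-style) and compression of AU/emotion time
# traces into per-trace behavioral features.

#' Default EMFACS-style emotion-to-AU mapping
#'
#' Each basic emotion is composed as the arithmetic mean of its constituent
#' AU intensity traces. Contempt is omitted: it requires unilateral AUs the
#' 17-channel intensity set does not separate. The mapping is configuration,
#' not a constant — pass a modified copy to [compose_emotions()] to use a
#' different dictionary.
#'
#' @return Named list mapping emotion label to a character vector of AU labels.
#' @export
#' @examples
#' default_emotion_mapping()$happiness
default_emotion_mapping <- function() {
  list(
    happiness = c("AU06", "AU12"),
    sadness   = c("AU01", "AU04", "AU15"),
    surprise  = c("AU01", "AU02", "AU05", "AU26"),
    fear      = c("AU01", "AU02", "AU04", "AU05", "AU07", "AU20", "AU26"),
    anger     = c("AU04", "AU05", "AU07", "AU23"),
    disgust   = c("AU09", "AU15")
  )
}

#' Names of the seven per-trace statistics
#' @return Character vector, in the canonical column order.
#' @export
feature_statistics <- function() {
  c("mean_raw", "mean_highpass", "trend", "rate",
    "mean_duration", "mean_area", "mean_amplitude")
}

#' Full feature vocabulary
#'
#' All feature names produced by [build_feature_matrix()]:
#' 7 statistics for each of the 17 AU traces, the 6 emotion traces of the
#' mapping, and valence — `<trace>_<statistic>`, in deterministic order
#' (trace, then statistic).
#'
#' @param mapping Emotion mapping (see [default_emotion_mapping()]).
#' @return Character vector of feature names (168 under the default mapping).
#' @export
feature_vocabulary <- function(mapping = default_emotion_mapping()) {
  traces <- c(au_channels(), names(mapping), "valence")
  as.vector(t(outer(traces, feature_statistics(), paste, sep = "_")))
}

#' Compose emotion traces from AU intensities
#'
#' Per frame, each emotion's activity is the arithmetic mean of its
#' constituent AU intensities. Valence is derived as happiness activity
#' minus the mean of the anger, disgust, fear, and sadness activities, so it
#' may be negative.
#'
#' @param recording A `candidate_recording`.
#' @param mapping Emotion-to-AU table; see [default_emotion_mapping()].
#' @return Named list of per-frame numeric vectors: the mapped emotions plus
#'   `valence`.
#' @export
compose_emotions <- function(recording, mapping = default_emotion_mapping()) {
  stopifnot(inherits(recording, "candidate_recording"))
  absent <- setdiff(unique(unlist(mapping)), names(recording$traces))
  if (length(absent) > 0) {
    stop("emotion mapping configuration error: AU(s) not in recording: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  emotions <- lapply(mapping, function(aus) {
    Reduce(`+`, recording$traces[aus]) / length(aus)
  })
  neg <- c("anger", "disgust", "fear", "sadness")
  neg <- neg[neg %in% names(emotions)]
  neg_mean <- if (length(neg) > 0) {
    Reduce(`+`, emotions[neg]) / length(neg)
  } else {
    0
  }
  emotions$valence <- (emotions$happiness %||% 0) - neg_mean
  emotions
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Detect supra-threshold activity episodes in a trace
#'
#' An episode is a maximal run of consecutive frames whose value is strictly
#' above `median(values) + 1 SD(values)` (population SD). For a constant
#' trace the SD is zero and no sample lies strictly above the threshold, so
#' no episodes are returned.
#'
#' @param values Numeric trace, length >= 2.
#' @param fps Frames per second (> 0).
#' @return A data.frame with one row per episode: `start`, `end` (1-based
#'   inclusive frame indices), `duration` in seconds, `area` (sum of value
#'   minus threshold, divided by fps; intensity-seconds), and `amplitude`
#'   (peak value within the episode). The threshold used is attached as
#'   attribute `"threshold"`.
#' @export
detect_episodes <- function(values, fps) {
  stopifnot(length(values) >= 2, fps > 0, all(is.finite(values)))
  threshold <- stats::median(values) + pop_sd(values)
  above <- values > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  starts <- starts[keep]; ends <- ends[keep]
  out <- data.frame(
    start = starts, end = ends,
    duration = (ends - starts + 1L) / fps,
    area = vapply(seq_along(starts), function(i) {
      sum(values[starts[i]:ends[i]] - threshold) / fps
    }, numeric(1)),
    amplitude = vapply(seq_along(starts), function(i) {
      max(values[starts[i]:ends[i]])
    }, numeric(1))
  )
  attr(out, "threshold") <- threshold
  out
}

# Centered moving average whose window shrinks at the edges.
centered_moving_average <- function(v, half_width) {
  n <- length(v)
  if (half_width < 1) return(v)
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_width)
  hi <- pmin(n, i + half_width)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Compress a trace into its seven behavioral statistics
#'
#' Computes, for one AU or emotion trace:
#' * `mean_raw` — arithmetic mean of the values;
#' * `mean_highpass` — mean absolute high-pass residual, where the high-pass
#'   signal is the trace minus a centered moving average of width
#'   `lowpass_window` seconds (set `rectify = FALSE` for the signed mean);
#' * `trend` — OLS slope of value versus time in seconds (units per second);
#' * `rate` — supra-threshold episodes per minute (see [detect_episodes()]);
#' * `mean_duration`, `mean_area`, `mean_amplitude` — means over episodes,
#'   all zero by convention when no episode occurs.
#'
#' @param values Numeric trace, length >= 2, all finite.
#' @param fps Frames per second.
#' @param label Trace label used to prefix the feature names.
#' @param lowpass_window Width of the moving-average low-pass, in seconds.
#' @param rectify If `TRUE` (default), `mean_highpass` averages the absolute
#'   residual; a signed high-pass mean is ~0 by construction.
#' @return Named numeric vector of 7 statistics, names `<label>_<statistic>`.
#' @export
extract_features <- function(values, fps, label = "trace",
                             lowpass_window = 10, rectify = TRUE) {
  if (any(!is.finite(values))) {
    stop("trace data error: non-finite values in ", label, call. = FALSE)
  }
  stopifnot(length(values) >= 2, fps > 0)
  n <- length(values)
  half <- floor(round(lowpass_window * fps) / 2)
  residual <- values - centered_moving_average(values, half)
  tsec <- (seq_len(n) - 1) / fps
  tc <- tsec - mean(tsec)
  trend <- sum(tc * (values - mean(values))) / sum(tc^2)
  eps <- detect_episodes(values, fps)
  duration_min <- n / fps / 60
  out <- c(
    mean_raw = mean(values),
    mean_highpass = if (rectify) mean(abs(residual)) else mean(residual),
    trend = trend,
    rate = nrow(eps) / duration_min,
    mean_duration = if (nrow(eps) > 0) mean(eps$duration) else 0,
    mean_area = if (nrow(eps) > 0) mean(eps$area) else 0,
    mean_amplitude = if (nrow(eps) > 0) mean(eps$amplitude) else 0
  )
  names(out) <- paste(label, names(out), sep = "_")
  out
}

#' Build the candidates-by-features matrix
#'
#' Runs [compose_emotions()] and [extract_features()] over every recording:
#' 7 statistics for each of the 17 AU traces plus the mapped emotion traces
#' and valence (168 features under the default mapping), computed over each
#' candidate's full interview. Column order is deterministic: trace label
#' (AUs first, then emotions, then valence), then statistic.
#'
#' @param recordings List of `candidate_recording` objects.
#' @param mapping Emotion mapping; see [default_emotion_mapping()].
#' @param lowpass_window Low-pass window in seconds for `mean_highpass`.
#' @param rectify Passed to [extract_features()].
#' @return A [feature_matrix()].
#' @export
build_feature_matrix <- function(recordings, mapping = default_emotion_mapping(),
                                 lowpass_window = 10, rectify = TRUE) {
  stopifnot(length(recordings) >= 1)
  ids <- vapply(recordings, function(r) r$candidate_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate candidate_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  vocab <- feature_vocabulary(mapping)
  rows <- lapply(recordings, function(rec) {
    traces <- c(rec$traces, compose_emotions(rec, mapping))
    unlist(lapply(names(traces), function(lbl) {
      extract_features(traces[[lbl]], rec$fps, label = lbl,
                       lowpass_window = lowpass_window, rectify = rectify)
    }))
  })
  values <- do.call(rbind, rows)
  values <- values[, vocab, drop = FALSE]
  rownames(values) <- ids
  feature_matrix(values, candidate_ids = ids, feature_names = vocab)
}
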