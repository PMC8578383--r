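# Fixtures are built in code at test time; nothing is stored on disk.

# Minimal OpenFace-dialect CSV with the 17 AU intensity columns.
write_openface_fixture <- function(path, n_frames = 300, fps = 60,
                                   au_values = NULL, success = NULL,
                                   confidence = NULL, drop_column = NULL) {
  aus <- au_channels()
  if (is.null(au_values)) {
    au_values <- matrix(0.5, n_frames, length(aus),
                        dimnames = list(NULL, aus))
  }
  if (is.null(success)) success <- rep(1L, n_frames)
  if (is.null(confidence)) confidence <- rep(0.98, n_frames)
  df <- data.frame(frame = seq_len(n_frames),
                   timestamp = (seq_len(n_frames) - 1) / fps,
                   confidence = confidence, success = success,
                   check.names = FALSE)
  for (au in aus) df[[paste0(au, "_r")]] <- au_values[, au]
  if (!is.null(drop_column)) df[[drop_column]] <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# A tiny in-memory recording without touching disk.
make_recording <- function(id = "c1", n_frames = 120, fps = 30,
                           traces = NULL, gender = NA_character_,
                           age = NA_integer_) {
  aus <- au_channels()
  if (is.null(traces)) {
    traces <- setNames(lapply(aus, function(a) rep(0.5, n_frames)), aus)
  } else {
    n_frames <- length(traces[[1]])
  }
  motivAU:::new_candidate_recording(
    candidate_id = id, gender = gender, age = age, fps = fps,
    timestamps = (seq_len(n_frames) - 1) / fps,
    confidence = rep(0.99, n_frames), success = rep(TRUE, n_frames),
    traces = traces
  )
}

# Independent brute-force oracle for supra-threshold episode runs: a plain
# frame-by-frame scan, no rle.
brute_force_episodes <- function(values, fps) {
  med <- median(values)
  sdev <- sqrt(mean((values - mean(values))^2))
  threshold <- med + sdev
  starts <- integer(0); ends <- integer(0)
  inside <- FALSE
  start <- NA_integer_
  for (i in seq_along(values)) {
    if (values[i] > threshold && !inside) {
      inside <- TRUE; start <- i
    }
    if (inside && (values[i] <= threshold || i == length(values))) {
      end <- if (values[i] <= threshold) i - 1L else i
      starts <- c(starts, start); ends <- c(ends, end)
      inside <- FALSE
    }
  }
  data.frame(
    start = starts, end = ends,
    duration = (ends - starts + 1L) / fps,
    area = vapply(seq_along(starts), function(j)
      sum(values[starts[j]:ends[j]] - threshold) / fps, numeric(1)),
    amplitude = vapply(seq_along(starts), function(j)
      max(values[starts[j]:ends[j]]), numeric(1)))
}

# Brute-force Krippendorff alpha over all ordered pairs of pairable values
# (interval metric), following the definition directly.
brute_force_krippendorff <- function(values) {
  mu <- colSums(!is.na(values))
  keep <- which(mu >= 2)
  num <- 0; n_tot <- 0
  pooled <- c()
  for (u in keep) {
    v <- values[, u]; v <- v[!is.na(v)]
    m <- length(v)
    pairs <- expand.grid(i = seq_len(m), j = seq_len(m))
    pairs <- pairs[pairs$i != pairs$j, ]
    num <- num + sum((v[pairs$i] - v[pairs$j])^2) / (m - 1)
    n_tot <- n_tot + m
    pooled <- c(pooled, v)
  }
  d_o <- num / n_tot
  allpairs <- expand.grid(i = seq_along(pooled), j = seq_along(pooled))
  allpairs <- allpairs[allpairs$i != allpairs$j, ]
  d_e <- sum((pooled[allpairs$i] - pooled[allpairs$j])^2) /
    (n_tot * (n_tot - 1))
  if (d_e == 0) 1 else 1 - d_o / d_e
}
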