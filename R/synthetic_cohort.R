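# Synthetic cohort generator: candidate recordings with planted feature
# effects, self-reports, and configurable recruiter raters.

planted_stats <- c("mean_raw", "rate", "mean_amplitude", "mean_duration")

split_feature_name <- function(feature) {
  for (stat in feature_statistics()) {
    suffix <- paste0("_", stat)
    if (endsWith(feature, suffix)) {
      return(list(trace = substr(feature, 1, nchar(feature) - nchar(suffix)),
                  stat = stat))
    }
  }
  stop("cannot parse feature name: ", feature, call. = FALSE)
}

#' Configure a synthetic cohort
#'
#' Describes the study conditions a generated cohort emulates: cohort size
#' and demographics, recording geometry, the latent motivation distribution,
#' the feature effects planted into the AU traces, trace noise, and
#' recruiter rating behavior.
#'
#' The `motivation` mean/SD are the *observed* moments of the truncated
#' score distribution; the generator solves numerically for the underlying
#' normal parameters so that draws truncated to the scale reproduce them.
#'
#' @param n_candidates Number of candidates (>= 2).
#' @param seed Integer seed; drives every draw.
#' @param fps Frames per second of the synthetic recordings.
#' @param duration Recording length in seconds (`duration * fps >= 10`).
#' @param motivation List with `mean`, `sd`, `min`, `max`: target moments
#'   and truncation bounds of the latent motivation score.
#' @param planted_effects Named list: feature name (must exist in
#'   [feature_vocabulary()], with statistic one of `mean_raw`, `rate`,
#'   `mean_amplitude`, `mean_duration`, on an AU trace) ->
#'   `list(slope, base)`, the linear target `base + slope * m` for that
#'   feature given latent motivation `m`. Rates in episodes/minute,
#'   durations in seconds, levels/amplitudes in intensity units.
#' @param trace_noise_sd Per-frame Gaussian intensity noise SD.
#' @param candidate_sd SD of the per-candidate, per-AU baseline offset
#'   (independent of motivation; individual differences in resting
#'   expression).
#' @param au_base Resting intensity level of unplanted AU traces.
#' @param n_recruiters Number of simulated raters.
#' @param n_rated Candidates rated per recruiter (random subset).
#' @param recruiter List with `mean_offset` (score units), `noise_sd` (score
#'   units), `validity_weight` (signed weight on the standardized
#'   visible-feature composite: happiness episode rate + mean valence; a
#'   negative value makes raters systematically misread the visible signal),
#'   `gender_bias` (score units added for male candidates by the biased
#'   rater), `biased_rater` (index of that rater, or 0 for none).
#' @param gender_counts Named integer vector with `female`, `male`, `other`
#'   counts; padded/truncated to `n_candidates`.
#' @return A validated `cohort_config`.
#' @export
cohort_config <- function(n_candidates = 154, seed = 1, fps = 30,
                          duration = 120,
                          motivation = list(mean = 4.6, sd = 2.5,
                                            min = 1, max = 10),
                          planted_effects = default_planted_effects(),
                          trace_noise_sd = 0.15, candidate_sd = 0.3,
                          au_base = 0.5,
                          n_recruiters = 6, n_rated = 104,
                          recruiter = list(mean_offset = 6.9, noise_sd = 1,
                                           validity_weight = -0.7,
                                           gender_bias = 1,
                                           biased_rater = 1),
                          gender_counts = c(female = 53, male = 51,
                                            other = 50)) {
  stopifnot(n_candidates >= 2, duration * fps >= 10, fps > 0,
            trace_noise_sd >= 0, candidate_sd >= 0,
            n_recruiters >= 1, n_rated >= 2)
  vocab <- feature_vocabulary()
  for (f in names(planted_effects)) {
    if (!(f %in% vocab)) {
      stop("planted effect configuration error: unknown feature '", f, "'",
           call. = FALSE)
    }
    parts <- split_feature_name(f)
    if (!(parts$stat %in% planted_stats)) {
      stop("planted effect configuration error: statistic '", parts$stat,
           "' of '", f, "' is not generatively controllable", call. = FALSE)
    }
    if (!(parts$trace %in% au_channels())) {
      stop("planted effect configuration error: effects must target AU ",
           "traces, not derived emotion traces ('", f, "')", call. = FALSE)
    }
    stopifnot(is.numeric(planted_effects[[f]]$slope),
              is.numeric(planted_effects[[f]]$base))
    if (is.null(planted_effects[[f]]$noise)) planted_effects[[f]]$noise <- 0
    stopifnot(planted_effects[[f]]$noise >= 0)
  }
  structure(list(n_candidates = n_candidates, seed = seed, fps = fps,
                 duration = duration, motivation = motivation,
                 planted_effects = planted_effects,
                 trace_noise_sd = trace_noise_sd, candidate_sd = candidate_sd,
                 au_base = au_base, n_recruiters = n_recruiters,
                 n_rated = min(n_rated, n_candidates), recruiter = recruiter,
                 gender_counts = gender_counts),
            class = "cohort_config")
}

#' Default planted feature effects
#'
#' Five linear effects of latent motivation `m` on extracted features,
#' chosen so that motivated candidates smile more often (AU12 episode rate),
#' furrow the brow less (AU04 baseline), show weaker dimpler episodes (AU14
#' amplitude), hold chin-raiser episodes longer (AU17 duration), and blink
#' less often (AU45 rate). Three effects are negative so that sign recovery
#' is a two-sided check. The carriers of the amplitude, duration, and rate
#' effects (AU14, AU17, AU45) sit outside the emotion dictionary, so the
#' derived emotion traces do not duplicate them feature-for-feature.
#'
#' @return Named list of `list(slope, base)` per feature.
#' @export
default_planted_effects <- function() {
  # `noise` is the SD of the per-candidate deviation from the linear target
  # (individual style, independent of motivation); it sets each feature's
  # achievable correlation with the latent score to a realistic ~0.6-0.7
  # rather than a near-deterministic one.
  list(
    AU12_rate           = list(slope =  0.5,  base = 2.0,  noise = 1.4),  # smiles/min
    AU14_mean_amplitude = list(slope = -0.18, base = 3.0,  noise = 0.35), # dimpler strength
    AU04_mean_raw       = list(slope = -0.1,  base = 1.3,  noise = 0),    # brow lowerer
    AU17_mean_duration  = list(slope =  0.06, base = 0.3,  noise = 0.17), # chin raiser, s
    AU45_rate           = list(slope = -0.8,  base = 14.0, noise = 2.3)   # blinks/min
  )
}

#' Study-scale cohort configuration
#'
#' The default conditions every end-to-end check runs under: 154 candidates
#' (51 men, 53 women, 50 other/unknown), latent motivation with observed
#' mean 4.6 and SD 2.5 on the 1-10 scale, the five default planted effects,
#' and 6 recruiters rating 104 candidates each whose scores sit around 6.8,
#' track the visible-feature composite with a *negative* weight, and include
#' one rater with a positive male gender bias of 1 score unit.
#'
#' @param seed Integer seed stored in the config.
#' @return A `cohort_config`.
#' @export
default_study_config <- function(seed = 1) {
  cohort_config(seed = seed)
}

# Solve for normal(mu, sigma) such that truncation to [lo, hi] has the
# requested mean and sd (closed-form truncated-normal moments).
solve_truncnorm_params <- function(mean_t, sd_t, lo, hi) {
  moments <- function(mu, sigma) {
    a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
    z <- stats::pnorm(b) - stats::pnorm(a)
    if (z < 1e-12) return(c(NA_real_, NA_real_))
    da <- stats::dnorm(a); db <- stats::dnorm(b)
    m <- mu + sigma * (da - db) / z
    v <- sigma^2 * (1 + (ifelse(is.finite(a), a * da, 0) -
                         ifelse(is.finite(b), b * db, 0)) / z -
                    ((da - db) / z)^2)
    c(m, sqrt(max(v, 0)))
  }
  obj <- function(par) {
    mm <- moments(par[1], exp(par[2]))
    if (any(is.na(mm))) return(1e6)
    (mm[1] - mean_t)^2 + (mm[2] - sd_t)^2
  }
  fit <- stats::optim(c(mean_t, log(sd_t)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtruncnorm <- function(n, mu, sigma, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), mu, sigma)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Place k non-overlapping bursts: one per equal segment, jittered start,
# with a guard gap so smoothing cannot merge neighbors.
place_bursts <- function(n_frames, k, burst_len) {
  if (k <= 0) return(integer(0))
  seg <- floor(n_frames / k)
  if (seg < burst_len + 12) {
    k <- max(1, floor(n_frames / (burst_len + 12)))
    seg <- floor(n_frames / k)
  }
  slack <- max(1L, seg - burst_len - 10L)
  offsets <- floor(stats::runif(k) * slack)
  starts <- (seq_len(k) - 1L) * seg + 1L + offsets
  starts[starts + burst_len - 1L <= n_frames]
}

synth_trace <- function(n_frames, fps, level, bursts, noise_sd) {
  v <- rep(level, n_frames) + stats::rnorm(n_frames, 0, noise_sd)
  for (b in bursts) {
    idx <- b$start:min(n_frames, b$start + b$len - 1L)
    v[idx] <- v[idx] + b$amp
  }
  # moving average (~1/3 s) emulates the temporal coherence of facial
  # dynamics: burst plateaus survive, frame noise is strongly attenuated so
  # the episode threshold sits several sigma above the baseline
  v <- centered_moving_average(v, max(1L, round(fps / 6)))
  pmax(v, 0)
}

#' Generate a synthetic cohort
#'
#' Draws a latent motivation score per candidate, synthesizes 17-channel AU
#' recordings whose extracted features follow the planted linear targets in
#' expectation (supra-threshold bursts injected on a noisy baseline at the
#' rate, height, or length the effect implies), and produces self-reports
#' (`round(m)` clipped to the scale) and a recruiter ratings matrix with the
#' configured offset, noise, validity weight, and gender bias. All draws
#' come from a single seeded stream, so equal seeds give identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort`: list with `recordings` (list of
#'   `candidate_recording`), `self_reports` (data.frame: `candidate_id`,
#'   `gender`, `age`, `self_report`), `recruiter_matrix`
#'   ([ratings_matrix()]), `ground_truth` (data.frame with the latent `m`,
#'   the planted per-candidate feature targets, and the visible-feature
#'   composite), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_candidates
  n_frames <- round(config$duration * config$fps)
  dur_min <- config$duration / 60
  ids <- sprintf("cand%03d", seq_len(n))

  gc_ <- config$gender_counts
  pool <- rep(c("female", "male", "other"),
              c(gc_[["female"]], gc_[["male"]], gc_[["other"]]))
  pool <- rep(pool, length.out = max(n, length(pool)))[seq_len(n)]
  gender <- sample(pool)
  age <- pmin(26L, pmax(18L, as.integer(round(stats::rnorm(n, 22, 2)))))

  tn <- solve_truncnorm_params(config$motivation$mean, config$motivation$sd,
                               config$motivation$min, config$motivation$max)
  m <- rtruncnorm(n, tn$mu, tn$sigma, config$motivation$min,
                  config$motivation$max)
  self_report <- pmin(config$motivation$max,
                      pmax(config$motivation$min, round(m)))

  effects <- lapply(names(config$planted_effects), function(f) {
    parts <- split_feature_name(f)
    c(parts, config$planted_effects[[f]], list(feature = f))
  })
  effect_by_au <- setNames(effects, vapply(effects, `[[`, "", "trace"))

  truth_targets <- base::matrix(NA_real_, n, length(effects),
                                dimnames = list(ids, vapply(effects, `[[`, "",
                                                            "feature")))
  recordings <- vector("list", n)
  for (i in seq_len(n)) {
    traces <- vector("list", length(au_channels()))
    names(traces) <- au_channels()
    for (au in au_channels()) {
      eff <- effect_by_au[[au]]
      level <- config$au_base + stats::rnorm(1, 0, config$candidate_sd)
      bursts <- list()
      if (is.null(eff) || eff$stat == "mean_raw") {
        # spontaneous background activity: every AU shows occasional
        # movements whose rate/height/length vary per candidate but are
        # independent of motivation; without it, episode peaks on a flat
        # trace degenerate into (baseline + threshold), duplicating mean_raw
        bg_rate <- max(2, stats::rnorm(1, 3.5, 2))
        bg_amp <- max(0.9, stats::rnorm(1, 2.2, 0.7))
        bg_len <- max(round(0.3 * config$fps),
                      round(config$fps * stats::rnorm(1, 0.45, 0.1)))
        k_bg <- max(1L, as.integer(round(bg_rate * dur_min)))
        starts <- place_bursts(n_frames, k_bg, bg_len)
        bursts <- lapply(starts, function(s) {
          list(start = s, len = bg_len,
               amp = max(0.5, bg_amp + stats::rnorm(1, 0, 0.45)))
        })
      }
      if (!is.null(eff)) {
        target <- eff$base + eff$slope * m[i]
        truth_targets[i, eff$feature] <- target
        # realized per-candidate value = linear target + style deviation
        target <- target + stats::rnorm(1, 0, eff$noise)
        # Only the planted statistic tracks motivation; the other burst
        # parameters vary per candidate independently of m (individual
        # expression style), so within-trace surrogate statistics carry
        # little of the planted signal.
        if (eff$stat == "mean_raw") {
          level <- max(0.05, target) + stats::rnorm(1, 0, config$candidate_sd)
        } else if (eff$stat == "rate") {
          # floor of 1.5 episodes/min: keeps enough burst mass that the
          # episode threshold stays several sigma above the noise floor
          k <- as.integer(round(max(1.5, target) * dur_min))
          amp_c <- max(1.3, stats::rnorm(1, 2.2, 0.45))
          # length floor 0.4 s: keeps burst plateaus above the 1/3-s
          # smoothing window so detection cannot silently fail
          len_c <- max(round(0.4 * config$fps),
                       round(config$fps * stats::rnorm(1, 0.55, 0.15)))
          starts <- place_bursts(n_frames, k, len_c + round(0.36 * config$fps))
          bursts <- lapply(starts, function(s) {
            list(start = s,
                 len = max(round(0.4 * config$fps),
                           len_c + round(config$fps *
                                           stats::rnorm(1, 0, 0.12))),
                 amp = max(1.0, amp_c + stats::rnorm(1, 0, 0.3)))
          })
        } else if (eff$stat == "mean_amplitude") {
          rate_c <- max(2.5, stats::rnorm(1, 5, 2))
          k <- max(1L, as.integer(round(rate_c * dur_min)))
          len_c <- max(round(0.4 * config$fps),
                       round(config$fps * stats::rnorm(1, 0.55, 0.25)))
          starts <- place_bursts(n_frames, k, len_c + round(0.45 * config$fps))
          bursts <- lapply(starts, function(s) {
            list(start = s,
                 len = max(round(0.4 * config$fps),
                           len_c + round(config$fps *
                                           stats::rnorm(1, 0, 0.25))),
                 amp = max(0.3, target + stats::rnorm(1, 0, 0.1)))
          })
        } else if (eff$stat == "mean_duration") {
          rate_c <- max(2.5, stats::rnorm(1, 5, 1))
          k <- max(1L, as.integer(round(rate_c * dur_min)))
          amp_c <- max(1.2, stats::rnorm(1, 2, 0.6))
          len_frames <- round(config$fps *
                                pmax(0.1, target + stats::rnorm(k, 0, 0.03)))
          starts <- place_bursts(n_frames, k, max(len_frames))
          bursts <- lapply(seq_along(starts), function(j) {
            list(start = starts[j], len = len_frames[min(j, length(len_frames))],
                 amp = max(1, amp_c + stats::rnorm(1, 0, 0.4)))
          })
        }
      }
      level <- max(0.05, level)
      traces[[au]] <- synth_trace(n_frames, config$fps, level, bursts,
                                  config$trace_noise_sd)
    }
    recordings[[i]] <- new_candidate_recording(
      candidate_id = ids[i], gender = gender[i], age = age[i],
      fps = config$fps, timestamps = (seq_len(n_frames) - 1) / config$fps,
      confidence = round(stats::runif(n_frames, 0.9, 1), 3),
      success = rep(TRUE, n_frames), traces = traces
    )
  }

  fm <- build_feature_matrix(recordings)
  zs <- function(x) if (stats::sd(x) == 0) x * 0 else (x - mean(x)) / stats::sd(x)
  composite <- zs(zs(fm$values[, "happiness_rate"]) +
                  zs(fm$values[, "valence_mean_raw"]))

  rc <- config$recruiter
  rvals <- base::matrix(NA_real_, config$n_recruiters, n,
                        dimnames = list(sprintf("recruiter%d",
                                                seq_len(config$n_recruiters)),
                                        ids))
  for (j in seq_len(config$n_recruiters)) {
    rated <- sort(sample.int(n, config$n_rated))
    score <- rc$mean_offset + rc$validity_weight * composite[rated] +
      (if (j == rc$biased_rater) rc$gender_bias else 0) *
        (gender[rated] == "male") +
      stats::rnorm(length(rated), 0, rc$noise_sd)
    rvals[j, rated] <- pmin(config$motivation$max,
                            pmax(config$motivation$min, round(score)))
  }

  structure(
    list(recordings = recordings,
         self_reports = data.frame(candidate_id = ids, gender = gender,
                                   age = age, self_report = self_report,
                                   stringsAsFactors = FALSE),
         recruiter_matrix = ratings_matrix(rvals,
                                           scale_min = config$motivation$min,
                                           scale_max = config$motivation$max),
         ground_truth = data.frame(candidate_id = ids, gender = gender,
                                   age = age, m_latent = m,
                                   self_report = self_report,
                                   composite = unname(composite),
                                   truth_targets, check.names = FALSE,
                                   stringsAsFactors = FALSE),
         feature_matrix = fm,
         config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d candidates, %d recruiters, %d planted effect(s), seed %d\n",
              length(x$recordings), x$config$n_recruiters,
              length(x$config$planted_effects), x$config$seed))
  invisible(x)
}

format_csv_num <- function(x, digits = 6) {
  out <- formatC(x, digits = digits, format = "f")
  sub("0+$", "0", out)
}

#' Write a synthetic cohort to disk
#'
#' Emits one OpenFace-dialect CSV per candidate (`recordings/<id>.csv`), a
#' self-report table, a recruiter ratings table, and the ground-truth log,
#' all as plain text. Output is byte-identical for equal cohorts.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rec_dir <- file.path(dir, "recordings")
  dir.create(rec_dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) {
    df <- cbind(
      frame = seq_len(rec$n_frames),
      timestamp = format_csv_num(rec$timestamps, 4),
      confidence = format_csv_num(rec$confidence, 3),
      success = as.integer(rec$success),
      do.call(cbind, lapply(rec$traces, format_csv_num))
    )
    colnames(df)[-(1:4)] <- paste0(names(rec$traces), "_r")
    lines <- c(paste(colnames(df), collapse = ","),
               apply(df, 1, paste, collapse = ","))
    writeLines(lines, file.path(rec_dir, paste0(rec$candidate_id, ".csv")))
  }
  utils::write.csv(cohort$self_reports,
                   file.path(dir, "self_reports.csv"), row.names = FALSE)
  write_ratings_table(cohort$recruiter_matrix,
                      file.path(dir, "recruiter_ratings.csv"))
  utils::write.csv(cohort$ground_truth,
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
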