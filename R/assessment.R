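#' Classify interoceptive breath-monitoring trials as attended or distracted
#'
#' In the eyes-closed interoceptive assessment the participant taps every two
#' breaths; the inter-tap response times (RTs) index attentional consistency.
#' A trial is attended when its RT lies within one median absolute deviation
#' (MAD) of the median RT, and distracted otherwise. The MAD is unscaled
#' (no 1.4826 normal-consistency factor): `MAD = median(|rt - median(rt)|)`.
#'
#' By default the rule is two-sided (`|rt - median| <= MAD`), treating both
#' unusually slow and unusually fast taps as miscounts; `sided = "upper"`
#' flags only slow outliers (`rt - median > MAD`) as distracted.
#' Ties at exactly one MAD are attended.
#'
#' @param rts Positive response times in seconds, at least 3.
#' @param sided `"two"` (default) or `"upper"`.
#' @param block_id Optional block index per trial (recycled).
#' @return An object of class `"trial_series"`: a list with `trials` (data
#'   frame: trial, rt, block_id, label), `median_rt`, `mad_rt`, `n_attended`,
#'   `n_distracted`, `sided`.
#' @examples
#' classify_trials(c(1.0, 1.1, 0.9, 1.5, 0.5))
#' @export
classify_trials <- function(rts, sided = c("two", "upper"), block_id = 1L) {
  sided <- match.arg(sided)
  rts <- as.numeric(rts)
  if (length(rts) < 3)
    stop("classification requires at least 3 trials")
  if (anyNA(rts) || any(!is.finite(rts)) || any(rts <= 0))
    stop("all response times must be positive and finite")

  med <- stats::median(rts)
  mad_rt <- stats::median(abs(rts - med))
  # floating-point guard so exact 1-MAD ties land on "attended"
  tol <- mad_rt * (1 + 1e-8) + 1e-12
  attended <- if (sided == "two") {
    abs(rts - med) <= tol
  } else {
    (rts - med) <= tol
  }
  labels <- ifelse(attended, "attended", "distracted")
  trials <- data.frame(trial = seq_along(rts), rt = rts,
                       block_id = rep_len(block_id, length(rts)),
                       label = factor(labels,
                                      levels = c("attended", "distracted")))
  structure(list(trials = trials, median_rt = med, mad_rt = mad_rt,
                 n_attended = sum(attended),
                 n_distracted = sum(!attended),
                 sided = sided),
            class = "trial_series")
}

#' @export
print.trial_series <- function(x, ...) {
  cat("Interoceptive trial series: ", nrow(x$trials), " trials\n", sep = "")
  cat("  median RT ", round(x$median_rt, 3), " s, MAD ",
      round(x$mad_rt, 3), " s (", x$sided, "-sided rule)\n", sep = "")
  cat("  attended ", x$n_attended, ", distracted ", x$n_distracted, "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.trial_series <- function(object, ...) {
  with(object, data.frame(n = nrow(trials), median_rt = median_rt,
                          mad_rt = mad_rt, n_attended = n_attended,
                          n_distracted = n_distracted,
                          frac_distracted = n_distracted / nrow(trials)))
}

#' Simulate one interoceptive assessment run
#'
#' The participant taps every `breaths_per_tap` breaths for `duration_s`
#' seconds (two 2.5-minute blocks by default), with breath periods and lapses
#' drawn from the user's model; a terminal beep closes the run. RTs are the
#' inter-tap intervals (the first tap has no preceding tap and contributes no
#' RT).
#'
#' @param user A [simulated_user()].
#' @param duration_s Run duration in seconds (default 300, i.e. two 2.5-minute
#'   blocks).
#' @param breaths_per_tap Breaths per tap (default 2).
#' @param seed Optional integer seed.
#' @return A list with `tap_times` (seconds), `rts` (inter-tap intervals),
#'   `block_id` per RT, `beep_time_s`, and `series` (a `"trial_series"` from
#'   [classify_trials()], or `NULL` when fewer than 3 RTs are available).
#' @examples
#' run <- simulate_assessment_run(simulated_user(lapse_rate = 0), seed = 2)
#' run$series
#' @export
simulate_assessment_run <- function(user, duration_s = 300,
                                    breaths_per_tap = 2, seed = NULL) {
  stopifnot(inherits(user, "simulated_user"), duration_s >= 0,
            breaths_per_tap >= 1)
  if (!is.null(seed)) set.seed(seed)
  lp <- lnorm_params(user$breath_period_mean, user$breath_period_sd)
  p_lapse <- 1 - (1 - user$lapse_rate)^breaths_per_tap
  taps <- numeric(0)
  t <- 0
  repeat {
    interval <- sum(stats::rlnorm(breaths_per_tap, lp$meanlog, lp$sdlog))
    if (stats::runif(1) < p_lapse) {
      if (stats::runif(1) < 0.5) {
        # missed count: keep breathing one extra cycle before tapping
        interval <- interval +
          sum(stats::rlnorm(breaths_per_tap, lp$meanlog, lp$sdlog))
      } else {
        interval <- interval * stats::runif(1, 1.5, 2.5)
      }
    }
    t <- t + interval
    if (t > duration_s) break
    taps <- c(taps, t)
  }
  rts <- diff(taps)
  block_id <- if (length(rts) > 0)
    ifelse(taps[-1] <= duration_s / 2, 1L, 2L) else integer(0)
  series <- if (length(rts) >= 3)
    classify_trials(rts, block_id = block_id) else NULL
  list(tap_times = taps, rts = rts, block_id = block_id,
       beep_time_s = duration_s, series = series)
}

#' Read/write labeled trial series as CSV
#'
#' @param series A `"trial_series"`.
#' @param path Output CSV path.
#' @param participant_id,timepoint Identifiers added as columns.
#' @return The written data frame, invisibly.
#' @export
write_trial_series <- function(series, path, participant_id = "P01",
                               timepoint = "T1") {
  stopifnot(inherits(series, "trial_series"))
  df <- cbind(participant_id = participant_id, timepoint = timepoint,
              series$trials)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
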