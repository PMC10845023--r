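#' Configuration for the closed-loop adaptive breath-training engine
#'
#' The training is organised in levels 1..`max_level`. At level L the user
#' monitors L breaths per tap and a block lasts L minutes, so the level jointly
#' encodes the breath-counting span and the time-on-task. Promotion to the next
#' level requires `repeats_required` consecutive consistent blocks; an
#' inconsistent block resets the streak. At `max_level` the user stays there
#' for the remainder of the assigned sessions. A new compassion prompt is
#' unveiled every `prompt_block_size` sessions, covering the ten staged
#' prompts over `total_sessions` sessions.
#'
#' @param max_level Highest achievable level (breaths per tap and minutes per
#'   block at that level).
#' @param repeats_required Consecutive consistent blocks needed for promotion.
#' @param total_sessions Number of assigned training sessions.
#' @param prompt_block_size Sessions per compassion prompt.
#' @param session_minutes_min,session_minutes_max Target session duration
#'   bounds in minutes; blocks are appended until the session reaches at least
#'   `session_minutes_min` without exceeding `session_minutes_max`.
#' @param consistency_cv_threshold Maximum coefficient of variation of
#'   inter-tap intervals for a block to count as consistent (dimensionless).
#' @param tap_count_tolerance Allowed absolute deviation of the tap count from
#'   the expected count.
#' @param nominal_breath_s Nominal breath period in seconds used to derive the
#'   expected tap count of a block.
#'
#' @return An object of class `"training_config"` (a named list).
#' @examples
#' cfg <- training_config()
#' cfg$max_level
#' @export
training_config <- function(max_level = 10L,
                            repeats_required = 3L,
                            total_sessions = 60L,
                            prompt_block_size = 6L,
                            session_minutes_min = 5,
                            session_minutes_max = 10,
                            consistency_cv_threshold = 0.25,
                            tap_count_tolerance = 1L,
                            nominal_breath_s = 6) {
  stopifnot(max_level >= 1, repeats_required >= 1, total_sessions >= 1,
            prompt_block_size >= 1, session_minutes_min > 0,
            session_minutes_max >= session_minutes_min,
            consistency_cv_threshold > 0, tap_count_tolerance >= 0,
            nominal_breath_s > 0)
  cfg <- list(
    max_level = as.integer(max_level),
    repeats_required = as.integer(repeats_required),
    total_sessions = as.integer(total_sessions),
    prompt_block_size = as.integer(prompt_block_size),
    session_minutes_min = session_minutes_min,
    session_minutes_max = session_minutes_max,
    consistency_cv_threshold = consistency_cv_threshold,
    tap_count_tolerance = as.integer(tap_count_tolerance),
    nominal_breath_s = nominal_breath_s
  )
  class(cfg) <- "training_config"
  cfg
}

#' Titles of the ten staged compassion prompts
#'
#' Prompts increase in complexity across training, from settling the mind to
#' an integrated compassion cultivation practice.
#'
#' @format Character vector of length 10.
#' @export
compassion_prompts <- c(
  "settling the mind",
  "compassion for a loved one",
  "compassion for oneself",
  "loving kindness for oneself",
  "embracing common humanity",
  "embracing common humanity continued",
  "cultivating compassion for oneself and others",
  "cultivating compassion for others continued",
  "active compassion",
  "integrated compassion cultivation practice"
)

#' Per-participant training state
#'
#' @param level Current level, in `[1, max_level]`.
#' @param consecutive_consistent Current streak of consistent blocks.
#' @param session_index 1-based index of the current session.
#' @param cumulative_minutes Total practice minutes accumulated so far.
#' @return An object of class `"training_state"`.
#' @export
training_state <- function(level = 1L, consecutive_consistent = 0L,
                           session_index = 1L, cumulative_minutes = 0) {
  stopifnot(level >= 1, consecutive_consistent >= 0, session_index >= 1)
  structure(list(level = as.integer(level),
                 consecutive_consistent = as.integer(consecutive_consistent),
                 session_index = as.integer(session_index),
                 cumulative_minutes = cumulative_minutes),
            class = "training_state")
}

# Expected taps in a block: block lasts `level` minutes and the user taps every
# `level` breaths, so at the nominal breath period the count is independent of
# the level (10 taps at the 6 s default).
expected_tap_count <- function(level, config) {
  as.integer(round(level * 60 / (level * config$nominal_breath_s)))
}

#' Evaluate the consistency of one training block
#'
#' A block is consistent when the number of taps is within
#' `tap_count_tolerance` of the expected count for the level and the
#' coefficient of variation (CV) of the inter-tap intervals does not exceed
#' `consistency_cv_threshold`. Chimes model the gentle distraction reminder:
#' a chime fires whenever an inter-tap interval exceeds
#' `(1 + consistency_cv_threshold)` times the running median of the preceding
#' intervals.
#'
#' @param tap_times Strictly increasing tap times in seconds from block start.
#' @param level Level of the block, in `[1, max_level]`.
#' @param config A [training_config()].
#' @return An object of class `"block_log"`: level, tap_times, expected_taps,
#'   consistent (logical), chimes (integer).
#' @examples
#' cfg <- training_config()
#' evaluate_block(seq(6, 60, by = 6), level = 1, config = cfg)$consistent
#' @export
evaluate_block <- function(tap_times, level, config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  if (level < 1 || level > config$max_level)
    stop("level must be in [1, max_level]")
  tap_times <- as.numeric(tap_times)
  if (anyNA(tap_times)) stop("tap_times must not contain NA")
  if (length(tap_times) > 1 && any(diff(tap_times) <= 0))
    stop("tap_times must be strictly increasing")

  expected <- expected_tap_count(level, config)
  n <- length(tap_times)

  if (n == 0) {
    return(structure(list(level = as.integer(level), tap_times = tap_times,
                          expected_taps = expected, consistent = FALSE,
                          chimes = 0L),
                     class = "block_log"))
  }

  intervals <- diff(tap_times)
  cv <- if (length(intervals) >= 2) {
    stats::sd(intervals) / mean(intervals)
  } else {
    Inf
  }

  chimes <- 0L
  if (length(intervals) >= 2) {
    thr <- 1 + config$consistency_cv_threshold
    for (i in 2:length(intervals)) {
      running_median <- stats::median(intervals[seq_len(i - 1)])
      if (intervals[i] > thr * running_median) chimes <- chimes + 1L
    }
  }

  consistent <- abs(n - expected) <= config$tap_count_tolerance &&
    cv <= config$consistency_cv_threshold

  structure(list(level = as.integer(level), tap_times = tap_times,
                 expected_taps = expected, consistent = consistent,
                 chimes = chimes),
            class = "block_log")
}

#' Advance the training state after a block
#'
#' A consistent block extends the streak; when the streak reaches
#' `repeats_required` the level increments (capped at `max_level`) and the
#' streak resets. An inconsistent block resets the streak without demotion.
#' The level trajectory is therefore nondecreasing.
#'
#' @param state A [training_state()].
#' @param block A `"block_log"` from [evaluate_block()] at the state's level.
#' @param config A [training_config()].
#' @return The updated `"training_state"`.
#' @export
update_level <- function(state, block, config = training_config()) {
  stopifnot(inherits(state, "training_state"), inherits(block, "block_log"))
  if (block$level != state$level)
    stop("block level (", block$level, ") does not match state level (",
         state$level, ")")
  new <- state
  new$cumulative_minutes <- state$cumulative_minutes + block$level
  if (isTRUE(block$consistent)) {
    cc <- state$consecutive_consistent + 1L
    if (cc >= config$repeats_required) {
      new$level <- min(state$level + 1L, config$max_level)
      new$consecutive_consistent <- 0L
    } else {
      new$consecutive_consistent <- cc
    }
  } else {
    new$consecutive_consistent <- 0L
  }
  new
}

#' Compassion prompt scheduled for a session
#'
#' Prompts advance every `prompt_block_size` sessions:
#' `prompt_id = min(ceiling(session_index / prompt_block_size), 10)`.
#'
#' @param session_index Session number in `[1, total_sessions]`.
#' @param config A [training_config()].
#' @return Integer prompt id in 1..10, with the prompt title as its name.
#' @examples
#' prompt_for_session(7)  # second prompt
#' @export
prompt_for_session <- function(session_index, config = training_config()) {
  if (any(session_index < 1 | session_index > config$total_sessions))
    stop("session_index must be in [1, total_sessions]")
  id <- pmin(ceiling(session_index / config$prompt_block_size),
             length(compassion_prompts))
  id <- as.integer(id)
  names(id) <- compassion_prompts[id]
  id
}

#' Simulated-user model for training and assessment
#'
#' Breath periods are lognormal with the given mean and standard deviation;
#' each breath independently carries a lapse probability. A lapse during the
#' breaths that make up one tap either suppresses the tap (the interval merges
#' with the next) or delays it, producing both count errors and interval
#' variability. The motivation parameters give the truncated-normal
#' distribution of sessions completed.
#'
#' @param breath_period_mean,breath_period_sd Breath period moments (seconds).
#' @param lapse_rate Per-breath probability of an attentional lapse.
#' @param motivation_mean,motivation_sd,motivation_min,motivation_max
#'   Truncated-normal parameters for the number of sessions completed.
#' @return An object of class `"simulated_user"`.
#' @export
simulated_user <- function(breath_period_mean = 6,
                           breath_period_sd = 0.6,
                           lapse_rate = 0.05,
                           motivation_mean = 40.64,
                           motivation_sd = 17.79,
                           motivation_min = 0,
                           motivation_max = 60) {
  stopifnot(breath_period_mean > 0, breath_period_sd >= 0,
            lapse_rate >= 0, lapse_rate <= 1,
            motivation_min <= motivation_max)
  structure(list(breath_period_mean = breath_period_mean,
                 breath_period_sd = breath_period_sd,
                 lapse_rate = lapse_rate,
                 motivation_mean = motivation_mean,
                 motivation_sd = motivation_sd,
                 motivation_min = motivation_min,
                 motivation_max = motivation_max),
            class = "simulated_user")
}

# Lognormal parameters matching a target mean/sd on the natural scale.
lnorm_params <- function(m, s) {
  if (s <= 0) return(list(meanlog = log(m), sdlog = 0))
  s2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# Tap times for one block under the breath/lapse model. Taps every `level`
# breaths. Two lapse channels per breath: a miscount (probability
# `lapse_rate`) silently adds an extra breath to the current interval --
# a large relative error at low levels, small at high levels -- and a
# zone-out (probability `lapse_rate / 3`) suppresses the tap entirely,
# which bites hardest at high levels where a tap spans many breaths.
simulate_block_taps <- function(user, level, config) {
  duration <- level * 60
  lp <- lnorm_params(user$breath_period_mean, user$breath_period_sd)
  p_skip_tap <- 1 - (1 - user$lapse_rate / 3)^level
  taps <- numeric(0)
  t <- 0
  repeat {
    n_breaths <- level + stats::rbinom(1, level, user$lapse_rate)
    interval <- sum(stats::rlnorm(n_breaths, lp$meanlog, lp$sdlog))
    skip <- stats::runif(1) < p_skip_tap
    t <- t + interval
    if (t > duration) break
    if (!skip) taps <- c(taps, t)
  }
  taps
}

#' Simulate a participant's full training course
#'
#' Sessions are composed of blocks at the participant's current level; blocks
#' are appended until the session reaches `session_minutes_min` (so sessions
#' span roughly 5-10 minutes across all levels). The number of sessions is
#' drawn from the user's truncated-normal motivation distribution unless
#' overridden.
#'
#' @param user A [simulated_user()].
#' @param config A [training_config()].
#' @param seed Optional integer seed.
#' @param n_sessions Optional fixed number of sessions (overrides the
#'   motivation draw); clipped to `[0, total_sessions]`.
#' @return A list with elements `log` (data frame: session_index, block_index,
#'   level, n_taps, consistent, chimes, prompt_id), `taps` (list of per-block
#'   tap-time vectors), `final_state` (a `"training_state"`), and
#'   `n_sessions`.
#' @examples
#' course <- simulate_participant_course(simulated_user(lapse_rate = 0),
#'                                       seed = 1, n_sessions = 30)
#' course$final_state$level
#' @export
simulate_participant_course <- function(user, config = training_config(),
                                        seed = NULL, n_sessions = NULL) {
  stopifnot(inherits(user, "simulated_user"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_sessions)) {
    n_sessions <- round(stats::rnorm(1, user$motivation_mean, user$motivation_sd))
    n_sessions <- max(user$motivation_min, min(user$motivation_max, n_sessions))
  }
  n_sessions <- max(0L, min(as.integer(n_sessions), config$total_sessions))

  state <- training_state()
  rows <- list()
  taps_list <- list()
  k <- 0L
  for (s in seq_len(n_sessions)) {
    state$session_index <- s
    session_minutes <- 0
    block_index <- 0L
    repeat {
      lvl <- state$level
      if (session_minutes + lvl > config$session_minutes_max) break
      block_index <- block_index + 1L
      taps <- simulate_block_taps(user, lvl, config)
      blk <- evaluate_block(taps, lvl, config)
      state <- update_level(state, blk, config)
      session_minutes <- session_minutes + lvl
      k <- k + 1L
      rows[[k]] <- data.frame(session_index = s, block_index = block_index,
                              level = lvl, n_taps = length(taps),
                              consistent = blk$consistent, chimes = blk$chimes,
                              prompt_id = unname(prompt_for_session(s, config)))
      taps_list[[k]] <- taps
      if (session_minutes >= config$session_minutes_min) break
    }
  }
  log <- if (k > 0) do.call(rbind, rows) else
    data.frame(session_index = integer(0), block_index = integer(0),
               level = integer(0), n_taps = integer(0),
               consistent = logical(0), chimes = integer(0),
               prompt_id = integer(0))
  list(log = log, taps = taps_list, final_state = state,
       n_sessions = n_sessions)
}

#' @export
print.training_state <- function(x, ...) {
  cat("Training state: level", x$level,
      "| streak", x$consecutive_consistent,
      "| session", x$session_index,
      "| minutes", round(x$cumulative_minutes, 1), "\n")
  invisible(x)
}

#' @export
print.block_log <- function(x, ...) {
  cat("Block (level ", x$level, "): ", length(x$tap_times), " taps (expected ",
      x$expected_taps, "), ",
      if (x$consistent) "consistent" else "inconsistent",
      ", ", x$chimes, " chime(s)\n", sep = "")
  invisible(x)
}

#' Write a simulated training course as a session-log data frame
#'
#' Long CSV-ready form with one row per tap.
#'
#' @param course Result of [simulate_participant_course()].
#' @param participant_id Identifier recycled into the output.
#' @return Data frame with columns participant_id, session_index, block_index,
#'   level, tap_time_s, consistent, chimes.
#' @export
course_to_log_frame <- function(course, participant_id = "P01") {
  log <- course$log
  if (nrow(log) == 0) {
    return(data.frame(participant_id = character(0), session_index = integer(0),
                      block_index = integer(0), level = integer(0),
                      tap_time_s = numeric(0), consistent = logical(0),
                      chimes = integer(0)))
  }
  out <- lapply(seq_len(nrow(log)), function(i) {
    taps <- course$taps[[i]]
    if (length(taps) == 0) taps <- NA_real_
    data.frame(participant_id = participant_id,
               session_index = log$session_index[i],
               block_index = log$block_index[i],
               level = log$level[i],
               tap_time_s = taps,
               consistent = log$consistent[i],
               chimes = log$chimes[i])
  })
  do.call(rbind, out)
}
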