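cfg <- training_config()

test_that("block evaluation applies the count and CV rules", {
  # perfectly regular breathing at the nominal rate
  b <- evaluate_block(seq(6, 60, by = 6), level = 1, config = cfg)
  expect_true(b$consistent)
  expect_identical(b$expected_taps, 10L)
  expect_identical(b$chimes, 0L)

  # far too few taps for a 1-minute level-1 block
  b2 <- evaluate_block(c(10, 25, 40, 55), level = 1, config = cfg)
  expect_false(b2$consistent)

  # regular count but erratic intervals fails the CV gate
  tt <- cumsum(c(2, 9, 3, 10, 2, 9, 3, 10, 2, 9))
  b3 <- evaluate_block(tt, level = 1, config = cfg)
  expect_false(b3$consistent)

  # expected count is level-invariant (L-minute block, L breaths per tap)
  expect_identical(evaluate_block(numeric(0), 7, cfg)$expected_taps, 10L)
})

test_that("chime fires on intervals exceeding the running-median rule", {
  # hand evaluation: intervals [6,6,6,18,6,6]; at the 18 s interval the
  # running median of prior intervals is 6, threshold 1.25 * 6 = 7.5
  taps <- cumsum(c(6, 6, 6, 18, 6, 6))
  b <- evaluate_block(taps, level = 1, config = cfg)
  expect_gte(b$chimes, 1L)
  expect_identical(b$chimes, 1L)
})

test_that("degenerate and invalid tap inputs are handled", {
  b <- evaluate_block(numeric(0), 1, cfg)
  expect_false(b$consistent)
  expect_identical(b$chimes, 0L)
  expect_error(evaluate_block(c(5, 4, 6), 1, cfg), "increasing")
  expect_error(evaluate_block(c(1, 2), 0, cfg), "level")
})

test_that("level promotion needs the full streak and caps at the maximum", {
  good <- evaluate_block(seq(6, 60, by = 6), 1, cfg)
  s <- update_level(training_state(1, 2), good, cfg)
  expect_identical(s$level, 2L)
  expect_identical(s$consecutive_consistent, 0L)

  # at the cap the user stays there, streak still resets on promotion
  good10 <- evaluate_block(seq(60, 600, by = 60), 10, cfg)
  s10 <- update_level(training_state(10, 2), good10, cfg)
  expect_identical(s10$level, 10L)
  expect_identical(s10$consecutive_consistent, 0L)

  # failure resets the streak without demotion
  bad <- evaluate_block(c(10, 25, 40, 55), 3, cfg)
  bad$level <- 3L
  s3 <- update_level(training_state(3, 2), bad, cfg)
  expect_identical(s3$level, 3L)
  expect_identical(s3$consecutive_consistent, 0L)

  expect_error(update_level(training_state(2), good, cfg), "does not match")
})

test_that("prompt schedule is a nondecreasing step over all ten prompts", {
  ids <- unname(prompt_for_session(1:60, cfg))
  expect_identical(ids[1], 1L)
  expect_identical(ids[7], 2L)
  expect_identical(ids[60], 10L)
  expect_true(all(diff(ids) >= 0))
  expect_identical(sort(unique(ids)), 1:10)
  # changes exactly at multiples of prompt_block_size
  expect_equal(which(diff(ids) == 1L), seq(6, 54, by = 6))
  expect_error(prompt_for_session(0, cfg))
  expect_error(prompt_for_session(61, cfg))
})

test_that("level trajectories are nondecreasing for arbitrary block outcomes", {
  set.seed(71)
  good <- evaluate_block(seq(6, 60, by = 6), 1, cfg)
  bad <- evaluate_block(c(10, 25, 40, 55), 1, cfg)
  for (rep in 1:400) {
    s <- training_state()
    n_blocks <- 25
    flips <- stats::runif(n_blocks) < stats::runif(1)
    lev <- integer(n_blocks)
    for (i in seq_len(n_blocks)) {
      blk <- if (flips[i]) good else bad
      blk$level <- s$level
      s <- update_level(s, blk, cfg)
      lev[i] <- s$level
    }
    expect_true(all(diff(lev) >= 0))
    expect_lte(max(lev), cfg$max_level)
  }
})

test_that("an always-consistent user promotes every repeats_required blocks", {
  s <- training_state()
  good <- evaluate_block(seq(6, 60, by = 6), 1, cfg)
  n_blocks <- 0L
  while (s$level < cfg$max_level) {
    blk <- good
    blk$level <- s$level
    s <- update_level(s, blk, cfg)
    n_blocks <- n_blocks + 1L
  }
  expect_identical(n_blocks, cfg$repeats_required * (cfg$max_level - 1L))
})

test_that("simulated courses respect session packing and motivation bounds", {
  course <- simulate_participant_course(simulated_user(lapse_rate = 0),
                                        seed = 5, n_sessions = 60)
  expect_identical(course$final_state$level, 10L)
  # per-session minutes within the configured window
  mins <- tapply(course$log$level, course$log$session_index, sum)
  expect_true(all(mins >= cfg$session_minutes_min))
  expect_true(all(mins <= cfg$session_minutes_max))

  empty <- simulate_participant_course(simulated_user(), seed = 6,
                                       n_sessions = 0)
  expect_identical(nrow(empty$log), 0L)
  expect_identical(empty$final_state$level, 1L)

  # log frame export carries one row per tap
  lf <- course_to_log_frame(course, "P9")
  expect_true(all(c("participant_id", "tap_time_s", "level") %in% names(lf)))
  expect_identical(unique(lf$participant_id), "P9")
})

test_that("sessions completed and final level correlate positively", {
  set.seed(42)
  n <- 22
  sess <- pmin(pmax(round(stats::rnorm(n, 40.64, 17.79)), 0), 60)
  lev <- vapply(seq_len(n), function(i) {
    u <- simulated_user(lapse_rate = stats::rbeta(1, 3, 120))
    simulate_participant_course(u, n_sessions = sess[i])$final_state$level
  }, 1L)
  rho <- suppressWarnings(stats::cor(sess, lev, method = "spearman"))
  expect_gt(rho, 0)
})
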