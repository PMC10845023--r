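# One lead field shared across tests (deterministic construction).
lf <- make_leadfield()

test_that("lead field geometry and parcellation are well formed", {
  expect_identical(dim(lf$gain), c(24L, 200L))
  expect_true(all(is.finite(lf$gain)))
  counts <- table(lf$network)
  expect_true(all(counts[c("FPN", "CON", "DMN")] >= 1))
  # columns are unit-normalised
  expect_equal(unname(colSums(lf$gain^2)), rep(1, 200))
  # every named region claimed sources
  expect_identical(sort(setdiff(levels(lf$region), "none")),
                   sort(network_parcellation()$region))
})

test_that("alpha band-pass preserves in-band tones and rejects out-of-band", {
  srate <- 250
  tt <- seq(0, 20, by = 1 / srate)[-1]
  mk <- function(f) {
    eeg_recording(matrix(rep(sin(2 * pi * f * tt), 24), nrow = 24,
                         byrow = TRUE), srate = srate)
  }
  mid <- function(x) x[, round(0.2 * length(tt)):round(0.8 * length(tt))]

  in_band <- bandpass_alpha(mk(10))
  expect_identical(dim(in_band$data), dim(mk(10)$data))
  amp_ratio <- max(abs(mid(in_band$data))) / 1
  expect_gt(amp_ratio, 0.99)
  expect_lt(amp_ratio, 1.01)

  out_band <- bandpass_alpha(mk(2))
  # >= 20 dB attenuation at 2 Hz
  expect_lt(max(abs(mid(out_band$data))), 0.1)

  # filtered white noise concentrates its variance in 8-12 Hz
  set.seed(301)
  wn <- eeg_recording(matrix(rnorm(24 * length(tt)), nrow = 24),
                      srate = srate)
  fw <- bandpass_alpha(wn)
  sp <- stats::spec.pgram(fw$data[1, ], plot = FALSE, taper = 0)
  f_hz <- sp$freq * srate
  in_frac <- sum(sp$spec[f_hz >= 7 & f_hz <= 13]) / sum(sp$spec)
  expect_gt(in_frac, 0.9)

  expect_error(bandpass_alpha(eeg_recording(matrix(0, 24, 100), srate = 20)),
               "sampling rate")
})

test_that("pre-event epoching uses the exact 4 s window and drops early events", {
  srate <- 500
  n <- srate * 12
  dat <- matrix(0, 24, n)
  dat[1, ] <- seq_len(n)  # sample index as signal
  rec <- eeg_recording(dat, srate = srate, events = c(2, 10))

  expect_message(ep <- epoch_before_events(rec), "dropped")
  expect_identical(dim(ep), c(1L, 24L, 2000L))
  expect_identical(attr(ep, "dropped"), 2)
  # event at t = 10 s covers samples (3000, 5000] in 0-based [3000, 5000)
  expect_equal(ep[1, 1, 1], (10 - 4) * srate + 1)
  expect_equal(ep[1, 1, 2000], 10 * srate)

  rec37 <- eeg_recording(matrix(0, 24, srate * 40), srate = srate,
                         events = c(1, 3, seq(5, 39, length.out = 35)))
  expect_message(ep37 <- epoch_before_events(rec37), "2 event")
  expect_identical(dim(ep37)[1], 35L)

  expect_error(epoch_before_events(eeg_recording(matrix(0, 24, 100),
                                                 srate = 500,
                                                 events = 0.1)),
               "no events")
})

test_that("minimum-norm projection recovers source geometry", {
  # single active source, noiseless: its own region has the top envelope
  srate <- 250
  tt <- seq_len(srate * 6) / srate
  src_idx <- which(lf$network == "DMN")[1]
  sig <- 1e-4 * sin(2 * pi * 10 * tt)
  dat <- lf$gain[, src_idx, drop = FALSE] %*% t(sig)
  rec <- eeg_recording(dat, srate = srate, events = c(4.5, 5.5))
  ep <- epoch_before_events(bandpass_alpha(rec), events = 5.5)
  proj <- source_project(ep, lf)
  env <- colMeans(proj$envelope)
  top_region <- lf$region[which.max(env)]
  expect_identical(as.character(top_region), as.character(lf$region[src_idx]))

  # all-zero data projects to all-zero sources
  zero <- array(0, dim = c(2, 24, 100))
  expect_true(all(source_project(zero, lf)$envelope == 0))

  expect_error(source_project(array(0, dim = c(1, 10, 50)), lf),
               "channel count")
})

test_that("two distant sources are recovered with correlated amplitudes", {
  set.seed(302)
  srate <- 250
  tt <- seq_len(srate * 110) / srate
  i1 <- which(lf$region == "mPFC")[1]
  i2 <- which(lf$region == "PCC_precuneus")[1]
  events <- seq(5, 105, by = 5)  # non-overlapping 4 s pre-event windows
  a1 <- runif(length(events), 0.5, 2) * 1e-4
  a2 <- runif(length(events), 0.5, 2) * 1e-4
  dat <- matrix(0, 24, length(tt))
  for (k in seq_along(events)) {
    w <- which(tt > events[k] - 4 & tt <= events[k])
    dat[, w] <- dat[, w] +
      lf$gain[, i1, drop = FALSE] %*% t(a1[k] * sin(2 * pi * 10 * tt[w])) +
      lf$gain[, i2, drop = FALSE] %*% t(a2[k] * sin(2 * pi * 9.5 * tt[w] + 1))
  }
  rec <- eeg_recording(dat, srate = srate, events = events)
  ep <- epoch_before_events(bandpass_alpha(rec))
  proj <- source_project(ep, lf)
  env1 <- proj$envelope[, i1]
  env2 <- proj$envelope[, i2]
  expect_gt(cor(env1, a1), 0.9)
  expect_gt(cor(env2, a2), 0.9)
})

test_that("network aggregation handles conditions, contrasts and scaling", {
  set.seed(303)
  n_ep <- 10
  env <- matrix(rlnorm(n_ep * 200, -9, 0.2), n_ep, 200)
  labels <- rep(c("attended", "distracted"), each = 5)

  # identical epochs in both classes: zero contrast everywhere
  env_same <- matrix(rep(env[1, ], n_ep), n_ep, byrow = TRUE)
  act0 <- network_activity(env_same, labels, lf)
  expect_equal(act0$contrast, rep(0, 3))

  # linearity: scaling the envelope scales reported activity
  act1 <- network_activity(env, labels, lf)
  act3 <- network_activity(3 * env, labels, lf)
  expect_equal(act3$overall, 3 * act1$overall, tolerance = 1e-10)
  expect_equal(act3$contrast, 3 * act1$contrast, tolerance = 1e-10)

  # ratio contrast variant
  actr <- network_activity(env, labels, lf, contrast = "ratio")
  expect_equal(actr$contrast, actr$distracted / actr$attended)

  # permuted labels: contrast averages to zero over permutations
  perm_means <- replicate(200, {
    network_activity(env, sample(labels), lf)$contrast[3]
  })
  expect_lt(abs(mean(perm_means)),
            3 * sd(perm_means) / sqrt(length(perm_means)) + 1e-12)

  # a label class with no epochs flags the condition as missing
  actm <- network_activity(env, rep("attended", n_ep), lf)
  expect_true(all(actm$missing_condition))
  expect_true(all(is.na(actm$contrast)))

  expect_error(network_activity(env, labels[-1], lf), "label count")
})

test_that("noiseless forward simulation matches the gain topography", {
  amps <- list(FPN = c(attended = 0, distracted = 0),
               CON = c(attended = 0, distracted = 0),
               DMN = c(attended = 4e-4, distracted = 4e-4))
  sim <- simulate_eeg_session(amps, lf, srate = 200, n_trials = 6,
                              noise_white = 0, noise_pink = 0, seed = 304)
  # sensor variance pattern lies in the span of DMN gain columns
  dmn_idx <- which(lf$network == "DMN")
  G <- lf$gain[, dmn_idx]
  X <- sim$recording$data
  proj <- G %*% solve(crossprod(G), crossprod(G, X))
  rel_err <- norm(X - proj, "F") / norm(X, "F")
  expect_lt(rel_err, 1e-8)
  expect_identical(length(sim$rts), 6L)
  expect_identical(length(sim$recording$events), 6L)
})

test_that("single-network activity is attributed to the correct network", {
  # leakage bound: the correct network should carry at least 70% of the
  # summed network-mean envelope on noiseless single-network data
  for (net in c("FPN", "CON", "DMN")) {
    amps <- list(FPN = c(attended = 0, distracted = 0),
                 CON = c(attended = 0, distracted = 0),
                 DMN = c(attended = 0, distracted = 0))
    amps[[net]] <- c(attended = 4e-4, distracted = 4e-4)
    sim <- simulate_eeg_session(amps, lf, srate = 200, n_trials = 24,
                                noise_white = 0, noise_pink = 0,
                                seed = 305)
    act <- eeg_network_pipeline(sim$recording, rts = sim$rts, leadfield = lf)
    share <- act$overall[act$network == net] / sum(act$overall)
    expect_gt(share, 0.70)
  }
})

test_that("pipeline rejects high-amplitude epochs and aligns labels", {
  amps <- list(FPN = c(attended = 2e-4, distracted = 2e-4),
               CON = c(attended = 2e-4, distracted = 2e-4),
               DMN = c(attended = 4e-4, distracted = 5e-4))
  sim <- simulate_eeg_session(amps, lf, srate = 200, n_trials = 10,
                              seed = 306)
  rec <- sim$recording
  # inject a gross artifact into the window before the third event
  w <- round((rec$events[3] - 2) * rec$srate)
  rec$data[5, w:(w + 20)] <- 500
  act <- eeg_network_pipeline(rec, rts = sim$rts, leadfield = lf,
                              reject_uV = 100)
  series <- attr(act, "series")
  expect_identical(nrow(series$trials), 9L)
  expect_false(any(act$missing_condition))
})
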