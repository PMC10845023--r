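#' Approximate 3D positions of a 24-channel 10-20 montage
#'
#' Electrodes are placed on a unit sphere (scalp radius 1) using standard
#' 10-20 inclination/azimuth angles. Coordinates: +x right, +y anterior,
#' +z superior.
#'
#' @return Data frame with columns label, x, y, z.
#' @export
eeg_montage_24 <- function() {
  # label, inclination from vertex (deg), azimuth (deg, 0 = anterior,
  # positive clockwise toward the right ear)
  ang <- rbind(
    c("Fp1", 72, -18), c("Fp2", 72,  18),
    c("F7",  72, -54), c("F3",  50, -39), c("Fz",  45,   0),
    c("F4",  50,  39), c("F8",  72,  54),
    c("FC5", 60, -69), c("FC1", 32, -45), c("FC2", 32,  45), c("FC6", 60, 69),
    c("T7",  90, -90), c("C3",  45, -90), c("Cz",   0,   0),
    c("C4",  45,  90), c("T8",  90,  90),
    c("CP5", 60, -111), c("CP1", 32, -135), c("CP2", 32, 135), c("CP6", 60, 111),
    c("P7",  72, -126), c("P3",  50, -141), c("Pz",  45, 180), c("P4", 50, 141)
  )
  incl <- as.numeric(ang[, 2]) * pi / 180
  azim <- as.numeric(ang[, 3]) * pi / 180
  data.frame(label = ang[, 1],
             x = sin(incl) * sin(azim),
             y = sin(incl) * cos(azim),
             z = cos(incl))
}

#' Network parcellation seed directions for the toy cortical model
#'
#' Region centres (unit directions) for the default mode network (DMN: medial
#' prefrontal, posterior cingulate/precuneus, bilateral angular gyri), the
#' fronto-parietal network (FPN: bilateral dorsolateral prefrontal and
#' superior parietal) and the cingulo-opercular network (CON: bilateral
#' anterior insular/opercular and dorsal anterior cingulate).
#'
#' @return Data frame with columns region, network, x, y, z (unit vectors).
#' @export
network_parcellation <- function() {
  seeds <- rbind(
    c("mPFC",            "DMN",  0.00,  0.95,  0.31),
    c("PCC_precuneus",   "DMN",  0.00, -0.78,  0.62),
    c("angular_L",       "DMN", -0.84, -0.48,  0.25),
    c("angular_R",       "DMN",  0.84, -0.48,  0.25),
    c("dlPFC_L",         "FPN", -0.68,  0.60,  0.42),
    c("dlPFC_R",         "FPN",  0.68,  0.60,  0.42),
    c("sup_parietal_L",  "FPN", -0.36, -0.24,  0.90),
    c("sup_parietal_R",  "FPN",  0.36, -0.24,  0.90),
    c("ant_insula_L",    "CON", -0.97,  0.17, -0.20),
    c("ant_insula_R",    "CON",  0.97,  0.17, -0.20),
    c("dACC",            "CON",  0.00,  0.46,  0.88)
  )
  v <- apply(seeds[, 3:5], 2, as.numeric)
  v <- v / sqrt(rowSums(v^2))
  data.frame(region = seeds[, 1], network = seeds[, 2],
             x = v[, 1], y = v[, 2], z = v[, 3])
}

#' Build the toy spherical-head lead field
#'
#' Sources are distributed on a cortical sphere (radius `source_radius`,
#' restricted to `z >` `min_z` so the grid covers the cortex rather than the
#' neck) via a Fibonacci lattice; sensors sit on the scalp sphere at the
#' 24-channel 10-20 positions. The gain of a radially oriented dipole at
#' source s seen by channel c is the free-space potential term
#' `(q_s . (x_c - x_s)) / |x_c - x_s|^3`; columns are normalised to unit
#' Euclidean norm so unit source amplitude produces comparable sensor power
#' across depths. Each parcellation region claims its `sources_per_region`
#' nearest grid sources; remaining sources are labelled `"none"`.
#'
#' The construction is fully deterministic: no random numbers are used.
#'
#' @param n_sources Number of cortical grid sources (~200 by default).
#' @param source_radius Cortical sphere radius (scalp = 1).
#' @param min_z Lower z cut for the source grid.
#' @param sources_per_region Grid sources assigned to each named region.
#' @return Object of class `"leadfield"`: `gain` (channels x sources),
#'   `channels`, `source_pos` (sources x 3), `region` (factor per source),
#'   `network` (factor per source: FPN/CON/DMN/none).
#' @examples
#' lf <- make_leadfield()
#' table(lf$network)
#' @export
make_leadfield <- function(n_sources = 200, source_radius = 0.8,
                           min_z = -0.25, sources_per_region = 3) {
  mont <- eeg_montage_24()
  sens <- as.matrix(mont[, c("x", "y", "z")])

  # Fibonacci lattice on the sphere, then cut below min_z
  pts <- NULL
  n_try <- n_sources
  repeat {
    i <- seq_len(n_try) - 0.5
    phi <- acos(1 - 2 * i / n_try)
    theta <- pi * (1 + sqrt(5)) * i
    p <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
    keep <- p[, 3] > min_z
    if (sum(keep) >= n_sources) {
      pts <- p[keep, , drop = FALSE][seq_len(n_sources), ]
      break
    }
    n_try <- ceiling(n_try * 1.2)
  }
  src <- pts * source_radius

  gain <- matrix(0, nrow(sens), n_sources)
  for (s in seq_len(n_sources)) {
    q <- pts[s, ]  # radial orientation
    d <- sweep(sens, 2, src[s, ])
    dist3 <- rowSums(d^2)^1.5
    gain[, s] <- (d %*% q) / dist3
  }
  cn <- sqrt(colSums(gain^2))
  gain <- sweep(gain, 2, cn, "/")

  parc <- network_parcellation()
  region <- rep("none", n_sources)
  network <- rep("none", n_sources)
  taken <- rep(FALSE, n_sources)
  for (r in seq_len(nrow(parc))) {
    ctr <- as.numeric(parc[r, c("x", "y", "z")])
    dd <- colSums((t(pts) - ctr)^2)
    dd[taken] <- Inf
    idx <- order(dd)[seq_len(sources_per_region)]
    region[idx] <- parc$region[r]
    network[idx] <- parc$network[r]
    taken[idx] <- TRUE
  }

  structure(list(gain = gain, channels = mont$label, source_pos = src,
                 region = factor(region),
                 network = factor(network,
                                  levels = c("FPN", "CON", "DMN", "none"))),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat("Lead field:", nrow(x$gain), "channels x", ncol(x$gain), "sources\n")
  print(table(x$network))
  invisible(x)
}

#' Construct an EEG recording object
#'
#' @param data Channels x samples matrix (microvolts).
#' @param srate Sampling rate in Hz.
#' @param channel_names Character vector, one per row of `data`.
#' @param events Event (tap) times in seconds, within the recording span.
#' @return Object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(data, srate = 500,
                          channel_names = eeg_montage_24()$label,
                          events = numeric(0)) {
  data <- as.matrix(data)
  stopifnot(srate > 0, nrow(data) == length(channel_names))
  dur <- ncol(data) / srate
  if (length(events) && (any(events < 0) || any(events > dur)))
    stop("events must lie within the recording span")
  structure(list(data = data, srate = srate,
                 channel_names = channel_names, events = as.numeric(events)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording:", nrow(x$data), "channels,",
      round(ncol(x$data) / x$srate, 1), "s at", x$srate, "Hz,",
      length(x$events), "events\n")
  invisible(x)
}

#' Zero-phase alpha-band filter
#'
#' Band-passes every channel to the alpha band (8-12 Hz by default) with a
#' 4th-order Butterworth filter applied forward and backward
#' ([signal::filtfilt()]), preserving length and phase.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz.
#' @param order Butterworth order (per pass).
#' @return The filtered `"eeg_recording"`.
#' @export
bandpass_alpha <- function(rec, low = 8, high = 12, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"), low > 0, high > low)
  if (rec$srate <= 2 * high)
    stop("sampling rate must exceed twice the upper band edge")
  bf <- signal::butter(order, c(low, high) / (rec$srate / 2), type = "pass")
  out <- rec
  out$data <- t(apply(rec$data, 1, function(ch)
    signal::filtfilt(bf, ch)))
  out
}

#' Extract fixed pre-event epochs
#'
#' Cuts the `window_s` seconds preceding each event (default the 0-4 s
#' pre-response window). Events closer than `window_s` to the recording start
#' are dropped and reported in the `"dropped"` attribute.
#'
#' @param rec An [eeg_recording()].
#' @param events Event times in seconds (defaults to `rec$events`).
#' @param window_s Epoch length in seconds before each event.
#' @return 3-d array epochs x channels x samples with attributes
#'   `"event_times"` (retained events) and `"dropped"` (dropped events).
#' @export
epoch_before_events <- function(rec, events = rec$events, window_s = 4) {
  stopifnot(inherits(rec, "eeg_recording"), window_s > 0)
  n_samp <- round(window_s * rec$srate)
  starts <- round((events - window_s) * rec$srate) + 1
  ends <- starts + n_samp - 1
  ok <- starts >= 1 & ends <= ncol(rec$data)
  if (!any(ok)) stop("no events with a full ", window_s, " s pre-window")
  dropped <- events[!ok]
  if (length(dropped))
    message(length(dropped), " event(s) dropped (insufficient pre-window)")
  keep <- which(ok)
  ep <- array(0, dim = c(length(keep), nrow(rec$data), n_samp))
  for (i in seq_along(keep)) {
    ep[i, , ] <- rec$data[, starts[keep[i]]:ends[keep[i]]]
  }
  attr(ep, "event_times") <- events[ok]
  attr(ep, "dropped") <- dropped
  ep
}

# Analytic-signal magnitude (Hilbert envelope) of each column of x.
hilbert_envelope <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n)
}

#' Minimum-norm source projection of epoched EEG
#'
#' Computes the Tikhonov-regularised minimum-norm inverse
#' `K = G' (G G' + lambda * mu * I)^{-1}` with `mu` the mean eigenvalue of
#' `G G'` (i.e. `trace(G G') / n_channels`), applies it to every epoch, and
#' summarises each source by the mean magnitude of its analytic signal over
#' the epoch (the alpha envelope when the input was alpha-band filtered).
#'
#' @param epochs Epoch array from [epoch_before_events()].
#' @param leadfield A [make_leadfield()] object with matching channel count.
#' @param lambda Relative regularisation parameter (default 0.1).
#' @return List with `envelope` (epochs x sources mean-envelope matrix) and
#'   `operator` (the inverse operator, sources x channels).
#' @export
source_project <- function(epochs, leadfield, lambda = 0.1) {
  stopifnot(inherits(leadfield, "leadfield"))
  G <- leadfield$gain
  if (dim(epochs)[2] != nrow(G))
    stop("epoch channel count does not match lead field")
  GGt <- G %*% t(G)
  mu <- sum(diag(GGt)) / nrow(GGt)
  M <- GGt + lambda * mu * diag(nrow(GGt))
  Minv <- tryCatch(solve(M), error = function(e)
    stop("sensor covariance is singular; use lambda > 0"))
  K <- t(G) %*% Minv

  n_ep <- dim(epochs)[1]
  env <- matrix(0, n_ep, ncol(G))
  for (i in seq_len(n_ep)) {
    src <- K %*% epochs[i, , ]            # sources x samples
    env[i, ] <- colMeans(hilbert_envelope(t(src)))
  }
  list(envelope = env, operator = K)
}

#' Network-level alpha activity by attention condition
#'
#' Averages source envelopes within each network (FPN, CON, DMN), then within
#' each attention condition, and reports the distracted-versus-attended
#' relative response. Values are reported in units of `unit_scale^{-1}`
#' cortical-source arbitrary units (1e-4 by default, so a raw envelope of
#' 5e-4 prints as 5).
#'
#' @param source_env Epochs x sources envelope matrix (or the list returned by
#'   [source_project()]).
#' @param labels Factor/character of `"attended"`/`"distracted"` per epoch, or
#'   a `"trial_series"` whose trial labels are used.
#' @param leadfield The [make_leadfield()] used for projection.
#' @param contrast `"difference"` (distracted - attended, default) or
#'   `"ratio"` (distracted / attended).
#' @param unit_scale Reporting scale (reported = raw / unit_scale).
#' @return Data frame of class `"network_activity"`: one row per network with
#'   columns network, attended, distracted, overall, contrast, n_attended,
#'   n_distracted, missing_condition.
#' @export
network_activity <- function(source_env, labels, leadfield,
                             contrast = c("difference", "ratio"),
                             unit_scale = 1e-4) {
  contrast <- match.arg(contrast)
  if (is.list(source_env) && !is.null(source_env$envelope))
    source_env <- source_env$envelope
  if (inherits(labels, "trial_series")) labels <- labels$trials$label
  labels <- as.character(labels)
  if (nrow(source_env) != length(labels))
    stop("epoch count (", nrow(source_env), ") must equal label count (",
         length(labels), ")")

  nets <- c("FPN", "CON", "DMN")
  rows <- lapply(nets, function(nw) {
    idx <- which(leadfield$network == nw)
    if (!length(idx)) stop("network ", nw, " has no sources in the lead field")
    per_epoch <- rowMeans(source_env[, idx, drop = FALSE])
    att <- per_epoch[labels == "attended"]
    dis <- per_epoch[labels == "distracted"]
    missing <- (length(att) == 0) || (length(dis) == 0)
    m_att <- if (length(att)) mean(att) / unit_scale else NA_real_
    m_dis <- if (length(dis)) mean(dis) / unit_scale else NA_real_
    ctr <- if (missing) NA_real_
      else if (contrast == "difference") m_dis - m_att else m_dis / m_att
    data.frame(network = nw, attended = m_att, distracted = m_dis,
               overall = mean(per_epoch) / unit_scale, contrast = ctr,
               n_attended = length(att), n_distracted = length(dis),
               missing_condition = missing)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("network_activity", "data.frame")
  attr(out, "contrast") <- contrast
  out
}

# Pink (1/f amplitude) noise, one column per channel, sd-normalised.
# Generated at the next power-of-two length (fast FFT) and truncated.
pink_noise <- function(n, k) {
  m <- stats::nextn(n, 2)
  white <- matrix(stats::rnorm(m * k), m, k)
  f <- c(1, seq_len(m - 1))
  shape <- 1 / sqrt(pmin(f, m - f + 1))
  x <- Re(stats::mvfft(stats::mvfft(white) * shape, inverse = TRUE) / m)
  x <- x[seq_len(n), , drop = FALSE]
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

#' Simulate one EEG assessment session through the forward model
#'
#' Places alpha-band oscillators (random phase, frequency jittered within the
#' band) at every source of each network during the 4 s window preceding each
#' tap, with amplitude set by the trial's intended attention condition,
#' projects them through the lead field, and adds white plus 1/f sensor
#' noise. Tap times are built from an RT sequence whose attended trials
#' cluster tightly around `rt_mean` and whose distracted trials are delayed
#' outliers, so the median/MAD classifier recovers the intended mix.
#'
#' @param amplitudes Named list per network (`FPN`, `CON`, `DMN`), each a
#'   numeric vector `c(attended =, distracted =)` of per-source oscillator
#'   amplitudes in source units.
#' @param leadfield A [make_leadfield()].
#' @param srate Sampling rate in Hz.
#' @param n_trials Number of labelled trials (pre-tap windows).
#' @param frac_distracted Intended fraction of distracted trials.
#' @param rt_mean,rt_sd Attended inter-tap interval moments (seconds);
#'   `rt_mean` must comfortably exceed the 4 s analysis window.
#' @param session_jitter_sd Lognormal sd of the session-level amplitude state
#'   factor (shared by all trials of the session).
#' @param trial_jitter_sd Lognormal sd of per-trial amplitude jitter.
#' @param noise_white,noise_pink Sensor noise standard deviations, on the
#'   same arbitrary scale as the source amplitudes (defaults sized so that
#'   reported network activity lands in single-digit 1e-4 units).
#' @param seed Optional integer seed.
#' @return List with `recording` (an [eeg_recording()], events = tap times
#'   with a preceding full window), `rts` (inter-tap intervals matching the
#'   events), `intended` (intended condition per event) and `session_gain`
#'   (the realised session state factor).
#' @export
simulate_eeg_session <- function(amplitudes, leadfield, srate = 250,
                                 n_trials = 20, frac_distracted = 0.25,
                                 rt_mean = 5, rt_sd = 0.15,
                                 session_jitter_sd = 0.2,
                                 trial_jitter_sd = 0.1,
                                 noise_white = 1e-4, noise_pink = 1e-4,
                                 seed = NULL) {
  stopifnot(inherits(leadfield, "leadfield"), rt_mean > 4)
  if (!is.null(seed)) set.seed(seed)
  nets <- c("FPN", "CON", "DMN")
  for (nw in nets) {
    a <- amplitudes[[nw]]
    if (is.null(a) || any(a < 0) ||
        !all(c("attended", "distracted") %in% names(a)))
      stop("amplitudes$", nw,
           " must be a nonnegative vector with names attended/distracted")
  }

  n_dis <- round(frac_distracted * n_trials)
  intended <- sample(rep(c("distracted", "attended"),
                         c(n_dis, n_trials - n_dis)))
  rts <- stats::rnorm(n_trials, rt_mean, rt_sd)
  rts[intended == "distracted"] <-
    rt_mean + stats::runif(sum(intended == "distracted"), 1.5, 3.5)
  rts <- pmax(rts, 4.2)

  first_tap <- 4.5
  taps <- first_tap + cumsum(c(0, rts))    # n_trials + 1 taps
  events <- taps[-1]                       # labelled taps (have an RT)
  n_samp <- ceiling((max(taps) + 0.5) * srate)
  tt <- seq_len(n_samp) / srate

  session_gain <- stats::rlnorm(1, -session_jitter_sd^2 / 2, session_jitter_sd)

  n_src <- ncol(leadfield$gain)
  active <- which(leadfield$network %in% nets)
  src_act <- matrix(0, length(active), n_samp)
  for (k in seq_len(n_trials)) {
    i0 <- max(1L, round((events[k] - 4) * srate) + 1L)
    i1 <- min(n_samp, round(events[k] * srate))
    seg <- tt[i0:i1]
    for (nw in nets) {
      rows <- which(leadfield$network[active] == nw)
      amp <- amplitudes[[nw]][[intended[k]]] * session_gain *
        stats::rlnorm(1, -trial_jitter_sd^2 / 2, trial_jitter_sd)
      if (amp <= 0) next
      freq <- stats::runif(1, 8.5, 11.5)
      phase <- stats::runif(length(rows), 0, 2 * pi)
      for (j in seq_along(rows)) {
        src_act[rows[j], i0:i1] <- src_act[rows[j], i0:i1] +
          amp * sin(2 * pi * freq * seg + phase[j])
      }
    }
  }

  sens <- leadfield$gain[, active, drop = FALSE] %*% src_act
  n_ch <- nrow(sens)
  if (noise_white > 0)
    sens <- sens + noise_white * matrix(stats::rnorm(n_ch * n_samp),
                                        n_ch, n_samp)
  if (noise_pink > 0)
    sens <- sens + noise_pink * t(pink_noise(n_samp, n_ch))

  rec <- eeg_recording(sens, srate = srate,
                       channel_names = leadfield$channels, events = events)
  list(recording = rec, rts = rts, intended = intended,
       session_gain = session_gain)
}

#' Full per-session EEG network-activity pipeline
#'
#' Convenience wrapper: alpha band-pass, pre-event epoching, amplitude-based
#' epoch rejection, minimum-norm projection, median/MAD trial labelling and
#' network aggregation.
#'
#' @param rec An [eeg_recording()] with tap events.
#' @param rts Inter-tap RTs aligned with `rec$events` (defaults to
#'   `diff(c(NA, rec$events))` pattern: if omitted, RTs are recomputed as
#'   successive event differences with the first event dropped).
#' @param leadfield A [make_leadfield()].
#' @param lambda Minimum-norm regularisation.
#' @param reject_uV Peak-amplitude epoch-rejection threshold (microvolts);
#'   `Inf` disables rejection.
#' @param sided Sidedness of the MAD rule, see [classify_trials()].
#' @param contrast Passed to [network_activity()].
#' @return The `"network_activity"` data frame, with the `"trial_series"`
#'   attached as attribute `"series"`.
#' @export
eeg_network_pipeline <- function(rec, rts = NULL, leadfield,
                                 lambda = 0.1, reject_uV = 100,
                                 sided = "two",
                                 contrast = "difference") {
  events <- rec$events
  if (is.null(rts)) {
    if (length(events) < 4) stop("need at least 4 events to derive RTs")
    rts <- diff(events)
    events <- events[-1]
  }
  if (length(rts) != length(events))
    stop("rts must align one-to-one with events")
  filt <- bandpass_alpha(rec)
  ep <- epoch_before_events(filt, events = events)
  kept_events <- attr(ep, "event_times")
  rts <- rts[events %in% kept_events]
  # amplitude-threshold artifact rejection on the raw (unfiltered) epochs
  if (is.finite(reject_uV)) {
    raw_ep <- epoch_before_events(rec, events = kept_events)
    peak <- apply(abs(raw_ep), 1, max)
    keep <- peak <= reject_uV
    if (!any(keep)) stop("all epochs rejected at ", reject_uV, " uV")
    ep <- ep[keep, , , drop = FALSE]
    rts <- rts[keep]
  }
  series <- classify_trials(rts, sided = sided)
  proj <- source_project(ep, leadfield, lambda = lambda)
  act <- network_activity(proj, series, leadfield, contrast = contrast)
  attr(act, "series") <- series
  act
}

#' @export
print.network_activity <- function(x, ...) {
  cat("Alpha-band network activity (1e-4 cortical source a.u.):\n")
  df <- as.data.frame(x)
  df[, c("attended", "distracted", "overall", "contrast")] <-
    round(df[, c("attended", "distracted", "overall", "contrast")], 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export recording signals and events to CSV
#'
#' @param rec An [eeg_recording()].
#' @param signal_path,events_path Output CSV paths (either may be `NULL`).
#' @return Invisibly, `rec`.
#' @export
write_eeg_csv <- function(rec, signal_path = NULL, events_path = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.null(signal_path)) {
    df <- as.data.frame(t(rec$data))
    names(df) <- rec$channel_names
    df <- cbind(time_s = seq_len(ncol(rec$data)) / rec$srate, df)
    utils::write.csv(df, signal_path, row.names = FALSE)
  }
  if (!is.null(events_path)) {
    utils::write.csv(data.frame(tap_time_s = rec$events), events_path,
                     row.names = FALSE)
  }
  invisible(rec)
}
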