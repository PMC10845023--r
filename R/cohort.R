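#' Specification of a synthetic trial cohort
#'
#' Defaults reproduce the published study conditions: group sizes 22/21,
#' per-outcome per-timepoint means and SDs, adherence distribution (mean
#' 40.64, SD 17.79 sessions, truncated to 0-60), target rank correlations
#' between adherence and behavioural change and between DMN change and
#' self-compassion change, and missing-completely-at-random follow-up
#' dropout (2 trained, 1 control).
#'
#' Outcome scores at T2/T3 are anchored to baseline via the test-retest
#' correlation `r_tt`; couplings are induced on the Gaussian latents
#' (a Gaussian copula), so they survive the monotone clipping to scale
#' ranges. Network activity uses a lower test-retest correlation
#' (`r_tt_activity`) reflecting the high session-to-session state
#' variability of alpha-band source activity.
#'
#' @param n_training,n_control Group sizes.
#' @param r_tt Test-retest correlation of behavioural latents.
#' @param r_tt_activity Test-retest correlation of network-activity latents.
#' @param sessions_mean,sessions_sd,sessions_min,sessions_max Adherence
#'   distribution (normal, clipped to the bounds).
#' @param rho_sessions_dsc Target Spearman between sessions completed and
#'   self-compassion change (T2-T1) in the trained group.
#' @param rho_sessions_dmind Same for state mindfulness.
#' @param rho_ddmn_dsc Target Spearman between DMN activity change and
#'   self-compassion change (negative: suppression tracks improvement).
#' @param usr_coupling Gaussian coupling between the uncompassionate
#'   self-responding innovation and the (negated) self-compassion
#'   innovation.
#' @param dropout_t3 Named vector: participants missing at follow-up per
#'   group.
#' @param outcome_params,activity_params Nested lists of per-group,
#'   per-timepoint `c(mean, sd)` entries (see defaults in the source);
#'   override to change the ground truth.
#' @return Object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_training = 22, n_control = 21,
                        r_tt = 0.7, r_tt_activity = 0.3,
                        sessions_mean = 40.64, sessions_sd = 17.79,
                        sessions_min = 0, sessions_max = 60,
                        rho_sessions_dsc = 0.52,
                        rho_sessions_dmind = 0.38,
                        rho_ddmn_dsc = -0.368,
                        usr_coupling = 0.8,
                        dropout_t3 = c(training = 2, control = 1),
                        outcome_params = NULL,
                        activity_params = NULL) {
  stopifnot(n_training > 0, n_control > 0, abs(rho_sessions_dsc) < 1,
            abs(rho_sessions_dmind) < 1, abs(rho_ddmn_dsc) < 1,
            r_tt > -1, r_tt < 1, all(dropout_t3 >= 0),
            dropout_t3[["training"]] < n_training,
            dropout_t3[["control"]] < n_control)
  if (is.null(outcome_params)) {
    outcome_params <- list(
      self_compassion = list(
        training = list(T1 = c(2.69, 0.57), T2 = c(3.02, 0.58),
                        T3 = c(3.14, 0.55)),
        control  = list(T1 = c(3.09, 0.73), T2 = c(3.15, 0.67),
                        T3 = c(3.29, 0.54)),
        range = c(1, 5)),
      state_mindfulness = list(
        training = list(T1 = c(2.94, 0.79), T2 = c(3.37, 0.85),
                        T3 = c(3.41, 1.08)),
        control  = list(T1 = c(3.22, 0.94), T2 = c(3.25, 0.82),
                        T3 = c(3.55, 0.78)),
        range = c(1, 5)),
      usr = list(
        training = list(T1 = c(3.30, 0.70), T2 = c(2.88, 0.70),
                        T3 = c(2.48, 1.20)),
        control  = list(T1 = c(3.00, 0.80), T2 = c(2.97, 0.80),
                        T3 = c(2.90, 0.80)),
        range = c(1, 5)),
      mbi_ee = list(
        training = list(T1 = c(16.27, 4.45), T2 = c(15.00, 5.86)),
        control  = list(T1 = c(24.05, 10.22), T2 = c(23.05, 12.45)),
        range = c(0, 54)),
      mbi_pa = list(
        training = list(T1 = c(21.41, 3.63), T2 = c(21.64, 4.41)),
        control  = list(T1 = c(32.86, 6.73), T2 = c(34.67, 7.77)),
        range = c(0, 48)),
      mbi_dp = list(
        training = list(T1 = c(5.36, 3.33), T2 = c(4.50, 3.71)),
        control  = list(T1 = c(9.29, 7.93), T2 = c(7.57, 7.37)),
        range = c(0, 30))
    )
  }
  if (is.null(activity_params)) {
    activity_params <- list(
      FPN = list(training = list(T1 = c(3.08, 3.14), T2 = c(1.96, 1.45)),
                 control  = list(T1 = c(3.45, 3.39), T2 = c(1.08, 3.08))),
      CON = list(training = list(T1 = c(2.55, 2.18), T2 = c(1.44, 1.76)),
                 control  = list(T1 = c(1.88, 1.77), T2 = c(4.57, 9.86))),
      DMN = list(training = list(T1 = c(11.92, 12.55), T2 = c(1.44, 11.66)),
                 control  = list(T1 = c(4.94, 7.10), T2 = c(10.26, 15.43)))
    )
  }
  structure(list(n_training = n_training, n_control = n_control,
                 r_tt = r_tt, r_tt_activity = r_tt_activity,
                 sessions_mean = sessions_mean, sessions_sd = sessions_sd,
                 sessions_min = sessions_min, sessions_max = sessions_max,
                 rho_sessions_dsc = rho_sessions_dsc,
                 rho_sessions_dmind = rho_sessions_dmind,
                 rho_ddmn_dsc = rho_ddmn_dsc,
                 usr_coupling = usr_coupling,
                 dropout_t3 = dropout_t3,
                 outcome_params = outcome_params,
                 activity_params = activity_params),
            class = "cohort_spec")
}

# Spearman target -> Pearson correlation on Gaussian latents.
rho_spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Mixing weight gamma so that corr(T2 - T1, z) = rho_p when
# T2 = m2 + s2 (r z1 + sqrt(1-r^2) w), w = gamma z + sqrt(1-gamma^2) e.
coupling_weight <- function(rho_s, s1, s2, r, pair) {
  rho_p <- rho_spearman_to_pearson(rho_s)
  sd_delta <- sqrt(s1^2 + s2^2 - 2 * r * s1 * s2)
  g <- rho_p * sd_delta / (s2 * sqrt(1 - r^2))
  if (!is.finite(g) || abs(g) > 1)
    stop("infeasible correlation target for ", pair,
         " (requires mixing weight ", round(g, 3), ")")
  g
}

#' Generate a complete synthetic trial dataset
#'
#' Draws the behavioural outcome table, adherence counts, training logs and
#' per-network activity records with the couplings configured in the
#' [cohort_spec()]. Latent scores are Gaussian, matched to the per-timepoint
#' means/SDs, coupled through shared standard-normal innovations, and
#' clipped to scale ranges; follow-up dropout is applied completely at
#' random. `self_compassion` totals and the uncompassionate subscale (USR)
#' are generated jointly and the compassionate subscale (CSR) is derived
#' from the scoring identity `total = (csr + (6 - usr)) / 2`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @param session_logs If `TRUE`, run the closed-loop engine for every
#'   trained participant (heterogeneous lapse rates) to produce session logs
#'   and final levels; if `FALSE`, `final_level` is `NA` and `courses` is
#'   empty (much faster for Monte-Carlo use).
#' @return List with `outcomes` (long data frame, see [analyze_trial()]),
#'   `activity` (participant x timepoint x network records with attended /
#'   distracted / contrast columns), `courses` (per trained participant,
#'   when requested) and `spec`.
#' @examples
#' coh <- generate_cohort(cohort_spec(), seed = 1, session_logs = FALSE)
#' head(coh$outcomes)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL,
                            session_logs = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  r <- spec$r_tt
  ra <- spec$r_tt_activity

  groups <- list(training = spec$n_training, control = spec$n_control)
  out_rows <- list(); act_rows <- list()
  courses <- list()
  for (g in names(groups)) {
    n <- groups[[g]]
    ids <- sprintf("%s%02d", ifelse(g == "training", "T", "C"), seq_len(n))

    z_s <- stats::rnorm(n)  # adherence latent (unused for controls)
    sessions <- if (g == "training") {
      pmin(pmax(round(spec$sessions_mean + spec$sessions_sd * z_s),
                spec$sessions_min), spec$sessions_max)
    } else rep(0L, n)

    draw_outcome <- function(par, w2, w3 = stats::rnorm(n)) {
      m <- list()
      z1 <- stats::rnorm(n)
      m$T1 <- par$T1[1] + par$T1[2] * z1
      m$z1 <- z1
      if (!is.null(par$T2))
        m$T2 <- par$T2[1] + par$T2[2] * (r * z1 + sqrt(1 - r^2) * w2)
      if (!is.null(par$T3))
        m$T3 <- par$T3[1] + par$T3[2] * (r * z1 + sqrt(1 - r^2) * w3)
      m
    }

    op <- lapply(spec$outcome_params, function(o) o[[g]])
    rng <- lapply(spec$outcome_params, function(o) o$range)

    # self-compassion: innovation shares a component with adherence
    sc_par <- op$self_compassion
    g_sc <- if (g == "training")
      coupling_weight(spec$rho_sessions_dsc, sc_par$T1[2], sc_par$T2[2], r,
                      "sessions ~ delta self-compassion") else 0
    w_sc <- g_sc * z_s + sqrt(1 - g_sc^2) * stats::rnorm(n)
    sc <- draw_outcome(sc_par, w_sc)
    # standardised self-compassion change innovation (eta)
    sd_dsc <- sqrt(sc_par$T1[2]^2 + sc_par$T2[2]^2 -
                     2 * r * sc_par$T1[2] * sc_par$T2[2])
    eta <- (sc$T2 - sc$T1 - (sc_par$T2[1] - sc_par$T1[1])) / sd_dsc

    # state mindfulness: weaker adherence coupling
    mi_par <- op$state_mindfulness
    g_mi <- if (g == "training")
      coupling_weight(spec$rho_sessions_dmind, mi_par$T1[2], mi_par$T2[2], r,
                      "sessions ~ delta mindfulness") else 0
    w_mi <- g_mi * z_s + sqrt(1 - g_mi^2) * stats::rnorm(n)
    mi <- draw_outcome(mi_par, w_mi)

    # USR: improvement in total self-compassion is driven by falling USR
    ku <- spec$usr_coupling
    w_u <- -ku * eta + sqrt(1 - ku^2) * stats::rnorm(n)
    us <- draw_outcome(op$usr, w_u)

    others <- lapply(op[c("mbi_ee", "mbi_pa", "mbi_dp")], function(par)
      draw_outcome(par, stats::rnorm(n)))

    clip <- function(x, rg) pmin(pmax(x, rg[1]), rg[2])
    vals <- list(
      self_compassion = lapply(sc[c("T1", "T2", "T3")], clip,
                               rg = rng$self_compassion),
      state_mindfulness = lapply(mi[c("T1", "T2", "T3")], clip,
                                 rg = rng$state_mindfulness),
      usr = lapply(us[c("T1", "T2", "T3")], clip, rg = rng$usr))
    for (nm in names(others))
      vals[[nm]] <- lapply(others[[nm]][intersect(c("T1", "T2", "T3"),
                                                  names(others[[nm]]))],
                           clip, rg = rng[[nm]])
    # CSR from the scoring identity, clipped to the scale
    vals$csr <- lapply(c("T1", "T2", "T3"), function(tp)
      clip(2 * vals$self_compassion[[tp]] - (6 - vals$usr[[tp]]), c(1, 5)))
    names(vals$csr) <- c("T1", "T2", "T3")

    # network activity records, DMN change coupled to eta
    ap <- lapply(spec$activity_params, function(a) a[[g]])
    act <- list()
    for (nw in names(ap)) {
      par <- ap[[nw]]
      z1 <- stats::rnorm(n)
      if (nw == "DMN") {
        delta_sd <- sqrt(par$T1[2]^2 + par$T2[2]^2 -
                           2 * ra * par$T1[2] * par$T2[2])
        rho_p <- rho_spearman_to_pearson(spec$rho_ddmn_dsc)
        dl <- rho_p * delta_sd / (par$T2[2] * sqrt(1 - ra^2))
        if (abs(dl) > 1)
          stop("infeasible correlation target for delta DMN ~ delta ",
               "self-compassion")
        w <- dl * eta + sqrt(1 - dl^2) * stats::rnorm(n)
      } else {
        w <- stats::rnorm(n)
      }
      a1 <- par$T1[1] + par$T1[2] * z1
      a2 <- par$T2[1] + par$T2[2] * (ra * z1 + sqrt(1 - ra^2) * w)
      act[[nw]] <- list(T1 = a1, T2 = a2)
    }

    # dropout at follow-up, completely at random
    drop_idx <- if (spec$dropout_t3[[g]] > 0)
      sample(n, spec$dropout_t3[[g]]) else integer(0)

    # training courses (engine-generated logs and final levels)
    final_level <- rep(NA_integer_, n)
    if (session_logs && g == "training") {
      for (i in seq_len(n)) {
        usr_model <- simulated_user(lapse_rate = stats::rbeta(1, 3, 120))
        course <- simulate_participant_course(usr_model,
                                              n_sessions = sessions[i])
        final_level[i] <- course$final_state$level
        courses[[ids[i]]] <- course
      }
    }

    for (tp in c("T1", "T2", "T3")) {
      has <- vapply(vals, function(v) !is.null(v[[tp]]), TRUE)
      if (!has[["self_compassion"]]) next
      row <- data.frame(participant_id = ids, group = g, timepoint = tp,
                        self_compassion = vals$self_compassion[[tp]],
                        csr = vals$csr[[tp]], usr = vals$usr[[tp]],
                        state_mindfulness = vals$state_mindfulness[[tp]],
                        mbi_ee = if (has[["mbi_ee"]]) vals$mbi_ee[[tp]]
                          else NA_real_,
                        mbi_pa = if (has[["mbi_pa"]]) vals$mbi_pa[[tp]]
                          else NA_real_,
                        mbi_dp = if (has[["mbi_dp"]]) vals$mbi_dp[[tp]]
                          else NA_real_,
                        sessions_completed = sessions,
                        final_level = final_level)
      if (tp == "T3" && length(drop_idx)) row <- row[-drop_idx, ]
      out_rows[[paste(g, tp)]] <- row
    }
    for (nw in names(act)) {
      for (tp in c("T1", "T2")) {
        overall <- act[[nw]][[tp]]
        contrast_gap <- abs(overall) * 0.15 +
          stats::rnorm(n, 0, 0.05 * max(stats::sd(overall), 1e-12))
        act_rows[[paste(g, nw, tp)]] <-
          data.frame(participant_id = ids, group = g, timepoint = tp,
                     network = nw, activity = overall,
                     attended = overall - contrast_gap / 2,
                     distracted = overall + contrast_gap / 2,
                     contrast = contrast_gap)
      }
    }
  }

  outcomes <- do.call(rbind, out_rows)
  rownames(outcomes) <- NULL
  activity <- do.call(rbind, act_rows)
  rownames(activity) <- NULL
  list(outcomes = outcomes, activity = activity, courses = courses,
       spec = spec)
}

#' Generate a synthetic EEG sub-cohort with configurable DMN plasticity
#'
#' Per participant, a baseline DMN oscillator amplitude is drawn lognormally
#' and the post-training amplitude is set by the configured T2/T1 ratio plus
#' individual noise; with `coupling = TRUE` the amplitude change is
#' additionally tied to the baseline level so that higher-baseline
#' participants show larger suppression (target Spearman
#' `rho_baseline_change`). FPN and CON amplitudes are unchanged between
#' sessions. Optionally synthesises the raw recordings and runs the full
#' network pipeline on them.
#'
#' @param n Number of participants.
#' @param leadfield A [make_leadfield()] (needed when `run_pipeline`).
#' @param dmn_t2_ratio Mean T2/T1 DMN amplitude ratio (0.5 = halved; 1 =
#'   null configuration).
#' @param coupling Couple amplitude change to baseline amplitude.
#' @param rho_baseline_change Target baseline-to-change Spearman when
#'   `coupling` (negative).
#' @param base_amp Named mean source amplitudes per network (source units).
#' @param subject_cv Lognormal coefficient of variation of per-subject
#'   amplitudes.
#' @param change_noise_cv SD of the individual change noise, as a fraction
#'   of the mean baseline amplitude.
#' @param run_pipeline Simulate recordings and run [eeg_network_pipeline()]
#'   for both sessions.
#' @param seed Optional integer seed.
#' @param ... Passed to [simulate_eeg_session()] (e.g. `srate`, `n_trials`,
#'   noise levels).
#' @return List with `params` (per-participant amplitude table) and, when
#'   `run_pipeline`, `activity` (long data frame participant x timepoint x
#'   network with the pipeline-estimated overall/attended/distracted values).
#' @export
generate_eeg_cohort <- function(n = 17, leadfield = NULL,
                                dmn_t2_ratio = 0.5, coupling = TRUE,
                                rho_baseline_change = -0.74,
                                base_amp = c(FPN = 2.5e-4, CON = 2.5e-4,
                                             DMN = 4e-4),
                                subject_cv = 0.3,
                                change_noise_cv = 0.15,
                                run_pipeline = FALSE, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(base_amp >= 0), dmn_t2_ratio >= 0)
  lp <- lnorm_params(1, subject_cv)
  A1 <- base_amp[["DMN"]] * stats::rlnorm(n, lp$meanlog, lp$sdlog)
  mu <- base_amp[["DMN"]]
  sigma_e <- change_noise_cv * mu
  b <- if (coupling && n > 1) {
    rho_p <- abs(rho_spearman_to_pearson(rho_baseline_change))
    # slope so that corr(A1, delta) = -rho_p given sd(A1) and noise
    rho_p / sqrt(1 - rho_p^2) * sigma_e / stats::sd(A1)
  } else 0
  delta <- (dmn_t2_ratio - 1) * mu - b * (A1 - mean(A1)) +
    stats::rnorm(n, 0, sigma_e)
  A2 <- pmax(A1 + delta, 0.02 * mu)
  fpn <- base_amp[["FPN"]] * stats::rlnorm(n, lp$meanlog, lp$sdlog)
  con <- base_amp[["CON"]] * stats::rlnorm(n, lp$meanlog, lp$sdlog)
  params <- data.frame(participant_id = sprintf("S%02d", seq_len(n)),
                       dmn_T1 = A1, dmn_T2 = A2, fpn = fpn, con = con)

  activity <- NULL
  if (run_pipeline) {
    if (is.null(leadfield)) stop("leadfield required to run the pipeline")
    rows <- list(); k <- 0
    for (i in seq_len(n)) {
      for (tp in c("T1", "T2")) {
        dmn_amp <- if (tp == "T1") A1[i] else A2[i]
        amps <- list(
          FPN = c(attended = fpn[i], distracted = fpn[i]),
          CON = c(attended = con[i], distracted = con[i]),
          DMN = c(attended = dmn_amp, distracted = 1.3 * dmn_amp))
        sim <- simulate_eeg_session(amps, leadfield, ...)
        act <- eeg_network_pipeline(sim$recording, rts = sim$rts,
                                    leadfield = leadfield)
        act <- as.data.frame(act)
        act$participant_id <- params$participant_id[i]
        act$timepoint <- tp
        k <- k + 1
        rows[[k]] <- act[, c("participant_id", "timepoint", "network",
                             "overall", "attended", "distracted",
                             "contrast")]
      }
    }
    activity <- do.call(rbind, rows)
    names(activity)[names(activity) == "overall"] <- "activity"
    rownames(activity) <- NULL
  }
  list(params = params, activity = activity)
}
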