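outcome_columns <- function() {
  c("self_compassion", "csr", "usr", "state_mindfulness",
    "mbi_ee", "mbi_pa", "mbi_dp")
}

# Wide participant x timepoint matrix for one outcome column.
outcome_wide <- function(outcomes, col) {
  d <- outcomes[, c("participant_id", "group", "timepoint", col)]
  names(d)[4] <- "value"
  w <- stats::reshape(d, idvar = c("participant_id", "group"),
                      timevar = "timepoint", direction = "wide")
  names(w) <- sub("^value\\.", "", names(w))
  w
}

#' Wide per-participant timepoint table for one outcome
#'
#' @param outcomes Long outcome table (see [analyze_trial()]).
#' @param col Outcome column name.
#' @param group Optional group filter.
#' @return Data frame with `participant_id`, `group` and one column per
#'   timepoint.
#' @export
outcome_change <- function(outcomes, col, group = NULL) {
  w <- outcome_wide(outcomes, col)
  if (!is.null(group)) w <- w[w$group == group, ]
  w
}

#' Analyse a full trial dataset
#'
#' The umbrella analysis: baseline group comparisons (normality-gated t /
#' rank-sum), within-group post-versus-pre and follow-up-versus-pre tests
#' with pooled-SD Cohen d per outcome, between-group change-score effect
#' sizes, adherence correlations (sessions completed vs outcome change and
#' final level), the change-in-DMN vs change-in-self-compassion partial
#' Spearman correlation (controlling for group and baseline emotional
#' exhaustion) and the per-network two-by-two mixed ANOVA. Outcomes with a
#' missing timepoint are analysed on complete cases; participants missing a
#' timepoint are dropped from that contrast only.
#'
#' @param outcomes Long data frame with columns `participant_id`, `group`
#'   (two levels, reference level is the trained group), `timepoint`
#'   (`"T1"`, `"T2"`, optionally `"T3"`), outcome columns among
#'   `self_compassion`, `csr`, `usr`, `state_mindfulness`, `mbi_ee`,
#'   `mbi_pa`, `mbi_dp`, and per-participant `sessions_completed`,
#'   `final_level`.
#' @param activity Optional network-activity data frame with columns
#'   `participant_id`, `timepoint`, `network`, `activity` (1e-4 source
#'   units), as produced by [generate_cohort()] or aggregated from
#'   [eeg_network_pipeline()] output.
#' @param training_group Level of `group` that received the intervention
#'   (default the first level).
#' @return Object of class `"trial_analysis"` with components `effect_sizes`
#'   (one row per outcome x group x contrast), `between_group`, `baseline`,
#'   `adherence`, `neurobehavioral`, `network_anova`, `skipped`.
#' @export
analyze_trial <- function(outcomes, activity = NULL, training_group = NULL) {
  stopifnot(all(c("participant_id", "group", "timepoint") %in%
                  names(outcomes)))
  outcomes$group <- factor(outcomes$group)
  if (nlevels(outcomes$group) != 2) stop("both groups must be present")
  if (is.null(training_group)) training_group <- levels(outcomes$group)[1]
  control_group <- setdiff(levels(outcomes$group), training_group)
  cols <- intersect(outcome_columns(), names(outcomes))
  tps <- intersect(c("T2", "T3"), unique(outcomes$timepoint))
  skipped <- character(0)

  ## baseline comparisons -------------------------------------------------
  base <- outcomes[outcomes$timepoint == "T1", ]
  baseline <- do.call(rbind, lapply(cols, function(cl) {
    x <- base[base$group == training_group, cl]
    y <- base[base$group == control_group, cl]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    normal <- length(x) >= 3 && length(y) >= 3 &&
      stats::shapiro.test(x)$p.value > 0.05 &&
      stats::shapiro.test(y)$p.value > 0.05
    if (normal) {
      tt <- stats::t.test(x, y)
      data.frame(outcome = cl, mean_training = mean(x), sd_training = stats::sd(x),
                 mean_control = mean(y), sd_control = stats::sd(y),
                 p = tt$p.value, test_used = "t")
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      data.frame(outcome = cl, mean_training = mean(x), sd_training = stats::sd(x),
                 mean_control = mean(y), sd_control = stats::sd(y),
                 p = wt$p.value, test_used = "rank-sum")
    }
  }))

  ## within-group contrasts + effect sizes --------------------------------
  es_rows <- list(); bg_rows <- list(); k <- 0; kb <- 0
  for (cl in cols) {
    w <- outcome_wide(outcomes, cl)
    for (tp in tps) {
      if (!tp %in% names(w)) { skipped <- c(skipped, paste(cl, tp)); next }
      deltas <- list()
      for (g in c(training_group, control_group)) {
        wi <- w[w$group == g, ]
        ok <- stats::complete.cases(wi$T1, wi[[tp]])
        if (sum(ok) < 3) { skipped <- c(skipped, paste(cl, tp, g)); next }
        pre <- wi$T1[ok]; post <- wi[[tp]][ok]
        test <- choose_and_run_paired_test(pre, post)
        k <- k + 1
        es_rows[[k]] <- data.frame(
          outcome = cl, group = g, contrast = paste0(tp, "-T1"),
          n = sum(ok),
          mean_pre = mean(pre), sd_pre = stats::sd(pre),
          mean_post = mean(post), sd_post = stats::sd(post),
          cohen_d = cohen_d_paired(pre, post),
          p = test$p, test_used = test$test_used)
        deltas[[g]] <- post - pre
      }
      if (length(deltas) == 2) {
        kb <- kb + 1
        bg_rows[[kb]] <- data.frame(
          outcome = cl, contrast = paste0(tp, "-T1"),
          cohen_d = cohen_d_between(deltas[[training_group]],
                                    deltas[[control_group]]))
      }
    }
  }
  effect_sizes <- if (k > 0) do.call(rbind, es_rows) else NULL
  between_group <- if (kb > 0) do.call(rbind, bg_rows) else NULL

  ## adherence correlations (trained group only) --------------------------
  adherence <- NULL
  if ("sessions_completed" %in% names(outcomes)) {
    tr1 <- outcomes[outcomes$timepoint == "T1" &
                      outcomes$group == training_group, ]
    sess <- tr1$sessions_completed
    rows <- list(); ka <- 0
    if ("final_level" %in% names(outcomes) &&
        any(!is.na(tr1$final_level)) && stats::sd(tr1$final_level) > 0) {
      sp <- spearman(sess, tr1$final_level)
      ka <- ka + 1
      rows[[ka]] <- data.frame(pair = "sessions~final_level",
                               rho = sp$rho, p = sp$p, n = sp$n)
    }
    for (cl in intersect(c("self_compassion", "state_mindfulness"), cols)) {
      w <- outcome_wide(outcomes, cl)
      wi <- w[w$group == training_group, ]
      if (!"T2" %in% names(wi)) next
      delta <- wi$T2 - wi$T1
      sp <- try(spearman(sess[match(wi$participant_id, tr1$participant_id)],
                         delta), silent = TRUE)
      if (!inherits(sp, "try-error")) {
        ka <- ka + 1
        rows[[ka]] <- data.frame(pair = paste0("sessions~delta_", cl),
                                 rho = sp$rho, p = sp$p, n = sp$n)
      }
    }
    if (ka > 0) adherence <- do.call(rbind, rows)
  }

  ## neurobehavioral partial correlations + network ANOVA -----------------
  neurobehavioral <- NULL
  network_anova <- NULL
  if (!is.null(activity)) {
    aw <- stats::reshape(
      activity[activity$network == "DMN",
               c("participant_id", "timepoint", "activity")],
      idvar = "participant_id", timevar = "timepoint", direction = "wide")
    names(aw) <- sub("^activity\\.", "", names(aw))
    if (all(c("T1", "T2") %in% names(aw))) {
      aw$delta_dmn <- aw$T2 - aw$T1
      meta <- outcomes[outcomes$timepoint == "T1",
                       c("participant_id", "group",
                         intersect("mbi_ee", names(outcomes)))]
      rows <- list(); kn <- 0
      for (cl in intersect(c("self_compassion", "state_mindfulness",
                             "csr", "usr"), cols)) {
        w <- outcome_wide(outcomes, cl)
        if (!"T2" %in% names(w)) next
        w$delta <- w$T2 - w$T1
        m <- merge(merge(w[, c("participant_id", "delta")], aw), meta)
        covs <- data.frame(group = as.numeric(factor(m$group)))
        if ("mbi_ee" %in% names(m)) covs$mbi_ee <- m$mbi_ee
        sp <- try(spearman_partial(m$delta_dmn, m$delta, covs), silent = TRUE)
        if (!inherits(sp, "try-error")) {
          kn <- kn + 1
          rows[[kn]] <- data.frame(pair = paste0("delta_DMN~delta_", cl),
                                   rho = sp$rho, p = sp$p, n = sp$n)
        }
      }
      # baseline-activity vs change within the trained group
      tr_ids <- unique(outcomes$participant_id[outcomes$group ==
                                                 training_group])
      awt <- aw[aw$participant_id %in% tr_ids, ]
      if (nrow(awt) >= 4 && stats::sd(awt$T1) > 0) {
        sp <- spearman(awt$T1, awt$delta_dmn)
        kn <- kn + 1
        rows[[kn]] <- data.frame(pair = "baseline_DMN~delta_DMN_training",
                                 rho = sp$rho, p = sp$p, n = sp$n)
      }
      if (kn > 0) neurobehavioral <- do.call(rbind, rows)
    }

    grp_map <- unique(outcomes[, c("participant_id", "group")])
    network_anova <- lapply(split(activity, activity$network), function(a) {
      a <- a[a$timepoint %in% c("T1", "T2"), ]
      a <- merge(a, grp_map)
      dat <- data.frame(participant = a$participant_id, group = a$group,
                        session = a$timepoint, value = a$activity)
      tryCatch(mixed_anova(dat), error = function(e) NULL)
    })
    network_anova <- network_anova[!vapply(network_anova, is.null, TRUE)]
  }

  structure(list(effect_sizes = effect_sizes, between_group = between_group,
                 baseline = baseline, adherence = adherence,
                 neurobehavioral = neurobehavioral,
                 network_anova = network_anova,
                 skipped = skipped,
                 groups = c(training = training_group,
                            control = control_group)),
            class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, digits = 2, ...) {
  cat("Trial analysis (training group:", x$groups[["training"]], ")\n\n")
  if (!is.null(x$effect_sizes)) {
    cat("Within-group contrasts:\n")
    df <- x$effect_sizes
    df$cohen_d <- round(df$cohen_d, digits)
    df$p <- signif(df$p, 2)
    print(df[, c("outcome", "group", "contrast", "n", "cohen_d", "p",
                 "test_used")], row.names = FALSE)
  }
  if (!is.null(x$between_group)) {
    cat("\nBetween-group change-score effect sizes:\n")
    df <- x$between_group
    df$cohen_d <- round(df$cohen_d, digits)
    print(df, row.names = FALSE)
  }
  if (!is.null(x$adherence)) {
    cat("\nAdherence correlations (Spearman):\n")
    df <- x$adherence; df$rho <- round(df$rho, 2); df$p <- signif(df$p, 2)
    print(df, row.names = FALSE)
  }
  if (!is.null(x$neurobehavioral)) {
    cat("\nNeurobehavioral correlations:\n")
    df <- x$neurobehavioral; df$rho <- round(df$rho, 2)
    df$p <- signif(df$p, 2)
    print(df, row.names = FALSE)
  }
  if (length(x$network_anova)) {
    cat("\nNetwork mixed ANOVAs (group x session):\n")
    for (nw in names(x$network_anova)) {
      a <- x$network_anova[[nw]]
      cat(sprintf("  %s: F(%d,%d) = %.2f, p = %.3g, partial eta^2 = %.2f\n",
                  nw, a$df[1], a$df[2], a$F, a$p, a$partial_eta_sq))
    }
  }
  if (length(x$skipped))
    cat("\nSkipped (insufficient data):", paste(x$skipped, collapse = "; "),
        "\n")
  invisible(x)
}

#' @export
summary.trial_analysis <- function(object, ...) {
  list(effect_sizes = object$effect_sizes,
       between_group = object$between_group,
       adherence = object$adherence,
       neurobehavioral = object$neurobehavioral)
}
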