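#' Pipeline run configuration
#'
#' Collects the seed, stage toggles and the thresholds of every stage in one
#' serialisable object. The configuration round-trips losslessly through
#' YAML ([write_run_config()] / [read_run_config()]).
#'
#' @param seed Integer seed used for every stochastic stage.
#' @param n_training,n_control Cohort sizes.
#' @param stages Named logical vector toggling `cohort`, `training`,
#'   `assessment`, `eeg`, `analyze`.
#' @param cv_threshold Training consistency CV threshold.
#' @param lambda Minimum-norm regularisation.
#' @param alpha_band Alpha band edges in Hz.
#' @param mad_sided Sidedness of the MAD trial rule.
#' @param reject_uV Epoch-rejection amplitude threshold.
#' @param eeg_n Participants in the (expensive) raw-EEG demonstration stage.
#' @param eeg_srate,eeg_n_trials Raw-EEG simulation size parameters.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(seed = 1L,
                       n_training = 22L, n_control = 21L,
                       stages = c(cohort = TRUE, training = TRUE,
                                  assessment = TRUE, eeg = TRUE,
                                  analyze = TRUE),
                       cv_threshold = 0.25,
                       lambda = 0.1,
                       alpha_band = c(8, 12),
                       mad_sided = "two",
                       reject_uV = 100,
                       eeg_n = 4L,
                       eeg_srate = 250,
                       eeg_n_trials = 16L) {
  cfg <- list(seed = as.integer(seed), n_training = as.integer(n_training),
              n_control = as.integer(n_control),
              stages = as.list(stages), cv_threshold = cv_threshold,
              lambda = lambda, alpha_band = alpha_band,
              mad_sided = mad_sided, reject_uV = reject_uV,
              eeg_n = as.integer(eeg_n), eeg_srate = eeg_srate,
              eeg_n_trials = as.integer(eeg_n_trials))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config A `"run_config"`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$stages <- lapply(cfg$stages, as.logical)
  do.call(run_config, c(cfg[setdiff(names(cfg), "stages")],
                        list(stages = unlist(cfg$stages))))
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full study pipeline on synthetic data
#'
#' Simulate (cohort + training logs) -> score an assessment run -> EEG
#' network activity -> trial analysis, writing a machine-readable JSON
#' report, Markdown summary tables and a provenance block (config echo and
#' hash, seed, package version) into `out_dir`. Stages toggled off are
#' marked as skipped in the report; a failing stage aborts with a
#' stage-named error, retaining the outputs of completed stages.
#'
#' The EEG stage demonstrates the raw-signal path on a reduced sub-cohort
#' (`eeg_n` participants); the trial analysis itself uses the cohort's
#' activity records so that the behavioural and neural ns match.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param activity_override Optional replacement for the cohort activity
#'   records (used for fault injection in tests; `NA` forces an EEG-stage
#'   error).
#' @return Invisibly, a list with the report, the analysis object and the
#'   output paths.
#' @export
run_full_pipeline <- function(config = run_config(), out_dir = tempfile(),
                              activity_override = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  report <- list(stages = list())
  on <- function(s) isTRUE(config$stages[[s]])

  cohort <- NULL
  if (on("cohort")) {
    cohort <- stage_try("cohort", {
      spec <- cohort_spec(n_training = config$n_training,
                          n_control = config$n_control)
      generate_cohort(spec, session_logs = on("training"))
    })
    utils::write.csv(cohort$outcomes, file.path(out_dir, "outcomes.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$activity, file.path(out_dir, "activity.csv"),
                     row.names = FALSE)
    report$stages$cohort <- list(
      status = "ok", n = config$n_training + config$n_control)
  } else report$stages$cohort <- list(status = "skipped")

  if (on("training") && !is.null(cohort)) {
    report$stages$training <- stage_try("training", {
      lv <- vapply(cohort$courses, function(cc) cc$final_state$level, 1L)
      sess <- vapply(cohort$courses, function(cc) cc$n_sessions, 1L)
      list(status = "ok", n_courses = length(lv),
           mean_sessions = mean(sess), mean_final_level = mean(lv))
    })
  } else report$stages$training <- list(status = "skipped")

  if (on("assessment")) {
    report$stages$assessment <- stage_try("assessment", {
      run <- simulate_assessment_run(simulated_user(lapse_rate = 0.15))
      s <- summary(run$series)
      list(status = "ok", n_trials = s$n, median_rt = s$median_rt,
           mad_rt = s$mad_rt, frac_distracted = s$frac_distracted)
    })
  } else report$stages$assessment <- list(status = "skipped")

  activity <- if (!is.null(cohort)) cohort$activity else NULL
  if (on("eeg")) {
    report$stages$eeg <- stage_try("eeg", {
      if (!is.null(activity_override)) {
        if (!is.data.frame(activity_override))
          stop("corrupt activity input")
        activity <- activity_override
      }
      lf <- make_leadfield()
      demo <- generate_eeg_cohort(n = config$eeg_n, leadfield = lf,
                                  run_pipeline = TRUE,
                                  srate = config$eeg_srate,
                                  n_trials = config$eeg_n_trials)
      dmn <- demo$activity[demo$activity$network == "DMN", ]
      list(status = "ok", n = config$eeg_n,
           mean_dmn_T1 = mean(dmn$activity[dmn$timepoint == "T1"]),
           mean_dmn_T2 = mean(dmn$activity[dmn$timepoint == "T2"]))
    })
  } else report$stages$eeg <- list(status = "skipped")

  analysis <- NULL
  if (on("analyze") && !is.null(cohort)) {
    analysis <- stage_try("analyze",
                          analyze_trial(cohort$outcomes, activity,
                                        training_group = "training"))
    report$stages$analyze <- list(status = "ok")
    report$effect_sizes <- analysis$effect_sizes
    report$between_group <- analysis$between_group
    report$adherence <- analysis$adherence
    report$neurobehavioral <- analysis$neurobehavioral
    md <- file.path(out_dir, "report.md")
    writeLines(format_analysis_md(analysis), md)
  } else report$stages$analyze <- list(status = "skipped")

  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  report$provenance <- list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("breathloop")))
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows", na = "null")
  invisible(list(report = report, analysis = analysis,
                 paths = list(json = json_path, out_dir = out_dir)))
}

# Markdown tables mirroring the within/between-group summaries.
format_analysis_md <- function(analysis) {
  es <- analysis$effect_sizes
  lines <- c("# Trial analysis report", "",
             "## Within-group contrasts", "",
             "| outcome | group | contrast | n | d | p | test |",
             "|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(es))) {
    lines <- c(lines, sprintf("| %s | %s | %s | %d | %.2f | %.3g | %s |",
                              es$outcome[i], es$group[i], es$contrast[i],
                              es$n[i], es$cohen_d[i], es$p[i],
                              es$test_used[i]))
  }
  if (!is.null(analysis$between_group)) {
    bg <- analysis$between_group
    lines <- c(lines, "", "## Between-group change-score effect sizes", "",
               "| outcome | contrast | d |", "|---|---|---|",
               sprintf("| %s | %s | %.2f |", bg$outcome, bg$contrast,
                       bg$cohen_d))
  }
  if (!is.null(analysis$adherence)) {
    ad <- analysis$adherence
    lines <- c(lines, "", "## Adherence correlations", "",
               "| pair | rho | p | n |", "|---|---|---|---|",
               sprintf("| %s | %.2f | %.3g | %d |", ad$pair, ad$rho, ad$p,
                       ad$n))
  }
  lines
}
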