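#' Score the 12-item short self-compassion scale
#'
#' The scale has six positively worded items measuring compassionate
#' self-responding (CSR: self-kindness, common humanity, mindfulness) and six
#' negatively worded items measuring uncompassionate self-responding (USR:
#' self-judgment, isolation, overidentification). The total is the mean of
#' all 12 items with the negative items reverse-scored (`6 - response` on the
#' 1-5 scale); CSR is the mean of the positive items and USR the mean of the
#' negative items left unreversed, so a USR decrease indicates improvement.
#'
#' @param item_responses Numeric vector of 12 responses in 1..5, or a matrix
#'   with 12 columns (one respondent per row).
#' @param positive_items Indices of the six CSR items (default the standard
#'   short-form keying: items 2, 3, 5, 6, 7, 10).
#' @return A list (or data frame for matrix input) with `total`, `csr`,
#'   `usr`.
#' @examples
#' score_scs12(rep(3, 12))
#' @export
score_scs12 <- function(item_responses,
                        positive_items = c(2, 3, 5, 6, 7, 10)) {
  if (is.matrix(item_responses) || is.data.frame(item_responses)) {
    m <- as.matrix(item_responses)
    out <- t(apply(m, 1, function(r)
      unlist(score_scs12(r, positive_items))))
    return(as.data.frame(out))
  }
  x <- as.numeric(item_responses)
  if (length(x) != 12) stop("expected 12 item responses")
  if (anyNA(x)) stop("missing items are not imputed; supply all 12 responses")
  if (any(x < 1 | x > 5)) stop("item responses must be in 1..5")
  stopifnot(length(positive_items) == 6)
  neg <- setdiff(1:12, positive_items)
  csr <- mean(x[positive_items])
  usr <- mean(x[neg])
  total <- mean(c(x[positive_items], 6 - x[neg]))
  list(total = total, csr = csr, usr = usr)
}

#' Within-group Cohen d from summary statistics
#'
#' Pooled-SD form: `d = (m2 - m1) / sqrt((s1^2 + s2^2) / 2)`, the mean
#' post-versus-pre difference expressed in pooled SD units. Rounding to the
#' conventional two decimals is left to report formatting.
#'
#' @param m1,s1 Mean and SD at the first timepoint.
#' @param m2,s2 Mean and SD at the second timepoint.
#' @return The effect size `d` (dimensionless).
#' @examples
#' cohen_d_within(2.69, 0.57, 3.02, 0.58)  # ~0.57
#' @export
cohen_d_within <- function(m1, s1, m2, s2) {
  if (any(c(s1, s2) <= 0)) stop("standard deviations must be positive")
  (m2 - m1) / sqrt((s1^2 + s2^2) / 2)
}

#' Within-group Cohen d from paired samples
#'
#' @param x_pre,x_post Paired vectors (complete cases only are used).
#' @return `d` computed from the sample means/SDs via [cohen_d_within()].
#' @export
cohen_d_paired <- function(x_pre, x_post) {
  ok <- stats::complete.cases(x_pre, x_post)
  cohen_d_within(mean(x_pre[ok]), stats::sd(x_pre[ok]),
                 mean(x_post[ok]), stats::sd(x_post[ok]))
}

#' Between-group Cohen d on change scores
#'
#' Standardised difference of mean change: the two groups' change scores are
#' pooled with Hedges weighting,
#' `d = (mean(d1) - mean(d2)) / sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2))`.
#'
#' @param delta1,delta2 Change-score vectors for the two groups.
#' @return The between-group effect size.
#' @export
cohen_d_between <- function(delta1, delta2) {
  delta1 <- delta1[!is.na(delta1)]
  delta2 <- delta2[!is.na(delta2)]
  n1 <- length(delta1); n2 <- length(delta2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 complete cases per group")
  sp <- sqrt(((n1 - 1) * stats::var(delta1) + (n2 - 1) * stats::var(delta2)) /
               (n1 + n2 - 2))
  if (sp <= 0) stop("pooled SD of change scores is zero")
  (mean(delta1) - mean(delta2)) / sp
}

#' Normality-gated paired test
#'
#' Runs a two-tailed paired t test when the difference scores pass the
#' normality gate, otherwise the Wilcoxon signed-rank test. The default gate
#' is the Shapiro-Wilk test on the differences at `alpha_gate`; a Levene-type
#' gate (Brown-Forsythe on the absolute deviations of pre vs post) is
#' available for comparison.
#'
#' @param x_pre,x_post Paired observations, equal length, n >= 3.
#' @param gate `"shapiro"` (default) or `"levene"`.
#' @param alpha_gate Gate significance level.
#' @return List with `p`, `test_used` (`"paired-t"`, `"wilcoxon-signed-rank"`
#'   or `"degenerate"`), `statistic`, `degenerate`.
#' @export
choose_and_run_paired_test <- function(x_pre, x_post,
                                       gate = c("shapiro", "levene"),
                                       alpha_gate = 0.05) {
  gate <- match.arg(gate)
  ok <- stats::complete.cases(x_pre, x_post)
  x_pre <- x_pre[ok]; x_post <- x_post[ok]
  if (length(x_pre) != length(x_post)) stop("paired vectors of equal length")
  if (length(x_pre) < 3) stop("need n >= 3 pairs")
  d <- x_post - x_pre
  if (all(d == 0)) {
    return(list(p = 1, test_used = "degenerate", statistic = NA_real_,
                degenerate = TRUE))
  }
  normal <- if (gate == "shapiro") {
    if (stats::sd(d) == 0) FALSE else stats::shapiro.test(d)$p.value > alpha_gate
  } else {
    # Brown-Forsythe: |deviation from median| compared between pre and post
    z1 <- abs(x_pre - stats::median(x_pre))
    z2 <- abs(x_post - stats::median(x_post))
    grp <- factor(rep(c("pre", "post"), c(length(z1), length(z2))))
    stats::anova(stats::lm(c(z1, z2) ~ grp))[["Pr(>F)"]][1] > alpha_gate
  }
  if (normal) {
    tt <- stats::t.test(x_post, x_pre, paired = TRUE)
    list(p = tt$p.value, test_used = "paired-t",
         statistic = unname(tt$statistic), degenerate = FALSE)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x_post, x_pre, paired = TRUE,
                                              exact = FALSE, correct = TRUE))
    list(p = wt$p.value, test_used = "wilcoxon-signed-rank",
         statistic = unname(wt$statistic), degenerate = FALSE)
  }
}

#' Cronbach's alpha internal-consistency reliability
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total score))`.
#'
#' @param item_matrix Respondents x items numeric matrix, k >= 2 items and
#'   >= 2 respondents.
#' @return Alpha (can be negative for inconsistent scales).
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2 || nrow(m) < 2)
    stop("need at least 2 items and 2 respondents")
  if (anyNA(m)) stop("item matrix must be complete")
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop("total-score variance is zero; alpha undefined")
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Spearman rank correlation
#'
#' Thin wrapper around [stats::cor.test()] (method `"spearman"`, asymptotic
#' p), returning `rho` and `p`.
#'
#' @param x,y Equal-length numeric vectors; incomplete pairs are dropped.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Spearman partial correlation
#'
#' Rank-transforms `x`, `y` and every covariate, residualises the ranks of
#' `x` and `y` on the covariate ranks by least squares, and correlates the
#' residuals. The p value uses the t approximation with `n - 2 - k` degrees
#' of freedom for `k` covariates. With no covariates this reduces exactly to
#' the plain Spearman coefficient.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data frame / matrix of covariates (may include
#'   binary group indicators); `NULL` for none.
#' @return List with `rho`, `p`, `n`, `df`.
#' @export
spearman_partial <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0) {
    cov_m <- NULL
  } else {
    cov_m <- as.matrix(as.data.frame(lapply(as.data.frame(covariates),
                                            as.numeric)))
  }
  ok <- if (is.null(cov_m)) stats::complete.cases(x, y)
    else stats::complete.cases(x, y, cov_m)
  x <- x[ok]; y <- y[ok]
  if (!is.null(cov_m)) cov_m <- cov_m[ok, , drop = FALSE]
  n <- length(x)
  k <- if (is.null(cov_m)) 0 else ncol(cov_m)
  if (n < 4 + k) stop("too few complete cases for partial correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; correlation undefined")
  rx <- rank(x); ry <- rank(y)
  if (is.null(cov_m)) {
    res_x <- rx - mean(rx); res_y <- ry - mean(ry)
  } else {
    rc <- apply(cov_m, 2, rank)
    res_x <- stats::lm.fit(cbind(1, rc), rx)$residuals
    res_y <- stats::lm.fit(cbind(1, rc), ry)$residuals
  }
  rho <- stats::cor(res_x, res_y)
  df <- n - 2 - k
  tval <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(rho = rho, p = p, n = n, df = df)
}

#' Two-by-two mixed (split-plot) ANOVA
#'
#' Between-subject factor `group`, within-subject factor `session` (two
#' levels, e.g. pre/post), complete cases only. Reports the group-by-session
#' interaction F, degrees of freedom, Greenhouse-Geisser corrected p (with
#' two within levels the GG epsilon is exactly 1, so the correction is a
#' no-op and is noted as such) and partial eta squared.
#'
#' @param values Data frame with columns `participant`, `group`, `session`,
#'   `value`; exactly two sessions.
#' @return Object of class `"anova_report"`: `F`, `df` (num, den), `p`,
#'   `partial_eta_sq`, `gg_epsilon`, `note`, plus main-effect rows in
#'   `effects`.
#' @export
mixed_anova <- function(values) {
  req <- c("participant", "group", "session", "value")
  if (!all(req %in% names(values))) stop("values needs columns: ",
                                         paste(req, collapse = ", "))
  values$participant <- factor(values$participant)
  values$group <- factor(values$group)
  values$session <- factor(values$session)
  if (nlevels(values$session) != 2) stop("exactly 2 sessions required")
  if (nlevels(values$group) != 2) stop("exactly 2 groups required")
  # complete cases: participants with both sessions
  tab <- table(values$participant)
  keep <- names(tab)[tab == 2]
  values <- values[values$participant %in% keep & !is.na(values$value), ]
  tab <- table(values$participant)
  values <- values[values$participant %in% names(tab)[tab == 2], ]
  values$participant <- droplevels(values$participant)
  per_group <- table(unique(values[, c("participant", "group")])$group)
  if (any(per_group < 2)) stop("each group needs >= 2 complete cases")

  fit <- stats::aov(value ~ group * session + Error(participant / session),
                    data = values)
  sm <- summary(fit)
  within <- sm[["Error: participant:session"]][[1]]
  between <- sm[["Error: participant"]][[1]]
  rn <- trimws(rownames(within))
  i_int <- which(rn == "group:session")
  i_ses <- which(rn == "session")
  i_res <- which(rn == "Residuals")
  F_int <- within[i_int, "F value"]
  df_num <- within[i_int, "Df"]
  df_den <- within[i_res, "Df"]
  p_int <- within[i_int, "Pr(>F)"]
  ss_int <- within[i_int, "Sum Sq"]
  ss_res <- within[i_res, "Sum Sq"]
  peta <- ss_int / (ss_int + ss_res)

  rnb <- trimws(rownames(between))
  i_grp <- which(rnb == "group")
  effects <- data.frame(
    effect = c("group", "session", "group:session"),
    F = c(between[i_grp, "F value"], within[i_ses, "F value"], F_int),
    p = c(between[i_grp, "Pr(>F)"], within[i_ses, "Pr(>F)"], p_int))

  structure(list(F = F_int, df = c(df_num, df_den), p = p_int,
                 partial_eta_sq = peta, gg_epsilon = 1,
                 note = paste("two within-subject levels:",
                              "Greenhouse-Geisser epsilon = 1,",
                              "correction is a no-op"),
                 effects = effects,
                 n = nlevels(values$participant)),
            class = "anova_report")
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf("Mixed ANOVA group x session interaction: F(%d,%d) = %.2f, p = %.4g, partial eta^2 = %.2f\n",
              x$df[1], x$df[2], x$F, x$p, x$partial_eta_sq))
  cat("  GG epsilon =", x$gg_epsilon, "(", x$note, ")\n")
  invisible(x)
}
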