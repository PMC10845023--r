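test_that("self-compassion scoring matches the keying and the oracle", {
  s <- score_scs12(rep(3, 12))
  expect_equal(unlist(s), c(total = 3, csr = 3, usr = 3))

  # positive items at 5, negative at 1: fully self-compassionate sheet
  resp <- rep(1, 12)
  resp[c(2, 3, 5, 6, 7, 10)] <- 5
  s2 <- score_scs12(resp)
  expect_equal(unlist(s2), c(total = 5, csr = 5, usr = 1))

  set.seed(201)
  for (i in 1:50) {
    resp <- sample(1:5, 12, replace = TRUE)
    got <- score_scs12(resp)
    ref <- brute_force_scs12(resp)
    expect_equal(got$total, ref$total)
    expect_equal(got$csr, ref$csr)
    expect_equal(got$usr, ref$usr)
  }

  expect_error(score_scs12(rep(3, 11)), "12")
  expect_error(score_scs12(c(rep(3, 11), NA)), "missing")
  expect_error(score_scs12(c(rep(3, 11), 6)), "1..5")
})

test_that("pooled-SD Cohen d has the expected algebraic properties", {
  expect_equal(cohen_d_within(2, 1, 2, 1), 0)
  # antisymmetry under swapping the two timepoints
  expect_equal(cohen_d_within(2.7, 0.6, 3.1, 0.5),
               -cohen_d_within(3.1, 0.5, 2.7, 0.6))
  # invariance under common positive rescaling
  expect_equal(cohen_d_within(2.7, 0.6, 3.1, 0.5),
               cohen_d_within(27, 6, 31, 5))
  expect_error(cohen_d_within(1, 0, 2, 1), "positive")

  set.seed(202)
  x <- rnorm(20); y <- rnorm(20) + 0.4
  expect_equal(cohen_d_paired(x, y),
               (mean(y) - mean(x)) / sqrt((var(x) + var(y)) / 2))
})

test_that("normality gate selects the paired test appropriately", {
  set.seed(203)
  picks_normal <- replicate(60, {
    x <- rnorm(22); y <- x + 0.5 + rnorm(22, 0, 0.5)
    choose_and_run_paired_test(x, y)$test_used
  })
  expect_gt(mean(picks_normal == "paired-t"), 0.85)

  picks_heavy <- replicate(60, {
    x <- rnorm(22); y <- x + rcauchy(22)
    choose_and_run_paired_test(x, y)$test_used
  })
  expect_gt(mean(picks_heavy == "wilcoxon-signed-rank"), 0.6)

  # identical vectors: degenerate flag, p = 1
  x <- rnorm(10)
  deg <- choose_and_run_paired_test(x, x)
  expect_true(deg$degenerate)
  expect_identical(deg$p, 1)

  # a shifted-normal alternative is usually detected at n = 22
  set.seed(204)
  power <- mean(replicate(200, {
    x <- rnorm(22); y <- x + 0.5 + rnorm(22, 0, 1)
    choose_and_run_paired_test(x, y)$p < 0.05
  }))
  expect_gt(power, 0.5)

  # Levene-style gate is available
  res <- choose_and_run_paired_test(rnorm(15), rnorm(15), gate = "levene")
  expect_true(res$test_used %in% c("paired-t", "wilcoxon-signed-rank"))
})

test_that("Cronbach alpha matches hand computation and limiting cases", {
  m <- cbind(c(1, 2, 3, 4), c(2, 4, 4, 5), c(3, 5, 6, 8))
  # hand arithmetic: item variances 5/3 + 19/12 + 13/3, total variance 251/12
  expect_equal(cronbach_alpha(m), 240 / 251)

  dup <- cbind(c(1, 3, 2, 5), c(1, 3, 2, 5), c(1, 3, 2, 5))
  expect_equal(cronbach_alpha(dup), 1)

  set.seed(205)
  indep <- matrix(rnorm(5000 * 4), 5000, 4)
  expect_lt(abs(cronbach_alpha(indep)), 0.08)

  expect_error(cronbach_alpha(matrix(1, 4, 3)), "zero")
  expect_error(cronbach_alpha(matrix(1:3, ncol = 1)), "at least 2")
})

test_that("Spearman correlation is rank-invariant and matches its oracle", {
  x <- seq(-2, 2, length.out = 20)
  expect_equal(spearman(x, x^3)$rho, 1)

  set.seed(206)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    got <- spearman(x, y)
    # classical rank formula (no ties with continuous data)
    dif <- rank(x) - rank(y)
    expect_equal(got$rho, 1 - 6 * sum(dif^2) / (30 * (30^2 - 1)))
  }
  expect_error(spearman(rep(1, 10), rnorm(10)), "constant")
})

test_that("partial Spearman reduces to plain Spearman and removes covariates", {
  set.seed(207)
  for (i in 1:100) {
    x <- rnorm(25); y <- rnorm(25)
    expect_equal(spearman_partial(x, y)$rho, spearman(x, y)$rho)
  }

  # y = x + z with independent z: partialling z recovers the x-y link
  set.seed(208)
  x <- rnorm(200); z <- rnorm(200) * 3
  y <- x + z
  raw <- spearman(x, y)$rho
  part <- spearman_partial(x, y, data.frame(z = z))$rho
  expect_gt(part, 0.9)
  expect_gt(part, raw)

  # binary group covariate is accepted; rank residualisation removes most
  # of the group shift (rank transforms are only piecewise linear in it)
  grp <- rep(0:1, each = 100)
  res <- spearman_partial(x, y + 2 * grp, data.frame(z = z, grp = grp))
  expect_gt(res$rho, 0.8)
  raw <- spearman(x, y + 2 * grp)$rho
  expect_gt(res$rho, raw)
})

test_that("mixed ANOVA matches textbook formulas and its symmetries", {
  set.seed(209)
  make_data <- function(n_per = 8, interaction = 0) {
    d <- expand.grid(participant = sprintf("p%02d", seq_len(2 * n_per)),
                     session = c("T1", "T2"))
    d$group <- rep(rep(c("a", "b"), each = n_per), 2)
    d$value <- rnorm(nrow(d)) +
      ifelse(d$group == "b" & d$session == "T2", interaction, 0)
    d
  }

  d <- make_data()
  a <- mixed_anova(d)
  expect_equal(a$F, textbook_mixed_anova_F(d), tolerance = 1e-8)
  expect_identical(a$df, c(1, 2 * 8 - 2))
  expect_identical(a$gg_epsilon, 1)

  # label symmetry: swapping group names leaves F unchanged
  d2 <- d
  d2$group <- ifelse(d$group == "a", "b", "a")
  expect_equal(mixed_anova(d2)$F, a$F)

  # interaction-only data: interaction significant, main session effect
  # present by construction is half the interaction -- test interaction
  d3 <- make_data(n_per = 20, interaction = 2)
  a3 <- mixed_anova(d3)
  expect_lt(a3$p, 0.001)
  expect_gt(a3$partial_eta_sq, 0.3)

  expect_error(mixed_anova(data.frame(participant = 1:4,
                                      group = c("a", "a", "a", "b"),
                                      session = c("T1", "T2", "T1", "T2"),
                                      value = rnorm(4))),
               ">= 2 complete cases")
})

test_that("between-group change-score d behaves sensibly", {
  set.seed(210)
  d1 <- rnorm(22, 0.5); d2 <- rnorm(21, 0)
  d <- cohen_d_between(d1, d2)
  expect_gt(d, 0)
  expect_equal(cohen_d_between(d2, d1), -d)
  expect_equal(cohen_d_between(2 * d1, 2 * d2), d)
})
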