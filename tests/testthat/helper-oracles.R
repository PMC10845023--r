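# Independent brute-force reference for the median/MAD trial classifier:
# everything computed by explicit sorting, no calls to the package.
brute_force_classify <- function(rts) {
  n <- length(rts)
  srt <- sort(rts)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else
    (srt[n / 2] + srt[n / 2 + 1]) / 2
  dev <- abs(rts - med)
  sdev <- sort(dev)
  mad0 <- if (n %% 2 == 1) sdev[(n + 1) / 2] else
    (sdev[n / 2] + sdev[n / 2 + 1]) / 2
  list(median = med, mad = mad0,
       attended = dev <= mad0 * (1 + 1e-8) + 1e-12)
}

# Item-by-item reference scorer for the 12-item self-compassion sheet.
brute_force_scs12 <- function(resp, pos = c(2, 3, 5, 6, 7, 10)) {
  tot <- 0
  csr <- 0
  usr <- 0
  for (i in 1:12) {
    if (i %in% pos) {
      tot <- tot + resp[i]
      csr <- csr + resp[i]
    } else {
      tot <- tot + (6 - resp[i])
      usr <- usr + resp[i]
    }
  }
  list(total = tot / 12, csr = csr / 6, usr = usr / 6)
}

# Textbook split-plot sums of squares for a balanced-or-not 2 x 2 design.
textbook_mixed_anova_F <- function(df) {
  w <- stats::reshape(df[, c("participant", "group", "session", "value")],
                      idvar = c("participant", "group"),
                      timevar = "session", direction = "wide")
  names(w)[3:4] <- c("s1", "s2")
  gm <- mean(c(w$s1, w$s2))
  groups <- split(w, w$group)
  ss_int <- 0
  ss_err <- 0
  ses_mean <- c(mean(w$s1), mean(w$s2))
  for (g in groups) {
    gmean <- mean(c(g$s1, g$s2))
    for (j in 1:2) {
      col <- if (j == 1) g$s1 else g$s2
      cell <- mean(col)
      ss_int <- ss_int + nrow(g) * (cell - gmean - ses_mean[j] + gm)^2
      subj <- (g$s1 + g$s2) / 2
      ss_err <- ss_err + sum((col - subj - cell + gmean)^2)
    }
  }
  (ss_int / 1) / (ss_err / (nrow(w) - 2))
}

# Small deterministic RT vectors used across classifier tests.
random_rt_vector <- function(n) {
  stats::rlnorm(n, log(5), 0.4)
}
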