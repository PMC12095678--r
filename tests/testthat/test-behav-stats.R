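# Explicit sums-of-squares oracle for a balanced two-way design with one
# within-subject factor (feedback) and one between-subject factor
# (group), no covariates.
rm_anova_oracle <- function(y, subject, group, feedback) {
  grand <- mean(y)
  subj_means <- tapply(y, subject, mean)
  grp_of <- tapply(group, subject, function(g) g[1])
  n_per_cell <- length(y) / length(unique(feedback)) / length(unique(group))
  k_fb <- length(unique(feedback))
  # between stratum
  ss_group <- k_fb * sum(tapply(y, group, function(v) 0) * 0) +
    k_fb * sum((tapply(subj_means, grp_of, mean) - grand)^2 *
                 tabulate(factor(grp_of)))
  ss_subj_tot <- k_fb * sum((subj_means - grand)^2)
  ss_subj_err <- ss_subj_tot - ss_group
  # within stratum
  fb_means <- tapply(y, feedback, mean)
  ss_fb <- length(unique(subject)) * sum((fb_means - grand)^2)
  cell_means <- tapply(y, interaction(group, feedback), mean)
  grp_means <- tapply(y, group, mean)
  ss_cells <- n_per_cell * sum((cell_means - grand)^2)
  ss_int <- ss_cells - ss_fb - sum((grp_means - grand)^2) *
    (length(y) / length(unique(group)))
  ss_tot <- sum((y - grand)^2)
  ss_win_err <- ss_tot - ss_subj_tot - ss_fb - ss_int
  n_subj <- length(unique(subject)); n_grp <- length(unique(group))
  df_grp <- n_grp - 1; df_serr <- n_subj - n_grp
  df_fb <- k_fb - 1; df_int <- df_grp * df_fb
  df_werr <- (n_subj - n_grp) * df_fb
  list(F_group = (ss_group / df_grp) / (ss_subj_err / df_serr),
       F_feedback = (ss_fb / df_fb) / (ss_win_err / df_werr),
       F_interaction = (ss_int / df_int) / (ss_win_err / df_werr))
}

make_summary <- function(n_per_arm, group_eff = 0, fb_eff = 0, int_eff = 0,
                         subj_sd = 0.08, noise_sd = 0.05) {
  ids <- sprintf("s%03d", seq_len(2 * n_per_arm))
  grp <- rep(c("placebo", "drug"), each = n_per_arm)
  u <- rnorm(2 * n_per_arm, 0, subj_sd)
  rows <- list()
  for (i in seq_along(ids)) for (v in c("reward", "punish")) {
    y <- 0.7 + u[i] + (grp[i] == "drug") * group_eff +
      (v == "punish") * fb_eff +
      (grp[i] == "drug" && v == "punish") * int_eff +
      rnorm(1, 0, noise_sd)
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = ids[i], group = grp[i], valence = v, accuracy = y,
      mean_rt_s = 0.7 + rnorm(1, 0, 0.05), n_responded = 90,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

make_covariates <- function(summary, informative = FALSE) {
  s <- unique(summary[, c("subject_id", "group")])
  data.frame(s, age = round(runif(nrow(s), 20, 40)),
             sex = sample(c("F", "M"), nrow(s), replace = TRUE),
             iq = round(rnorm(nrow(s), 112, 9)), stringsAsFactors = FALSE)
}

test_that("behavioural summaries count good choices over responded trials only", {
  # hand-built: 4 responded reward trials, 3 good choices -> 0.75
  tr <- make_trials(valence = rep("reward", 5),
                    choice = c("good_stimulus", "good_stimulus",
                               "bad_stimulus", "good_stimulus", NA),
                    outcome = c(1, 0, 0, 1, NA))
  tr$rt_s[1:4] <- c(0.5, 0.7, 0.9, 0.7)
  # add punishment trials: the 30%-loss option is the "good" one
  tp <- make_trials(valence = rep("punish", 2),
                    choice = c("good_stimulus", "bad_stimulus"),
                    outcome = c(0, -1))
  tp$trial <- 6:7
  beh <- summarize_behaviour(rbind(tr, tp))
  expect_equal(beh$accuracy[beh$valence == "reward"], 0.75)
  expect_equal(beh$mean_rt_s[beh$valence == "reward"], 0.7)
  expect_equal(beh$accuracy[beh$valence == "punish"], 0.5)

  # an agent that always picks the good option scores exactly 1,
  # a value-blind one lands near 0.5
  d <- task_design(n_blocks = 1, trials_per_valence_per_block = 40)
  s <- generate_schedule(d, seed = 3)
  rand <- simulate_agent("M2", list(alpha_rew = .5, alpha_pun = .5,
                                    rho = 1e-9, tau = 0), s, d, seed = 5)
  br <- summarize_behaviour(rand)
  expect_lt(abs(br$accuracy[br$valence == "reward"] - 0.5), 0.25)
  always <- rand
  good <- always$valence != "neutral"
  always$choice[good] <- "good_stimulus"
  always$outcome[good] <- s$outcome_if_good[good]
  ba <- summarize_behaviour(always)
  expect_equal(ba$accuracy[ba$valence == "reward"], 1.0)
  expect_equal(ba$accuracy[ba$valence == "punish"], 1.0)
})

test_that("repeated-measures ANCOVA matches the explicit SS oracle without covariates", {
  set.seed(21)
  sm <- make_summary(10, group_eff = 0.04, fb_eff = -0.08, int_eff = 0.03)
  cov <- make_covariates(sm)
  # neutral covariates orthogonalised away: compare against the pure
  # two-way repeated-measures oracle using constant covariates
  cov0 <- cov; cov0$age <- 30; cov0$iq <- 110; cov0$sex <- "F"
  # aov drops constant covariates from the model frame implicitly only if
  # coded; centre to exactly zero so they contribute no SS
  res <- mixed_ancova(sm, cov0, "accuracy")
  orc <- rm_anova_oracle(sm$accuracy, sm$subject_id, sm$group, sm$valence)
  expect_equal(res$F[res$term == "group"], orc$F_group, tolerance = 1e-8)
  expect_equal(res$F[res$term == "feedback"], orc$F_feedback,
               tolerance = 1e-8)
  expect_equal(res$F[res$term == "group:feedback"], orc$F_interaction,
               tolerance = 1e-8)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$eta_sq >= 0 & res$eta_sq <= 1))
})

test_that("ANCOVA detects a pure feedback effect and keeps the null group effect null", {
  set.seed(22)
  ps_group <- numeric(40); F_fb <- numeric(40)
  for (k in 1:40) {
    sm <- make_summary(8, fb_eff = -0.10)
    cov <- make_covariates(sm)
    res <- mixed_ancova(sm, cov, "accuracy")
    ps_group[k] <- res$p[res$term == "group"]
    F_fb[k] <- res$F[res$term == "feedback"]
  }
  expect_gt(median(F_fb), 10)          # injected within-subject effect
  ks <- suppressWarnings(ks.test(ps_group, "punif"))
  expect_gt(ks$p.value, 0.01)          # null group p-values ~ uniform
})

test_that("ANCOVA drops subjects with missing cells with a warning", {
  set.seed(23)
  sm <- make_summary(6)
  sm$accuracy[1] <- NA
  cov <- make_covariates(sm)
  expect_warning(res <- mixed_ancova(sm, cov, "accuracy"), "missing cells")
  expect_equal(nrow(res), 3)
})

test_that("welch t reproduces published demographic rows and t.test", {
  iq <- welch_t(111.50, 9.51, 32, 112.22, 9.30, 32)
  expect_equal(round(iq$statistic, 2), -0.31)
  days <- welch_t(26.06, 2.78, 32, 26.06, 3.34, 32)
  expect_equal(days$statistic, 0)
  expect_equal(days$p, 1)
  expect_lt(abs(days$df - 60.03), 0.05)
  # dual route: summary-stat implementation vs stats::t.test on raw data
  set.seed(24)
  x <- rnorm(15, 1, 2); y <- rnorm(20, 0.4, 1.5)
  ours <- welch_t(mean(x), sd(x), 15, mean(y), sd(y), 20)
  ref <- t.test(x, y)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  # equal n and sd: equals Student's t
  ref2 <- t.test(x, y[1:15], var.equal = TRUE)
  xs <- sd(x)
  ours2 <- welch_t(mean(x), xs, 15, mean(y[1:15]) , xs, 15)
  student <- (mean(x) - mean(y[1:15])) / (xs * sqrt(2 / 15))
  expect_equal(ours2$statistic, student, tolerance = 1e-10)
  expect_error(welch_t(1, 0, 10, 2, 1, 10), "positive")
})

test_that("Cohen's d matches published rows and vanishes for equal means", {
  expect_equal(round(cohens_d(25.38, 5.77, 32, 24.25, 5.56, 32), 2), 0.20)
  expect_equal(round(abs(cohens_d(111.50, 9.51, 32, 112.22, 9.30, 32)), 2),
               0.08)
  expect_equal(cohens_d(5, 1, 10, 5, 2, 10), 0)
})

test_that("chi-squared matches the closed-form oracle and is symmetric", {
  blinding <- matrix(c(17, 5, 15, 26), 2)
  ct <- chi_square_2x2(blinding)
  expect_equal(round(ct$statistic, 2), 9.48)
  expect_equal(ct$df, 1)
  expect_equal(ct$phi, sqrt(ct$statistic / 63))
  # equal proportions: exactly zero
  expect_equal(chi_square_2x2(matrix(c(10, 20, 5, 10), 2))$statistic, 0)
  # random tables vs N(ad-bc)^2 / product-of-margins
  set.seed(25)
  for (k in 1:20) {
    m <- matrix(rpois(4, 12) + 1, 2)
    ours <- chi_square_2x2(m)$statistic
    a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; dd <- m[2, 2]
    n <- sum(m)
    oracle <- n * (a * dd - b * cc)^2 /
      ((a + b) * (cc + dd) * (a + cc) * (b + dd))
    expect_equal(ours, oracle, tolerance = 1e-10)
    expect_equal(chi_square_2x2(t(m))$statistic, ours, tolerance = 1e-12)
    expect_equal(chi_square_2x2(m[2:1, ])$statistic, ours, tolerance = 1e-12)
  }
  # Yates correction shrinks the statistic and is off by default
  expect_lt(chi_square_2x2(blinding, correct = TRUE)$statistic,
            ct$statistic)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("Benjamini-Hochberg step-up rejects the documented sets", {
  r <- bh_adjust(rep(0.001, 6))
  expect_true(all(r$rejected))
  r2 <- bh_adjust(c(0.01, 0.02, 0.03, 0.20), q = 0.05)
  expect_equal(r2$rejected, c(TRUE, TRUE, TRUE, FALSE))
  r3 <- bh_adjust(0.04)
  expect_true(r3$rejected)
  expect_equal(r3$adjusted, 0.04)
  # monotonicity: lowering any p never shrinks the rejection set
  set.seed(26)
  for (k in 1:20) {
    p <- runif(8)
    base <- bh_adjust(p)$rejected
    p2 <- p
    i <- sample(8, 1)
    p2[i] <- p2[i] * runif(1)
    after <- bh_adjust(p2)$rejected
    expect_true(all(after[base]))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("demographics_table assembles t/d and chi-squared rows", {
  tab <- demographics_table(list(
    age = c(25.38, 5.77, 32, 24.25, 5.56, 32),
    iq = c(111.50, 9.51, 32, 112.22, 9.30, 32),
    sex = matrix(c(21, 21, 11, 11), 2)))
  expect_equal(nrow(tab), 3)
  expect_equal(round(tab$effect_size[tab$variable == "age"], 2), 0.20)
  expect_equal(tab$effect_type[tab$variable == "sex"], "phi")
  expect_equal(tab$statistic[tab$variable == "sex"], 0)
})
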