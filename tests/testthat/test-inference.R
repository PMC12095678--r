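test_that("log_posterior matches closed-form priors and is additive in subjects", {
  prior <- hbrl_priors()
  P <- 4  # M2
  # prior-only: no subjects
  vec <- c(rnorm(2 * P, 0, .5), rnorm(P, -.5, .3))
  lp <- log_posterior("M2", NULL, prior, vec)
  mu <- vec[1:(2 * P)]; ls <- vec[(2 * P + 1):(3 * P)]
  analytic <- sum(dnorm(mu, 0, 1, log = TRUE)) +
    sum(dnorm(exp(ls), 0, 1, log = TRUE) + log(2) + ls)
  expect_equal(lp, analytic, tolerance = 1e-12)

  # duplicating a subject doubles the likelihood term exactly
  set.seed(8)
  d <- task_design(n_blocks = 1, trials_per_valence_per_block = 8)
  tr1 <- simulate_agent("M2", random_params("M2"), generate_schedule(d), d,
                        subject_id = "a", group = "placebo")
  tr2 <- tr1; tr2$subject_id <- "b"; tr2$group <- "drug"
  tr2dup <- tr1; tr2dup$subject_id <- "c"
  data1 <- prepare_cohort_data(rbind(tr1, tr2), "reward")
  data2 <- prepare_cohort_data(rbind(tr1, tr2, tr2dup), "reward")
  g <- rnorm(3 * P, 0, .3)
  z1 <- rnorm(P, 0, .3); z2 <- rnorm(P, 0, .3)
  lp1 <- log_posterior("M2", data1, prior, c(g, z1, z2))
  lp2 <- log_posterior("M2", data2, prior, c(g, z1, z2, z1))
  prior_only <- log_posterior("M2", NULL, prior, g)
  zp1 <- sum(dnorm(z1, log = TRUE)); zp2 <- sum(dnorm(z2, log = TRUE))
  sigma <- exp(g[(2 * P + 1):(3 * P)])
  mu_mat <- matrix(g[1:(2 * P)], nrow = P)
  th1 <- param_transform(mu_mat[, 1] + sigma * z1, "M2")
  th2 <- param_transform(mu_mat[, 2] + sigma * z2, "M2")
  lik_a <- naive_loglik("M2", tr1[tr1$valence == "reward", ], th1)
  lik_b <- naive_loglik("M2", tr2[tr2$valence == "reward", ], th2)
  # the duplicated subject shares arm and effects with subject a, so it
  # adds exactly subject a's likelihood plus one more z-prior term
  expect_equal(lp2 - lp1, lik_a + zp1, tolerance = 1e-8)
  # brute-force recomputation on the 2-subject toy
  expect_equal(lp1, prior_only + zp1 + zp2 + lik_a + lik_b,
               tolerance = 1e-8)

  expect_error(log_posterior("M2", data1, prior, g), "length")
})

test_that("hdi matches the exhaustive window oracle and handles edge cases", {
  # integer ramp: first minimal window of 95 draws
  expect_equal(hdi(0:99, 0.95), c(0, 94))
  # point mass: zero-width interval
  expect_equal(hdi(rep(3.3, 200), 0.9), c(3.3, 3.3))
  expect_error(hdi(rnorm(10), 1.5), "mass")
  expect_error(hdi(rnorm(10), 0), "mass")
  # symmetric unimodal: close to the equal-tailed interval
  set.seed(9)
  x <- rnorm(20000)
  h <- hdi(x, 0.95)
  q <- quantile(x, c(0.025, 0.975))
  expect_lt(max(abs(h - unname(q))), 0.1)
  # oracle agreement on random samples
  set.seed(10)
  for (k in 1:30) {
    n <- sample(100:1000, 1)
    x <- switch(1 + k %% 3, rnorm(n), rexp(n), rt(n, 3))
    m <- sample(c(0.5, 0.9, 0.95), 1)
    expect_identical(hdi(x, m), hdi_oracle(x, m))
  }
})

test_that("with a flat likelihood the sampler reproduces the prior", {
  # all trials unresponded: the likelihood contributes nothing, so the
  # group-level posterior must equal the prior (N(0,1) means,
  # half-normal(1) sds)
  d <- task_design(n_blocks = 1, trials_per_valence_per_block = 6)
  set.seed(2)
  trs <- lapply(1:8, function(i)
    simulate_agent("M1", list(alpha_rew = .3, alpha_pun = .3, rho = 2),
                   generate_schedule(d), d,
                   subject_id = sprintf("s%02d", i),
                   group = if (i <= 4) "placebo" else "drug",
                   p_lapse = 0.999999))
  trials <- do.call(rbind, trs)
  trials$responded <- FALSE; trials$choice <- NA; trials$outcome <- NA
  trials$rt_s <- NA
  fit <- suppressWarnings(hbrl_fit(trials, "M1", "reward", chains = 2,
                                   warmup = 400, iter = 800, seed = 3))
  mu_draws <- as.vector(fit$draws[, , "mu_placebo.alpha_rew"])
  ess <- fit$convergence$ess[fit$convergence$parameter ==
                               "mu_placebo.alpha_rew"]
  se_mean <- 1 / sqrt(ess)
  expect_lt(abs(mean(mu_draws) - 0), 3.5 * se_mean)
  expect_lt(abs(sd(mu_draws) - 1), 0.15)
  sg <- exp(as.vector(fit$draws[, , "log_sigma.rho"]))
  expect_lt(abs(mean(sg) - sqrt(2 / pi)), 0.1)  # half-normal mean
})

test_that("small cohort fits are deterministic and summarised sensibly", {
  d <- task_design(n_blocks = 1, trials_per_valence_per_block = 12)
  co <- simulate_cohort(4, "M2", design = d, seed = 14)
  f1 <- suppressWarnings(hbrl_fit(co$trials, "M2", "reward", chains = 2,
                                  warmup = 150, iter = 150, seed = 6))
  f2 <- suppressWarnings(hbrl_fit(co$trials, "M2", "reward", chains = 2,
                                  warmup = 150, iter = 150, seed = 6))
  expect_identical(f1$draws, f2$draws)
  md <- group_difference(f1)
  expect_equal(md$parameter, model_info("M2")$params)
  expect_true(all(md$hdi90_lower >= md$hdi95_lower - 1e-12))
  expect_true(all(md$hdi90_upper <= md$hdi95_upper + 1e-12))
  expect_output(print(f1), "Hierarchical RL fit")
  expect_output(print(summary(f1)), "Group differences")
  expect_match(format_md(md, 90)[1], "MD = .* \\[90% HDI .* to .*\\]")
  cf <- coef(f1)
  expect_equal(dim(cf), c(4L, 2L))
  expect_true(all(cf[c("alpha_rew", "alpha_pun"), ] > 0 &
                    cf[c("alpha_rew", "alpha_pun"), ] < 1))
})

test_that("group differences are zero for identical arms and linear in shifts", {
  d <- task_design(n_blocks = 1, trials_per_valence_per_block = 12)
  co <- simulate_cohort(4, "M2", design = d, seed = 15)
  fit <- suppressWarnings(hbrl_fit(co$trials, "M2", "reward", chains = 2,
                                   warmup = 150, iter = 150, seed = 7))
  # overwrite the drug-arm mean draws with the placebo ones: MD == 0
  same <- fit
  P <- 4
  same$draws[, , (P + 1):(2 * P)] <- same$draws[, , 1:P]
  md0 <- group_difference(same)
  expect_equal(md0$md_mean, rep(0, 4))
  expect_equal(md0$hdi95_lower, rep(0, 4))
  expect_equal(md0$hdi95_upper, rep(0, 4))
  expect_false(any(md0$excludes_zero_90))
  # tau is identity-linked: shifting its drug-arm draws by +c shifts its
  # natural-scale MD by exactly +c
  shifted <- fit
  tau_idx <- which(dimnames(fit$draws)[[3]] == "mu_drug.tau")
  shifted$draws[, , tau_idx] <- shifted$draws[, , tau_idx] + 0.25
  md1 <- group_difference(fit); md2 <- group_difference(shifted)
  expect_equal(md2$md_mean[md2$parameter == "tau"],
               md1$md_mean[md1$parameter == "tau"] + 0.25, tolerance = 1e-12)
})

test_that("posterior mean differences are stable when iterations double", {
  d <- task_design(n_blocks = 1, trials_per_valence_per_block = 10)
  co <- simulate_cohort(4, "M1", design = d, seed = 16)
  fa <- suppressWarnings(hbrl_fit(co$trials, "M1", "reward", chains = 2,
                                  warmup = 300, iter = 300, seed = 8))
  fb <- suppressWarnings(hbrl_fit(co$trials, "M1", "reward", chains = 2,
                                  warmup = 300, iter = 600, seed = 9))
  mda <- group_difference(fa); mdb <- group_difference(fb)
  for (p in c("alpha_rew", "alpha_pun")) {
    sa <- sd(fa$draws[, , paste0("mu_drug.", p)])
    ess <- max(50, min(fa$convergence$ess, na.rm = TRUE))
    mc_se <- 0.5 * sa / sqrt(ess)  # rough scale for the derived MD
    expect_lt(abs(mda$md_mean[mda$parameter == p] -
                    mdb$md_mean[mdb$parameter == p]), 6 * mc_se + 0.05)
  }
})
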