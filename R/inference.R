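# Hierarchical Bayesian estimation --------------------------------------
#
# Group model, per candidate model and valence condition:
#   group means      mu[p, arm] ~ Normal(0, mean_scale)   (unconstrained)
#   group sds        sigma[p]   ~ Half-Normal(sd_scale)   (shared by arms)
#   subject effects  z[i, p]    ~ Normal(0, 1)            (non-centred)
#   subject params   theta[i, p] = link^{-1}(mu[p, arm(i)] + sigma[p] z[i, p])
#   choices          ~ model likelihood (see subject_loglik)
#
# Sampling-scale parameter vector layout (used by log_posterior, the
# sampler and the bridge sampler): P = free-parameter count, N = subjects:
#   [ mu placebo (P) | mu drug (P) | log sigma (P) | z subject-major (N*P) ]

#' Hierarchical prior settings
#'
#' Standard-normal priors on the unconstrained group means and
#' half-normal priors on the shared group sds. The scales are exposed for
#' sensitivity analyses (e.g. 0.5 or 2).
#'
#' @param mean_scale Scale of the normal prior on each arm's group mean.
#' @param sd_scale Scale of the half-normal prior on each group sd.
#' @return An object of class `hbrl_prior`.
#' @export
hbrl_priors <- function(mean_scale = 1, sd_scale = 1) {
  if (mean_scale <= 0 || sd_scale <= 0)
    stop("prior scales must be positive", call. = FALSE)
  structure(list(mean_scale = mean_scale, sd_scale = sd_scale),
            class = "hbrl_prior")
}

transform_row <- function(x, info) {
  out <- x
  for (i in seq_along(info$transform)) {
    out[i] <- switch(info$transform[i],
      logit = plogis(x[i]), log = exp(x[i]), identity = x[i])
  }
  out
}

#' Encode a cohort's trials for likelihood evaluation
#'
#' Filters trials to one valence condition, groups them by subject, and
#' packs choices/outcomes into the flat arrays the compiled likelihood
#' consumes. Subjects are ordered by first appearance.
#'
#' @param trials Trial records (see [read_trials()]).
#' @param valence `"reward"` or `"punish"`; neutral trials are never fitted.
#' @return A list with the packed arrays, subject ids, and integer arm
#'   index (1 = placebo, 2 = drug) per subject.
#' @export
prepare_cohort_data <- function(trials, valence = c("reward", "punish")) {
  valence <- match.arg(valence)
  validate_trials(trials)
  tr <- trials[trials$valence == valence, , drop = FALSE]
  if (!nrow(tr)) stop("no trials of valence ", valence, call. = FALSE)
  ids <- unique(tr$subject_id)
  enc <- lapply(ids, function(id)
    encode_subject_trials(tr[tr$subject_id == id, , drop = FALSE]))
  len <- vapply(enc, function(e) length(e$pair), integer(1))
  start <- cumsum(c(1L, len[-length(len)]))
  arm <- vapply(ids, function(id)
    if (tr$group[match(id, tr$subject_id)] == "drug") 2L else 1L, integer(1))
  list(
    subject_id = ids, arm = unname(arm), n_subjects = length(ids),
    start = as.integer(start), len = as.integer(len),
    n_pairs = vapply(enc, function(e) e$n_pairs, integer(1)),
    pair = unlist(lapply(enc, `[[`, "pair")),
    choice = unlist(lapply(enc, `[[`, "choice")),
    outcome = unlist(lapply(enc, `[[`, "outcome")),
    responded = unlist(lapply(enc, `[[`, "responded")),
    is_reward = unlist(lapply(enc, `[[`, "is_reward")),
    valence = valence)
}

cohort_loglik <- function(model_id, data, theta_nat, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(data$n_subjects)
  cpp_cohort_loglik(.model_code(model_id), data$start, data$len, data$n_pairs,
                    data$pair, data$choice, data$outcome, data$responded,
                    data$is_reward, theta_nat, as.integer(subset))
}

unpack_vec <- function(vec, P, N) {
  list(mu = matrix(vec[1:(2 * P)], nrow = P),       # cols: placebo, drug
       ls = vec[(2 * P + 1):(3 * P)],
       z = matrix(vec[-(1:(3 * P))], nrow = N, byrow = TRUE))
}

theta_from_state <- function(mu, sigma, z, arm, info) {
  unc <- t(mu[, arm, drop = FALSE]) + z %*% diag(sigma, length(sigma))
  nat <- unc
  for (p in seq_along(info$transform)) {
    nat[, p] <- switch(info$transform[p],
      logit = plogis(unc[, p]), log = exp(unc[, p]), identity = unc[, p])
  }
  nat
}

#' Hierarchical log posterior density on the sampling scale
#'
#' Sum of every subject's choice log-likelihood plus the hierarchical log
#' prior (normal group means, half-normal group sds with the log-scale
#' Jacobian, standard-normal subject effects). The vector layout is
#' `[mu placebo (P), mu drug (P), log sigma (P), z subject-major (N*P)]`.
#'
#' @param model_id Model identifier.
#' @param data Encoded cohort from [prepare_cohort_data()]; may have zero
#'   subjects, in which case only the prior is evaluated.
#' @param prior An [hbrl_priors()] object.
#' @param vec Numeric parameter vector on the sampling scale.
#' @return Log density in nats (finite for interior points).
#' @export
log_posterior <- function(model_id, data, prior, vec) {
  model_id <- match.arg(model_id, model_ids())
  info <- model_info(model_id)
  P <- length(info$params)
  N <- if (is.null(data)) 0L else data$n_subjects
  if (length(vec) != 3 * P + N * P)
    stop(sprintf("expected parameter vector of length %d, got %d",
                 3 * P + N * P, length(vec)), call. = FALSE)
  st <- unpack_vec(vec, P, max(N, 1L))
  if (N == 0) st$z <- matrix(0, 0, P)
  sigma <- exp(st$ls)
  lp <- sum(dnorm(st$mu, 0, prior$mean_scale, log = TRUE)) +
    sum(dnorm(sigma, 0, prior$sd_scale, log = TRUE) + log(2) + st$ls)
  if (N > 0) {
    lp <- lp + sum(dnorm(st$z, 0, 1, log = TRUE))
    theta <- theta_from_state(st$mu, sigma, st$z, data$arm, info)
    lp <- lp + sum(cohort_loglik(model_id, data, theta))
  }
  lp
}

# Adaptive random-walk Metropolis-within-Gibbs. Subject effects are
# updated jointly per subject; group means and log-sds are updated as
# scalars. Step sizes adapt by Robbins-Monro during warmup only, so the
# kept draws come from a fixed transition kernel. Each sweep ends with
# an interweaved centred-parameterisation move (Yu & Meng style): with
# every subject's unconstrained parameter held fixed, the arm means are
# conjugate-normal draws and the group sd takes a cheap
# Metropolis step on its exact conditional, after which the subject
# effects are back-solved. The likelihood is untouched by that move, so
# it costs no likelihood evaluations while decorrelating the
# group-level parameters from the subject effects.
run_chain <- function(model_id, data, prior, warmup, iter, seed, info) {
  set.seed(seed)
  P <- length(info$params)
  N <- data$n_subjects
  mu <- matrix(rnorm(2 * P, 0, 0.2), nrow = P)
  ls <- rnorm(P, log(0.5), 0.1)
  z <- matrix(rnorm(N * P, 0, 0.2), nrow = N)
  sigma <- exp(ls)
  theta <- theta_from_state(mu, sigma, z, data$arm, info)
  lik <- cohort_loglik(model_id, data, theta)

  step_z <- rep(0.4, N); step_mu <- matrix(0.15, P, 2)
  step_ls <- rep(0.15, P); step_cs <- rep(0.3, P)
  # per-subject proposal shapes (Haario-style), learned during warmup
  z_mean <- z; z_cov <- array(0, c(N, P, P)); z_n <- 0
  z_chol <- array(0, c(N, P, P))
  for (i in seq_len(N)) z_chol[i, , ] <- diag(P)
  step_g <- 0.1; g_mean <- c(mu, ls); g_cov <- matrix(0, 3 * P, 3 * P)
  g_chol <- diag(3 * P); g_n <- 0
  D <- 3 * P + N * P
  draws <- matrix(NA_real_, iter, D)
  lp_draws <- numeric(iter)

  arm_idx <- list(which(data$arm == 1L), which(data$arm == 2L))
  total <- warmup + iter
  for (it in seq_len(total)) {
    adapting <- it <= warmup
    gam <- if (adapting) min(1, 5 / it^0.6) else 0

    # subject effects, one joint proposal per subject with an adapted
    # proposal shape
    eps <- matrix(rnorm(N * P), N, P)
    for (i in seq_len(N)) {
      zi <- z[i, ] + step_z[i] * drop(eps[i, ] %*% z_chol[i, , ])
      th_i <- transform_row(mu[, data$arm[i]] + sigma * zi, info)
      li <- cohort_loglik(model_id, data,
                          {tm <- theta; tm[i, ] <- th_i; tm}, subset = i)
      lr <- (li - lik[i]) + 0.5 * sum(z[i, ]^2 - zi^2)
      acc <- is.finite(lr) && log(runif(1)) < lr
      if (acc) { z[i, ] <- zi; theta[i, ] <- th_i; lik[i] <- li }
      if (adapting)
        step_z[i] <- exp(log(step_z[i]) + gam * ((if (acc) 1 else 0) - 0.3))
    }
    if (adapting) {
      z_n <- z_n + 1
      for (i in seq_len(N)) {
        d1 <- z[i, ] - z_mean[i, ]
        z_mean[i, ] <- z_mean[i, ] + d1 / z_n
        z_cov[i, , ] <- z_cov[i, , ] + tcrossprod(d1, z[i, ] - z_mean[i, ])
      }
      if (z_n >= 50 && z_n %% 25 == 0) {
        for (i in seq_len(N)) {
          S <- z_cov[i, , ] / (z_n - 1) + diag(1e-6, P)
          S <- S / mean(diag(S))  # shape only; step_z carries the scale
          z_chol[i, , ] <- tryCatch(chol(S), error = function(e) diag(P))
        }
      }
    }

    # arm-level means, scalar updates
    for (a in 1:2) {
      idx <- arm_idx[[a]]
      for (p in seq_len(P)) {
        mu_new <- mu[p, a] + step_mu[p, a] * rnorm(1)
        th_new <- theta
        unc_p <- mu_new + sigma[p] * z[idx, p]
        th_new[idx, p] <- switch(info$transform[p],
          logit = plogis(unc_p), log = exp(unc_p), identity = unc_p)
        li <- cohort_loglik(model_id, data, th_new, subset = idx)
        lr <- sum(li) - sum(lik[idx]) +
          (mu_new^2 - mu[p, a]^2) / (-2 * prior$mean_scale^2)
        acc <- is.finite(lr) && log(runif(1)) < lr
        if (acc) { mu[p, a] <- mu_new; theta[idx, p] <- th_new[idx, p]
                   lik[idx] <- li }
        if (adapting)
          step_mu[p, a] <- exp(log(step_mu[p, a]) +
                               gam * ((if (acc) 1 else 0) - 0.44))
      }
    }

    # shared log-sds, scalar updates
    for (p in seq_len(P)) {
      ls_new <- ls[p] + step_ls[p] * rnorm(1)
      s_new <- exp(ls_new)
      th_new <- theta
      unc_p <- mu[p, data$arm] + s_new * z[, p]
      th_new[, p] <- switch(info$transform[p],
        logit = plogis(unc_p), log = exp(unc_p), identity = unc_p)
      li <- cohort_loglik(model_id, data, th_new)
      lr <- sum(li) - sum(lik) +
        (s_new^2 - exp(ls[p])^2) / (-2 * prior$sd_scale^2) + (ls_new - ls[p])
      acc <- is.finite(lr) && log(runif(1)) < lr
      if (acc) { ls[p] <- ls_new; sigma[p] <- s_new; theta[, p] <- th_new[, p]
                 lik <- li }
      if (adapting)
        step_ls[p] <- exp(log(step_ls[p]) + gam * ((if (acc) 1 else 0) - 0.44))
    }

    # joint group-level proposal with adapted shape, to traverse
    # correlated directions (e.g. learning rate vs sensitivity)
    g <- c(mu, ls)
    g_new <- g + step_g * drop(rnorm(3 * P) %*% g_chol)
    mu_new <- matrix(g_new[1:(2 * P)], P); ls_new <- g_new[-(1:(2 * P))]
    s_new <- exp(ls_new)
    th_new <- theta_from_state(mu_new, s_new, z, data$arm, info)
    li <- cohort_loglik(model_id, data, th_new)
    lr <- sum(li) - sum(lik) +
      sum(g_new[1:(2 * P)]^2 - g[1:(2 * P)]^2) / (-2 * prior$mean_scale^2) +
      sum(s_new^2 - sigma^2) / (-2 * prior$sd_scale^2) + sum(ls_new - ls)
    acc <- is.finite(lr) && log(runif(1)) < lr
    if (acc) { mu <- mu_new; ls <- ls_new; sigma <- s_new
               theta <- th_new; lik <- li }
    if (adapting) {
      step_g <- exp(log(step_g) + gam * ((if (acc) 1 else 0) - 0.25))
      g_n <- g_n + 1
      d1 <- c(mu, ls) - g_mean
      g_mean <- g_mean + d1 / g_n
      g_cov <- g_cov + tcrossprod(d1, c(mu, ls) - g_mean)
      if (g_n >= 50 && g_n %% 25 == 0) {
        S <- g_cov / (g_n - 1) + diag(1e-6, 3 * P)
        S <- S / mean(diag(S))
        g_chol <- tryCatch(chol(S), error = function(e) diag(3 * P))
      }
    }

    # interweaved centred-parameterisation move: theta (hence the
    # likelihood) is held fixed while (mu, sigma) are refreshed against
    # the subject-level unconstrained values, then z is back-solved
    for (p in seq_len(P)) {
      unc_p <- mu[p, data$arm] + sigma[p] * z[, p]
      for (a in 1:2) {
        idx <- arm_idx[[a]]
        prec <- 1 / prior$mean_scale^2 + length(idx) / sigma[p]^2
        m_post <- sum(unc_p[idx]) / sigma[p]^2 / prec
        mu[p, a] <- rnorm(1, m_post, sqrt(1 / prec))
      }
      dev <- unc_p - mu[p, data$arm]
      cond <- function(l) {
        s <- exp(l)
        -s^2 / (2 * prior$sd_scale^2) + l -
          N * l - sum(dev^2) / (2 * s^2)
      }
      ls_new <- ls[p] + step_cs[p] * rnorm(1)
      lr <- cond(ls_new) - cond(ls[p])
      acc <- is.finite(lr) && log(runif(1)) < lr
      if (acc) { ls[p] <- ls_new; sigma[p] <- exp(ls_new) }
      if (adapting)
        step_cs[p] <- exp(log(step_cs[p]) + gam * ((if (acc) 1 else 0) - 0.44))
      z[, p] <- dev / sigma[p]
    }

    if (!adapting) {
      k <- it - warmup
      draws[k, ] <- c(mu[, 1], mu[, 2], ls, as.vector(t(z)))
      lp_draws[k] <- sum(lik) +
        sum(dnorm(mu, 0, prior$mean_scale, log = TRUE)) +
        sum(dnorm(sigma, 0, prior$sd_scale, log = TRUE) + log(2) + ls) +
        sum(dnorm(z, 0, 1, log = TRUE))
    }
  }
  list(draws = draws, lp = lp_draws,
       steps = list(z = step_z, mu = step_mu, ls = step_ls))
}

param_vector_names <- function(info, subject_ids) {
  P <- length(info$params)
  c(paste0("mu_placebo.", info$params),
    paste0("mu_drug.", info$params),
    paste0("log_sigma.", info$params),
    as.vector(t(outer(subject_ids, info$params, paste, sep = "."))))
}

#' Fit a hierarchical reinforcement-learning model to cohort data
#'
#' Samples the hierarchical posterior for one candidate model and one
#' valence condition with an adaptive Metropolis-within-Gibbs sampler on
#' the non-centred parameterisation (subject effects proposed jointly per
#' subject, group-level parameters as scalars; step sizes tuned during
#' warmup only). Convergence is summarised by split R-hat and effective
#' sample size per group-level parameter; any R-hat above 1.05 triggers a
#' warning and is flagged in the returned report.
#'
#' @param trials Trial records for the whole cohort.
#' @param model_id One of `"M1"`-`"M4"`.
#' @param valence Which condition to fit (`"reward"` or `"punish"`);
#'   conditions are fitted separately.
#' @param prior An [hbrl_priors()] object.
#' @param chains Number of chains (>= 2).
#' @param warmup,iter Warmup (discarded, with adaptation) and kept
#'   iterations per chain.
#' @param seed Integer seed; chain c uses `seed + c`.
#' @return An object of class `hbrl_fit` with the draws array
#'   (iterations x chains x parameters), the encoded data, the prior, and
#'   a convergence report.
#' @seealso [group_difference()], [logml()], [compare_models()]
#' @export
hbrl_fit <- function(trials, model_id = "M2", valence = "reward",
                     prior = hbrl_priors(), chains = 2,
                     warmup = 1000, iter = 1000, seed = 1) {
  model_id <- match.arg(model_id, model_ids())
  if (chains < 2) stop("need at least 2 chains", call. = FALSE)
  data <- prepare_cohort_data(trials, valence)
  if (min(tabulate(data$arm, 2)) < 2)
    stop("need at least 2 subjects per arm", call. = FALSE)
  info <- model_info(model_id)
  t0 <- proc.time()[["elapsed"]]
  res <- lapply(seq_len(chains), function(ch)
    run_chain(model_id, data, prior, warmup, iter,
              seed = as.integer(seed) + ch, info = info))
  elapsed <- proc.time()[["elapsed"]] - t0
  D <- ncol(res[[1]]$draws)
  draws <- array(NA_real_, c(iter, chains, D))
  for (ch in seq_len(chains)) draws[, ch, ] <- res[[ch]]$draws
  dimnames(draws) <- list(NULL, paste0("chain", seq_len(chains)),
                          param_vector_names(info, data$subject_id))
  lp <- vapply(res, `[[`, numeric(iter), "lp")
  fit <- structure(list(
    model_id = model_id, valence = valence, prior = prior,
    draws = draws, lp = lp, data = data, seed = as.integer(seed),
    warmup = warmup, iter = iter, chains = chains, elapsed_s = elapsed),
    class = "hbrl_fit")
  fit$convergence <- convergence_report(fit)
  if (any(fit$convergence$rhat > 1.05, na.rm = TRUE))
    warning(sprintf("R-hat > 1.05 for: %s",
                    paste(fit$convergence$parameter[
                      fit$convergence$rhat > 1.05], collapse = ", ")),
            call. = FALSE)
  fit
}

split_rhat <- function(mat) {
  # mat: iterations x chains; split each chain in half
  n <- nrow(mat) %/% 2
  halves <- cbind(mat[1:n, , drop = FALSE],
                  mat[(nrow(mat) - n + 1):nrow(mat), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(mat) {
  # crude multi-chain ESS: per-chain Geyer initial-positive truncation
  total <- 0
  for (ch in seq_len(ncol(mat))) {
    x <- mat[, ch]
    n <- length(x)
    if (var(x) == 0) { total <- total + n; next }
    rho <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    s <- 0; k <- 1
    while (k <= length(rho) - 1) {
      pair <- rho[k] + rho[k + 1]
      if (pair < 0) break
      s <- s + pair
      k <- k + 2
    }
    total <- total + n / (1 + 2 * s)
  }
  total
}

#' Convergence diagnostics for a fitted model
#'
#' Split R-hat and effective sample size for every group-level parameter
#' (arm means and group sds) plus the subject effects' worst R-hat.
#'
#' @param fit An `hbrl_fit`.
#' @return Data frame with columns `parameter`, `rhat`, `ess`.
#' @export
convergence_report <- function(fit) {
  P <- length(model_info(fit$model_id)$params)
  nm <- dimnames(fit$draws)[[3]]
  group_idx <- seq_len(3 * P)
  rows <- lapply(group_idx, function(j) {
    m <- fit$draws[, , j]
    data.frame(parameter = nm[j], rhat = split_rhat(m), ess = ess_basic(m),
               stringsAsFactors = FALSE)
  })
  subj <- setdiff(seq_len(dim(fit$draws)[3]), group_idx)
  if (length(subj)) {
    r <- vapply(subj, function(j) split_rhat(fit$draws[, , j]), numeric(1))
    rows <- c(rows, list(data.frame(parameter = "subject_effects_max",
                                    rhat = max(r, na.rm = TRUE),
                                    ess = NA_real_, stringsAsFactors = FALSE)))
  }
  do.call(rbind, rows)
}

#' Highest density interval of a posterior sample
#'
#' The narrowest contiguous interval containing `ceiling(mass * n)` of
#' the sorted draws; ties go to the first (left-most) minimal window.
#'
#' @param draws Numeric sample.
#' @param mass Probability mass in (0, 1), typically 0.90 or 0.95.
#' @return Numeric `c(lower, upper)`.
#' @examples
#' hdi(rnorm(1000), 0.95)
#' @export
hdi <- function(draws, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1)
    stop("mass must be a single value in (0, 1)", call. = FALSE)
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 1) stop("no finite draws", call. = FALSE)
  s <- sort(draws)
  m <- min(n, ceiling(mass * n))
  if (m == n) return(c(s[1], s[n]))
  w <- s[m:n] - s[1:(n - m + 1)]
  i <- which.min(w)
  c(s[i], s[i + m - 1])
}

group_mean_draws <- function(fit, scale = c("natural", "unconstrained")) {
  scale <- match.arg(scale)
  info <- model_info(fit$model_id)
  P <- length(info$params)
  flat <- function(j) as.vector(fit$draws[, , j])
  out <- list()
  for (p in seq_len(P)) {
    pla <- flat(p); dru <- flat(P + p)
    if (scale == "natural") {
      f <- switch(info$transform[p], logit = plogis, log = exp,
                  identity = identity)
      pla <- f(pla); dru <- f(dru)
    }
    out[[info$params[p]]] <- cbind(placebo = pla, drug = dru)
  }
  out
}

#' Group mean-difference summary with highest density intervals
#'
#' For every model parameter, transforms each arm's group-level mean to
#' the natural scale per posterior draw, takes the difference
#' (drug minus placebo), and summarises the difference posterior with its
#' mean and 90%/95% HDIs, flagging intervals that exclude zero (the
#' "credible difference" decision rule).
#'
#' @param fit An `hbrl_fit`.
#' @param scale `"natural"` (default, matching how group effects are
#'   reported) or `"unconstrained"`.
#' @return A data frame of class `hbrl_md` with one row per parameter:
#'   `parameter`, `md_mean`, `hdi90_lower`, `hdi90_upper`, `hdi95_lower`,
#'   `hdi95_upper`, `excludes_zero_90`, `excludes_zero_95`.
#' @export
group_difference <- function(fit, scale = c("natural", "unconstrained")) {
  gm <- group_mean_draws(fit, scale)
  rows <- lapply(names(gm), function(p) {
    md <- gm[[p]][, "drug"] - gm[[p]][, "placebo"]
    h90 <- hdi(md, 0.90); h95 <- hdi(md, 0.95)
    data.frame(parameter = p, md_mean = mean(md),
               hdi90_lower = h90[1], hdi90_upper = h90[2],
               hdi95_lower = h95[1], hdi95_upper = h95[2],
               excludes_zero_90 = h90[1] > 0 | h90[2] < 0,
               excludes_zero_95 = h95[1] > 0 | h95[2] < 0,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("hbrl_md", "data.frame"))
}

#' Format a mean-difference row in reporting style
#'
#' Produces lines such as `"MD = -0.15 [90% HDI -0.31 to -0.01]"`.
#'
#' @param md An `hbrl_md` row or data frame.
#' @param level 90 or 95.
#' @return Character vector, one line per parameter.
#' @export
format_md <- function(md, level = 95) {
  level <- match.arg(as.character(level), c("90", "95"))
  lo <- md[[paste0("hdi", level, "_lower")]]
  hi <- md[[paste0("hdi", level, "_upper")]]
  sprintf("%s: MD = %.2f [%s%% HDI %.2f to %.2f]", md$parameter,
          md$md_mean, level, lo, hi)
}

# S3 methods -------------------------------------------------------------

#' @export
print.hbrl_fit <- function(x, ...) {
  cat(sprintf("Hierarchical RL fit: model %s, %s trials\n",
              x$model_id, x$valence))
  cat(sprintf("  %d subjects (%d placebo, %d drug), %d chains x %d draws (+%d warmup)\n",
              x$data$n_subjects, sum(x$data$arm == 1), sum(x$data$arm == 2),
              x$chains, x$iter, x$warmup))
  cr <- x$convergence
  cat(sprintf("  max R-hat %.3f, min group-level ESS %.0f, %.1f s\n",
              max(cr$rhat, na.rm = TRUE), min(cr$ess, na.rm = TRUE),
              x$elapsed_s))
  invisible(x)
}

#' @export
summary.hbrl_fit <- function(object, ...) {
  md <- group_difference(object)
  out <- list(fit = object, md = md, convergence = object$convergence)
  class(out) <- "summary.hbrl_fit"
  out
}

#' @export
print.summary.hbrl_fit <- function(x, ...) {
  print(x$fit)
  cat("\nGroup differences (drug - placebo, natural scale):\n")
  for (line in format_md(x$md, 95)) cat(" ", line, "\n")
  flagged <- x$md$parameter[x$md$excludes_zero_90]
  if (length(flagged))
    cat("  90% HDI excludes zero for:", paste(flagged, collapse = ", "), "\n")
  else cat("  no parameter's 90% HDI excludes zero\n")
  invisible(x)
}

#' Posterior means of the group-level parameters
#'
#' @param object An `hbrl_fit`.
#' @param scale `"natural"` or `"unconstrained"`.
#' @param ... Unused.
#' @return Matrix parameter x arm of posterior-mean group means.
#' @export
coef.hbrl_fit <- function(object, scale = "natural", ...) {
  gm <- group_mean_draws(object, scale)
  t(vapply(gm, colMeans, numeric(2)))
}

#' Trace and difference-posterior plot for a fit
#'
#' @param x An `hbrl_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.hbrl_fit <- function(x, ...) {
  P <- length(model_info(x$model_id)$params)
  nm <- dimnames(x$draws)[[3]][seq_len(2 * P)]
  old <- graphics::par(mfrow = c(2, P), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (j in seq_len(2 * P))
    graphics::matplot(x$draws[, , j], type = "l", lty = 1, main = nm[j],
                      xlab = "", ylab = "", ...)
  invisible(x)
}

#' Posterior-mean subject parameters
#'
#' Per-subject natural-scale parameter estimates (posterior mean of each
#' subject's transformed parameters), e.g. for recovery scatterplots.
#'
#' @param fit An `hbrl_fit`.
#' @return Matrix subjects x parameters.
#' @export
subject_estimates <- function(fit) {
  info <- model_info(fit$model_id)
  P <- length(info$params)
  N <- fit$data$n_subjects
  nm <- dimnames(fit$draws)[[3]]
  mu_idx <- function(p, a) (a - 1) * P + p
  out <- matrix(0, N, P, dimnames = list(fit$data$subject_id, info$params))
  for (i in seq_len(N)) for (p in seq_len(P)) {
    unc <- as.vector(fit$draws[, , mu_idx(p, fit$data$arm[i])]) +
      exp(as.vector(fit$draws[, , 2 * P + p])) *
      as.vector(fit$draws[, , 3 * P + (i - 1) * P + p])
    nat <- switch(info$transform[p], logit = plogis(unc), log = exp(unc),
                  identity = unc)
    out[i, p] <- mean(nat)
  }
  out
}

#' Parameter-recovery experiment
#'
#' Simulates cohorts with known arm-level parameters (optionally with a
#' natural-scale shift injected on one or more drug-arm parameters), fits
#' the model, and records per replicate the mean-difference posterior,
#' whether the 90%/95% HDIs exclude zero, and whether the 95% HDI covers
#' the true difference.
#'
#' @param model_id Generating and fitted model.
#' @param natural_shift Named vector of natural-scale drug-arm shifts
#'   (NULL for a null experiment).
#' @param valence Condition to fit.
#' @param n_per_arm Subjects per arm.
#' @param design Task design.
#' @param replicates Number of simulated replicates.
#' @param seed Base seed; replicate r uses `seed + 1000 * r`.
#' @param chains,warmup,iter MCMC settings passed to [hbrl_fit()].
#' @param parameter Which parameter's recovery to tabulate (defaults to
#'   the shifted one, or the first).
#' @return List with the per-replicate table and aggregate `bias`,
#'   `coverage95`, `sign_rate` (fraction of replicates whose MD posterior
#'   mean has the true sign) and `hdi90_excludes_zero_rate`.
#' @export
parameter_recovery <- function(model_id = "M2", natural_shift = NULL,
                               valence = "punish", n_per_arm = 32,
                               design = task_design(), replicates = 5,
                               seed = 1, chains = 2, warmup = 800,
                               iter = 800, parameter = NULL) {
  arm <- default_arm_params(model_id, natural_shift)
  info <- model_info(model_id)
  true_md <- transform_row(arm$means[, "drug"], info) -
    transform_row(arm$means[, "placebo"], info)
  names(true_md) <- info$params
  if (is.null(parameter))
    parameter <- if (!is.null(natural_shift)) names(natural_shift)[1] else
      info$params[1]
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    rep_seed <- as.integer(seed) + 1000L * r
    cohort <- simulate_cohort(n_per_arm, model_id, arm$means, arm$sds,
                              design, seed = rep_seed)
    fit <- hbrl_fit(cohort$trials, model_id, valence, chains = chains,
                    warmup = warmup, iter = iter, seed = rep_seed)
    md <- group_difference(fit)
    m <- md[md$parameter == parameter, ]
    rows[[r]] <- data.frame(
      replicate = r, md_mean = m$md_mean,
      hdi90_lower = m$hdi90_lower, hdi90_upper = m$hdi90_upper,
      hdi95_lower = m$hdi95_lower, hdi95_upper = m$hdi95_upper,
      excludes_zero_90 = m$excludes_zero_90,
      excludes_zero_95 = m$excludes_zero_95,
      covers_truth_95 = m$hdi95_lower <= true_md[parameter] &
        true_md[parameter] <= m$hdi95_upper)
  }
  tab <- do.call(rbind, rows)
  list(parameter = parameter, true_md = unname(true_md[parameter]),
       replicates = tab,
       bias = mean(tab$md_mean) - true_md[[parameter]],
       coverage95 = mean(tab$covers_truth_95),
       sign_rate = mean(sign(tab$md_mean) ==
                          sign(true_md[[parameter]] + 0 * tab$md_mean)),
       hdi90_excludes_zero_rate = mean(tab$excludes_zero_90))
}
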