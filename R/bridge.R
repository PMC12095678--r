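# Bridge-sampling marginal likelihood ------------------------------------
#
# Meng-Wong optimal bridge with a moment-matched multivariate-normal
# proposal, computed on the unconstrained sampling scale. Posterior draws
# are split in half: the first half fits the proposal, the second enters
# the fixed-point iteration, which makes the estimator (nearly) unbiased
# with respect to proposal fitting.

mvn_prep <- function(x) {
  m <- colMeans(x)
  S <- stats::cov(x)
  # ridge keeps the Cholesky well-posed when draws are few relative to d
  ridge <- 1e-8 * mean(diag(S))
  L <- tryCatch(chol(S + diag(ridge, ncol(S))),
                error = function(e) chol(S + diag(1e-4 * mean(diag(S)),
                                                  ncol(S))))
  list(m = m, L = L, logdet = 2 * sum(log(diag(L))))
}

mvn_logpdf <- function(x, prep) {
  d <- length(prep$m)
  z <- backsolve(prep$L, t(x) - prep$m, transpose = TRUE)
  -0.5 * (d * log(2 * pi) + prep$logdet + colSums(z^2))
}

mvn_draw <- function(n, prep) {
  d <- length(prep$m)
  z <- matrix(rnorm(n * d), n, d)
  sweep(z %*% prep$L, 2, prep$m, `+`)
}

#' Bridge-sampling estimate of a log marginal likelihood
#'
#' Estimates the log normalising constant of an unnormalised density from
#' posterior draws. The draws are split in two halves; a moment-matched
#' multivariate-normal proposal is fitted to the first half, an
#' equal-sized proposal sample is drawn, and the Meng-Wong optimal-bridge
#' fixed point is iterated on the second half until the relative change
#' falls below `tol` (default 1e-10) or `max_iter` iterations. Non-finite
#' density evaluations are dropped and counted. The Monte-Carlo standard
#' error assumes approximately independent draws.
#'
#' @param log_post Function taking a parameter vector (or matrix of rows)
#'   and returning the log unnormalised posterior density.
#' @param draws Matrix of posterior draws (rows = draws, columns =
#'   parameters on the sampling scale).
#' @param seed Integer seed for the proposal sample.
#' @param tol Relative fixed-point tolerance.
#' @param max_iter Maximum fixed-point iterations.
#' @param reverse_halves Use the second half for the proposal instead
#'   (for stability checks).
#' @return An object of class `hbrl_logml`: `logml`, `se`, `iterations`,
#'   `converged`, `n_nonfinite`, `n_draws`.
#' @examples
#' # standard normal is already normalised: log ML ~ 0
#' set.seed(1)
#' bridge_sample_logml(function(x) -0.5 * sum(x^2) - 0.5 * log(2 * pi),
#'                     matrix(rnorm(2000), ncol = 1))
#' @export
bridge_sample_logml <- function(log_post, draws, seed = 1, tol = 1e-10,
                                max_iter = 1000, reverse_halves = FALSE) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 20) stop("need more posterior draws", call. = FALSE)
  set.seed(as.integer(seed))
  idx <- seq_len(nrow(draws))
  first <- idx[idx %% 2 == 1]
  second <- idx[idx %% 2 == 0]
  if (reverse_halves) { tmp <- first; first <- second; second <- tmp }
  prep <- mvn_prep(draws[first, , drop = FALSE])
  post <- draws[second, , drop = FALSE]
  prop <- mvn_draw(nrow(post), prep)

  eval_lp <- function(x) {
    if (is.matrix(x)) apply(x, 1, log_post) else log_post(x)
  }
  l1 <- eval_lp(post) - mvn_logpdf(post, prep)   # posterior draws
  l2 <- eval_lp(prop) - mvn_logpdf(prop, prep)   # proposal draws
  bad <- sum(!is.finite(l1)) + sum(!is.finite(l2))
  l1 <- l1[is.finite(l1)]; l2 <- l2[is.finite(l2)]
  n1 <- length(l1); n2 <- length(l2)
  if (n1 < 10 || n2 < 10)
    stop("too many non-finite density evaluations", call. = FALSE)
  s1 <- n1 / (n1 + n2); s2 <- n2 / (n1 + n2)
  lstar <- median(l1)
  e1 <- exp(l1 - lstar); e2 <- exp(l2 - lstar)

  r <- 1; converged <- FALSE; it <- 0
  while (it < max_iter) {
    it <- it + 1
    num <- mean(e2 / (s1 * e2 + s2 * r))
    den <- mean(1 / (s1 * e1 + s2 * r))
    r_new <- num / den
    if (!is.finite(r_new) || r_new <= 0) break
    if (abs(r_new - r) / r_new < tol) { r <- r_new; converged <- TRUE; break }
    r <- r_new
  }
  f1 <- e2 / (s1 * e2 + s2 * r)
  f2 <- 1 / (s1 * e1 + s2 * r)
  re2 <- var(f1) / (n2 * mean(f1)^2) + var(f2) / (n1 * mean(f2)^2)
  structure(list(logml = log(r) + lstar, se = sqrt(re2),
                 iterations = it, converged = converged,
                 n_nonfinite = bad, n_draws = n1 + n2),
            class = "hbrl_logml")
}

#' @export
print.hbrl_logml <- function(x, ...) {
  cat(sprintf("log marginal likelihood = %.3f (MC se %.3f, %d draws%s)\n",
              x$logml, x$se, x$n_draws,
              if (x$converged) "" else ", NOT CONVERGED"))
  invisible(x)
}

#' Marginal likelihood of a fitted hierarchical model
#'
#' Applies [bridge_sample_logml()] to a fitted model, using the fit's own
#' posterior draws and its hierarchical log posterior on the sampling
#' scale.
#'
#' @param fit An `hbrl_fit`.
#' @param seed Seed for the proposal sample (defaults to the fit's seed).
#' @param ... Passed to [bridge_sample_logml()].
#' @return An `hbrl_logml` object with `model_id` and `valence` attached.
#' @export
logml <- function(fit, seed = NULL, ...) {
  if (!inherits(fit, "hbrl_fit")) stop("fit must be an hbrl_fit", call. = FALSE)
  if (is.null(seed)) seed <- fit$seed + 97L
  D <- dim(fit$draws)[3]
  mat <- matrix(fit$draws, ncol = D)
  lp <- function(v) log_posterior(fit$model_id, fit$data, fit$prior, v)
  out <- bridge_sample_logml(lp, mat, seed = seed, ...)
  out$model_id <- fit$model_id
  out$valence <- fit$valence
  out
}

#' Fit and compare candidate models by marginal likelihood
#'
#' Fits each requested model to each valence condition and ranks them by
#' bridge-sampled log marginal likelihood. The winner per condition is
#' the model with the highest log ML; an overall winner is declared only
#' if the same model wins (or ties within `tie_margin` nats) in every
#' fitted condition. If any estimate fails to converge the winner is
#' withheld but the table is still returned.
#'
#' @param trials Cohort trial records.
#' @param models Character vector of model ids.
#' @param valences Conditions to fit.
#' @param prior An [hbrl_priors()].
#' @param chains,warmup,iter MCMC settings per fit.
#' @param seed Base seed; each model/valence combination offsets it.
#' @param tie_margin Log-ML margin treated as a tie (nats).
#' @return An object of class `hbrl_model_comparison`: `table` (model_id,
#'   valence, log_ml, se, converged, delta_vs_best), `winner` per
#'   valence, `overall_winner` (NA if withheld or conditions disagree),
#'   and the fits.
#' @export
compare_models <- function(trials, models = model_ids(),
                           valences = c("reward", "punish"),
                           prior = hbrl_priors(), chains = 2,
                           warmup = 800, iter = 800, seed = 1,
                           tie_margin = 1) {
  models <- match.arg(models, model_ids(), several.ok = TRUE)
  fits <- list(); mls <- list()
  rows <- list()
  k <- 0
  for (v in valences) for (m in models) {
    k <- k + 1
    fit <- hbrl_fit(trials, m, v, prior, chains, warmup, iter,
                    seed = as.integer(seed) + 13L * k)
    ml <- logml(fit)
    fits[[paste(m, v, sep = ".")]] <- fit
    mls[[paste(m, v, sep = ".")]] <- ml
    rows[[k]] <- data.frame(model_id = m, valence = v, log_ml = ml$logml,
                            se = ml$se, converged = ml$converged,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$delta_vs_best <- NA_real_
  winner <- setNames(rep(NA_character_, length(valences)), valences)
  for (v in valences) {
    i <- tab$valence == v
    best <- max(tab$log_ml[i])
    tab$delta_vs_best[i] <- tab$log_ml[i] - best
    if (all(tab$converged[i])) {
      top <- tab$model_id[i][tab$log_ml[i] >= best - tie_margin]
      winner[v] <- if (length(top) == 1) top else
        paste(top, collapse = "/")  # tie reported, not broken
    }
  }
  overall <- NA_character_
  if (!anyNA(winner) && length(unique(winner)) == 1 &&
      !grepl("/", winner[1], fixed = TRUE))
    overall <- unname(winner[1])
  structure(list(table = tab, winner = winner, overall_winner = overall,
                 fits = fits, logml = mls),
            class = "hbrl_model_comparison")
}

#' @export
print.hbrl_model_comparison <- function(x, ...) {
  cat("Model comparison by bridge-sampled log marginal likelihood\n")
  print(x$table, row.names = FALSE, digits = 5)
  for (v in names(x$winner))
    cat(sprintf("  %s condition winner: %s\n", v,
                ifelse(is.na(x$winner[v]), "withheld (non-converged)",
                       x$winner[v])))
  if (!is.na(x$overall_winner))
    cat("  overall winner:", x$overall_winner, "\n")
  invisible(x)
}
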