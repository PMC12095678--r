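#' @useDynLib hbrl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats plogis qlogis rnorm runif rlnorm rbinom sd var
#'   median quantile aov pchisq pt pf p.adjust chisq.test setNames
#'   complete.cases dnorm acf
NULL

# Model registry ---------------------------------------------------------
#
# Four candidate models of two-alternative probabilistic learning:
#   M1: reward learning rate, punishment learning rate, reinforcement
#       sensitivity (softmax temperature fixed at 1).
#   M2: M1 + stimulus stickiness (additive bias to repeat the previous
#       choice within a stimulus pair).
#   M3: single learning rate, reinforcement sensitivity, stickiness.
#   M4: experience-weighted attraction: value decay phi, experience decay
#       rho_ew, free softmax inverse temperature beta.
#
# Parameters are stored on the natural scale; MCMC operates on the
# unconstrained scale (logit for unit-interval, log for positive,
# identity for stickiness).

.model_registry <- list(
  M1 = list(
    params = c("alpha_rew", "alpha_pun", "rho"),
    transform = c("logit", "logit", "log")
  ),
  M2 = list(
    params = c("alpha_rew", "alpha_pun", "rho", "tau"),
    transform = c("logit", "logit", "log", "identity")
  ),
  M3 = list(
    params = c("alpha", "rho", "tau"),
    transform = c("logit", "logit", "log", "identity")[-1]
  ),
  M4 = list(
    params = c("phi", "rho_ew", "beta"),
    transform = c("logit", "logit", "log")
  )
)

#' Model metadata for the four reinforcement-learning models
#'
#' Returns the free parameters of one of the candidate models `"M1"` to
#' `"M4"` and the link used to map each onto the unconstrained sampling
#' scale (`logit` for rates/decays in (0,1), `log` for strictly positive
#' parameters, `identity` for the unbounded stickiness).
#'
#' @param model_id One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @return A list with elements `params` (character vector of parameter
#'   names) and `transform` (matching link names).
#' @export
model_info <- function(model_id) {
  model_id <- match.arg(model_id, names(.model_registry))
  .model_registry[[model_id]]
}

#' @rdname model_info
#' @export
model_ids <- function() names(.model_registry)

validate_params <- function(model_id, params) {
  info <- model_info(model_id)
  missing <- setdiff(info$params, names(params))
  if (length(missing))
    stop(sprintf("model %s requires parameter(s): %s", model_id,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (i in seq_along(info$params)) {
    p <- info$params[i]
    v <- params[[p]]
    if (!is.finite(v)) stop(sprintf("parameter %s is not finite", p), call. = FALSE)
    # closed unit interval: boundary values are meaningful in direct
    # evaluation (no learning / no decay); the hierarchical transform
    # only ever produces interior points
    ok <- switch(info$transform[i],
      logit = v >= 0 && v <= 1,
      log = v > 0,
      identity = TRUE)
    if (!ok) stop(sprintf("parameter %s = %g outside its support", p, v),
                  call. = FALSE)
  }
  invisible(params)
}

#' Map between natural and unconstrained parameter scales
#'
#' Sampling happens on an unconstrained real vector; `param_transform()`
#' maps such a vector to natural-scale parameters (logistic for
#' unit-interval parameters, exponential for positive ones, identity for
#' stickiness) and `param_untransform()` is its exact inverse.
#'
#' @param x Numeric vector on the unconstrained scale, length equal to the
#'   model's free-parameter count (order as in [model_info()]).
#' @param params Named list or vector of natural-scale parameters.
#' @param model_id Model identifier.
#' @return `param_transform()`: a named list of natural-scale parameters;
#'   `param_untransform()`: a named numeric vector.
#' @examples
#' param_transform(c(0, 0, 0), "M1")  # learning rates 0.5, rho 1
#' @export
param_transform <- function(x, model_id) {
  info <- model_info(model_id)
  if (length(x) != length(info$params))
    stop(sprintf("expected %d values for %s, got %d",
                 length(info$params), model_id, length(x)), call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite unconstrained parameter", call. = FALSE)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    out[i] <- switch(info$transform[i],
      logit = plogis(x[i]),
      log = exp(x[i]),
      identity = x[i])
  }
  as.list(setNames(out, info$params))
}

#' @rdname param_transform
#' @export
param_untransform <- function(params, model_id) {
  info <- model_info(model_id)
  params <- as.list(params)
  validate_params(model_id, params)
  out <- numeric(length(info$params))
  for (i in seq_along(info$params)) {
    v <- params[[info$params[i]]]
    out[i] <- switch(info$transform[i],
      logit = qlogis(v),
      log = log(v),
      identity = v)
  }
  setNames(out, info$params)
}

# Value state ------------------------------------------------------------

#' Initialise the learner's value state for a schedule
#'
#' Values start at zero for every stimulus of every pair, the
#' previous-choice indicator is empty, and (for the experience-weighted
#' model) experience weights start at 1. Pairs are identified by
#' `pair_id`; fresh pairs in later blocks get fresh state.
#'
#' @param schedule A schedule data frame (see [generate_schedule()]) or
#'   anything with a `pair_id` column/field.
#' @return A list with matrices `V` (pairs x 2 stimuli), `n` (experience
#'   weights), and integer vector `prev` (0 = no previous choice,
#'   1 = good stimulus, 2 = bad stimulus), row-named by pair id.
#' @export
initial_state <- function(schedule) {
  ids <- unique(as.character(schedule$pair_id))
  if (!length(ids)) stop("schedule lists no pair_ids", call. = FALSE)
  V <- matrix(0, nrow = length(ids), ncol = 2,
              dimnames = list(ids, c("good", "bad")))
  n <- matrix(1, nrow = length(ids), ncol = 2,
              dimnames = list(ids, c("good", "bad")))
  prev <- setNames(integer(length(ids)), ids)
  list(V = V, n = n, prev = prev)
}

# Effective learning rate for M1-M3. A no-change outcome (r = 0) is the
# relatively bad outcome on a reward trial and the relatively good one on
# a punishment trial, so it engages the opposite rate.
.alpha_eff <- function(model_id, params, r, valence) {
  if (model_id == "M3") return(params$alpha)
  if (r > 0) params$alpha_rew
  else if (r < 0) params$alpha_pun
  else if (valence == "reward") params$alpha_pun
  else params$alpha_rew
}

#' Advance the value state after one responded trial
#'
#' For M1-M3 the chosen stimulus is updated by the delta rule
#' `V <- V + alpha_eff * (rho * r - V)` where `alpha_eff` is the reward
#' rate for wins, the punishment rate for losses, and the opposite rate
#' for a no-change outcome relative to the trial's valence. For M4 the
#' chosen stimulus's experience weight and value follow the
#' experience-weighted attraction updates
#' `n <- rho_ew * n_prev + 1`, `V <- (phi * n_prev * V + r) / n`.
#' Only the chosen option is updated; the previous-choice indicator for
#' the pair is set to the chosen stimulus. Unresponded trials leave the
#' state unchanged.
#'
#' @param model_id Model identifier.
#' @param state State list from [initial_state()].
#' @param trial A single-row data frame (or list) with fields `pair_id`,
#'   `valence`, `choice` (`"good_stimulus"`/`"bad_stimulus"`),
#'   `responded`, `outcome`.
#' @param params Named list of natural-scale parameters.
#' @return The updated state list.
#' @export
update_state <- function(model_id, state, trial, params) {
  model_id <- match.arg(model_id, names(.model_registry))
  validate_params(model_id, params)
  if (!isTRUE(as.logical(trial$responded))) return(state)
  pid <- as.character(trial$pair_id)
  if (!pid %in% rownames(state$V))
    stop(sprintf("unknown pair_id '%s'", pid), call. = FALSE)
  j <- if (as.character(trial$choice) == "good_stimulus") 1L else 2L
  r <- as.numeric(trial$outcome)
  if (model_id == "M4") {
    n_prev <- state$n[pid, j]
    n_new <- params$rho_ew * n_prev + 1
    state$V[pid, j] <- (params$phi * n_prev * state$V[pid, j] + r) / n_new
    state$n[pid, j] <- n_new
  } else {
    a <- .alpha_eff(model_id, params, r, as.character(trial$valence))
    state$V[pid, j] <- state$V[pid, j] + a * (params$rho * r - state$V[pid, j])
  }
  state$prev[pid] <- j
  state
}

#' Probability of choosing the good stimulus of a pair
#'
#' Softmax over the two stimulus propensities. For M1-M3 the propensity
#' of stimulus a is `V_a + tau * [a == previous choice]` (tau = 0 in M1)
#' with temperature fixed at 1; for M4 it is `beta * V_a`.
#'
#' @inheritParams update_state
#' @param pair_id Which pair's stimuli are on screen.
#' @return Probability in (0, 1) of choosing the "good" stimulus (the
#'   70%-win or 30%-loss option).
#' @export
choice_probability <- function(model_id, state, pair_id, params) {
  model_id <- match.arg(model_id, names(.model_registry))
  validate_params(model_id, params)
  pid <- as.character(pair_id)
  if (!pid %in% rownames(state$V))
    stop(sprintf("unknown pair_id '%s'", pid), call. = FALSE)
  v <- state$V[pid, ]
  if (model_id == "M4") {
    z <- params$beta * v
  } else {
    tau <- if (model_id == "M1") 0 else params$tau
    z <- v
    p_prev <- state$prev[pid]
    if (p_prev > 0) z[p_prev] <- z[p_prev] + tau
  }
  unname(1 / (1 + exp(z[2] - z[1])))
}

# Internal: encode a single subject's trials of one valence condition
# into the integer vectors consumed by the C++ likelihood.
encode_subject_trials <- function(trials) {
  trials <- trials[order(trials$trial), , drop = FALSE]
  keep <- trials$valence %in% c("reward", "punish")
  trials <- trials[keep, , drop = FALSE]
  pid <- as.character(trials$pair_id)
  upid <- unique(pid)
  responded <- as.logical(trials$responded)
  choice <- rep(NA_integer_, nrow(trials))
  choice[responded] <- ifelse(trials$choice[responded] == "good_stimulus", 1L, 2L)
  outcome <- as.numeric(trials$outcome)
  outcome[!responded] <- 0
  list(
    pair = match(pid, upid),
    n_pairs = length(upid),
    choice = ifelse(is.na(choice), 0L, choice),
    outcome = outcome,
    responded = as.integer(responded),
    is_reward = as.integer(trials$valence == "reward")
  )
}

.model_code <- function(model_id) match(model_id, names(.model_registry))

params_to_vector <- function(model_id, params) {
  info <- model_info(model_id)
  validate_params(model_id, params)
  unlist(params[info$params], use.names = FALSE)
}

#' Log-likelihood of one subject's choices under a model
#'
#' Sums the log choice probability of each observed choice over the
#' responded, non-neutral trials of a single subject, updating the value
#' state sequentially. Unresponded trials contribute nothing and do not
#' update the state. Trials must belong to a single subject; reward- and
#' punishment-trial data are normally fitted separately, so `trials` is
#' typically pre-filtered to one valence condition.
#'
#' @param model_id Model identifier.
#' @param trials Data frame of trials for one subject (columns as in
#'   [read_trials()]).
#' @param params Named list of natural-scale parameters.
#' @param engine `"cpp"` (default, compiled) or `"r"` (reference R loop
#'   built from [update_state()] and [choice_probability()]).
#' @return Log-likelihood in nats.
#' @export
subject_loglik <- function(model_id, trials, params, engine = c("cpp", "r")) {
  model_id <- match.arg(model_id, names(.model_registry))
  engine <- match.arg(engine)
  validate_params(model_id, params)
  if (length(unique(trials$subject_id)) > 1)
    stop("trials must belong to a single subject", call. = FALSE)
  if (engine == "r") return(subject_loglik_r(model_id, trials, params))
  enc <- encode_subject_trials(trials)
  cpp_subject_loglik(.model_code(model_id), enc$pair, enc$n_pairs, enc$choice,
                     enc$outcome, enc$responded, enc$is_reward,
                     params_to_vector(model_id, params))
}

subject_loglik_r <- function(model_id, trials, params) {
  trials <- trials[order(trials$trial), , drop = FALSE]
  trials <- trials[trials$valence %in% c("reward", "punish"), , drop = FALSE]
  if (!nrow(trials)) return(0)
  state <- initial_state(trials)
  ll <- 0
  for (k in seq_len(nrow(trials))) {
    tr <- trials[k, ]
    if (!isTRUE(as.logical(tr$responded))) next
    p_good <- choice_probability(model_id, state, tr$pair_id, params)
    p <- if (tr$choice == "good_stimulus") p_good else 1 - p_good
    ll <- ll + log(p)
    state <- update_state(model_id, state, tr, params)
  }
  ll
}
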