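# Task paradigm: schedule generation and forward simulation ------------
#
# Two-alternative probabilistic learning with three interleaved pair
# valences per block. The "good" stimulus of a reward pair wins (+1)
# with probability p_good and otherwise pays nothing; the bad stimulus
# wins with p_bad. Punishment pairs are symmetric with losses: the good
# stimulus loses (-1) only with probability p_bad. Neutral pairs never
# pay. Stimuli are fresh in each block, so each block x valence is a new
# pair.

#' Construct a task design
#'
#' Defaults describe the study paradigm: 3 blocks, 32 trials per valence
#' per block (96 per valence in total), 70/30 outcome contingencies,
#' unit win/loss, 2 s response window.
#'
#' @param n_blocks Number of blocks, each with fresh stimuli.
#' @param trials_per_valence_per_block Trials of each valence per block.
#' @param p_good Outcome probability for the better option (win for
#'   reward pairs; loss probability for the *worse* punishment option).
#' @param p_bad Outcome probability for the worse reward option / better
#'   punishment option.
#' @param win_value,loss_value Outcome magnitudes (win > 0 > loss).
#' @param response_window_s Response deadline in seconds (metadata).
#' @return An object of class `task_design`.
#' @examples
#' task_design()
#' @export
task_design <- function(n_blocks = 3, trials_per_valence_per_block = 32,
                        p_good = 0.70, p_bad = 0.30,
                        win_value = 1, loss_value = -1,
                        response_window_s = 2.0) {
  if (!(p_bad >= 0 && p_good <= 1 && p_bad < p_good))
    stop("need 0 <= p_bad < p_good <= 1", call. = FALSE)
  if (trials_per_valence_per_block < 1 || n_blocks < 1)
    stop("need at least one block and one trial per valence per block",
         call. = FALSE)
  if (!(win_value > 0 && loss_value < 0))
    stop("need win_value > 0 > loss_value", call. = FALSE)
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_valence_per_block =
                   as.integer(trials_per_valence_per_block),
                 p_good = p_good, p_bad = p_bad,
                 win_value = win_value, loss_value = loss_value,
                 response_window_s = response_window_s),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat("Probabilistic reward/punishment task design\n")
  cat(sprintf("  %d block(s) x %d trials per valence (reward/punish/neutral)\n",
              x$n_blocks, x$trials_per_valence_per_block))
  cat(sprintf("  contingencies: good option %.0f%%, bad option %.0f%%\n",
              100 * x$p_good, 100 * x$p_bad))
  cat(sprintf("  outcomes: win %+g / loss %+g, response window %.1f s\n",
              x$win_value, x$loss_value, x$response_window_s))
  invisible(x)
}

.valences <- c("reward", "punish", "neutral")

#' Generate a randomised task schedule
#'
#' Produces the full trial list for one session: within each block the
#' three valences are interleaved by a uniform shuffle, and both options'
#' probabilistic outcomes are pre-drawn for every trial so that the
#' realised feedback is a property of the schedule, not of the agent.
#' Only the chosen option's outcome is ever shown to an agent.
#'
#' @param design A [task_design()].
#' @param seed Integer seed; the schedule is reproducible given the seed.
#' @return A data frame with one row per trial: `block`,
#'   `trial_in_block`, `trial` (global index), `valence`, `pair_id`,
#'   `outcome_if_good`, `outcome_if_bad`.
#' @export
generate_schedule <- function(design = task_design(), seed = NULL) {
  if (!inherits(design, "task_design")) design <- do.call(task_design, design)
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- design$trials_per_valence_per_block
  blocks <- lapply(seq_len(design$n_blocks), function(b) {
    val <- sample(rep(.valences, each = m))
    pair_id <- paste0("b", b, "_", val)
    og <- numeric(length(val))
    ob <- numeric(length(val))
    rw <- val == "reward"
    pu <- val == "punish"
    og[rw] <- design$win_value * rbinom(sum(rw), 1, design$p_good)
    ob[rw] <- design$win_value * rbinom(sum(rw), 1, design$p_bad)
    og[pu] <- design$loss_value * rbinom(sum(pu), 1, design$p_bad)
    ob[pu] <- design$loss_value * rbinom(sum(pu), 1, design$p_good)
    data.frame(block = b, trial_in_block = seq_along(val), valence = val,
               pair_id = pair_id, outcome_if_good = og, outcome_if_bad = ob,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  out$trial <- seq_len(nrow(out))
  out[, c("block", "trial_in_block", "trial", "valence", "pair_id",
          "outcome_if_good", "outcome_if_bad")]
}

#' Simulate one agent on a schedule
#'
#' Walks the schedule in order, drawing each choice from the model's
#' choice probabilities (neutral pairs carry no value signal and are
#' chosen at random), reading the realised outcome off the pre-drawn
#' schedule, and updating the value state. A lapse probability can
#' produce omitted responses, which neither earn feedback nor update the
#' state. Reaction times are decorative log-normal draws truncated at
#' the response window.
#'
#' @param model_id Model identifier.
#' @param params Named list of natural-scale parameters for the model.
#' @param schedule Schedule from [generate_schedule()].
#' @param design The [task_design()] the schedule came from.
#' @param subject_id,group Identifiers copied into the output.
#' @param p_lapse Probability of a missed response per trial.
#' @param seed Optional integer seed.
#' @return A data frame of trial records: `subject_id`, `group`,
#'   `block`, `trial`, `valence`, `pair_id`, `choice`, `responded`,
#'   `outcome`, `rt_s`.
#' @export
simulate_agent <- function(model_id, params, schedule,
                           design = task_design(), subject_id = "s1",
                           group = "placebo", p_lapse = 0, seed = NULL) {
  model_id <- match.arg(model_id, model_ids())
  validate_params(model_id, params)
  if (p_lapse < 0 || p_lapse >= 1) stop("p_lapse must be in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(schedule)
  state <- initial_state(schedule)
  choice <- rep(NA_character_, n)
  outcome <- rep(NA_real_, n)
  rt <- rep(NA_real_, n)
  responded <- runif(n) >= p_lapse
  u_choice <- runif(n)
  for (t in seq_len(n)) {
    if (!responded[t]) next
    tr <- schedule[t, ]
    p_good <- if (tr$valence == "neutral") 0.5 else
      choice_probability(model_id, state, tr$pair_id, params)
    good <- u_choice[t] < p_good
    choice[t] <- if (good) "good_stimulus" else "bad_stimulus"
    outcome[t] <- if (tr$valence == "neutral") 0 else
      if (good) tr$outcome_if_good else tr$outcome_if_bad
    rec <- list(pair_id = tr$pair_id, valence = tr$valence,
                choice = choice[t], responded = TRUE, outcome = outcome[t])
    if (tr$valence != "neutral")
      state <- update_state(model_id, state, rec, params)
    else
      state$prev[as.character(tr$pair_id)] <-
        if (good) 1L else 2L
  }
  rt[responded] <- pmin(rlnorm(sum(responded), log(0.65), 0.3),
                        design$response_window_s)
  data.frame(subject_id = subject_id, group = group,
             block = schedule$block, trial = schedule$trial,
             valence = schedule$valence, pair_id = schedule$pair_id,
             choice = choice, responded = responded,
             outcome = ifelse(responded, outcome, NA_real_), rt_s = rt,
             stringsAsFactors = FALSE)
}

#' Default arm-level generating parameters on the unconstrained scale
#'
#' Study-scale defaults used by [simulate_cohort()] and the recovery
#' experiments: moderate learning rates (about 0.35), reinforcement
#' sensitivity about 3, mild stickiness. A natural-scale shift can be
#' injected on one parameter of the drug arm (e.g. a lower punishment
#' learning rate), implemented exactly on the transformed group mean so
#' the true group mean difference on the natural scale equals the shift.
#'
#' @param model_id Model identifier.
#' @param natural_shift Named numeric vector of natural-scale additive
#'   shifts applied to the drug arm's group means (placebo means are the
#'   defaults).
#' @return List with matrices `means` (parameter x arm, unconstrained)
#'   and vector `sds` (shared between-subject sds, unconstrained scale).
#' @export
default_arm_params <- function(model_id, natural_shift = NULL) {
  info <- model_info(model_id)
  nat <- switch(model_id,
    M1 = c(alpha_rew = 0.35, alpha_pun = 0.35, rho = 3),
    M2 = c(alpha_rew = 0.35, alpha_pun = 0.35, rho = 3, tau = 0.4),
    M3 = c(alpha = 0.35, rho = 3, tau = 0.4),
    M4 = c(phi = 0.7, rho_ew = 0.5, beta = 3))
  sds <- setNames(rep(0.5, length(info$params)), info$params)
  mk <- function(natvec) param_untransform(as.list(natvec), model_id)
  drug_nat <- nat
  if (!is.null(natural_shift)) {
    bad <- setdiff(names(natural_shift), info$params)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    drug_nat[names(natural_shift)] <- drug_nat[names(natural_shift)] +
      natural_shift
  }
  means <- cbind(placebo = mk(nat), drug = mk(drug_nat))
  list(means = means, sds = sds)
}

# Covariate summaries matching the study cohort's demographics.
.covariate_spec <- list(
  placebo = list(age = c(25.38, 5.77), iq = c(111.50, 9.51), p_female = 21 / 32),
  drug    = list(age = c(24.25, 5.56), iq = c(112.22, 9.30), p_female = 21 / 32)
)

#' Simulate a two-arm cohort
#'
#' Draws per-subject parameters from arm-specific normal distributions on
#' the unconstrained scale (non-centred: `mu_arm + sd * z`), transforms
#' them to the natural scale, and simulates each subject on an
#' independently generated schedule. Covariates (age, sex, IQ) are drawn
#' to match the study's demographic summaries.
#'
#' @param n_per_arm Subjects per arm.
#' @param model_id Generating model.
#' @param arm_means Parameter x arm matrix of unconstrained group means
#'   (columns `placebo`, `drug`); defaults from [default_arm_params()].
#' @param arm_sds Named vector of shared between-subject sds
#'   (unconstrained scale), all > 0.
#' @param design A [task_design()].
#' @param p_lapse Per-trial omission probability.
#' @param seed Integer seed; the whole cohort is reproducible given it.
#' @return List with data frames `trials`, `covariates`
#'   (subject_id, group, age, sex, iq), and `true_params` (the per-subject
#'   natural-scale generating parameters).
#' @export
simulate_cohort <- function(n_per_arm = 32, model_id = "M2",
                            arm_means = NULL, arm_sds = NULL,
                            design = task_design(), p_lapse = 0,
                            seed = 1) {
  model_id <- match.arg(model_id, model_ids())
  if (n_per_arm < 1) stop("n_per_arm must be >= 1", call. = FALSE)
  defaults <- default_arm_params(model_id)
  if (is.null(arm_means)) arm_means <- defaults$means
  if (is.null(arm_sds)) arm_sds <- defaults$sds
  if (any(arm_sds <= 0)) stop("arm_sds must be positive", call. = FALSE)
  info <- model_info(model_id)
  set.seed(as.integer(seed))
  subjects <- data.frame(
    subject_id = sprintf("s%03d", seq_len(2 * n_per_arm)),
    group = rep(c("placebo", "drug"), each = n_per_arm),
    stringsAsFactors = FALSE)
  P <- length(info$params)
  z <- matrix(rnorm(nrow(subjects) * P), ncol = P)
  unc <- t(arm_means[, subjects$group]) + z %*% diag(arm_sds[info$params], P)
  colnames(unc) <- info$params
  trials <- vector("list", nrow(subjects))
  true_params <- matrix(NA_real_, nrow(subjects), P,
                        dimnames = list(subjects$subject_id, info$params))
  cov_rows <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    pars <- param_transform(unc[i, ], model_id)
    true_params[i, ] <- unlist(pars)
    sched <- generate_schedule(design)
    trials[[i]] <- simulate_agent(model_id, pars, sched, design,
                                  subject_id = subjects$subject_id[i],
                                  group = subjects$group[i],
                                  p_lapse = p_lapse)
    cs <- .covariate_spec[[subjects$group[i]]]
    cov_rows[[i]] <- data.frame(
      subject_id = subjects$subject_id[i], group = subjects$group[i],
      age = round(min(max(rnorm(1, cs$age[1], cs$age[2]), 18), 45)),
      sex = if (runif(1) < cs$p_female) "F" else "M",
      iq = round(rnorm(1, cs$iq[1], cs$iq[2]), 1),
      stringsAsFactors = FALSE)
  }
  list(trials = do.call(rbind, trials),
       covariates = do.call(rbind, cov_rows),
       true_params = true_params,
       model_id = model_id, arm_means = arm_means, arm_sds = arm_sds,
       seed = as.integer(seed))
}
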