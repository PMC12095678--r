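# Independent brute-force oracles, deliberately written from scratch
# (environment-based state, explicit softmax) rather than reusing any
# package internals.

# Naive trial-by-trial log-likelihood for a single subject.
naive_loglik <- function(model_id, trials, params) {
  trials <- trials[order(trials$trial), ]
  trials <- trials[trials$valence %in% c("reward", "punish"), ]
  V <- new.env(parent = emptyenv())
  NW <- new.env(parent = emptyenv())
  PREV <- new.env(parent = emptyenv())
  get0v <- function(env, key, default) {
    if (is.null(env[[key]])) default else env[[key]]
  }
  ll <- 0
  for (k in seq_len(nrow(trials))) {
    tr <- trials[k, ]
    if (!isTRUE(as.logical(tr$responded))) next
    pid <- as.character(tr$pair_id)
    vg <- get0v(V, paste0(pid, ".g"), 0)
    vb <- get0v(V, paste0(pid, ".b"), 0)
    prev <- get0v(PREV, pid, "")
    if (model_id == "M4") {
      zg <- params$beta * vg
      zb <- params$beta * vb
    } else {
      tau <- if (model_id == "M1") 0 else params$tau
      zg <- vg + if (identical(prev, "g")) tau else 0
      zb <- vb + if (identical(prev, "b")) tau else 0
    }
    pg <- exp(zg) / (exp(zg) + exp(zb))
    chose_good <- tr$choice == "good_stimulus"
    ll <- ll + log(if (chose_good) pg else 1 - pg)
    r <- as.numeric(tr$outcome)
    key <- paste0(pid, if (chose_good) ".g" else ".b")
    v_old <- if (chose_good) vg else vb
    if (model_id == "M4") {
      n_old <- get0v(NW, key, 1)
      n_new <- params$rho_ew * n_old + 1
      V[[key]] <- (params$phi * n_old * v_old + r) / n_new
      NW[[key]] <- n_new
    } else {
      a <- if (model_id == "M3") params$alpha
        else if (r > 0) params$alpha_rew
        else if (r < 0) params$alpha_pun
        else if (tr$valence == "reward") params$alpha_pun
        else params$alpha_rew
      V[[key]] <- v_old + a * (params$rho * r - v_old)
    }
    PREV[[pid]] <- if (chose_good) "g" else "b"
  }
  ll
}

# Exhaustive minimal-window HDI search.
hdi_oracle <- function(x, mass) {
  s <- sort(x)
  n <- length(s)
  m <- min(n, ceiling(mass * n))
  best <- c(s[1], s[n])
  best_w <- Inf
  for (i in seq_len(n - m + 1)) {
    w <- s[i + m - 1] - s[i]
    if (w < best_w) { best_w <- w; best <- c(s[i], s[i + m - 1]) }
  }
  best
}

# Random natural-scale parameters inside each model's support.
random_params <- function(model_id) {
  switch(model_id,
    M1 = list(alpha_rew = runif(1, 0.05, 0.95),
              alpha_pun = runif(1, 0.05, 0.95), rho = runif(1, 0.5, 6)),
    M2 = list(alpha_rew = runif(1, 0.05, 0.95),
              alpha_pun = runif(1, 0.05, 0.95), rho = runif(1, 0.5, 6),
              tau = runif(1, -1.5, 1.5)),
    M3 = list(alpha = runif(1, 0.05, 0.95), rho = runif(1, 0.5, 6),
              tau = runif(1, -1.5, 1.5)),
    M4 = list(phi = runif(1, 0.1, 0.95), rho_ew = runif(1, 0.1, 0.95),
              beta = runif(1, 0.5, 6)))
}

# Small random single-subject dataset.
random_subject_trials <- function(design = task_design(n_blocks = 1,
                                                       trials_per_valence_per_block = 10),
                                  model_id = "M2", params = NULL,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) params <- random_params(model_id)
  sched <- generate_schedule(design)
  simulate_agent(model_id, params, sched, design)
}

# Hand-buildable trial data frame.
make_trials <- function(valence, choice, outcome, subject_id = "s1",
                        group = "placebo", pair_id = NULL,
                        responded = NULL, rt_s = NULL) {
  n <- length(valence)
  if (is.null(pair_id)) pair_id <- paste0("b1_", valence)
  if (is.null(responded)) responded <- !is.na(choice)
  if (is.null(rt_s)) rt_s <- ifelse(responded, 0.7, NA_real_)
  data.frame(subject_id = subject_id, group = group, block = 1L,
             trial = seq_len(n), valence = valence, pair_id = pair_id,
             choice = choice, responded = responded, outcome = outcome,
             rt_s = rt_s, stringsAsFactors = FALSE)
}
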