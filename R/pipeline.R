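# End-to-end pipeline -----------------------------------------------------
#
# Programmatic equivalents of a simulate / behav / fit / compare / report
# workflow. Every stage is deterministic given the config seed, writes
# CSV outputs plus a manifest carrying the serialised config and its
# hash, and can be re-run from stored outputs.

#' Pipeline configuration
#'
#' Validated bundle of task-design overrides, model set, prior scales,
#' MCMC settings, valence conditions and output directory. The full
#' config (and a hash of it) is written into every stage manifest.
#'
#' @param out_dir Output directory (created if absent).
#' @param design A [task_design()].
#' @param models Models to fit/compare.
#' @param valences Conditions to fit.
#' @param n_per_arm Cohort size per arm for simulation.
#' @param natural_shift Optional named natural-scale drug-arm shift for
#'   the simulated cohort.
#' @param prior An [hbrl_priors()].
#' @param chains,warmup,iter MCMC settings.
#' @param seed Integer master seed; each stage derives its own stream.
#' @return Object of class `hbrl_config`.
#' @export
pipeline_config <- function(out_dir, design = task_design(),
                            models = model_ids(),
                            valences = c("reward", "punish"),
                            n_per_arm = 32, natural_shift = NULL,
                            prior = hbrl_priors(), chains = 2,
                            warmup = 800, iter = 800, seed = 1) {
  stopifnot(inherits(design, "task_design"), inherits(prior, "hbrl_prior"))
  models <- match.arg(models, model_ids(), several.ok = TRUE)
  valences <- match.arg(valences, c("reward", "punish"), several.ok = TRUE)
  if (warmup < 1 || iter < 1 || chains < 2)
    stop("invalid mcmc settings", call. = FALSE)
  cfg <- structure(list(out_dir = out_dir, design = design, models = models,
                        valences = valences, n_per_arm = n_per_arm,
                        natural_shift = natural_shift, prior = prior,
                        chains = chains, warmup = warmup, iter = iter,
                        seed = as.integer(seed)),
                   class = "hbrl_config")
  cfg$hash <- config_hash(cfg)
  cfg
}

config_hash <- function(cfg) {
  cfg$hash <- NULL
  s <- paste(deparse(cfg[setdiff(names(cfg), "out_dir")]), collapse = "")
  # small rolling hash; stable across sessions, no external deps
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

write_manifest <- function(cfg, stage, extra = list()) {
  man <- c(list(stage = stage, config_hash = cfg$hash, seed = cfg$seed,
                models = paste(cfg$models, collapse = ","),
                valences = paste(cfg$valences, collapse = ","),
                n_per_arm = cfg$n_per_arm,
                prior_mean_scale = cfg$prior$mean_scale,
                prior_sd_scale = cfg$prior$sd_scale,
                chains = cfg$chains, warmup = cfg$warmup, iter = cfg$iter),
           extra)
  path <- file.path(cfg$out_dir, paste0("manifest_", stage, ".txt"))
  writeLines(paste(names(man), vapply(man, paste, "", collapse = ","),
                   sep = ": "), path)
  invisible(path)
}

#' Run pipeline stages
#'
#' `run_simulate()` writes the simulated cohort (trials + covariates
#' CSVs), `run_behav()` the behavioural summary and ANCOVA tables,
#' `run_fit()` the group-difference summary per model x valence plus a
#' convergence report, `run_compare()` the model-comparison table, and
#' `pipeline_report()` assembles a single human-readable report from the
#' stored outputs. `run_pipeline()` chains them all.
#'
#' @param cfg An [pipeline_config()].
#' @return Each stage returns its main result invisibly and writes CSVs
#'   under `cfg$out_dir`.
#' @export
run_simulate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  arm <- default_arm_params(cfg$models[1], cfg$natural_shift)
  cohort <- simulate_cohort(cfg$n_per_arm, cfg$models[1], arm$means,
                            arm$sds, cfg$design, seed = cfg$seed)
  write_trials(cohort$trials, file.path(cfg$out_dir, "trials.csv"))
  write_covariates(cohort$covariates,
                   file.path(cfg$out_dir, "covariates.csv"))
  utils::write.csv(data.frame(subject_id = rownames(cohort$true_params),
                              cohort$true_params),
                   file.path(cfg$out_dir, "true_params.csv"),
                   row.names = FALSE)
  write_manifest(cfg, "simulate",
                 list(n_subjects = nrow(cohort$covariates)))
  invisible(cohort)
}

#' @rdname run_simulate
#' @export
run_behav <- function(cfg) {
  trials <- read_trials(file.path(cfg$out_dir, "trials.csv"))
  covs <- read_covariates(file.path(cfg$out_dir, "covariates.csv"))
  beh <- summarize_behaviour(trials)
  utils::write.csv(beh, file.path(cfg$out_dir, "behaviour.csv"),
                   row.names = FALSE)
  anc <- do.call(rbind, lapply(c("accuracy", "mean_rt_s"), function(resp) {
    a <- mixed_ancova(beh, covs, resp)
    a$response <- resp
    a
  }))
  anc$p_bh <- bh_adjust(anc$p)$adjusted
  utils::write.csv(anc, file.path(cfg$out_dir, "ancova.csv"),
                   row.names = FALSE)
  write_manifest(cfg, "behav")
  invisible(list(behaviour = beh, ancova = anc))
}

#' @rdname run_simulate
#' @export
run_fit <- function(cfg) {
  trials <- read_trials(file.path(cfg$out_dir, "trials.csv"))
  results <- list()
  conv <- list()
  k <- 0
  for (v in cfg$valences) for (m in cfg$models) {
    k <- k + 1
    fit <- hbrl_fit(trials, m, v, cfg$prior, cfg$chains, cfg$warmup,
                    cfg$iter, seed = cfg$seed + 13L * k)
    md <- group_difference(fit)
    md$model_id <- m; md$valence <- v
    results[[paste(m, v, sep = ".")]] <- fit
    utils::write.csv(md, file.path(cfg$out_dir,
                                   sprintf("md_%s_%s.csv", m, v)),
                     row.names = FALSE)
    cr <- fit$convergence; cr$model_id <- m; cr$valence <- v
    conv[[k]] <- cr
  }
  conv <- do.call(rbind, conv)
  utils::write.csv(conv, file.path(cfg$out_dir, "convergence.csv"),
                   row.names = FALSE)
  write_manifest(cfg, "fit",
                 list(max_rhat = sprintf("%.4f",
                                         max(conv$rhat, na.rm = TRUE))))
  invisible(results)
}

#' @rdname run_simulate
#' @export
run_compare <- function(cfg) {
  trials <- read_trials(file.path(cfg$out_dir, "trials.csv"))
  cmp <- compare_models(trials, cfg$models, cfg$valences, cfg$prior,
                        cfg$chains, cfg$warmup, cfg$iter, seed = cfg$seed)
  utils::write.csv(cmp$table, file.path(cfg$out_dir, "model_comparison.csv"),
                   row.names = FALSE)
  winners <- data.frame(valence = names(cmp$winner), winner = cmp$winner,
                        stringsAsFactors = FALSE)
  utils::write.csv(winners, file.path(cfg$out_dir, "winners.csv"),
                   row.names = FALSE)
  write_manifest(cfg, "compare",
                 list(overall_winner = ifelse(is.na(cmp$overall_winner),
                                              "withheld", cmp$overall_winner)))
  invisible(cmp)
}

#' @rdname run_simulate
#' @export
pipeline_report <- function(cfg) {
  out <- cfg$out_dir
  lines <- c("Reinforcement-learning pipeline report",
             sprintf("config hash %s, seed %d", cfg$hash, cfg$seed), "")
  f <- function(p) file.path(out, p)
  if (file.exists(f("ancova.csv"))) {
    anc <- utils::read.csv(f("ancova.csv"))
    lines <- c(lines, "Behavioural ANCOVA (sequential SS, covariates first):")
    lines <- c(lines, sprintf(
      "  %s [%s]: F(%d, %d) = %.2f, p = %.3f, eta2 = %.3f",
      anc$term, anc$response, anc$df, anc$df_resid, anc$F, anc$p,
      anc$eta_sq), "")
  } else lines <- c(lines, "Behavioural ANCOVA: not run", "")
  md_files <- list.files(out, pattern = "^md_.*\\.csv$", full.names = TRUE)
  if (length(md_files)) {
    lines <- c(lines, "Group differences (drug - placebo, natural scale):")
    for (mf in sort(md_files)) {
      md <- utils::read.csv(mf)
      lines <- c(lines, sprintf("  model %s, %s trials:", md$model_id[1],
                                md$valence[1]),
                 paste0("    ", format_md(md, 90)))
    }
    lines <- c(lines, "")
  } else lines <- c(lines, "Model fits: not run", "")
  if (file.exists(f("winners.csv"))) {
    w <- utils::read.csv(f("winners.csv"))
    lines <- c(lines, "Model comparison:",
               sprintf("  winning model (%s trials): %s", w$valence,
                       w$winner), "")
  } else lines <- c(lines, "Model comparison: not run", "")
  writeLines(lines, f("report.txt"))
  invisible(lines)
}

#' @rdname run_simulate
#' @export
run_pipeline <- function(cfg) {
  run_simulate(cfg)
  run_behav(cfg)
  run_fit(cfg)
  run_compare(cfg)
  pipeline_report(cfg)
  invisible(cfg)
}
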