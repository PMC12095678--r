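# Classical behavioural statistics ---------------------------------------

#' Per-subject accuracy and reaction-time summary
#'
#' Accuracy is the proportion of responded reward/punishment trials on
#' which the better option was chosen ("better" = the 70%-win option on
#' reward pairs, the 30%-loss option on punishment pairs); neutral trials
#' are excluded. Mean RT is taken over responded trials of the valence.
#' Subjects with no responded trials in a valence get an `NA` cell and a
#' warning.
#'
#' @param trials Trial records.
#' @return Data frame: `subject_id`, `group`, `valence`, `accuracy`,
#'   `mean_rt_s`, `n_responded`.
#' @export
summarize_behaviour <- function(trials) {
  validate_trials(trials)
  tr <- trials[trials$valence %in% c("reward", "punish"), , drop = FALSE]
  key <- interaction(tr$subject_id, tr$valence, drop = FALSE)
  subjects <- unique(tr[, c("subject_id", "group")])
  grid <- expand.grid(subject_id = subjects$subject_id,
                      valence = c("reward", "punish"),
                      stringsAsFactors = FALSE)
  grid$group <- subjects$group[match(grid$subject_id, subjects$subject_id)]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    d <- tr[tr$subject_id == grid$subject_id[i] &
              tr$valence == grid$valence[i], , drop = FALSE]
    d <- d[as.logical(d$responded), , drop = FALSE]
    data.frame(grid[i, c("subject_id", "group", "valence")],
               accuracy = if (nrow(d)) mean(d$choice == "good_stimulus")
                          else NA_real_,
               mean_rt_s = if (nrow(d)) mean(d$rt_s) else NA_real_,
               n_responded = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (any(out$n_responded == 0))
    warning("subject(s) with no responded trials in a valence: ",
            paste(unique(out$subject_id[out$n_responded == 0]),
                  collapse = ", "), call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Repeated-measures ANCOVA on the behavioural summary
#'
#' Mixed ANCOVA with the within-subject factor feedback (reward vs
#' punishment), the between-subject factor group (placebo vs drug), and
#' age, sex and IQ as covariates entered first (sequential, Type I sums
#' of squares, as `aov` computes them). Age and IQ are mean-centred and
#' sex enters as a binary covariate. The default model uses a subject
#' error stratum; `stratum = FALSE` fits the flat long-format model.
#'
#' @param summary Output of [summarize_behaviour()].
#' @param covariates Data frame `subject_id, group, age, sex, iq`.
#' @param response `"accuracy"` or `"mean_rt_s"`.
#' @param stratum Use an `Error(subject)` stratum (default TRUE).
#' @return Data frame with one row per tested term (`group`, `feedback`,
#'   `group:feedback`): `df`, `df_resid`, `ss`, `F`, `p`, `eta_sq`
#'   (partial, within its error stratum).
#' @export
mixed_ancova <- function(summary, covariates,
                         response = c("accuracy", "mean_rt_s"),
                         stratum = TRUE) {
  response <- match.arg(response)
  d <- merge(summary, covariates[, c("subject_id", "age", "sex", "iq")],
             by = "subject_id")
  d$y <- d[[response]]
  drop_ids <- unique(d$subject_id[is.na(d$y)])
  if (length(drop_ids)) {
    warning("dropping subject(s) with missing cells: ",
            paste(drop_ids, collapse = ", "), call. = FALSE)
    d <- d[!d$subject_id %in% drop_ids, , drop = FALSE]
  }
  d$subject_id <- factor(d$subject_id)
  d$group <- factor(d$group, levels = c("placebo", "drug"))
  d$feedback <- factor(d$valence, levels = c("reward", "punish"))
  d$age_c <- d$age - mean(d$age)
  d$iq_c <- d$iq - mean(d$iq)
  d$sex_b <- as.numeric(factor(d$sex)) - 1
  form <- if (stratum)
    y ~ age_c + sex_b + iq_c + group * feedback + Error(subject_id)
  else
    y ~ age_c + sex_b + iq_c + group * feedback
  fit <- aov(form, data = d)
  tabs <- if (stratum) lapply(summary(fit), function(s) s[[1]])
          else list(summary(fit)[[1]])
  rows <- list()
  for (tab in tabs) {
    terms <- trimws(rownames(tab))
    resid_i <- which(terms == "Residuals")
    if (!length(resid_i)) next
    ss_res <- tab[resid_i, "Sum Sq"]
    df_res <- tab[resid_i, "Df"]
    for (term in c("group", "feedback", "group:feedback")) {
      i <- which(terms == term)
      if (!length(i)) next
      rows[[term]] <- data.frame(
        term = term, df = tab[i, "Df"], df_resid = df_res,
        ss = tab[i, "Sum Sq"], F = tab[i, "F value"],
        p = tab[i, "Pr(>F)"],
        eta_sq = tab[i, "Sum Sq"] / (tab[i, "Sum Sq"] + ss_res),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[c("group", "feedback", "group:feedback")])
  rownames(out) <- NULL
  out
}

#' Welch's two-sample t test from summary statistics
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-tailed p value, computed from group means, sds and
#' sizes (as needed to recompute published demographic tables).
#'
#' @param mean1,sd1,n1 First group (e.g. placebo).
#' @param mean2,sd2,n2 Second group.
#' @return List: `statistic`, `df`, `p`, `label`.
#' @examples
#' welch_t(111.50, 9.51, 32, 112.22, 9.30, 32)  # t ~ -0.31
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("sds must be positive", call. = FALSE)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df), label = "welch_t")
}

#' Cohen's d from summary statistics (pooled-sd convention)
#'
#' `d = (mean1 - mean2) / s_pooled` with the pooled sd weighted by
#' `n - 1` per group.
#'
#' @inheritParams welch_t
#' @return Numeric effect size.
#' @examples
#' cohens_d(25.38, 5.77, 32, 24.25, 5.56, 32)  # ~0.20
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("sds must be positive", call. = FALSE)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (mean1 - mean2) / sp
}

#' Pearson chi-squared test on a 2x2 table with phi
#'
#' Uncorrected by default (`correct = TRUE` applies Yates' continuity
#' correction). The effect size is `phi = sqrt(chi2 / N)`.
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @param correct Apply Yates' continuity correction.
#' @return List: `statistic`, `df`, `p`, `phi`, `n`.
#' @examples
#' chi_square_2x2(matrix(c(17, 5, 15, 26), 2))  # ~9.48
#' @export
chi_square_2x2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2)) stop("counts must be 2x2", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin", call. = FALSE)
  ct <- suppressWarnings(chisq.test(counts, correct = correct))
  n <- sum(counts)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, phi = sqrt(unname(ct$statistic) / n), n = n)
}

#' Benjamini-Hochberg step-up correction
#'
#' @param p Vector of raw p values in `[0, 1]`.
#' @param q Target false discovery rate.
#' @return List: `adjusted` (BH-adjusted p values, original order) and
#'   `rejected` (logical, `adjusted <= q`).
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.20), q = 0.05)
#' @export
bh_adjust <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]", call. = FALSE)
  adj <- p.adjust(p, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}

#' Demographic comparison table from summary statistics
#'
#' Recomputes the study-style demographics table (Welch t, two-tailed p,
#' Cohen's d per continuous row; chi-squared and phi for sex counts) from
#' per-arm summaries.
#'
#' @param rows Named list; each continuous entry is
#'   `list(mean1, sd1, n1, mean2, sd2, n2)`, each categorical entry a 2x2
#'   count matrix.
#' @return Data frame with columns `variable`, `statistic`, `p`,
#'   `effect_size`, `effect_type`.
#' @export
demographics_table <- function(rows) {
  out <- lapply(names(rows), function(nm) {
    r <- rows[[nm]]
    if (is.matrix(r)) {
      ct <- chi_square_2x2(r)
      data.frame(variable = nm, statistic = ct$statistic, p = ct$p,
                 effect_size = ct$phi, effect_type = "phi",
                 stringsAsFactors = FALSE)
    } else {
      tt <- do.call(welch_t, unname(as.list(r)))
      d <- do.call(cohens_d, unname(as.list(r)))
      data.frame(variable = nm, statistic = tt$statistic, p = tt$p,
                 effect_size = d, effect_type = "cohens_d",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
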