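# Delimited-text serialisation of trial records and covariates ---------

.trial_cols <- c("subject_id", "group", "block", "trial", "valence",
                 "pair_id", "choice", "responded", "outcome", "rt_s")

#' Validate a trial-record data frame
#'
#' Checks the structural invariants of trial records: required columns,
#' legal factor levels, zero outcomes on neutral trials, and missing
#' choice/outcome exactly when the trial was unresponded. Errors name
#' the first offending row.
#'
#' @param trials Data frame of trial records.
#' @return The validated data frame, invisibly.
#' @export
validate_trials <- function(trials) {
  missing <- setdiff(.trial_cols, names(trials))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  fail <- function(rows, what) {
    if (any(rows))
      stop(sprintf("invalid trial record at row %d: %s", which(rows)[1], what),
           call. = FALSE)
  }
  fail(!trials$valence %in% c("reward", "punish", "neutral"),
       "valence must be reward/punish/neutral")
  fail(!trials$group %in% c("placebo", "drug"), "group must be placebo/drug")
  fail(!is.na(trials$choice) &
         !trials$choice %in% c("good_stimulus", "bad_stimulus"),
       "choice must be good_stimulus/bad_stimulus or missing")
  fail(is.na(trials$responded), "responded must be TRUE/FALSE")
  resp <- as.logical(trials$responded)
  fail(resp & (is.na(trials$choice) | is.na(trials$outcome)),
       "responded trials need a choice and an outcome")
  fail(!resp & (!is.na(trials$choice) | !is.na(trials$outcome)),
       "unresponded trials must have missing choice and outcome")
  fail(resp & trials$valence == "neutral" & trials$outcome != 0,
       "neutral trials must have outcome 0")
  fail(resp & !trials$outcome %in% c(-1, 0, 1),
       "outcome must be -1, 0 or +1")
  invisible(trials)
}

#' Read and write trial records as CSV
#'
#' Comma-delimited UTF-8 text with one header line
#' (`subject_id,group,block,trial,valence,pair_id,choice,responded,outcome,rt_s`)
#' and empty fields for missing values. `read_trials()` validates every
#' structural invariant and reports the offending line on failure;
#' write-then-read is an identity on valid records.
#'
#' @param trials Data frame of trial records.
#' @param path File path.
#' @return `read_trials()` returns the validated data frame.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials[, .trial_cols], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = "",
                            colClasses = c(subject_id = "character",
                                           group = "character",
                                           valence = "character",
                                           pair_id = "character",
                                           choice = "character"))
  out <- tryCatch(validate_trials(trials), error = function(e) {
    # data row r is file line r + 1 (header)
    msg <- conditionMessage(e)
    m <- regmatches(msg, regexec("row ([0-9]+)", msg))[[1]]
    if (length(m) == 2)
      msg <- sub(sprintf("row %s", m[2]),
                 sprintf("line %d", as.integer(m[2]) + 1L), msg)
    stop("parse error in ", path, ": ", msg, call. = FALSE)
  })
  out$responded <- as.logical(out$responded)
  out
}

#' Read and write subject covariates as CSV
#'
#' Columns `subject_id, group, age, sex, iq`.
#'
#' @param covariates Data frame of covariates.
#' @param path File path.
#' @return `read_covariates()` returns the data frame.
#' @export
write_covariates <- function(covariates, path) {
  need <- c("subject_id", "group", "age", "sex", "iq")
  missing <- setdiff(need, names(covariates))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  utils::write.csv(covariates[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(subject_id = "character",
                                 group = "character", sex = "character"))
}
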