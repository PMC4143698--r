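#' Select the first available visit per subject
#'
#' Forms a cross-sectional data set from longitudinal records by taking, for
#' each subject, the lowest-numbered visit at which SBP and all four
#' covariates (age, sex, smoking, blood-pressure medication) are observed.
#' Subjects with no complete visit are dropped; the number dropped is
#' reported in a message.
#'
#' @param pheno Long-format data.frame with columns `subject_id`, `visit`,
#'   `SBP`, `age`, `sex`, `smoke`, `bpmed` (at most 4 visits per subject).
#' @return One row per retained subject, with `source_visit` recording the
#'   visit used.
#' @export
select_first_visit <- function(pheno) {
  need <- c("subject_id", "visit", "SBP", "age", "sex", "smoke", "bpmed")
  stopifnot(all(need %in% names(pheno)))
  if (anyDuplicated(pheno[, c("subject_id", "visit")]))
    stop("duplicate (subject, visit) rows in phenotype table")
  if (max(table(pheno$subject_id)) > 4)
    stop("more than 4 visits per subject")
  complete <- !is.na(pheno$SBP) & !is.na(pheno$age) & !is.na(pheno$sex) &
    !is.na(pheno$smoke) & !is.na(pheno$bpmed)
  cc <- pheno[complete, , drop = FALSE]
  cc <- cc[order(cc$subject_id, cc$visit), , drop = FALSE]
  first <- cc[!duplicated(cc$subject_id), , drop = FALSE]
  n_in <- length(unique(pheno$subject_id))
  n_dropped <- n_in - nrow(first)
  if (n_dropped > 0)
    message(n_dropped, " of ", n_in,
            " subjects had no complete visit and were dropped")
  first$source_visit <- first$visit
  rownames(first) <- NULL
  first
}

#' Log-transform and standardize SBP
#'
#' Returns `(log(x) - mean) / sd`, with the sample SD (denominator n - 1),
#' so the output has mean 0 and unit variance. The log tames the right skew
#' of blood pressure; unit variance makes the model's residual variance
#' directly interpretable as 1 - R-squared.
#'
#' @param sbp Vector of positive SBP values (mmHg).
#' @return A list: `y` (standardized logSBP), `log_mean`, `log_sd` (the
#'   transform record, for back-transformation).
#' @export
log_standardize <- function(sbp) {
  if (length(sbp) < 2) stop("need at least 2 observations to standardize")
  if (any(is.na(sbp))) stop("SBP contains missing values")
  if (any(sbp <= 0)) stop("SBP values must be positive")
  lx <- log(sbp)
  m <- mean(lx)
  s <- stats::sd(lx)
  if (s == 0) stop("logSBP has zero variance; cannot standardize")
  list(y = (lx - m) / s, log_mean = m, log_sd = s)
}

#' Build the fixed-covariate matrix
#'
#' Columns in fixed order: age (years), sex, smoking, medication (all binary
#' but age). The intercept is handled separately by the regression model. A
#' constant column triggers a warning (rank deficiency with the intercept).
#'
#' @param records Cross-sectional records from [select_first_visit()].
#' @return n x 4 numeric matrix with column names
#'   `c("age", "sex", "smoke", "bpmed")`.
#' @export
build_covariate_matrix <- function(records) {
  need <- c("age", "sex", "smoke", "bpmed")
  stopifnot(all(need %in% names(records)))
  Z <- as.matrix(records[, need])
  if (anyNA(Z)) stop("covariates contain missing values")
  const <- apply(Z, 2, function(col) length(unique(col)) == 1)
  if (any(const))
    warning("constant covariate column(s): ",
            paste(need[const], collapse = ", "),
            " (rank deficient with intercept)")
  storage.mode(Z) <- "double"
  Z
}

#' Prepare the analysis-ready cohort
#'
#' Convenience wrapper: first-available-visit selection, log transform and
#' unit-variance standardization of SBP, and covariate matrix assembly.
#'
#' @param pheno Long-format phenotype table.
#' @return A list: `records`, `y` (standardized logSBP), `Z` (covariate
#'   matrix), `transform` (logSBP mean/sd), `n_dropped`.
#' @export
prepare_cohort <- function(pheno) {
  n_in <- length(unique(pheno$subject_id))
  records <- select_first_visit(pheno)
  tr <- log_standardize(records$SBP)
  Z <- build_covariate_matrix(records)
  rownames(Z) <- records$subject_id
  list(records = records, y = tr$y, Z = Z,
       transform = list(log_mean = tr$log_mean, log_sd = tr$log_sd),
       n_dropped = n_in - nrow(records))
}
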