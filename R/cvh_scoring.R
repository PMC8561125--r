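.cvh_levels <- c("poor", "intermediate", "ideal")

#' Clinical CVH category factor
#'
#' Builds the ordered poor/intermediate/ideal factor used throughout the
#' package. Points are `as.integer(category) - 1`: poor = 0, intermediate = 1,
#' ideal = 2.
#'
#' @param x character vector of category labels (or `NA`).
#' @return factor with levels `poor < intermediate < ideal`.
#' @export
cvh_category <- function(x) {
  factor(x, levels = .cvh_levels, ordered = TRUE)
}

#' Categorize body mass index
#'
#' Applies the AHA clinical thresholds for the BMI component of the clinical
#' cardiovascular health score. Adults (age >= 20 years) are classified on
#' BMI in kg/m^2: ideal below 25, intermediate 25 to <30, poor at 30 and
#' above. Children and adolescents (age < 20) are classified on the age- and
#' sex-specific BMI percentile: ideal below the 85th, intermediate 85th-95th,
#' poor above the 95th.
#'
#' A missing required input (BMI for adults, percentile for youths) yields
#' `NA`, marking the factor uncategorizable rather than raising an error.
#'
#' @param age age in years (vector).
#' @param bmi body mass index, kg/m^2.
#' @param bmi_pct BMI-for-age percentile in \[0, 100\]; used when `age < 20`.
#' @return a [cvh_category()] factor.
#' @export
#' @examples
#' categorize_bmi(c(30, 30, 12), bmi = c(24.9, 25, NA), bmi_pct = c(NA, NA, 96))
categorize_bmi <- function(age, bmi = NULL, bmi_pct = NULL) {
  n <- length(age)
  bmi <- .recycle_or_na(bmi, n)
  bmi_pct <- .recycle_or_na(bmi_pct, n)
  out <- rep(NA_character_, n)

  adult <- !is.na(age) & age >= 20 & !is.na(bmi)
  out[adult & bmi < 25] <- "ideal"
  out[adult & bmi >= 25 & bmi < 30] <- "intermediate"
  out[adult & bmi >= 30] <- "poor"

  ped <- !is.na(age) & age < 20 & !is.na(bmi_pct)
  out[ped & bmi_pct < 85] <- "ideal"
  out[ped & bmi_pct >= 85 & bmi_pct <= 95] <- "intermediate"
  out[ped & bmi_pct > 95] <- "poor"

  cvh_category(out)
}

#' Categorize blood pressure
#'
#' Adults (age >= 18): poor if SBP >= 140 or DBP >= 90 mm Hg; ideal if
#' SBP < 120 and DBP < 80 and unmedicated; intermediate otherwise (including
#' pressure treated to below 120/80). Youths (age < 18) use the pediatric BP
#' percentile: poor above the 95th percentile; ideal below the 90th with
#' absolute SBP < 120 and DBP < 80; intermediate otherwise (90th-95th
#' percentile, or SBP >= 120, or DBP >= 80). The pediatric rows of the AHA
#' criteria carry no medication clause, so `bp_med` only affects ages >= 18.
#'
#' @param age age in years.
#' @param sbp,dbp systolic / diastolic blood pressure, mm Hg.
#' @param bp_pct pediatric BP percentile in \[0, 100\]; used when `age < 18`.
#' @param bp_med logical, on antihypertensive medication. `NA` is treated as
#'   `FALSE` (unmedicated), the conventional assumption when cohort data lack
#'   the flag.
#' @return a [cvh_category()] factor.
#' @export
categorize_bp <- function(age, sbp = NULL, dbp = NULL, bp_pct = NULL,
                          bp_med = FALSE) {
  n <- length(age)
  sbp <- .recycle_or_na(sbp, n)
  dbp <- .recycle_or_na(dbp, n)
  bp_pct <- .recycle_or_na(bp_pct, n)
  bp_med <- .as_flag(bp_med, n)
  out <- rep(NA_character_, n)

  adult <- !is.na(age) & age >= 18 & !is.na(sbp) & !is.na(dbp)
  out[adult] <- "intermediate"
  out[adult & sbp < 120 & dbp < 80 & !bp_med] <- "ideal"
  out[adult & (sbp >= 140 | dbp >= 90)] <- "poor"

  ped <- !is.na(age) & age < 18 & !is.na(bp_pct) & !is.na(sbp) & !is.na(dbp)
  out[ped] <- "intermediate"
  out[ped & bp_pct < 90 & sbp < 120 & dbp < 80] <- "ideal"
  out[ped & bp_pct > 95] <- "poor"

  cvh_category(out)
}

#' Categorize total cholesterol
#'
#' Poor at 220 mg/dL and above; ideal below 185 mg/dL unmedicated;
#' intermediate otherwise (185-219, or treated to below 185).
#'
#' @param total_chol total cholesterol, mg/dL.
#' @param lipid_med logical, on lipid-lowering medication (`NA` -> `FALSE`).
#' @return a [cvh_category()] factor.
#' @export
categorize_cholesterol <- function(total_chol, lipid_med = FALSE) {
  n <- length(total_chol)
  lipid_med <- .as_flag(lipid_med, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(total_chol)
  out[ok] <- "intermediate"
  out[ok & total_chol < 185 & !lipid_med] <- "ideal"
  out[ok & total_chol >= 220] <- "poor"
  cvh_category(out)
}

#' Categorize fasting glucose
#'
#' Poor at 126 mg/dL and above; ideal below 100 mg/dL unmedicated;
#' intermediate otherwise (100-125, or treated to below 100).
#'
#' @param glucose fasting blood glucose, mg/dL.
#' @param glucose_med logical, on glucose-lowering medication (`NA` -> `FALSE`).
#' @return a [cvh_category()] factor.
#' @export
categorize_glucose <- function(glucose, glucose_med = FALSE) {
  n <- length(glucose)
  glucose_med <- .as_flag(glucose_med, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(glucose)
  out[ok] <- "intermediate"
  out[ok & glucose < 100 & !glucose_med] <- "ideal"
  out[ok & glucose >= 126] <- "poor"
  cvh_category(out)
}

#' Score all examinations in a long-format dataset
#'
#' Appends per-factor category columns (`bmi_cat`, `bp_cat`, `chol_cat`,
#' `glu_cat`), the summed clinical CVH score (`cvh_score`, 0-8) and a
#' `complete` flag (all four factors categorizable at that examination).
#'
#' If `data` carries no raw clinical measurement columns but already has a
#' `cvh_score` column (as produced by the score-mode synthetic generator),
#' scoring is skipped and completeness is defined as a non-missing score.
#'
#' @param data data frame of examination records; see [read_cvh_csv()] for the
#'   column schema.
#' @param percentile_provider optional function `f(data)` returning `data`
#'   with `bmi_pct` / `bp_pct` filled in from an external pediatric reference;
#'   the default expects percentiles already present where required.
#' @return `data` with category, `cvh_score` and `complete` columns.
#' @export
score_exams <- function(data, percentile_provider = NULL) {
  if (!is.null(percentile_provider)) data <- percentile_provider(data)
  raw_cols <- c("bmi", "bmi_pct", "sbp", "dbp", "bp_pct", "total_chol", "glucose")
  has_raw <- any(raw_cols %in% names(data))
  if (!has_raw && "cvh_score" %in% names(data)) {
    data$complete <- !is.na(data$cvh_score)
    return(data)
  }
  if (!"age" %in% names(data)) stop("scoring requires an 'age' column")
  getcol <- function(nm) if (nm %in% names(data)) data[[nm]] else NULL
  data$bmi_cat <- categorize_bmi(data$age, getcol("bmi"), getcol("bmi_pct"))
  data$bp_cat <- categorize_bp(data$age, getcol("sbp"), getcol("dbp"),
                               getcol("bp_pct"), getcol("bp_med"))
  data$chol_cat <- categorize_cholesterol(
    .recycle_or_na(getcol("total_chol"), nrow(data)), getcol("lipid_med"))
  data$glu_cat <- categorize_glucose(
    .recycle_or_na(getcol("glucose"), nrow(data)), getcol("glucose_med"))
  pts <- cbind(as.integer(data$bmi_cat), as.integer(data$bp_cat),
               as.integer(data$chol_cat), as.integer(data$glu_cat)) - 1L
  data$complete <- rowSums(is.na(pts)) == 0L
  data$cvh_score <- ifelse(data$complete, rowSums(pts), NA_integer_)
  data
}

#' Clinical CVH score for a single examination
#'
#' Convenience wrapper around [score_exams()] for one record (a one-row data
#' frame or a named list). The score is the sum of 0/1/2 points over the four
#' clinical factors and is only defined when all four are categorizable.
#'
#' @param record one examination: named list or one-row data frame.
#' @return list with `categories` (named factor vector), `score` (integer 0-8
#'   or `NA`) and `complete` (logical).
#' @export
#' @examples
#' clinical_cvh_score(list(age = 30, bmi = 24, sbp = 118, dbp = 78,
#'                         total_chol = 180, glucose = 95))
clinical_cvh_score <- function(record) {
  df <- as.data.frame(record, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 1L)
  s <- score_exams(df)
  list(
    categories = c(bmi = as.character(s$bmi_cat), bp = as.character(s$bp_cat),
                   cholesterol = as.character(s$chol_cat),
                   glucose = as.character(s$glu_cat)),
    score = if (isTRUE(s$complete)) as.integer(s$cvh_score) else NA_integer_,
    complete = isTRUE(s$complete)
  )
}

#' Score a dataset and apply the completeness inclusion filter
#'
#' Scores every examination, drops examinations where any of the four
#' clinical factors is uncategorizable, and excludes subjects left with zero
#' complete examinations — the "at least one clinical CVH score" inclusion
#' rule. An inclusion report records the attrition.
#'
#' @inheritParams score_exams
#' @return object of class `cvh_scored`: list with `data` (the retained,
#'   scored examinations) and `report` (counts of examinations and subjects
#'   before/after filtering).
#' @export
score_dataset <- function(data, percentile_provider = NULL) {
  if (!"subject_id" %in% names(data)) stop("dataset requires a 'subject_id' column")
  scored <- score_exams(data, percentile_provider)
  n_exams <- nrow(scored)
  n_subjects <- length(unique(scored$subject_id))
  keep <- scored$complete %in% TRUE
  out <- scored[keep, , drop = FALSE]
  rownames(out) <- NULL
  res <- list(
    data = out,
    report = list(
      n_exams = n_exams,
      n_exams_complete = nrow(out),
      n_subjects = n_subjects,
      n_subjects_retained = length(unique(out$subject_id))
    )
  )
  class(res) <- "cvh_scored"
  res
}

#' @export
print.cvh_scored <- function(x, ...) {
  r <- x$report
  cat("Clinical CVH scored dataset\n")
  cat(sprintf("  examinations: %d of %d complete (all 4 factors)\n",
              r$n_exams_complete, r$n_exams))
  cat(sprintf("  subjects:     %d of %d retained (>= 1 complete exam)\n",
              r$n_subjects_retained, r$n_subjects))
  invisible(x)
}

# internal: recycle a scalar, keep a vector, or fill NA
.recycle_or_na <- function(x, n) {
  if (is.null(x)) return(rep(NA_real_, n))
  if (length(x) == 1L) return(rep(as.numeric(x), n))
  stopifnot(length(x) == n)
  as.numeric(x)
}

# internal: medication flags; NA means unmedicated
.as_flag <- function(x, n) {
  if (is.null(x)) return(rep(FALSE, n))
  x <- as.logical(x)
  if (length(x) == 1L) x <- rep(x, n)
  stopifnot(length(x) == n)
  x[is.na(x)] <- FALSE
  x
}
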