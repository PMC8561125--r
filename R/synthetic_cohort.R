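# Synthetic multi-cohort longitudinal generator.
#
# Emulates a pooled design of five cohorts with overlapping age windows
# spanning ages 8-55.99 years, repeated visits, subject-level random
# intercept and slope, and a continuous piecewise-linear population mean for
# the clinical CVH score.

#' Ground-truth piecewise-linear mixed model
#'
#' Describes the data-generating process for the synthetic cohort: a
#' population mean that is continuous and piecewise linear in age with up to
#' two change points, additive categorical covariate effects, a bivariate
#' normal random intercept and slope per subject, and i.i.d. Gaussian
#' residual noise. The intercept and the random effects are parameterized at
#' age 8 years, the entry age of the design.
#'
#' @param intercept_at_age8 population mean score at age 8 for the reference
#'   covariate levels, in score points.
#' @param psi change-point ages (years), strictly increasing, each inside
#'   (8, 55.99); length 0-2.
#' @param segment_slopes slope of the mean per segment, points/year; length
#'   `length(psi) + 1`.
#' @param covariate_effects named list of named numeric vectors, e.g.
#'   `list(sex = c(male = 0.05))`; levels not listed have effect 0.
#' @param re_sd_intercept,re_sd_slope standard deviations of the subject
#'   random intercept (points) and slope (points/year).
#' @param re_corr correlation between random intercept and slope, in \[-1, 1\].
#' @param resid_sd residual standard deviation, points.
#' @return object of class `cvh_true_model`.
#' @export
true_model <- function(intercept_at_age8, psi = numeric(), segment_slopes,
                       covariate_effects = list(),
                       re_sd_intercept = 0, re_sd_slope = 0, re_corr = 0,
                       resid_sd = 0) {
  psi <- as.numeric(psi)
  if (length(psi) > 2) stop("at most 2 change points are supported")
  if (length(psi) && (is.unsorted(psi, strictly = TRUE) ||
                      any(psi <= 8) || any(psi >= 55.99)))
    stop("psi must be strictly increasing and inside (8, 55.99)")
  if (length(segment_slopes) != length(psi) + 1L)
    stop("need exactly length(psi) + 1 segment slopes")
  if (re_sd_intercept < 0 || re_sd_slope < 0 || resid_sd < 0)
    stop("standard deviations must be nonnegative")
  if (abs(re_corr) > 1) stop("re_corr must lie in [-1, 1]")
  structure(list(
    intercept_at_age8 = intercept_at_age8,
    psi = psi,
    segment_slopes = as.numeric(segment_slopes),
    covariate_effects = covariate_effects,
    re_sd_intercept = re_sd_intercept,
    re_sd_slope = re_sd_slope,
    re_corr = re_corr,
    resid_sd = resid_sd
  ), class = "cvh_true_model")
}

#' Sampling design of one synthetic cohort
#'
#' @param name cohort label.
#' @param n_subjects number of subjects (>= 1).
#' @param baseline_age_range numeric length-2, baseline ages drawn uniformly
#'   within this window (subset of \[8, 55.99\]).
#' @param visit_interval years between scheduled visits (> 0).
#' @param n_visits scheduled visits per subject; visits past age 55.99 are
#'   truncated.
#' @param sex_p probability a subject is female.
#' @param race_levels named probability vector over race labels.
#' @return object of class `cvh_cohort_design`.
#' @export
cohort_design <- function(name, n_subjects, baseline_age_range,
                          visit_interval, n_visits, sex_p = 0.5,
                          race_levels = c(White = 1)) {
  stopifnot(n_subjects >= 1, visit_interval > 0, n_visits >= 1,
            length(baseline_age_range) == 2,
            baseline_age_range[1] <= baseline_age_range[2])
  if (baseline_age_range[1] < 8 || baseline_age_range[2] > 55.99)
    stop("baseline_age_range must lie within [8, 55.99]")
  if (abs(sum(race_levels) - 1) > 1e-8) stop("race_levels must sum to 1")
  structure(list(name = name, n_subjects = as.integer(n_subjects),
                 baseline_age_range = as.numeric(baseline_age_range),
                 visit_interval = visit_interval,
                 n_visits = as.integer(n_visits),
                 sex_p = sex_p, race_levels = race_levels),
            class = "cvh_cohort_design")
}

#' Generator configuration
#'
#' @param true_model a [true_model()].
#' @param cohorts list of [cohort_design()] objects (nonempty).
#' @param seed integer RNG seed; regeneration with the same config is
#'   bit-identical.
#' @param missing_exam_p probability in \[0, 1) that a visit is missing at
#'   least one of the four clinical factors (and so carries no score).
#' @param raw_metric_mode if `TRUE`, [generate_raw_metrics()] may be used to
#'   emit raw clinical measurements instead of latent scores.
#' @param discretize if `TRUE`, [generate_cvh_scores()] clamps the continuous
#'   latent score into \[0, 8\] and rounds to an integer.
#' @param raw_noise_scale multiplier on the raw-metric noise components
#'   (0 = deterministic means, 1 = calibrated dispersion).
#' @return object of class `cvh_generator_config`.
#' @export
generator_config <- function(true_model, cohorts, seed = 1L,
                             missing_exam_p = 0, raw_metric_mode = FALSE,
                             discretize = FALSE, raw_noise_scale = 1) {
  if (!inherits(true_model, "cvh_true_model")) stop("true_model must be a cvh_true_model")
  if (!length(cohorts)) stop("configuration error: empty cohort list")
  if (!all(vapply(cohorts, inherits, TRUE, "cvh_cohort_design")))
    stop("cohorts must be cvh_cohort_design objects")
  if (missing_exam_p < 0 || missing_exam_p > 1)
    stop("missing_exam_p must lie in [0, 1]")
  structure(list(true_model = true_model, cohorts = cohorts,
                 seed = as.integer(seed), missing_exam_p = missing_exam_p,
                 raw_metric_mode = raw_metric_mode, discretize = discretize,
                 raw_noise_scale = raw_noise_scale),
            class = "cvh_generator_config")
}

#' Continuous piecewise-linear population mean
#'
#' Evaluates the ground-truth mean score at given ages:
#' `mu(age) = intercept + s1 * (age - 8) + sum_j (s_{j+1} - s_j) * (age - psi_j)_+`,
#' which is continuous at every change point by construction.
#'
#' @param age ages in years.
#' @param model a [true_model()].
#' @return numeric vector of mean scores.
#' @export
piecewise_mean <- function(age, model) {
  s <- model$segment_slopes
  mu <- model$intercept_at_age8 + s[1] * (age - 8)
  if (length(model$psi)) {
    d <- diff(s)
    for (j in seq_along(model$psi))
      mu <- mu + d[j] * pmax(age - model$psi[j], 0)
  }
  mu
}

#' Additive covariate effect for given levels
#'
#' @param model a [true_model()].
#' @param ... named character vectors of covariate levels, e.g.
#'   `sex = "male", race = "White"`.
#' @return numeric vector of additive effects (points).
#' @export
covariate_effect <- function(model, ...) {
  levs <- list(...)
  n <- max(lengths(levs), 1L)
  eff <- numeric(n)
  for (cov in names(levs)) {
    tab <- model$covariate_effects[[cov]]
    if (is.null(tab)) next
    v <- tab[as.character(levs[[cov]])]
    v[is.na(v)] <- 0
    eff <- eff + v
  }
  unname(eff)
}

# internal: subject-level frame (id, cohort, sex, race, baseline age, b0, b1)
.draw_subjects <- function(config) {
  tm <- config$true_model
  pieces <- lapply(config$cohorts, function(co) {
    n <- co$n_subjects
    baseline <- runif(n, co$baseline_age_range[1], co$baseline_age_range[2])
    sex <- ifelse(runif(n) < co$sex_p, "female", "male")
    race <- sample(names(co$race_levels), n, replace = TRUE,
                   prob = co$race_levels)
    z1 <- rnorm(n); z2 <- rnorm(n)
    b0 <- tm$re_sd_intercept * z1
    b1 <- tm$re_sd_slope * (tm$re_corr * z1 + sqrt(1 - tm$re_corr^2) * z2)
    data.frame(cohort = co$name,
               subject_id = sprintf("%s_%04d", co$name, seq_len(n)),
               sex = sex, race = race, baseline_age = baseline,
               n_visits = co$n_visits, visit_interval = co$visit_interval,
               b0 = b0, b1 = b1, stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

# internal: expand subjects to visit rows, truncated at age 55.99
.expand_visits <- function(subjects) {
  idx <- rep(seq_len(nrow(subjects)), subjects$n_visits)
  k <- sequence(subjects$n_visits) - 1L
  rows <- subjects[idx, , drop = FALSE]
  rows$age <- rows$baseline_age + k * rows$visit_interval
  rows <- rows[rows$age <= 55.99, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Generate a long-format dataset of continuous clinical CVH scores
#'
#' Simulates `score = mu(age) + covariate effects + b0 + b1 * (age - 8) + eps`
#' per visit, where `mu` is the piecewise-linear population mean of the
#' configured [true_model()]. Visits occur at `baseline_age + k *
#' visit_interval` and are truncated at age 55.99. With probability
#' `missing_exam_p` a visit carries no score (`NA`), emulating an incomplete
#' examination. Deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return data frame with columns `subject_id, cohort, sex, race, age,
#'   cvh_score` (continuous, or clamped/rounded 0-8 integers when
#'   `config$discretize` is `TRUE`).
#' @export
generate_cvh_scores <- function(config) {
  stopifnot(inherits(config, "cvh_generator_config"))
  tm <- config$true_model
  set.seed(config$seed)
  rows <- .expand_visits(.draw_subjects(config))
  n <- nrow(rows)
  eff <- covariate_effect(tm, sex = rows$sex, race = rows$race,
                          cohort = rows$cohort)
  score <- piecewise_mean(rows$age, tm) + eff +
    rows$b0 + rows$b1 * (rows$age - 8) +
    (if (tm$resid_sd > 0) rnorm(n, 0, tm$resid_sd) else 0)
  if (config$discretize) score <- pmin(pmax(round(score), 0), 8)
  if (config$missing_exam_p > 0)
    score[runif(n) < config$missing_exam_p] <- NA_real_
  out <- rows[, c("subject_id", "cohort", "sex", "race", "age")]
  out$cvh_score <- score
  out
}

# Anchor means/SDs of the raw clinical metrics at ages 8/17/37/55 by sex;
# trajectories interpolate linearly between anchors and are flat outside.
.raw_anchor_ages <- c(8, 17, 37, 55)
.raw_anchors <- list(
  female = list(
    bmi        = list(mean = c(17.2, 22.2, 27.5, 31.4), sd = c(3.1, 4.5, 7.2, 7.7)),
    sbp        = list(mean = c(96.5, 110.7, 109.7, 117.6), sd = c(8.8, 9.0, 14.4, 15.9)),
    dbp        = list(mean = c(45.1, 61.1, 70.7, 72.6), sd = c(12.0, 8.6, 11.0, 11.2)),
    total_chol = list(mean = c(167.6, 163.3, 181.4, 201.7), sd = c(27.9, 30.6, 33.1, 36.3)),
    glucose    = list(mean = c(80.7, 81.6, 90.1, 95.9), sd = c(8.0, 8.2, 18.0, 15.8))
  ),
  male = list(
    bmi        = list(mean = c(17.0, 22.3, 27.6, 30.3), sd = c(2.9, 4.1, 5.4, 6.1)),
    sbp        = list(mean = c(96.8, 117.0, 116.2, 121.4), sd = c(8.3, 11.7, 12.9, 15.9)),
    dbp        = list(mean = c(44.1, 59.6, 75.0, 73.9), sd = c(10.9, 10.3, 10.4, 10.3)),
    total_chol = list(mean = c(164.2, 151.1, 193.3, 182.4), sd = c(25.8, 28.2, 40.5, 35.9)),
    glucose    = list(mean = c(82.4, 86.0, 96.3, 104.0), sd = c(9.0, 8.4, 25.9, 21.9))
  )
)

#' Expected raw clinical metric value at a given age and sex
#'
#' Linear interpolation between the calibrated anchor ages (8, 17, 37, 55
#' years), flat beyond the outermost anchors.
#'
#' @param metric one of `"bmi"`, `"sbp"`, `"dbp"`, `"total_chol"`, `"glucose"`.
#' @param sex `"female"` or `"male"` (vector allowed).
#' @param age ages in years.
#' @param what `"mean"` or `"sd"`.
#' @return numeric vector.
#' @export
raw_metric_mean <- function(metric, sex, age, what = c("mean", "sd")) {
  what <- match.arg(what)
  metric <- match.arg(metric, names(.raw_anchors$female))
  n <- max(length(sex), length(age))
  sex <- rep_len(sex, n); age <- rep_len(age, n)
  out <- numeric(n)
  for (s in c("female", "male")) {
    i <- sex == s
    if (!any(i)) next
    a <- .raw_anchors[[s]][[metric]][[what]]
    out[i] <- approx(.raw_anchor_ages, a, xout = age[i], rule = 2)$y
  }
  out
}

#' Generate raw clinical metric examination records
#'
#' Emits one `ExamRecord` row per visit with BMI, systolic/diastolic BP,
#' total cholesterol and fasting glucose drawn around sex- and age-specific
#' mean trajectories anchored at ages 8, 17, 37 and 55 years. Half of the
#' dispersion is a subject-level random effect, half is visit-level noise, so
#' the marginal SD matches the calibrated age-specific SD. Pediatric
#' percentile columns are emitted directly from the simulated within-age,
#' within-sex rank: `bmi_pct` for ages < 20 and `bp_pct` (the larger of the
#' SBP and DBP ranks) for ages < 18. Medication flags are all `FALSE`.
#'
#' @param config a [generator_config()] with `raw_metric_mode = TRUE`.
#' @return data frame with the full examination-record schema
#'   (`subject_id, cohort, sex, race, age, bmi, bmi_pct, sbp, dbp, bp_pct,
#'   total_chol, glucose, bp_med, lipid_med, glucose_med`).
#' @export
generate_raw_metrics <- function(config) {
  stopifnot(inherits(config, "cvh_generator_config"))
  if (!config$raw_metric_mode)
    stop("generate_raw_metrics requires raw_metric_mode = TRUE")
  set.seed(config$seed)
  subjects <- .draw_subjects(config)
  rows <- .expand_visits(subjects)
  n <- nrow(rows)
  scale <- config$raw_noise_scale
  metrics <- names(.raw_anchors$female)
  # per-subject standardized effects, one per metric
  u <- matrix(rnorm(nrow(subjects) * length(metrics)), nrow(subjects),
              length(metrics), dimnames = list(NULL, metrics))
  subj_index <- match(rows$subject_id, subjects$subject_id)
  z <- list()
  for (m in metrics) {
    sd_a <- raw_metric_mean(m, rows$sex, rows$age, "sd")
    zm <- sqrt(0.5) * u[subj_index, m] + sqrt(0.5) * rnorm(n)
    rows[[m]] <- raw_metric_mean(m, rows$sex, rows$age, "mean") +
      scale * sd_a * zm
    z[[m]] <- scale * zm  # standardized deviation, drives percentiles
  }
  rows$bmi_pct <- ifelse(rows$age < 20, 100 * pnorm(z$bmi), NA_real_)
  rows$bp_pct <- ifelse(rows$age < 18,
                        100 * pmax(pnorm(z$sbp), pnorm(z$dbp)), NA_real_)
  rows$bp_med <- FALSE
  rows$lipid_med <- FALSE
  rows$glucose_med <- FALSE
  if (config$missing_exam_p > 0) {
    miss <- runif(n) < config$missing_exam_p
    which_factor <- sample(c("bmi", "bp", "chol", "glu"), n, replace = TRUE)
    blank <- function(cols, sel) for (cl in cols) rows[[cl]][sel] <<- NA_real_
    blank(c("bmi", "bmi_pct"), miss & which_factor == "bmi")
    blank(c("sbp", "dbp", "bp_pct"), miss & which_factor == "bp")
    blank("total_chol", miss & which_factor == "chol")
    blank("glucose", miss & which_factor == "glu")
  }
  rows[, c("subject_id", "cohort", "sex", "race", "age", "bmi", "bmi_pct",
           "sbp", "dbp", "bp_pct", "total_chol", "glucose", "bp_med",
           "lipid_med", "glucose_med")]
}

#' Built-in generator presets
#'
#' * `"paper2021"` — the calibrated pooled-cohort preset: five cohorts with
#'   overlapping age windows spanning ages 8-55.99, about 2,000 subjects,
#'   ground truth change points at 16.9 and 37.2 years with segment slopes
#'   0.01 / -0.07 / -0.08 points/year, and variance components chosen so the
#'   first-visit score distribution has mean near 6.9 and SD near 1.2.
#' * `"single_break"` — one change point at age 25, slopes 0 / -0.08; a
#'   single broad cohort. The canonical one-break fixture for estimator and
#'   coverage studies.
#' * `"linear_null"` — no change point, one slope; for type-I-error and
#'   model-selection null suites.
#'
#' @param name preset name.
#' @param seed RNG seed stored in the returned config.
#' @param n_subjects optional total subject count; cohort sizes are scaled
#'   proportionally (each kept >= 1).
#' @param ... further arguments passed to [generator_config()] (e.g.
#'   `missing_exam_p`, `discretize`, `raw_metric_mode`).
#' @return a [generator_config()].
#' @export
#' @examples
#' cfg <- cvh_preset("single_break", seed = 7, n_subjects = 50)
#' head(generate_cvh_scores(cfg))
cvh_preset <- function(name, seed = 1L, n_subjects = NULL, ...) {
  presets <- c("paper2021", "single_break", "linear_null")
  if (!name %in% presets)
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(presets, collapse = ", ")))
  if (name == "paper2021") {
    tm <- true_model(
      intercept_at_age8 = 6.95,
      psi = c(16.9, 37.2),
      segment_slopes = c(0.01, -0.07, -0.08),
      covariate_effects = list(
        sex = c(male = 0.05),
        race = c(White = 0.10),
        cohort = c(YoungFinns = 0.10, CARDIA = -0.05, STRIP = 0.10)
      ),
      re_sd_intercept = 0.95, re_sd_slope = 0.02, re_corr = -0.2,
      resid_sd = 0.7
    )
    cohorts <- list(
      cohort_design("Bogalusa", 1004, c(8, 17), 4, 9, sex_p = 0.50,
                    race_levels = c(White = 0.65, Black = 0.35)),
      cohort_design("CARDIA", 556, c(18, 30), 5, 8, sex_p = 0.55,
                    race_levels = c(White = 0.50, Black = 0.50)),
      cohort_design("YoungFinns", 342, c(8, 18), 4, 8, sex_p = 0.52,
                    race_levels = c(White = 1)),
      cohort_design("HeartBeat", 45, c(8, 14), 1, 5, sex_p = 0.50,
                    race_levels = c(White = 0.80, Black = 0.20)),
      cohort_design("STRIP", 53, c(8, 11), 1, 6, sex_p = 0.49,
                    race_levels = c(White = 1))
    )
  } else if (name == "single_break") {
    tm <- true_model(
      intercept_at_age8 = 7.0,
      psi = 25,
      segment_slopes = c(0, -0.08),
      covariate_effects = list(),
      re_sd_intercept = 0.9, re_sd_slope = 0.02, re_corr = -0.2,
      resid_sd = 0.7
    )
    cohorts <- list(
      cohort_design("main", 300, c(8, 44), 4, 4, sex_p = 0.5,
                    race_levels = c(White = 0.7, Black = 0.3))
    )
  } else { # linear_null
    tm <- true_model(
      intercept_at_age8 = 7.0,
      psi = numeric(),
      segment_slopes = -0.03,
      covariate_effects = list(),
      re_sd_intercept = 0.9, re_sd_slope = 0.02, re_corr = -0.2,
      resid_sd = 0.7
    )
    cohorts <- list(
      cohort_design("main", 300, c(8, 44), 4, 4, sex_p = 0.5,
                    race_levels = c(White = 0.7, Black = 0.3))
    )
  }
  if (!is.null(n_subjects)) {
    tot <- sum(vapply(cohorts, `[[`, 1L, "n_subjects"))
    cohorts <- lapply(cohorts, function(co) {
      co$n_subjects <- max(1L, as.integer(round(co$n_subjects * n_subjects / tot)))
      co
    })
  }
  generator_config(tm, cohorts, seed = seed, ...)
}
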