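# Clinical CVH scoring: category thresholds, score arithmetic, inclusion
# filter.

test_that("factor thresholds follow the AHA clinical criteria", {
  cases <- list(
    # BMI: adult kg/m2, pediatric percentile
    list(categorize_bmi(30, bmi = 24.9), "ideal"),
    list(categorize_bmi(30, bmi = 25.0), "intermediate"),
    list(categorize_bmi(30, bmi = 29.99), "intermediate"),
    list(categorize_bmi(30, bmi = 30.0), "poor"),
    list(categorize_bmi(12, bmi_pct = 84.9), "ideal"),
    list(categorize_bmi(12, bmi_pct = 85), "intermediate"),
    list(categorize_bmi(12, bmi_pct = 95), "intermediate"),
    list(categorize_bmi(12, bmi_pct = 96), "poor"),
    # BP: adult absolute, pediatric percentile + absolute demotion
    list(categorize_bp(25, 118, 78, bp_med = FALSE), "ideal"),
    list(categorize_bp(25, 118, 78, bp_med = TRUE), "intermediate"),
    list(categorize_bp(25, 142, 70), "poor"),
    list(categorize_bp(25, 120, 70), "intermediate"),
    list(categorize_bp(25, 118, 90), "poor"),
    list(categorize_bp(15, 112, 70, bp_pct = 92), "intermediate"),
    list(categorize_bp(15, 112, 70, bp_pct = 89), "ideal"),
    list(categorize_bp(15, 122, 70, bp_pct = 50), "intermediate"),
    list(categorize_bp(15, 112, 70, bp_pct = 96), "poor"),
    # cholesterol
    list(categorize_cholesterol(184, FALSE), "ideal"),
    list(categorize_cholesterol(185, FALSE), "intermediate"),
    list(categorize_cholesterol(219, FALSE), "intermediate"),
    list(categorize_cholesterol(220, FALSE), "poor"),
    list(categorize_cholesterol(180, TRUE), "intermediate"),
    # glucose
    list(categorize_glucose(99, FALSE), "ideal"),
    list(categorize_glucose(100, FALSE), "intermediate"),
    list(categorize_glucose(125, FALSE), "intermediate"),
    list(categorize_glucose(126, FALSE), "poor"),
    list(categorize_glucose(95, TRUE), "intermediate")
  )
  for (cs in cases) expect_equal(as.character(cs[[1]]), cs[[2]])
})

test_that("categories partition each factor's domain on a fine grid", {
  bmi_grid <- seq(12, 60, by = 0.037)
  expect_false(anyNA(categorize_bmi(rep(30, length(bmi_grid)),
                                    bmi = bmi_grid)))
  pct_grid <- seq(0, 100, by = 0.073)
  expect_false(anyNA(categorize_bmi(rep(12, length(pct_grid)),
                                    bmi_pct = pct_grid)))
  bp <- expand.grid(sbp = seq(85, 180, by = 1.7), dbp = seq(40, 120, by = 1.3),
                    med = c(TRUE, FALSE))
  expect_false(anyNA(categorize_bp(rep(30, nrow(bp)), bp$sbp, bp$dbp,
                                   bp_med = bp$med)))
  ped <- expand.grid(pct = seq(0, 100, by = 2.1), sbp = seq(85, 150, by = 3.3),
                     dbp = seq(40, 100, by = 2.7))
  expect_false(anyNA(categorize_bp(rep(12, nrow(ped)), ped$sbp, ped$dbp,
                                   bp_pct = ped$pct)))
  chol <- seq(100, 320, by = 0.41)
  for (m in c(TRUE, FALSE))
    expect_false(anyNA(categorize_cholesterol(chol, m)))
  glu <- seq(60, 220, by = 0.37)
  for (m in c(TRUE, FALSE))
    expect_false(anyNA(categorize_glucose(glu, m)))
  # missing required inputs are uncategorizable, not errors
  expect_true(is.na(categorize_bmi(25)))       # adult without bmi
  expect_true(is.na(categorize_bmi(12, bmi = 20)))  # youth without percentile
  expect_true(is.na(categorize_bp(25, 120, NA)))
})

test_that("worsening any single input never increases the score", {
  base <- list(age = 30, bmi = 22, sbp = 110, dbp = 70, total_chol = 170,
               glucose = 90, bp_med = FALSE, lipid_med = FALSE,
               glucose_med = FALSE)
  score_of <- function(rec) clinical_cvh_score(rec)$score
  worsen_paths <- list(
    bmi = seq(22, 40, by = 0.5),
    sbp = seq(110, 165, by = 2),
    dbp = seq(70, 100, by = 1),
    total_chol = seq(170, 260, by = 3),
    glucose = seq(90, 140, by = 2)
  )
  for (field in names(worsen_paths)) {
    scores <- vapply(worsen_paths[[field]], function(v) {
      rec <- base; rec[[field]] <- v; score_of(rec)
    }, numeric(1))
    expect_true(all(diff(scores) <= 0), label = paste("monotone in", field))
  }
  # adding medication to an ideal factor never raises the score
  for (med in c("bp_med", "lipid_med", "glucose_med")) {
    rec <- base; rec[[med]] <- TRUE
    expect_lte(score_of(rec), score_of(base))
  }
  # pediatric percentiles
  ped <- list(age = 12, bmi_pct = 50, sbp = 100, dbp = 60, bp_pct = 50,
              total_chol = 150, glucose = 85)
  for (field in c("bmi_pct", "bp_pct")) {
    scores <- vapply(seq(50, 100, by = 1), function(v) {
      rec <- ped; rec[[field]] <- v; score_of(rec)
    }, numeric(1))
    expect_true(all(diff(scores) <= 0), label = paste("monotone in", field))
  }
})

test_that("the score is the sum of the four factor points", {
  expect_equal(clinical_cvh_score(list(age = 30, bmi = 22, sbp = 110,
                                       dbp = 70, total_chol = 170,
                                       glucose = 90))$score, 8)
  expect_equal(clinical_cvh_score(list(age = 30, bmi = 35, sbp = 150,
                                       dbp = 95, total_chol = 240,
                                       glucose = 140))$score, 0)
  # ideal BMI + ideal BP + intermediate chol + poor glucose = 2+2+1+0
  expect_equal(clinical_cvh_score(list(age = 30, bmi = 22, sbp = 110,
                                       dbp = 70, total_chol = 200,
                                       glucose = 130))$score, 5)
  # property: score equals sum of category points on random records
  set.seed(42)
  n <- 400
  d <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                  age = runif(n, 20, 55),
                  bmi = runif(n, 17, 42),
                  sbp = runif(n, 90, 170),
                  dbp = runif(n, 55, 105),
                  total_chol = runif(n, 120, 280),
                  glucose = runif(n, 70, 150))
  s <- score_exams(d)
  pts <- (as.integer(s$bmi_cat) - 1) + (as.integer(s$bp_cat) - 1) +
    (as.integer(s$chol_cat) - 1) + (as.integer(s$glu_cat) - 1)
  expect_equal(s$cvh_score, pts)
  expect_true(all(s$cvh_score >= 0 & s$cvh_score <= 8))
})

test_that("the completeness filter keeps subjects with >= 1 complete exam", {
  d <- data.frame(
    subject_id = c("a", "a", "b", "c", "c"),
    age = c(30, 34, 40, 25, 29),
    bmi = c(22, 23, NA, 24, 25),     # subject b never has BMI
    sbp = c(110, 112, 118, 120, 122),
    dbp = c(70, 72, 74, 76, 78),
    total_chol = c(170, 175, 180, 185, 190),
    glucose = c(90, NA, 95, 98, 99)  # a's second exam incomplete
  )
  res <- score_dataset(d)
  expect_equal(res$report$n_subjects, 3)
  expect_equal(res$report$n_subjects_retained, 2)
  expect_equal(res$report$n_exams_complete, 3)
  expect_setequal(unique(res$data$subject_id), c("a", "c"))

  # fully complete dataset passes through unchanged
  d2 <- d[c(1, 4, 5), ]
  res2 <- score_dataset(d2)
  expect_equal(res2$report$n_exams_complete, nrow(d2))
  expect_equal(res2$report$n_subjects_retained, 2)

  # empty input -> empty output, zero counts
  res0 <- score_dataset(d[0, ])
  expect_equal(nrow(res0$data), 0)
  expect_equal(res0$report$n_subjects_retained, 0)
})

test_that("retention under random missingness matches the closed form", {
  # 4 visits/subject, each independently incomplete with p = 0.5:
  # P(subject retained) = 1 - 0.5^4 = 0.9375
  cfg <- simple_config(n = 1500, seed = 9, missing_exam_p = 0.5)
  d <- generate_cvh_scores(cfg)
  res <- score_dataset(d)
  frac <- res$report$n_subjects_retained / res$report$n_subjects
  expect_equal(frac, 1 - 0.5^4, tolerance = 0.025)
})

test_that("total missingness empties the filtered dataset", {
  cfg <- simple_config(n = 40, seed = 2, missing_exam_p = 1)
  res <- score_dataset(generate_cvh_scores(cfg))
  expect_equal(nrow(res$data), 0)
  expect_equal(res$report$n_subjects_retained, 0)
})
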