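# Model selection, piecewise interaction contrasts, descriptive comparisons.

test_that("AIC and BIC identities hold for every fitted model", {
  d <- scored_preset("single_break", seed = 2, n_subjects = 150)
  cmp <- compare_models(d)
  tab <- cmp$table[!cmp$table$failed, ]
  n <- nrow(d)
  expect_equal(tab$aic, -2 * tab$loglik + 2 * tab$n_params)
  expect_equal(tab$bic, -2 * tab$loglik + log(n) * tab$n_params)
  expect_equal(nrow(cmp$table), 5)
  # segmented models count their change points as parameters
  p_lin <- tab$n_params[tab$model == "linear"]
  expect_equal(tab$n_params[tab$model == "segmented_1"], p_lin + 2)
  expect_equal(tab$n_params[tab$model == "segmented_2"], p_lin + 4)
  # LRTs only for nested pairs, with the Davies caution flag on break tests
  expect_true(all(cmp$lrt$approximate[cmp$lrt$alternative %in%
                                        c("segmented_1", "segmented_2")]))
  expect_false(any(cmp$lrt$approximate[cmp$lrt$alternative == "cubic"]))
})

test_that("curvature is detected by the quadratic-vs-linear LRT", {
  reject <- vapply(1:10, function(s) {
    set.seed(500 + s)
    n <- 1000
    ids <- sprintf("s%04d", seq_len(n))
    baseline <- runif(n, 8, 40)
    b0 <- rnorm(n, 0, 0.9)
    rows <- do.call(rbind, lapply(0:3, function(k)
      data.frame(subject_id = ids, age = baseline + 4 * k, b0 = b0)))
    rows <- rows[rows$age <= 55.99, ]
    rows$cvh_score <- 7 - 0.002 * (rows$age - 8)^2 + rows$b0 +
      rnorm(nrow(rows), 0, 0.7)
    cmp <- compare_models(rows)
    lrt <- cmp$lrt
    lrt$p_value[lrt$null == "linear" & lrt$alternative == "quadratic"] < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.9)
})

test_that("a linear truth is not beaten decisively by richer models", {
  close_calls <- vapply(1:12, function(s) {
    d <- scored_preset("linear_null", seed = 700 + s, n_subjects = 200)
    cmp <- suppressWarnings(compare_models(d))
    tab <- cmp$table[!cmp$table$failed, ]
    tab$aic[tab$model == "linear"] - min(tab$aic) <= 2
  }, logical(1))
  expect_gte(sum(close_calls), 8)
})

test_that("noiseless two-group slopes and differences are recovered exactly", {
  n <- 40
  grid <- expand.grid(subject_id = sprintf("s%02d", seq_len(n)),
                      k = 0:7, KEEP.OUT.ATTRS = FALSE)
  grid$age <- 8 + 4 * grid$k
  grid$sex <- ifelse(as.integer(factor(grid$subject_id)) <= n / 2,
                     "female", "male")
  mu_f <- 7.0 + 0.00 * (grid$age - 8) - 0.06 * pmax(grid$age - 17, 0)
  mu_m <- 7.1 - 0.01 * (grid$age - 8) - 0.08 * pmax(grid$age - 17, 0)
  grid$cvh_score <- ifelse(grid$sex == "female", mu_f, mu_m)
  pw <- fit_piecewise_interaction(grid, knots = 17, group = "sex",
                                  adjust = character())
  # female slopes (0, -0.06); male (-0.01, -0.09); differences (-0.01, -0.03)
  f <- pw$group_slopes[pw$group_slopes$group == "female", ]
  m <- pw$group_slopes[pw$group_slopes$group == "male", ]
  expect_equal(f$estimate, c(0, -0.06), tolerance = 1e-7)
  expect_equal(m$estimate, c(-0.01, -0.09), tolerance = 1e-7)
  expect_equal(pw$differences$estimate, c(-0.01, -0.03), tolerance = 1e-7)
  expect_equal(pw$means_at_8$estimate, c(7.0, 7.1), tolerance = 1e-7)
})

test_that("difference rows equal per-group slope subtraction exactly", {
  d <- scored_preset("paper2021", seed = 6, n_subjects = 300)
  pw <- fit_piecewise_interaction(d, knots = c(17, 37), group = "sex",
                                  adjust = c("race", "cohort"))
  for (s in 1:3) {
    gs <- pw$group_slopes
    diff_s <- gs$estimate[gs$group == "male" & gs$segment == s] -
      gs$estimate[gs$group == "female" & gs$segment == s]
    expect_equal(pw$differences$estimate[pw$differences$segment == s],
                 diff_s, tolerance = 1e-12)
  }
  # cumulative change over a segment is slope times width
  gs <- pw$group_slopes
  expect_equal(gs$total_delta, gs$estimate * (gs$to - gs$from),
               tolerance = 1e-12)
})

test_that("null group contrasts are calibrated", {
  # identical male/female mean structure: |slope diff| < 2 SE in >= 90%
  inside <- unlist(lapply(1:25, function(s) {
    cfg <- simple_config(n = 120, seed = 900 + s)
    d <- score_dataset(generate_cvh_scores(cfg))$data
    pw <- fit_piecewise_interaction(d, knots = 25, group = "sex",
                                    adjust = character())
    abs(pw$differences$estimate) < 2 * pw$differences$se
  }))
  expect_gte(mean(inside), 0.9)
})

test_that("a segment without one group's data is marked inestimable", {
  grid <- expand.grid(subject_id = sprintf("s%02d", 1:30), k = 0:3,
                      KEEP.OUT.ATTRS = FALSE)
  grid$sex <- ifelse(as.integer(factor(grid$subject_id)) <= 15,
                     "female", "male")
  # males observed only before the knot
  grid$age <- ifelse(grid$sex == "male", 8 + 2 * grid$k, 8 + 6 * grid$k)
  set.seed(1)
  grid$cvh_score <- 7 - 0.05 * (grid$age - 8) + rnorm(nrow(grid), 0, 0.3)
  pw <- fit_piecewise_interaction(grid, knots = 17, group = "sex",
                                  adjust = character())
  male2 <- pw$group_slopes[pw$group_slopes$group == "male" &
                             pw$group_slopes$segment == 2, ]
  expect_true(is.na(male2$estimate))
  expect_true(is.na(pw$differences$estimate[pw$differences$segment == 2]))
})

test_that("Welch reduces to Student's t when sample variances are equal", {
  set.seed(8)
  x <- rnorm(30)
  y <- x + 0.4  # identical sample variance, shifted mean
  res <- mean_difference_test(x, y)
  ref <- t.test(y, x, var.equal = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(res$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(res$difference, 0.4, tolerance = 1e-12)
})

test_that("degenerate samples follow the stated conventions", {
  x <- c(1.2, 3.4, 2.2, 1.8)
  same <- mean_difference_test(x, x)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  expect_equal(mean_difference_test(rep(2, 3), rep(2, 4))$p_value, 1)
  expect_equal(mean_difference_test(rep(2, 3), rep(3, 3))$p_value, 0)
})

test_that("the Welch p-value agrees with a permutation oracle", {
  set.seed(55)
  a <- rnorm(25, 0, 1)
  b <- rnorm(25, 0.45, 1)
  res <- mean_difference_test(a, b)
  pooled <- c(a, b)
  obs <- abs(mean(b) - mean(a))
  set.seed(56)
  n_perm <- 100000
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(50, 25)
    d_i <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
    if (d_i >= obs - 1e-12) hits <- hits + 1L
  }
  p_perm <- hits / n_perm
  expect_equal(res$p_value, p_perm, tolerance = 0.005)
})

test_that("baseline table matches a direct aggregation", {
  d <- scored_preset("paper2021", seed = 13, n_subjects = 500)
  bt <- baseline_table(d)
  # independent streaming computation of the female baseline mean score
  first_idx <- tapply(seq_len(nrow(d)), d$subject_id,
                      function(i) i[which.min(d$age[i])])
  first <- d[unlist(first_idx), ]
  for (s in c("female", "male")) {
    ref_mean <- mean(first$cvh_score[first$sex == s])
    got <- bt$numeric[bt$numeric$variable == "cvh_score" &
                        bt$numeric$sex == s, ]
    expect_equal(got$mean, ref_mean, tolerance = 1e-12)
    expect_equal(got$n, sum(first$sex == s))
  }
  expect_equal(bt$n$share[bt$n$sex == "female"], 0.52, tolerance = 0.07)
  expect_equal(sum(bt$n$n), length(unique(d$subject_id)))
  # single-subject input: one row per sex level present, absent SDs
  one <- baseline_table(d[d$subject_id == d$subject_id[1], ])
  expect_equal(one$n_subjects, 1)
  expect_true(all(is.na(one$numeric$sd)))
})

test_that("the three-way interaction screen flags a constructed interaction", {
  set.seed(77)
  n <- 400
  ids <- sprintf("s%04d", seq_len(n))
  sex <- rep(c("female", "male"), length.out = n)
  race <- rep(c("White", "Black"), each = n / 2)
  baseline <- runif(n, 8, 40)
  b0 <- rnorm(n, 0, 0.5)
  rows <- do.call(rbind, lapply(0:3, function(k)
    data.frame(subject_id = ids, sex = sex, race = race,
               age = baseline + 4 * k, b0 = b0)))
  slope <- with(rows, -0.02 - 0.06 * (sex == "male" & race == "White"))
  rows$cvh_score <- 7 + slope * (rows$age - 8) + rows$b0 +
    rnorm(nrow(rows), 0, 0.5)
  scr <- interaction_screen(rows, factors = c("race", "sex"))
  expect_lt(scr$p_value, 0.001)
  expect_equal(scr$df, 1)
})
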