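# Model selection, the fixed-knot piecewise interaction analysis and the
# descriptive sex comparisons at the influential ages.

#' Compare candidate mean structures for the score trajectory
#'
#' Fits, by maximum likelihood on identical data, five mixed models for the
#' age trend — linear, quadratic, cubic, segmented with 1 change point and
#' segmented with 2 change points (all with random intercept and slope) —
#' and tabulates log-likelihood, parameter count, AIC and BIC. Likelihood
#' ratio tests are reported for the polynomial nestings and for the
#' segmented pairs evaluated at the estimated change points; tests involving
#' a segmented alternative are flagged approximate because the change point
#' is unidentified under the null (the Davies problem), so AIC/BIC drive the
#' default verdict.
#'
#' @inheritParams fit_segmented
#' @return object of class `cvh_model_comparison`: list with `table`
#'   (per-model fit statistics), `lrt` (nested-pair tests), `best_aic`,
#'   `best_bic`, and the fitted objects in `fits`.
#' @export
compare_models <- function(data, covariates = character(),
                           response = "cvh_score", min_gap = 3,
                           tol_psi = 1e-3, max_iter = 50L) {
  fit_one <- function(label, expr) {
    tryCatch(eval(expr), error = function(e) {
      warning(sprintf("model '%s' failed: %s", label, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  }
  fits <- list(
    linear = fit_one("linear", quote(
      fit_lmm_fixed_knots(data, covariates = covariates, response = response))),
    quadratic = fit_one("quadratic", quote(
      fit_lmm_fixed_knots(data, covariates = covariates, response = response,
                          poly_degree = 2))),
    cubic = fit_one("cubic", quote(
      fit_lmm_fixed_knots(data, covariates = covariates, response = response,
                          poly_degree = 3))),
    segmented_1 = fit_one("segmented_1", quote(
      fit_segmented(data, n_changepoints = 1, covariates = covariates,
                    response = response, min_gap = min_gap,
                    tol_psi = tol_psi, max_iter = max_iter))),
    segmented_2 = fit_one("segmented_2", quote(
      fit_segmented(data, n_changepoints = 2, covariates = covariates,
                    response = response, min_gap = min_gap,
                    tol_psi = tol_psi, max_iter = max_iter)))
  )
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (is.null(f)) {
      data.frame(model = nm, loglik = NA_real_, n_params = NA_integer_,
                 aic = NA_real_, bic = NA_real_, converged = FALSE,
                 failed = TRUE)
    } else {
      data.frame(model = nm, loglik = f$loglik, n_params = f$n_params,
                 aic = f$aic, bic = f$bic,
                 converged = if (inherits(f, "cvh_segmented")) f$converged else TRUE,
                 failed = FALSE)
    }
  }))
  lrt_pair <- function(small, big, df, approximate = FALSE) {
    fs <- fits[[small]]; fb <- fits[[big]]
    if (is.null(fs) || is.null(fb)) return(NULL)
    stat <- 2 * (fb$loglik - fs$loglik)
    data.frame(null = small, alternative = big, df = df,
               statistic = stat,
               p_value = pchisq(max(stat, 0), df, lower.tail = FALSE),
               approximate = approximate)
  }
  lrt <- do.call(rbind, Filter(Negate(is.null), list(
    lrt_pair("linear", "quadratic", 1),
    lrt_pair("quadratic", "cubic", 1),
    lrt_pair("linear", "cubic", 2),
    # fixed-psi-hat comparisons; psi unidentified under the null (Davies)
    lrt_pair("linear", "segmented_1", 1, approximate = TRUE),
    lrt_pair("segmented_1", "segmented_2", 1, approximate = TRUE)
  )))
  ok <- !tab$failed
  res <- list(table = tab,
              lrt = lrt,
              best_aic = tab$model[ok][which.min(tab$aic[ok])],
              best_bic = tab$model[ok][which.min(tab$bic[ok])],
              fits = fits)
  class(res) <- "cvh_model_comparison"
  res
}

#' @export
print.cvh_model_comparison <- function(x, ...) {
  cat("Model comparison (ML fits on identical data)\n")
  print(transform(x$table, aic = round(aic, 1), bic = round(bic, 1),
                  loglik = round(loglik, 2)), row.names = FALSE)
  cat(sprintf("Best by AIC: %s | best by BIC: %s\n", x$best_aic, x$best_bic))
  invisible(x)
}

#' Fixed-knot piecewise model with group interactions
#'
#' Fits the multivariable piecewise linear mixed model with fixed knots
#' (default ages 17 and 37, the rounded estimated change points) in which
#' the full spline basis — `age - 8`, `(age - k1)_+`, `(age - k2)_+` — is
#' interacted with a grouping factor (default sex), adjusting for additional
#' covariate main effects, with a random intercept and slope per subject.
#' Reports per-group segment slopes, between-group slope differences
#' (non-reference minus reference level, e.g. male minus female) with Wald
#' tests, the cumulative change over each segment (slope times segment
#' width, computed on unrounded slopes), and group means at age 8.
#'
#' @inheritParams fit_segmented
#' @param knots fixed knot ages (length 1 or 2).
#' @param group name of the grouping factor column.
#' @param adjust names of adjustment covariate columns (main effects).
#' @param segment_bounds optional numeric vector of segment boundary ages
#'   used for the segment widths; defaults to `c(8, round(knots), 55.9)`.
#' @return object of class `cvh_piecewise`: list with `group_slopes`,
#'   `differences`, `means_at_8`, `knots`, `segment_bounds`, `beta`,
#'   `vcov_beta`, `vc`, `loglik`, `aic`, `bic` and the lme4 `model`.
#' @export
fit_piecewise_interaction <- function(data, knots = c(17, 37), group = "sex",
                                      adjust = c("race", "cohort"),
                                      response = "cvh_score",
                                      segment_bounds = NULL,
                                      conf_level = 0.95) {
  knots <- sort(as.numeric(knots))
  k <- length(knots)
  stopifnot(k >= 1, k <= 2)
  adjust <- intersect(adjust, names(data))
  need <- c("subject_id", "age", response, group, adjust)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  df <- data.frame(.y = data[[response]], .a = data$age - 8,
                   subject_id = factor(data$subject_id))
  base_terms <- ".a"
  for (j in seq_len(k)) {
    nm <- paste0(".k", j)
    df[[nm]] <- pmax(data$age - knots[j], 0)
    base_terms <- c(base_terms, nm)
  }
  df$.g <- factor(data[[group]])
  for (cv in adjust) df[[cv]] <- factor(data[[cv]])
  if (nlevels(df$.g) < 2) stop("group must have at least 2 levels")
  fml <- paste(".y ~ (", paste(base_terms, collapse = " + "), ") * .g",
               if (length(adjust)) paste("+", paste(adjust, collapse = " + ")) else "",
               "+ (1 + .a | subject_id)")
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(as.formula(fml), data = df, REML = FALSE,
                 control = .lmer_ctrl()))),
    error = function(e) stop("piecewise interaction fit failed: ",
                             conditionMessage(e), call. = FALSE))
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  nm <- names(beta)
  zq <- qnorm(1 - (1 - conf_level) / 2)

  if (is.null(segment_bounds)) segment_bounds <- c(8, round(knots), 55.9)
  widths <- diff(segment_bounds)

  glev <- levels(df$.g)
  ref <- glev[1]
  # estimability: each group level needs >= 2 distinct ages inside a segment
  seg_of <- findInterval(data$age, c(-Inf, knots, Inf))
  estimable <- function(g, s) {
    a <- unique(data$age[df$.g == g & seg_of == s])
    length(a) >= 2
  }
  contrast_row <- function(w, label_cols) {
    keep <- !is.na(w)
    est <- sum(w[keep] * beta[keep])
    se <- sqrt(drop(t(w[keep]) %*% V[keep, keep] %*% w[keep]))
    cbind(label_cols,
          data.frame(estimate = est, se = se, lower = est - zq * se,
                     upper = est + zq * se,
                     p_value = 2 * pnorm(-abs(est / se))))
  }
  slope_weights <- function(g, s) {
    w <- setNames(rep(0, length(nm)), nm)
    w[".a"] <- 1
    if (s > 1) w[paste0(".k", seq_len(s - 1))] <- 1
    if (g != ref) {
      gl <- paste0(".g", g)
      w[paste0(".a:", gl)] <- 1
      if (s > 1) w[paste0(".k", seq_len(s - 1), ":", gl)] <- 1
    }
    w
  }
  group_slopes <- NULL
  for (g in glev) for (s in seq_len(k + 1)) {
    if (!estimable(g, s)) {
      row <- data.frame(group = g, segment = s, from = segment_bounds[s],
                        to = segment_bounds[s + 1], estimate = NA_real_,
                        se = NA_real_, lower = NA_real_, upper = NA_real_,
                        p_value = NA_real_, total_delta = NA_real_)
    } else {
      row <- contrast_row(slope_weights(g, s),
                          data.frame(group = g, segment = s,
                                     from = segment_bounds[s],
                                     to = segment_bounds[s + 1]))
      row$total_delta <- total_delta(row$estimate, widths[s])
    }
    group_slopes <- rbind(group_slopes, row)
  }
  differences <- NULL
  for (g in setdiff(glev, ref)) for (s in seq_len(k + 1)) {
    if (!estimable(g, s) || !estimable(ref, s)) {
      row <- data.frame(group = g, reference = ref, segment = s,
                        estimate = NA_real_, se = NA_real_, lower = NA_real_,
                        upper = NA_real_, p_value = NA_real_,
                        total_delta = NA_real_)
    } else {
      w <- slope_weights(g, s) - slope_weights(ref, s)
      row <- contrast_row(w, data.frame(group = g, reference = ref,
                                        segment = s))
      row$total_delta <- total_delta(row$estimate, widths[s])
    }
    differences <- rbind(differences, row)
  }
  means_at_8 <- do.call(rbind, lapply(glev, function(g) {
    w <- setNames(rep(0, length(nm)), nm)
    w["(Intercept)"] <- 1
    if (g != ref) w[paste0(".g", g)] <- 1
    contrast_row(w, data.frame(group = g))
  }))

  ll <- as.numeric(logLik(fit))
  p <- attr(logLik(fit), "df")
  out <- list(model = fit, knots = knots, group = group, adjust = adjust,
              segment_bounds = segment_bounds,
              group_slopes = group_slopes, differences = differences,
              means_at_8 = means_at_8, beta = beta, vcov_beta = V,
              vc = .extract_vc(fit), loglik = ll,
              aic = -2 * ll + 2 * p, bic = -2 * ll + log(nrow(df)) * p)
  class(out) <- "cvh_piecewise"
  out
}

#' @export
print.cvh_piecewise <- function(x, digits = 3, ...) {
  cat(sprintf("Piecewise linear mixed model, knots at %s, by '%s'\n",
              paste(x$knots, collapse = ", "), x$group))
  cat("Segment slopes by group (points/year):\n")
  print(cbind(x$group_slopes[, 1:4],
              round(x$group_slopes[, -(1:4)], digits)), row.names = FALSE)
  cat("Slope differences (group - reference):\n")
  print(cbind(x$differences[, 1:3],
              round(x$differences[, -(1:3)], digits)), row.names = FALSE)
  invisible(x)
}

#' Cumulative change over an age segment
#'
#' The total change in score across a segment: slope (points/year) times
#' segment width (years).
#'
#' @param slope segment slope, points/year.
#' @param width segment width, years (> 0).
#' @return total change in points.
#' @export
#' @examples
#' total_delta(-0.09, 20)  # -1.8 over ages 17-37
total_delta <- function(slope, width) {
  stopifnot(all(width > 0))
  slope * width
}

#' Wald screen for a three-way age-by-group interaction
#'
#' Fits the fully interacted linear mixed model `score ~ age * f1 * f2` with
#' random intercept and slope and tests the three-way interaction
#' coefficients (age x f1 x f2) jointly with a Wald chi-square test. A small
#' p-value motivates stratifying the change-point analysis by one factor.
#'
#' @param data scored dataset.
#' @param factors character vector of two factor column names.
#' @param response response column name.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
interaction_screen <- function(data, factors = c("race", "sex"),
                               response = "cvh_score") {
  stopifnot(length(factors) == 2)
  df <- data.frame(.y = data[[response]], .a = data$age - 8,
                   subject_id = factor(data$subject_id),
                   f1 = factor(data[[factors[1]]]),
                   f2 = factor(data[[factors[2]]]))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(.y ~ .a * f1 * f2 + (1 + .a | subject_id), data = df,
               REML = FALSE, control = .lmer_ctrl())))
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  idx <- grep("^\\.a:f1.*:f2", names(beta))
  if (!length(idx)) stop("no three-way interaction terms are estimable")
  b <- beta[idx]
  stat <- drop(t(b) %*% solve(V[idx, idx, drop = FALSE]) %*% b)
  list(statistic = stat, df = length(idx),
       p_value = pchisq(stat, length(idx), lower.tail = FALSE))
}

#' Welch comparison of group means
#'
#' Two-sample t-test with unequal variances (Welch) comparing the means of
#' two measurement vectors; the reported difference is `mean(b) - mean(a)`
#' (e.g. male minus female). When both groups have zero variance the test is
#' degenerate: equal means give p = 1 by convention, unequal means p = 0.
#'
#' @param values_a,values_b numeric vectors (each of length >= 2).
#' @param labels length-2 character labels for the groups.
#' @param conf_level confidence level.
#' @return data frame with one row: group means and SDs, `difference`
#'   (b minus a), CI bounds, `t`, `df`, `p_value`.
#' @export
#' @examples
#' mean_difference_test(rnorm(50, 163), rnorm(50, 151),
#'                      labels = c("female", "male"))
mean_difference_test <- function(values_a, values_b,
                                 labels = c("a", "b"), conf_level = 0.95) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  diff <- mean(values_b) - mean(values_a)
  if (sd(values_a) < .Machine$double.eps^0.5 &&
      sd(values_b) < .Machine$double.eps^0.5) {
    p <- if (abs(diff) < .Machine$double.eps^0.5) 1 else 0
    return(data.frame(group_a = labels[1], group_b = labels[2],
                      mean_a = mean(values_a), sd_a = sd(values_a),
                      mean_b = mean(values_b), sd_b = sd(values_b),
                      difference = diff, lower = diff, upper = diff,
                      t = NA_real_, df = NA_real_, p_value = p))
  }
  tt <- t.test(values_b, values_a, var.equal = FALSE,
               conf.level = conf_level)
  data.frame(group_a = labels[1], group_b = labels[2],
             mean_a = mean(values_a), sd_a = sd(values_a),
             mean_b = mean(values_b), sd_b = sd(values_b),
             difference = diff,
             lower = tt$conf.int[1], upper = tt$conf.int[2],
             t = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value)
}

#' Baseline descriptive table by sex
#'
#' Each subject's baseline is their first complete examination (smallest
#' age among retained rows). Numeric characteristics are summarized as mean
#' (SD) per sex; categorical characteristics (race, cohort) as counts and
#' shares.
#'
#' @param data scored, filtered dataset (e.g. `score_dataset(...)$data`).
#' @return object of class `cvh_baseline`: list with `n` (per-sex counts and
#'   shares), `numeric` (long data frame: variable, sex, n, mean, sd) and
#'   `categorical` (variable, level, sex, n, share).
#' @export
baseline_table <- function(data) {
  stopifnot(all(c("subject_id", "age") %in% names(data)))
  ord <- order(data$subject_id, data$age)
  d <- data[ord, , drop = FALSE]
  first <- d[!duplicated(d$subject_id), , drop = FALSE]
  sexes <- if ("sex" %in% names(first)) sort(unique(as.character(first$sex))) else "all"
  if (!"sex" %in% names(first)) first$sex <- "all"
  n_tab <- as.data.frame(table(sex = first$sex), stringsAsFactors = FALSE)
  names(n_tab)[2] <- "n"
  n_tab$share <- n_tab$n / sum(n_tab$n)
  num_vars <- intersect(c("age", "cvh_score", "bmi", "sbp", "dbp",
                          "total_chol", "glucose"), names(first))
  numeric_tab <- do.call(rbind, lapply(num_vars, function(v) {
    do.call(rbind, lapply(sexes, function(s) {
      x <- first[[v]][first$sex == s]
      x <- x[!is.na(x)]
      data.frame(variable = v, sex = s, n = length(x),
                 mean = if (length(x)) mean(x) else NA_real_,
                 sd = if (length(x) >= 2) sd(x) else NA_real_)
    }))
  }))
  cat_vars <- intersect(c("race", "cohort"), names(first))
  categorical_tab <- do.call(rbind, lapply(cat_vars, function(v) {
    do.call(rbind, lapply(sexes, function(s) {
      tb <- table(first[[v]][first$sex == s])
      if (!length(tb)) return(NULL)
      data.frame(variable = v, level = names(tb), sex = s,
                 n = as.integer(tb), share = as.numeric(tb) / sum(tb))
    }))
  }))
  out <- list(n = n_tab, numeric = numeric_tab, categorical = categorical_tab,
              n_subjects = nrow(first))
  class(out) <- "cvh_baseline"
  out
}

#' @export
print.cvh_baseline <- function(x, digits = 2, ...) {
  cat(sprintf("Baseline characteristics (first complete exam), %d subjects\n",
              x$n_subjects))
  print(transform(x$n, share = round(share, 3)), row.names = FALSE)
  print(transform(x$numeric, mean = round(mean, digits),
                  sd = round(sd, digits)), row.names = FALSE)
  invisible(x)
}
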