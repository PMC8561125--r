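# Shared fixtures and the independent marginal-likelihood oracle.

# scored long-format dataset from a preset
scored_preset <- function(name, seed = 1, n_subjects = NULL, ...) {
  cfg <- cvh_preset(name, seed = seed, n_subjects = n_subjects, ...)
  score_dataset(generate_cvh_scores(cfg))$data
}

# one-cohort config with full control over the truth
simple_config <- function(n = 100, seed = 1, psi = 25,
                          slopes = c(0, -0.08), intercept = 7,
                          re_sd_intercept = 0.9, re_sd_slope = 0.02,
                          re_corr = -0.2, resid_sd = 0.7,
                          baseline = c(8, 40), interval = 4, visits = 4,
                          ...) {
  tm <- true_model(intercept, psi = psi, segment_slopes = slopes,
                   re_sd_intercept = re_sd_intercept,
                   re_sd_slope = re_sd_slope, re_corr = re_corr,
                   resid_sd = resid_sd)
  generator_config(tm, list(cohort_design("main", n, baseline, interval,
                                          visits)),
                   seed = seed, ...)
}

# Direct maximization of the marginal Gaussian likelihood of the random
# intercept + slope model, written from scratch: per-subject covariance
# Sigma_j = Z_j G Z_j' + sigma^2 I with Z_j = [1, age - 8], GLS-profiled
# fixed effects, optim over (log sd0, log sd1, atanh rho, log sigma).
direct_marginal_loglik <- function(data, knots = numeric(),
                                   response = "cvh_score") {
  a <- data$age - 8
  X <- cbind(1, a)
  for (k in knots) X <- cbind(X, pmax(data$age - k, 0))
  y <- data[[response]]
  idx <- split(seq_along(y), factor(data$subject_id))
  negll <- function(par) {
    sd0 <- exp(par[1]); sd1 <- exp(par[2])
    rho <- tanh(par[3]); sig <- exp(par[4])
    G <- matrix(c(sd0^2, rho * sd0 * sd1, rho * sd0 * sd1, sd1^2), 2)
    p <- ncol(X)
    XtX <- matrix(0, p, p); Xty <- numeric(p)
    Sinv <- vector("list", length(idx)); logdet <- 0
    for (j in seq_along(idx)) {
      i <- idx[[j]]
      Z <- cbind(1, a[i])
      S <- Z %*% G %*% t(Z) + diag(sig^2, length(i))
      cS <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(cS)) return(1e10)
      logdet <- logdet + 2 * sum(log(diag(cS)))
      Si <- chol2inv(cS)
      Sinv[[j]] <- Si
      Xi <- X[i, , drop = FALSE]
      XtX <- XtX + t(Xi) %*% Si %*% Xi
      Xty <- Xty + t(Xi) %*% Si %*% y[i]
    }
    beta <- solve(XtX, Xty)
    q <- 0
    for (j in seq_along(idx)) {
      i <- idx[[j]]
      r <- y[i] - X[i, , drop = FALSE] %*% beta
      q <- q + drop(t(r) %*% Sinv[[j]] %*% r)
    }
    0.5 * (length(y) * log(2 * pi) + logdet + q)
  }
  start <- c(log(sd(y) * 0.8), log(0.05), 0, log(sd(y) * 0.6))
  opt <- optim(start, negll, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-12))
  opt <- optim(opt$par, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  -opt$value
}

# subject-level nonparametric bootstrap of the per-segment slopes at fixed
# knots; returns the SD of each segment slope over resamples
bootstrap_segment_slope_sd <- function(data, knots, n_boot = 200, seed = 1) {
  set.seed(seed)
  ids <- unique(data$subject_id)
  rows_of <- split(seq_len(nrow(data)), data$subject_id)
  k <- length(knots)
  slopes <- matrix(NA_real_, n_boot, k + 1)
  for (b in seq_len(n_boot)) {
    take <- sample(ids, length(ids), replace = TRUE)
    pieces <- lapply(seq_along(take), function(j) {
      d <- data[rows_of[[take[j]]], , drop = FALSE]
      d$subject_id <- sprintf("bs%04d", j)
      d
    })
    db <- do.call(rbind, pieces)
    f <- fit_lmm_fixed_knots(db, knots = knots)
    bet <- f$beta
    slopes[b, ] <- cumsum(c(bet[".a"], bet[paste0(".k", seq_len(k))]))
  }
  apply(slopes, 2, sd)
}
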