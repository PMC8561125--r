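# Segmented (broken-line) linear mixed models.
#
# The population mean of the score is piecewise linear in age with unknown
# change points psi. Estimation follows the iterative linearization scheme:
# at the current psi each break contributes two working covariates,
#   U_k = (age - psi_k)_+        (slope increment, coefficient delta_k)
#   V_k = -1{age > psi_k}        (gap term, coefficient gamma_k)
# and psi is updated by psi_k <- psi_k + gamma_k / delta_k until the gap
# coefficients vanish. All fits are maximum likelihood (not REML) so nested
# mean structures are comparable by LRT/AIC/BIC.

.lmer_ctrl <- function() {
  lme4::lmerControl(calc.derivs = FALSE,
                    check.conv.grad = "ignore",
                    check.conv.singular = "ignore",
                    check.conv.hess = "ignore")
}

# internal: assemble the model frame with centered age and basis columns.
# knots -> .k1, .k2 truncated-line terms; uv at psi -> .U1/.V1 (.U2/.V2);
# poly_degree -> .a2, .a3. Age is centered at 8 so the intercept is the
# mean score at age 8 for reference covariate levels.
.build_frame <- function(data, response, covariates, knots = numeric(),
                         uv_psi = NULL, poly_degree = 1) {
  need <- c("subject_id", "age", response, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- data.frame(
    .y = data[[response]],
    .a = data$age - 8,
    subject_id = factor(data$subject_id)
  )
  terms <- ".a"
  if (poly_degree >= 2) { df$.a2 <- df$.a^2; terms <- c(terms, ".a2") }
  if (poly_degree >= 3) { df$.a3 <- df$.a^3; terms <- c(terms, ".a3") }
  for (j in seq_along(knots)) {
    nm <- paste0(".k", j)
    df[[nm]] <- pmax(data$age - knots[j], 0)
    terms <- c(terms, nm)
  }
  for (j in seq_along(uv_psi)) {
    un <- paste0(".U", j); vn <- paste0(".V", j)
    df[[un]] <- pmax(data$age - uv_psi[j], 0)
    df[[vn]] <- -as.numeric(data$age > uv_psi[j])
    terms <- c(terms, un, vn)
  }
  for (cv in covariates) {
    df[[cv]] <- factor(data[[cv]])
    terms <- c(terms, cv)
  }
  list(df = df, terms = terms)
}

# internal: ML fit of .y ~ fixed terms + (1 + .a | subject_id)
.fit_ml_lmm <- function(frame, start = NULL) {
  fml <- as.formula(paste(".y ~", paste(frame$terms, collapse = " + "),
                          "+ (1 + .a | subject_id)"))
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(fml, data = frame$df, REML = FALSE, control = .lmer_ctrl(),
                 start = start)
    )),
    error = function(e) stop("mixed-model estimation failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  beta <- lme4::fixef(fit)
  X_cols <- ncol(lme4::getME(fit, "X"))
  if (length(beta) < length(frame$terms) + 1L || X_cols < length(frame$terms) + 1L)
    stop("mixed-model design is rank deficient (aliased fixed effects); ",
         "check for constant or collinear covariates", call. = FALSE)
  fit
}

# internal: variance components from a merMod as a plain list
.extract_vc <- function(fit) {
  vc <- lme4::VarCorr(fit)$subject_id
  sds <- attr(vc, "stddev")
  list(sd_intercept = unname(sds[1]),
       sd_slope = unname(sds[2]),
       corr = unname(attr(vc, "correlation")[1, 2]),
       sd_resid = unname(attr(lme4::VarCorr(fit), "sc")))
}

#' Linear mixed model with fixed spline knots
#'
#' Fits, by maximum likelihood, a linear mixed model whose fixed-effect mean
#' is `intercept + slope * (age - 8) + sum_j delta_j * (age - k_j)_+` plus
#' main effects of the requested categorical covariates, with a correlated
#' random intercept and slope per subject. With no knots this is the plain
#' linear mixed model; `poly_degree` 2 or 3 instead adds quadratic/cubic age
#' terms (no knots allowed then).
#'
#' @param data long-format scored dataset with columns `subject_id`, `age`,
#'   the response, and any covariates.
#' @param knots fixed knot ages (years), strictly inside the observed range.
#' @param covariates character vector of categorical covariate column names.
#' @param response response column name.
#' @param poly_degree polynomial degree of the age trend (1, 2 or 3); only
#'   degree 1 may be combined with knots.
#' @param n_psi_params number of estimated change points to count as extra
#'   parameters in AIC/BIC (used internally by [fit_segmented()]).
#' @param start optional lme4 start value (e.g. `list(theta = ...)`) to
#'   warm-start the variance-component optimizer from a neighboring fit.
#' @return object of class `cvh_lmm`: list with the lme4 `model`, `beta`,
#'   `vcov_beta`, variance components `vc`, `loglik`, `n_params`, `aic`,
#'   `bic`, `knots`, `covariates`, `n_obs`, `n_subjects`.
#' @export
fit_lmm_fixed_knots <- function(data, knots = numeric(),
                                covariates = character(),
                                response = "cvh_score", poly_degree = 1,
                                n_psi_params = 0L, start = NULL) {
  knots <- as.numeric(knots)
  if (length(knots) && poly_degree != 1)
    stop("knots require poly_degree = 1")
  rng <- range(data$age)
  if (length(knots) && (any(knots <= rng[1]) || any(knots >= rng[2])))
    stop("knots must lie strictly inside the observed age range")
  frame <- .build_frame(data, response, covariates, knots = knots,
                        poly_degree = poly_degree)
  fit <- .fit_ml_lmm(frame, start = start)
  ll <- logLik(fit)
  p <- attr(ll, "df") + n_psi_params
  n <- nrow(frame$df)
  out <- list(
    model = fit,
    beta = lme4::fixef(fit),
    vcov_beta = as.matrix(vcov(fit)),
    vc = .extract_vc(fit),
    loglik = as.numeric(ll),
    n_params = p,
    aic = -2 * as.numeric(ll) + 2 * p,
    bic = -2 * as.numeric(ll) + log(n) * p,
    knots = knots,
    covariates = covariates,
    response = response,
    poly_degree = poly_degree,
    n_obs = n,
    n_subjects = nlevels(frame$df$subject_id),
    theta = lme4::getME(fit, "theta")
  )
  class(out) <- "cvh_lmm"
  out
}

#' @export
print.cvh_lmm <- function(x, ...) {
  cat(sprintf("Linear mixed model (ML), %d obs / %d subjects\n",
              x$n_obs, x$n_subjects))
  if (length(x$knots))
    cat("  knots:", paste(format(x$knots, digits = 4), collapse = ", "), "\n")
  cat(sprintf("  logLik %.3f | AIC %.1f | BIC %.1f\n", x$loglik, x$aic, x$bic))
  invisible(x)
}

# internal: project a psi proposal into the admissible region
.project_psi <- function(psi, lo, hi, min_gap) {
  psi <- sort(psi)
  psi <- pmin(pmax(psi, lo), hi)
  if (length(psi) == 2 && diff(psi) < min_gap) {
    mid <- mean(psi)
    psi <- c(mid - min_gap / 2, mid + min_gap / 2)
    if (psi[1] < lo) psi <- c(lo, lo + min_gap)
    if (psi[2] > hi) psi <- c(hi - min_gap, hi)
  }
  psi
}

# internal: working (U/V) model at psi, with the pieces the update needs
.fit_uv <- function(data, psi, covariates, response, start = NULL) {
  frame <- .build_frame(data, response, covariates, uv_psi = psi)
  m <- .fit_ml_lmm(frame, start = start)
  beta <- lme4::fixef(m)
  k <- length(psi)
  list(model = m, beta = beta,
       vcov_beta = as.matrix(vcov(m)),
       loglik = as.numeric(logLik(m)),
       gamma = unname(beta[paste0(".V", seq_len(k))]),
       delta = unname(beta[paste0(".U", seq_len(k))]),
       theta = lme4::getME(m, "theta"),
       psi = psi)
}

# internal: fast ordinary-least-squares profile over candidate knots.
# Ignores the within-subject clustering, so it is used only to rank starting
# values for the mixed-model search (the ranking, not the likelihood value,
# is what matters).
.ols_profile_scan <- function(data, response, covariates, candidates) {
  y <- data[[response]]
  base <- cbind(1, data$age - 8)
  if (length(covariates)) {
    cf <- as.data.frame(lapply(data[covariates], factor))
    base <- cbind(base, model.matrix(~ ., data = cf)[, -1, drop = FALSE])
  }
  vapply(candidates, function(cd) {
    U <- vapply(cd, function(k) pmax(data$age - k, 0), numeric(length(y)))
    r <- lm.fit(cbind(base, U), y)$residuals
    -0.5 * length(y) * log(sum(r^2))
  }, numeric(1))
}

# internal: greedy selection of well-separated top candidates from a scan
.top_separated <- function(cands, score, n_keep, sep) {
  ord <- order(score, decreasing = TRUE)
  picked <- list()
  for (i in ord) {
    cd <- cands[[i]]
    if (all(vapply(picked, function(p) max(abs(p - cd)) >= sep, TRUE))) {
      picked[[length(picked) + 1]] <- cd
      if (length(picked) >= n_keep) break
    }
  }
  picked
}

#' One iteration of the change-point linearization
#'
#' Fits the working model with `U = (age - psi)_+` and `V = -1{age > psi}`
#' terms at the current change points and proposes
#' `psi_next = psi + gamma / delta` (gap over slope-increment coefficient),
#' projected back into the admissible age range with the minimum gap
#' enforced. If `loglik_ref` is supplied (normally the working-model
#' log-likelihood at the current `psi`), the working model is refit at the
#' proposal and the step is halved (up to `max_halvings` times) while its
#' log-likelihood falls below the reference; a step that cannot improve is
#' returned with `stalled = TRUE`.
#'
#' @param data scored long-format dataset.
#' @param psi current change-point ages (sorted, inside the admissible range).
#' @param covariates categorical adjustment covariates.
#' @param min_gap minimum separation between change points and from the edges
#'   of the observed age range (years).
#' @param response response column name.
#' @param loglik_ref reference log-likelihood for step-halving; omit for a
#'   raw, unguarded update.
#' @param max_halvings maximum number of step halvings.
#' @param tol_psi proposals moving less than this are accepted without the
#'   halving guard: a vanishing update means the gap coefficient is zero and
#'   the iteration has converged.
#' @param uv_fit optional working fit at `psi` (as returned in `uv_next` by a
#'   previous step), reused instead of refitting.
#' @return list with `psi` (accepted proposal), `gamma`, `delta` and
#'   `uv_fit` (working fit at the current `psi`); when `loglik_ref` is given
#'   also `uv_next` (working fit at the accepted proposal) and `stalled`.
#' @export
muggeo_step <- function(data, psi, covariates = character(), min_gap = 3,
                        response = "cvh_score", loglik_ref = NULL,
                        max_halvings = 6L, tol_psi = 1e-3, uv_fit = NULL) {
  rng <- range(data$age)
  lo <- rng[1] + min_gap; hi <- rng[2] - min_gap
  if (is.null(uv_fit)) uv_fit <- .fit_uv(data, psi, covariates, response)
  warm <- list(theta = uv_fit$theta)
  gamma <- uv_fit$gamma
  delta <- uv_fit$delta
  if (any(abs(delta) < 1e-10))
    stop("flat kink: a slope-increment coefficient is zero; ",
         "re-initialize the change points", call. = FALSE)
  proposal <- .project_psi(psi + gamma / delta, lo, hi, min_gap)
  if (is.null(loglik_ref)) {
    return(list(psi = proposal, uv_fit = uv_fit, gamma = gamma,
                delta = delta, uv_next = NULL, stalled = FALSE))
  }
  if (max(abs(proposal - psi)) < tol_psi) {
    return(list(psi = proposal, uv_fit = uv_fit, gamma = gamma,
                delta = delta, uv_next = uv_fit, stalled = FALSE))
  }
  stalled <- FALSE
  uv_next <- NULL
  for (h in 0:max_halvings) {
    uv_next <- .fit_uv(data, proposal, covariates, response, start = warm)
    # small slack: likelihoods of neighboring working designs carry
    # optimizer noise of order 1e-6
    if (uv_next$loglik >= loglik_ref - 1e-6) break
    if (h == max_halvings) {
      proposal <- psi
      uv_next <- uv_fit
      stalled <- TRUE
      break
    }
    proposal <- .project_psi(psi + (proposal - psi) / 2, lo, hi, min_gap)
  }
  list(psi = proposal, uv_fit = uv_fit, gamma = gamma, delta = delta,
       uv_next = uv_next, stalled = stalled)
}

#' Segmented linear mixed model with estimated change points
#'
#' Estimates 1 or 2 population-level change points in the age trend of the
#' score by iterating [muggeo_step()] until the largest change-point update
#' falls below `tol_psi` (or `max_iter` is reached), followed by a local
#' fixed-knot likelihood polish that re-launches the iteration from any
#' strictly better neighboring point (the profile can carry near-tied
#' micro-modes at data-age boundaries). The reported fixed
#' effects, log-likelihood, AIC and BIC come from a final fixed-knot refit at
#' the estimated change points (no gap terms); the change-point standard
#' errors use the ratio delta method on the gap and slope-increment
#' coefficients of a final working fit, whose covariance supplies
#' `Var(gamma/delta)`. With `n_changepoints = 0` this is the plain linear
#' mixed model.
#'
#' @inheritParams muggeo_step
#' @param n_changepoints 0, 1 or 2.
#' @param psi_init `"auto"` (profile-seeded: a fast OLS profile scan over
#'   the admissible range ranks candidate starts and the best few
#'   well-separated candidates are re-scored under the mixed model) or a
#'   numeric vector of starting ages.
#' @param tol_psi convergence tolerance on the change points, years.
#' @param max_iter maximum number of iterations.
#' @param conf_level confidence level of the change-point intervals.
#' @return object of class `cvh_segmented`: list with `psi` (data frame:
#'   estimate, se, lower, upper), `beta`, `delta` (slope increments),
#'   `gamma` (final gap coefficients), `segment_slopes` (data frame via
#'   [segment_slopes()]), `vc`, `loglik`, `aic`, `bic`, `trace`, `converged`
#'   (`TRUE` when the update fell below `tol_psi` or no improving step
#'   remained; `FALSE` on budget exhaustion or a degenerate kink, with
#'   `stalled` recording the halving stalls), `knot_fit` (the final
#'   `cvh_lmm`), plus the control settings.
#' @export
fit_segmented <- function(data, n_changepoints = 2,
                          covariates = character(), psi_init = "auto",
                          tol_psi = 1e-3, max_iter = 50L, min_gap = 3,
                          response = "cvh_score", conf_level = 0.95) {
  stopifnot(n_changepoints %in% 0:2, tol_psi > 0, min_gap > 0)
  if (n_changepoints == 0) {
    knot_fit <- fit_lmm_fixed_knots(data, covariates = covariates,
                                    response = response)
    out <- list(psi = data.frame(estimate = numeric(), se = numeric(),
                                 lower = numeric(), upper = numeric()),
                beta = knot_fit$beta, delta = numeric(), gamma = numeric(),
                vc = knot_fit$vc, loglik = knot_fit$loglik,
                aic = knot_fit$aic, bic = knot_fit$bic,
                n_params = knot_fit$n_params,
                trace = data.frame(iter = 0L, loglik = knot_fit$loglik),
                converged = TRUE, knot_fit = knot_fit,
                n_changepoints = 0L, covariates = covariates,
                control = list(tol_psi = tol_psi, max_iter = max_iter,
                               min_gap = min_gap))
    out$segment_slopes <- data.frame(
      segment = 1L, from = min(data$age), to = max(data$age),
      slope = unname(knot_fit$beta[".a"]),
      se = sqrt(knot_fit$vcov_beta[".a", ".a"]))
    class(out) <- "cvh_segmented"
    return(out)
  }
  rng <- range(data$age)
  lo <- rng[1] + min_gap; hi <- rng[2] - min_gap
  if (lo >= hi) stop("age range too narrow for the requested change points")
  if (identical(psi_init, "auto")) {
    # Profile-seeded start: broken-line likelihoods can be multimodal, so a
    # single median start can land on a local mode.
    best <- NULL
    if (n_changepoints == 1) {
      # coarse scan of the mixed-model profile itself, warm-chained along
      # the grid (the variance components change slowly with the knot)
      warm <- NULL
      for (p in seq(lo, hi, by = 2.5)) {
        f <- tryCatch(fit_lmm_fixed_knots(data, knots = p,
                                          covariates = covariates,
                                          response = response,
                                          n_psi_params = 1L, start = warm),
                      error = function(e) NULL)
        if (is.null(f)) next
        warm <- list(theta = f$theta)
        if (is.null(best) || f$loglik > best$loglik)
          best <- list(psi = p, loglik = f$loglik, theta = f$theta)
      }
    } else {
      # pair lattice is too large for a full mixed-model scan: rank pairs
      # by a fast OLS profile, then re-score a spread of the best
      # candidates under the mixed model
      g <- seq(lo, hi, by = 1.5)
      pairs <- expand.grid(a = g, b = g)
      pairs <- pairs[pairs$b - pairs$a >= min_gap, , drop = FALSE]
      cands <- lapply(seq_len(nrow(pairs)), function(i)
        c(pairs$a[i], pairs$b[i]))
      scan <- .ols_profile_scan(data, response, covariates, cands)
      starts <- .top_separated(cands, scan, n_keep = 6, sep = 3)
      warm <- NULL
      for (cd in starts) {
        f <- tryCatch(fit_lmm_fixed_knots(data, knots = cd,
                                          covariates = covariates,
                                          response = response,
                                          n_psi_params = 2L, start = warm),
                      error = function(e) NULL)
        if (is.null(f)) next
        warm <- list(theta = f$theta)
        if (is.null(best) || f$loglik > best$loglik)
          best <- list(psi = cd, loglik = f$loglik, theta = f$theta)
      }
    }
    if (is.null(best)) stop("no admissible starting value for the change points")
    psi <- best$psi
  } else {
    psi <- as.numeric(psi_init)
    if (length(psi) != n_changepoints)
      stop("psi_init must have length n_changepoints")
  }
  psi <- .project_psi(psi, lo, hi, min_gap)

  k <- n_changepoints
  trace <- NULL
  run_id <- 1L
  add_trace <- function(it, psi, ll) {
    rbind(trace, data.frame(run = run_id, iter = it,
                            t(setNames(psi, paste0("psi", seq_len(k)))),
                            loglik = ll))
  }
  run_iterations <- function(psi, uv_cur, iter0, budget) {
    converged <- FALSE; stalled <- FALSE
    it <- iter0
    for (step in seq_len(budget)) {
      it <- it + 1L
      st <- tryCatch(
        muggeo_step(data, psi, covariates = covariates, min_gap = min_gap,
                    response = response, loglik_ref = uv_cur$loglik,
                    tol_psi = tol_psi, uv_fit = uv_cur),
        error = function(e) e)
      if (inherits(st, "error")) { stalled <- TRUE; it <- it - 1L; break }
      move <- max(abs(st$psi - psi))
      psi <- st$psi
      uv_cur <- st$uv_next
      trace <<- add_trace(it, psi, uv_cur$loglik)
      if (st$stalled) {
        # no improving step remains along the linearization direction:
        # terminated at a local optimum within numerical resolution
        stalled <- TRUE; converged <- TRUE; break
      }
      if (move < tol_psi) { converged <- TRUE; break }
    }
    list(psi = psi, uv = uv_cur, converged = converged, stalled = stalled,
         iter = it)
  }

  warm0 <- if (identical(psi_init, "auto")) list(theta = best$theta) else NULL
  uv0 <- .fit_uv(data, psi, covariates, response, start = warm0)
  trace <- add_trace(0L, psi, uv0$loglik)
  run <- run_iterations(psi, uv0, 0L, max_iter)
  knot_at <- function(p, warm = NULL) fit_lmm_fixed_knots(
    data, knots = p, covariates = covariates, response = response,
    n_psi_params = k, start = warm)
  knot_fit <- knot_at(run$psi)
  best <- list(psi = run$psi, knot_fit = knot_fit, uv = run$uv,
               converged = run$converged, stalled = run$stalled)

  # Local polish (basin hopping): the profile can carry near-tied micro-
  # modes a fraction of a year apart, and the linearized update only finds
  # the mode of the basin it starts in. Scan the fixed-knot likelihood on a
  # small lattice around the estimate, re-launch the iteration from the
  # most promising near-tied candidates, and keep whichever refined point
  # maximizes the fixed-knot likelihood. Candidate fits are cold (no warm
  # start) -- the identical code path to profile_grid_oracle -- so
  # near-tied modes are ordered consistently with a brute-force scan.
  offsets <- if (k == 1) seq(-1.5, 1.5, by = 0.5) else seq(-0.5, 0.5, by = 0.25)
  for (round in 1:2) {
    improved <- FALSE
    cand <- list()
    for (j in seq_len(k)) for (o in offsets) {
      if (abs(o) < 1e-9) next
      p <- best$psi; p[j] <- p[j] + o
      p <- .project_psi(p, lo, hi, min_gap)
      if (max(abs(p - best$psi)) > 1e-9) cand[[length(cand) + 1]] <- p
    }
    if (!length(cand)) break
    cand_fit <- lapply(cand, function(p)
      tryCatch(knot_at(p), error = function(e) NULL))
    cand_ll <- vapply(cand_fit, function(f)
      if (is.null(f)) -Inf else f$loglik, numeric(1))
    # refine the best few candidates within 0.05 log-likelihood of the
    # incumbent: a nearby basin can hide a higher peak between lattice points
    promising <- order(cand_ll, decreasing = TRUE)
    promising <- promising[cand_ll[promising] > best$knot_fit$loglik - 0.05]
    promising <- head(promising, if (k == 1) 2L else 1L)
    for (i in promising) {
      psi_jump <- cand[[i]]
      uv_jump <- .fit_uv(data, psi_jump, covariates, response,
                         start = list(theta = cand_fit[[i]]$theta))
      run_id <- run_id + 1L
      if (cand_ll[i] > best$knot_fit$loglik + 1e-6) {
        best <- list(psi = psi_jump, knot_fit = cand_fit[[i]], uv = uv_jump,
                     converged = TRUE, stalled = FALSE)
        improved <- TRUE
      }
      it0 <- max(trace$iter) + 1L
      trace <- add_trace(it0, psi_jump, uv_jump$loglik)
      rerun <- run_iterations(psi_jump, uv_jump, it0, 10L)
      if (max(abs(rerun$psi - best$psi)) > 1e-9) {
        refit <- tryCatch(knot_at(rerun$psi), error = function(e) NULL)
        if (!is.null(refit) && refit$loglik > best$knot_fit$loglik + 1e-6) {
          best <- list(psi = rerun$psi, knot_fit = refit, uv = rerun$uv,
                       converged = rerun$converged, stalled = rerun$stalled)
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }

  psi <- best$psi
  knot_fit <- best$knot_fit
  converged <- best$converged
  stalled <- best$stalled

  # delta-method standard errors from the final working fit (gap
  # coefficients ~ 0 at convergence)
  uv_final <- best$uv
  V <- uv_final$vcov_beta
  delta <- uv_final$delta
  gamma <- uv_final$gamma
  se <- vapply(seq_len(k), function(j) {
    un <- paste0(".U", j); vn <- paste0(".V", j)
    r <- gamma[j] / delta[j]
    v <- (V[vn, vn] - 2 * r * V[vn, un] + r^2 * V[un, un]) / delta[j]^2
    sqrt(max(v, 0))
  }, numeric(1))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  psi_df <- data.frame(estimate = psi, se = se,
                       lower = psi - zq * se, upper = psi + zq * se)

  out <- list(
    psi = psi_df,
    beta = knot_fit$beta,
    delta = unname(knot_fit$beta[paste0(".k", seq_len(k))]),
    gamma = gamma,
    vc = knot_fit$vc,
    loglik = knot_fit$loglik,
    aic = knot_fit$aic,
    bic = knot_fit$bic,
    n_params = knot_fit$n_params,
    trace = trace,
    converged = converged,
    stalled = stalled,
    knot_fit = knot_fit,
    uv_vcov = V,
    n_changepoints = k,
    covariates = covariates,
    conf_level = conf_level,
    age_range = rng,
    control = list(tol_psi = tol_psi, max_iter = max_iter, min_gap = min_gap)
  )
  class(out) <- "cvh_segmented"
  out$segment_slopes <- segment_slopes(out)
  out
}

#' Per-segment slopes of a segmented fit
#'
#' The slope of segment `k` is the baseline slope plus the accumulated
#' slope increments, `slope_k = beta_1 + sum_{j < k} delta_j` (the
#' telescoping identity). Standard errors come from the corresponding linear
#' contrast on the fixed-effect covariance of the final fixed-knot fit.
#'
#' @param fit a `cvh_segmented` object.
#' @param conf_level confidence level.
#' @return data frame with one row per segment: `segment`, `from`, `to`,
#'   `slope`, `se`, `lower`, `upper`.
#' @export
segment_slopes <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "cvh_segmented"))
  kf <- fit$knot_fit
  k <- fit$n_changepoints
  if (k == 0) return(fit$segment_slopes)
  nm <- names(kf$beta)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  bounds <- c(fit$age_range[1], fit$psi$estimate, fit$age_range[2])
  rows <- lapply(seq_len(k + 1), function(s) {
    w <- setNames(numeric(length(nm)), nm)
    w[".a"] <- 1
    if (s > 1) w[paste0(".k", seq_len(s - 1))] <- 1
    est <- sum(w * kf$beta)
    se <- sqrt(drop(t(w) %*% kf$vcov_beta %*% w))
    data.frame(segment = s, from = bounds[s], to = bounds[s + 1],
               slope = est, se = se,
               lower = est - zq * se, upper = est + zq * se)
  })
  do.call(rbind, rows)
}

#' @export
print.cvh_segmented <- function(x, digits = 3, ...) {
  cat(sprintf("Segmented linear mixed model: %d change point(s), %s\n",
              x$n_changepoints,
              if (x$converged) "converged" else "NOT converged"))
  if (x$n_changepoints > 0) {
    cat("Change points (years):\n")
    print(round(x$psi, digits))
  }
  cat("Segment slopes (points/year):\n")
  print(round(x$segment_slopes, digits))
  cat(sprintf("logLik %.3f | AIC %.1f | BIC %.1f | iterations %d\n",
              x$loglik, x$aic, x$bic, max(x$trace$iter)))
  invisible(x)
}

#' Brute-force profile-likelihood grid search for the change points
#'
#' Fits the fixed-knot mixed model at every admissible grid point (for two
#' change points, every ordered pair separated by at least `min_gap`) and
#' returns the grid argmax with the full profile. Serves as an independent
#' check of the iterative estimator: by construction the profile value at
#' the argmax is at least the profile value anywhere else on the grid.
#'
#' @inheritParams fit_segmented
#' @param grid_step grid resolution in years.
#' @param range optional numeric length-2 restricting the search window
#'   (defaults to the observed age range shrunk by `min_gap`).
#' @return list with `psi` (grid argmax), `loglik` (profile maximum) and
#'   `profile` (data frame of grid points and log-likelihoods).
#' @export
profile_grid_oracle <- function(data, n_changepoints = 1,
                                covariates = character(), grid_step = 0.5,
                                range = NULL, min_gap = 3,
                                response = "cvh_score") {
  stopifnot(n_changepoints %in% 1:2, grid_step > 0)
  rng <- base::range(data$age)
  lo <- rng[1] + min_gap; hi <- rng[2] - min_gap
  if (!is.null(range)) { lo <- max(lo, range[1]); hi <- min(hi, range[2]) }
  if (lo > hi) stop("configuration error: empty change-point grid")
  grid1 <- seq(lo, hi, by = grid_step)
  if (n_changepoints == 1) {
    pts <- data.frame(psi1 = grid1)
  } else {
    pts <- expand.grid(psi1 = grid1, psi2 = grid1)
    pts <- pts[pts$psi2 - pts$psi1 >= min_gap, , drop = FALSE]
    if (!nrow(pts)) stop("configuration error: empty change-point grid")
  }
  pts$loglik <- vapply(seq_len(nrow(pts)), function(i) {
    fit_lmm_fixed_knots(data, knots = as.numeric(pts[i, seq_len(n_changepoints)]),
                        covariates = covariates, response = response)$loglik
  }, numeric(1))
  best <- which.max(pts$loglik)
  list(psi = as.numeric(pts[best, seq_len(n_changepoints)]),
       loglik = pts$loglik[best],
       profile = pts)
}
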