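#' Mixed-effects model specification for growth-law fitting
#'
#' Specifies which growth law to fit to longitudinal log-PSA data and which
#' parameters carry per-patient random effects. The response is
#' \eqn{y_{ij} = \ln(P_{ij}/P_R)}; the mean function is the law's log-PSA
#' trajectory with per-patient parameter vector
#' \eqn{\phi_i = \beta + Z b_i}, \eqn{b_i \sim N(0, \Omega)} (diagonal),
#' and additive Gaussian residuals. All parameters are estimated on a
#' transformed scale (log for positive rates and capacities, logit for
#' exponents in (0,1), identity for the per-patient log-baseline `u0`), so
#' random effects are lognormal/logit-normal on the natural scale.
#'
#' @param law a [growth_law()] carrying the law name, P_R, and (optionally)
#'   starting values for the fixed effects.
#' @param random names of parameters with per-patient random effects, a
#'   subset of `c("u0", names(law_parameter_scales(law$name)))`. The default
#'   `c("u0", "a")` (per-patient baseline and growth rate) is the smallest
#'   specification that accommodates the wide baseline spread of sparse
#'   registry-style cohorts.
#' @param censored how to treat observations flagged censored-at-P_R:
#'   `"exclude"` (default) drops them, `"floor"` keeps them at P_R.
#' @return object of class `nmem_spec`.
#' @export
nmem_spec <- function(law, random = c("u0", "a"),
                      censored = c("exclude", "floor")) {
  stopifnot(inherits(law, "growth_law"))
  censored <- match.arg(censored)
  all_pars <- c("u0", names(law_parameter_scales(law$name)))
  bad <- setdiff(random, all_pars)
  if (length(bad) > 0)
    stop("random-effect names not in the parameter set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(law = law, random = random, censored = censored),
            class = "nmem_spec")
}

# transformed-scale parameterization: u0 identity + law params per scale map
.theta_scales <- function(law_name) {
  c(u0 = "identity", law_parameter_scales(law_name))
}

.theta_to_natural <- function(theta, scales) {
  out <- theta
  for (nm in names(theta)) out[nm] <- .from_transformed(
    min(max(theta[[nm]], -30), 30), scales[[nm]])
  out
}

# fast internal law construction (skips constructor validation; transforms
# guarantee the constraints)
.law_from_theta <- function(name, PR, nat) {
  law <- as.list(nat[setdiff(names(nat), "u0")])
  law$name <- name
  law$PR <- PR
  class(law) <- "growth_law"
  law
}

# build a law-specific vectorized mean function f(TH, t): TH is an N x p
# matrix of transformed parameters (one row per observation), t a length-N
# time vector. Built once per fit; transforms are inlined and clamped so the
# optimizer can roam freely.
.make_mean_fun_v <- function(law_name, PR) {
  cl <- identity   # beta is box-bounded by the optimizer; overflow guarded
  switch(law_name,
    exponential = function(TH, t) cl(TH[, 1]) + exp(cl(TH[, 2])) * t,
    gompertz = function(TH, t) {
      u0 <- cl(TH[, 1]); a <- exp(cl(TH[, 2])); uK <- cl(TH[, 3]) - log(PR)
      uK + (u0 - uK) * exp(-a * t)
    },
    logistic = function(TH, t) {
      u0 <- cl(TH[, 1]); a <- exp(cl(TH[, 2])); uK <- cl(TH[, 3]) - log(PR)
      uK - log1p(expm1(uK - u0) * exp(-a * t))
    },
    generalized_logistic = function(TH, t) {
      u0 <- cl(TH[, 1]); a <- exp(cl(TH[, 2])); uK <- cl(TH[, 3]) - log(PR)
      g <- stats::plogis(cl(TH[, 4]))
      w <- g * (u0 - uK)
      s <- exp(-g * a * t)
      uK + (w - log(exp(w) * (1 - s) + s)) / g
    },
    powerlog = function(TH, t) {
      u0 <- cl(TH[, 1]); a <- exp(cl(TH[, 2])); b <- exp(cl(TH[, 3]))
      g <- stats::plogis(cl(TH[, 4]))
      neg <- u0 < 0
      tst <- ifelse(neg, -u0 / a, 0)
      v0 <- ifelse(neg, 1, (1 + b * pmax(u0, 0))^(1 - g))
      v <- v0 + (1 - g) * a * b * pmax(t - tst, 0)
      u <- (v^(1 / (1 - g)) - 1) / b
      ifelse(neg & t <= tst, u0 + a * t, u)
    },
    time_modulated = function(TH, t) {
      u0 <- cl(TH[, 1]); a <- exp(cl(TH[, 2])); lam <- exp(cl(TH[, 3]))
      g <- stats::plogis(cl(TH[, 4]))
      rhs <- exp(-g * u0) - g * a * (t + lam * t^2 / 2)
      u <- rep(700, length(rhs))
      ok <- rhs > 0
      u[ok] <- pmin(-log(rhs[ok]) / g, 700)
      u
    },
    modulated_exponent = {
      scales <- .theta_scales(law_name)
      function(TH, t) {
        # no closed form: integrate per distinct parameter row
        out <- numeric(length(t))
        key <- apply(TH, 1, paste, collapse = "\r")
        for (kk in unique(key)) {
          sel <- key == kk
          th <- TH[which(sel)[1], ]
          names(th) <- names(scales)
          out[sel] <- .nmem_mean(th, scales, law_name, PR, t[sel])
        }
        out
      }
    })
}

# mean function on the natural-scale path (reference implementation; used by
# fit_metrics and as the modulated_exponent fallback)
.nmem_mean <- function(theta, scales, law_name, PR, t) {
  nat <- .theta_to_natural(theta, scales)
  law <- .law_from_theta(law_name, PR, nat)
  u <- u_closed_form(law, nat[["u0"]], t)
  if (is.null(u)) {  # modulated_exponent: u' = a exp(k u), k = k0 + lambda t
    grid <- unique(c(0, sort(t)))
    rhs <- function(tt, y, parms) {
      k <- law$k0 + law$lambda * tt
      list(law$a * exp(pmin(k * y[[1]], 700)))
    }
    sol <- try(deSolve::lsoda(c(u = nat[["u0"]]), grid, rhs, parms = NULL,
                              rtol = 1e-8, atol = 1e-10), silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < length(grid))
      return(rep(NaN, length(t)))
    u <- sol[match(t, sol[, "time"]), "u"]
  }
  u
}

# stack per-patient data for the lockstep fitter
.stack_data <- function(dat) {
  n_i <- vapply(dat, function(d) length(d$y), integer(1))
  list(y = unlist(lapply(dat, `[[`, "y"), use.names = FALSE),
       t = unlist(lapply(dat, `[[`, "t"), use.names = FALSE),
       idx = rep(seq_along(dat), n_i),
       M = length(dat), N = sum(n_i), n_i = n_i)
}

# lockstep penalized Gauss-Newton: finds all patients' random-effect modes
# simultaneously. Returns list(B, rss_i, pen_i, logdet_i, g, ok).
.modes_lockstep <- function(st, beta, Zidx, omega, sigma, mv, B0 = NULL,
                            max_iter = 30) {
  q <- length(Zidx)
  n_beta <- length(beta)
  TH0 <- matrix(beta, st$N, n_beta, byrow = TRUE)
  expand <- function(B) {
    TH <- TH0
    if (q > 0) TH[, Zidx] <- TH[, Zidx] + B[st$idx, , drop = FALSE]
    TH
  }
  grpsum <- function(v) {
    out <- numeric(st$M)
    s <- rowsum(v, st$idx)
    out[as.integer(rownames(s))] <- s
    out
  }
  if (q == 0) {
    g <- mv(TH0, st$t)
    if (any(!is.finite(g))) return(list(ok = FALSE))
    return(list(B = matrix(0, st$M, 0), rss_i = grpsum((st$y - g)^2),
                pen_i = numeric(st$M), logdet_i = numeric(st$M), g = g,
                ok = TRUE))
  }
  iw <- 1 / omega^2
  B <- if (is.null(B0) || !is.matrix(B0) || any(dim(B0) != c(st$M, q)))
    matrix(0, st$M, q) else B0
  g <- mv(expand(B), st$t)
  if (any(!is.finite(g))) { B <- matrix(0, st$M, q); g <- mv(expand(B), st$t) }
  if (any(!is.finite(g))) return(list(ok = FALSE))
  pen_i <- as.numeric(B^2 %*% iw) / 2
  f <- grpsum((st$y - g)^2) / (2 * sigma^2) + pen_i
  h <- 1e-6
  jac <- function(B, g) {
    J <- matrix(0, st$N, q)
    for (k in seq_len(q)) {
      Bk <- B; Bk[, k] <- Bk[, k] + h
      gk <- mv(expand(Bk), st$t)
      if (any(!is.finite(gk))) return(NULL)
      J[, k] <- (gk - g) / h
    }
    J
  }
  solve_step <- function(A11, A12, A22, g1, g2) {
    if (q == 1) return(cbind(-g1 / A11))
    det <- A11 * A22 - A12^2
    cbind((-g1 * A22 + g2 * A12) / det, (g1 * A12 - g2 * A11) / det)
  }
  for (it in seq_len(max_iter)) {
    J <- jac(B, g)
    if (is.null(J)) return(list(ok = FALSE))
    res <- st$y - g
    A11 <- grpsum(J[, 1]^2) / sigma^2 + iw[1]
    g1 <- -grpsum(J[, 1] * res) / sigma^2 + B[, 1] * iw[1]
    if (q == 2) {
      A22 <- grpsum(J[, 2]^2) / sigma^2 + iw[2]
      A12 <- grpsum(J[, 1] * J[, 2]) / sigma^2
      g2 <- -grpsum(J[, 2] * res) / sigma^2 + B[, 2] * iw[2]
    } else { A22 <- A12 <- g2 <- NULL }
    step <- solve_step(A11, A12, A22, g1, g2)
    step[!is.finite(step)] <- 0
    scl <- rep(1, st$M)
    all_acc <- FALSE
    for (bt in 1:12) {
      Bc <- B + step * scl
      gc <- mv(expand(Bc), st$t)
      fc <- grpsum((st$y - gc)^2) / (2 * sigma^2) +
        as.numeric(Bc^2 %*% iw) / 2
      fc[!is.finite(fc)] <- Inf
      fail <- fc > f + 1e-12
      if (!any(fail)) { all_acc <- TRUE; break }
      scl[fail] <- scl[fail] / 2
      if (all(scl[fail] < 1e-7)) { step[fail, ] <- 0; scl[fail] <- 0 }
    }
    acc <- fc <= f + 1e-12
    moved <- if (any(acc)) max(abs((step * scl)[acc, , drop = FALSE])) else 0
    if (all_acc) {               # reuse the already-computed trial solution
      B <- Bc; g <- gc; f <- fc
    } else {
      B[acc, ] <- (B + step * scl)[acc, ]
      g <- mv(expand(B), st$t)
      f <- grpsum((st$y - g)^2) / (2 * sigma^2) + as.numeric(B^2 %*% iw) / 2
    }
    if (moved < 1e-8) break
  }
  J <- jac(B, g)
  if (is.null(J)) return(list(ok = FALSE))
  A11 <- grpsum(J[, 1]^2) / sigma^2 + iw[1]
  if (q == 2) {
    A22 <- grpsum(J[, 2]^2) / sigma^2 + iw[2]
    A12 <- grpsum(J[, 1] * J[, 2]) / sigma^2
    det <- A11 * A22 - A12^2
    if (any(det <= 0)) return(list(ok = FALSE))
    logdet <- log(det)
  } else logdet <- log(A11)
  list(B = B, rss_i = grpsum((st$y - g)^2),
       pen_i = as.numeric(B^2 %*% iw) / 2, logdet_i = logdet, g = g,
       ok = TRUE)
}

# Laplace-approximate marginal negative log-likelihood over all patients
.marginal_nll <- function(par, st, Zidx, n_beta, mv, warm) {
  n_re <- length(Zidx)
  beta <- par[seq_len(n_beta)]
  omega <- exp(par[n_beta + seq_len(n_re)])
  sigma <- exp(par[n_beta + n_re + 1])
  m <- .modes_lockstep(st, beta, Zidx, omega, sigma, mv, B0 = warm$B)
  if (!isTRUE(m$ok)) return(1e10)
  warm$B <- m$B
  nll <- sum(m$rss_i) / (2 * sigma^2) + sum(m$pen_i) +
    st$N * log(sigma) + st$N / 2 * log(2 * pi)
  if (n_re > 0)
    nll <- nll + st$M * sum(log(omega)) + 0.5 * sum(m$logdet_i)
  if (!is.finite(nll)) return(1e10)
  nll
}

# data-driven starting values on the transformed scale
.nmem_init <- function(dat, law, scales) {
  u0s <- vapply(dat, function(d) d$y[1], numeric(1))
  slopes <- vapply(dat, function(d) {
    if (length(unique(d$t)) < 2) return(NA_real_)
    coef(lm(d$y ~ d$t))[2]
  }, numeric(1))
  slope <- median(slopes[is.finite(slopes) & slopes > 0])
  if (!is.finite(slope)) slope <- 1e-3
  Pmax <- max(vapply(dat, function(d) max(d$y), numeric(1)))
  init <- c(u0 = mean(u0s))
  for (nm in names(scales)[-1]) {
    v <- switch(nm,
      a = slope,                                  # data-driven
      b = if (!is.null(law$b)) law$b else 0.5,
      gamma = if (!is.null(law$gamma)) law$gamma else 0.5,
      K = max(if (!is.null(law$K)) law$K else 0, law$PR * exp(Pmax) * 4),
      lambda = if (!is.null(law$lambda)) law$lambda else 1e-4,
      k0 = if (!is.null(law$k0)) law$k0 else 0.5)
    init[nm] <- .to_transformed(v, scales[[nm]])
  }
  init
}

#' Fit a growth law to a cohort by nonlinear mixed-effects
#'
#' Maximum (approximate) marginal likelihood estimation of the fixed effects,
#' diagonal random-effect variances, and residual variance, fitting
#' \eqn{\ln(P/P_R)} trajectories to the log PSA observations. The marginal
#' likelihood is approximated by the Laplace method with a nested penalized
#' Gauss-Newton search for each patient's random-effect mode (the individual
#' parameters are these posterior modes). Multi-start initialization guards
#' against local optima; the run is deterministic given data, spec, and seed.
#'
#' @param cohort cohort data.frame (`patient_id`, `time_days`, `psa_ng_ml`,
#'   optionally `censored_flag`).
#' @param spec [nmem_spec()].
#' @param n_starts number of optimizer starts (first from data-driven
#'   heuristics, the rest jittered).
#' @param seed seed for the start jitter (does not touch the global RNG
#'   stream).
#' @return object of class `nmem_fit`: fixed effects on the natural and
#'   transformed scales, random-effect SDs, residual SD, per-patient modes,
#'   marginal NLL, MSE, R^2 (individual predictions, log scale), AIC, BIC,
#'   parameter count (fixed effects + random-effect variances + residual
#'   variance), and convergence diagnostics.
#' @export
fit_nmem <- function(cohort, spec, n_starts = 5, seed = 1) {
  stopifnot(inherits(spec, "nmem_spec"), n_starts >= 1)
  law <- spec$law
  scales <- .theta_scales(law$name)
  dat <- .nmem_data(cohort, law$PR, spec$censored)
  if (length(dat) < 2)
    stop("need at least 2 patients with >= 2 usable observations",
         call. = FALSE)
  Zidx <- match(spec$random, names(scales))
  n_beta <- length(scales)
  n_re <- length(Zidx)
  init <- .nmem_init(dat, law, scales)
  st <- .stack_data(dat)
  mv <- .make_mean_fun_v(law$name, law$PR)
  omega0 <- rep(0.4, n_re)
  par0 <- c(init, log(omega0), log(0.4))
  lower <- c(rep(-30, n_beta), rep(log(1e-4), n_re), log(1e-6))
  upper <- c(rep(30, n_beta), rep(log(10), n_re), log(10))

  jitters <- matrix(0, n_starts, n_beta)
  if (n_starts > 1) {
    rng <- local({ set.seed(seed); matrix(rnorm((n_starts - 1) * n_beta,
                                                0, 0.4),
                                          n_starts - 1, n_beta) })
    jitters[-1, ] <- rng
  }
  best <- NULL
  evals <- new.env()
  evals$trace <- numeric(0)
  for (s in seq_len(n_starts)) {
    warm <- new.env(); warm$B <- NULL
    par_s <- par0
    par_s[seq_len(n_beta)] <- par_s[seq_len(n_beta)] + jitters[s, ]
    obj <- function(par) {
      v <- .marginal_nll(par, st, Zidx, n_beta, mv, warm)
      evals$trace <- c(evals$trace, v)
      v
    }
    fit <- try(nlminb(par_s, obj, lower = lower, upper = upper,
                      control = list(iter.max = 400, eval.max = 900,
                                     rel.tol = 1e-9)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best) || !is.finite(best$objective) || best$objective >= 1e10)
    stop("mixed-effects fit failed to converge from all starts", call. = FALSE)

  par <- best$par
  beta <- setNames(par[seq_len(n_beta)], names(scales))
  omega <- setNames(exp(par[n_beta + seq_len(n_re)]), spec$random)
  sigma <- unname(exp(par[n_beta + n_re + 1]))
  if (n_re > 0 && any(omega <= 2e-4))
    warning("random-effect variance collapsed towards zero for: ",
            paste(spec$random[omega <= 2e-4], collapse = ", "),
            "; effectively a fixed effect", call. = FALSE)

  # individual modes and fitted values at the optimum
  m <- .modes_lockstep(st, beta, Zidx, omega, sigma, mv)
  if (!isTRUE(m$ok))
    stop("failed to recover individual modes at the optimum", call. = FALSE)
  modes <- matrix(NA_real_, length(dat), n_beta,
                  dimnames = list(names(dat), names(scales)))
  for (i in seq_along(dat)) {
    th <- beta
    if (n_re > 0) th[Zidx] <- th[Zidx] + m$B[i, ]
    modes[i, ] <- .theta_to_natural(th, scales)
  }
  y_all <- st$y
  yhat <- m$g
  mse <- mean((y_all - yhat)^2)
  sst <- sum((y_all - mean(y_all))^2)
  r2 <- if (sst > 0) 1 - sum((y_all - yhat)^2) / sst else NA_real_
  n_obs <- length(y_all)
  n_params <- n_beta + n_re + 1
  nll <- best$objective
  structure(list(
    law_name = law$name, PR = law$PR, spec = spec,
    fixed_transformed = beta,
    fixed_estimates = .theta_to_natural(beta, scales),
    random_sd = omega, residual_sd = sigma,
    individual_modes = modes,
    nll = nll, mse = mse, r2 = r2,
    aic = 2 * n_params + 2 * nll, bic = n_params * log(n_obs) + 2 * nll,
    n_obs = n_obs, n_params = n_params,
    convergence = best$convergence, message = best$message,
    objective_trace = evals$trace,
    fitted = data.frame(patient_id = rep(names(dat), st$n_i),
                        time_days = st$t,
                        observed = y_all, predicted = yhat)
  ), class = "nmem_fit")
}

# split cohort into per-patient (t, y) lists on the log(P/PR) scale
.nmem_data <- function(cohort, PR, censored) {
  stopifnot(all(c("patient_id", "time_days", "psa_ng_ml") %in% names(cohort)))
  if (censored == "exclude" && "censored_flag" %in% names(cohort))
    cohort <- cohort[!cohort$censored_flag, , drop = FALSE]
  sp <- split(cohort, cohort$patient_id)
  sp <- lapply(sp, function(d) {
    d <- d[order(d$time_days), ]
    list(t = d$time_days, y = log(d$psa_ng_ml / PR))
  })
  sp[vapply(sp, function(d) length(d$y) >= 2, logical(1))]
}

#' @export
print.nmem_fit <- function(x, ...) {
  cat("<nmem_fit> law:", x$law_name, "\n fixed effects (natural scale):\n")
  print(signif(x$fixed_estimates, 5))
  cat(" random-effect SD (transformed scale):",
      if (length(x$random_sd)) paste(names(x$random_sd),
                                     signif(x$random_sd, 4),
                                     sep = "=", collapse = ", ") else "none",
      "\n residual SD:", signif(x$residual_sd, 4),
      "\n NLL:", round(x$nll, 2), " AIC:", round(x$aic, 2),
      " BIC:", round(x$bic, 2),
      "\n parameter count (fixed + RE variances + residual):", x$n_params,
      "\n", sep = " ")
  invisible(x)
}

#' Fit-quality metrics recomputed from a fit and its cohort
#'
#' Independently recomputes MSE and R^2 on the log(P/P_R) scale from the
#' stored per-patient modes, and the AIC/BIC identities from the reported
#' NLL and parameter count. The parameter count convention is: fixed effects
#' + random-effect variances + residual variance.
#'
#' @param fit an [nmem_fit()] result.
#' @param cohort the cohort the fit was computed on.
#' @return named list `mse`, `r2`, `nll`, `aic`, `bic`.
#' @export
fit_metrics <- function(fit, cohort) {
  stopifnot(inherits(fit, "nmem_fit"))
  scales <- .theta_scales(fit$law_name)
  dat <- .nmem_data(cohort, fit$PR, fit$spec$censored)
  y <- c(); yhat <- c()
  for (i in seq_along(dat)) {
    nat <- fit$individual_modes[i, ]
    th <- vapply(names(scales), function(nm)
      .to_transformed(nat[[nm]], scales[[nm]]), numeric(1))
    pred <- .nmem_mean(setNames(th, names(scales)), scales, fit$law_name,
                       fit$PR, dat[[i]]$t)
    y <- c(y, dat[[i]]$y); yhat <- c(yhat, pred)
  }
  sst <- sum((y - mean(y))^2)
  if (sst == 0) warning("zero-variance response: R^2 undefined", call. = FALSE)
  list(mse = mean((y - yhat)^2),
       r2 = if (sst > 0) 1 - sum((y - yhat)^2) / sst else NA_real_,
       nll = fit$nll,
       aic = 2 * fit$n_params + 2 * fit$nll,
       bic = fit$n_params * log(fit$n_obs) + 2 * fit$nll)
}

#' Compare growth laws on a cohort
#'
#' Fits each candidate law by [fit_nmem()] and ranks the results by AIC
#' (ties broken by BIC, then by fewer parameters). Failed fits are recorded
#' with NA metrics and ranked last, not fatal.
#'
#' @param cohort cohort data.frame.
#' @param laws character vector of law names (fitted with default
#'   specifications) or a list of [nmem_spec()] objects.
#' @param n_starts optimizer starts per law.
#' @param seed start-jitter seed.
#' @param PR reference PSA level used when `laws` is a character vector.
#' @return data.frame with one row per law, sorted by rank.
#' @export
model_selection <- function(cohort, laws, n_starts = 3, seed = 1, PR = 1) {
  if (is.character(laws)) {
    laws <- lapply(laws, function(nm) nmem_spec(.default_law(nm, PR)))
    names(laws) <- vapply(laws, function(s) s$law$name, character(1))
  }
  if (is.null(names(laws)))
    names(laws) <- vapply(laws, function(s) s$law$name, character(1))
  rows <- lapply(names(laws), function(nm) {
    fit <- tryCatch(suppressWarnings(
      fit_nmem(cohort, laws[[nm]], n_starts = n_starts, seed = seed)),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(model = nm, n_params = NA_integer_, mse = NA_real_,
                        r2 = NA_real_, nll = NA_real_, aic = NA_real_,
                        bic = NA_real_))
    data.frame(model = nm, n_params = fit$n_params, mse = fit$mse,
               r2 = fit$r2, nll = fit$nll, aic = fit$aic, bic = fit$bic)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$aic, out$bic, out$n_params, na.last = TRUE)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# default law objects for model comparison (starting values only; the
# fitter estimates all free parameters)
.default_law <- function(name, PR = 1) {
  switch(name,
    exponential = growth_law("exponential", a = 1e-3, PR = PR),
    gompertz = growth_law("gompertz", a = 1e-3, K = 1e3 * PR, PR = PR),
    logistic = growth_law("logistic", a = 1e-3, K = 1e3 * PR, PR = PR),
    generalized_logistic = growth_law("generalized_logistic", a = 1e-3,
                                      K = 1e3 * PR, gamma = 2 / 3, PR = PR),
    powerlog = growth_law("powerlog", a = 1e-3, b = 0.5, gamma = 0.5,
                          PR = PR),
    time_modulated = growth_law("time_modulated", a = 1e-3, lambda = 1e-4,
                                gamma = 0.5, PR = PR),
    modulated_exponent = growth_law("modulated_exponent", a = 1e-3, k0 = 0.5,
                                    lambda = 1e-4, PR = PR),
    stop("unknown law: ", name, call. = FALSE))
}
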