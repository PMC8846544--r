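#' Available per-capita growth laws
#'
#' Names of the growth-law family understood by [growth_law()]. `powerlog`
#' is the featured law of the package, \eqn{f(P) = a (1 + b \ln(P/P_R))^\gamma}
#' above the detection level \eqn{P_R} and \eqn{f(P) = a} below it, giving
#' exponential growth below detection and super-exponential growth above.
#'
#' @export
growth_law_names <- function() {
  c("exponential", "gompertz", "logistic", "generalized_logistic",
    "powerlog", "time_modulated", "modulated_exponent")
}

#' Construct a growth-law specification
#'
#' A growth law defines the per-capita PSA growth rate \eqn{f} in
#' \eqn{\dot P = P f(P, t)}. Supported laws and their parameters:
#' \describe{
#'   \item{exponential}{\eqn{f = a}.}
#'   \item{gompertz}{\eqn{f = -a \ln(P/K)}; saturates at carrying capacity `K`.}
#'   \item{logistic}{\eqn{f = a (1 - P/K)}.}
#'   \item{generalized_logistic}{\eqn{f = a (1 - (P/K)^\gamma)}; `gamma = 2/3`
#'     recovers the Greenspan avascular-tumor special case.}
#'   \item{powerlog}{\eqn{f = a} for \eqn{P \le P_R},
#'     \eqn{f = a (1 + b \ln(P/P_R))^\gamma} for \eqn{P > P_R}, with
#'     \eqn{b > 0} and \eqn{\gamma \in (0,1)}. Continuous at \eqn{P_R};
#'     unbounded, faster than exponential above the detection level.}
#'   \item{time_modulated}{\eqn{f = a (1 + \lambda t)(P/P_R)^\gamma}.}
#'   \item{modulated_exponent}{\eqn{f = a (P/P_R)^{k(t)}} with
#'     \eqn{\dot k = \lambda}, \eqn{k(0) = k0}; requires co-integration of
#'     the exponent, so trajectories solve a 2-ODE system.}
#' }
#'
#' `PR` is the PSA reference (detection) level in ng/ml. It is a fixed
#' constant of the law, never a fitted parameter; the default is 1 ng/ml.
#'
#' @param name one of [growth_law_names()].
#' @param a maximal per-capita growth rate (1/day); must be positive.
#' @param b dimensionless log-slope of the `powerlog` law (> 0).
#' @param gamma dimensionless exponent; in (0,1) for `powerlog`, positive for
#'   `generalized_logistic` and `time_modulated`.
#' @param K carrying capacity (ng/ml), for saturating laws.
#' @param lambda linear time-modulation rate (1/day).
#' @param k0 initial exponent of the `modulated_exponent` law.
#' @param PR detection/reference PSA level (ng/ml), fixed.
#' @return an object of class `growth_law`.
#' @examples
#' law <- growth_law("powerlog", a = 0.001, b = 0.5, gamma = 0.5)
#' per_capita_rate(2, law)
#' @export
growth_law <- function(name, a, b = NULL, gamma = NULL, K = NULL,
                       lambda = NULL, k0 = NULL, PR = 1) {
  name <- match.arg(name, growth_law_names())
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a > 0,
            is.numeric(PR), length(PR) == 1L, PR > 0)
  need <- function(x, nm, cond = x > 0) {
    if (is.null(x) || length(x) != 1L || !is.finite(x) || !cond)
      stop(sprintf("law '%s' requires a valid parameter '%s'", name, nm),
           call. = FALSE)
    x
  }
  pars <- list(a = a, PR = PR)
  switch(name,
    exponential = NULL,
    gompertz = {
      pars$K <- need(K, "K")
    },
    logistic = {
      pars$K <- need(K, "K")
    },
    generalized_logistic = {
      pars$K <- need(K, "K")
      pars$gamma <- need(gamma, "gamma")
    },
    powerlog = {
      pars$b <- need(b, "b")
      pars$gamma <- need(gamma, "gamma", cond = gamma > 0 && gamma < 1)
    },
    time_modulated = {
      pars$lambda <- need(lambda, "lambda")
      pars$gamma <- need(gamma, "gamma")
    },
    modulated_exponent = {
      pars$lambda <- need(lambda, "lambda")
      pars$k0 <- need(k0, "k0", cond = is.finite(k0))
    }
  )
  structure(c(list(name = name), pars), class = "growth_law")
}

#' @export
print.growth_law <- function(x, ...) {
  pars <- x[setdiff(names(x), "name")]
  cat("<growth_law:", x$name, "> ",
      paste(names(pars), signif(unlist(pars), 5), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Per-capita growth rate f(P, t)
#'
#' Evaluates the per-capita PSA growth rate of a law. For `powerlog` the rate
#' equals `a` for all \eqn{P \le P_R} (exponential growth below detection) and
#' \eqn{a(1 + b\ln(P/P_R))^\gamma} above, continuous at \eqn{P_R}. Gompertz is
#' evaluated by its limit convention \eqn{f(0^+) = +\infty} (returned as `Inf`);
#' logistic returns `a` at `P = 0`.
#'
#' @param P PSA level(s), ng/ml, non-negative.
#' @param law a [growth_law()].
#' @param t time in days; only used by time-dependent laws.
#' @return per-capita rate(s), 1/day.
#' @export
per_capita_rate <- function(P, law, t = 0) {
  stopifnot(inherits(law, "growth_law"), is.numeric(P))
  if (any(P < 0)) stop("negative PSA level", call. = FALSE)
  a <- law$a; PR <- law$PR
  switch(law$name,
    exponential = rep_len(a, length(P)),
    gompertz = ifelse(P == 0, Inf, -a * log(P / law$K)),
    logistic = a * (1 - P / law$K),
    generalized_logistic = a * (1 - (P / law$K)^law$gamma),
    powerlog = ifelse(P <= PR, a,
                      a * (1 + law$b * log(P / PR))^law$gamma),
    time_modulated = a * (1 + law$lambda * t) * (P / PR)^law$gamma,
    modulated_exponent = a * (P / PR)^(law$k0 + law$lambda * t)
  )
}

# closed-form log(P/PR) trajectories on the u = ln(P/PR) scale, vectorized
# over t; returns NULL for laws with no closed form (modulated_exponent).
# Blow-up (time_modulated) is capped at u = 700 so exp(u) stays finite.
u_closed_form <- function(law, u0, t) {
  a <- law$a
  switch(law$name,
    exponential = u0 + a * t,
    gompertz = {
      uK <- log(law$K / law$PR)
      uK + (u0 - uK) * exp(-a * t)
    },
    logistic = {
      uK <- log(law$K / law$PR)
      uK - log1p(expm1(uK - u0) * exp(-a * t))
    },
    generalized_logistic = {
      g <- law$gamma
      uK <- log(law$K / law$PR)
      w <- g * (u0 - uK)            # log Q0
      s <- exp(-g * a * t)
      # Q = Q0 / (Q0 + (1 - Q0) s);  u = uK + log(Q)/g
      uK + (w - log(exp(w) * (1 - s) + s)) / g
    },
    powerlog = {
      b <- law$b; g <- law$gamma
      from_zero <- function(tt) {           # start at u = 0
        v <- 1 + (1 - g) * a * b * tt
        (v^(1 / (1 - g)) - 1) / b
      }
      if (u0 >= 0) {
        v0 <- (1 + b * u0)^(1 - g)
        v <- v0 + (1 - g) * a * b * t
        (v^(1 / (1 - g)) - 1) / b
      } else {
        tstar <- -u0 / a
        ifelse(t <= tstar, u0 + a * t, from_zero(t - tstar))
      }
    },
    time_modulated = {
      g <- law$gamma
      rhs <- exp(-g * u0) - g * a * (t + law$lambda * t^2 / 2)
      u <- rep(700, length(rhs))          # finite-time blow-up: capped
      ok <- rhs > 0
      u[ok] <- pmin(-log(rhs[ok]) / g, 700)
      u
    },
    modulated_exponent = NULL
  )
}

#' Predicted log PSA ratio ln(P(t)/P_R)
#'
#' The quantity fitted by the mixed-effects module: the natural log of the
#' PSA trajectory relative to the reference level. Uses the law's closed-form
#' solution where one exists (all laws except `modulated_exponent`, which is
#' integrated numerically as a (P, k) system).
#'
#' @param law a [growth_law()].
#' @param P0 initial PSA (ng/ml), positive.
#' @param t vector of times (days), non-negative.
#' @param ... passed to [integrate_growth()] for laws without a closed form.
#' @return vector ln(P(t)/P_R), same length as `t`.
#' @export
log_psa_prediction <- function(law, P0, t, ...) {
  stopifnot(inherits(law, "growth_law"), P0 > 0, all(t >= 0))
  u0 <- log(P0 / law$PR)
  u <- u_closed_form(law, u0, t)
  if (!is.null(u)) return(u)
  ord <- order(t)
  grid <- unique(c(0, t[ord]))
  traj <- integrate_growth(P0, law, grid, ...)
  log(traj$psa_ng_ml[match(t, traj$time_days)] / law$PR)
}

#' Integrate a PSA growth law
#'
#' Numerically solves \eqn{\dot P = P f(P, t)} with an adaptive stiff-aware
#' integrator (`deSolve::lsodar`). For the `modulated_exponent` law the
#' exponent \eqn{k} is co-integrated (\eqn{\dot k = \lambda}). Since several
#' laws are super-exponential, integration stops when PSA exceeds `cap`; the
#' returned trajectory is then truncated, carries attribute `blowup` with the
#' bracketing times, and a warning is raised.
#'
#' @param P0 initial PSA (ng/ml), positive.
#' @param law a [growth_law()].
#' @param t_grid strictly increasing times (days).
#' @param rtol,atol solver tolerances.
#' @param cap PSA blow-up cap (ng/ml).
#' @return data.frame with columns `time_days`, `psa_ng_ml` (class
#'   `psa_trajectory`).
#' @export
integrate_growth <- function(P0, law, t_grid, rtol = 1e-8, atol = 1e-10,
                             cap = 1e6) {
  stopifnot(inherits(law, "growth_law"), is.numeric(P0), P0 > 0,
            length(t_grid) >= 2, all(diff(t_grid) > 0))
  two_dim <- law$name == "modulated_exponent"
  y0 <- if (two_dim) c(P = P0, k = law$k0) else c(P = P0)
  deriv <- function(t, y, parms) {
    lw <- law
    if (two_dim) lw$k0 <- y[["k"]] - lw$lambda * t  # k(t) carried in state
    P <- max(y[["P"]], 0)               # guard solver overshoot near zero
    dP <- if (P == 0) 0 else P * per_capita_rate(P, lw, t)
    if (two_dim) list(c(dP, law$lambda)) else list(dP)
  }
  root <- function(t, y, parms) y[["P"]] - cap
  sol <- deSolve::lsodar(y0, t_grid, deriv, parms = NULL,
                         rtol = rtol, atol = atol, rootfunc = root)
  out <- data.frame(time_days = sol[, "time"], psa_ng_ml = sol[, "P"])
  troot <- attr(sol, "troot")
  if (length(troot) > 0 && max(out$time_days) < max(t_grid)) {
    before <- max(c(0, t_grid[t_grid < troot[1]]))
    attr(out, "blowup") <- c(lower = before, upper = troot[1])
    warning(sprintf("PSA exceeded cap %g between t = %.6g and t = %.6g days",
                    cap, before, troot[1]), call. = FALSE)
  }
  class(out) <- c("psa_trajectory", "data.frame")
  out
}
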