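#' Acquired-resistance parameters
#'
#' Two phenomenological resistance mechanisms, each a saturating state
#' variable driven by drug exposure, \eqn{\dot r_i = \beta_i L (1 - r_i/l_i)},
#' \eqn{r_i(0) = 0}:
#' mechanism 1 (testosterone independence) feeds the PSA equation through
#' \eqn{g_1(r_1) = a_1 r_1}; mechanism 2 (resistance to the drug itself)
#' replaces the drug level inside the testosterone production term by
#' \eqn{g_2(r_2) = L (a_2 + e^{r_2}) / ((a_2 + 1) e^{r_2})}, which equals L at
#' \eqn{r_2 = 0} and decreases towards \eqn{L/(a_2+1)}.
#'
#' @param beta1,beta2 induction rates (1/(day * drug-unit)), >= 0; 0 switches
#'   the mechanism off.
#' @param l1,l2 saturation levels (> 0); each \eqn{r_i} stays in
#'   \eqn{[0, l_i)}.
#' @param a1 slope of the linear PSA-side influence `g1`.
#' @param a2 shape of the drug-side influence `g2` (> 0).
#' @return object of class `resistance_params`.
#' @export
resistance_params <- function(beta1 = 0, beta2 = 0, l1 = 1, l2 = 1,
                              a1 = 0, a2 = 1) {
  p <- list(beta1 = beta1, beta2 = beta2, l1 = l1, l2 = l2, a1 = a1, a2 = a2)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v) && v >= 0, logical(1))))
    stop("resistance parameters must be nonnegative scalars", call. = FALSE)
  stopifnot(l1 > 0, l2 > 0, a2 > 0)
  structure(p, class = "resistance_params")
}

#' Drug-side resistance influence g2
#'
#' \eqn{g_2(r_2) = L (a_2 + e^{r_2}) / ((a_2+1) e^{r_2})}: the effective drug
#' level felt by the testosterone production term. \eqn{g_2(0) = L},
#' decreasing, with infimum \eqn{L/(a_2+1)}.
#'
#' @param r2 resistance state(s), >= 0.
#' @param L drug level.
#' @param a2 shape parameter (> 0).
#' @export
g2_effective_drug <- function(r2, L, a2) L * (a2 + exp(r2)) / ((a2 + 1) * exp(r2))

#' Closed-form resistance trajectory under constant drug level
#'
#' Solution of \eqn{\dot r = \beta L (1 - r/l)}, \eqn{r(0)=0}:
#' \eqn{r(t) = l (1 - e^{-\beta L t / l})}, bounded in \eqn{[0, l)}.
#'
#' @param t time(s), days.
#' @param beta induction rate.
#' @param l saturation level (> 0).
#' @param L constant drug level.
#' @export
resistance_closed_form <- function(t, beta, l, L) {
  stopifnot(all(t >= 0), beta >= 0, l > 0, L >= 0)
  l * (1 - exp(-beta * L * t / l))
}

#' Full treatment-model parameters
#'
#' Parameters of the coupled PSA-hormone model under ADT. The PSA equation is
#' \deqn{\dot P = P f(P) + d_P (z - \bar z_0 + g_1(r_1)) P,}
#' coupled to the drug-influenced two-hormone system and the two resistance
#' states. \eqn{\bar z_0}, the untreated testosterone steady state, is always
#' derived from the hormone submodel at L = 0 (never a free parameter), so
#' the untreated baseline is self-consistent: at L = 0 with no resistance the
#' hormones settle at \eqn{(\bar x_0, \bar z_0)} and PSA follows the pure
#' growth law.
#'
#' @param growth a [growth_law()] (the threshold formulas require `powerlog`).
#' @param dP testosterone-coupling coefficient (1/(day * TES-unit)), >= 0.
#'   Large values reflect strongly hormone-sensitive tumors; small values
#'   reflect castrate-resistant disease.
#' @param hormones [hormone_params()].
#' @param resistance [resistance_params()].
#' @return object of class `full_model_params` with cached `z0_bar`.
#' @export
full_model_params <- function(growth, dP, hormones = hormone_params(),
                              resistance = resistance_params()) {
  stopifnot(inherits(growth, "growth_law"), inherits(hormones, "hormone_params"),
            inherits(resistance, "resistance_params"),
            is.numeric(dP), length(dP) == 1L, dP >= 0)
  z0 <- steady_state_two_with_drug(hormones, 0)[["z"]]
  structure(list(growth = growth, dP = dP, hormones = hormones,
                 resistance = resistance, z0_bar = z0),
            class = "full_model_params")
}

#' Critical growth rate for curability
#'
#' \eqn{\tilde a = d_P \bar z_0}: if the law's base growth rate `a` exceeds
#' this, no drug level (however large) creates a positive PSA steady state
#' and PSA escapes for every initial condition. `dP = 0` gives
#' \eqn{\tilde a = 0} (the castrate-resistant limit: always incurable).
#'
#' @param p [full_model_params()].
#' @return critical rate, 1/day.
#' @export
critical_growth_rate <- function(p) {
  stopifnot(inherits(p, "full_model_params"))
  p$dP * p$z0_bar
}

# effective testosterone deficit A = z0 - zL - (optional r1-saturation term)
.threshold_deficit <- function(p, L, r1_saturated, case1_extra_dp) {
  zL <- steady_state_two_with_drug(p$hormones, L)[["z"]]
  adj <- 0
  if (r1_saturated) {
    adj <- p$resistance$a1 * p$resistance$l1
    if (case1_extra_dp) adj <- adj * p$dP
  }
  p$z0_bar - zL - adj
}

#' Threshold (separatrix) PSA level under constant drug
#'
#' For the `powerlog` growth law and constant drug level L, the asymptotic
#' PSA equation \eqn{\dot P = P f(P) + d_P(\bar z_L - \bar z_0) P} has an
#' unstable positive steady state
#' \deqn{\bar P = P_R \exp\Big(\frac{(d_P(\bar z_0 - \bar z_L)/a)^{1/\gamma}
#'   - 1}{b}\Big)}
#' whenever \eqn{a < d_P(\bar z_0 - \bar z_L)}; below it PSA decays to zero,
#' above it PSA escapes. \eqn{\bar P \ge P_R} whenever it exists and is
#' increasing in L. With resistance mechanism 1 saturated
#' (`r1_saturated = TRUE`) the deficit is reduced by \eqn{a_1 l_1}; the
#' variant reading with an extra \eqn{d_P} factor on that term is available
#' via `case1_extra_dp = TRUE`.
#'
#' @param p [full_model_params()] with a `powerlog` growth law.
#' @param L constant drug level, >= 0.
#' @param r1_saturated account for mechanism 1 at its saturation level l1.
#' @param case1_extra_dp alternative reading of the saturated-mechanism-1
#'   correction (multiplies `a1*l1` by `dP`).
#' @return the threshold PSA (ng/ml), or `NA_real_` when no positive steady
#'   state exists.
#' @export
psa_threshold <- function(p, L, r1_saturated = FALSE, case1_extra_dp = FALSE) {
  stopifnot(inherits(p, "full_model_params"), L >= 0)
  if (p$growth$name != "powerlog")
    stop("the threshold formula is specific to the 'powerlog' growth law",
         call. = FALSE)
  A <- .threshold_deficit(p, L, r1_saturated, case1_extra_dp)
  a <- p$growth$a
  if (!(p$dP * A >= a)) return(NA_real_)   # boundary case: P_bar = P_R
  p$growth$PR * exp(((p$dP * A / a)^(1 / p$growth$gamma) - 1) / p$growth$b)
}

#' Asymptotic fate of PSA under constant drug
#'
#' Integrates the asymptotic single PSA equation
#' \eqn{\dot P = P[f(P) - d_P(\bar z_0 - \bar z_L - adj)]} (on the log scale)
#' and classifies the outcome: `"decay"` once PSA falls below `0.5 * P_R`,
#' `"escape"` once it exceeds `cap`, `"indeterminate"` if neither happens by
#' `horizon`.
#'
#' @inheritParams psa_threshold
#' @param P0 initial PSA (ng/ml), > 0.
#' @param horizon integration horizon (days).
#' @param cap escape cap (ng/ml).
#' @param rtol,atol solver tolerances.
#' @return list with `fate` and `time` (days at which the fate fired, or NA).
#' @export
psa_fate <- function(p, L, P0, horizon = 20000, cap = 1e6,
                     r1_saturated = FALSE, case1_extra_dp = FALSE,
                     rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(p, "full_model_params"), P0 > 0)
  A <- .threshold_deficit(p, L, r1_saturated, case1_extra_dp)
  law <- p$growth
  drop_rate <- p$dP * A
  u0 <- log(P0 / law$PR)
  u_lo <- log(0.5)
  if (u0 <= u_lo) return(list(fate = "decay", time = 0))
  # keep the escape root strictly above the start so root detection works
  u_hi <- max(log(cap / law$PR), u0 + log(1000))
  rhs <- function(t, y, parms) {
    P <- law$PR * exp(y[[1]])
    list(per_capita_rate(P, law) - drop_rate)
  }
  root <- function(t, y, parms) c(y[[1]] - u_lo, y[[1]] - u_hi)
  sol <- deSolve::lsodar(c(u = u0), c(0, horizon), rhs, parms = NULL,
                         rtol = rtol, atol = atol, rootfunc = root)
  troot <- attr(sol, "troot")
  if (length(troot) == 0)
    return(list(fate = "indeterminate", time = NA_real_))
  u_end <- sol[nrow(sol), "u"]
  fate <- if (abs(u_end - u_lo) < abs(u_end - u_hi)) "decay" else "escape"
  list(fate = fate, time = troot[1])
}

#' Classify the treatment regime
#'
#' Compares the growth rate `a` with the critical rate \eqn{\tilde a} and
#' with the drug-dependent deficit \eqn{d_P(\bar z_0 - \bar z_L)}:
#' \itemize{
#'   \item `a > a_tilde`: no positive steady state for any drug level; PSA
#'     escapes regardless of the initial condition.
#'   \item `a < dP (z0 - zL)` at the given L: a threshold \eqn{\bar P}
#'     exists; PSA decays for \eqn{P_0 < \bar P} and escapes for
#'     \eqn{P_0 > \bar P}.
#'   \item otherwise the drug level is insufficient for this growth rate and
#'     PSA escapes.
#' }
#'
#' @inheritParams psa_fate
#' @param simulate also run [psa_fate()] to confirm the prediction.
#' @return list of class `regime_report`: `regime`
#'   (`"no_positive_SS_unbounded"` or `"threshold_exists"`), `P_bar`,
#'   `a_tilde`, `effective_condition`, `predicted_fate`, and optionally
#'   `simulated_fate`.
#' @export
classify_regime <- function(p, L, P0, simulate = FALSE,
                            r1_saturated = FALSE, case1_extra_dp = FALSE,
                            horizon = 20000, cap = 1e6) {
  stopifnot(inherits(p, "full_model_params"), P0 > 0)
  a <- p$growth$a
  at <- critical_growth_rate(p)
  A <- .threshold_deficit(p, L, r1_saturated, case1_extra_dp)
  Pbar <- psa_threshold(p, L, r1_saturated, case1_extra_dp)
  if (is.na(Pbar)) {
    regime <- "no_positive_SS_unbounded"
    cond <- if (a > at) "a > a_tilde (incurable at any drug level)"
            else "a >= dP*(z0 - zL) at this L (drug level insufficient)"
    fate <- "escape"
  } else {
    regime <- "threshold_exists"
    cond <- "a < dP*(z0 - zL): threshold P_bar exists"
    if (abs(P0 - Pbar) < 1e-10 * Pbar) {
      warning("P0 equals the threshold: non-generic unstable equilibrium",
              call. = FALSE)
      fate <- "threshold"
    } else fate <- if (P0 < Pbar) "decay" else "escape"
  }
  out <- list(regime = regime, P_bar = Pbar, a_tilde = at,
              deficit = A, effective_condition = cond, predicted_fate = fate)
  if (simulate)
    out$simulated_fate <- psa_fate(p, L, P0, horizon = horizon, cap = cap,
                                   r1_saturated = r1_saturated,
                                   case1_extra_dp = case1_extra_dp)$fate
  class(out) <- "regime_report"
  out
}

#' @export
print.regime_report <- function(x, ...) {
  cat("<regime_report>\n  regime: ", x$regime,
      "\n  a_tilde: ", signif(x$a_tilde, 6),
      "\n  P_bar: ", if (is.na(x$P_bar)) "none" else signif(x$P_bar, 6),
      "\n  condition: ", x$effective_condition,
      "\n  predicted fate: ", x$predicted_fate, "\n", sep = "")
  if (!is.null(x$simulated_fate))
    cat("  simulated fate: ", x$simulated_fate, "\n", sep = "")
  invisible(x)
}

#' Integrate the full treatment model with resistance
#'
#' Solves the five-equation system
#' \deqn{\dot P = P f(P) + d_P (z - \bar z_0 + a_1 r_1) P,\quad
#'       \dot x = h_1(z) - d_1 x,\quad
#'       \dot z = h_3(x, g_2(r_2)) - d_3 z,\quad
#'       \dot r_i = \beta_i L (1 - r_i/l_i).}
#' With both `beta_i = 0` the right-hand side reduces exactly to the
#' no-resistance model. The drug level may be a constant, a function of time,
#' or a PK trajectory data.frame (`time_days`, `concentration`), which is
#' linearly interpolated; with time-varying L the resistance equations use
#' the instantaneous L(t) (an extension beyond the constant-L analysis).
#' Integration stops if PSA exceeds `cap` (clinical escape); the trajectory
#' is then truncated with attribute `blowup` and a warning.
#'
#' @param p [full_model_params()].
#' @param L constant drug level, function of time, or PK trajectory
#'   data.frame.
#' @param s0 named initial state `c(P=, x=, z=)` (resistance always starts
#'   at 0). Defaults to hormones at their untreated steady state and
#'   `P = 2 * PR`.
#' @param t_grid increasing output times (days).
#' @param cap PSA escape cap (ng/ml).
#' @param rtol,atol solver tolerances.
#' @return data.frame with `time_days`, `P`, `x`, `z`, `r1`, `r2`, `L`.
#' @export
integrate_full_model <- function(p, L, s0 = NULL, t_grid, cap = 1e6,
                                 rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "full_model_params"), all(diff(t_grid) > 0))
  h <- p$hormones; rs <- p$resistance
  L_fun <- if (is.function(L)) L
           else if (is.data.frame(L))
             approxfun(L$time_days, L$concentration, rule = 2)
           else function(t) L
  if (is.null(s0)) {
    ss <- steady_state_two_with_drug(h, 0)
    s0 <- c(P = 2 * p$growth$PR, x = ss[["x"]], z = ss[["z"]])
  }
  stopifnot(all(c("P", "x", "z") %in% names(s0)), s0[["P"]] > 0,
            s0[["x"]] >= 0, s0[["z"]] >= 0)
  y0 <- c(P = s0[["P"]], x = s0[["x"]], z = s0[["z"]], r1 = 0, r2 = 0)
  rhs <- function(t, y, parms) {
    Lt <- L_fun(t)
    g2 <- g2_effective_drug(y[["r2"]], Lt, rs$a2)
    P <- max(y[["P"]], 0)               # guard solver overshoot in remission
    dP_eq <- if (P == 0) 0 else
      P * per_capita_rate(P, p$growth, t) +
        p$dP * (y[["z"]] - p$z0_bar + rs$a1 * y[["r1"]]) * P
    list(c(dP_eq,
           .h1(y[["z"]], h) - h$d1 * y[["x"]],
           .h3(y[["x"]], g2, h) - h$d3 * y[["z"]],
           rs$beta1 * Lt * (1 - y[["r1"]] / rs$l1),
           rs$beta2 * Lt * (1 - y[["r2"]] / rs$l2)))
  }
  root <- function(t, y, parms) y[["P"]] - cap
  sol <- deSolve::lsodar(y0, t_grid, rhs, parms = NULL, rtol = rtol,
                         atol = atol, rootfunc = root)
  out <- as.data.frame(sol)
  names(out)[1] <- "time_days"
  out$P <- pmax(out$P, 0)               # clip solver noise below zero
  out$L <- vapply(out$time_days, L_fun, numeric(1))
  troot <- attr(sol, "troot")
  if (length(troot) > 0 && max(out$time_days) < max(t_grid)) {
    before <- max(c(0, t_grid[t_grid < troot[1]]))
    attr(out, "blowup") <- c(lower = before, upper = troot[1])
    warning(sprintf("PSA exceeded cap %g between t = %.6g and t = %.6g days",
                    cap, before, troot[1]), call. = FALSE)
  }
  out
}

#' Steady state of the reduced (x, z, r2) resistance subsystem
#'
#' Under constant drug the (x, z, r2) subsystem decouples from PSA and
#' mechanism 1. Its unique positive steady state has \eqn{\bar r_2 = l_2} and
#' testosterone solving
#' \deqn{(c_3 + g_2(l_2))\bar z^2 + (q_1 + c_1 (c_3 + g_2(l_2)))\bar z
#'   - q_1 q_3 = 0,}
#' with \eqn{q_i = p_i/(b_i d_i)}, \eqn{c_i = 1/b_i}; it is locally stable
#' for all parameter values.
#'
#' @param p [full_model_params()].
#' @param L constant drug level.
#' @return named vector `c(x, z, r2)`.
#' @export
reduced_resistance_steady_state <- function(p, L) {
  stopifnot(inherits(p, "full_model_params"), L >= 0)
  h <- p$hormones; rs <- p$resistance
  g2l <- g2_effective_drug(rs$l2, L, rs$a2)
  q1 <- h$p1 / (h$b1 * h$d1); c1 <- 1 / h$b1
  q3 <- h$p3 / (h$b3 * h$d3); c3 <- 1 / h$b3
  z <- .pos_quad_root(c3 + g2l, q1 + c1 * (c3 + g2l), q1 * q3)
  c(x = q1 / (c1 + z), z = z, r2 = rs$l2)
}

#' Integrate the reduced (x, z, r2) resistance subsystem
#'
#' @param p [full_model_params()].
#' @param L constant drug level.
#' @param s0 named initial state `c(x=, z=)`; r2 starts at 0.
#' @param t_grid increasing output times (days).
#' @param rtol,atol solver tolerances.
#' @return data.frame with `time_days`, `x`, `z`, `r2`.
#' @export
reduced_resistance_system <- function(p, L, s0 = NULL, t_grid,
                                      rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(p, "full_model_params"), is.numeric(L), length(L) == 1L,
            L >= 0, all(diff(t_grid) > 0))
  h <- p$hormones; rs <- p$resistance
  if (is.null(s0)) {
    ss <- steady_state_two_with_drug(h, 0)
    s0 <- c(x = ss[["x"]], z = ss[["z"]])
  }
  y0 <- c(x = s0[["x"]], z = s0[["z"]], r2 = 0)
  beta3 <- rs$beta2 * L
  rhs <- function(t, y, parms) {
    g2 <- g2_effective_drug(y[["r2"]], L, rs$a2)
    list(c(.h1(y[["z"]], h) - h$d1 * y[["x"]],
           .h3(y[["x"]], g2, h) - h$d3 * y[["z"]],
           beta3 * (1 - y[["r2"]] / rs$l2)))
  }
  out <- as.data.frame(deSolve::lsoda(y0, t_grid, rhs, parms = NULL,
                                      rtol = rtol, atol = atol))
  names(out)[1] <- "time_days"
  out
}

#' Detect biochemical failure in a PSA trajectory
#'
#' Biochemical failure is a sustained PSA rise above the post-treatment
#' nadir. This detector returns the first time at which PSA exceeds
#' `rise_factor` times the running nadir (the minimum over all earlier
#' points, restricted to times within `nadir_window` if given).
#'
#' @param traj data.frame with a time column (`time_days`) and a PSA column
#'   (`P` or `psa_ng_ml`).
#' @param nadir_window only times `<= nadir_window` contribute to the nadir
#'   (default `Inf`: running minimum over the whole past).
#' @param rise_factor multiplicative rise over the nadir that defines failure.
#' @return failure time in days, or `NA_real_` if PSA never rises that much.
#' @export
detect_biochemical_failure <- function(traj, nadir_window = Inf,
                                       rise_factor = 2) {
  stopifnot(is.data.frame(traj), nrow(traj) > 0, rise_factor > 1)
  tcol <- if ("time_days" %in% names(traj)) "time_days" else names(traj)[1]
  pcol <- if ("P" %in% names(traj)) "P"
          else if ("psa_ng_ml" %in% names(traj)) "psa_ng_ml"
          else stop("no PSA column ('P' or 'psa_ng_ml') in trajectory",
                    call. = FALSE)
  tt <- traj[[tcol]]; P <- traj[[pcol]]
  nadir_seq <- cummin(ifelse(tt <= nadir_window, P, Inf))
  hit <- which(P > rise_factor * nadir_seq)
  if (length(hit) == 0) return(NA_real_)
  tt[hit[1]]
}
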