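#' Dosing schedule for depot injections
#'
#' @param time_days injection times (days), non-decreasing.
#' @param dose_mg doses (mg), positive; recycled to the length of `time_days`.
#' @return object of class `dose_schedule` (a data.frame).
#' @seealso [depot_schedule()] for the four labeled leuprolide depots.
#' @export
dose_schedule <- function(time_days, dose_mg) {
  stopifnot(is.numeric(time_days), is.numeric(dose_mg))
  if (length(time_days) > 0) {
    if (any(diff(time_days) < 0)) stop("dose times must be non-decreasing",
                                       call. = FALSE)
    dose_mg <- rep_len(dose_mg, length(time_days))
    if (any(dose_mg <= 0)) stop("doses must be positive", call. = FALSE)
  } else dose_mg <- numeric(0)
  structure(data.frame(time_days = time_days, dose_mg = dose_mg),
            class = c("dose_schedule", "data.frame"))
}

#' Standard leuprolide depot schedules
#'
#' The four labeled depot formulations: 7.5 mg every 4 weeks, 22.5 mg every
#' 12 weeks, 30 mg every 16 weeks, 45 mg every 24 weeks.
#'
#' @param preset one of `"7.5mg_4wk"`, `"22.5mg_12wk"`, `"30mg_16wk"`,
#'   `"45mg_24wk"`.
#' @param n_injections number of consecutive injections starting at day 0.
#' @return a [dose_schedule()].
#' @export
depot_schedule <- function(preset = c("7.5mg_4wk", "22.5mg_12wk",
                                      "30mg_16wk", "45mg_24wk"),
                           n_injections = 4) {
  preset <- match.arg(preset)
  stopifnot(n_injections >= 1)
  spec <- switch(preset,
                 "7.5mg_4wk" = c(7.5, 28), "22.5mg_12wk" = c(22.5, 84),
                 "30mg_16wk" = c(30, 112), "45mg_24wk" = c(45, 168))
  dose_schedule(time_days = (seq_len(n_injections) - 1) * spec[2],
                dose_mg = spec[1])
}

#' Mass-action (transit-compartment) PK parameters
#'
#' Parameters of the linear transit-compartment model for depot leuprolide:
#' a depot D feeding a chain of n transit compartments (delayed first-order
#' absorption at rate `k1`), direct first-order absorption `k2` from the
#' depot, optional zero-order absorption `k3`, central/peripheral exchange
#' `Q`, and central clearance `d_L`. The simplifying assumptions
#' `beta = k_tr = k1` (depot clearance and transit rates equal the delayed
#' absorption rate) and `Q = 0` (single compartment) are the defaults and
#' are recorded in the object; the full system remains available by setting
#' `beta`, `k_tr`, `Q` explicitly.
#'
#' @param alpha fraction of each administered dose entering the depot.
#' @param k1 delayed (transit-chain) absorption rate, 1/day.
#' @param k2 dimensionless immediate first-order absorption coefficient.
#' @param k3 zero-order absorption rate (amount/day); default 0 (off).
#' @param n_transit number of transit compartments (>= 1).
#' @param d_L central clearance rate, 1/day.
#' @param beta depot clearance rate, 1/day; defaults to `k1`.
#' @param k_tr transit rate, 1/day; defaults to `k1`.
#' @param Q central-peripheral flux, 1/day; default 0.
#' @return object of class `mass_action_pk`.
#' @export
mass_action_pk <- function(alpha = 1, k1 = 0.05, k2 = 0.01, k3 = 0,
                           n_transit = 5, d_L = 2,
                           beta = k1, k_tr = k1, Q = 0) {
  p <- list(alpha = alpha, k1 = k1, k2 = k2, k3 = k3, n_transit = n_transit,
            d_L = d_L, beta = beta, k_tr = k_tr, Q = Q)
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                  is.finite(v) && v >= 0, logical(1))
  if (!all(num)) stop("mass-action PK parameters must be nonnegative scalars",
                      call. = FALSE)
  stopifnot(n_transit >= 1, alpha > 0, k1 > 0, d_L > 0)
  p$n_transit <- as.integer(n_transit)
  p$simplified <- (beta == k1 && k_tr == k1 && Q == 0)
  structure(p, class = "mass_action_pk")
}

#' Closed-form transit-compartment amounts
#'
#' Amount of drug in the j-th transit compartment after a single dose at
#' t = 0, under the equal-rates simplification (`beta = k_tr = k1`):
#' \eqn{L_j(t) = \alpha (k_1 t)^j e^{-k_1 t} / j!} — a gamma-shaped pulse
#' peaking at \eqn{t = j/k_1}. `j = 0` returns the depot itself,
#' \eqn{D(t) = \alpha e^{-k_1 t}}.
#'
#' @param t time(s), days, >= 0.
#' @param j compartment index, 0 (depot) .. n.
#' @param alpha amount deposited at t = 0.
#' @param k1 transit/absorption rate, 1/day.
#' @return amount(s) in compartment `j`.
#' @export
transit_closed_form <- function(t, j, alpha, k1) {
  stopifnot(all(t >= 0), length(j) == 1L, j >= 0, j == round(j),
            alpha > 0, k1 > 0)
  if (j == 0) return(alpha * exp(-k1 * t))
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- alpha * exp(j * log(k1 * t[pos]) - k1 * t[pos] - lgamma(j + 1))
  out
}

#' Quasi-steady closed-form drug amount (single dose)
#'
#' The one-compartment approximation for a single dose at t = 0 with
#' `k3 = 0`: the central amount is taken at quasi-steady state with its
#' inflow, \eqn{L(t) = \alpha e^{-k_1 t}(k_2 + k_1^{n+1} t^n/n!)/d_L}, i.e.
#' \eqn{(k_2 D(t) + k_1 L_n(t))/d_L}. Accurate when clearance is fast
#' relative to the absorption kinetics (`d_L >> k1`, past the initial
#' boundary layer of width ~ `1/d_L`).
#'
#' @param t time(s), days, >= 0.
#' @param p [mass_action_pk()].
#' @return drug amount(s) in the central compartment.
#' @export
mass_action_concentration <- function(t, p) {
  stopifnot(inherits(p, "mass_action_pk"), all(t >= 0))
  n <- p$n_transit
  poly <- numeric(length(t))
  pos <- t > 0
  poly[pos] <- exp((n + 1) * log(p$k1) + n * log(t[pos]) - lgamma(n + 1))
  p$alpha * exp(-p$k1 * t) * (p$k2 + poly) / p$d_L
}

#' Integrate the full transit-compartment PK system
#'
#' Numerical solution of the linear depot/transit/central/peripheral system
#' with impulsive dosing: each dose at time \eqn{t_d} adds
#' \eqn{\alpha \cdot dose} to the depot. The system is linear, so multi-dose
#' trajectories superpose exactly. A nonzero `k3` acts as a continuous
#' zero-order infusion into the central compartment.
#'
#' @param p [mass_action_pk()].
#' @param schedule a [dose_schedule()].
#' @param t_grid increasing output times (days).
#' @param rtol,atol solver tolerances.
#' @return data.frame with `time_days`, `depot`, `transit_1..n`, `central`,
#'   `peripheral`, and `concentration` (= central amount).
#' @export
integrate_mass_action <- function(p, schedule, t_grid,
                                  rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(p, "mass_action_pk"), inherits(schedule, "dose_schedule"),
            all(diff(t_grid) > 0))
  n <- p$n_transit
  nm <- c("D", paste0("T", seq_len(n)), "Lc", "Lp")
  y0 <- setNames(rep(0, n + 3), nm)
  rhs <- function(t, y, parms) {
    D <- y[1]; Tr <- y[2:(n + 1)]; Lc <- y[n + 2]; Lp <- y[n + 3]
    dT <- p$k_tr * c(D, Tr[-n]) - p$k_tr * Tr
    dLc <- p$k1 * Tr[n] + p$k2 * D + p$k3 - p$Q * Lc + p$Q * Lp - p$d_L * Lc
    list(c(-p$beta * D, dT, dLc, p$Q * Lc - p$Q * Lp))
  }
  if (nrow(schedule) > 0 && any(schedule$time_days < t_grid[1]))
    stop("doses before the start of the time grid are not supported",
         call. = FALSE)
  times <- sort(unique(c(t_grid, schedule$time_days)))
  ev <- NULL
  if (nrow(schedule) > 0) {
    agg <- tapply(schedule$dose_mg, schedule$time_days, sum)
    dtime <- as.numeric(names(agg))
    damt <- p$alpha * as.numeric(agg)
    at_start <- dtime == times[1]
    y0["D"] <- sum(damt[at_start])      # events cannot fire at the initial time
    if (any(!at_start))
      ev <- list(data = data.frame(var = "D", time = dtime[!at_start],
                                   value = damt[!at_start], method = "add"))
  }
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol,
                        atol = atol, events = ev)
  out <- as.data.frame(sol)[match(t_grid, times), , drop = FALSE]
  names(out) <- c("time_days", "depot", paste0("transit_", seq_len(n)),
                  "central", "peripheral")
  out$concentration <- out$central
  rownames(out) <- NULL
  out
}
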