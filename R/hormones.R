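#' Hormone feedback parameters
#'
#' Parameters of the LHRH/LH/testosterone (x, y, z) feedback cascade.
#' LHRH production is inhibited by testosterone through
#' \eqn{h_1(z) = p_1/(1 + b_1 z)}; in the drug-influenced two-variable system
#' testosterone production is \eqn{h_3(x, L) = p_3 x / (1 + b_3 (x + L))},
#' a competition between LHRH and the LHRH-agonist drug for receptors.
#'
#' @param p1 LHRH production scale (amount/day).
#' @param b1 testosterone feedback strength (1/TES-unit).
#' @param d1,d2,d3 clearance rates of LHRH, LH, TES (1/day).
#' @param p2,p3 production rates of LH and TES (1/day). In the reduced
#'   two-variable systems `p3` plays the role of the quasi-steady compound
#'   rate \eqn{p_2 p_3 / d_2}; it is kept as an independent named parameter.
#' @param b3 drug/LHRH competition coefficient (1/amount).
#' @return object of class `hormone_params`.
#' @examples
#' steady_state_three(hormone_params())  # all parameters 1
#' @export
hormone_params <- function(p1 = 1, b1 = 1, d1 = 1, d2 = 1, d3 = 1,
                           p2 = 1, p3 = 1, b3 = 1) {
  p <- list(p1 = p1, b1 = b1, d1 = d1, d2 = d2, d3 = d3,
            p2 = p2, p3 = p3, b3 = b3)
  bad <- !vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                   is.finite(v) && v > 0, logical(1))
  if (any(bad))
    stop("hormone parameters must be strictly positive scalars: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  structure(p, class = "hormone_params")
}

#' @export
print.hormone_params <- function(x, ...) {
  cat("<hormone_params> ",
      paste(names(unclass(x)), signif(unlist(x), 5), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# positive root of A z^2 + B z - C = 0 (A, C > 0)
.pos_quad_root <- function(A, B, C) (-B + sqrt(B^2 + 4 * A * C)) / (2 * A)

#' Steady state of the three-hormone system
#'
#' Unique positive steady state of the LHRH/LH/TES cascade: the crossing of
#' the decreasing production curve \eqn{h_1(z)} with the line
#' \eqn{(d_1 d_2 d_3/(p_2 p_3)) z}, solved in closed form as a quadratic.
#'
#' @param p [hormone_params()].
#' @return named vector `c(x, y, z)`.
#' @export
steady_state_three <- function(p) {
  stopifnot(inherits(p, "hormone_params"))
  cc <- p$d1 * p$d2 * p$d3 / (p$p2 * p$p3)
  z <- .pos_quad_root(p$b1 * cc, cc, p$p1)
  c(x = p$d2 * p$d3 / (p$p2 * p$p3) * z, y = p$d3 / p$p3 * z, z = z)
}

#' Steady state of the reduced two-hormone system (no drug)
#'
#' @param p [hormone_params()].
#' @return named vector `c(x, z)`.
#' @export
steady_state_two <- function(p) {
  stopifnot(inherits(p, "hormone_params"))
  cc <- p$d1 * p$d3 / p$p3
  z <- .pos_quad_root(p$b1 * cc, cc, p$p1)
  c(x = p$d3 / p$p3 * z, z = z)
}

#' Steady state of the drug-influenced two-hormone system
#'
#' For a constant drug level L, the testosterone steady state is the unique
#' positive root of
#' \deqn{b_1(1 + b_3 L)\,\bar z^2 + (1 + b_3 L + p_1 b_3/d_1)\,\bar z
#'       - p_1 p_3/(d_1 d_3) = 0,}
#' and \eqn{\bar x_L = (p_1/d_1)/(1 + b_1 \bar z_L)}. \eqn{\bar z_L} is
#' strictly decreasing in L with limit 0; \eqn{\bar x_L} increases to
#' \eqn{p_1/d_1}.
#'
#' @param p [hormone_params()].
#' @param L constant drug amount, >= 0.
#' @return named vector `c(x, z)`.
#' @export
steady_state_two_with_drug <- function(p, L = 0) {
  stopifnot(inherits(p, "hormone_params"), is.numeric(L), length(L) == 1L,
            L >= 0)
  A <- p$b1 * (1 + p$b3 * L)
  B <- 1 + p$b3 * L + p$p1 * p$b3 / p$d1
  C <- p$p1 * p$p3 / (p$d1 * p$d3)
  z <- .pos_quad_root(A, B, C)
  c(x = (p$p1 / p$d1) / (1 + p$b1 * z), z = z)
}

#' Sensitivity of the testosterone steady state to the drug level
#'
#' Implicit-function derivative \eqn{d\bar z_L/dL} of the steady-state
#' quadratic of [steady_state_two_with_drug()]:
#' \deqn{\frac{d\bar z_L}{dL} = -\,\frac{b_3 \bar z_L (1 + b_1 \bar z_L)}
#'   {2 b_1 (1 + b_3 L) \bar z_L + 1 + b_3 L + p_1 b_3/d_1} < 0.}
#'
#' @param p [hormone_params()].
#' @param L constant drug amount, >= 0.
#' @return scalar derivative (TES-units per drug-unit).
#' @export
dz_steady_dL <- function(p, L = 0) {
  z <- steady_state_two_with_drug(p, L)[["z"]]
  -(p$b3 * z * (1 + p$b1 * z)) /
    (2 * p$b1 * (1 + p$b3 * L) * z + 1 + p$b3 * L + p$p1 * p$b3 / p$d1)
}

# right-hand sides -----------------------------------------------------------

.h1 <- function(z, p) p$p1 / (1 + p$b1 * z)
.h3 <- function(x, L, p) p$p3 * x / (1 + p$b3 * (x + L))

.hormone_rhs <- function(system, p, L_fun) {
  switch(system,
    three = function(t, s, parms) {
      list(c(.h1(s[["z"]], p) - p$d1 * s[["x"]],
             p$p2 * s[["x"]] - p$d2 * s[["y"]],
             p$p3 * s[["y"]] - p$d3 * s[["z"]]))
    },
    two = function(t, s, parms) {
      list(c(.h1(s[["z"]], p) - p$d1 * s[["x"]],
             p$p3 * s[["x"]] - p$d3 * s[["z"]]))
    },
    two_with_drug = function(t, s, parms) {
      list(c(.h1(s[["z"]], p) - p$d1 * s[["x"]],
             .h3(s[["x"]], L_fun(t), p) - p$d3 * s[["z"]]))
    }
  )
}

#' Integrate a hormone feedback system
#'
#' Solves one of the three variants of the testosterone secretion model:
#' the full three-variable LHRH/LH/TES cascade (`"three"`), the reduced
#' two-variable quasi-steady system (`"two"`), or the two-variable system
#' with drug competition in the testosterone production term
#' (`"two_with_drug"`). All variants dissipate into a compact attractor and
#' converge to the unique positive steady state.
#'
#' @param p [hormone_params()].
#' @param system one of `"three"`, `"two"`, `"two_with_drug"`.
#' @param L constant drug level or a function of time (days); only used by
#'   `"two_with_drug"`.
#' @param s0 named nonnegative initial state: `c(x=, y=, z=)` for the
#'   three-variable system, `c(x=, z=)` otherwise.
#' @param t_grid increasing output times (days).
#' @param rtol,atol solver tolerances.
#' @return data.frame with `time_days` and one column per state variable.
#' @export
integrate_hormones <- function(p, system = c("three", "two", "two_with_drug"),
                               L = 0, s0 = NULL, t_grid,
                               rtol = 1e-10, atol = 1e-12) {
  system <- match.arg(system)
  stopifnot(inherits(p, "hormone_params"), all(diff(t_grid) > 0))
  L_fun <- if (is.function(L)) L else function(t) L
  vars <- if (system == "three") c("x", "y", "z") else c("x", "z")
  if (is.null(s0)) s0 <- setNames(rep(0, length(vars)), vars)
  stopifnot(all(vars %in% names(s0)), all(s0[vars] >= 0))
  sol <- deSolve::lsoda(s0[vars], t_grid, .hormone_rhs(system, p, L_fun),
                        parms = NULL, rtol = rtol, atol = atol)
  out <- as.data.frame(sol)
  names(out)[1] <- "time_days"
  out
}

#' Local stability of a hormone-system steady state
#'
#' Computes the steady state, its Jacobian, and the Jacobian eigenvalues.
#' For the three-variable cascade the Routh-Hurwitz coefficients of the
#' characteristic polynomial are reported as well. All three systems have
#' their unique positive steady state locally asymptotically stable for
#' every positive parameter set; this function provides the numerical
#' verification.
#'
#' @inheritParams integrate_hormones
#' @param L constant drug level (only for `"two_with_drug"`).
#' @return list with `steady_state`, `jacobian`, `eigenvalues`,
#'   `max_real_part`, `stable`, and (three-variable case) `routh_hurwitz`.
#' @export
local_stability <- function(p, system = c("three", "two", "two_with_drug"),
                            L = 0) {
  system <- match.arg(system)
  stopifnot(inherits(p, "hormone_params"))
  h1p <- function(z) -p$p1 * p$b1 / (1 + p$b1 * z)^2
  if (system == "three") {
    ss <- steady_state_three(p)
    J <- rbind(c(-p$d1, 0, h1p(ss[["z"]])),
               c(p$p2, -p$d2, 0),
               c(0, p$p3, -p$d3))
  } else if (system == "two") {
    ss <- steady_state_two(p)
    J <- rbind(c(-p$d1, h1p(ss[["z"]])),
               c(p$p3, -p$d3))
  } else {
    ss <- steady_state_two_with_drug(p, L)
    dh3dx <- p$p3 * (1 + p$b3 * L) / (1 + p$b3 * (ss[["x"]] + L))^2
    J <- rbind(c(-p$d1, h1p(ss[["z"]])),
               c(dh3dx, -p$d3))
  }
  ev <- eigen(J, only.values = TRUE)$values
  out <- list(steady_state = ss, jacobian = J, eigenvalues = ev,
              max_real_part = max(Re(ev)), stable = max(Re(ev)) < 0)
  if (system == "three") {
    # char poly lambda^3 + a2 lambda^2 + a1 lambda + a0
    a2 <- -sum(diag(J))
    a1 <- sum(diag(J)[1] * diag(J)[2], diag(J)[1] * diag(J)[3],
              diag(J)[2] * diag(J)[3]) -
      (J[1, 2] * J[2, 1] + J[1, 3] * J[3, 1] + J[2, 3] * J[3, 2])
    a0 <- -det(J)
    out$routh_hurwitz <- c(a2 = a2, a1 = a1, a0 = a0,
                           a2a1_minus_a0 = a2 * a1 - a0)
  }
  out
}

#' Dissipativity functional of the three-hormone system
#'
#' Evaluates \eqn{U(x,y,z) = x + \frac{d_1}{2 p_2} y +
#' \frac{d_1 d_2}{4 p_2 p_3} z} and its orbital derivative. Along any
#' trajectory \eqn{\dot U \le h_1(0) - \alpha U} for
#' \eqn{0 < \alpha \le \min(d_1,d_2,d_3)/2}, which bounds all trajectories
#' eventually by \eqn{h_1(0)/\alpha}.
#'
#' @param state named vector or data.frame with `x`, `y`, `z`.
#' @param p [hormone_params()].
#' @return data.frame with columns `U` and `Udot`.
#' @export
dissipativity_functional <- function(state, p) {
  stopifnot(inherits(p, "hormone_params"))
  x <- state[["x"]]; y <- state[["y"]]; z <- state[["z"]]
  U <- x + p$d1 / (2 * p$p2) * y + p$d1 * p$d2 / (4 * p$p2 * p$p3) * z
  Udot <- (.h1(z, p) - p$d1 * x) +
    p$d1 / (2 * p$p2) * (p$p2 * x - p$d2 * y) +
    p$d1 * p$d2 / (4 * p$p2 * p$p3) * (p$p3 * y - p$d3 * z)
  data.frame(U = U, Udot = Udot)
}
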