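#' Diffusion-release PK parameters
#'
#' Parameters of the microsphere diffusion-release formulation: the depot is
#' a population of polymer microspheres from which the drug diffuses with an
#' absorbing surface, giving the classical spherical-release series. The
#' release rate `release_rate` is the ratio \eqn{D/R^2} of the diffusion
#' coefficient to the squared sphere radius (1/day); `M0` is the reference
#' dose mass contained in the spheres; `k` scales released drug into plasma
#' concentration units; `d_L` is the plasma clearance.
#'
#' The plasma equation driven by a dose of mass m injected at \eqn{t_d} is
#' \deqn{\dot L = k \frac{m}{M_0} \psi(r (t - t_d)) - d_L L,}
#' where \eqn{\psi} is the theta-type series of [psi()] and
#' \eqn{r} = `release_rate` by default. Supplying `a_rel` instead sets
#' \eqn{r = a_{rel}/M_0}, the alternative parameterization in which the
#' release clock is scaled by the dose mass. Dose mass scales the amplitude
#' only, so concentrations are exactly linear in dose and multi-dose curves
#' superpose.
#'
#' @param M0 reference initial drug mass in the spheres (mg).
#' @param release_rate \eqn{D/R^2} (1/day).
#' @param k release-to-plasma scaling (concentration/day at unit psi).
#' @param d_L plasma clearance (1/day).
#' @param a_rel optional alternative release-clock parameter; when given the
#'   psi argument rate is `a_rel / M0` instead of `release_rate`.
#' @return object of class `diffusion_pk`.
#' @export
diffusion_pk <- function(M0 = 7.5, release_rate = 0.01, k = 1, d_L = 2,
                         a_rel = NULL) {
  p <- list(M0 = M0, release_rate = release_rate, k = k, d_L = d_L,
            a_rel = a_rel)
  chk <- p[!vapply(p, is.null, logical(1))]
  if (!all(vapply(chk, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v) && v >= 0, logical(1))))
    stop("diffusion PK parameters must be nonnegative scalars", call. = FALSE)
  stopifnot(M0 > 0, release_rate > 0, k > 0)   # d_L = 0 allowed (no clearance)
  structure(p, class = "diffusion_pk")
}

.psi_rate <- function(p) if (is.null(p$a_rel)) p$release_rate else p$a_rel / p$M0

#' Theta-type exponential series psi(x)
#'
#' \eqn{\psi(x) = \sum_{n \ge 1} e^{-\pi^2 n^2 x}}, the series driving
#' diffusion release from a sphere. For moderate and large `x` the series is
#' summed directly, truncated when the next (positive, decreasing) term falls
#' below `tol`; for `x < 0.05`, where the naive series needs
#' \eqn{O(x^{-1/2})} terms, the Poisson-summation (Jacobi theta) identity
#' \deqn{\psi(x) = \frac{1}{2\sqrt{\pi x}}\Big(1 + 2\sum_{n\ge1} e^{-n^2/x}\Big)
#'   - \frac 12}
#' is used instead. Arguments below `1e-8` are floored at `1e-8`.
#'
#' @param x positive argument(s) (dimensionless release-clock time).
#' @param tol truncation tolerance.
#' @return psi value(s); diverges as \eqn{1/(2\sqrt{\pi x})} for small x,
#'   decays as \eqn{e^{-\pi^2 x}} for large x.
#' @export
psi <- function(x, tol = 1e-14) {
  stopifnot(is.numeric(x))
  if (any(x <= 0)) stop("psi(x) requires x > 0 (series diverges at 0)",
                        call. = FALSE)
  .psi_core(pmax(x, 1e-8), tol)
}

# psi without the evaluation floor; used where the 1/sqrt(x) growth near 0 is
# handled analytically (sqrt-time substitution in integrate_diffusion_pk)
.psi_core <- function(x, tol = 1e-14) {
  out <- numeric(length(x))
  small <- x < 0.05
  if (any(small)) {
    xs <- x[small]
    nmax <- ceiling(sqrt(max(xs) * log(1 / tol))) + 1
    s <- 0
    for (n in seq_len(nmax)) s <- s + exp(-n^2 / xs)
    out[small] <- (1 + 2 * s) / (2 * sqrt(pi * xs)) - 0.5
  }
  if (any(!small)) {
    xl <- x[!small]
    nmax <- ceiling(sqrt(log(1 / tol) / (pi^2 * min(xl)))) + 1
    s <- 0
    for (n in seq_len(nmax)) s <- s + exp(-pi^2 * n^2 * xl)
    out[!small] <- s
  }
  out
}

#' Drug mass remaining inside a microsphere
#'
#' Series solution for the mass still inside a sphere with uniform initial
#' loading and an absorbing surface:
#' \deqn{M_{in}(t) = M_0 \frac{6}{\pi^2} \sum_{n\ge1} \frac{1}{n^2}
#'   e^{-n^2 \pi^2 \tau}, \qquad \tau = (D/R^2)\,t.}
#' \eqn{M_{in}(0) = M_0} (via \eqn{\sum 1/n^2 = \pi^2/6}) and
#' \eqn{M_{in}} decreases to 0. For very small \eqn{\tau} the short-time
#' expansion \eqn{M_0(1 - 6\sqrt{\tau/\pi} + 3\tau)} is used (its neglected
#' terms are \eqn{O(e^{-1/\tau})}).
#'
#' @param t time(s), days, >= 0.
#' @param p [diffusion_pk()].
#' @param tol truncation tolerance (relative to M0).
#' @return remaining mass(es), mg.
#' @export
sphere_drug_mass <- function(t, p, tol = 1e-10) {
  stopifnot(inherits(p, "diffusion_pk"), all(t >= 0))
  tau <- p$release_rate * t
  out <- numeric(length(tau))
  small <- tau < 1e-4
  out[small] <- p$M0 * (1 - 6 * sqrt(tau[small] / pi) + 3 * tau[small])
  if (any(!small)) {
    tl <- tau[!small]
    nmax <- ceiling(sqrt(log(6 / (pi^2 * tol)) / (pi^2 * min(tl)))) + 1
    s <- 0
    for (n in seq_len(nmax)) s <- s + exp(-n^2 * pi^2 * tl) / n^2
    out[!small] <- p$M0 * 6 / pi^2 * s
  }
  out
}

#' Integrate the diffusion-release plasma model
#'
#' Solves \eqn{\dot L = \sum_d k (m_d/M_0)\, \psi(r (t - t_d)) - d_L L},
#' L(0) = 0, where the sum runs over doses already given and each dose
#' carries its own release clock starting at its injection time. The system
#' is linear, so the solution is computed as the superposition of single-dose
#' responses; each single-dose response is integrated in the substituted
#' variable \eqn{s = \sqrt{t - t_d}}, which removes the integrable
#' \eqn{1/\sqrt{t}} singularity of \eqn{\psi} at the dose time (the
#' right-limit convention for evaluation exactly at a dose time).
#'
#' With `d_L = 0`, a single dose of mass `M0`, and `k = 6 * release_rate * M0`,
#' the solution is the released mass \eqn{M_{out}(t)} itself, and
#' \eqn{M_{in}(t) + M_{out}(t) = M_0} for all t (mass balance).
#'
#' @param p [diffusion_pk()]; `d_L = 0` is allowed here (no clearance).
#' @param schedule a [dose_schedule()].
#' @param t_grid increasing output times (days), all >= 0.
#' @param rtol,atol solver tolerances.
#' @param tol psi truncation tolerance.
#' @return data.frame with `time_days`, `concentration`.
#' @export
integrate_diffusion_pk <- function(p, schedule, t_grid,
                                   rtol = 1e-10, atol = 1e-12, tol = 1e-14) {
  stopifnot(inherits(p, "diffusion_pk"), inherits(schedule, "dose_schedule"),
            all(diff(t_grid) > 0), all(t_grid >= 0))
  r <- .psi_rate(p)
  L <- numeric(length(t_grid))
  if (nrow(schedule) > 0) {
    for (d in seq_len(nrow(schedule))) {
      te <- t_grid - schedule$time_days[d]
      idx <- which(te > 0)
      if (length(idx) == 0) next
      s_out <- sqrt(te[idx])
      s_grid <- sort(unique(c(0, s_out)))
      amp <- p$k * schedule$dose_mg[d] / p$M0
      # dL/ds = 2 s (amp psi(r s^2) - d_L L); at s = 0 the drive limit is
      # amp / sqrt(pi r) since psi(x) ~ 1/(2 sqrt(pi x))
      rhs <- function(s, y, parms) {
        dr <- if (s <= 0) amp / sqrt(pi * r)
              else 2 * s * (amp * .psi_core(r * s^2, tol) - p$d_L * y[[1]])
        list(dr)
      }
      sol <- deSolve::lsoda(c(L = 0), s_grid, rhs, parms = NULL,
                            rtol = rtol, atol = atol)
      L[idx] <- L[idx] + sol[match(s_out, s_grid), "L"]
    }
  }
  data.frame(time_days = t_grid, concentration = L)
}
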