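# shared fixtures and small oracles used across test files

# hormone parameters from the nullcline-figure configuration:
# b1 = b3 = p1/d1 = 1, p3/d3 = 20
fig_hormones <- function() {
  hormone_params(p1 = 1, b1 = 1, d1 = 1, d2 = 1, d3 = 1,
                 p2 = 1, p3 = 20, b3 = 1)
}

# positive root of A z^2 + B z - C = 0, quadratic-formula oracle
quad_root <- function(A, B, C) (-B + sqrt(B^2 + 4 * A * C)) / (2 * A)

ref_powerlog <- function(PR = 1) {
  growth_law("powerlog", a = 0.001, b = 0.5, gamma = 0.5, PR = PR)
}

# geometric bisection on the fate of the asymptotic PSA equation: locates the
# separatrix between decay and escape; independent of the threshold formula
bisect_separatrix <- function(p, L, lo, hi, iters = 40, horizon = 30000) {
  for (i in seq_len(iters)) {
    mid <- sqrt(lo * hi)
    f <- psa_fate(p, L, mid, horizon = horizon)
    if (f$fate == "decay") lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# Crank-Nicolson finite-difference solution of the radial diffusion problem
# (substitution u = rho * r turns it into the 1-D heat equation); returns the
# drug mass remaining inside the sphere at the requested times. Independent
# PDE oracle for the series solution.
cn_sphere_mass <- function(release_rate, times, M0 = 1, R = 1, nr = 300,
                           dt = 2e-3) {
  D <- release_rate * R^2
  rho0 <- M0 / (4 / 3 * pi * R^3)
  r <- seq(0, R, length.out = nr + 1)
  h <- r[2] - r[1]
  u <- rho0 * r
  u[nr + 1] <- 0
  lam <- D * dt / (2 * h^2)
  n <- nr - 1
  main <- rep(1 + 2 * lam, n)
  off <- rep(-lam, n - 1)
  out <- numeric(length(times))
  tcur <- 0
  steps <- round(max(times) / dt)
  nexti <- 1
  times <- sort(times)
  for (s in seq_len(steps)) {
    ui <- u[2:nr]
    rhs <- ui + lam * (c(ui[-1], 0) - 2 * ui + c(0, ui[-n]))
    cp <- numeric(n); dp <- numeric(n)
    cp[1] <- off[1] / main[1]; dp[1] <- rhs[1] / main[1]
    for (i in 2:n) {
      m <- main[i] - off[i - 1] * cp[i - 1]
      if (i < n) cp[i] <- off[i] / m
      dp[i] <- (rhs[i] - off[i - 1] * dp[i - 1]) / m
    }
    x <- numeric(n); x[n] <- dp[n]
    for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
    u[2:nr] <- x
    tcur <- tcur + dt
    while (nexti <= length(times) && abs(tcur - times[nexti]) < dt / 2) {
      rho <- c(0, u[2:nr] / r[2:nr], 0)
      f <- rho * r^2
      out[nexti] <- 4 * pi * (sum(f) - (f[1] + f[nr + 1]) / 2) * h
      nexti <- nexti + 1
    }
  }
  out
}

# log-uniform random draw helper for randomized parameter sweeps
rlu <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))
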