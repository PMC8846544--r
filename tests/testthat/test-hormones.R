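test_that("three-hormone steady state solves the quadratic and its residuals vanish", {
  p <- hormone_params()            # all parameters 1
  ss <- steady_state_three(p)
  expect_equal(ss[["z"]], (sqrt(5) - 1) / 2, tolerance = 1e-12)
  expect_equal(unname(ss), rep((sqrt(5) - 1) / 2, 3), tolerance = 1e-12)
  set.seed(101)
  for (i in 1:25) {
    pr <- hormone_params(p1 = rlu(1, .1, 5), b1 = rlu(1, .1, 5),
                         d1 = rlu(1, .1, 5), d2 = rlu(1, .1, 5),
                         d3 = rlu(1, .1, 5), p2 = rlu(1, .1, 5),
                         p3 = rlu(1, .1, 5), b3 = rlu(1, .1, 5))
    ss <- steady_state_three(pr)
    res <- c(pr$p1 / (1 + pr$b1 * ss[["z"]]) - pr$d1 * ss[["x"]],
             pr$p2 * ss[["x"]] - pr$d2 * ss[["y"]],
             pr$p3 * ss[["y"]] - pr$d3 * ss[["z"]])
    expect_lt(max(abs(res)), 1e-12)
    # uniqueness: h1(z) - c z changes sign exactly once on (0, z_max]
    cc <- pr$d1 * pr$d2 * pr$d3 / (pr$p2 * pr$p3)
    zg <- seq(1e-6, 10 * ss[["z"]], length.out = 4000)
    sgn <- sign(pr$p1 / (1 + pr$b1 * zg) - cc * zg)
    expect_identical(sum(diff(sgn) != 0), 1L)
  }
  # production shut-off limit
  p0 <- hormone_params(p1 = 1e-10)
  expect_lt(max(steady_state_three(p0)), 1e-5)
})

test_that("drug-influenced steady state matches the quadratic-formula oracle", {
  hp <- fig_hormones()             # b1 = b3 = p1/d1 = 1, p3/d3 = 20
  ss0 <- steady_state_two_with_drug(hp, 0)
  expect_equal(ss0[["z"]], -1 + sqrt(21), tolerance = 1e-12)
  ss05 <- steady_state_two_with_drug(hp, 0.5)
  expect_equal(ss05[["z"]], quad_root(1.5, 2.5, 20), tolerance = 1e-12)
  # large-L limits: z -> 0, x -> p1/d1
  ssL <- steady_state_two_with_drug(hp, 1e6)
  expect_lt(ssL[["z"]], 1e-2)
  expect_equal(ssL[["x"]], 1, tolerance = 0.01)
})

test_that("steady state moves monotonically with the drug level", {
  hp <- fig_hormones()
  Ls <- seq(0, 49, length.out = 50)
  ss <- vapply(Ls, function(L) steady_state_two_with_drug(hp, L), numeric(2))
  expect_true(all(diff(ss["z", ]) < 0))
  expect_true(all(diff(ss["x", ]) > 0))
  expect_true(all(ss["x", ] < hp$p1 / hp$d1))
  # implicit-function derivative vs central finite differences
  for (L in c(0, 0.5, 2, 9, 19)) {
    h <- 1e-6
    fd <- (steady_state_two_with_drug(hp, L + h)[["z"]] -
             steady_state_two_with_drug(hp, max(L - h, 0))[["z"]]) /
      (h + min(L, h))
    expect_equal(dz_steady_dL(hp, L), fd, tolerance = 1e-6)
    expect_lt(dz_steady_dL(hp, L), 0)
  }
})

test_that("trajectories stay at the steady state and converge to it", {
  p <- hormone_params()
  ss <- steady_state_three(p)
  tg <- seq(0, 50, 0.5)
  tr <- integrate_hormones(p, "three", s0 = ss, t_grid = tg)
  expect_lt(max(abs(tr$z - ss[["z"]])), 1e-8)
  set.seed(7)
  # multi-start convergence to the golden-ratio testosterone level
  for (i in 1:20) {
    s0 <- c(x = runif(1, 0, 5), y = runif(1, 0, 5), z = runif(1, 0, 5))
    tr <- integrate_hormones(p, "three", s0 = s0, t_grid = c(0, 100))
    expect_equal(tr$z[2], (sqrt(5) - 1) / 2, tolerance = 1e-7)
  }
  # drug-influenced system: convergence to the quadratic root
  hp <- fig_hormones()
  for (L in c(0, 0.5, 9)) {
    tr <- integrate_hormones(hp, "two_with_drug", L = L,
                             s0 = c(x = 4, z = 0.01), t_grid = c(0, 300))
    expect_equal(tr$z[2], steady_state_two_with_drug(hp, L)[["z"]],
                 tolerance = 1e-8)
  }
})

test_that("reduced two-hormone system tracks the full cascade quantitatively", {
  p <- hormone_params()            # the comparison configuration: all 1
  tg <- seq(0, 30, 0.1)
  tr3 <- integrate_hormones(p, "three", s0 = c(x = 1, y = 1, z = 1),
                            t_grid = tg)
  tr2 <- integrate_hormones(p, "two", s0 = c(x = 1, z = 1), t_grid = tg)
  expect_lt(max(abs(tr3$z - tr2$z)), 0.2)   # bounded sup-norm gap
  # identical steady states by construction of the quasi-steady reduction
  expect_equal(steady_state_two(p)[["z"]], steady_state_three(p)[["z"]],
               tolerance = 1e-12)
})

test_that("steady states are locally stable for arbitrary positive parameters", {
  st <- local_stability(hormone_params(), "three")
  expect_lt(st$max_real_part, 0)
  expect_true(all(st$routh_hurwitz > 0))
  set.seed(11)
  for (i in 1:100) {
    pr <- hormone_params(p1 = rlu(1, .05, 20), b1 = rlu(1, .05, 20),
                         d1 = rlu(1, .05, 20), d2 = rlu(1, .05, 20),
                         d3 = rlu(1, .05, 20), p2 = rlu(1, .05, 20),
                         p3 = rlu(1, .05, 20), b3 = rlu(1, .05, 20))
    for (sys in c("three", "two")) {
      expect_lt(local_stability(pr, sys)$max_real_part, 0)
    }
    for (L in c(0, 1, 10)) {
      st <- local_stability(pr, "two_with_drug", L = L)
      expect_lt(st$max_real_part, 0)
      J <- st$jacobian            # 2x2 sign structure
      expect_equal(sum(diag(J)), -(pr$d1 + pr$d3), tolerance = 1e-12)
      expect_gt(det(J), 0)
    }
  }
})

test_that("the dissipativity functional decreases outside its absorbing set", {
  p <- hormone_params(p1 = 2, b1 = 0.7, d1 = 0.8, d2 = 1.2, d3 = 0.9,
                      p2 = 1.5, p3 = 0.6, b3 = 1)
  tg <- seq(0, 40, 0.25)
  tr <- integrate_hormones(p, "three", s0 = c(x = 8, y = 6, z = 9),
                           t_grid = tg)
  dd <- dissipativity_functional(tr, p)
  alpha <- min(p$d1, p$d2, p$d3) / 2
  h10 <- p$p1
  expect_true(all(dd$Udot <= h10 - alpha * dd$U + 1e-9))
})
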