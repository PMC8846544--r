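test_that("noiseless identifiable cohorts are recovered essentially exactly", {
  des <- cohort_design(n_patients = 6, points_per_patient = c(6, 10),
                       timespan_days = c(400, 1200), baseline_psa = c(2, 10))
  law <- growth_law("exponential", a = 0.01)
  pop <- population_spec(law, random_effect_sd = c(a = 0), residual_sd = 0)
  coh <- generate_cohort(des, pop, seed = 7)
  fit <- suppressWarnings(fit_nmem(coh, nmem_spec(law), n_starts = 2))
  expect_equal(fit$fixed_estimates[["a"]], 0.01, tolerance = 1e-6)
  expect_lt(fit$residual_sd, 1e-5)
  expect_lt(fit$mse, 1e-10)
})

test_that("linear special case agrees with an independent mixed-model fit", {
  skip_if_not_installed("lme4")
  # exponential law with a random baseline only is a random-intercept linear
  # mixed model on the log scale; lme4 (ML) is the independent route
  des <- cohort_design(n_patients = 15, baseline_psa = c(0.5, 20))
  law <- growth_law("exponential", a = 0.002, PR = 0.1)
  pop <- population_spec(law, random_effect_sd = c(a = 0), residual_sd = 0.25)
  coh <- generate_cohort(des, pop, seed = 31)
  fit <- fit_nmem(coh, nmem_spec(law, random = "u0"), n_starts = 3)
  d <- coh[!coh$censored_flag, ]
  d$y <- log(d$psa_ng_ml / 0.1)
  lf <- lme4::lmer(y ~ time_days + (1 | patient_id), data = d, REML = FALSE)
  fe <- lme4::fixef(lf)
  expect_equal(fit$fixed_estimates[["a"]], unname(fe["time_days"]),
               tolerance = 1e-3)
  expect_equal(fit$fixed_estimates[["u0"]], unname(fe["(Intercept)"]),
               tolerance = 1e-3)
  expect_equal(fit$residual_sd, stats::sigma(lf), tolerance = 1e-2)
  expect_equal(2 * fit$nll, unname(-2 * as.numeric(stats::logLik(lf))),
               tolerance = 0.01)
})

test_that("metric identities hold and recomputation reproduces reported values", {
  des <- cohort_design(n_patients = 8)
  law <- ref_powerlog(PR = 0.1)
  coh <- generate_cohort(des, population_spec(law), seed = 21)
  fit <- suppressWarnings(fit_nmem(coh, nmem_spec(law), n_starts = 2))
  expect_equal(fit$aic, 2 * fit$n_params + 2 * fit$nll, tolerance = 1e-12)
  expect_equal(fit$bic, fit$n_params * log(fit$n_obs) + 2 * fit$nll,
               tolerance = 1e-12)
  m <- fit_metrics(fit, coh)
  expect_equal(m$mse, fit$mse, tolerance = 1e-6)
  expect_equal(m$r2, fit$r2, tolerance = 1e-6)
  expect_equal(m$aic, fit$aic)
  expect_lt(fit$mse, var(fit$fitted$observed))   # explains some variance
  expect_lte(fit$r2, 1)
  # optimizer never reports a likelihood above its own starting point
  expect_lte(fit$nll, fit$objective_trace[1])
})

test_that("estimates are invariant to patient relabeling", {
  des <- cohort_design(n_patients = 8)
  law <- ref_powerlog(PR = 0.1)
  coh <- generate_cohort(des, population_spec(law), seed = 22)
  perm <- coh
  relabel <- setNames(c(5, 3, 8, 1, 7, 2, 6, 4), 1:8)
  perm$patient_id <- relabel[as.character(coh$patient_id)]
  perm <- perm[order(perm$patient_id, perm$time_days), ]
  f1 <- suppressWarnings(fit_nmem(coh, nmem_spec(law), n_starts = 2))
  f2 <- suppressWarnings(fit_nmem(perm, nmem_spec(law), n_starts = 2))
  expect_equal(f1$fixed_estimates, f2$fixed_estimates, tolerance = 1e-6)
  expect_equal(f1$nll, f2$nll, tolerance = 1e-8)
})

test_that("individual modes shrink toward the population mean as noise grows", {
  # at fixed variance components, the posterior modes are pulled toward zero
  # as the residual SD grows (the data term loses weight in the penalty)
  law <- ref_powerlog(PR = 0.1)
  pop <- population_spec(law, random_effect_sd = c(a = 0.3),
                         residual_sd = 0.2)
  coh <- generate_cohort(cohort_design(n_patients = 14), pop, seed = 77)
  dat <- adtpsa:::.nmem_data(coh, 0.1, "exclude")
  st <- adtpsa:::.stack_data(dat)
  mv <- adtpsa:::.make_mean_fun_v("powerlog", 0.1)
  beta <- c(u0 = 1.9, a = log(0.001), b = log(0.5), gamma = 0)
  spread <- function(sigma) {
    m <- adtpsa:::.modes_lockstep(st, beta, Zidx = c(1L, 2L),
                                  omega = c(1, 0.3), sigma = sigma, mv = mv)
    sd(m$B[, 2])
  }
  expect_lt(spread(2), spread(0.5))
  expect_lt(spread(0.5), spread(0.05))
})

test_that("model comparison table is ranked and robust to single-law input", {
  des <- cohort_design(n_patients = 8)
  law <- ref_powerlog(PR = 0.1)
  coh <- generate_cohort(des, population_spec(law), seed = 23)
  tab1 <- model_selection(coh, "exponential", n_starts = 1, PR = 0.1)
  expect_identical(nrow(tab1), 1L)
  expect_identical(tab1$rank, 1L)
  tab <- model_selection(coh, c("exponential", "powerlog"), n_starts = 1,
                         PR = 0.1)
  expect_identical(tab$rank, 1:2)
  expect_true(all(diff(tab$aic) >= 0))
  expect_true(all(c("model", "mse", "r2", "nll", "aic", "bic") %in%
                    names(tab)))
})

test_that("exponential data does not reward the extra Gompertz parameter", {
  law <- growth_law("exponential", a = 0.002, PR = 0.1)
  wins <- 0
  for (seed in 1:3) {
    coh <- generate_cohort(cohort_design(n_patients = 12),
                           population_spec(law), seed = seed)
    tab <- model_selection(coh, c("exponential", "gompertz"), n_starts = 2,
                           PR = 0.1)
    daic <- tab$aic[tab$model == "gompertz"] -
      tab$aic[tab$model == "exponential"]
    if (daic > -2) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("degenerate inputs are rejected with informative errors", {
  law <- ref_powerlog()
  expect_error(nmem_spec(law, random = "nope"), "random-effect")
  one <- data.frame(patient_id = 1, time_days = c(0, 10),
                    psa_ng_ml = c(2, 3), censored_flag = FALSE)
  expect_error(fit_nmem(one, nmem_spec(law)), "at least 2 patients")
})
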