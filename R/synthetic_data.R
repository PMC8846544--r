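#' Cohort sampling design
#'
#' Describes the observational structure of a longitudinal pre-treatment PSA
#' cohort: how many patients, how many samples per patient, over what
#' follow-up spans, and from what baseline PSA range. The default mirrors the
#' summary statistics of a 19-patient watchful-waiting registry cohort
#' (6-22 points per patient, 388-5724 day spans).
#'
#' Per-patient point counts, timespans, and baselines are sampled
#' log-uniformly within their ranges: registry summaries of this kind are
#' right-skewed (the medians sit near the geometric midpoint of the range,
#' e.g. median 10 of 6-22, median 1162 days of 388-5724), and log-uniform
#' draws reproduce that skew where uniform draws would not.
#'
#' @param n_patients number of patients (>= 1).
#' @param points_per_patient integer range `c(min, max)` of observations per
#'   patient (min >= 2).
#' @param timespan_days range `c(min, max)` of per-patient follow-up (days),
#'   positive.
#' @param baseline_psa range `c(min, max)` of baseline PSA (ng/ml). The
#'   default starts patients between the 0.1 ng/ml detection level and
#'   5 ng/ml, so that a growing cohort reproduces an observation median of a
#'   few ng/ml with excursions to the 10^3 range.
#' @param sampling `"uniform_random"` (irregular visits, first at t = 0) or
#'   `"evenly_spaced"`.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_patients = 19,
                          points_per_patient = c(6, 22),
                          timespan_days = c(388, 5724),
                          baseline_psa = c(0.1, 5),
                          sampling = c("uniform_random", "evenly_spaced")) {
  sampling <- match.arg(sampling)
  chk_range <- function(r, nm, lo = 0) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] || r[1] < lo ||
        r[2] <= 0)
      stop(sprintf("invalid range for %s", nm), call. = FALSE)
  }
  stopifnot(n_patients >= 1)
  chk_range(points_per_patient, "points_per_patient", lo = 2)
  if (timespan_days[1] <= 0) stop("timespans must be positive", call. = FALSE)
  chk_range(timespan_days, "timespan_days")
  chk_range(baseline_psa, "baseline_psa")
  if (baseline_psa[1] <= 0)
    stop("baseline PSA bounds must be positive (sampled on the log scale)",
         call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 points_per_patient = as.integer(points_per_patient),
                 timespan_days = timespan_days,
                 baseline_psa = baseline_psa,
                 sampling = sampling),
            class = "cohort_design")
}

#' Population specification for cohort generation
#'
#' Fixed effects (population-typical growth-law parameters), between-patient
#' variability, and residual noise. Individual parameters are drawn
#' lognormally around the fixed effects (normal perturbations on the
#' transformed fitting scale: log for positive rates, logit for gamma), which
#' guarantees positivity; the residual is additive Gaussian noise on the
#' log(P/P_R) scale.
#'
#' @param law a [growth_law()] holding the fixed effects.
#' @param random_effect_sd named vector of between-patient SDs on the
#'   transformed scale, e.g. `c(a = 0.3)`; parameters not named get SD 0.
#' @param residual_sd SD of additive noise on log(P/P_R), >= 0.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(law, random_effect_sd = c(a = 0.3),
                            residual_sd = 0.3) {
  stopifnot(inherits(law, "growth_law"), residual_sd >= 0,
            all(random_effect_sd >= 0))
  if (length(random_effect_sd) > 0) {
    bad <- setdiff(names(random_effect_sd), names(law_parameter_scales(law$name)))
    if (length(bad) > 0)
      stop("random_effect_sd names not parameters of this law: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(law = law, random_effect_sd = random_effect_sd,
                 residual_sd = residual_sd),
            class = "population_spec")
}

#' Transformed-scale map of a law's free parameters
#'
#' Returns the named transformation scale (`"log"`, `"logit"`, `"identity"`)
#' of each free parameter of a growth law: the scale on which random effects
#' perturb individuals and on which the mixed-effects fitter works.
#'
#' @param name a growth-law name.
#' @return named character vector.
#' @export
law_parameter_scales <- function(name) {
  name <- match.arg(name, growth_law_names())
  switch(name,
    exponential = c(a = "log"),
    gompertz = c(a = "log", K = "log"),
    logistic = c(a = "log", K = "log"),
    generalized_logistic = c(a = "log", K = "log", gamma = "logit"),
    powerlog = c(a = "log", b = "log", gamma = "logit"),
    time_modulated = c(a = "log", lambda = "log", gamma = "logit"),
    modulated_exponent = c(a = "log", k0 = "identity", lambda = "log")
  )
}

.to_transformed <- function(value, scale) {
  switch(scale, log = log(value), logit = log(value / (1 - value)),
         identity = value)
}
.from_transformed <- function(value, scale) {
  switch(scale, log = exp(value), logit = 1 / (1 + exp(-value)),
         identity = value)
}

# perturb a law's parameters by normal draws on the transformed scale
.individual_law <- function(law, re_sd) {
  scales <- law_parameter_scales(law$name)
  for (nm in names(re_sd)) {
    if (re_sd[[nm]] == 0) next
    tv <- .to_transformed(law[[nm]], scales[[nm]]) + rnorm(1, 0, re_sd[[nm]])
    law[[nm]] <- .from_transformed(tv, scales[[nm]])
  }
  law
}

#' Generate a synthetic longitudinal PSA cohort
#'
#' Draws per-patient designs (number of points, timespan, baseline PSA) from
#' the cohort design, per-patient growth parameters lognormally around the
#' population fixed effects, deterministic log-PSA trajectories from the
#' growth law, and additive Gaussian noise on the log scale. Observations
#' that fall below the detection level P_R are floored at P_R and flagged
#' as censored. A single global seed feeds a per-patient substream, so
#' cohorts are reproducible patient by patient.
#'
#' @param design [cohort_design()].
#' @param pop [population_spec()].
#' @param seed integer seed.
#' @return data.frame with columns `patient_id`, `time_days`, `psa_ng_ml`,
#'   `censored_flag`; attribute `individual_params` holds the per-patient
#'   parameter draws (for recovery experiments).
#' @export
generate_cohort <- function(design, pop, seed = 1) {
  stopifnot(inherits(design, "cohort_design"), inherits(pop, "population_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, design$n_patients)
  law <- pop$law
  rows <- vector("list", design$n_patients)
  ipars <- vector("list", design$n_patients)
  for (i in seq_len(design$n_patients)) {
    set.seed(patient_seeds[i])
    n_i <- round(exp(runif(1, log(design$points_per_patient[1]),
                           log(design$points_per_patient[2]))))
    n_i <- min(max(n_i, design$points_per_patient[1]),
               design$points_per_patient[2])
    span <- exp(runif(1, log(design$timespan_days[1]),
                      log(design$timespan_days[2])))
    P0 <- exp(runif(1, log(design$baseline_psa[1]),
                    log(design$baseline_psa[2])))
    # first visit at t = 0, last at the end of follow-up, the rest irregular
    times <- if (design$sampling == "uniform_random")
      c(0, sort(runif(n_i - 2, 0, span)), span)
    else seq(0, span, length.out = n_i)
    ilaw <- .individual_law(law, pop$random_effect_sd)
    u <- log_psa_prediction(ilaw, P0, times)
    y <- u + rnorm(n_i, 0, pop$residual_sd)
    psa <- law$PR * exp(y)
    cens <- psa < law$PR
    psa[cens] <- law$PR
    rows[[i]] <- data.frame(patient_id = i, time_days = times,
                            psa_ng_ml = psa, censored_flag = cens)
    ipars[[i]] <- c(unlist(ilaw[names(law_parameter_scales(law$name))]),
                    P0 = P0)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "individual_params") <- do.call(rbind, ipars)
  attr(out, "seed") <- seed
  attr(out, "PR") <- law$PR
  out
}

#' Generate synthetic depot concentration profiles
#'
#' Smooth concentration curves from the diffusion-release PK model for a set
#' of dosing schedules, with optional multiplicative lognormal noise
#' (`noise_sd` is the SD on the log-concentration scale). Stands in for
#' label-derived mean concentration curves as fixture data.
#'
#' @param schedules named list of [dose_schedule()]s, or a character vector
#'   of [depot_schedule()] preset names.
#' @param params [diffusion_pk()].
#' @param noise_sd multiplicative noise SD (log scale), >= 0.
#' @param seed integer seed.
#' @param t_grid output times (days); default daily over the span of each
#'   schedule plus one inter-dose interval.
#' @return data.frame with `schedule_id`, `time_days`, `concentration`.
#' @export
generate_pk_profiles <- function(schedules, params, noise_sd = 0, seed = 1,
                                 t_grid = NULL) {
  stopifnot(inherits(params, "diffusion_pk"))
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (is.character(schedules))
    schedules <- setNames(lapply(schedules, depot_schedule), schedules)
  if (is.null(names(schedules)))
    names(schedules) <- paste0("schedule_", seq_along(schedules))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- lapply(names(schedules), function(id) {
    sch <- schedules[[id]]
    tg <- t_grid
    if (is.null(tg)) {
      gap <- if (nrow(sch) > 1) diff(sch$time_days)[1] else 28
      tg <- seq(0, max(sch$time_days) + gap, by = 1)
    }
    conc <- integrate_diffusion_pk(params, sch, tg)$concentration
    if (noise_sd > 0) conc <- conc * exp(rnorm(length(conc), 0, noise_sd))
    data.frame(schedule_id = id, time_days = tg, concentration = conc)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write / read a cohort as tab-delimited text
#'
#' Columns: `patient_id`, `time_days`, `psa_ng_ml`, `censored_flag`.
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(all(c("patient_id", "time_days", "psa_ng_ml", "censored_flag")
                %in% names(cohort)))
  write.table(cohort, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  out$censored_flag <- as.logical(out$censored_flag)
  out
}
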