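#' Configuration for the synthetic microdata generator
#'
#' Defaults put the generator on the scale of a large national labour-force
#' survey: log weekly wages around exp(5.1) ~ 164 pounds at age 0 growing
#' ~0.5% per year of age, a male differential of 0.27 log-points, minor- and
#' unit-group intercept SDs of 0.37 and 0.32, a unit-level age-slope SD of
#' 0.0055, no minor-level slope variation, and residual SD 0.53. The health
#' link is a latent logit of poor health declining 0.3 per 100 pounds of
#' weekly wage with prevalence near 25%. All draws are pure functions of
#' `seed`; each generator stage uses its own documented sub-stream
#' (seed + 1 classification, + 2 group effects, + 3 master individuals,
#' + 4 health survey) so adding a stage never perturbs earlier draws.
#'
#' @param n_minor Number of minor groups (<= 999).
#' @param units_per_minor Units per minor group: a count or a `c(lo, hi)`
#'   range (<= 9).
#' @param n_obs Individuals in the master (wage) table.
#' @param n_survey Individuals in the health survey.
#' @param beta0,beta_age,beta_male Fixed effects, log-pound scale.
#' @param sd_minor_int,sd_minor_slope,sd_unit_int,sd_unit_slope,sd_resid
#'   Generative standard deviations.
#' @param age_range_male,age_range_female Inclusive age ranges.
#' @param male_fraction Proportion male.
#' @param years Survey years of the master data.
#' @param reference_year CPI reference year.
#' @param cpi_annual_drift Annual CPI growth rate.
#' @param transitory_income_sd SD of multiplicative log-normal noise giving
#'   "reported" income from the true wage (single-time-point measurement of
#'   a variable quantity).
#' @param health_alpha,health_gamma Intercept and per-100-pound slope of the
#'   latent poor-health logit.
#' @param health_beta_age,health_beta_male Age and sex terms of that logit.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_minor = 80, units_per_minor = 4,
                       n_obs = 50000, n_survey = 10000,
                       beta0 = 5.1, beta_age = 0.005, beta_male = 0.27,
                       sd_minor_int = 0.37, sd_minor_slope = 0,
                       sd_unit_int = 0.32, sd_unit_slope = 0.0055,
                       sd_resid = 0.53,
                       age_range_male = c(16, 65),
                       age_range_female = c(16, 60),
                       male_fraction = 0.5,
                       years = 2001:2010, reference_year = 2006,
                       cpi_annual_drift = 0.025,
                       transitory_income_sd = 0.3,
                       health_alpha = -1.3, health_gamma = -0.3,
                       health_beta_age = 0.02, health_beta_male = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  sds <- c(sd_minor_int, sd_minor_slope, sd_unit_int, sd_unit_slope, sd_resid)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (male_fraction < 0 || male_fraction > 1) {
    stop("male_fraction must be in [0, 1]", call. = FALSE)
  }
  if (n_minor > 999) stop("classification capacity: n_minor <= 999",
                          call. = FALSE)
  if (max(units_per_minor) > 9) {
    stop("classification capacity: units_per_minor <= 9", call. = FALSE)
  }
  if (n_obs < n_minor * max(units_per_minor)) {
    stop("n_obs must be >= n_minor * units_per_minor", call. = FALSE)
  }
  if (!reference_year %in% years) {
    stop("reference_year must be among years", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' CPI table implied by a generator configuration
#'
#' Index 100 in the reference year, growing at the configured annual drift.
#'
#' @param config A [sim_config()].
#' @return A [cpi_table()].
#' @export
sim_cpi <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  idx <- 100 * (1 + config$cpi_annual_drift)^(config$years - config$reference_year)
  cpi_table(config$years, idx, config$reference_year)
}

#' Generate a synthetic tiered classification
#'
#' Minor-group codes are drawn (seeded) from the 3-digit code space; each
#' carries its configured number of 4-digit unit codes.
#'
#' @param config A [sim_config()].
#' @return A [classification_table()].
#' @export
generate_classification <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  minors <- sort(sample(sprintf("%03d", 1:999), config$n_minor))
  k <- config$units_per_minor
  n_units <- if (length(k) == 2L) {
    sample(k[1L]:k[2L], config$n_minor, replace = TRUE)
  } else rep(k, config$n_minor)
  units <- unlist(mapply(function(m, nu) paste0(m, seq_len(nu)),
                         minors, n_units, SIMPLIFY = FALSE))
  classification_table(units)
}

# Group-level effects for every minor and unit group (sub-stream seed + 2).
.generate_effects <- function(config, classification) {
  set.seed(config$seed + 2L)
  idx <- soc_group_index(classification)
  minors <- sort(unique(idx$minor_code))
  minor <- tibble::tibble(
    minor_code = minors,
    u_int = stats::rnorm(length(minors), 0, config$sd_minor_int),
    u_slope = stats::rnorm(length(minors), 0, config$sd_minor_slope))
  unit <- tibble::tibble(
    unit_code = idx$unit_code,
    v_int = stats::rnorm(nrow(idx), 0, config$sd_unit_int),
    v_slope = stats::rnorm(nrow(idx), 0, config$sd_unit_slope))
  list(minor = minor, unit = unit)
}

# Draw individuals: sex, age within sex-specific range, occupation, year.
.draw_people <- function(config, n, classification) {
  sex <- ifelse(stats::runif(n) < config$male_fraction, "male", "female")
  age <- integer(n)
  is_m <- sex == "male"
  age[is_m] <- sample(config$age_range_male[1L]:config$age_range_male[2L],
                      sum(is_m), replace = TRUE)
  age[!is_m] <- sample(config$age_range_female[1L]:config$age_range_female[2L],
                       sum(!is_m), replace = TRUE)
  soc <- sample(classification$unit_code, n, replace = TRUE)
  list(sex = sex, age = as.numeric(age), soc = soc)
}

# Latent log wage at reference-year prices for given people.
.log_wage <- function(config, people, effects) {
  mpos <- match(substr(people$soc, 1L, 3L), effects$minor$minor_code)
  upos <- match(people$soc, effects$unit$unit_code)
  config$beta0 + config$beta_age * people$age +
    config$beta_male * (people$sex == "male") +
    effects$minor$u_int[mpos] + effects$unit$v_int[upos] +
    (effects$minor$u_slope[mpos] + effects$unit$v_slope[upos]) * people$age +
    stats::rnorm(length(people$age), 0, config$sd_resid)
}

#' Generate a synthetic master (wage) survey
#'
#' Draws group effects at both classification tiers, then individual log
#' wages from the three-level process; wages are exponentiated to pounds
#' and inflated to each record's survey-year price level, so preprocessing
#' has real deflation work to do.
#'
#' @param config A [sim_config()].
#' @param truth Optional truth object from a previous call (to share the
#'   classification and group effects across datasets).
#' @return A tibble of raw wage records (`person_id`, `age`, `sex`,
#'   `soc_unit`, `gross_weekly_wage`, `survey_year`, `employed_last_week`)
#'   with attribute `truth` (config, classification, group effects, CPI).
#' @export
generate_master <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) {
    classification <- generate_classification(config)
    effects <- .generate_effects(config, classification)
    truth <- list(config = config, classification = classification,
                  effects = effects, cpi = sim_cpi(config))
  }
  set.seed(config$seed + 3L)
  n <- config$n_obs
  people <- .draw_people(config, n, truth$classification)
  year <- sample(config$years, n, replace = TRUE)
  lw <- .log_wage(config, people, truth$effects)
  idx <- match(year, truth$cpi$years)
  ref <- truth$cpi$index[match(config$reference_year, truth$cpi$years)]
  nominal <- exp(lw) * truth$cpi$index[idx] / ref
  out <- tibble::tibble(
    person_id = sprintf("P%06d", seq_len(n)),
    age = people$age,
    sex = people$sex,
    soc_unit = people$soc,
    gross_weekly_wage = nominal,
    survey_year = year,
    employed_last_week = TRUE
  )
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic health survey
#'
#' Each respondent gets a true wage from the same wage process (at
#' reference-year prices), a reported income equal to the true wage times
#' log-normal transitory noise, and a poor-health indicator drawn from a
#' logit linear in wage (per 100 pounds), age and sex. A categorical SEP
#' covariate (`sep_class`) is derived by binning the respondent's
#' minor-group wage effect into thirds; it is a synthetic stand-in for
#' social-class or area-deprivation adjustment variables.
#'
#' @param config A [sim_config()].
#' @param truth Truth object from [generate_master()]; generated afresh if
#'   omitted.
#' @return A tibble with columns `age`, `sex`, `soc`, `true_wage`,
#'   `reported_income`, `poor_health`, `sep_class`.
#' @export
generate_health_survey <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) {
    classification <- generate_classification(config)
    effects <- .generate_effects(config, classification)
    truth <- list(config = config, classification = classification,
                  effects = effects, cpi = sim_cpi(config))
  }
  set.seed(config$seed + 4L)
  n <- config$n_survey
  people <- .draw_people(config, n, truth$classification)
  lw <- .log_wage(config, people, truth$effects)
  true_wage <- exp(lw)
  reported <- true_wage *
    exp(stats::rnorm(n, 0, config$transitory_income_sd))
  eta <- config$health_alpha + config$health_gamma * (true_wage / 100) +
    config$health_beta_age * people$age +
    config$health_beta_male * (people$sex == "male")
  poor <- stats::rbinom(n, 1L, stats::plogis(eta))
  u <- truth$effects$minor$u_int
  cuts <- stats::quantile(u, c(1 / 3, 2 / 3))
  mpos <- match(substr(people$soc, 1L, 3L), truth$effects$minor$minor_code)
  sep <- cut(u[mpos], c(-Inf, cuts, Inf), labels = c("low", "mid", "high"))
  tibble::tibble(
    age = people$age,
    sex = people$sex,
    soc = people$soc,
    true_wage = true_wage,
    reported_income = reported,
    poor_health = poor,
    sep_class = as.character(sep)
  )
}

#' Generate a full synthetic study
#'
#' One call producing everything the pipeline needs: the master wage table,
#' the target health survey (sharing the same classification and group
#' effects), the CPI table and the generative truth.
#'
#' @param config A [sim_config()].
#' @return List with elements `master`, `survey`, `cpi`, `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  master <- generate_master(config)
  truth <- attr(master, "truth")
  survey <- generate_health_survey(config, truth)
  list(master = master, survey = survey, cpi = truth$cpi, truth = truth)
}
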