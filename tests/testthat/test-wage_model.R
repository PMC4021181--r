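beta_true <- c(intercept = 5, age = 0.006, male = 0.3)

test_that("marginal likelihood matches a dense multivariate-normal oracle", {
  m <- tiny_sim_master(n = 150, sd_minor_slope = 0.004, sd_unit_slope = 0.003)
  vcs <- list(
    M1 = vc_full(0.09, 0, 0, 0, 0.16),
    M2 = vc_full(0.09, 1.6e-5, 0, 0, 0.16),
    M3 = vc_full(0.09, 0, 0.04, 0, 0.16),
    M4 = vc_full(0.09, 1.6e-5, 0.04, 9e-6, 0.16))
  for (cfg in names(vcs)) {
    spec <- model_spec(cfg)
    ll <- marginal_loglik(m, spec, beta_true, vcs[[cfg]])
    expect_equal(ll, dense_loglik(m, spec, beta_true, vcs[[cfg]]),
                 tolerance = 1e-9, label = cfg)
  }
})

test_that("with all group variances 0 the likelihood is the iid normal one", {
  m <- tiny_sim_master(n = 60)
  vc <- vc_full(var_resid = 0.2)
  mu <- beta_true[["intercept"]] + beta_true[["age"]] * m$age +
    beta_true[["male"]] * (m$sex == "male")
  expect_equal(marginal_loglik(m, model_spec("M4"), beta_true, vc),
               sum(dnorm(m$log_wage, mu, sqrt(0.2), log = TRUE)))
})

test_that("row duplication doubles the likelihood only without group effects", {
  m <- tiny_sim_master(n = 40)
  m2 <- as_master(rep(m$age, 2), rep(m$sex, 2), rep(m$unit_code, 2),
                  rep(m$log_wage, 2))
  spec <- model_spec("M3")
  vc0 <- vc_full(var_resid = 0.2)
  expect_equal(marginal_loglik(m2, spec, beta_true, vc0),
               2 * marginal_loglik(m, spec, beta_true, vc0))
  vc1 <- vc_full(0.09, 0, 0.04, 0, 0.2)
  ll1 <- marginal_loglik(m, spec, beta_true, vc1)
  ll2 <- marginal_loglik(m2, spec, beta_true, vc1)
  expect_equal(ll2, dense_loglik(m2, spec, beta_true, vc1), tolerance = 1e-9)
  expect_gt(abs(ll2 - 2 * ll1), 1e-3)  # correlation handling breaks equality
})

test_that("likelihood validates its parameters", {
  m <- tiny_sim_master(n = 30)
  expect_error(marginal_loglik(m, model_spec("M1"), beta_true,
                               vc_full(var_resid = -1)), "var_resid")
  expect_error(marginal_loglik(m, model_spec("M1"), beta_true,
                               vc_full(var_unit_int = 0.1, var_resid = 1)),
               "must be 0")
  expect_error(marginal_loglik(m, model_spec("M1"), c(a = 1),
                               vc_full(var_resid = 1)), "beta")
})

test_that("one-group EB intercept follows the closed-form BLUP", {
  # n tau^2 / (n tau^2 + sigma^2) * rbar, checked on a size ladder
  for (n in c(1, 4, 25)) {
    m <- as_master(rep(0, n), rep("female", n), rep("1121", n),
                   rep(2, n))  # all residuals exactly 2 under beta = 0
    eb <- eb_residuals(m, model_spec("M1"),
                       c(intercept = 0, age = 0, male = 0),
                       vc_full(var_minor_int = 1, var_resid = 1))
    expect_equal(unname(eb$minor$intercept), n * 2 / (n + 1))
  }
})

test_that("zero prior variance gives zero EB effects", {
  m <- tiny_sim_master(n = 50)
  eb <- eb_residuals(m, model_spec("M4"), beta_true,
                     vc_full(0, 0, 0, 0, 0.3))
  expect_true(all(eb$minor$intercept == 0))
  expect_true(all(eb$unit$intercept == 0))
})

test_that("EB residuals match the joint mixed-model-equations solve", {
  m <- tiny_sim_master(n = 180, sd_minor_slope = 0.004, sd_unit_slope = 0.003)
  vcs <- list(
    M1 = vc_full(0.09, 0, 0, 0, 0.16),
    M2 = vc_full(0.09, 1.6e-5, 0, 0, 0.16),
    M3 = vc_full(0.09, 0, 0.04, 0, 0.16),
    M4 = vc_full(0.09, 1.6e-5, 0.04, 9e-6, 0.16))
  for (cfg in names(vcs)) {
    spec <- model_spec(cfg)
    eb <- eb_residuals(m, spec, beta_true, vcs[[cfg]])
    o <- mme_blup(m, spec, beta_true, vcs[[cfg]])
    expect_equal(eb_as_vector(eb, o$type, o$code), o$b,
                 tolerance = 1e-10, label = cfg)
  }
})

test_that("shrinkage grows with group size towards the raw group mean", {
  sizes <- c(2, 5, 20, 100, 1000)
  ebs <- vapply(sizes, function(n) {
    m <- as_master(rep(0, n), rep("female", n), rep("1121", n), rep(1.5, n))
    eb_residuals(m, model_spec("M1"), c(intercept = 0, age = 0, male = 0),
                 vc_full(var_minor_int = 0.5, var_resid = 1))$minor$intercept
  }, numeric(1))
  expect_true(all(diff(ebs) > 0))
  expect_true(all(ebs > 0 & ebs < 1.5))
  expect_equal(ebs[length(ebs)], 1.5, tolerance = 0.01)
})

test_that("data without group structure reduce the fit to OLS", {
  set.seed(5)
  n <- 2000
  soc <- sample(c("1121", "1122", "2431", "2432"), n, replace = TRUE)
  age <- sample(16:65, n, replace = TRUE)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  lw <- 5 + 0.006 * age + 0.3 * (sex == "male") + rnorm(n, 0, 0.4)
  m <- as_master(age, sex, soc, lw)
  fit <- suppressWarnings(fit_wage_model(m, model_spec("M4")))
  ols <- lm(log_wage ~ age + I(sex == "male"), data = m)
  se <- sqrt(diag(vcov(ols)))
  expect_true(all(abs(unname(fit$beta) - unname(coef(ols))) < 2 * se))
  expect_lt(fit$varcomps$var_minor_int, 0.002)
  expect_lt(fit$varcomps$var_unit_int, 0.002)
})

test_that("fit agrees with an independent mixed-model implementation", {
  cfg <- sim_config(n_minor = 30, units_per_minor = 4, n_obs = 8000,
                    n_survey = 10, sd_unit_slope = 0.004, seed = 21)
  rec <- generate_master(cfg)
  m <- build_master(rec, sim_cpi(cfg))
  d <- as.data.frame(m)
  d$male <- as.numeric(d$sex == "male")
  for (cfg_name in c("M3", "M4")) {
    fit <- suppressWarnings(fit_wage_model(m, model_spec(cfg_name)))
    form <- if (cfg_name == "M3") {
      log_wage ~ age + male + (1 | minor_code) + (1 | unit_code)
    } else {
      log_wage ~ age + male + (1 | minor_code) + (0 + age | minor_code) +
        (1 | unit_code) + (0 + age | unit_code)
    }
    ref <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = d, REML = FALSE)))
    # our optimum must be at least as good, and agree closely (either
    # implementation may stop a hair early near a variance boundary)
    expect_gte(fit$loglik, as.numeric(logLik(ref)) - 1e-4)
    expect_lt(abs(fit$loglik - as.numeric(logLik(ref))), 0.1)
    expect_lt(max(abs(unname(fit$beta) - unname(lme4::fixef(ref)))), 1e-3)
  }
})

test_that("maximised likelihoods respect model nesting", {
  m <- tiny_sim_master(n = 400, n_minor = 6, sd_unit_slope = 0.004, seed = 9)
  lls <- vapply(c("M1", "M2", "M3", "M4"), function(cc) {
    suppressWarnings(fit_wage_model(m, model_spec(cc)))$loglik
  }, numeric(1))
  expect_gte(lls[["M2"]], lls[["M1"]] - 1e-6)
  expect_gte(lls[["M3"]], lls[["M1"]] - 1e-6)
  expect_gte(lls[["M4"]], lls[["M3"]] - 1e-6)
  expect_gte(lls[["M4"]], lls[["M2"]] - 1e-6)
})

test_that("relabelling the reference sex flips the male effect exactly", {
  m <- tiny_sim_master(n = 300, seed = 13)
  f1 <- suppressWarnings(fit_wage_model(m, model_spec("M3")))
  m2 <- m
  m2$sex <- ifelse(m$sex == "male", "female", "male")
  f2 <- suppressWarnings(fit_wage_model(m2, model_spec("M3")))
  expect_equal(f2$beta[["male"]], -f1$beta[["male"]], tolerance = 1e-6)
  expect_equal(f2$beta[["intercept"]], f1$beta[["intercept"]] + f1$beta[["male"]],
               tolerance = 1e-6)
  # fitted values unchanged
  p1 <- predict_log_wage(f1, m$age, m$sex, m$unit_code)$log_wage_hat
  p2 <- predict_log_wage(f2, m2$age, m2$sex, m2$unit_code)$log_wage_hat
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("accepted optimiser iterates never decrease the likelihood", {
  m <- tiny_sim_master(n = 250, seed = 31)
  fit <- suppressWarnings(fit_wage_model(m, model_spec("M4")))
  expect_true(all(diff(fit$trace) >= 0))
})

test_that("unidentifiable configurations are refused", {
  m <- as_master(rep(30, 20), rep("female", 20), rep("1121", 20), rnorm(20, 5))
  expect_error(fit_wage_model(m, model_spec("M1")), "2 minor groups")
  m2 <- as_master(rep(30, 20), rep("female", 20),
                  rep(c("1121", "2431"), 10), rnorm(20, 5))
  expect_error(fit_wage_model(m2, model_spec("M3")), "unit groups")
})

test_that("REML is available as a sensitivity flag and differs from ML", {
  m <- tiny_sim_master(n = 300, seed = 17)
  ml <- suppressWarnings(fit_wage_model(m, model_spec("M1")))
  rm <- suppressWarnings(fit_wage_model(m, model_spec("M1"),
                                        fit_control(reml = TRUE)))
  expect_gte(rm$varcomps$var_resid, ml$varcomps$var_resid)
})

test_that("serialisation round-trips losslessly to full float precision", {
  m <- tiny_sim_master(n = 200, sd_unit_slope = 0.004, seed = 23)
  fit <- suppressWarnings(fit_wage_model(m, model_spec("M4")))
  path <- withr::local_tempfile(fileext = ".json")
  write_wage_fit(fit, path)
  fit2 <- read_wage_fit(path)
  expect_identical(fit2$beta, fit$beta)
  expect_identical(fit2$varcomps, fit$varcomps)
  expect_identical(fit2$loglik, fit$loglik)
  expect_identical(fit2$eb$minor$intercept, fit$eb$minor$intercept)
  expect_identical(fit2$eb$unit$intercept, fit$eb$unit$intercept)
  expect_identical(fit2$eb$unit$slope, fit$eb$unit$slope)
  expect_identical(fit2$spec$config, fit$spec$config)
  # predictions from the reloaded model are bit-identical
  p1 <- predict_log_wage(fit, 30, "male", "1121")
  p2 <- predict_log_wage(fit2, 30, "male", "1121")
  expect_identical(p1$log_wage_hat, p2$log_wage_hat)
})
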