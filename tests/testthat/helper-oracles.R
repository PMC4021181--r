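# Independent oracles and fixture builders shared across tests.
# The oracles deliberately use the dense, whole-dataset formulation of the
# model (full n x n covariance; joint Henderson solve) so they share no code
# path with the package's blockwise implementation.

# Build a master_data-style tibble directly from components.
as_master <- function(age, sex, unit_code, log_wage) {
  idx <- synthwage::soc_group_index(unique(unit_code))
  pos <- match(unit_code, idx$unit_code)
  out <- tibble::tibble(
    age = as.numeric(age), sex = as.character(sex),
    minor_code = idx$minor_code[pos], unit_code = idx$unit_code[pos],
    minor_id = idx$minor_id[pos], unit_id = idx$unit_id[pos],
    wage = exp(log_wage), log_wage = as.numeric(log_wage))
  class(out) <- c("master_data", class(out))
  out
}

# Full random-effects design matrix and per-column variances for a spec.
dense_design <- function(data, spec, varcomps) {
  vc <- varcomps
  age <- data$age - spec$age_centering
  comp <- spec$components
  cols <- list()
  vars <- numeric(0)
  meta <- list()
  for (m in sort(unique(data$minor_code))) {
    ind <- as.numeric(data$minor_code == m)
    cols[[length(cols) + 1L]] <- ind
    vars <- c(vars, vc[["var_minor_int"]])
    meta[[length(meta) + 1L]] <- c("minor_int", m)
    if (comp[["minor_slope"]]) {
      cols[[length(cols) + 1L]] <- ind * age
      vars <- c(vars, vc[["var_minor_slope"]])
      meta[[length(meta) + 1L]] <- c("minor_slope", m)
    }
  }
  if (comp[["unit_int"]]) {
    for (u in sort(unique(data$unit_code))) {
      ind <- as.numeric(data$unit_code == u)
      cols[[length(cols) + 1L]] <- ind
      vars <- c(vars, vc[["var_unit_int"]])
      meta[[length(meta) + 1L]] <- c("unit_int", u)
      if (comp[["unit_slope"]]) {
        cols[[length(cols) + 1L]] <- ind * age
        vars <- c(vars, vc[["var_unit_slope"]])
        meta[[length(meta) + 1L]] <- c("unit_slope", u)
      }
    }
  }
  list(Z = do.call(cbind, cols), g = vars,
       type = vapply(meta, `[`, "", 1L), code = vapply(meta, `[`, "", 2L))
}

dense_fixed_part <- function(data, spec, beta) {
  age <- data$age - spec$age_centering
  beta[["intercept"]] + beta[["age"]] * age +
    beta[["male"]] * as.numeric(data$sex == "male")
}

# Oracle 1: marginal log-likelihood via the full n x n multivariate normal.
dense_loglik <- function(data, spec, beta, varcomps) {
  d <- dense_design(data, spec, varcomps)
  n <- nrow(data)
  V <- diag(varcomps[["var_resid"]], n) +
    d$Z %*% (d$g * t(d$Z))
  r <- data$log_wage - dense_fixed_part(data, spec, beta)
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + drop(t(r) %*% solve(V, r)))
}

# Oracle 2: EB/BLUP random effects from the joint mixed-model-equations
# solve over the whole dataset (beta held fixed).
mme_blup <- function(data, spec, beta, varcomps) {
  d <- dense_design(data, spec, varcomps)
  act <- d$g > 0
  Z <- d$Z[, act, drop = FALSE]
  g <- d$g[act]
  s2 <- varcomps[["var_resid"]]
  r <- data$log_wage - dense_fixed_part(data, spec, beta)
  A <- crossprod(Z) / s2 + diag(1 / g, length(g))
  b <- numeric(length(d$g))
  b[act] <- solve(A, crossprod(Z, r) / s2)
  list(type = d$type, code = d$code, b = b)
}

# Extract a package EB table into the oracle's (type, code) layout.
eb_as_vector <- function(eb, type, code) {
  vapply(seq_along(type), function(i) {
    if (grepl("^minor", type[i])) {
      row <- match(code[i], eb$minor$minor_code)
      if (type[i] == "minor_int") eb$minor$intercept[row] else eb$minor$slope[row]
    } else {
      row <- match(code[i], eb$unit$unit_code)
      if (type[i] == "unit_int") eb$unit$intercept[row] else eb$unit$slope[row]
    }
  }, numeric(1))
}

# Small simulated master dataset, independent of the package generator.
tiny_sim_master <- function(n = 120, n_minor = 4, units_per_minor = 3,
                            beta0 = 5, beta_age = 0.006, beta_male = 0.3,
                            sd_minor = 0.3, sd_minor_slope = 0,
                            sd_unit = 0.2, sd_unit_slope = 0,
                            sd_resid = 0.4, seed = 42) {
  set.seed(seed)
  minors <- sprintf("%03d", seq(101, by = 7, length.out = n_minor))
  units <- unlist(lapply(minors, function(m) paste0(m, 1:units_per_minor)))
  u_int <- stats::setNames(rnorm(n_minor, 0, sd_minor), minors)
  u_slo <- stats::setNames(rnorm(n_minor, 0, sd_minor_slope), minors)
  v_int <- stats::setNames(rnorm(length(units), 0, sd_unit), units)
  v_slo <- stats::setNames(rnorm(length(units), 0, sd_unit_slope), units)
  soc <- sample(units, n, replace = TRUE)
  mnr <- substr(soc, 1, 3)
  age <- sample(16:65, n, replace = TRUE)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  lw <- beta0 + beta_age * age + beta_male * (sex == "male") +
    u_int[mnr] + v_int[soc] + (u_slo[mnr] + v_slo[soc]) * age +
    rnorm(n, 0, sd_resid)
  as_master(age, sex, soc, unname(lw))
}

vc_full <- function(var_minor_int = 0, var_minor_slope = 0, var_unit_int = 0,
                    var_unit_slope = 0, var_resid = 1) {
  c(var_minor_int = var_minor_int, var_minor_slope = var_minor_slope,
    var_unit_int = var_unit_int, var_unit_slope = var_unit_slope,
    var_resid = var_resid)
}
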