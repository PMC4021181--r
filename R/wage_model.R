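#' Model specification for the nested wage model
#'
#' Four configurations of the log-wage model, all with fixed effects for
#' age and sex (female reference):
#' \describe{
#'   \item{M1}{random intercepts for minor groups (2-level)}
#'   \item{M2}{random intercepts and age slopes for minor groups}
#'   \item{M3}{random intercepts for minor and unit groups (3-level)}
#'   \item{M4}{random intercepts and age slopes at both tiers}
#' }
#' Random intercepts and slopes at the same tier are mutually independent
#' (no intercept-slope covariance). Age enters uncentred by default, so the
#' intercept is interpreted at age 0 on the log-pound scale; a centering
#' constant is available for numerical conditioning.
#'
#' @param config One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param age_centering Constant subtracted from age before modelling.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(config = c("M4", "M1", "M2", "M3"), age_centering = 0) {
  config <- match.arg(config)
  comp <- c(minor_int = TRUE,
            minor_slope = config %in% c("M2", "M4"),
            unit_int = config %in% c("M3", "M4"),
            unit_slope = config == "M4")
  structure(list(config = config, age_centering = age_centering,
                 components = comp), class = "model_spec")
}

# Variance components as a full named vector; absent components are 0.
.vc_names <- c("var_minor_int", "var_minor_slope", "var_unit_int",
               "var_unit_slope", "var_resid")

.as_varcomps <- function(varcomps) {
  out <- stats::setNames(numeric(5L), .vc_names)
  varcomps <- unlist(varcomps)
  unknown <- setdiff(names(varcomps), .vc_names)
  if (length(unknown)) {
    stop("unknown variance component(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out[names(varcomps)] <- varcomps
  if (any(out[1:4] < 0) || out["var_resid"] <= 0) {
    stop("variance components must be >= 0 and var_resid > 0", call. = FALSE)
  }
  out
}

# Precompute per-minor-group sufficient statistics. Observations in
# different minor groups are independent, so the marginal likelihood, the
# GLS fixed-effect solve and the EB solve all decompose into these blocks.
# Within a block the random-effect design Z has one column per component:
# minor intercept (1), minor age slope (age), one indicator per unit group,
# and one age-by-indicator column per unit group. Only crossproducts are
# kept, so likelihood evaluations cost O(q^3) per block, independent of n.
.make_blocks <- function(data, spec) {
  age <- data$age - spec$age_centering
  male <- as.numeric(data$sex == "male")
  y <- data$log_wage
  X <- cbind(intercept = 1, age = age, male = male)
  comp <- spec$components
  rows <- split(seq_len(nrow(data)), data$minor_id)
  lapply(rows, function(i) {
    Xi <- X[i, , drop = FALSE]
    yi <- y[i]
    Z <- matrix(1, nrow = length(i), ncol = 1L)
    types <- "minor_int"
    if (comp["minor_slope"]) {
      Z <- cbind(Z, age[i])
      types <- c(types, "minor_slope")
    }
    unit_codes <- character(0)
    if (comp["unit_int"]) {
      uf <- factor(data$unit_code[i])
      unit_codes <- levels(uf)
      Zu <- matrix(0, nrow = length(i), ncol = nlevels(uf))
      Zu[cbind(seq_along(i), as.integer(uf))] <- 1
      Z <- cbind(Z, Zu)
      types <- c(types, rep("unit_int", nlevels(uf)))
      if (comp["unit_slope"]) {
        Z <- cbind(Z, Zu * age[i])
        types <- c(types, rep("unit_slope", nlevels(uf)))
      }
    }
    list(n = length(i),
         minor_code = data$minor_code[i][1L],
         unit_codes = unit_codes,
         types = types,
         ZtZ = crossprod(Z), ZtX = crossprod(Z, Xi), Zty = drop(crossprod(Z, yi)),
         XtX = crossprod(Xi), Xty = drop(crossprod(Xi, yi)), yty = sum(yi^2))
  })
}

# Map component variances to per-column variances of a block's Z.
.col_vars <- function(block, vc) {
  v <- c(minor_int = vc[["var_minor_int"]],
         minor_slope = vc[["var_minor_slope"]],
         unit_int = vc[["var_unit_int"]],
         unit_slope = vc[["var_unit_slope"]])
  unname(v[block$types])
}

# Per-block Woodbury pieces at given variances. With W = Z D^(1/2) and
# M = s2 I_q + D^(1/2) Z'Z D^(1/2):
#   A'V^-1 B = (A'B - (W'A)' M^-1 (W'B)) / s2
#   log det V = (n - q) log s2 + log det M
.block_gls <- function(block, vc) {
  s2 <- vc[["var_resid"]]
  d <- sqrt(.col_vars(block, vc))
  q <- length(d)
  M <- block$ZtZ * tcrossprod(d)
  diag(M) <- diag(M) + s2
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) {
    stop("numerically singular covariance block (minor group ",
         block$minor_code, ")", call. = FALSE)
  }
  WtX <- d * block$ZtX          # q x p
  Wty <- d * block$Zty          # q
  SX <- backsolve(R, forwardsolve(t(R), WtX))
  Sy <- backsolve(R, forwardsolve(t(R), Wty))
  list(XtVX = (block$XtX - crossprod(WtX, SX)) / s2,
       XtVy = (block$Xty - drop(crossprod(WtX, Sy))) / s2,
       ytVy = (block$yty - sum(block$Zty * d * Sy)) / s2,
       logdet = (block$n - q) * log(s2) + 2 * sum(log(diag(R))),
       R = R, d = d, s2 = s2)
}

# Profiled (GLS) likelihood machinery over all blocks.
.profile_fit <- function(blocks, vc, reml = FALSE) {
  p <- 3L
  A <- matrix(0, p, p)
  b <- numeric(p)
  cc <- 0
  ld <- 0
  n <- 0L
  for (blk in blocks) {
    g <- .block_gls(blk, vc)
    A <- A + g$XtVX
    b <- b + g$XtVy
    cc <- cc + g$ytVy
    ld <- ld + g$logdet
    n <- n + blk$n
  }
  beta <- drop(solve(A, b))
  rss <- cc - sum(b * beta)
  ll <- -0.5 * (n * log(2 * pi) + ld + rss)
  if (reml) {
    ll <- ll - 0.5 * (determinant(A, logarithm = TRUE)$modulus -
                        p * log(2 * pi))
  }
  list(loglik = as.numeric(ll), beta = stats::setNames(beta, c("intercept", "age", "male")),
       vcov_beta = solve(A), n = n)
}

#' Marginal log-likelihood of the nested wage model
#'
#' Evaluates the log marginal normal likelihood of the observed log wages at
#' the supplied fixed effects and variance components, after integrating out
#' all random effects. Computation is blockwise by minor group (observations
#' in different minor groups are independent).
#'
#' @param data A `master_data` tibble ([build_master()]).
#' @param spec A [model_spec()].
#' @param beta Named fixed effects `c(intercept=, age=, male=)`.
#' @param varcomps Named variances among `var_minor_int`, `var_minor_slope`,
#'   `var_unit_int`, `var_unit_slope`, `var_resid`; components absent from
#'   the spec must be 0.
#' @return The log-likelihood (scalar).
#' @export
marginal_loglik <- function(data, spec, beta, varcomps) {
  stopifnot(inherits(spec, "model_spec"))
  vc <- .as_varcomps(varcomps)
  inactive <- .vc_names[1:4][!spec$components]
  if (any(vc[inactive] != 0)) {
    stop("variance component(s) not in the model spec must be 0: ",
         paste(inactive[vc[inactive] != 0], collapse = ", "), call. = FALSE)
  }
  beta <- beta[c("intercept", "age", "male")]
  if (anyNA(beta)) stop("beta must name intercept, age, male", call. = FALSE)
  blocks <- .make_blocks(data, spec)
  ll <- 0
  for (blk in blocks) {
    g <- .block_gls(blk, vc)
    quad <- g$ytVy - 2 * sum(g$XtVy * beta) + drop(t(beta) %*% g$XtVX %*% beta)
    ll <- ll - 0.5 * (blk$n * log(2 * pi) + g$logdet + quad)
  }
  if (!is.finite(ll)) stop("non-finite log-likelihood", call. = FALSE)
  ll
}

#' Empirical Bayes (BLUP) group residuals
#'
#' Posterior-mean random effects for every minor and unit group given the
#' data, fixed effects and variance components, solved exactly per
#' minor-group block. Groups about which the data carry little information
#' are shrunk towards 0, the prior mean.
#'
#' @inheritParams marginal_loglik
#' @return A list with tibbles `minor` (`minor_code`, `intercept`, `slope`)
#'   and `unit` (`unit_code`, `intercept`, `slope`); slope columns are 0 for
#'   specs without the corresponding slope term.
#' @export
eb_residuals <- function(data, spec, beta, varcomps) {
  stopifnot(inherits(spec, "model_spec"))
  vc <- .as_varcomps(varcomps)
  beta <- beta[c("intercept", "age", "male")]
  blocks <- .make_blocks(data, spec)
  .eb_from_blocks(blocks, vc, beta, spec)
}

.eb_from_blocks <- function(blocks, vc, beta, spec) {
  minor <- list()
  unit <- list()
  for (blk in blocks) {
    g <- .block_gls(blk, vc)
    Ztr <- blk$Zty - drop(blk$ZtX %*% beta)
    sol <- backsolve(g$R, forwardsolve(t(g$R), g$d * Ztr))
    ZtVr <- (Ztr - drop(blk$ZtZ %*% (g$d * sol))) / g$s2
    bhat <- .col_vars(blk, vc) * ZtVr
    types <- blk$types
    m_int <- bhat[types == "minor_int"]
    m_slo <- if (any(types == "minor_slope")) bhat[types == "minor_slope"] else 0
    minor[[blk$minor_code]] <- c(m_int, m_slo)
    if (length(blk$unit_codes)) {
      u_int <- bhat[types == "unit_int"]
      u_slo <- if (any(types == "unit_slope")) bhat[types == "unit_slope"] else
        numeric(length(u_int))
      for (k in seq_along(blk$unit_codes)) {
        unit[[blk$unit_codes[k]]] <- c(u_int[k], u_slo[k])
      }
    }
  }
  mcodes <- sort(names(minor))
  mmat <- do.call(rbind, minor[mcodes])
  out_minor <- tibble::tibble(minor_code = mcodes,
                              intercept = unname(mmat[, 1L]),
                              slope = unname(mmat[, 2L]))
  if (length(unit)) {
    ucodes <- sort(names(unit))
    umat <- do.call(rbind, unit[ucodes])
    out_unit <- tibble::tibble(unit_code = ucodes,
                               intercept = unname(umat[, 1L]),
                               slope = unname(umat[, 2L]))
  } else {
    out_unit <- tibble::tibble(unit_code = character(0),
                               intercept = numeric(0), slope = numeric(0))
  }
  list(minor = out_minor, unit = out_unit)
}

#' Optimiser control for [fit_wage_model()]
#'
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Maximum optimiser iterations.
#' @param reml Use REML instead of ML (sensitivity analysis; ML is the
#'   default criterion).
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(tol = 1e-8, max_iter = 500L, reml = FALSE) {
  structure(list(tol = tol, max_iter = as.integer(max_iter), reml = reml),
            class = "fit_control")
}

#' Fit the nested random-effects wage model
#'
#' Maximises the marginal likelihood over fixed effects and variance
#' components. Variances are parameterised as log standard deviations for
#' positivity; at each variance iterate the fixed effects are profiled out
#' by generalised least squares, so the optimiser works in at most five
#' dimensions. Variance estimates below 1e-10 are reported as 0 with a
#' boundary flag.
#'
#' @param data A `master_data` tibble ([build_master()]).
#' @param spec A [model_spec()].
#' @param control A [fit_control()].
#' @return An object of class `wage_fit`: fixed effects (`beta`) with
#'   standard errors, variance components (`varcomps`) and their square
#'   roots (`sd`), `boundary` flags, EB residual tables (`eb`), `loglik`,
#'   counts, and the optimiser's accepted log-likelihood trace.
#' @export
fit_wage_model <- function(data, spec = model_spec("M4"),
                           control = fit_control()) {
  stopifnot(inherits(spec, "model_spec"), inherits(control, "fit_control"))
  comp <- spec$components
  if (length(unique(data$minor_id)) < 2L) {
    stop("at least 2 minor groups are required", call. = FALSE)
  }
  if (comp["unit_int"]) {
    units_per_minor <- tapply(data$unit_id, data$minor_id,
                              function(u) length(unique(u)))
    if (max(units_per_minor) < 2L) {
      stop("unit-level components require >= 2 unit groups in at least one minor group",
           call. = FALSE)
    }
  }
  blocks <- .make_blocks(data, spec)
  active <- .vc_names[1:4][comp]

  # Start values from OLS residual decomposition.
  ols <- stats::lm.fit(cbind(1, data$age - spec$age_centering,
                             as.numeric(data$sex == "male")), data$log_wage)
  r <- ols$residuals
  s0 <- stats::sd(r)
  minor_means <- tapply(r, data$minor_id, mean)
  start_sd <- c(
    var_minor_int = max(stats::sd(minor_means), 0.05 * s0),
    var_minor_slope = 0.005,
    var_unit_int = 0.05,
    var_unit_slope = 0.005)
  if (comp["unit_int"]) {
    unit_means <- tapply(r, data$unit_id, mean)
    start_sd["var_unit_int"] <- max(stats::sd(unit_means), 0.05 * s0)
  }
  theta0 <- log(c(start_sd[active], var_resid = 0.9 * s0))

  trace_env <- new.env(parent = emptyenv())
  trace_env$ll <- numeric(0)
  objective <- function(theta) {
    vc <- stats::setNames(numeric(5L), .vc_names)
    vc[c(active, "var_resid")] <- exp(2 * theta)
    pf <- tryCatch(.profile_fit(blocks, vc, reml = control$reml),
                   error = function(e) NULL)
    if (is.null(pf) || !is.finite(pf$loglik)) return(1e10)
    trace_env$ll <- c(trace_env$ll, pf$loglik)
    -pf$loglik
  }
  lower <- rep(log(1e-8), length(theta0))
  upper <- rep(log(1e3), length(theta0))
  # tol is absolute on the log-likelihood; nlminb's criterion is relative,
  # so scale it well below tol for typical |loglik| magnitudes
  ctl <- list(iter.max = control$max_iter,
              eval.max = 10L * control$max_iter,
              rel.tol = max(1e-15, control$tol * 1e-4))
  opt <- stats::nlminb(theta0, objective, lower = lower, upper = upper,
                       control = ctl)
  # Second start from small group variances guards against local optima and
  # enforces dominance over nested specs.
  theta1 <- theta0
  theta1[seq_along(active)] <- log(0.01)
  opt2 <- stats::nlminb(theta1, objective, lower = lower, upper = upper,
                        control = ctl)
  if (opt2$objective < opt$objective) opt <- opt2
  # quasi-Newton polish squeezes the last ~1e-6, so nested-model dominance
  # holds to tight tolerance
  pol <- stats::optim(opt$par, objective, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 200L))
  if (pol$value < opt$objective) {
    opt$par <- pmin(pmax(pol$par, lower), upper)
    opt$objective <- pol$value
  }
  if (!opt$convergence %in% c(0L, 1L) && opt$objective >= 1e10) {
    stop("wage model fit failed to converge; log-likelihood trace: ",
         paste(utils::tail(round(trace_env$ll, 4), 10), collapse = ", "),
         call. = FALSE)
  }

  vc <- stats::setNames(numeric(5L), .vc_names)
  vc[c(active, "var_resid")] <- exp(2 * opt$par)
  boundary <- vc[1:4] < 1e-10 & comp
  if (any(boundary)) {
    vc[names(boundary)[boundary]] <- 0
    warning("variance component(s) at boundary, reported as 0: ",
            paste(names(boundary)[boundary], collapse = ", "), call. = FALSE)
  }
  pf <- .profile_fit(blocks, vc, reml = control$reml)
  eb <- .eb_from_blocks(blocks, vc, pf$beta, spec)

  structure(list(
    spec = spec,
    beta = pf$beta,
    se_beta = stats::setNames(sqrt(diag(pf$vcov_beta)),
                              c("intercept", "age", "male")),
    varcomps = as.list(vc),
    sd = as.list(sqrt(vc)),
    boundary = as.list(boundary),
    eb = eb,
    loglik = pf$loglik,
    reml = control$reml,
    n_obs = pf$n,
    n_minor = length(blocks),
    n_unit = nrow(eb$unit),
    convergence = opt$convergence,
    trace = cummax(trace_env$ll)
  ), class = "wage_fit")
}

#' @export
print.wage_fit <- function(x, ...) {
  cat("Nested random-effects wage model (", x$spec$config, ", ",
      if (x$reml) "REML" else "ML", ")\n", sep = "")
  cat(sprintf("  n = %d observations, %d minor groups, %d unit groups\n",
              x$n_obs, x$n_minor, x$n_unit))
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  cat("Fixed effects (log-pound scale):\n")
  for (nm in names(x$beta)) {
    cat(sprintf("  %-10s %10.5f  (se %.5f)\n", nm, x$beta[[nm]],
                x$se_beta[[nm]]))
  }
  cat("Variance components:\n")
  for (nm in .vc_names) {
    if (nm != "var_resid" && !x$spec$components[[sub("var_", "", nm)]]) next
    flag <- if (!is.null(x$boundary[[nm]]) && isTRUE(x$boundary[[nm]]))
      " (boundary)" else ""
    cat(sprintf("  %-16s %.6g  (sd %.6g)%s\n", nm, x$varcomps[[nm]],
                x$sd[[nm]], flag))
  }
  invisible(x)
}

#' Serialise / deserialise a fitted wage model
#'
#' Writes the full fit (spec, fixed effects, variance components, per-group
#' EB residual tables keyed by group code, log-likelihood, counts, package
#' version) to a JSON document. The round-trip is lossless to full float
#' precision.
#'
#' @param fit A `wage_fit` object.
#' @param path Output / input file path.
#' @rdname wage_fit_io
#' @export
write_wage_fit <- function(fit, path) {
  stopifnot(inherits(fit, "wage_fit"))
  doc <- list(
    format = "synthwage-model",
    version = as.character(utils::packageVersion("synthwage")),
    spec = list(config = fit$spec$config,
                age_centering = fit$spec$age_centering),
    beta = as.list(fit$beta),
    se_beta = as.list(fit$se_beta),
    varcomps = fit$varcomps,
    boundary = fit$boundary,
    loglik = fit$loglik,
    reml = fit$reml,
    n_obs = fit$n_obs, n_minor = fit$n_minor, n_unit = fit$n_unit,
    convergence = fit$convergence,
    eb_minor = as.list(fit$eb$minor),
    eb_unit = as.list(fit$eb$unit)
  )
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname wage_fit_io
#' @export
read_wage_fit <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, "synthwage-model")) {
    stop("not a synthwage model file: ", path, call. = FALSE)
  }
  spec <- model_spec(doc$spec$config, doc$spec$age_centering)
  eb <- list(
    minor = tibble::as_tibble(doc$eb_minor),
    unit = if (length(doc$eb_unit$unit_code))
      tibble::as_tibble(doc$eb_unit)
    else tibble::tibble(unit_code = character(0), intercept = numeric(0),
                        slope = numeric(0))
  )
  eb$minor$minor_code <- as.character(eb$minor$minor_code)
  eb$unit$unit_code <- as.character(eb$unit$unit_code)
  structure(list(
    spec = spec,
    beta = unlist(doc$beta),
    se_beta = unlist(doc$se_beta),
    varcomps = as.list(unlist(doc$varcomps)),
    sd = as.list(sqrt(unlist(doc$varcomps))),
    boundary = as.list(unlist(doc$boundary)),
    eb = eb,
    loglik = doc$loglik,
    reml = isTRUE(doc$reml),
    n_obs = doc$n_obs, n_minor = doc$n_minor, n_unit = doc$n_unit,
    convergence = doc$convergence,
    trace = numeric(0)
  ), class = "wage_fit")
}
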