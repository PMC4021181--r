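#' Geometric mean wage
#'
#' exp(mean of logs); the baseline predictor for internal validation.
#'
#' @param wages Positive vector.
#' @return Scalar geometric mean.
#' @export
geometric_mean <- function(wages) {
  if (length(wages) == 0L || any(!is.finite(wages) | wages <= 0)) {
    stop("geometric mean requires positive finite values", call. = FALSE)
  }
  exp(mean(log(wages)))
}

#' Baseline wage predictions for a holdout set
#'
#' `"grand"`: every holdout row gets the master data's grand geometric mean
#' wage. `"per_unit_group"`: each row gets the geometric mean of its unit
#' group's training wages, falling back to the grand mean for groups absent
#' from training.
#'
#' @param master A `master_data` tibble (training data).
#' @param holdout A data frame with an occupation column.
#' @param kind `"grand"` or `"per_unit_group"`.
#' @param soc_col Name of the occupation column in `holdout`.
#' @return Numeric vector of pound-scale predictions, one per holdout row.
#' @export
baseline_predictions <- function(master, holdout,
                                 kind = c("grand", "per_unit_group"),
                                 soc_col = "soc") {
  kind <- match.arg(kind)
  if (nrow(master) == 0L) stop("empty master data", call. = FALSE)
  grand <- geometric_mean(master$wage)
  if (kind == "grand") return(rep(grand, nrow(holdout)))
  gm_unit <- tapply(log(master$wage), master$unit_code, mean)
  codes <- as.character(holdout[[soc_col]])
  pred <- exp(gm_unit[codes])
  pred[is.na(pred)] <- grand
  unname(pred)
}

#' Residual deviation of predictions
#'
#' The deviation statistic for internal validation: by default the standard
#' deviation (denominator n-1) of actual minus predicted wage on the pound
#' scale; `"rms"` gives the root-mean-square residual about zero instead
#' (the two differ when predictions are biased).
#'
#' @param predicted,actual Equal-length pound-scale vectors.
#' @param method `"sd"` (default) or `"rms"`.
#' @return Scalar deviation in pounds.
#' @export
residual_deviation <- function(predicted, actual, method = c("sd", "rms")) {
  method <- match.arg(method)
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length", call. = FALSE)
  }
  if (length(actual) < 2L) stop("need at least 2 observations", call. = FALSE)
  r <- actual - predicted
  switch(method, sd = stats::sd(r), rms = sqrt(mean(r^2)))
}

#' Percent reduction of deviation
#'
#' Reduction relative to a baseline, on the variance scale:
#' 100 * (1 - (dev / dev_baseline)^2). The squared ratio is what makes a
#' deviation pair like (150, 209) evaluate to ~48.5%.
#'
#' @param dev Deviation of the predictor under evaluation (>= 0).
#' @param dev_baseline Deviation of the baseline (> 0).
#' @return Percent reduction.
#' @export
pct_reduction <- function(dev, dev_baseline) {
  stopifnot(all(dev >= 0), all(dev_baseline > 0))
  100 * (1 - (dev / dev_baseline)^2)
}

#' Split raw records by survey year
#'
#' Utility for internal validation: hold out one survey year and train on
#' the rest.
#'
#' @param records Raw microdata with a `survey_year` column.
#' @param holdout_year Year to hold out.
#' @return List with elements `train` and `holdout`.
#' @export
split_by_year <- function(records, holdout_year) {
  is_hold <- records$survey_year == holdout_year
  if (!any(is_hold)) stop("no records in holdout year ", holdout_year,
                          call. = FALSE)
  list(train = records[!is_hold, , drop = FALSE],
       holdout = records[is_hold, , drop = FALSE])
}

#' Internal validation report
#'
#' Compares fitted wage models against the grand and per-unit-group
#' geometric-mean baselines on a holdout sample, reporting the residual
#' deviation of each predictor and its percent reduction relative to the
#' grand baseline. The lowest-deviation row is flagged.
#'
#' @param fits Named list of `wage_fit` objects (may be empty: baselines
#'   only).
#' @param master Training `master_data`.
#' @param holdout Data frame with columns `age`, `sex`, `soc` and `wage`
#'   (actual wage, standardised pounds). Must be disjoint from training;
#'   see [split_by_year()].
#' @param method Deviation statistic, see [residual_deviation()].
#' @return A tibble of class `deviation_report` with columns `predictor`,
#'   `deviation`, `pct_reduction`, `best`; attributes `n` and
#'   `baseline_name`.
#' @export
internal_validation <- function(fits, master, holdout, method = "sd") {
  stopifnot(is.list(fits))
  actual <- holdout$wage
  preds <- list(
    grand_geometric_mean = baseline_predictions(master, holdout, "grand"),
    unit_group_geometric_mean =
      baseline_predictions(master, holdout, "per_unit_group")
  )
  for (nm in names(fits)) {
    preds[[nm]] <- predict_log_wage(fits[[nm]], holdout$age, holdout$sex,
                                    holdout$soc)$wage_hat
  }
  dev <- vapply(preds, residual_deviation, numeric(1),
                actual = actual, method = method)
  out <- tibble::tibble(
    predictor = names(dev),
    deviation = unname(dev),
    pct_reduction = pct_reduction(unname(dev), dev[["grand_geometric_mean"]]),
    best = seq_along(dev) == which.min(dev)
  )
  structure(out, n = length(actual), baseline_name = "grand_geometric_mean",
            method = method,
            class = c("deviation_report", class(out)))
}

#' Decile groups
#'
#' Rank-based assignment into 10 groups whose sizes differ by at most one;
#' ties are broken by stable input order, and group 1 holds the lowest
#' values. With all values equal the groups are still balanced, purely by
#' input order (documented degenerate behaviour).
#'
#' @param x Numeric vector, length >= 10.
#' @return Integer vector of group labels 1..10 aligned with `x`.
#' @export
decile_groups <- function(x) {
  n <- length(x)
  if (n < 10L) stop("need at least 10 observations for deciles", call. = FALSE)
  ord <- order(x, seq_len(n))  # stable: ties keep input order
  g <- integer(n)
  g[ord] <- ceiling(seq_len(n) * 10 / n)
  g
}

#' Binary recoding of a self-rated health item
#'
#' Codes the worse end of an ordered response scale to 1. Different surveys
#' word and scale the item differently, so the set of "poor" levels is a
#' parameter (e.g. fair/bad/very bad vs good/very good).
#'
#' @param response Character or factor vector of responses.
#' @param poor_levels Levels coded 1.
#' @return Integer 0/1 vector (NA preserved).
#' @export
code_poor_health <- function(response,
                             poor_levels = c("fair", "bad", "very bad")) {
  as.integer(as.character(response) %in% poor_levels) *
    ifelse(is.na(response), NA_integer_, 1L)
}

.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Logistic regression with odds ratios and fit correlation
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()]) of a binary outcome on main effects of the supplied
#' predictors. Reports Wald standard errors, odds ratios with 95%
#' confidence intervals (exp(coef +/- 1.96 se)), significance stars, and
#' the correlation-based fit measure of [zheng_agresti_r()].
#'
#' @param y Binary 0/1 outcome containing both classes.
#' @param x Data frame of predictors (continuous and/or factors). Scale
#'   continuous income to units of 100 pounds before calling (done by
#'   [external_validation()]).
#' @return An object of class `logistic_fit`: tibble `coefficients`
#'   (term, estimate, se, z, p_value, odds_ratio, or_low, or_high, stars),
#'   `fit_r`, `n`, `terms`.
#' @export
fit_logistic <- function(y, x) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) stop("y must contain both classes", call. = FALSE)
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y))
  df <- cbind(data.frame(.y = y), x)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design: ", paste(names(cf)[is.na(cf)], collapse = ", "),
         call. = FALSE)
  }
  if (!fit$converged ||
      (sep_warn && (fit$deviance < 1e-4 || max(abs(cf[-1L])) > 15))) {
    stop("(quasi-)separation detected: coefficients diverge", call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  z <- cf / se
  p <- 2 * stats::pnorm(-abs(z))
  coefs <- tibble::tibble(
    term = names(cf),
    estimate = unname(cf),
    se = unname(se),
    z = unname(z),
    p_value = unname(p),
    odds_ratio = exp(unname(cf)),
    or_low = exp(unname(cf) - 1.96 * unname(se)),
    or_high = exp(unname(cf) + 1.96 * unname(se)),
    stars = .stars(unname(p))
  )
  structure(list(coefficients = coefs,
                 fit_r = zheng_agresti_r(y, stats::fitted(fit)),
                 n = length(y),
                 terms = names(x)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit: n =", x$n, " fit r =", format(x$fit_r, digits = 4), "\n")
  df <- as.data.frame(x$coefficients)
  df$estimate <- round(df$estimate, 4)
  df$odds_ratio <- round(df$odds_ratio, 3)
  df$or_low <- round(df$or_low, 3)
  df$or_high <- round(df$or_high, 3)
  print(df[, c("term", "odds_ratio", "or_low", "or_high", "stars")],
        row.names = FALSE)
  invisible(x)
}

#' Correlation-based fit measure for binary-outcome models
#'
#' The Pearson product-moment correlation between the observed 0/1 outcomes
#' and the model's fitted probabilities; higher is better. Useful for
#' comparing non-nested logistic models of the same outcome.
#'
#' @param y Binary outcomes.
#' @param p_hat Fitted probabilities, same length.
#' @return Correlation in \[-1, 1\].
#' @export
zheng_agresti_r <- function(y, p_hat) {
  if (length(y) != length(p_hat)) {
    stop("y and p_hat must have equal length", call. = FALSE)
  }
  if (stats::var(y) == 0 || stats::var(p_hat) == 0) {
    stop("zero variance in outcomes or fitted probabilities", call. = FALSE)
  }
  stats::cor(y, p_hat)
}

#' External validation: health gradients of income measures
#'
#' For each income measure and each adjustment set, fits two age/sex
#' adjusted logistic regressions of the binary poor-health outcome: one on
#' the continuous measure scaled in units of 100 pounds, and one on its
#' deciles (lowest decile as reference, nine indicator terms). Each fit is
#' complete-case on its own variables, so sample sizes may differ across
#' measures.
#'
#' @param survey Data frame with columns `poor_health` (0/1), `age`, `sex`,
#'   the income measure columns, and any adjustment covariate columns.
#' @param income_measures Character vector of income column names (pound
#'   scale), optionally named for reporting.
#' @param adjustments Named list of character vectors of extra covariate
#'   columns; `character(0)` means age/sex adjustment only.
#' @return A nested list `result[[measure]][[adjustment]]` with elements
#'   `continuous` and `decile`, each a `logistic_fit`; class
#'   `external_validation`.
#' @export
external_validation <- function(survey, income_measures,
                                adjustments = list(age_sex = character(0))) {
  survey <- as.data.frame(survey)
  if (is.null(names(income_measures))) names(income_measures) <- income_measures
  stopifnot(all(c("poor_health", "age", "sex") %in% names(survey)))
  out <- list()
  for (mi in seq_along(income_measures)) {
    m <- income_measures[[mi]]
    mname <- names(income_measures)[mi]
    out[[mname]] <- list()
    for (ai in seq_along(adjustments)) {
      adj <- adjustments[[ai]]
      aname <- names(adjustments)[ai]
      vars <- c("poor_health", m, "age", "sex", adj)
      miss <- setdiff(vars, names(survey))
      if (length(miss)) {
        stop("missing column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
      }
      cc <- stats::complete.cases(survey[, vars, drop = FALSE])
      d <- survey[cc, , drop = FALSE]
      base <- data.frame(age = d$age, sex = factor(d$sex))
      for (v in adj) base[[v]] <- factor(d[[v]])
      xc <- cbind(data.frame(income100 = d[[m]] / 100), base)
      xd <- cbind(data.frame(decile = factor(decile_groups(d[[m]]))), base)
      out[[mname]][[aname]] <- list(
        continuous = fit_logistic(d$poor_health, xc),
        decile = fit_logistic(d$poor_health, xd)
      )
    }
  }
  structure(out, class = "external_validation")
}

#' Tidy table of external-validation results
#'
#' One row per measure x adjustment x model form x term, with odds ratios,
#' confidence intervals, fit correlation and sample size.
#'
#' @param ev An `external_validation` object.
#' @return A tibble.
#' @export
external_validation_table <- function(ev) {
  rows <- list()
  for (m in names(ev)) {
    for (a in names(ev[[m]])) {
      for (form in c("continuous", "decile")) {
        f <- ev[[m]][[a]][[form]]
        cf <- f$coefficients
        keep <- if (form == "continuous") cf$term == "income100"
                else grepl("^decile", cf$term)
        cf <- cf[keep, , drop = FALSE]
        cf$measure <- m
        cf$adjustment <- a
        cf$form <- form
        cf$fit_r <- f$fit_r
        cf$n <- f$n
        rows[[length(rows) + 1L]] <- cf
      }
    }
  }
  out <- do.call(rbind, rows)
  out[, c("measure", "adjustment", "form", "term", "odds_ratio",
          "or_low", "or_high", "stars", "fit_r", "n")]
}
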