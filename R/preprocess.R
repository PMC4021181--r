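#' Consumer-price-index table
#'
#' Holds an annual price index and the reference year all wages are
#' deflated to. Index values are on an arbitrary positive scale; only the
#' ratio between years matters.
#'
#' @param years Integer vector of calendar years.
#' @param index Positive index value per year.
#' @param reference_year Year wages are standardised to; must be in `years`.
#' @return An object of class `cpi_table`.
#' @export
cpi_table <- function(years, index, reference_year) {
  years <- as.integer(years)
  if (length(years) != length(index)) {
    stop("years and index must have equal length", call. = FALSE)
  }
  if (anyDuplicated(years)) stop("duplicate years in CPI table", call. = FALSE)
  if (any(!is.finite(index) | index <= 0)) {
    stop("CPI index values must be positive and finite", call. = FALSE)
  }
  reference_year <- as.integer(reference_year)
  if (!reference_year %in% years) {
    stop("reference year ", reference_year, " not present in CPI table",
         call. = FALSE)
  }
  structure(list(years = years, index = as.numeric(index),
                 reference_year = reference_year),
            class = "cpi_table")
}

#' Read a CPI file
#'
#' Two-column delimited text (year, index) with a header row.
#'
#' @param path File path.
#' @param reference_year Reference year for standardisation.
#' @param delim Field delimiter.
#' @return A [cpi_table()].
#' @export
read_cpi <- function(path, reference_year, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          comment.char = "#", stringsAsFactors = FALSE)
  cpi_table(df[[1L]], df[[2L]], reference_year)
}

#' Standardise wages to reference-year prices
#'
#' Multiplies each wage by index(reference year) / index(its survey year),
#' putting all amounts on the reference year's price level.
#'
#' @param wage Positive wage amounts.
#' @param year Survey year per wage (recycled if scalar).
#' @param cpi A [cpi_table()].
#' @return Standardised wages.
#' @examples
#' cpi <- cpi_table(c(2001, 2006), c(90, 100), 2006)
#' standardise_wage(90, 2001, cpi)  # 100
#' @export
standardise_wage <- function(wage, year, cpi) {
  stopifnot(inherits(cpi, "cpi_table"))
  pos <- match(as.integer(year), cpi$years)
  if (anyNA(pos)) {
    stop("year(s) absent from CPI table: ",
         paste(unique(year[is.na(pos)]), collapse = ", "), call. = FALSE)
  }
  ref <- cpi$index[match(cpi$reference_year, cpi$years)]
  wage * ref / cpi$index[pos]
}

#' Working-age eligibility
#'
#' Working age is 16-65 for men and 16-60 for women, both bounds inclusive.
#'
#' @param age Age in years.
#' @param sex `"female"` or `"male"`.
#' @return Logical keep-mask.
#' @export
working_age_filter <- function(age, sex) {
  upper <- ifelse(sex == "male", 65L, 60L)
  !is.na(age) & !is.na(sex) & age >= 16L & age <= upper
}

#' Employment eligibility
#'
#' Keeps only respondents in employment in the week before the survey;
#' a missing flag is treated as not employed (complete-case rule).
#'
#' @param employed_last_week Logical vector.
#' @return Logical keep-mask.
#' @export
employment_filter <- function(employed_last_week) {
  !is.na(employed_last_week) & employed_last_week
}

#' Outlier trimming policy
#'
#' @param lower_q,upper_q Quantile bounds for the initial trim.
#' @param skew_threshold Absolute skewness of log wage tolerated after the
#'   quantile trim; beyond it the most extreme values are removed one at a
#'   time, capped at 1% additional removals.
#' @return A list of class `trim_policy`.
#' @export
trim_policy <- function(lower_q = 0.001, upper_q = 0.999, skew_threshold = 1.0) {
  stopifnot(lower_q >= 0, upper_q <= 1, lower_q < upper_q, skew_threshold > 0)
  structure(list(lower_q = lower_q, upper_q = upper_q,
                 skew_threshold = skew_threshold), class = "trim_policy")
}

#' Sample skewness (third-moment estimator)
#'
#' g1 = m3 / m2^(3/2) with central moments m2, m3; returns 0 for a
#' zero-variance sample.
#'
#' @param x Numeric vector.
#' @return Skewness value.
#' @export
sample_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' Trim outlying wages
#'
#' Two-stage deterministic rule: (1) drop wages outside the empirical
#' [lower_q, upper_q] quantiles; (2) if the sample skewness of log wage
#' still exceeds the threshold in absolute value, iteratively remove the
#' value farthest (in |log wage - median log wage|) from the running median,
#' until the threshold is met or 1% additional rows have been removed.
#'
#' @param wages Positive wage vector.
#' @param policy A [trim_policy()].
#' @return Logical keep-mask over the input.
#' @export
trim_outliers <- function(wages, policy = trim_policy()) {
  stopifnot(inherits(policy, "trim_policy"))
  if (length(wages) == 0L) stop("empty wage vector", call. = FALSE)
  if (any(!is.finite(wages) | wages <= 0)) {
    stop("wages must be positive and finite", call. = FALSE)
  }
  # inverse-ECDF quantiles: actual sample values, so nothing is trimmed
  # from a small clean sample
  q <- stats::quantile(wages, c(policy$lower_q, policy$upper_q),
                       names = FALSE, type = 1)
  keep <- wages >= q[1L] & wages <= q[2L]
  lw <- log(wages)
  cap <- ceiling(0.01 * sum(keep))
  removed <- 0L
  while (removed < cap && abs(sample_skewness(lw[keep])) > policy$skew_threshold) {
    med <- stats::median(lw[keep])
    cand <- which(keep)
    worst <- cand[which.max(abs(lw[cand] - med))]  # ties: first index
    keep[worst] <- FALSE
    removed <- removed + 1L
  }
  if (sum(keep) < 10L) {
    stop("degenerate wage distribution: fewer than 10 values remain after trimming",
         call. = FALSE)
  }
  keep
}

#' Build the master modelling dataset
#'
#' Applies, in order: complete-case restriction on the modelling variables
#' (wage, age, sex, occupation) -> working-age filter -> employment filter ->
#' CPI standardisation -> outlier trim -> log transform -> group-index join.
#' Rows dropped at each stage are counted.
#'
#' @param records A data frame of raw survey microdata with columns `age`,
#'   `sex` (`"female"`/`"male"`), `soc_unit` (4-digit occupation code),
#'   `gross_weekly_wage`, `survey_year`, `employed_last_week`.
#' @param cpi A [cpi_table()].
#' @param table Optional [classification_table()]; when supplied, rows whose
#'   occupation is not listed are dropped (and counted). By default the
#'   hierarchy is derived from the codes present in the data.
#' @param policy A [trim_policy()].
#' @return A tibble of class `master_data` with columns `age`, `sex`,
#'   `minor_code`, `unit_code`, `minor_id`, `unit_id`, `wage` (standardised
#'   pounds/week) and `log_wage`, plus attributes `drop_counts`, `n_input`
#'   and `reference_year`.
#' @export
build_master <- function(records, cpi, table = NULL, policy = trim_policy()) {
  records <- as.data.frame(records)
  need <- c("age", "sex", "soc_unit", "gross_weekly_wage", "survey_year",
            "employed_last_week")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  n_input <- nrow(records)
  drops <- c(missing = 0L, working_age = 0L, employment = 0L,
             unknown_soc = 0L, outlier = 0L)

  soc_ok <- !is.na(records$soc_unit) &
    grepl("^\\s*[0-9]{4}\\s*$", as.character(records$soc_unit))
  cc <- !is.na(records$age) & !is.na(records$sex) &
    !is.na(records$gross_weekly_wage) & records$gross_weekly_wage > 0 &
    !is.na(records$survey_year) & soc_ok
  drops["missing"] <- sum(!cc)
  records <- records[cc, , drop = FALSE]

  wa <- working_age_filter(records$age, records$sex)
  drops["working_age"] <- sum(!wa)
  records <- records[wa, , drop = FALSE]

  emp <- employment_filter(records$employed_last_week)
  drops["employment"] <- sum(!emp)
  records <- records[emp, , drop = FALSE]

  if (!is.null(table)) {
    known <- trimws(as.character(records$soc_unit)) %in% table$unit_code
    drops["unknown_soc"] <- sum(!known)
    records <- records[known, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    stop("no records remain after eligibility filters", call. = FALSE)
  }

  wage_std <- standardise_wage(records$gross_weekly_wage,
                               records$survey_year, cpi)
  # trimming needs a distribution to look at; tiny tables pass through
  keep <- if (nrow(records) >= 10L) trim_outliers(wage_std, policy) else
    rep(TRUE, nrow(records))
  drops["outlier"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  wage_std <- wage_std[keep]

  codes <- parse_soc(records$soc_unit)
  index <- soc_group_index(if (is.null(table)) codes else table$unit_code)
  pos <- match(codes, index$unit_code)

  out <- tibble::tibble(
    age = as.numeric(records$age),
    sex = as.character(records$sex),
    minor_code = index$minor_code[pos],
    unit_code = index$unit_code[pos],
    minor_id = index$minor_id[pos],
    unit_id = index$unit_id[pos],
    wage = wage_std,
    log_wage = log(wage_std)
  )
  stopifnot(all(is.finite(out$log_wage)))
  structure(out, drop_counts = drops, n_input = n_input,
            reference_year = cpi$reference_year,
            class = c("master_data", class(out)))
}

#' Write / read a master dataset
#'
#' The table goes to delimited text; the drop-count provenance goes to a
#' JSON sidecar (`<path>.meta.json`).
#'
#' @param master A `master_data` tibble from [build_master()].
#' @param path Output file path.
#' @rdname master_io
#' @export
write_master <- function(master, path) {
  utils::write.csv(as.data.frame(master), path, row.names = FALSE)
  meta <- list(drop_counts = as.list(attr(master, "drop_counts")),
               n_input = attr(master, "n_input"),
               reference_year = attr(master, "reference_year"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname master_io
#' @export
read_master <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    minor_code = "character", unit_code = "character", sex = "character"))
  out <- tibble::as_tibble(df)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(out, "drop_counts") <- unlist(meta$drop_counts)
    attr(out, "n_input") <- meta$n_input
    attr(out, "reference_year") <- meta$reference_year
  }
  class(out) <- c("master_data", class(out))
  out
}
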