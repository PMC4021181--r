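#' Tiers of a digit-coded occupational classification
#'
#' The classification is tiered: 1-digit major groups contain 2-digit
#' sub-major groups, which contain 3-digit minor groups, which contain
#' 4-digit unit groups. The tier of a code is determined solely by its
#' length, and the ancestor of a code at any coarser tier is a prefix.
#'
#' @format A character vector of the four tier names, ordered coarse to fine.
#' @export
soc_tiers <- c("major", "sub-major", "minor", "unit")

#' Parse and validate occupation codes
#'
#' Accepts digit-strings of length 1 to 4 (major through unit tier).
#' Leading/trailing whitespace is stripped; anything else non-digit or
#' over-length is an error naming the offending value.
#'
#' @param raw Character vector (or coercible) of raw codes.
#' @return Character vector of validated codes.
#' @examples
#' parse_soc(c("1121", " 243 "))
#' @export
parse_soc <- function(raw) {
  x <- trimws(as.character(raw))
  ok <- !is.na(x) & grepl("^[0-9]{1,4}$", x)
  if (!all(ok)) {
    bad <- unique(raw[!ok])
    stop("malformed occupation code(s): ",
         paste(sQuote(as.character(bad)), collapse = ", "), call. = FALSE)
  }
  x
}

#' Tier of an occupation code
#'
#' @param code Validated occupation code(s), see [parse_soc()].
#' @return Character vector of tier names ("major", "sub-major", "minor",
#'   "unit").
#' @export
soc_tier <- function(code) {
  code <- parse_soc(code)
  soc_tiers[nchar(code)]
}

#' Ancestor of a code at a coarser tier
#'
#' Returns the prefix of the code at the requested tier. Requesting the
#' code's own tier returns the code unchanged; requesting a finer tier than
#' the code carries is an error (a minor code cannot be refined to a unit).
#'
#' @param code Occupation code(s).
#' @param tier One of `"major"`, `"sub-major"`, `"minor"`, `"unit"`.
#' @return Character vector of ancestor codes.
#' @examples
#' soc_ancestor("1121", "minor")  # "112"
#' @export
soc_ancestor <- function(code, tier = c("major", "sub-major", "minor", "unit")) {
  tier <- match.arg(tier)
  code <- parse_soc(code)
  len <- match(tier, soc_tiers)
  if (any(len > nchar(code))) {
    stop("cannot derive tier ", sQuote(tier), " from coarser code(s): ",
         paste(sQuote(code[len > nchar(code)]), collapse = ", "), call. = FALSE)
  }
  substr(code, 1L, len)
}

#' Build a classification table from unit codes
#'
#' A classification table is the set of unit-tier (4-digit) codes in use,
#' with optional human-readable labels. The coarser tiers are derivable from
#' the codes themselves by prefix, so no external lookup is needed and any
#' tiered digit-coded scheme works.
#'
#' @param unit_codes Character vector of 4-digit unit codes, no duplicates.
#' @param labels Optional character vector of labels, same length.
#' @return A tibble with columns `unit_code` and `label`, sorted by code.
#' @export
classification_table <- function(unit_codes, labels = NULL) {
  unit_codes <- parse_soc(unit_codes)
  if (any(nchar(unit_codes) != 4L)) {
    stop("classification entries must be unit-tier (4-digit) codes",
         call. = FALSE)
  }
  if (anyDuplicated(unit_codes)) {
    stop("duplicate unit codes: ",
         paste(sQuote(unique(unit_codes[duplicated(unit_codes)])),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(labels)) labels <- NA_character_
  out <- tibble::tibble(unit_code = unit_codes,
                        label = as.character(labels))
  out[order(out$unit_code), , drop = FALSE]
}

#' Read a classification file
#'
#' Two-column delimited text (unit_code, label), UTF-8, header row required.
#'
#' @param path File path.
#' @param delim Field delimiter (default comma).
#' @return A classification table, see [classification_table()].
#' @export
read_classification <- function(path, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          colClasses = "character", comment.char = "#",
                          quote = "\"", encoding = "UTF-8",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("classification file has no columns", call. = FALSE)
  labels <- if (ncol(df) >= 2L) df[[2L]] else NULL
  classification_table(df[[1L]], labels)
}

#' Dense group indices for the minor and unit tiers
#'
#' Maps every unit code to a (minor-group id, unit-group id) pair. Ids are
#' dense consecutive integers assigned in lexicographic code order, so the
#' mapping is deterministic given the set of codes; units sharing a 3-digit
#' prefix share a minor id.
#'
#' @param table A classification table ([classification_table()]) or a
#'   character vector of unit codes.
#' @return A tibble with columns `unit_code`, `minor_code`, `minor_id`,
#'   `unit_id`.
#' @export
soc_group_index <- function(table) {
  codes <- if (is.data.frame(table)) table$unit_code else parse_soc(table)
  if (length(codes) == 0L) stop("empty classification table", call. = FALSE)
  if (any(nchar(codes) != 4L)) {
    stop("group index requires unit-tier (4-digit) codes", call. = FALSE)
  }
  codes <- sort(unique(codes))
  minor <- substr(codes, 1L, 3L)
  tibble::tibble(
    unit_code = codes,
    minor_code = minor,
    minor_id = match(minor, sort(unique(minor))),
    unit_id = seq_along(codes)
  )
}
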