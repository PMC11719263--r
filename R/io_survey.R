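#' Build an item codebook
#'
#' A codebook declares, for every survey item, its identity, free-text
#' description, community membership (e.g. `"lifestyle"` vs `"outcome"`),
#' whether the item is reverse coded (items worded with a "less" prefix so
#' that higher always means healthier), and its ordinal response levels.
#'
#' @param id character vector of unique item labels (e.g. `"L7"`, `"H5"`).
#' @param community community label per item; at least one non-empty value.
#' @param description optional free text per item.
#' @param reverse_coded logical per item; `FALSE` by default.
#' @param level_min,level_max integer bounds of the ordinal scale
#'   (default 1..5). The scale is the contiguous integer range between them.
#' @return A `likert_codebook`: data frame with columns `id`, `description`,
#'   `community`, `reverse_coded`, `level_min`, `level_max`.
#' @export
codebook <- function(id, community, description = id,
                     reverse_coded = FALSE, level_min = 1L, level_max = 5L) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("codebook item ids must be unique")
  community <- rep_len(as.character(community), length(id))
  if (any(!nzchar(community))) stop("community labels must be non-empty")
  reverse_coded <- rep_len(as.logical(reverse_coded), length(id))
  level_min <- rep_len(as.integer(level_min), length(id))
  level_max <- rep_len(as.integer(level_max), length(id))
  if (any(level_max - level_min < 1L))
    stop("each item needs at least 2 ordered levels")
  cb <- data.frame(id = id, description = rep_len(as.character(description),
                                                  length(id)),
                   community = community, reverse_coded = reverse_coded,
                   level_min = level_min, level_max = level_max,
                   stringsAsFactors = FALSE)
  class(cb) <- c("likert_codebook", "data.frame")
  cb
}

#' Read a codebook from a YAML or JSON file
#'
#' The file holds a list of item records with fields `id`, `community` and
#' optionally `description`, `reverse_coded`, `level_min`, `level_max`.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return A [codebook()].
#' @export
read_codebook <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    stop("unsupported codebook format: .", ext))
  if (!is.null(raw$items)) raw <- raw$items
  get1 <- function(rec, f, d) if (is.null(rec[[f]])) d else rec[[f]]
  codebook(
    id = vapply(raw, function(r) as.character(r$id), ""),
    community = vapply(raw, function(r) as.character(r$community), ""),
    description = vapply(raw, function(r) as.character(get1(r, "description", r$id)), ""),
    reverse_coded = vapply(raw, function(r) isTRUE(get1(r, "reverse_coded", FALSE)), NA),
    level_min = vapply(raw, function(r) as.integer(get1(r, "level_min", 1L)), 1L),
    level_max = vapply(raw, function(r) as.integer(get1(r, "level_max", 5L)), 1L))
}

#' The 18-lifestyle / 13-health-outcome instrument codebook
#'
#' Codebook of the 31-item instrument used in the 29-country study this
#' package models: 18 lifestyle items (L1-L18) and 13 health outcomes
#' (H1-H13) on a 1-5 scale, with the "less"-prefixed items flagged as
#' reverse coded.
#'
#' @return A [codebook()] with 31 items.
#' @export
default_codebook <- function() {
  read_codebook(system.file("extdata", "codebook_lifestyle_outcomes.yaml",
                            package = "likertnet", mustWork = TRUE))
}

#' Construct a survey matrix
#'
#' @param values integer matrix (respondents x items), `NA` = missing; column
#'   names must match codebook item ids (order taken from the codebook).
#' @param codebook a [codebook()] covering all columns.
#' @param country country tag for reporting.
#' @return A `survey_matrix`: list with `values`, `item_ids`, `country`,
#'   `codebook`, `n`.
#' @export
survey_matrix <- function(values, codebook, country = "unknown") {
  stopifnot(inherits(codebook, "likert_codebook"))
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("values must have item-id column names")
  missing_items <- setdiff(codebook$id, colnames(values))
  if (length(missing_items))
    stop("survey table is missing item column(s): ",
         paste(missing_items, collapse = ", "))
  values <- values[, codebook$id, drop = FALSE]
  storage.mode(values) <- "integer"
  if (nrow(values) < 1L) stop("survey matrix needs at least one respondent")
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    bad <- !is.na(v) & (v < codebook$level_min[j] | v > codebook$level_max[j])
    if (any(bad))
      stop(sprintf("item %s has out-of-range value(s) (first at row %d): scale is %d..%d",
                   codebook$id[j], which(bad)[1], codebook$level_min[j],
                   codebook$level_max[j]))
  }
  structure(list(values = values, item_ids = codebook$id,
                 country = country, codebook = codebook, n = nrow(values)),
            class = "survey_matrix")
}

#' @export
print.survey_matrix <- function(x, ...) {
  cat(sprintf("survey_matrix: %d respondents x %d items (%s)\n", x$n,
              length(x$item_ids), x$country))
  comm <- table(x$codebook$community)
  cat("  communities:", paste(names(comm), comm, sep = "=", collapse = ", "), "\n")
  cat("  missing cells:", sum(is.na(x$values)), "\n")
  invisible(x)
}

#' Load a survey table from CSV
#'
#' One row per respondent, one integer column per codebook item; empty cells
#' are missing. Extra columns are ignored with a message. By default the
#' reverse-coded items are flipped at load time so that downstream analysis
#' always sees "higher = healthier".
#'
#' @param table_file CSV path.
#' @param codebook a [codebook()] or path to one.
#' @param country country tag; defaults to a `country` column when present.
#' @param apply_reverse flip reverse-coded items on load (default `TRUE`).
#' @return A [survey_matrix()].
#' @export
load_survey <- function(table_file, codebook, country = NULL,
                        apply_reverse = TRUE) {
  if (is.character(codebook)) codebook <- read_codebook(codebook)
  df <- read.csv(table_file, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  extra <- setdiff(colnames(df), c(codebook$id, "country"))
  if (length(extra))
    message("ignoring non-codebook column(s): ", paste(extra, collapse = ", "))
  missing_items <- setdiff(codebook$id, colnames(df))
  if (length(missing_items))
    stop("survey table is missing item column(s): ",
         paste(missing_items, collapse = ", "))
  if (is.null(country))
    country <- if ("country" %in% colnames(df) && nrow(df))
      as.character(df$country[1]) else "unknown"
  vals <- matrix(NA_integer_, nrow(df), nrow(codebook),
                 dimnames = list(NULL, codebook$id))
  for (j in seq_len(nrow(codebook))) {
    raw <- trimws(df[[codebook$id[j]]])
    empty <- !nzchar(raw) | is.na(raw)
    parsed <- suppressWarnings(as.integer(raw))
    bad <- !empty & (is.na(parsed) | parsed != suppressWarnings(as.numeric(raw)))
    if (any(bad))
      stop(sprintf("non-integer cell at row %d, column %s: '%s'",
                   which(bad)[1], codebook$id[j], raw[which(bad)[1]]))
    parsed[empty] <- NA_integer_
    vals[, j] <- parsed
  }
  m <- survey_matrix(vals, codebook, country)
  if (apply_reverse) m <- reverse_code(m) else m
}

#' Write a survey matrix to CSV (round-trips with [load_survey()])
#'
#' @param matrix a [survey_matrix()].
#' @param path output CSV path.
#' @export
write_survey <- function(matrix, path) {
  df <- as.data.frame(matrix$values)
  df$country <- matrix$country
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Flip reverse-coded items
#'
#' Flagged items are mapped x -> (min + max) - x on their declared scale;
#' missing cells stay missing. Applying the function twice is the identity.
#'
#' @param matrix a [survey_matrix()].
#' @param codebook optional codebook override (defaults to the attached one).
#' @return A [survey_matrix()] with flagged columns flipped.
#' @export
reverse_code <- function(matrix, codebook = matrix$codebook) {
  stopifnot(inherits(matrix, "survey_matrix"))
  for (j in which(codebook$reverse_coded)) {
    lo <- codebook$level_min[j]; hi <- codebook$level_max[j]
    matrix$values[, j] <- as.integer(lo + hi) - matrix$values[, j]
  }
  matrix
}

#' Minimum sample size for a partial-correlation network
#'
#' Applies the planning rule of at least `per_parameter` respondents per
#' estimated parameter (edge): `per_parameter * p(p-1)/2`.
#'
#' @param p_nodes number of network nodes (>= 2).
#' @param per_parameter respondents per parameter (default 3).
#' @return Required respondent count (integer).
#' @export
required_sample_size <- function(p_nodes, per_parameter = 3) {
  if (p_nodes < 2) stop("a network needs at least 2 nodes")
  as.integer(per_parameter * p_nodes * (p_nodes - 1) / 2)
}

#' Exclusion ledger arithmetic
#'
#' Partitions a screened respondent pool into per-rule exclusion counts and
#' the eligible remainder, with the conservation identity
#' `eligible = screened - sum(per_rule)` enforced.
#'
#' @param screened number of screened records.
#' @param per_rule named integer vector of exclusion counts per rule.
#' @return An `exclusion_ledger` list with `screened`, `per_rule`, `eligible`.
#' @export
exclusion_ledger <- function(screened, per_rule) {
  screened <- as.integer(screened)
  per_rule <- vapply(per_rule, as.integer, 1L)
  if (screened < 0 || any(per_rule < 0)) stop("ledger counts must be >= 0")
  eligible <- screened - sum(per_rule)
  if (eligible < 0) stop("exclusions exceed the screened count")
  structure(list(screened = screened, per_rule = per_rule,
                 eligible = eligible), class = "exclusion_ledger")
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat("screened:", x$screened, "\n")
  for (r in names(x$per_rule)) cat(sprintf("  - %s: %d\n", r, x$per_rule[[r]]))
  cat("eligible:", x$eligible, "\n")
  invisible(x)
}

.exclusion_rule_order <- c("blank_incomplete", "duplicate",
                           "inconsistent_validation",
                           "nonparticipating_country", "missing_age_gender")

#' Screen raw survey records through the exclusion rules
#'
#' Applies, in fixed order, the study's data-quality rules: blank/incomplete
#' responses, duplicates, failed validation questions, non-participating
#' countries, and records missing age or gender. A record failing several
#' rules is counted only under the first that matches, so the ledger
#' partitions the screened set.
#'
#' @param records data frame of raw records: codebook item columns plus any
#'   sociodemographic columns the rules reference. Empty strings count as
#'   missing.
#' @param codebook a [codebook()]; its items define completeness.
#' @param rules list with optional entries: `validation_column` and
#'   `validation_accepted` (accepted answers, matched after lowercasing and
#'   trimming), `countries` (participating-country whitelist),
#'   `country_column` (default `"country"`), `duplicate_key` (columns that
#'   define a duplicate; default all item columns), `age_column`,
#'   `gender_column`.
#' @return list with `matrix` (a [survey_matrix()] of eligible records, or
#'   `NULL` when none) and `ledger` (an [exclusion_ledger()]).
#' @export
apply_exclusions <- function(records, codebook, rules = list()) {
  n0 <- nrow(records)
  per_rule <- setNames(integer(length(.exclusion_rule_order)),
                       .exclusion_rule_order)
  is_blank <- function(col) {
    v <- records[[col]]
    is.na(v) | (is.character(v) & !nzchar(trimws(v)))
  }
  excluded <- rep(FALSE, n0)
  mark <- function(hit, rule) {
    hit <- hit & !excluded
    per_rule[[rule]] <<- sum(hit)
    excluded <<- excluded | hit
  }
  if (n0 > 0) {
    item_cols <- intersect(codebook$id, colnames(records))
    blank <- Reduce(`|`, lapply(item_cols, is_blank), rep(FALSE, n0))
    mark(blank, "blank_incomplete")

    key_cols <- if (is.null(rules$duplicate_key)) item_cols else rules$duplicate_key
    key <- do.call(paste, c(lapply(key_cols, function(c) records[[c]]),
                            sep = "\r"))
    mark(duplicated(key), "duplicate")

    if (!is.null(rules$validation_column)) {
      ans <- tolower(trimws(as.character(records[[rules$validation_column]])))
      ok <- ans %in% tolower(trimws(rules$validation_accepted))
      mark(!ok, "inconsistent_validation")
    }
    if (!is.null(rules$countries)) {
      cc <- rules$country_column %||% "country"
      mark(!(records[[cc]] %in% rules$countries), "nonparticipating_country")
    }
    agc <- rules$age_column %||% "age"
    gdc <- rules$gender_column %||% "gender"
    need <- intersect(c(agc, gdc), colnames(records))
    if (length(need))
      mark(Reduce(`|`, lapply(need, is_blank), rep(FALSE, n0)),
           "missing_age_gender")
  }
  ledger <- exclusion_ledger(n0, per_rule)
  eligible <- records[!excluded, , drop = FALSE]
  mat <- NULL
  if (nrow(eligible) > 0) {
    vals <- sapply(codebook$id, function(cid)
      as.integer(as.character(eligible[[cid]])))
    vals <- matrix(vals, nrow = nrow(eligible),
                   dimnames = list(NULL, codebook$id))
    mat <- survey_matrix(vals, codebook)
  }
  list(matrix = mat, ledger = ledger)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
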