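# Reading, validation and canonicalization of household-roster and
# individual-women files.
#
# Native dialect: UTF-8 CSV with a header. Roster schema:
#   household_key, line_number, rel_label, sex (F/M/empty), age, weight
# Individual schema:
#   household_key, line_number, age, marital_status, weight

#' Build a relationship-code map
#'
#' A code map translates raw "relationship to head" labels (e.g.
#' `"DAUGHTER-IN-LAW"`) to the canonical categories of
#' [rel_to_head_codes()]. Maps are matched case-insensitively after
#' whitespace trimming. The sentinel canonical value
#' `"parent_or_parent_in_law"` marks surveys whose labels merge parents and
#' parents-in-law; it is accepted here but always a FATAL finding in
#' [validate_code_map()] because mother-in-law detection is then impossible.
#'
#' @param entries Data frame with columns `raw_label` and `canonical`.
#' @param strict If `TRUE` (default), an input label missing from the map
#'   rejects the file; if `FALSE` unmapped rows are kept with `NA` code and
#'   counted in the load report.
#' @return A `mil_code_map` object.
#' @export
code_map <- function(entries, strict = TRUE) {
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("raw_label", "canonical") %in% names(entries)))
  entries$raw_label <- toupper(trimws(entries$raw_label))
  entries$canonical <- trimws(entries$canonical)
  bad <- setdiff(unique(entries$canonical),
                 c(rel_to_head_codes(), merged_parent_code()))
  if (length(bad) > 0) {
    stop("code map has non-canonical target(s): ", paste(bad, collapse = ", "))
  }
  structure(list(entries = entries, strict = isTRUE(strict)),
            class = "mil_code_map")
}

#' Read a code map from a CSV file
#'
#' @param path CSV with columns `raw_label`, `canonical`.
#' @inheritParams code_map
#' @return A `mil_code_map` object.
#' @export
read_code_map <- function(path, strict = TRUE) {
  m <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  code_map(m, strict = strict)
}

#' Default DHS hv101 label map
#'
#' Label map for the common wording of the DHS relationship-to-head variable
#' (hv101), shipped as `inst/extdata/hv101_default_map.csv`.
#'
#' @inheritParams code_map
#' @return A `mil_code_map` object.
#' @export
default_code_map <- function(strict = TRUE) {
  read_code_map(
    system.file("extdata", "hv101_default_map.csv",
                package = "milresidence", mustWork = TRUE),
    strict = strict
  )
}

# Identity map over canonical codes; used to re-read rosters written by
# write_roster().
canonical_code_map <- function(strict = TRUE) {
  code_map(
    tibble::tibble(raw_label = rel_to_head_codes(),
                   canonical = rel_to_head_codes()),
    strict = strict
  )
}

#' Validate a code map for mother-in-law analysis
#'
#' Checks that (a) no raw label is mapped to two different canonical codes
#' and (b) parents and parents-in-law are distinguishable: some label maps
#' to `parent`, some label maps to `parent_in_law`, and no label uses the
#' merged `parent_or_parent_in_law` sentinel. A survey failing (b) cannot
#' support mother-in-law detection and is marked ineligible, mirroring the
#' exclusion of surveys whose instruments pooled the two categories.
#'
#' @param map A `mil_code_map`.
#' @return A tibble of findings (columns `check`, `status`, `detail`) with
#'   attribute `status` equal to `"PASS"` or `"FATAL"`.
#' @export
validate_code_map <- function(map) {
  stopifnot(inherits(map, "mil_code_map"))
  e <- map$entries
  findings <- list()

  dup <- unique(e$raw_label[duplicated(e$raw_label)])
  conflicting <- dup[vapply(
    dup, function(l) length(unique(e$canonical[e$raw_label == l])) > 1, TRUE
  )]
  findings[[length(findings) + 1]] <- tibble::tibble(
    check = "duplicate_mapping",
    status = if (length(conflicting) > 0) "FATAL" else "PASS",
    detail = if (length(conflicting) > 0) {
      paste("conflicting targets for:", paste(conflicting, collapse = ", "))
    } else ""
  )

  merged <- any(e$canonical == merged_parent_code())
  has_parent <- any(e$canonical == "parent")
  has_pil <- any(e$canonical == "parent_in_law")
  findings[[length(findings) + 1]] <- tibble::tibble(
    check = "parent_vs_parent_in_law",
    status = if (merged || !has_parent || !has_pil) "FATAL" else "PASS",
    detail = if (merged) {
      "labels merge parent and parent-in-law; survey ineligible"
    } else if (!has_parent || !has_pil) {
      "map lacks a distinct parent or parent-in-law label; survey ineligible"
    } else ""
  )

  report <- dplyr::bind_rows(findings)
  attr(report, "status") <-
    if (any(report$status == "FATAL")) "FATAL" else "PASS"
  report
}

.apply_code_map <- function(raw_labels, map) {
  e <- map$entries
  lut <- stats::setNames(e$canonical, e$raw_label)
  unname(lut[toupper(trimws(raw_labels))])
}

.normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("f", "female", "2")] <- "female"
  out[s %in% c("m", "male", "1")] <- "male"
  out
}

#' Read and canonicalize a household roster
#'
#' Reads a roster CSV (one row per household member), translates raw
#' relationship labels through a code map, normalizes sex to
#' `"female"`/`"male"`/`NA`, and attaches a load report. Rows with missing
#' key fields (household key or line number) are dropped and counted as
#' malformed; a member with missing sex or age is kept (their dyads simply
#' cannot establish sex-dependent relations).
#'
#' @param path Roster CSV with columns `household_key`, `line_number`,
#'   `rel_label`, `sex`, `age`, `weight`.
#' @param map A `mil_code_map`; defaults to [default_code_map()].
#' @param dhs_weight_scale If `TRUE`, divide weights by 1,000,000 (the DHS
#'   storage convention for six-implied-decimal weights).
#' @return Tibble of members (`household_key`, `line_number`, `rel_to_head`,
#'   `sex`, `age_years`, `weight`) with attribute `load_report` (counts of
#'   `total`, `mapped`, `unmapped`, `malformed` rows).
#' @export
read_roster <- function(path, map = default_code_map(),
                        dhs_weight_scale = FALSE) {
  stopifnot(inherits(map, "mil_code_map"))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      household_key = "c", line_number = "i", rel_label = "c",
      sex = "c", age = "d", weight = "d"
    ),
    progress = FALSE
  )
  need <- c("household_key", "line_number", "rel_label", "sex", "age", "weight")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("roster file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  total <- nrow(raw)
  malformed <- is.na(raw$household_key) | is.na(raw$line_number) |
    (!is.na(raw$age) & raw$age < 0) | (!is.na(raw$weight) & raw$weight < 0)
  raw <- raw[!malformed, , drop = FALSE]

  key <- paste(raw$household_key, raw$line_number, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (household_key, line_number) in roster: ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  }

  code <- .apply_code_map(raw$rel_label, map)
  unmapped_labels <- unique(toupper(trimws(raw$rel_label[is.na(code)])))
  if (map$strict && length(unmapped_labels) > 0) {
    stop("unmapped relationship label(s): ",
         paste(unmapped_labels, collapse = ", "))
  }
  if (any(!is.na(code) & code == merged_parent_code())) {
    stop("code map merges parent and parent-in-law; ",
         "survey is ineligible for mother-in-law analysis")
  }

  members <- tibble::tibble(
    household_key = as.character(raw$household_key),
    line_number = as.integer(raw$line_number),
    rel_to_head = code,
    sex = .normalize_sex(raw$sex),
    age_years = as.integer(raw$age),
    weight = ifelse(is.na(raw$weight), 1, raw$weight) /
      if (dhs_weight_scale) 1e6 else 1
  )
  attr(members, "load_report") <- list(
    total = total,
    mapped = sum(!is.na(code)),
    unmapped = sum(is.na(code)),
    malformed = sum(malformed),
    unmapped_labels = unmapped_labels
  )
  members
}

#' Write a canonicalized roster
#'
#' Writes members back to the native CSV schema with canonical codes as
#' labels, so re-reading with the canonical identity map round-trips.
#'
#' @param members Roster tibble from [read_roster()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(members, path) {
  out <- tibble::tibble(
    household_key = members$household_key,
    line_number = members$line_number,
    rel_label = members$rel_to_head,
    sex = c(female = "F", male = "M")[members$sex],
    age = members$age_years,
    weight = members$weight
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Audit household headship
#'
#' The relationship matrix is anchored on the household head, so dyad
#' relations are undefined in households with zero or multiple heads; such
#' households are excluded from inference.
#'
#' @param members Roster tibble.
#' @return Tibble `household_key`, `n_members`, `n_heads`, `eligible`.
#' @export
validate_households <- function(members) {
  members |>
    dplyr::group_by(.data$household_key) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_heads = sum(!is.na(.data$rel_to_head) & .data$rel_to_head == "head"),
      .groups = "drop"
    ) |>
    dplyr::mutate(eligible = .data$n_heads == 1L)
}

#' Read an individual-women file
#'
#' Reads the interviewed-women file (one row per woman aged 15-49 eligible
#' for the individual questionnaire), keeps only women aged 15-49, and
#' parses marital status to a current-marriage flag. By default both
#' `married` and `living with partner`/`living together` count as currently
#' married, the usual pooling for DHS "currently in union" analyses.
#'
#' @param path CSV with columns `household_key`, `line_number`, `age`,
#'   `marital_status`, `weight`.
#' @param married_statuses Character vector of status labels (matched
#'   case-insensitively) treated as currently married.
#' @param dhs_weight_scale As in [read_roster()].
#' @return Tibble `household_key`, `line_number`, `age_years`,
#'   `currently_married`, `weight`, with attribute `load_report` recording
#'   rows read and rows dropped for age.
#' @export
read_individuals <- function(path,
                             married_statuses = c("married",
                                                  "living with partner",
                                                  "living together"),
                             dhs_weight_scale = FALSE) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      household_key = "c", line_number = "i", age = "d",
      marital_status = "c", weight = "d"
    ),
    progress = FALSE
  )
  need <- c("household_key", "line_number", "age", "marital_status", "weight")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("individual file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  total <- nrow(raw)
  in_range <- !is.na(raw$age) & raw$age >= 15 & raw$age <= 49
  raw <- raw[in_range, , drop = FALSE]
  women <- tibble::tibble(
    household_key = as.character(raw$household_key),
    line_number = as.integer(raw$line_number),
    age_years = as.integer(raw$age),
    currently_married =
      tolower(trimws(raw$marital_status)) %in% tolower(married_statuses),
    weight = ifelse(is.na(raw$weight), 1, raw$weight) /
      if (dhs_weight_scale) 1e6 else 1
  )
  attr(women, "load_report") <- list(
    total = total,
    retained = nrow(women),
    dropped_age = total - nrow(women)
  )
  women
}
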