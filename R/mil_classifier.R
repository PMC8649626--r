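# Flagging women who share a household with their mother-in-law.

#' Flag women living with their mother-in-law
#'
#' A woman lives with her mother-in-law when some dyad makes her the
#' son/daughter-in-law of another member (`relation == "child_in_law"`) and
#' that other member is female. Exactly four head-anchored patterns produce
#' this relation: a daughter-in-law of the head paired with the head or the
#' head's spouse, a female head paired with her parent-in-law, and the
#' head's wife paired with the head's parent. Relations that would qualify
#' except that the partner's sex is missing do not qualify (conservative:
#' the measure undercounts rather than overcounts). A woman with several
#' qualifying partners (e.g. in a polygynous household where each of the
#' head's wives is her mother-in-law's co-wife) still counts once.
#'
#' @param members Roster tibble.
#' @param dyads Optional precomputed dyads from [build_dyads()]; when `NULL`
#'   dyads are built internally with the index side restricted to women
#'   15-49 (the only dyads the rule inspects).
#' @return Tibble with one row per female roster member aged 15-49:
#'   `household_key`, `line_number`, `age_years`, `weight`,
#'   `lives_with_mil`, `mil_line` (line number of the identified
#'   mother-in-law, `NA` when none).
#' @export
classify_mil <- function(members, dyads = NULL) {
  women <- members |>
    dplyr::filter(!is.na(.data$sex), .data$sex == "female",
                  !is.na(.data$age_years),
                  .data$age_years >= 15, .data$age_years <= 49)
  if (is.null(dyads)) {
    dyads <- build_dyads(members, index_only = women)
  }
  hits <- dyads |>
    dplyr::filter(!is.na(.data$relation), .data$relation == "child_in_law",
                  !is.na(.data$other_sex), .data$other_sex == "female") |>
    dplyr::arrange(.data$other_line) |>
    dplyr::distinct(.data$household_key, .data$index_line,
                    .keep_all = TRUE) |>
    dplyr::select("household_key", "index_line", mil_line = "other_line")

  women |>
    dplyr::left_join(
      hits,
      by = c(household_key = "household_key", line_number = "index_line")
    ) |>
    dplyr::mutate(lives_with_mil = !is.na(.data$mil_line)) |>
    dplyr::select("household_key", "line_number", "age_years", "weight",
                  "lives_with_mil", "mil_line")
}

#' Merge roster flags onto the individual-women file
#'
#' Joins the interviewed-women file to the roster-derived co-residence
#' flags. Women without a matching female roster member (no (household,
#' line) match, or a roster member not recorded as female) are excluded and
#' counted in the `merge_report` attribute. The estimation set for
#' published rates is `currently_married == TRUE`; unmarried women are kept
#' with their flag but `estimation = FALSE`.
#'
#' @param individuals Tibble from [read_individuals()].
#' @param flags Tibble from [classify_mil()].
#' @return Tibble of eligible women: `household_key`, `line_number`,
#'   `age_years`, `age_group`, `currently_married`, `weight`,
#'   `lives_with_mil`, `mil_line`, `estimation`. Attribute `merge_report`
#'   holds counts of merged and unmerged women.
#' @export
attach_flags <- function(individuals, flags) {
  merged <- dplyr::inner_join(
    individuals,
    flags |>
      dplyr::select("household_key", "line_number", "lives_with_mil",
                    "mil_line"),
    by = c("household_key", "line_number")
  )
  unmatched <- nrow(individuals) - nrow(merged)
  out <- merged |>
    dplyr::mutate(
      age_group = age_group_of(.data$age_years),
      estimation = .data$currently_married
    ) |>
    dplyr::select("household_key", "line_number", "age_years", "age_group",
                  "currently_married", "weight", "lives_with_mil",
                  "mil_line", "estimation")
  attr(out, "merge_report") <- list(
    individuals = nrow(individuals),
    merged = nrow(merged),
    unmatched = unmatched
  )
  out
}

#' Export per-woman flags for audit
#'
#' @param women Tibble from [attach_flags()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flags <- function(women, path) {
  readr::write_csv(women, path, na = "", progress = FALSE)
  invisible(path)
}
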