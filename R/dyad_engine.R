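# Enumeration of ordered within-household dyads with inferred relations.

#' Build all ordered within-household dyads
#'
#' For every household with exactly one head, emits every ordered pair of
#' distinct members (n members give n*(n-1) dyads) together with the
#' relation of the index member to the other member from the relationship
#' matrix. Households with zero or multiple heads are excluded with a
#' message (head-anchored relations are undefined there); their exclusion
#' count is recorded in the `excluded_households` attribute.
#'
#' @param members Roster tibble from [read_roster()] (or the synthetic
#'   generator).
#' @param index_only Optional tibble/data frame with columns
#'   `household_key`, `line_number`: restrict the index side to these
#'   members (the partner side still ranges over the whole household).
#' @return Tibble with one row per ordered dyad: `household_key`,
#'   `index_line`, `other_line`, `index_rel`, `other_rel`, `relation`,
#'   `index_sex`, `other_sex`, `index_age`, `other_age`.
#' @export
build_dyads <- function(members, index_only = NULL) {
  hh <- validate_households(members)
  excluded <- hh$household_key[!hh$eligible]
  if (length(excluded) > 0) {
    message(length(excluded),
            " household(s) excluded from dyad construction ",
            "(zero or multiple heads)")
  }
  keep <- members[members$household_key %in% hh$household_key[hh$eligible], ,
                  drop = FALSE]

  index <- tibble::tibble(
    household_key = keep$household_key,
    index_line = keep$line_number,
    index_rel = keep$rel_to_head,
    index_sex = keep$sex,
    index_age = keep$age_years
  )
  if (!is.null(index_only)) {
    index <- dplyr::semi_join(
      index,
      tibble::tibble(household_key = index_only$household_key,
                     index_line = index_only$line_number),
      by = c("household_key", "index_line")
    )
  }
  other <- tibble::tibble(
    household_key = keep$household_key,
    other_line = keep$line_number,
    other_rel = keep$rel_to_head,
    other_sex = keep$sex,
    other_age = keep$age_years
  )

  dyads <- dplyr::inner_join(index, other, by = "household_key",
                             relationship = "many-to-many") |>
    dplyr::filter(.data$index_line != .data$other_line) |>
    dplyr::mutate(relation = rel_lookup(.data$index_rel, .data$other_rel)) |>
    dplyr::select("household_key", "index_line", "other_line",
                  "index_rel", "other_rel", "relation",
                  "index_sex", "other_sex", "index_age", "other_age")
  attr(dyads, "excluded_households") <- excluded
  dyads
}

#' Export dyads for audit
#'
#' @param dyads Tibble from [build_dyads()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dyads <- function(dyads, path) {
  readr::write_csv(dyads, path, na = "", progress = FALSE)
  invisible(path)
}
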