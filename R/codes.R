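# Canonical vocabularies shared across modules.

#' Canonical relationship-to-head categories
#'
#' The thirteen categories that raw "relationship to household head" labels
#' are cleaned into: head, wife_or_husband, son_or_daughter,
#' son_or_daughter_in_law, parent, parent_in_law, sibling, grandparent,
#' grandchild, adopted_child, other_relative, not_related, other.
#'
#' @return Character vector of the thirteen canonical codes.
#' @export
rel_to_head_codes <- function() {
  c(
    "head", "wife_or_husband", "son_or_daughter", "son_or_daughter_in_law",
    "parent", "parent_in_law", "sibling", "grandparent", "grandchild",
    "adopted_child", "other_relative", "not_related", "other"
  )
}

# Sentinel for code maps that cannot separate parents from parents-in-law;
# valid in a map file but always a FATAL finding at validation.
merged_parent_code <- function() "parent_or_parent_in_law"

#' Pairwise dyad relation vocabulary
#'
#' All relation codes a dyad can carry after one application of the
#' head-anchored relationship matrix, including the ambiguous compound codes
#' that sex-based disambiguation may later resolve.
#'
#' @return Character vector of the 27 dyad relation codes.
#' @export
dyad_relation_codes <- function() {
  c(
    "self", "spouse", "parent", "child", "parent_in_law", "child_in_law",
    "sibling", "sibling_in_law", "grandparent", "grandchild",
    "grandparent_in_law", "grandchild_in_law", "aunt_uncle", "niece_nephew",
    "aunt_uncle_in_law", "niece_nephew_in_law", "co_in_law",
    "great_grandparent", "great_grandchild", "great_aunt_uncle",
    "great_niece_nephew", "spouse_or_sibling_in_law", "parent_or_aunt_uncle",
    "sibling_or_cousin", "spouse_or_both_parents_in_law", "other_in_law",
    "other"
  )
}

#' Five-year age-group labels for women 15-49
#'
#' @return Character vector of the seven reproductive-age groups.
#' @export
age_group_levels <- function() {
  c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-49")
}

#' Assign ages to five-year age groups
#'
#' @param age_years Integer vector of ages in completed years.
#' @return Factor with levels [age_group_levels()]; `NA` outside 15-49.
#' @export
age_group_of <- function(age_years) {
  idx <- findInterval(age_years, seq(15, 50, by = 5))
  idx[is.na(age_years) | age_years < 15 | age_years > 49] <- NA_integer_
  factor(age_group_levels()[idx], levels = age_group_levels())
}
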