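# Head-anchored relationship matrix: the relation between two household
# members given each one's relation to the household head.

.matrix_cache <- new.env(parent = emptyenv())

#' The pairwise relationship matrix
#'
#' Returns the lookup grid giving, for every ordered pair of
#' relationship-to-head categories, the relation of the index member TO the
#' other member. The grid ships as a plain CSV
#' (`inst/extdata/relationship_matrix.csv`) so it can be audited or
#' overridden without code changes; the twelve printed categories are
#' extended with a `grandparent` row/column filled by converse where a
#' printed cell determines it and `other` elsewhere.
#'
#' @param path Optional path to an alternative matrix CSV with columns
#'   `index_code`, `other_code`, `relation`.
#' @return A tibble with one row per ordered pair (169 rows for the default
#'   matrix).
#' @export
relationship_matrix <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.matrix_cache$default)) {
      return(.matrix_cache$default)
    }
    path <- system.file("extdata", "relationship_matrix.csv",
      package = "milresidence", mustWork = TRUE
    )
    default <- TRUE
  } else {
    default <- FALSE
  }
  m <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  stopifnot(all(c("index_code", "other_code", "relation") %in% names(m)))
  bad <- setdiff(unique(m$relation), dyad_relation_codes())
  if (length(bad) > 0) {
    stop("relationship matrix contains unknown relation codes: ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(paste(m$index_code, m$other_code))) {
    stop("relationship matrix has duplicate (index_code, other_code) cells")
  }
  if (default) .matrix_cache$default <- m
  m
}

.rel_lookup_vector <- function(matrix = NULL) {
  if (is.null(matrix) && !is.null(.matrix_cache$lookup)) {
    return(.matrix_cache$lookup)
  }
  m <- if (is.null(matrix)) relationship_matrix() else matrix
  v <- stats::setNames(m$relation, paste(m$index_code, m$other_code, sep = "|"))
  if (is.null(matrix)) .matrix_cache$lookup <- v
  v
}

#' Look up the relation of one member to another
#'
#' Resolves each ordered pair of relationship-to-head codes to the relation
#' of the index member to the other member, e.g. `rel_lookup("head",
#' "son_or_daughter")` is `"parent"` and `rel_lookup("wife_or_husband",
#' "parent")` is `"child_in_law"` (the head's spouse is the
#' son/daughter-in-law of the head's parent).
#'
#' @param index_rel,other_rel Character vectors of canonical
#'   relationship-to-head codes (recycled to common length).
#' @param matrix Optional alternative matrix tibble from
#'   [relationship_matrix()].
#' @return Character vector of dyad relation codes; `NA` input gives `NA`.
#' @export
rel_lookup <- function(index_rel, other_rel, matrix = NULL) {
  n <- max(length(index_rel), length(other_rel))
  index_rel <- rep_len(index_rel, n)
  other_rel <- rep_len(other_rel, n)
  known <- rel_to_head_codes()
  bad <- setdiff(unique(c(index_rel, other_rel)), c(known, NA))
  if (length(bad) > 0) {
    stop("non-canonical relationship-to-head code(s): ",
         paste(bad, collapse = ", "))
  }
  out <- unname(.rel_lookup_vector(matrix)[paste(index_rel, other_rel, sep = "|")])
  out[is.na(index_rel) | is.na(other_rel)] <- NA_character_
  out
}

#' Converse relation table
#'
#' Maps each dyad relation to the relation seen from the other member's side
#' (parent <-> child, grandparent <-> grandchild, symmetric codes to
#' themselves). `parent_or_aunt_uncle` has no converse in the vocabulary and
#' maps to `NA`; the printed cells carrying it are listed in
#' [relationship_converse_exceptions()].
#'
#' @return Named character vector: names are relation codes, values their
#'   converses.
#' @export
relation_converse <- function() {
  c(
    self = "self", spouse = "spouse",
    parent = "child", child = "parent",
    parent_in_law = "child_in_law", child_in_law = "parent_in_law",
    sibling = "sibling", sibling_in_law = "sibling_in_law",
    grandparent = "grandchild", grandchild = "grandparent",
    grandparent_in_law = "grandchild_in_law",
    grandchild_in_law = "grandparent_in_law",
    aunt_uncle = "niece_nephew", niece_nephew = "aunt_uncle",
    aunt_uncle_in_law = "niece_nephew_in_law",
    niece_nephew_in_law = "aunt_uncle_in_law",
    co_in_law = "co_in_law",
    great_grandparent = "great_grandchild",
    great_grandchild = "great_grandparent",
    great_aunt_uncle = "great_niece_nephew",
    great_niece_nephew = "great_aunt_uncle",
    spouse_or_sibling_in_law = "spouse_or_sibling_in_law",
    parent_or_aunt_uncle = NA_character_,
    sibling_or_cousin = "sibling_or_cousin",
    spouse_or_both_parents_in_law = "spouse_or_both_parents_in_law",
    other_in_law = "other_in_law",
    other = "other"
  )
}

#' Printed cells exempt from the converse property
#'
#' The shipped matrix reproduces its published source exactly, including
#' three cell pairs that are not converse-consistent: the
#' (parent, grandchild) cell prints the great-grandchild relation in the
#' wrong direction, and the four "parent or aunt/uncle" cells use a compound
#' category whose converse (child or niece/nephew) is not part of the
#' vocabulary. These cells are kept as printed rather than silently patched.
#'
#' @return Tibble with columns `index_code`, `other_code`, `relation`.
#' @export
relationship_converse_exceptions <- function() {
  tibble::tribble(
    ~index_code, ~other_code, ~relation,
    "parent", "grandchild", "great_grandchild",
    "grandchild", "parent", "great_grandchild",
    "son_or_daughter", "grandchild", "parent_or_aunt_uncle",
    "grandchild", "son_or_daughter", "parent_or_aunt_uncle",
    "son_or_daughter_in_law", "grandchild", "parent_or_aunt_uncle",
    "grandchild", "son_or_daughter_in_law", "parent_or_aunt_uncle"
  )
}

#' Resolve ambiguous dyad relations using the members' sexes
#'
#' The only sex-resolvable compound in the matrix is
#' `spouse_or_sibling_in_law`: members of opposite sex are taken as spouses,
#' members of the same sex as siblings-in-law, and a missing sex leaves the
#' code unchanged. Unambiguous codes pass through untouched.
#'
#' @param rel Character vector of dyad relation codes.
#' @param index_sex,other_sex Character vectors, `"female"`/`"male"`/`NA`.
#' @return Character vector of (possibly resolved) relation codes.
#' @export
disambiguate_relation <- function(rel, index_sex, other_sex) {
  n <- max(length(rel), length(index_sex), length(other_sex))
  rel <- rep_len(rel, n)
  index_sex <- rep_len(index_sex, n)
  other_sex <- rep_len(other_sex, n)
  amb <- !is.na(rel) & rel == "spouse_or_sibling_in_law" &
    !is.na(index_sex) & !is.na(other_sex)
  rel[amb & index_sex != other_sex] <- "spouse"
  rel[amb & index_sex == other_sex] <- "sibling_in_law"
  rel
}
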