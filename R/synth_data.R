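# Synthetic DHS-like household generator with known ground truth.
#
# Each simulated household is built around one focal woman aged 15-49. Her
# marital status, true mother-in-law co-residence, and household structure
# are drawn first; the roster is then assembled from structural templates.
# All non-focal adults are aged 50+ so that the individual-women file
# contains exactly the focal women and the generator's target rates remain
# identifiable from the output.

.household_types <- function() {
  c("nuclear", "patrilocal_stem", "wife_perspective", "head_with_parent",
    "woman_head_with_parent_in_law", "multi_branch_undetectable")
}

.mil_capable_types <- function() {
  c("patrilocal_stem", "wife_perspective", "woman_head_with_parent_in_law",
    "multi_branch_undetectable")
}

#' Simulation configuration
#'
#' Defaults describe a plausible high-co-residence survey population: the
#' age-specific co-residence targets follow the steep downward age gradient
#' typical of pooled survey estimates (28.4% at 15-19 falling to 3.8% at
#' 45-49), marriage probabilities rise through the twenties, the age
#' distribution of women is skewed young, and multi-branch households whose
#' in-law links run through "other relative" codes (structurally
#' undetectable from head-anchored relations) are a small minority.
#'
#' @param n_households Number of households (one focal woman each).
#' @param seed Integer RNG seed; generation is deterministic given the seed
#'   and the configuration.
#' @param household_type_mix Named probabilities over the six structural
#'   types `nuclear`, `patrilocal_stem`, `wife_perspective`,
#'   `head_with_parent`, `woman_head_with_parent_in_law`,
#'   `multi_branch_undetectable`; must sum to 1. A married focal woman who
#'   truly lives with her mother-in-law is housed in a MIL-capable type
#'   (the mix restricted to the last four, renormalized); other women draw
#'   from the full mix, capable types then appearing without the
#'   mother-in-law member.
#' @param marriage_prob_by_age Probability a focal woman in each five-year
#'   age group is currently married.
#' @param mil_rate_by_age Probability that a married focal woman in each
#'   age group truly has her mother-in-law in the household (the
#'   ground-truth rate schedule).
#' @param age_group_probs Distribution of focal women over the seven age
#'   groups (uniform within group).
#' @param weight_model `"uniform"` (all household weights 1) or
#'   `"lognormal"` (mean-1 lognormal weights with `weight_sigma`).
#' @param weight_sigma Log-scale SD for lognormal weights.
#' @param head_male_prob Probability the head of a patrilocal stem
#'   household is male (the mother-in-law is then the head's wife rather
#'   than the head herself).
#' @return A validated `mil_sim_config` list.
#' @export
sim_config <- function(n_households = 5000,
                       seed = 1L,
                       household_type_mix = c(
                         nuclear = 0.50, patrilocal_stem = 0.22,
                         wife_perspective = 0.12, head_with_parent = 0.06,
                         woman_head_with_parent_in_law = 0.05,
                         multi_branch_undetectable = 0.05
                       ),
                       marriage_prob_by_age = c(0.18, 0.55, 0.78, 0.86,
                                                0.88, 0.87, 0.85),
                       mil_rate_by_age = c(0.284, 0.216, 0.155, 0.109,
                                           0.077, 0.054, 0.038),
                       age_group_probs = c(0.14, 0.18, 0.18, 0.16,
                                           0.13, 0.11, 0.10),
                       weight_model = c("uniform", "lognormal"),
                       weight_sigma = 0.3,
                       head_male_prob = 0.7) {
  weight_model <- match.arg(weight_model)
  stopifnot(
    n_households >= 1,
    length(marriage_prob_by_age) == 7,
    length(mil_rate_by_age) == 7,
    length(age_group_probs) == 7,
    all(marriage_prob_by_age >= 0 & marriage_prob_by_age <= 1),
    all(mil_rate_by_age >= 0 & mil_rate_by_age <= 1),
    all(age_group_probs >= 0), sum(age_group_probs) > 0,
    head_male_prob >= 0, head_male_prob <= 1
  )
  types <- .household_types()
  if (!all(names(household_type_mix) %in% types)) {
    stop("unknown household type(s): ",
         paste(setdiff(names(household_type_mix), types), collapse = ", "))
  }
  mix <- stats::setNames(numeric(length(types)), types)
  mix[names(household_type_mix)] <- household_type_mix
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    stop("household_type_mix must be nonnegative and sum to 1")
  }
  if (any(mil_rate_by_age > 0) && sum(mix[.mil_capable_types()]) == 0) {
    stop("infeasible configuration: positive mother-in-law rates but no ",
         "MIL-capable household type in the mix")
  }
  structure(list(
    n_households = as.integer(n_households),
    seed = as.integer(seed),
    household_type_mix = mix,
    marriage_prob_by_age = marriage_prob_by_age,
    mil_rate_by_age = mil_rate_by_age,
    age_group_probs = age_group_probs / sum(age_group_probs),
    weight_model = weight_model,
    weight_sigma = weight_sigma,
    head_male_prob = head_male_prob
  ), class = "mil_sim_config")
}

# Structural templates. Each member: rel code, sex, age spec (offset from
# the focal woman's age, or a fixed child age), focal/MIL markers.
.variant_templates <- function() {
  t <- function(rel, sex, off, fixed = FALSE, focal = FALSE, mil = FALSE) {
    list(rel = rel, sex = sex, off = off, fixed = fixed, focal = focal,
         mil = mil)
  }
  list(
    natal = list(
      t("head", "male", 38), t("wife_or_husband", "female", 35),
      t("son_or_daughter", "female", 0, focal = TRUE)
    ),
    nuclear = list(
      t("head", "male", 4),
      t("wife_or_husband", "female", 0, focal = TRUE),
      t("son_or_daughter", "male", 3, fixed = TRUE)
    ),
    head_with_parent = list(
      t("head", "female", 0, focal = TRUE),
      t("parent", "female", 35),
      t("son_or_daughter", "male", 6, fixed = TRUE)
    ),
    stem_male_head_mil = list(
      t("head", "male", 37),
      t("wife_or_husband", "female", 35, mil = TRUE),
      t("son_or_daughter", "male", 4),
      t("son_or_daughter_in_law", "female", 0, focal = TRUE)
    ),
    stem_female_head_mil = list(
      t("head", "female", 35, mil = TRUE),
      t("son_or_daughter", "male", 4),
      t("son_or_daughter_in_law", "female", 0, focal = TRUE)
    ),
    stem_no_mil = list(
      t("head", "male", 37),
      t("son_or_daughter", "male", 4),
      t("son_or_daughter_in_law", "female", 0, focal = TRUE)
    ),
    wife_mil = list(
      t("head", "male", 4),
      t("wife_or_husband", "female", 0, focal = TRUE),
      t("parent", "female", 35, mil = TRUE),
      t("son_or_daughter", "male", 2, fixed = TRUE)
    ),
    wife_no_mil = list(
      t("head", "male", 4),
      t("wife_or_husband", "female", 0, focal = TRUE),
      t("parent", "male", 35),
      t("son_or_daughter", "male", 2, fixed = TRUE)
    ),
    woman_head_mil = list(
      t("head", "female", 0, focal = TRUE),
      t("parent_in_law", "female", 35, mil = TRUE),
      t("son_or_daughter", "female", 4, fixed = TRUE)
    ),
    woman_head_no_mil = list(
      t("head", "female", 0, focal = TRUE),
      t("parent_in_law", "male", 35),
      t("son_or_daughter", "female", 4, fixed = TRUE)
    ),
    multi_branch_mil = list(
      t("head", "male", 37),
      t("other_relative", "male", 4),
      t("other_relative", "female", 0, focal = TRUE),
      t("other_relative", "female", 35, mil = TRUE)
    ),
    multi_branch_no_mil = list(
      t("head", "male", 37),
      t("other_relative", "male", 4),
      t("other_relative", "female", 0, focal = TRUE)
    )
  )
}

#' Simulate a DHS-like survey with known ground truth
#'
#' Draws each focal woman's age, marital status, true mother-in-law
#' co-residence, and household structure from the configuration, then
#' assembles the household roster, the individual-women file, and a
#' ground-truth table. Deterministic given `config$seed`; the caller's RNG
#' state is left untouched.
#'
#' @param config A `mil_sim_config` from [sim_config()].
#' @return List of class `mil_simulation`: `roster` (canonicalized member
#'   tibble, same shape as [read_roster()] output), `individuals` (same
#'   shape as [read_individuals()] input expects, as a tibble with raw
#'   `marital_status`), `truth` (one row per focal woman:
#'   `true_mil_in_household`, `detectable_via_head`, `mil_line`,
#'   `household_type`), and `config`.
#' @export
simulate_households <- function(config) {
  stopifnot(inherits(config, "mil_sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  n <- config$n_households
  g <- sample.int(7, n, replace = TRUE, prob = config$age_group_probs)
  age <- 10L + 5L * g + sample.int(5, n, replace = TRUE) - 1L
  married <- stats::runif(n) < config$marriage_prob_by_age[g]
  has_mil <- married & stats::runif(n) < config$mil_rate_by_age[g]

  mix <- config$household_type_mix
  capable <- .mil_capable_types()
  type <- rep("natal", n)
  idx_mil <- which(has_mil)
  if (length(idx_mil) > 0) {
    p <- mix[capable] / sum(mix[capable])
    type[idx_mil] <- sample(capable, length(idx_mil), replace = TRUE, prob = p)
  }
  idx_nomil <- which(married & !has_mil)
  if (length(idx_nomil) > 0) {
    type[idx_nomil] <- sample(names(mix), length(idx_nomil), replace = TRUE,
                              prob = mix)
  }

  stem_male <- stats::runif(n) < config$head_male_prob
  variant <- dplyr::case_when(
    type == "natal" ~ "natal",
    type == "nuclear" ~ "nuclear",
    type == "head_with_parent" ~ "head_with_parent",
    type == "patrilocal_stem" & has_mil & stem_male ~ "stem_male_head_mil",
    type == "patrilocal_stem" & has_mil ~ "stem_female_head_mil",
    type == "patrilocal_stem" ~ "stem_no_mil",
    type == "wife_perspective" & has_mil ~ "wife_mil",
    type == "wife_perspective" ~ "wife_no_mil",
    type == "woman_head_with_parent_in_law" & has_mil ~ "woman_head_mil",
    type == "woman_head_with_parent_in_law" ~ "woman_head_no_mil",
    type == "multi_branch_undetectable" & has_mil ~ "multi_branch_mil",
    type == "multi_branch_undetectable" ~ "multi_branch_no_mil"
  )

  weight <- switch(config$weight_model,
    uniform = rep(1, n),
    lognormal = stats::rlnorm(n, meanlog = -config$weight_sigma^2 / 2,
                              sdlog = config$weight_sigma)
  )
  hh_key <- sprintf("H%07d", seq_len(n))

  templates <- .variant_templates()
  blocks <- vector("list", length(templates))
  truth_blocks <- vector("list", length(templates))
  bi <- 0L
  for (v in names(templates)) {
    rows <- which(variant == v)
    if (length(rows) == 0) next
    tpl <- templates[[v]]
    k <- length(tpl)
    m <- length(rows)
    off <- vapply(tpl, `[[`, numeric(1), "off")
    fixed <- vapply(tpl, `[[`, logical(1), "fixed")
    base_age <- rep(age[rows], each = k)
    mem_age <- ifelse(rep(fixed, times = m), rep(off, times = m),
                      base_age + rep(off, times = m))
    bi <- bi + 1L
    blocks[[bi]] <- tibble::tibble(
      household_key = rep(hh_key[rows], each = k),
      line_number = rep(seq_len(k), times = m),
      rel_to_head = rep(vapply(tpl, `[[`, character(1), "rel"), times = m),
      sex = rep(vapply(tpl, `[[`, character(1), "sex"), times = m),
      age_years = as.integer(mem_age),
      weight = rep(weight[rows], each = k)
    )
    focal_line <- which(vapply(tpl, `[[`, logical(1), "focal"))
    mil_line <- which(vapply(tpl, `[[`, logical(1), "mil"))
    truth_blocks[[bi]] <- tibble::tibble(
      household_key = hh_key[rows],
      line_number = focal_line,
      age_years = age[rows],
      currently_married = married[rows],
      weight = weight[rows],
      household_type = type[rows],
      true_mil_in_household = has_mil[rows],
      detectable_via_head = has_mil[rows] &
        type[rows] != "multi_branch_undetectable",
      mil_line = if (length(mil_line) == 1) mil_line else NA_integer_
    )
  }
  roster <- dplyr::arrange(dplyr::bind_rows(blocks[seq_len(bi)]),
                           .data$household_key, .data$line_number)
  truth <- dplyr::arrange(dplyr::bind_rows(truth_blocks[seq_len(bi)]),
                          .data$household_key)
  individuals <- tibble::tibble(
    household_key = truth$household_key,
    line_number = truth$line_number,
    age_years = truth$age_years,
    currently_married = truth$currently_married,
    weight = truth$weight
  )
  structure(list(roster = roster, individuals = individuals, truth = truth,
                 config = config),
            class = "mil_simulation")
}

# Canonical code -> default DHS-style label, for file output.
.canonical_to_label <- c(
  head = "HEAD", wife_or_husband = "WIFE OR HUSBAND",
  son_or_daughter = "SON/DAUGHTER",
  son_or_daughter_in_law = "SON/DAUGHTER-IN-LAW",
  parent = "PARENT", parent_in_law = "PARENT-IN-LAW",
  sibling = "BROTHER/SISTER", grandparent = "GRANDPARENT",
  grandchild = "GRANDCHILD", adopted_child = "ADOPTED/FOSTER/STEPCHILD",
  other_relative = "OTHER RELATIVE", not_related = "NOT RELATED",
  other = "OTHER"
)

#' Write a simulation to survey-style CSV files
#'
#' Writes `roster.csv` (DHS-style uppercase relationship labels, readable
#' with [default_code_map()]), `individuals.csv`, and `truth.csv` into
#' `dir`. Output is byte-identical for identical seed and configuration.
#'
#' @param sim A `mil_simulation`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "mil_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    roster = file.path(dir, "roster.csv"),
    individuals = file.path(dir, "individuals.csv"),
    truth = file.path(dir, "truth.csv")
  )
  roster_out <- tibble::tibble(
    household_key = sim$roster$household_key,
    line_number = sim$roster$line_number,
    rel_label = unname(.canonical_to_label[sim$roster$rel_to_head]),
    sex = c(female = "F", male = "M")[sim$roster$sex],
    age = sim$roster$age_years,
    weight = sim$roster$weight
  )
  readr::write_csv(roster_out, paths["roster"], na = "", progress = FALSE)
  ind_out <- tibble::tibble(
    household_key = sim$individuals$household_key,
    line_number = sim$individuals$line_number,
    age = sim$individuals$age_years,
    marital_status = ifelse(sim$individuals$currently_married,
                            "married", "never married"),
    weight = sim$individuals$weight
  )
  readr::write_csv(ind_out, paths["individuals"], na = "", progress = FALSE)
  readr::write_csv(sim$truth, paths["truth"], na = "", progress = FALSE)
  invisible(paths)
}

#' Ground-truth and detectable age schedules
#'
#' Builds, from the generator's bookkeeping, the true co-residence age
#' schedule (every woman whose mother-in-law is genuinely in the household)
#' and the head-detectable schedule (only those whose link runs through the
#' four head-anchored patterns). The head-detectable schedule is what a
#' roster-based classifier can at best recover; groupwise it never exceeds
#' the true schedule.
#'
#' @param truth Ground-truth tibble from [simulate_households()].
#' @return List of two `mil_schedule`s: `true` and `detectable`.
#' @export
truth_rates <- function(truth) {
  married <- truth[truth$currently_married, , drop = FALSE]
  base <- tibble::tibble(
    age_years = married$age_years,
    age_group = age_group_of(married$age_years),
    weight = married$weight
  )
  list(
    true = estimate_schedule(
      dplyr::mutate(base, lives_with_mil = married$true_mil_in_household),
      survey_id = "ground truth"
    ),
    detectable = estimate_schedule(
      dplyr::mutate(base, lives_with_mil = married$detectable_via_head),
      survey_id = "head-detectable"
    )
  )
}
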