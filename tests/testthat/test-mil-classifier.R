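# The four head-anchored patterns that can establish a mother-in-law link,
# plus the structural negatives.

test_that("all four detectable patterns flag the woman", {
  # daughter-in-law of a female head
  h1 <- make_household("p1", c("head", "son_or_daughter",
                               "son_or_daughter_in_law"),
                       c("female", "male", "female"), c(60, 30, 27))
  # daughter-in-law with male head, MIL is head's wife
  h2 <- make_household("p2", c("head", "wife_or_husband", "son_or_daughter",
                               "son_or_daughter_in_law"),
                       c("male", "female", "male", "female"),
                       c(62, 58, 30, 26))
  # female head with her parent-in-law
  h3 <- make_household("p3", c("head", "parent_in_law"),
                       c("female", "female"), c(32, 66))
  # head's wife with the head's mother
  h4 <- make_household("p4", c("head", "wife_or_husband", "parent"),
                       c("male", "female", "female"), c(35, 31, 68))
  flags <- classify_mil(dplyr::bind_rows(h1, h2, h3, h4))
  flagged <- flags[flags$lives_with_mil, ]
  expect_setequal(flagged$household_key, c("p1", "p2", "p3", "p4"))
  expect_equal(flagged$mil_line[match(c("p1", "p2", "p3", "p4"),
                                      flagged$household_key)],
               c(1L, 2L, 2L, 3L))
})

test_that("a co-resident own mother is not a mother-in-law", {
  h <- make_household("n1", c("head", "wife_or_husband", "parent"),
                      c("female", "male", "female"), c(30, 33, 60))
  # female head's own mother: dyad relation is child, not child_in_law
  flags <- classify_mil(h)
  expect_false(flags$lives_with_mil[flags$line_number == 1])
})

test_that("other-relative branches cannot establish the link", {
  h <- make_household("n2",
    rel = c("head", "other_relative", "other_relative", "other_relative"),
    sex = c("male", "male", "female", "female"),
    age = c(70, 30, 27, 55)
  )
  flags <- classify_mil(h)
  expect_false(any(flags$lives_with_mil))
})

test_that("a qualifying partner with missing sex does not qualify", {
  h <- make_household("n3", c("head", "son_or_daughter",
                              "son_or_daughter_in_law"),
                      c(NA, "male", "female"), c(60, 30, 27))
  flags <- classify_mil(h)
  expect_false(flags$lives_with_mil[flags$line_number == 3])
})

test_that("several qualifying partners still count the woman once", {
  # polygynous household: each wife of the head qualifies
  h <- make_household("m1",
    rel = c("head", "wife_or_husband", "wife_or_husband", "son_or_daughter",
            "son_or_daughter_in_law"),
    sex = c("male", "female", "female", "male", "female"),
    age = c(65, 60, 55, 30, 25)
  )
  flags <- classify_mil(h)
  focal <- flags[flags$line_number == 5, ]
  expect_true(focal$lives_with_mil)
  expect_equal(nrow(focal), 1)
  expect_equal(focal$mil_line, 2L)
})

test_that("attach_flags filters the estimation set and counts mismatches", {
  h <- make_household("a1", c("head", "wife_or_husband",
                              "son_or_daughter", "son_or_daughter_in_law"),
                      c("male", "female", "male", "female"),
                      c(52, 48, 30, 26))
  flags <- classify_mil(h)
  individuals <- tibble::tibble(
    household_key = c("a1", "a1", "ghost"),
    line_number = c(4L, 2L, 1L),
    age_years = c(26L, 48L, 30L),
    currently_married = c(TRUE, FALSE, TRUE),
    weight = 1
  )
  women <- attach_flags(individuals, flags)
  expect_equal(nrow(women), 2)
  expect_equal(attr(women, "merge_report")$unmatched, 1)
  expect_equal(women$estimation, c(TRUE, FALSE))
  expect_equal(women$lives_with_mil[women$line_number == 4], TRUE)
  expect_equal(sum(women$estimation), 1)
})

test_that("flags match ground truth exactly on detectable-only populations", {
  cfg <- sim_config(
    n_households = 2000, seed = 31,
    household_type_mix = c(patrilocal_stem = 0.5, wife_perspective = 0.3,
                           woman_head_with_parent_in_law = 0.2)
  )
  sim <- simulate_households(cfg)
  flags <- classify_mil(sim$roster)
  joined <- dplyr::inner_join(sim$truth, flags,
                              by = c("household_key", "line_number"))
  expect_equal(nrow(joined), nrow(sim$truth))
  expect_equal(joined$lives_with_mil, joined$true_mil_in_household)
  # and the identified mother-in-law is the generator's
  expect_equal(joined$mil_line.y[joined$lives_with_mil],
               joined$mil_line.x[joined$lives_with_mil])
})

test_that("no false positives on mixed populations", {
  cfg <- sim_config(n_households = 3000, seed = 32)
  sim <- simulate_households(cfg)
  flags <- classify_mil(sim$roster)
  joined <- dplyr::inner_join(sim$truth, flags,
                              by = c("household_key", "line_number"))
  expect_true(all(joined$true_mil_in_household[joined$lives_with_mil]))
  # flags equal the detectable subset exactly
  expect_equal(joined$lives_with_mil, joined$detectable_via_head)
})
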