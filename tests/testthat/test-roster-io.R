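roster_df <- function(...) {
  tibble::tibble(...)
}

test_that("raw labels canonicalize through the code map", {
  path <- write_temp_csv(roster_df(
    household_key = c("h1", "h1", "h1"),
    line_number = 1:3,
    rel_label = c("HEAD", "Wife or husband", "DAUGHTER-IN-LAW"),
    sex = c("M", "F", "F"),
    age = c(60, 55, 24),
    weight = 1
  ))
  r <- read_roster(path)
  expect_equal(r$rel_to_head,
               c("head", "wife_or_husband", "son_or_daughter_in_law"))
  expect_equal(r$sex, c("male", "female", "female"))
  rep <- attr(r, "load_report")
  expect_equal(rep$mapped, 3)
  expect_equal(rep$unmapped + rep$malformed, 0)
})

test_that("strict mode rejects files naming the unmapped label", {
  path <- write_temp_csv(roster_df(
    household_key = "h1", line_number = 1L,
    rel_label = "ZZZ-UNKNOWN", sex = "M", age = 40, weight = 1
  ))
  expect_error(read_roster(path), "ZZZ-UNKNOWN")
  lax <- read_roster(path, default_code_map(strict = FALSE))
  expect_true(is.na(lax$rel_to_head))
  expect_equal(attr(lax, "load_report")$unmapped, 1)
})

test_that("load report partitions every input row", {
  path <- write_temp_csv(roster_df(
    household_key = c("h1", "h1", NA, "h2"),
    line_number = c(1L, 2L, 3L, 1L),
    rel_label = c("HEAD", "MYSTERY", "HEAD", "HEAD"),
    sex = "M", age = 30, weight = 1
  ))
  r <- read_roster(path, default_code_map(strict = FALSE))
  rep <- attr(r, "load_report")
  expect_equal(rep$total, 4)
  expect_equal(rep$mapped + rep$unmapped + rep$malformed, rep$total)
  expect_equal(rep$malformed, 1)
})

test_that("empty file yields empty collection with zero-count report", {
  path <- write_temp_csv(roster_df(
    household_key = character(), line_number = integer(),
    rel_label = character(), sex = character(),
    age = numeric(), weight = numeric()
  ))
  r <- read_roster(path)
  expect_equal(nrow(r), 0)
  expect_equal(attr(r, "load_report")$total, 0)
})

test_that("duplicate (household, line) pairs are rejected", {
  path <- write_temp_csv(roster_df(
    household_key = c("h1", "h1"), line_number = c(1L, 1L),
    rel_label = "HEAD", sex = "M", age = 40, weight = 1
  ))
  expect_error(read_roster(path), "duplicate")
})

test_that("canonicalized rosters round-trip through write/read", {
  members <- make_household("h9",
    rel = c("head", "wife_or_husband", "son_or_daughter_in_law", "grandchild"),
    sex = c("male", "female", "female", NA),
    age = c(61, 58, 26, 3)
  )
  dir <- withr::local_tempdir()
  path <- file.path(dir, "roster.csv")
  write_roster(members, path)
  back <- read_roster(path, milresidence:::canonical_code_map())
  attr(back, "load_report") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(members))
})

test_that("DHS weight scaling divides by one million", {
  path <- write_temp_csv(roster_df(
    household_key = "h1", line_number = 1L, rel_label = "HEAD",
    sex = "M", age = 40, weight = 1250000
  ))
  expect_equal(read_roster(path, dhs_weight_scale = TRUE)$weight, 1.25)
})

test_that("code-map validation flags merged parent categories as FATAL", {
  merged <- code_map(tibble::tibble(
    raw_label = c("HEAD", "PARENT/PARENT-IN-LAW"),
    canonical = c("head", "parent_or_parent_in_law")
  ))
  rep <- validate_code_map(merged)
  expect_equal(attr(rep, "status"), "FATAL")
  expect_true(any(rep$check == "parent_vs_parent_in_law" &
                    rep$status == "FATAL"))

  ok <- validate_code_map(default_code_map())
  expect_equal(attr(ok, "status"), "PASS")

  dup <- code_map(tibble::tibble(
    raw_label = c("PARENT", "PARENT", "MOTHER-IN-LAW"),
    canonical = c("parent", "parent_in_law", "parent_in_law")
  ))
  rep_dup <- validate_code_map(dup)
  expect_true(any(rep_dup$check == "duplicate_mapping" &
                    rep_dup$status == "FATAL"))
})

test_that("individual file keeps only women 15-49 and parses marriage", {
  path <- write_temp_csv(tibble::tibble(
    household_key = c("h1", "h1", "h2", "h3"),
    line_number = c(2L, 3L, 2L, 2L),
    age = c(50, 15, 30, 14),
    marital_status = c("married", "married", "never married",
                       "living with partner"),
    weight = 1
  ))
  w <- read_individuals(path)
  expect_equal(nrow(w), 2)
  expect_equal(w$age_years, c(15L, 30L))
  expect_equal(w$currently_married, c(TRUE, FALSE))
  expect_equal(attr(w, "load_report")$dropped_age, 2)
})

test_that("households without a unique head are flagged ineligible", {
  members <- dplyr::bind_rows(
    make_household("ok", c("head", "wife_or_husband"),
                   c("male", "female"), c(40, 38)),
    make_household("nohead", c("sibling", "sibling"),
                   c("male", "female"), c(30, 28)),
    make_household("twohead", c("head", "head"),
                   c("male", "female"), c(50, 48))
  )
  hh <- validate_households(members)
  expect_equal(hh$eligible[match(c("ok", "nohead", "twohead"),
                                 hh$household_key)],
               c(TRUE, FALSE, FALSE))
})
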