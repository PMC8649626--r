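test_that("identical seed and config give byte-identical output files", {
  cfg <- sim_config(n_households = 200, seed = 77,
                    weight_model = "lognormal")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_simulation(simulate_households(cfg), d1)
  p2 <- write_simulation(simulate_households(cfg), d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_households(sim_config(n_households = 50, seed = 99)))
  expect_identical(runif(1), before)
})

test_that("generated rosters pass validation and headship audit", {
  sim <- simulate_households(sim_config(n_households = 400, seed = 3))
  hh <- validate_households(sim$roster)
  expect_true(all(hh$eligible))
  expect_true(all(sim$roster$rel_to_head %in% rel_to_head_codes()))
  key <- paste(sim$roster$household_key, sim$roster$line_number)
  expect_equal(anyDuplicated(key), 0)
  # written roster re-reads through the default label map
  paths <- write_simulation(sim, withr::local_tempdir())
  back <- read_roster(paths["roster"])
  expect_equal(attr(back, "load_report")$unmapped, 0)
  expect_equal(back$rel_to_head, sim$roster$rel_to_head)
})

test_that("nuclear-only populations have zero co-residence throughout", {
  cfg <- sim_config(
    n_households = 500, seed = 21,
    household_type_mix = c(nuclear = 1),
    mil_rate_by_age = rep(0, 7)
  )
  sim <- simulate_households(cfg)
  expect_false(any(sim$truth$true_mil_in_household))
  women <- attach_flags(
    dplyr::mutate(sim$individuals,
                  marital_status = ifelse(currently_married, "married",
                                          "never married")) |>
      dplyr::select(household_key, line_number, age_years,
                    currently_married, weight),
    classify_mil(sim$roster)
  )
  expect_equal(estimate_schedule(women)$overall$P, 0)
})

test_that("all-detectable saturated population estimates exactly 1", {
  cfg <- sim_config(
    n_households = 400, seed = 22,
    household_type_mix = c(patrilocal_stem = 1),
    mil_rate_by_age = rep(1, 7)
  )
  sim <- simulate_households(cfg)
  flags <- classify_mil(sim$roster)
  married <- sim$truth[sim$truth$currently_married, ]
  joined <- dplyr::inner_join(married, flags,
                              by = c("household_key", "line_number"))
  women <- tibble::tibble(
    age_years = joined$age_years.x,
    age_group = age_group_of(joined$age_years.x),
    weight = joined$weight.x,
    lives_with_mil = joined$lives_with_mil
  )
  expect_equal(estimate_schedule(women)$overall$P, 1.0)
})

test_that("half-undetectable mix halves the estimable rate", {
  cfg <- sim_config(
    n_households = 12000, seed = 23,
    household_type_mix = c(patrilocal_stem = 0.5,
                           multi_branch_undetectable = 0.5),
    mil_rate_by_age = rep(0.4, 7)
  )
  sim <- simulate_households(cfg)
  tr <- truth_rates(sim$truth)
  expect_equal(tr$true$overall$P, 0.4, tolerance = 0.05)
  expect_equal(tr$detectable$overall$P, 0.2, tolerance = 0.075)
  flags <- classify_mil(sim$roster)
  joined <- dplyr::inner_join(sim$truth, flags,
                              by = c("household_key", "line_number"))
  expect_equal(joined$lives_with_mil, joined$detectable_via_head)
})

test_that("infeasible configurations are rejected", {
  expect_error(
    sim_config(household_type_mix = c(nuclear = 1),
               mil_rate_by_age = rep(0.2, 7)),
    "infeasible"
  )
  expect_error(sim_config(household_type_mix = c(nuclear = 0.6)), "sum to 1")
  expect_error(sim_config(mil_rate_by_age = rep(1.5, 7)))
})

test_that("truth schedules: detectable never exceeds true, groupwise", {
  sim <- simulate_households(sim_config(n_households = 4000, seed = 24))
  tr <- truth_rates(sim$truth)
  ok <- !is.na(tr$true$by_age$rate)
  expect_true(all(tr$detectable$by_age$rate[ok] <= tr$true$by_age$rate[ok]))
  expect_equal(tr$true$by_age$composition, tr$detectable$by_age$composition)

  det <- simulate_households(sim_config(
    n_households = 1000, seed = 25,
    household_type_mix = c(patrilocal_stem = 0.6, wife_perspective = 0.4)
  ))
  trd <- truth_rates(det$truth)
  expect_equal(trd$true$by_age$rate, trd$detectable$by_age$rate)
})

test_that("lognormal weights average one and feed through estimation", {
  cfg <- sim_config(n_households = 4000, seed = 26,
                    weight_model = "lognormal", weight_sigma = 0.5)
  sim <- simulate_households(cfg)
  expect_equal(mean(sim$truth$weight), 1, tolerance = 0.05)
  expect_lt(estimate_schedule(
    dplyr::mutate(sim$truth[sim$truth$currently_married, ],
                  age_group = age_group_of(age_years),
                  lives_with_mil = true_mil_in_household)
  )$overall$n_eff, sum(sim$truth$currently_married))
})
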