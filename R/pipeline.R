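# End-to-end pipeline wiring: simulate -> estimate -> compare -> decompose,
# with a machine-readable manifest of every exclusion applied.

#' Estimate a survey from roster and individual files
#'
#' Full inference chain for one survey: read and canonicalize the roster,
#' validate the code map (a survey whose labels cannot separate parents
#' from parents-in-law is rejected), audit headship, build dyads, flag
#' mother-in-law co-residence, merge the individual-women file, and
#' estimate the weighted age schedule. Counts at every filter stage are
#' collected in a manifest.
#'
#' @param roster_path,individuals_path Input CSV paths.
#' @param map A `mil_code_map` (default [default_code_map()]).
#' @param survey_id Identifier for the survey.
#' @param dhs_weight_scale Divide weights by 1e6 on load.
#' @return List: `schedule` (a `mil_schedule`), `women` (per-woman flags),
#'   `manifest` (named list of stage counts).
#' @export
estimate_survey <- function(roster_path, individuals_path,
                            map = default_code_map(),
                            survey_id = "survey",
                            dhs_weight_scale = FALSE) {
  map_report <- validate_code_map(map)
  if (attr(map_report, "status") == "FATAL") {
    stop("code map validation FATAL; survey excluded: ",
         paste(map_report$detail[map_report$status == "FATAL"],
               collapse = "; "))
  }
  roster <- read_roster(roster_path, map, dhs_weight_scale = dhs_weight_scale)
  load_report <- attr(roster, "load_report")
  hh <- validate_households(roster)
  dyads <- build_dyads(
    roster,
    index_only = roster[!is.na(roster$sex) & roster$sex == "female" &
                          !is.na(roster$age_years) &
                          roster$age_years >= 15 & roster$age_years <= 49, ]
  )
  flags <- classify_mil(roster, dyads = dyads)
  individuals <- read_individuals(individuals_path,
                                  dhs_weight_scale = dhs_weight_scale)
  women <- attach_flags(individuals, flags)
  merge_report <- attr(women, "merge_report")
  schedule <- estimate_schedule(women, survey_id = survey_id)

  manifest <- list(
    survey_id = survey_id,
    roster_path = roster_path,
    individuals_path = individuals_path,
    roster_rows = load_report$total,
    roster_mapped = load_report$mapped,
    roster_unmapped = load_report$unmapped,
    roster_malformed = load_report$malformed,
    households = nrow(hh),
    households_excluded_headship = sum(!hh$eligible),
    dyads = nrow(dyads),
    women_individual_file = merge_report$individuals,
    women_merged = merge_report$merged,
    women_unmatched = merge_report$unmatched,
    women_married = sum(women$estimation),
    overall_P = schedule$overall$P
  )
  list(schedule = schedule, women = women, manifest = manifest)
}

#' Run one pipeline subcommand
#'
#' Programmatic equivalent of the command-line tool
#' (`inst/cli/milresidence.R`). Subcommands:
#' \describe{
#'   \item{simulate}{generate roster/individuals/truth CSVs from a
#'     [sim_config()].}
#'   \item{estimate}{run [estimate_survey()] and write the schedule CSV.}
#'   \item{compare}{read two schedule CSVs and test the change in the
#'     overall proportion.}
#'   \item{decompose}{read two schedule CSVs and write the decomposition
#'     table CSV.}
#' }
#' Every run writes a JSON manifest (`<out>.manifest.json`) recording
#' inputs, seed, filter-stage counts, and outputs.
#'
#' @param subcommand One of `"simulate"`, `"estimate"`, `"compare"`,
#'   `"decompose"`.
#' @param ... Subcommand arguments: `simulate(config, out_dir)`;
#'   `estimate(roster_path, individuals_path, out_path, map, survey_id,
#'   dhs_weight_scale)`; `compare(schedule1_path, schedule2_path, alpha)`;
#'   `decompose(schedule1_path, schedule2_path, out_path)`.
#' @return The subcommand's manifest (named list), invisibly for
#'   `simulate`/`estimate`/`decompose`, visibly for `compare`.
#' @export
run_pipeline <- function(subcommand = c("simulate", "estimate", "compare",
                                        "decompose"), ...) {
  subcommand <- match.arg(subcommand)
  args <- list(...)
  manifest <- switch(subcommand,
    simulate = {
      config <- args$config
      sim <- simulate_households(config)
      paths <- write_simulation(sim, args$out_dir)
      list(
        subcommand = "simulate", seed = config$seed,
        n_households = config$n_households,
        roster_rows = nrow(sim$roster),
        focal_women = nrow(sim$truth),
        outputs = as.list(paths)
      )
    },
    estimate = {
      res <- estimate_survey(
        args$roster_path, args$individuals_path,
        map = args$map %||% default_code_map(),
        survey_id = args$survey_id %||% "survey",
        dhs_weight_scale = isTRUE(args$dhs_weight_scale)
      )
      write_schedule(res$schedule, args$out_path)
      c(list(subcommand = "estimate"), res$manifest,
        list(outputs = list(schedule = args$out_path)))
    },
    compare = {
      s1 <- read_schedule(args$schedule1_path)
      s2 <- read_schedule(args$schedule2_path)
      cmp <- compare_surveys(s1, s2, alpha = args$alpha %||% 0.05)
      c(list(subcommand = "compare",
             schedule1 = args$schedule1_path,
             schedule2 = args$schedule2_path), cmp)
    },
    decompose = {
      s1 <- read_schedule(args$schedule1_path)
      s2 <- read_schedule(args$schedule2_path)
      dec <- decompose_change(s1, s2)
      readr::write_csv(decompose_report(dec), args$out_path,
                       progress = FALSE)
      list(
        subcommand = "decompose",
        schedule1 = args$schedule1_path,
        schedule2 = args$schedule2_path,
        total_change = dec$total_change,
        comp_total = dec$comp_total,
        rate_total = dec$rate_total,
        outputs = list(table = args$out_path)
      )
    }
  )
  manifest_path <- args$manifest_path
  if (!is.null(manifest_path)) {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  if (subcommand == "compare") manifest else invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
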