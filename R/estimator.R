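# Survey-weighted co-residence proportions by five-year age group.

new_mil_schedule <- function(survey_id, by_age, overall) {
  structure(list(survey_id = survey_id, by_age = by_age, overall = overall),
            class = "mil_schedule")
}

#' Construct an age schedule from vectors
#'
#' Low-level constructor for an age schedule (the per-age-group composition
#' and rate vectors of one survey), e.g. when reading published schedules
#' rather than estimating from microdata.
#'
#' @param composition Numeric vector over [age_group_levels()], summing
#'   to 1: the share of married women 15-49 in each group.
#' @param rate Numeric vector of per-group co-residence proportions in
#'   `[0, 1]`; `NA` marks an empty group (its composition must be 0).
#' @param survey_id Identifier for the survey.
#' @param n_eff Optional per-group effective sample sizes.
#' @return A `mil_schedule` object.
#' @export
as_mil_schedule <- function(composition, rate, survey_id = "survey",
                            n_eff = NULL) {
  groups <- age_group_levels()
  stopifnot(length(composition) == length(groups),
            length(rate) == length(groups))
  if (abs(sum(composition) - 1) > 1e-8) {
    stop("composition shares must sum to 1")
  }
  if (any(is.na(rate) & composition > 0)) {
    stop("rate may be NA only for groups with zero composition")
  }
  by_age <- tibble::tibble(
    age_group = groups,
    n_women = NA_integer_,
    n_eff = if (is.null(n_eff)) NA_real_ else n_eff,
    composition = as.numeric(composition),
    rate = as.numeric(rate)
  )
  P <- sum(by_age$composition * by_age$rate, na.rm = TRUE)
  new_mil_schedule(survey_id, by_age, list(
    P = P,
    n_women = NA_integer_,
    n_eff = if (is.null(n_eff)) NA_real_ else sum(n_eff)
  ))
}

#' Estimate the co-residence age schedule of one survey
#'
#' Computes, over currently married women 15-49, the weighted proportion
#' living with their mother-in-law overall and by five-year age group,
#' together with the weighted age composition. Effective sample sizes use
#' the Kish approximation `(sum w)^2 / sum w^2`, the standard calibration
#' for weighted proportions when no cluster/stratum design metadata is
#' available. All quantities are invariant to rescaling the weights.
#'
#' @param women Tibble from [attach_flags()] (or the generator's truth
#'   bookkeeping); rows with `estimation == FALSE` or missing flags are
#'   dropped. All retained women must be currently married with nonnegative
#'   weights that are not all zero.
#' @param survey_id Identifier carried into the result.
#' @return A `mil_schedule`: `by_age` tibble (`age_group`, `n_women`,
#'   `n_eff`, `composition`, `rate`; rate is `NA` for empty groups) and
#'   `overall` list (`P`, `n_women`, `n_eff`). By construction
#'   `P == sum(composition * rate)` over nonempty groups.
#' @export
estimate_schedule <- function(women, survey_id = "survey") {
  if ("estimation" %in% names(women)) {
    women <- women[women$estimation %in% TRUE, , drop = FALSE]
  }
  if (!"age_group" %in% names(women)) {
    women$age_group <- age_group_of(women$age_years)
  }
  if (nrow(women) == 0 || sum(women$weight) <= 0) {
    stop("no married women with positive weight to estimate from")
  }
  if (any(women$weight < 0)) stop("negative sampling weights")

  total_w <- sum(women$weight)
  by_age <- women |>
    dplyr::group_by(age_group = factor(.data$age_group,
                                       levels = age_group_levels())) |>
    dplyr::summarise(
      n_women = dplyr::n(),
      sum_w = sum(.data$weight),
      sum_w2 = sum(.data$weight^2),
      flagged_w = sum(.data$weight[.data$lives_with_mil]),
      .groups = "drop"
    ) |>
    tidyr::complete(age_group = factor(age_group_levels(),
                                       levels = age_group_levels()),
                    fill = list(n_women = 0L, sum_w = 0, sum_w2 = 0,
                                flagged_w = 0)) |>
    dplyr::mutate(
      age_group = as.character(.data$age_group),
      n_eff = ifelse(.data$sum_w2 > 0, .data$sum_w^2 / .data$sum_w2, 0),
      composition = .data$sum_w / total_w,
      rate = ifelse(.data$sum_w > 0, .data$flagged_w / .data$sum_w, NA_real_)
    ) |>
    dplyr::select("age_group", "n_women", "n_eff", "composition", "rate")

  overall <- list(
    P = sum(women$weight[women$lives_with_mil]) / total_w,
    n_women = nrow(women),
    n_eff = total_w^2 / sum(women$weight^2)
  )
  new_mil_schedule(survey_id, by_age, overall)
}

#' @export
print.mil_schedule <- function(x, ...) {
  cat("Mother-in-law co-residence schedule:", x$survey_id, "\n")
  cat(sprintf("  overall: %.1f%% of %s married women (n_eff %.0f)\n",
              100 * x$overall$P,
              format(x$overall$n_women, big.mark = ","),
              x$overall$n_eff))
  df <- x$by_age
  df$rate_pct <- ifelse(is.na(df$rate), NA, round(100 * df$rate, 1))
  df$composition <- round(df$composition, 4)
  print(as.data.frame(df[, c("age_group", "n_women", "n_eff",
                             "composition", "rate_pct")]),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write / read a schedule as tidy CSV
#'
#' The on-disk form is one row per age group with the overall proportion
#' repeated in `overall_P`, so a schedule file is self-contained.
#'
#' @param schedule A `mil_schedule`.
#' @param path CSV path.
#' @return `path` (write) or a `mil_schedule` (read).
#' @export
write_schedule <- function(schedule, path) {
  out <- schedule$by_age
  out$survey_id <- schedule$survey_id
  out$overall_P <- schedule$overall$P
  out$overall_n_eff <- schedule$overall$n_eff
  out$overall_n_women <- schedule$overall$n_women
  readr::write_csv(out[, c("survey_id", "age_group", "n_women", "n_eff",
                           "composition", "rate", "overall_P",
                           "overall_n_eff", "overall_n_women")],
                   path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    survey_id = "c", age_group = "c", n_women = "i", n_eff = "d",
    composition = "d", rate = "d", overall_P = "d", overall_n_eff = "d",
    overall_n_women = "i"
  ), progress = FALSE)
  df <- df[match(age_group_levels(), df$age_group), , drop = FALSE]
  new_mil_schedule(
    df$survey_id[1],
    tibble::as_tibble(df[, c("age_group", "n_women", "n_eff", "composition",
                             "rate")]),
    list(P = df$overall_P[1], n_women = df$overall_n_women[1],
         n_eff = df$overall_n_eff[1])
  )
}

#' Compare overall proportions between two surveys
#'
#' Tests whether the overall co-residence proportion changed between two
#' surveys with a design-naive two-sample z-test on weighted proportions,
#' using Kish effective sample sizes in place of raw counts (pooled-variance
#' form, equivalent to a chi-squared test without continuity correction).
#' Cluster-robust variance is deliberately out of scope; with large
#' effective samples the naive test is the reproducible baseline.
#'
#' @param s1,s2 `mil_schedule` objects with effective sample sizes.
#' @param alpha Two-sided significance level for the trend classification.
#' @return List: `difference` (P2 - P1, proportion scale),
#'   `difference_pp` (percentage points), `z`, `p_value`, `classification`
#'   in `{"increase", "decrease", "no change"}`, `degenerate` (`TRUE` when
#'   both proportions are 0 or both 1, where the test is undefined and "no
#'   change" with p = 1 is reported).
#' @export
compare_surveys <- function(s1, s2, alpha = 0.05) {
  stopifnot(inherits(s1, "mil_schedule"), inherits(s2, "mil_schedule"))
  p1 <- s1$overall$P; n1 <- s1$overall$n_eff
  p2 <- s2$overall$P; n2 <- s2$overall$n_eff
  if (is.na(n1) || is.na(n2)) stop("both schedules need effective sample sizes")
  pooled <- (p1 * n1 + p2 * n2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  degenerate <- !is.finite(se) || se == 0
  if (degenerate) {
    z <- 0
    p_value <- 1
  } else {
    z <- (p2 - p1) / se
    p_value <- 2 * stats::pnorm(-abs(z))
  }
  classification <- if (!degenerate && p_value < alpha) {
    if (p2 > p1) "increase" else "decrease"
  } else {
    "no change"
  }
  list(
    difference = p2 - p1,
    difference_pp = 100 * (p2 - p1),
    z = z,
    p_value = p_value,
    classification = classification,
    alpha = alpha,
    degenerate = degenerate
  )
}
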