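# Shared fixture builders and independent oracles.

# Compact roster constructor: one household from parallel vectors.
make_household <- function(key, rel, sex, age, weight = 1) {
  tibble::tibble(
    household_key = key,
    line_number = seq_along(rel),
    rel_to_head = rel,
    sex = sex,
    age_years = as.integer(age),
    weight = weight
  )
}

# Random roster of n_households small households with a guaranteed single
# head per household and otherwise arbitrary canonical codes.
random_roster <- function(n_households, max_size = 8) {
  codes <- setdiff(rel_to_head_codes(), "head")
  sizes <- sample.int(max_size, n_households, replace = TRUE)
  total <- sum(sizes)
  hh <- rep(sprintf("R%05d", seq_len(n_households)), times = sizes)
  line <- sequence(sizes)
  rel <- sample(codes, total, replace = TRUE)
  rel[line == 1] <- "head"
  tibble::tibble(
    household_key = hh,
    line_number = line,
    rel_to_head = rel,
    sex = sample(c("female", "male"), total, replace = TRUE),
    age_years = sample.int(90, total, replace = TRUE) - 1L,
    weight = 1
  )
}

# Independent dyad oracle: explicit double loop over the members of each
# household (no joins; one rel_lookup call per ordered pair).
oracle_dyads <- function(members) {
  parts <- split(members, members$household_key)
  out <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    h <- parts[[k]]
    if (sum(h$rel_to_head == "head", na.rm = TRUE) != 1) next
    n <- nrow(h)
    if (n < 2) next
    il <- integer(n * (n - 1))
    ol <- integer(n * (n - 1))
    rl <- character(n * (n - 1))
    p <- 0L
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        p <- p + 1L
        il[p] <- h$line_number[i]
        ol[p] <- h$line_number[j]
        rl[p] <- rel_lookup(h$rel_to_head[i], h$rel_to_head[j])
      }
    }
    out[[k]] <- data.frame(household_key = names(parts)[k],
                           index_line = il, other_line = ol, relation = rl,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) {
    return(data.frame(household_key = character(), index_line = integer(),
                      other_line = integer(), relation = character()))
  }
  dplyr::bind_rows(out)
}

# Canonical ordering for dyad-set comparison, attributes stripped.
sorted_dyads <- function(d) {
  d <- as.data.frame(d)[, c("household_key", "index_line", "other_line",
                            "relation")]
  attr(d, "excluded_households") <- NULL
  d <- d[order(d$household_key, d$index_line, d$other_line), ]
  rownames(d) <- NULL
  d
}

# Eligible-women tibble straight from vectors, for estimator tests.
make_women <- function(age, flag, weight = 1, married = TRUE) {
  tibble::tibble(
    household_key = sprintf("W%04d", seq_along(age)),
    line_number = 1L,
    age_years = as.integer(age),
    age_group = age_group_of(age),
    currently_married = married,
    weight = weight,
    lives_with_mil = flag,
    mil_line = ifelse(flag, 2L, NA_integer_),
    estimation = married
  )
}

# Schedule from bare composition/rate vectors over the 7 age groups.
make_schedule <- function(w, r, id = "s", n_eff = NULL) {
  as_mil_schedule(composition = w, rate = r, survey_id = id, n_eff = n_eff)
}

# Random valid schedule (no empty groups).
random_schedule <- function(id = "s") {
  w <- stats::runif(7)
  make_schedule(w / sum(w), stats::runif(7), id = id)
}

write_temp_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = ".csv")
  readr::write_csv(df, path, na = "", progress = FALSE)
  path
}
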