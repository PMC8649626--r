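# milresidence

Infers **mother-in-law / daughter-in-law co-residence** from the only
kinship information large household surveys record: each member's
*relationship to the household head*. The package is aimed at demographers
and health researchers working with DHS-style microdata (Person Recode
household rosters plus Individual Recode women's files) who want a
replicable, auditable measure of how many married women share a household
with their husband's mother — a living arrangement with documented
consequences for women's autonomy, healthcare access, and wellbeing.

## What it computes

Given a household roster, the package:

1. cleans raw relationship labels into 13 canonical categories
   (configurable label map; surveys that cannot separate *parent* from
   *parent-in-law* are rejected as ineligible);
2. enumerates every ordered pair of co-resident members — a household of
   *n* members yields *n*(*n*−1) dyads — and resolves each pair's relation
   through a head-anchored **relationship matrix** (shipped as an editable
   CSV);
3. flags a woman as living with her mother-in-law when some dyad makes her
   the *son/daughter-in-law* of a **female** co-resident (exactly four
   head-anchored patterns can do this; links through "other relative"
   codes are structurally undetectable, so the measure is a lower bound);
4. estimates weighted proportions among currently married women 15–49,
   overall and by five-year age group:
   *P* = Σₐ *cₐ·rₐ*, with Kish effective sample sizes
   (Σw)²/Σw² for design-naive trend tests;
5. decomposes change between two surveys with the two-factor Kitagawa
   identity

   *P*⁽²⁾ − *P*⁽¹⁾ = Σₐ (*cₐ*⁽²⁾ − *cₐ*⁽¹⁾)·(*rₐ*⁽¹⁾+*rₐ*⁽²⁾)/2
   + Σₐ (*rₐ*⁽²⁾ − *rₐ*⁽¹⁾)·(*cₐ*⁽¹⁾+*cₐ*⁽²⁾)/2

   splitting it into age-composition and rate-schedule contributions that
   sum exactly to the total.

A synthetic household generator with known ground truth
(`sim_config()` / `simulate_households()`) makes the whole chain testable
without any restricted-access data download.

## Worked example

Simulate a survey, run the estimation pipeline on its files, and compare
against an earlier, higher-co-residence survey:

```r
library(milresidence)

cfg <- sim_config(n_households = 20000, seed = 2024)
paths <- write_simulation(simulate_households(cfg), "demo")
res <- estimate_survey(paths["roster"], paths["individuals"],
                       survey_id = "demo-2024")
res$schedule
#> Mother-in-law co-residence schedule: demo-2024
#>   overall: 10.9% of 13,871 married women (n_eff 13871)
#>  age_group n_women n_eff composition rate_pct
#>      15-19     507   507      0.0366     22.7
#>      20-24    1994  1994      0.1438     19.7
#>      25-29    2816  2816      0.2030     15.5
#>      30-34    2820  2820      0.2033      9.9
#>      35-39    2195  2195      0.1582      6.5
#>      40-44    1877  1877      0.1353      4.5
#>      45-49    1662  1662      0.1198      3.5
```

10.9% of married women live with their mother-in-law, with the steep
downward age gradient the generator targets (22.7% at 15–19 falling to
3.5% at 45–49). Against an earlier simulated survey with a younger married
population and higher rates (`res2`, built the same way):

```r
compare_surveys(res2$schedule, res$schedule)
#> difference -4.86 pp, z = -11.8, p = 3.7e-32 => decrease

decompose_change(res2$schedule, res$schedule)
#> Decomposition of change: demo-1994 -> demo-2024
#>   total change        -4.86 pp
#>   age composition     -0.72 pp
#>   rate schedule       -4.14 pp
#>  age_group comp_contrib rate_contrib
#>      15-19       -0.421       -0.517
#>      20-24       -0.387       -1.200
#>      25-29       -0.180       -0.871
#>      30-34        0.114       -0.832
#>      35-39        0.003       -0.356
#>      40-44        0.093       -0.232
#>      45-49        0.058       -0.128
```

The 4.9-point decline is driven by falling age-specific rates
(−4.1 pp), not by the changing age structure of married women (−0.7 pp) —
the per-age contributions sum exactly to the total.

A thin command-line front end over the same functions ships in
`inst/cli/milresidence.R` with `simulate`, `estimate`, `compare` and
`decompose` subcommands; every run writes a JSON manifest of the exclusion
counts applied (unmapped labels, headship anomalies, unmerged women).

See `vignettes/mother-in-law-coresidence.Rmd` for the model, the
relationship-matrix edge cases, estimator and decomposition conventions,
and what the synthetic generator does and does not emulate.

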