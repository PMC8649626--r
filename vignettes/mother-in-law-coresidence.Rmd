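---
title: "Inferring mother-in-law co-residence from household rosters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring mother-in-law co-residence from household rosters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milresidence)
```

## The measurement problem

In many patrilocal societies a woman joins her husband's household at
marriage, so the senior woman of that household — her mother-in-law — often
shares her roof, her food budget, and a good part of her decision-making
autonomy. Large household surveys such as the Demographic and Health Surveys
(DHS) never ask "do you live with your mother-in-law?", but their household
schedules record, for every member, a *relationship to the household head*
(the hv101 variable), along with age and sex. That single head-anchored code
is enough to recover many pairwise kin relations: if one member is the
head's son and another is the head's daughter-in-law, the two are (almost
surely) spouses; if a woman is the head's daughter-in-law and the head's
wife is present, that wife is her mother-in-law.

`milresidence` operationalizes this inference chain:

1. **roster I/O** — clean raw relationship labels into thirteen canonical
   categories via a configurable label map;
2. **relationship matrix** — a 13 x 13 lookup giving the relation of any
   member to any co-resident member from their two head-anchored codes;
3. **dyads** — enumerate all ordered within-household pairs (a household of
   $n$ members yields $n(n-1)$ dyads) and attach the matrix relation;
4. **classifier** — flag a woman as living with her mother-in-law when some
   dyad makes her the son/daughter-in-law of a *female* co-resident;
5. **estimator** — survey-weighted proportions among currently married
   women 15–49, overall and by five-year age group;
6. **decomposer** — a two-factor (Kitagawa) decomposition of change between
   two surveys;
7. **synthetic generator** — DHS-like households with known ground truth,
   so the whole chain is testable without any restricted-access download.

## The relationship matrix and its edge cases

The matrix cell gives the **row (index) member's relation to the column
member**; orientation is pinned by the cell pair (head, son_or_daughter) =
parent versus (son_or_daughter, head) = child. Exactly four index-side
patterns produce the `child_in_law` relation the classifier needs:

| index member is … | partner is … |
|---|---|
| son/daughter-in-law of head | the head |
| son/daughter-in-law of head | the head's wife/husband |
| the head | the head's parent-in-law |
| the head's wife/husband | the head's parent |

This is verified by exhaustive enumeration in the test suite. Three design
points deserve note:

* **Converse consistency.** For almost every cell, `lookup(a, b)` and
  `lookup(b, a)` are converse relations (parent/child, grandparent/
  grandchild, …). The published grid contains three asymmetric cell pairs —
  the (parent, grandchild) cell and the four "parent or aunt/uncle" cells,
  whose converse category does not exist in the vocabulary. We ship the
  grid **as printed** and expose the exceptions through
  `relationship_converse_exceptions()` rather than silently patching a
  published table; none of these cells can affect mother-in-law detection.
* **The grandparent category** appears in the canonical category list but
  has no row in the published grid. We fill its dyads by converse where a
  printed cell determines them ((grandparent, head) → grandparent,
  (head, grandparent) → grandchild, likewise via the head's spouse) and
  `other` elsewhere. This invents no unprinted kin path and cannot create a
  false in-law link.
* **Ambiguous cells** (`spouse_or_sibling_in_law`,
  `parent_or_aunt_uncle`, `spouse_or_both_parents_in_law`, `co_in_law`,
  `sibling_or_cousin`) are retained as distinct codes. Only
  `spouse_or_sibling_in_law` is sex-resolvable
  (`disambiguate_relation()`); the classifier itself never needs a resolved
  ambiguous cell, so users can apply their own conventions downstream.

The grid ships as `inst/extdata/relationship_matrix.csv` so it can be
audited or overridden without touching code.

## Classification rules and their conservatism

A woman qualifies when at least one of her dyads carries `child_in_law`
**and** the partner is recorded female. Consequences we chose deliberately:

* a qualifying relation whose partner has *missing sex* does **not**
  qualify — the measure undercounts rather than overcounts;
* a woman with several qualifying partners (e.g. the head's two wives in a
  polygynous household) counts once; any female partner qualifies, so a
  stepmother-in-law counts — the head-anchored codes cannot distinguish
  her from the biological mother-in-law;
* in-law links running through `other_relative` codes are structurally
  invisible: a multi-branch household where neither the woman nor her
  mother-in-law is directly related to the head produces no `child_in_law`
  dyad. This is an inherent, one-sided limitation of head-anchored
  inference — estimates are a lower bound on true co-residence, never an
  overestimate — and the synthetic generator reproduces it so the property
  can be tested rather than assumed.

Surveys whose label set cannot separate *parent* from *parent-in-law* are
rejected outright (`validate_code_map()` returns FATAL): for them the
(wife, parent) pattern is undefined and any estimate would be meaningless.
Households with zero or several heads are excluded from dyad construction,
with counts logged in the run manifest, because every matrix relation is
anchored on a unique head.

## Estimation

For age group $a$, with sampling weights $w_i$,
$r_a = \sum_{i \in a, \text{MIL}} w_i / \sum_{i \in a} w_i$ over currently
married women 15–49, composition $c_a$ is group $a$'s share of the total
married-women weight, and the overall proportion satisfies
$P = \sum_a c_a r_a$ exactly. Everything is invariant to rescaling the
weights; the DHS six-implied-decimals convention is honoured by an explicit
`dhs_weight_scale` flag rather than guessed from magnitudes. Weights are
normalized per survey; pooling several surveys under a shared renormalization
policy is not implemented.

Because no cluster/stratum metadata is assumed, trend tests
(`compare_surveys()`) use a design-naive two-proportion $z$-test with Kish
effective sample sizes $n_\mathrm{eff} = (\sum w)^2 / \sum w^2$ (pooled
variance, equivalent to a chi-squared test without continuity correction).
With both proportions 0 or both 1 the statistic is undefined; we report
"no change" with $p = 1$ and a `degenerate` flag. A cluster-robust variance
is a natural extension point, not implemented here.

## Decomposition

Change between surveys decomposes with symmetric (Kitagawa) weighting:

$$P^{(2)} - P^{(1)} = \underbrace{\sum_a (c_a^{(2)} - c_a^{(1)})
\frac{r_a^{(1)} + r_a^{(2)}}{2}}_{\text{composition}} +
\underbrace{\sum_a (r_a^{(2)} - r_a^{(1)})
\frac{c_a^{(1)} + c_a^{(2)}}{2}}_{\text{rate schedule}}$$

The identity is exact (tested to $10^{-12}$ on random schedule pairs), the
decomposition is antisymmetric in the survey order, and results are
reported in percentage points. An age group empty in one survey enters with
rate 0 and a warning — this keeps additivity exact while flagging sparse
data. Reference results for four national survey pairs (Egypt 1992–2014,
Nepal 2011–2016, Senegal 1993–2019, Turkey 1993–2013) ship as a CSV
fixture; the test suite confirms that summing their per-age contributions
reproduces every column total within half a unit of the printed precision
(0.005 pp).

Formatted tables (`decompose_report()`) round per-age contributions to
three decimals and always recompute totals from unrounded values.

## The synthetic generator

`sim_config()` / `simulate_households()` build one household per *focal
woman* aged 15–49. Her age group (distribution skewed young, default
`c(0.14, 0.18, 0.18, 0.16, 0.13, 0.11, 0.10)`), marriage probability
(rising through the twenties, default `c(0.18, 0.55, 0.78, 0.86, 0.88,
0.87, 0.85)`), and — if married — true mother-in-law co-residence are drawn
first. The default rate schedule `c(0.284, 0.216, 0.155, 0.109, 0.077,
0.054, 0.038)` follows the steep downward age gradient typical of pooled
multi-country estimates. A woman who truly has her mother-in-law present is
housed in one of four MIL-capable structures drawn from the configured mix:

* **patrilocal stem** — head (male with probability 0.7) + head's wife +
  son + focal daughter-in-law; the mother-in-law is the head's wife, or the
  head herself when female;
* **wife perspective** — male head + focal wife + head's mother;
* **woman head** — focal female head + her parent-in-law (husband's
  mother), the rarely-rostered but fully supported pattern;
* **multi-branch undetectable** — the woman, her husband and her
  mother-in-law all coded `other_relative` under an uncle-like head; the
  mother-in-law is truly present but invisible to head-anchored inference
  (default share 0.05 — such households are believed infrequent in real
  rosters).

Women without a co-resident mother-in-law draw from the full mix, with
capable structures built *without* the mother-in-law member (a widowed
male head, a co-resident father-in-law instead of mother-in-law, and so
on — the no-MIL variants deliberately exercise the sex condition).
Unmarried focal women live as daughters in their natal household. The
`head_with_parent` type is a negative control: a female head co-residing
with her *own* mother, which must never be flagged.

With these semantics the ground-truth rate among married women equals the
configured $r_a$ exactly, and the pipeline estimate converges to $r_a$
times the detectable share — which is what makes the generator usable as an
oracle for parameter-recovery and undercount tests.

Simplifications relative to real rosters, and what that means for
inference: every non-focal adult is aged 50+, so the individual-women file
contains exactly the focal women and the target rates stay identifiable;
household size is fixed per template (3–4 members) rather than drawn from
an empirical distribution; there is at most one eligible woman per
household, so clustering of women within households — which inflates real
design-based variances — is absent. Passing tests therefore validate the
*inference logic* (mapping, dyads, classification, weighting, arithmetic),
not robustness to messy label sets, de jure/de facto residence filters, or
any particular country's household-size profile. Residence status is not
modelled at all: the loader keeps every roster row, and a usual-resident
filter would have to be applied upstream.

## Numerical and procedural choices

* Problem sizes in the shipped tests: oracle equivalence on 10,000 random
  households (≤ 8 members), classifier-versus-truth on 50,000 women,
  parameter recovery over 20 seeded replicates of ~50,000 married women
  (each age-specific estimate within 3 binomial SE of target in ≥ 95% of
  runs), undercount direction over 100 seeded mixed populations, and 1,000
  random schedule pairs for decomposition additivity.
* All generation is deterministic given `seed`; the generator saves and
  restores the caller's RNG state, and identical configurations produce
  byte-identical output files.
* Composition shares must sum to 1 within $10^{-8}$ on schedule
  construction; additivity identities are asserted at $10^{-12}$.
* Weighted rates are reported both as proportions and (in printing) as
  percentages rounded to one decimal.
* `lognormal` weights use `meanlog = -sigma^2/2` so the weight mean is 1
  and unweighted/weighted counts stay comparable.

## Known limitations

* Estimates are lower bounds: multi-branch households and missing-sex
  partners produce one-directional undercount.
* The naive $z$-test ignores survey design effects beyond the Kish
  approximation; with strong clustering its p-values are anti-conservative.
* One application of the relationship matrix only — no transitive kinship
  chains, so e.g. a mother-in-law reachable only through two in-law steps
  is out of scope, as are fathers-in-law and co-resident own mothers
  (trivial to add with the same machinery, deliberately not exposed).
* Stata/SPSS survey file dialects are not parsed; inputs are CSV.
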