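---
title: "Methods: completeness and concordance for an EMA fever registry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: completeness and concordance for an EMA fever registry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feverdq)
```

## The setting

An EMA (ecological momentary assessment) fever registry collects parental
diary entries about children's fever episodes in real time. Its data
quality cannot be monitored the way a clinical trial's can, so it is
assessed by comparison with structured reference records kept by a
pediatric office for the same families. Two GAMOQ indicators are
computed: completeness (TMF-1042) and concordance (TMF-1002). The data
are clustered — families contain child profiles, profiles contain fever
episodes, episodes contain diary entries — and every indicator is tied to
the level it was computed at, because rates aggregated at the family
level can look very different from rates at the episode level.

This vignette records the model, the parameters that matter, and the
decisions taken where the design was genuinely open.

## Episode segmentation

A fever episode is a maximal run of one profile's diary entries in which
no two consecutive entries are more than `gap_hours` apart (default 48
hours). The comparison is strict: a gap of exactly 48 h does **not**
split. Three consequences of this definition are worth making explicit:

- Entries with no fever-related content still drive segmentation timing;
  the rule operates on timestamps, not content.
- The app's *child healthy* button is advisory only. Users forget to
  press it, which is precisely why the gap rule exists; so a healthy
  marker followed by another entry within the gap window does not split
  the episode. Such "overrun" entries are counted
  (`attr(episodes, "healthy_overrun")`) so a report can flag them, but
  the gap rule stays authoritative. The alternative — letting the marker
  split sub-48-hour runs — would make episode counts depend on a button
  users demonstrably misuse.
- Episode aggregates apply the negation coercion: a missing answer about
  physician visits or medication counts as a "no". The maximum
  temperature is *not* coerced; a missing temperature stays missing and
  later grades as not comparable.

## Profile linkage

Within each 8-letter family code, app child profiles are matched to
office patients deterministically:

1. Synonymous duplicates — profiles with identical (gender, birth
   month/year) in one family, created when two caregivers register the
   same child on two devices — are collapsed onto the earliest-created
   profile. Profiles with a missing birth date never group, because
   identity cannot be confirmed.
2. Adults are set aside.
3. Greedy matching passes: full (gender *and* date-of-birth) agreement,
   then date-of-birth-only, then gender-only, each taking candidates in
   office-registration order. Dates of birth compare at month/year
   granularity because the app stores only month and year. The app's
   third gender option ("diverse") never auto-matches the office's two
   options and is recorded as a mismatch.
4. **Sole-remaining-candidate rule**: if exactly one child and one
   patient remain unmatched in a family, they are paired. This rule is a
   package decision. Without it, a genuine pair in which *both* recorded
   demographics are wrong could never be linked, yet such pairs occur
   (the original adjudication used children's names, which a pseudonymized
   export does not carry). In a one-child family the rule is almost
   always right; it can be disabled (`sole_pair = FALSE`).

Mismatches are reported symmetrically: the pipeline never decides which
source holds the correct value. A missing app birth date counts against
completeness, not against concordance.

## Episode matching

The reference study reports how many episodes were comparable but not how
they were aligned, so the correspondence algorithm is a declared
convention with explicit parameters:

- An acute office episode pairs with the app episode whose interval
  contains the visit date, else with the nearest app episode starting
  within `acute_window_days` (default 7 d).
- A past office episode (reported retrospectively at a later visit)
  pairs with the most recent unpaired app episode ending before the
  visit, looking back at most `past_window_days` (default 60 d — roughly
  the spacing of routine pediatric visits at fever-prone ages).
- Pairing is one-to-one and is completed by augmenting-path maximum
  bipartite matching over the feasible pairs: acute visits (in date
  order) claim their preferred episode first, and a later visit may
  displace an earlier pairing onto that visit's next-preferred feasible
  episode. The matching therefore always attains the maximum possible
  number of pairs — the tests verify this against an exhaustive
  assignment oracle on small instances — while keeping the
  containment-first preference.

Agreement grading: binary flags agree when equal after the negation
coercion; temperature agrees when |Δ| < 0.05 °C, i.e. exact agreement at
the sources' 0.1 °C resolution (`temp_tolerance` is a parameter; coarser
grading gives higher agreement by construction). Temperature differences
are reported app − office: positive means the parent's reading was
higher.

## Indicators and statistics

Rates are `k/n` with exact two-sided Clopper–Pearson intervals from beta
quantiles; the lower bound is 0 at `k = 0` and the upper 1 at `k = n`.
Concordance divides agreements by the paired-episode count; completeness
divides the same agreements by the *other source's* episode total, in
both directions. The threshold check (default 95%, the conventional
registry benchmark) is inclusive and configurable — the benchmark is not
scientifically validated.

The acute-vs-past agreement comparison uses the chi-square with Yates
continuity correction, `N(|ad−bc|−N/2)² / (r₁r₂c₁c₂)` with the
continuity term capped at zero so a perfectly proportional table scores
0; an uncorrected variant is available. Temperature-difference
distributions are compared with the Mann–Whitney rank-sum test (exact for
small tie-free samples, normal approximation with tie correction
otherwise) and summarized by median/IQR using the inclusive
linear-interpolation quantile convention. p-values below 0.001 render as
"<.001".

## The synthetic-data generator

`generate_cohort()` draws a two-source cohort with known ground truth:
families (with registration anomalies: families absent from the office
export, families without profiles, duplicate profiles, non-patient
siblings, adult profiles), children with true fever episodes, and
per-source recording of each episode. Episodes arrive uniformly over the
observation window with at least 3 days between the end of one episode
and the start of the next, so the >48 h segmentation rule can always
recover them; app-recorded episodes become clusters of 2–6 entries with
6–40 h internal gaps. True maximum temperatures follow a truncated
normal (mode 39.2 °C, range 38.0–42.4 °C) on the 0.1 °C grid; the
parental reading adds N(0, 0.3²) noise, and office recall of past
episodes is biased 0.4 °C downward, making app-minus-office differences
positive for past episodes.

Default probabilities are derived analytically from the validation
cohort's published cells rather than guessed: the app coverage of acute
office episodes fixes the per-episode recording probability
(`p_app_record = 424/681 ≈ 0.62`); with it, the identifiable app total
fixes the number of true episodes in active families and hence
`p_office_visit_acute = 681/2332 ≈ 0.29` and
`p_office_report_past ≈ 0.255`; the almost-complete app coverage of past
office episodes forces a much lower past-report probability for
unrecorded episodes (0.016) — parents who track fever in the app recall
past episodes far better; and the office episodes from families without
any app entry fix the family-activity share (0.84) and the overall
episode rate (2.05 per child-year over a 16-month window). Per-variable
submission probabilities approximate the published marginal response
rates and are documented as approximations. Demographic error rates are
the published mismatch fractions themselves.

`expected_dqi()` gives the closed-form concordance implied by a
configuration via the coercion algebra
`π(q_a q_o + (1−q_a)(1−q_o)) + (1−π)` for binary elements and a
grid-rounding normal probability for temperature; the test suite checks
it against Monte-Carlo simulation and then checks the whole pipeline
against it (parameter recovery pooled over 20 seeds at 100 families per
seed, within three binomial standard errors).

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: within-episode temperature
trajectories, behavioral change over time (e.g. parents using the app
less as they learn), correlated submission behavior across variables,
false-positive flags, and same-sex same-month twins. The last exclusion
is deliberate: the linkage key cannot distinguish such twins from
synonymous duplicates, so the generator draws distinct demographic keys
within each family to keep its ground truth identifiable.

## The reference-cohort reconstruction

`build_reference_cohort()` builds, without any randomness, a cohort whose
pipeline output reproduces the published validation-study numbers: 684
registered families reducing to 1012 comparable profiles (22 siblings, 2
adults, 5 duplicates, 6 profiles of unidentifiable families), the full
episode reconciliation (1481/1452 app, 1171 = 133+85+953 office, 686
paired of which 424 acute and 262 past), the demographic mismatch counts
(7 gender, 12 date-of-birth, 8 missing), and the per-variable agreement
counts. Episode timing is laid out on a 25-day grid so that the pairing
is unambiguous; temperatures and identifiers are synthetic.

Two published marginal tables are internally inconsistent with their own
agreement counts (the antipyretic source marginals and the office
temperature response counts do not sum to the cell totals). The
reconstruction gives precedence to the agreement counts — they drive
every indicator — and realizes the affected single-source marginals as
closely as the totals allow.

## Numerical choices and degenerate inputs

- Timestamps are timezone-naive local time at minute resolution,
  serialized as ISO-8601; ternary flags serialize as `yes`/`no`/empty.
- Temperature plausibility bounds for validation default to
  [34.0, 43.5] °C — the entry bounds are not documented, and the observed
  range is well inside — and are configurable.
- Empty inputs degrade gracefully: no entries → no episodes; no office
  episodes → all app episodes exclusive; a report on partially empty
  input carries warnings rather than failing.
- Chi-square marginal products are computed in double precision (the
  integer product overflows already at cohort scale).
- Tie-breaks are all deterministic (creation time, registration date,
  then identifier), so a fixed seed reproduces byte-identical exports and
  reports.

## Problem sizes

The test suite exercises the full reconstruction (≈1000 profiles, ≈2650
episodes) once, stochastic cohorts at 25–150 families, the exhaustive
pairing oracle up to 6×5 episodes, full enumeration of Clopper–Pearson
inversions up to n = 12, rank-sum permutation enumeration up to 6+6
samples, and the topline-shape check at the study's full scale (684
families). These sizes were chosen so each property is tested at the
scale where its failure modes live while the whole suite stays quick to
run during development.

## Known limitations

- Linkage is deterministic; no probabilistic record linkage, and no
  name-based adjudication of which source erred.
- The episode-pairing windows are conventions; the report exposes them as
  parameters precisely because the reference design did not specify
  alignment. Conservation of the reconciliation totals is the only
  external check on them.
- Completeness here is relative completeness against a second imperfect
  source, not against ground truth; both sources under-record.
- The Mann–Whitney statistic on temperature differences depends on the
  raw per-episode differences, which a count-level reconstruction cannot
  pin down; only its inputs' summary shape is reproduced.
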