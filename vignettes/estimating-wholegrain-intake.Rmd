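---
title: "Estimating whole-grain intake from diet diaries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating whole-grain intake from diet diaries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wholegrainr)
```

## The estimation problem

Whole-grain intake cannot be read off a nutrient databank: it is an
*ingredient* quantity. Given a multi-day food diary (who ate what, how many
grams, on which day) and a food composition registry stating how many grams
of whole grain each food carries per 100 g as consumed, the intake of a
participant is

$$
\text{intake (g/d)} \;=\;
\frac{1}{D}\sum_{\text{occasions } o}
m_o \cdot \frac{p_{f(o)}}{100},
$$

where $D$ is the number of diary days (3 or 4), $m_o$ the consumed mass of
occasion $o$ and $p_f$ the whole-grain percent of food $f$. Everything else
in the package — dry-matter conversion, cooking-loss correction, cut-off
tiers, energy adjustment, serving classes, survey-weighted summaries — is
scaffolding around this sum, and each piece embodies a methodological
choice documented here.

## Dry-matter basis and cooking loss

Registry contents are grams of whole-grain *ingredient dry matter* per
100 g of food as consumed. Different grains hold different amounts of
water — wholemeal wheat about 14 %, whole oat about 8.9 % — so wet-basis
percentages are not comparable across grains. `derive_wg_percent()`
converts a recipe (fresh ingredient mass per 100 g food, water percent,
processing loss percent) to a DM-basis content:
$m \cdot (1 - w/100) \cdot (1 - \ell/100)$ per grain. The water
percentages live in `grain_water_content()` (a data file), not in code.

Cooking changes the mass basis. Wholemeal bread loses 14.6 % of its weight
when toasted, so 85.4 g of toast is 100 g of bread. Rather than duplicate
percentages for every cooked variant, a cooked record may reference its
uncooked parent (`cooked_form_of` plus `cooking_loss_percent`);
`cooked_equivalent_mass()` maps the eaten mass back to the registry basis.
Equivalently, the cooked food's *effective* percent per 100 g as consumed
is the parent's percent divided by $1 - \ell/100$ — toast at 51 % bread
content becomes 59.7 g/100 g. We apply the cut-off tiers to this effective
as-consumed percent, because it describes the food the participant
actually ate; this is one consistent reading of applying food-level
cut-offs to cooked foods, and it means a food can cross a tier boundary by
being cooked (toast clears 51 % where its bread does not). The alternative
— thresholding on the uncooked parent's percent — would change nothing
else in the pipeline.

## Cut-off tiers, servings, energy adjustment

Three tiers are computed for every participant: `any` (foods with any
whole-grain content), `ge10` (foods with ≥ 10 % whole grain, comparable
with earlier British estimates) and `ge51` (≥ 51 %, the US "substantial
whole grain" food definition). The threshold applies to the food's *total*
percent summed over grain types, never per grain. Intakes are nested by
construction: any ≥ ge10 ≥ ge51.

A serving is 16 g of whole grain per day; classes are half-open and closed
below (`[16, 32)` is one serving, so exactly 16 g/d counts as one serving)
with a dedicated class for exact zero, the non-consumers. Non-consumers
are *retained* in every median and IQR — the skew they induce is a finding,
not a nuisance. Energy adjustment divides by the participant's reported
mean daily energy intake and rescales to 10 MJ: `intake * 10 / energy`.
All values are carried at full precision; rounding happens only in
reports.

## Survey-weighted statistics

Summaries are weighted medians and interquartile ranges with the
participant survey weights, computed with a type-1 (left-continuous)
weighted quantile: the smallest value whose cumulative normalised weight
reaches $q$. The convention is stated because it is visible: at an even
cumulative-weight split, a left-continuous median and an averaging median
differ. With integer weights the definition coincides with the type-1
quantile of the weight-expanded sample, which is what the tests assert.

The three inferential procedures are implemented in the package rather
than delegated, so that every branch is oracle-testable:

* **Mann–Whitney** (sex differences): $U$ from midranks; exact two-sided
  p by complete enumeration of group assignments when the pooled size is
  at most 12, otherwise a normal approximation with tie-corrected variance
  and no continuity correction.
* **Kruskal–Wallis** (NS-SEC classes): $H$ with the standard tie
  correction, chi-square p on $k-1$ degrees of freedom. With two groups
  and no ties, $H = z^2$ of the Mann–Whitney approximation — a relationship
  the test suite checks.
* **Linear trend by age**: weighted least squares of individual-level
  energy-adjusted intake on the ordinal age-band index (individual-level
  rather than band-median regression, preserving $n$), t-test on the
  slope. Degenerate perfect fits resolve deterministically (zero slope and
  zero residuals gives p = 1).

Rank tests run unweighted by default; survey weights can be incorporated
by integerised-weight replication, a transparent approximation to
design-aware rank tests. No multiple-testing correction is applied; each
comparison is reported with its own p-value. Age bands default to 1.5–4,
5–12, 13–17, 18–24, 25–34, 35–44, 45–54, 55–64 and 65+ years — a
configurable, pragmatic banding, not an assertion about any particular
survey's grouping.

## The synthetic diary survey

Real diet-diary microdata of this kind are access-restricted, so the
package ships a generator whose output has the statistical structure the
analysis assumes. Defaults describe the emulated population and were fixed
once, as study conditions, not tuned: 3073 participants with a 49 %
child/teenager share; 44 % of adults and 51 % of children male; NS-SEC
over eight classes with 2 % missing; 4-day diaries for 98 % of
participants and 3-day for 2 %; absolute non-consumer probability 0.18
for adults and 0.15 for children.

Whole-grain consumption is zero-inflated and right-skewed: a participant
is first drawn as a consumer or absolute non-consumer; consumers then
accumulate daily eating occasions per food commodity group (age-graded
probabilities: ready-to-eat cereals decline with age, porridge rises,
sweet snacks peak in teenagers) with lognormal portion sizes — the
simplest positive, right-skewed portion model consistent with medians
sitting well below means. Portion scale carries a socio-economic gradient
(meanlog declines linearly across NS-SEC classes) and a child/adult
offset. Energy intakes are lognormal around age/sex-typical means
(4.8–8.8 MJ/d); survey weights are lognormal around 1. One non-registry
"filler" food per diary day exercises the unknown-code path. The lognormal
σ values are free parameters of the emulation: the survey reports medians
and IQRs, not full distributions, so dispersion is a documented choice
(σ = 0.45 for portions), not an estimate.

Two properties matter for testing. First, a consumer is guaranteed at
least one whole-grain occasion (the diary is redrawn in the rare case
none was drawn), so the non-consumer count is exactly binomial in the
configured probability. Second, ground-truth intakes are recomputed from
the final tables by a deliberately plain loop that shares no code with the
scoring pipeline, making full-pipeline parameter recovery a genuine
two-implementation check.

`calibrate_config()` adjusts the per-stratum portion meanlog by monotone
search until generated weighted medians hit targets (default: adults
20 g/d, children 13 g/d, ±10 %). Under a fixed seed, shifting the meanlog
by $d$ multiplies every portion — hence every intake — by $e^d$, so the
search converges in one or two rounds; a non-convergent search errors with
the best achieved medians. Random streams are keyed per participant by
(seed, index), so growing the population leaves earlier participants
byte-identical.

What passing tests on synthetic data do **not** show: the generator has no
day-of-week or seasonal structure, no brand-level food vocabulary, no
correlation between energy intake and whole-grain propensity, no
misreporting, and its registry is an 18-food illustration rather than a
221-food survey list. Results on real diaries inherit none of these
simplifications' guarantees; the synthetic pipeline validates the
*machinery*, not any substantive population claim.

## Numerical choices and degenerate inputs

* Weighted quantile search uses a `1e-10` relative slack on the cumulative
  weight so exact boundary hits (e.g. cumulative weight exactly 0.5) are
  not lost to floating-point rounding.
* Exact-tier comparisons (`>=` on percents, `== 0` for non-consumers) are
  safe because percents come from the registry unmodified and zero intake
  is a true sum of zero terms.
* Foods absent from the registry contribute zero whole grain and are
  reported, not rejected; most foods in a real diary are not whole-grain
  foods.
* Empty strata yield `n = 0` rows with `NA` summaries; zero whole grain at
  a tier yields an empty, warned attribution rather than `NaN` percents.
* `cooking_loss_percent = 100` is rejected as degenerate (a food that
  vanishes on cooking), as are negative masses, non-positive weights and
  energies, and split-map fractions summing above 1.
* Problem sizes in the shipped tests: the exhaustive Mann–Whitney oracle
  runs all layouts to pooled n = 8; distributional invariants use 100
  generated surveys of n = 200; calibration recovery uses one survey of
  n = 5000; test size uses 2000 null replicates. These sizes give the
  checks their stated resolution (e.g. a binomial 99 % interval of ±2
  percentage points on the non-consumer fraction at n ≈ 2500 adults).

## Known limitations

Within-person day-to-day variance is not modelled (no usual-intake
correction), diary misreporting is taken at face value, medians carry no
confidence intervals (no Taylor linearisation or replicate weights), and
composite-food split fractions must be supplied by the user — the package
validates but cannot invent them.
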