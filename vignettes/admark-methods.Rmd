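---
title: "Methods: exposure metrics, PAHO classification and appeal-variety inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure metrics, PAHO classification and appeal-variety inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admark)
```

## The pipeline and its assumptions

`admark` reproduces, as reusable tested code, the analysis chain of a
television food-marketing monitoring study of child audiences: audience
ratings → exposure metrics → top-quantile sample → sample filters → PAHO
nutrient profiling → appeal-variety scoring → reliability → stratified
comparisons. The chain assumes:

* **Rating points are percentages.** 1 rating point = 1% of the stratum's
  child audience. Weekly impressions are therefore
  `(avg_rating / 100) × population × n_instances / 52`. The division by
  100 is stated prominently because ratings prose often omits it; it is
  the only convention consistent with the definition of a rating point.
  The weeks divisor is fixed at exactly 52, including leap years.
* **The unique ad is the creative, not the cut.** Versions differing only
  in duration are one ad; instance counts and average ratings pool all
  versions; content coding applies to the longest ("extended") cut and
  broadcasts to every product the ad promotes.
* **Selection before filtering.** The top `floor(0.20 × N)` ads by overall
  weekly impressions are selected first (floor reproduces the canonical
  2957 → 591 count); category, availability and missing-nutrition filters
  apply afterwards, in that order. Boundary ties in the selection break by
  ascending ad id — the choice is arbitrary but deterministic, which
  testing requires.

## PAHO classifier

Only processed and ultra-processed products are in scope (`applicable`);
the four-level processing category is an *input* (assigned by
nutritionists in real data, by the generator here) — the package does not
compute NOVA-style classifications. The six criteria are all inclusive
(≥): free sugars ≥ 10% of energy, total fat ≥ 30%, saturated fat ≥ 10%,
trans fat ≥ 1%, sodium ≥ 1 mg/kcal, any non-caloric sweetener. Inclusive
boundaries are asserted per criterion in the test suite.

Numerical choices:

* Energy conversions use Atwater factors — 4 kcal/g (free sugars),
  9 kcal/g (all fats); source nutrition tables that report kJ are
  converted by the reader (4.184 kJ/kcal) when an `energy_unit` column is
  present.
* **Zero-energy products:** a positive problematic nutrient with zero
  energy yields an infinite energy fraction and fires its criterion; a
  zero nutrient yields 0. The model's intent is flagging, and the ratio is
  otherwise undefined.
* The reference amount (per 100 g vs per serving) is not fixed: energy
  fractions and the mg/kcal ratio are scale-invariant, so the verdict only
  depends on it through the sweetener/zero-energy edge cases; inputs are
  taken as-is.

## Appeal codebook and variety scores

The variety score per strategy counts distinct flagged appeal types,
capped at 4 (ordinal 0–4); `no_coded_appeal` marks ads with neither
strategy. The shipped codebook carries five emotional types (senses,
cartoons, positive_emotions, fun, characters) and five rational types
(health, nutrition, freshness, ingredients, quality) with placeholder
definitions — definitions are payload for human coders, not logic. Five
emotional types (rather than the three most-cited ones) are needed for the
emotional variety scale to span its range: with three types the score caps
at 3 and the canonical emotional-median-of-2 world is unreachable.

For analysis, the reconciled coding is a single coder's table (coder 1 by
default): in the emulated design, reliability is established on a
subsample and coders then split the material, so double codings exist only
for the reliability stage.

## What the synthetic generator emulates

`sim_config()` defaults state the emulated world once; they are not tuned
per run:

| parameter | default | rationale |
|---|---|---|
| `n_unique_ads` | 500 | desk-scale; use 2500 to match a ~500-ad analyzed sample |
| `instances_mean`, `instances_dispersion` | 204, 1.0 (log-normal, ceiling'd) | ≈ 600k instances / 3000 unique ads in year-long logs; heavy tail makes a "top 20%" meaningful |
| `rating_base` | 0.5 points | typical child-audience ratings for single airings |
| `gender_gap` | 1.2 | female/male exposure ratio > 1, the gradient the emulated studies report |
| `ses_gradient` | 1.5 / 1.0 / 0.6 | exposure decreasing with SES |
| `frac_high_in` | 0.776 | published share of high-in products among advertised products |
| `coder_error_rate` | 0.03 | yields κ ≈ 0.8–1, the reported reliability range |
| populations | 2 470 700 overall; 1 260 057 F + 1 210 643 M; SES 1 235 350 / 938 866 / 444 726 | DANE 2017 projections as used by the ratings vendor |

The shipped SES populations sum to more than the overall count; that
inconsistency exists in the source projections and is deliberately kept
(only female + male = overall is enforced).

**Appeal prevalences.** The three most common emotional appeals use
published prevalence pairs — senses 45.8%/33.5%, cartoons 28.8%/21.2%,
positive emotions 31.8%/21.5% (high-in ads / not-high-in ads; the
not-high-in values for cartoons and positive emotions are derived from the
published all-products figures via
`all = 0.776 × high + 0.224 × not`, an identity that reproduces the
published senses 33.5% to within 0.2 points). The remaining two emotional
pairs are set by solving, under independence across types,
`P(any emotional | high-in) = 0.893` and
`P(any emotional | not high-in) = 0.749` with the two unknown
probabilities equal: 0.362 and 0.219. All five rational types share one
probability in both groups, solving `P(any rational) = 0.577`: 0.158.
Equal rational pairs make the rational-by-high-in comparison a true null.
These calibrations were fixed analytically before any test was run.

**High-in status is an ad-level draw.** When the generator derives the
product universe from the config, the high-in target is drawn once per ad
and shared by its 1–3 products: products promoted together come from one
brand line and share formulation. (An early per-product i.i.d. draw made
virtually every ad contain a high-in product at `frac_high_in = 0.776`,
which erased the product-level contrast the coding model creates — a
structural defect, not a tuning issue.) Nutrient amounts are constructed
on the intended side of every threshold and then *verified* by
`classify_products()`; the generator never bypasses the classifier.

**Coder 2 is symmetric bit-flip noise** on coder 1 at `coder_error_rate`.
The emulated reports publish only agreement ranges, not a disagreement
structure; the symmetric flip is the simplest model with a tunable κ.

What the generator does **not** emulate: program schedules and channel
structure (opaque labels only), co-viewing or time-shifted viewing,
seasonality, brand repetition across ads, correlated coder errors, or any
relationship between ad content and airing frequency. A green test on
synthetic data therefore establishes that the *pipeline arithmetic and
inference machinery* behave as specified under the stated world — not
that the substantive findings generalize to any real ratings export.

## Statistical tests: conventions

* **Wilcoxon signed-rank:** zero differences discarded (classical
  convention; ordinal variety data guarantee many zeros), absolute
  differences mid-ranked, statistic V = sum of positive ranks. Exact
  enumeration of all 2^n sign assignments when nonzero pairs ≤ 12;
  otherwise normal approximation with the standard tie correction and no
  continuity correction.
* **Mann–Whitney U:** mid-ranks, U reported for the first group; exact
  label-permutation enumeration when n_a + n_b ≤ 14, otherwise
  tie-corrected normal approximation.
* Two-sided p-values are `min(1, 2 × min(lower, upper))`; both null
  distributions are symmetric. All reported p-values are two-sided; a
  `holm_adjust` flag adds Holm-adjusted columns to the paired grids (off
  by default, matching the emulated reporting, which used no
  multiple-testing correction).
* **Paired t:** classical `mean(d) / (sd(d)/√n)` with n − 1 df.
  Zero-variance differences are reported explicitly: all-zero → p = 1
  with an `identical` flag; constant nonzero → `infinite_separation` with
  p = 0. A variety level with no ads returns an `empty_stratum` result
  rather than an error.
* **Cohen's κ:** when expected agreement is 1 (both coders used a single,
  identical category throughout) κ is undefined and reported as `NA`, not
  0 or 1 — collapsing the degenerate case would misstate reliability for
  rare codes.
* **Units of analysis** follow the emulated design: products for the
  Wilcoxon/Mann–Whitney stage, ads for the exposure t-tests.

### Known inferential caveat: within-ad clustering

Product-level tests broadcast each ad's variety scores to all its
products, so product observations are clustered within ads while the rank
tests assume independence. Under an equal-prevalence null this inflates
the product-level Mann–Whitney type-I error (empirically ~15% of seeds
reach p < 0.05 at α = 0.05). This mirrors the emulated study's own
framing and is preserved deliberately; consumers of the rational-appeal
null comparison should read it with that caveat. The type-I calibration
study therefore evaluates the tests on ad-level (unclustered) scores,
where their nominal levels apply — empirical levels over 1000 null
replicates: Wilcoxon 0.057, Mann–Whitney 0.051, paired t 0.046, all
within the accepted [0.03, 0.07] band.

The calibration world (`null_sim_config()`) sets every prevalence to 0.3,
gender gap 1, flat SES gradient, a gender-symmetric population table
(impressions bake populations in, so a true gender null needs equal
female/male counts), `frac_high_in = 0.5`, and 120 ads per replicate —
scaled down so 1000 replicates fit a single-CPU desk budget.

## Degenerate inputs and determinism

Every generator function seeds the RNG from `config$seed` (with fixed
offsets per stage), so a fixed config is byte-identical across runs, and
`write_report_bundle()` writes no wall-clock information, so report
bundles are byte-identical too. Validation errors carry the offending
field, row numbers, or id lists; the CLI maps validation errors to exit
code 1 and runtime errors to 2.

## Limitations

* The pipeline reproduces the published *procedures*; published aggregate
  numbers that depend on the proprietary ratings data (e.g. the overall
  mean weekly impressions, or the printed Wilcoxon "t" whose statistic
  convention cannot be verified) are not targets and are not reproduced.
* The PAHO implementation covers the six criteria used in the emulated
  monitoring design, not the full published model's additional
  provisions.
* Krippendorff's α and multi-coder generalizations of κ are out of scope;
  reliability is two-coder.
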