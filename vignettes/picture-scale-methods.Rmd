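---
title: "Methods: building, administering and validating a dynamic picture-based affect scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building, administering and validating a dynamic picture-based affect scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(hdrps)
```

## The measurement problem

Momentary affect is short-lived and drifts over a day, so instruments meant
for repeated daily use must be fast, reusable and resistant to learning
effects. Verbal inventories such as the PANAS are rich but slow and best
suited to single administrations; a dynamic picture-based scale instead asks
the respondent to pick, from a small set of photographs, the one that best
matches their current state. Because each administration draws a fresh
picture set from a large affect-labeled library, repeated testing presents
almost no repeated content.

This package implements the full computational workflow around such a
scale:

1. **Library construction** — screen multi-rater 9-point valence/arousal
   ratings of candidate pictures into a labeled library;
2. **Administration** — generate category-stratified picture-choice trials
   and score the selections;
3. **Validation** — the psychometric battery: rating-panel reliability,
   concurrent/discriminant validity, a pre/post reflection check, label
   consistency against the Self-Assessment Manikin (SAM), and rMSSD
   affective-instability analysis;
4. **Synthetic cohorts** — a generator with known ground truth, so every
   stage is testable without real photographs or human raters.

## From ratings to labels

Ratings are integers on the SAM-style 9-point scale. Valence ratings 1–3,
4–6 and 7–9 bin to *negative*, *neutral* and *positive*; arousal ratings bin
analogously to *low*, *medium* and *high*. The binning rule is stated on the
integer partition, so fractional ratings are rejected rather than rounded
(`valence_rating_to_label()`, `arousal_rating_to_label()`).

The **identity ratio** of a picture on one dimension is the fraction of
raters whose individual rating bins to the picture's modal label
(`identity_ratio()`). A picture passes a rating round iff a *unique* modal
label reaches the threshold — 0.60 by default — on *both* dimensions
(`screen_images()`). Two numerical choices deserve note:

* **Ties.** When two labels tie at the maximal frequency there is no
  dominant affect label; the modal label is undefined and the picture cannot
  be retained. At the working threshold of 0.60 a tie could never pass
  anyway with two or more raters per label; treating ties as failures keeps
  the rule total.
* **Abnormal rater affect.** Rating sessions taken while the rater's own
  pre-session affect check failed are excluded before counting
  (`rater_affect_valid = FALSE`), since a rater in a marked mood state
  contaminates the consensus.

Two independent rounds (a small expert panel, then a larger professional
panel) are merged by **label consistency** (`merge_rounds()`): a picture
enters the library only if it was retained in both rounds with the same
valence label and the same arousal label. Final mean ratings default to the
second round's panel, which is larger and therefore the better estimate; a
`means = "pooled"` switch combines both rounds weighted by rater count.

Neutral pictures are further split by mean valence into *low neutral*
((4, 5]) and *high neutral* ((5, 6]) subtypes (`neutral_subtype()`). Because
labels come from modal rater judgments while subtypes come from means, a
neutral picture's mean can occasionally fall outside (4, 6]; such pictures
are assigned the nearer subtype and flagged, so downstream users can exclude
them if they prefer a stricter library.

## Administration and scoring

A trial consists of five rounds, one per content category (people, animals,
plants, objects, scenes), in seeded random order. Each round presents one
picture per valence stratum — positive / high neutral / low neutral /
negative in the four-option version, with the two neutral strata collapsed
in the three-option version — drawn uniformly at random from that category's
library cell and shown in random order (`generate_trials()`). Identical
seeds and libraries reproduce identical trial sequences, a contract the
tests check exactly.

Scoring (`score_trial()`, `score_responses()`) produces:

* a **trial score**: the mean library valence of the five selected
  pictures. The instrument itself defines no numeric score, only labels; the
  mean selected valence is used because it is monotone in selection valence
  and lives on the same 1–9 scale as SAM, which makes the concurrent
  validity correlation directly interpretable. A modal-label ordinal code is
  a configurable alternative for users who prefer a purely categorical
  score.
* a **trial label**: the modal valence label of the five selections, with
  neutral subtypes collapsed first. A positive/negative tie resolves toward
  *neutral*: the middle category biases neither validity direction, and with
  five selections a tie always involves the two extremes.

`duplication_rate()` reports the fraction of presentations, from a
participant's second trial onward, that repeat a picture that participant
has already seen — the statistic that quantifies the reusability advantage
of a large library.

## The psychometric battery

* `cronbach_alpha()` uses the variance-ratio form
  \(\alpha = \frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_T^2\bigr)\). For
  rating-panel consistency the *raters* play the role of the scale's items
  (each rated picture is an observation); an `items = "columns"` switch
  restores the conventional orientation. The test suite cross-checks the
  implementation against the independent covariance identity
  \(k\bar c / (\bar v + (k-1)\bar c)\) to 1e-10.
* `mean_item_total_reliability()` averages each rater's Pearson correlation
  with the across-rater mean vector — the reliability usable for single-item
  instruments, where the five rounds play the role of raters. Constant
  rating vectors have undefined correlations and are excluded with a
  warning. The pass floor is 0.5.
* `pearson_validity()` applies the 0.45 cutoff with *strict* inequalities in
  both directions: concurrent validity passes above it, discriminant
  validity below it, and a correlation of exactly 0.45 passes neither.
* `paired_pre_post_test()` is the standard paired *t* on post − pre (via
  `stats::t.test`), read at two-tailed 0.05. Zero-variance differences with
  a nonzero mean are a degenerate input — the statistic is undefined — and
  are flagged rather than silently computed.

## The validation analyses

`reflection_check()` asks whether taking the scale *reflects* rather than
*induces* affect: the paired test on SAM ratings taken immediately before
and after a trial should find no shift, and most administrations should
change by less than 10 percentage points. "Percentage points" is read on the
scale span (9 − 1 = 8), so a change counts only when |post − pre| ≥ 0.8
scale units; the normalization is configurable because other spans (e.g.
percent of the pre score) are defensible.

`consistency_accuracy()` converts each paired SAM rating to its label and
reports the fraction of trials whose picture-scale label agrees, counted per
trial (not per participant). `rmssd()` is
\(\sqrt{\operatorname{mean}_t (x_{t+1}-x_t)^2}\), and
`instability_correlates()` correlates per-participant rMSSD of each
instrument with integer-coded covariates (gender, age, management level,
seniority, marital status, education, SDS, SAS), starring two-tailed 0.05
and 0.01. The PANAS enters both validity and instability analyses as the
balance composite PA − NA by default (PA-only and NA-only are available);
the composite choice is an assumption and is flagged as such.

## The synthetic cohort generator

`sim_config()` + `simulate_ratings()` + `simulate_respondents()` emulate the
statistical structure the analyses assume, with every generating value
recoverable:

* **True picture affect.** Per category, true valence is an equal-weight
  mixture over the four strata with component means 2.5, 4.5, 5.5 and 7.5
  (SD 0.6). The components are placed symmetrically about the scale midpoint
  so that the decision boundaries of a nearest-picture chooser (3.5 and 6.5)
  coincide with the rating-label boundaries — the placement a valence-graded
  instrument aims for, with items discriminating exactly at the category
  thresholds. True arousal is normal around the released per-category
  library means (SD 1.5).
* **Raters.** A score is `round(clip(true + N(0, sd), 1, 9))`; the default
  noise SD of 1.2 is a typical inter-rater spread for affective picture
  ratings on 9-point scales. Panels default to 7 and 35 raters per picture,
  the per-picture panel sizes implied by splitting a 14-expert panel in two
  and a ~210-judge panel in six. Two percent of rater sessions are flagged
  as taken under abnormal rater affect. 120 pictures per category keeps
  every (category, stratum) cell comfortably populated after screening at
  realistic noise, as the real library's cells are.
* **Respondents.** Latent valence follows a bounded random walk on [1, 9]
  parameterized by (start level, drift, volatility): every trajectory starts
  at the neutral scale midpoint (5) and diffuses with per-respondent
  volatility `0.3 · exp(−0.3·z(age) + 0.1·z(SAS) + 0.1·z(SDS))` — affective
  instability declining with age and rising with anxiety/depression, the
  direction reported throughout the instability literature. Choices follow a
  softmax in the distance between picture valence and current affect
  (temperature 0.5; computed with the max-shifted stable form so the
  argmax limit is exact); SAM reports are the rounded latent state plus
  N(0, 0.5) noise; PANAS subscales are weakly loaded affine projections
  (slope ±1.5, item noise SD 8, clipped to 10–50), emulating an instrument
  that measures a related but different (past-week) construct — which is
  what makes the discriminant validity correlation small.
* Demographics follow the formal validation cohort's published shares
  (gender, age bands, marital status, education, management level).

What the generator deliberately does **not** emulate: picture content and
aesthetics (only a scalar valence/arousal truth), personal preference for
particular pictures, learning or fatigue effects across administrations,
time-of-day structure, cultural differences in picture interpretation, and
missing/abnormal response patterns beyond simple flags. Passing tests
therefore demonstrate that the *pipeline arithmetic and statistics* behave
as specified under the assumed data-generating process — not that the real
instrument achieves any particular reliability in a new population.

One consequence worth knowing: with SAM report noise of 0.5 scale units,
identical pre/post SAM integers are rarer in the synthetic world than for
real respondents retested minutes apart, so the synthetic "fraction changed
< 10%" runs well below what a real immediate retest produces. The paired
reflection test is unaffected (there is no true shift by construction).

## Problem sizes and numerical conventions

The test and acceptance runs use desk-scale sizes chosen to make
Monte-Carlo checks stable: 600 simulated pictures rated by 7 + 35 raters;
100 respondents with 10–14 administrations (≥ 1,000 trials) for consistency
and validity; 1,000 replicates of n = 500 null pairs for the paired test's
type-I calibration (expected ≈ 5%); 2,000 trials for the within-stratum
uniformity check. Low-noise parameter recovery uses rater noise SD 0.25 and
choice temperature 0.1, where screened labels match the generating truth
and the picture-scale label matches the SAM label on ≥ 95% of trials.

Numerical conventions: ratings use R's `round()` (half-to-even) identically
for truth labels and simulated scores, so noiseless raters reproduce the
truth exactly; the latent walk reflects at the scale boundaries; all
generation restores the caller's RNG state and is fully determined by
`(config, seed)`.

## Known limitations

* Labels use valence only at administration time; arousal is carried in the
  library but not used to assemble trials — measuring both dimensions with
  one picture set remains open.
* The identity-ratio screen is computed against the modal label; screening
  against a pre-registered expected label would be stricter and is not
  implemented.
* The numeric trial score is a package convention (mean selected valence),
  not part of the original instrument's definition; comparisons across
  implementations should rely on labels.
* Reliability via mean item-total correlation includes the rater in the
  consensus mean, which inflates the coefficient slightly for small panels;
  with 5 or more raters the effect is minor and the convention matches
  common practice for consensus ratings.
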