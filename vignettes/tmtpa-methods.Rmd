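---
title: "Methods: TMT reporter quantification and physical-activity association"
author: "tmtpa package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TMT reporter quantification and physical-activity association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtpa)
```

## The scientific problem

Skeletal-muscle proteomes of healthy adults differ with habitual physical
activity, and quantifying those differences requires walking a long
arithmetic path: isobarically labeled (TMT 6-plex) peptide spectra carry
six reporter ions whose intensities encode the relative abundance of six
samples; those intensities must be unmixed from isotopic-impurity
crosstalk, filtered by identification-quality rules, normalized within
each labeling set, rolled up from spectra to proteins, corrected for
sample-loading differences, and finally regressed — protein by protein —
on an ordinal activity score while adjusting for age, race, BMI, muscle
fiber composition, and the labeling batch. This package implements that
pipeline as tested, reusable components, together with a seeded synthetic
cohort generator so every stage can be validated without access to any
deposited raw data.

## The model

For spectrum $s$ of peptide $j$ belonging to protein $p$, measured in
channel $c$ of TMT set $b$, the generator (and, implicitly, the analysis)
assumes the log2 reporter intensity

$$
\log_2 I_{s,c} \;=\; m_p + e_j
  + \beta^{PA}_p \, \mathrm{PA}_i + \beta^{age}_p \, \mathrm{age}_i
  + \beta^{BMI}_p \, \mathrm{BMI}_i
  + u_{p,b} + L_{b,c} + \varepsilon_{s,c},
$$

where $i$ is the donor in channel $c$, $m_p$ is the protein baseline,
$e_j$ a peptide ionization offset, $u_{p,b} \sim N(0, \tau^2)$ a
per-set batch intercept, $L_{b,c} \sim N(0, \sigma_L^2)$ a per-channel
loading offset, and $\varepsilon \sim N(0, \sigma^2)$ spectrum noise. The
reference channel of each set carries the covariate-free pooled profile
($m_p + e_j + u_{p,b} + L + \varepsilon$). Intensities are emitted on the
linear scale ($2^{\log_2 I}$) and mixed through the reporter purity
matrix, mirroring real PSM exports.

After quantification, the per-protein analysis model is the linear mixed
model

$$
y_{p,i} = \alpha_p + \beta_p \,\mathrm{PA}_i + \gamma_1 \mathrm{age}_i
  + \boldsymbol{\gamma}_2 \mathrm{race}_i + \gamma_3 \mathrm{BMI}_i
  + \gamma_4 \mathrm{fiber}_i + u_{b(i)} + \epsilon_{p,i},
\qquad u_b \sim N(0, \tau_p^2),
$$

fitted by REML with lme4, with the activity code $\mathrm{PA}_i \in
\{0,1,2,3\}$ entering as a single numeric slope and p-values from
lmerTest's Satterthwaite t-tests. $\beta_p$ (log2 units per activity
point) is the quantity of interest; Benjamini–Hochberg q-values are
reported alongside raw p, and proteins are called up/down at raw
$p < 0.05$ by the sign of $\beta_p$.

## Questionnaire scoring

Weekly minutes of moderate-to-vigorous physical activity (MVPA) are the
sum over brisk walking, weight/circuit training, and up to four vigorous
activities of (sessions in past two weeks) × (minutes per session),
divided by two. Casual walking is tabulated separately and never counts.
The ordinal code is lower-edge inclusive: `< 30` → 0, `[30, 75)` → 1,
`[75, 150)` → 2, `>= 150` → 3.

```{r coding}
categorizeActivity(c(20, 30, 74, 75, 149, 150))
computeMvpaMinutes(rbind(activityRecord("brisk_walking", 4, 30),
                         activityRecord("weight_circuit", 2, 45)))
```

## Retention rules and their order

Eight rules run in a fixed order, each reported with records in/removed/
out so the cascade telescopes: decoys; contaminants; peptide FDR
$\le 0.1\%$; protein FDR $\le 1\%$; spectra shared between proteins;
spectra not identified in all six channels of their set; peptides not
detected in every non-reference sample; and single-peptide proteins never
confirmed by a second search engine. The order is a package choice (the
rules themselves do not commute in their counts, though the final output
is order-invariant); placing the cheap flag-based rules first makes each
report line interpretable. An absent channel is encoded as an empty
field, and a literal zero intensity is treated as absent, because a
detected reporter ion is never truly zero. Purity correction runs before
the completeness rule, on raw presence, since only complete six-vectors
can be unmixed; incomplete records pass through flagged and are then
dropped by rule 6.

## Normalization arithmetic

All normalization uses medians, with the even-count median taken as the
mean of the two middle values:

1. **log2 transform** of the (purity-corrected) reporter intensities.
2. **Within-protein centering**: the median over all of a protein's
   spectrum–channel values is subtracted from each of them. By default
   the median is taken globally (one per protein, across all channels of
   all TMT sets); a per-(protein, set) scope is available
   (`scope = "set"`), which makes every per-(protein, set) median exactly
   zero. The reference channels participate in the median either way but
   are excluded from the output matrix. The scope choice matters
   statistically — see below.
3. **Roll-up**: the protein × sample abundance is the median over all
   spectrum-level values of all the protein's peptides in that sample's
   channel — one pooled median, not a median of peptide medians (the
   alternative reading; the pooled version weights peptides by their
   spectral support).
4. **Loading correction**: from every sample column, the median across
   proteins is subtracted, so every sample has exactly zero median. This
   is deliberately the single-pass channel-median centering, not Tukey's
   iterative row/column polish: one pass is what the loading-artifact
   model (a per-sample additive offset in log2 space) requires, and it
   removes such offsets exactly. Note that exactness holds at the matrix
   level; offsets present at the spectrum level additionally perturb the
   within-protein medians of step 2 by a protein-level quantity that the
   intercept (and, per set, the batch random intercept) later absorbs.

### Why the centering scope defaults to global

Per-set centering subtracts, for every protein, a per-set constant whose
value tracks the set's median covariate level. Under a randomized design
with five donors per set, roughly one fifth of the activity-score
variance lies between sets, and per-set centering removes the activity
signal riding on it. The random-intercept model still draws on
between-set contrasts (the protein-specific set offsets it sees are small
when effects are small, so REML gives between-set information substantial
weight), and the net effect is a systematic attenuation of small activity
slopes on the order of the between-set variance share (roughly 15–20% at
$|\beta| \le 0.1$ in simulations of this design), versus negligible
attenuation for within-set (fixed-set) estimation. Global centering
subtracts a single constant per protein, preserving between-set contrasts
and leaving genuine set-to-set batch offsets to the random intercept —
which is precisely the component the model is designed to absorb. With
global centering the random-intercept fits recover simulated slopes with
bias well under 10% at magnitudes 0.05–0.22 while the type-I error stays
at the nominal level. Both scopes satisfy their own zero-median
postconditions and both are exercised by the test suite; analysts who
prefer the per-set reading can set `center_scope: set` in the pipeline
configuration.

## The synthetic cohort

The generator's defaults emulate the study design the pipeline targets:
60 donors in twelve 6-plex sets, each set holding one donor from each of
five age strata (20–34, 35–49, 50–64, 65–79, 80+) plus a pooled reference
in one channel; activity codes drawn with frequencies 11/8/14/25 (of 58);
nonzero activity slopes on 25% of proteins with magnitudes uniform in
0.02–0.22 log2 units per activity point and two-thirds negative, matching
the reported per-protein effect spectrum. Variance-component defaults —
spectrum noise SD 0.2, batch intercept SD 0.05, loading SD 0.1, peptide
offset SD 0.3 (all log2 units) — are chosen as values a practitioner
would call typical for 6-plex reporter data at the spectrum level; they
were fixed once as the package's study conditions. Nuisance records are
injected at realistic low rates (2% decoys, 1% contaminants, 5% shared
spectra, 2% spectra with an absent channel, 3% of peptides missing from a
whole set).

Design choices worth stating explicitly:

* **Myosins are pinned.** MYH7/MYH1/MYH2/MYH4 are always simulated with
  the maximum peptide count and are exempt from the coverage-destroying
  nuisance processes, because the fiber-type covariate is computed from
  them and they are saturatingly abundant (hence always quantified) in
  real muscle data. Their activity, age and BMI effects are fixed at
  zero so the covariate is not itself activity-dependent.
* **The reference channel** is modeled as a pooled baseline without donor
  covariates, is included in within-protein centering, and is excluded
  from the quant matrix and the design matrix. The generator supports
  evaluating it differently, but "present, excluded from modeling" is the
  default.
* **Questionnaire records are constructed to round-trip.** A donor's
  target MVPA minutes are decomposed into whole sessions whose durations
  are exact divisors, so scoring the simulated records reproduces the
  target exactly; a casual-walking record is drawn independently.
* **Race** is a 3-level categorical (dummy-coded against the most
  frequent level at fit time) and **sex** binary; both default to zero
  effect on abundance — they exist so the model formula is estimable.
* One RNG stream, seeded from the config, carries every stochastic draw,
  which makes cohorts bit-reproducible.

What the generator does *not* emulate: peptide-specific reporter-ion
biases beyond an additive offset, intensity-dependent (heteroscedastic)
noise, missingness correlated with abundance, isoform-level shared-peptide
structure, or any chromatographic/search-engine behavior (FDR fields are
drawn directly). Passing tests therefore demonstrate the arithmetic and
inferential machinery under the assumed additive log-normal model, not
robustness to every pathology of real LC-MS data.

## Numerical and statistical choices

* **Fiber-type ratio** is computed on the linear scale,
  $2^{a_7} / (2^{a_1} + 2^{a_2} + 2^{a_4})$, from the log2 abundances of
  MYH7, MYH1, MYH2 and MYH4. A ratio of centered log2 values is
  sign-unstable around zero; the linear reading keeps the covariate
  positive and stable. The literal log2-ratio reading is available via
  `scale = "log2"`. The ratio is computed from the final
  (loading-corrected) matrix.
* **Boundary fits.** When the REML estimate of the batch variance lands
  on the zero boundary ("singular fit"), the mixed fit coincides with
  ordinary least squares; such fits are valid and are *not* treated as
  convergence failures. Genuine optimizer failures trigger a flagged
  refit without the random effect (residual df).
* **Zero-variance degeneracy.** With an identically zero response the
  slope t-statistic is 0/0; the package resolves it by the $t \to 0$
  limit (p = 1). In the exactly noise-free limit REML itself is undefined
  (the likelihood diverges), so noise-free identifiability is evaluated
  with the fixed-set solver (`modelSpec(batch = "fixed")`), which also
  sidesteps the fiber covariate being exactly constant there; in that
  configuration the pipeline recovers true slopes to machine precision.
* **TMT set: random vs fixed.** The set enters as a random intercept by
  default, mirroring lme4 usage for batch adjustment; a fixed-factor
  switch is provided since the adjustment could be read either way.
* **Per-protein failures** (rank deficiency, optimizer errors) are
  captured per row and never abort the sweep; rank deficiency is an
  error that names the collinear columns.
* **BH correction** is the standard step-up rule (via `p.adjust`),
  verified in the tests against an independent brute-force
  implementation of $q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j$.
* **Monotonicity of centering** holds within each (protein, set) group:
  subtracting one median per group preserves the ordering of that
  group's values. Cross-sample orderings are intentionally *not*
  preserved by the loading correction — removing per-sample offsets is
  its purpose.

## Problem sizes used in validation

The package's test suite validates the statistical properties at sizes a
desk-scale study of this design supports: the type-I-error check
aggregates over 5,000 per-protein fits from twenty all-null cohorts of
300 proteins and 60 donors and requires the raw-p < 0.05 fraction to lie
in \[0.03, 0.07\]; effect recovery is checked at slope magnitudes 0.05,
0.1 and 0.22 log2 units per activity point on 150-protein cohorts (bias
under 10% of the true magnitude, sign agreement among discoveries at
least 95%); the boundary-variance oracle compares at least 100 singular
mixed fits to closed-form least squares at 1e-6.

## Known limitations

* The retention rules assume one PSM table spanning all sets with a
  common peptide universe; fractions-level bookkeeping is out of scope.
* FDR fields are consumed as given — the package does not re-derive FDR
  from decoy counts nor model identification probabilities.
* No missing-value imputation: the coverage rule guarantees a complete
  matrix, at the cost of discarding incompletely observed peptides, which
  is the analyzed design's own trade-off.
* No moderated variance shrinkage across proteins, no interaction terms,
  and no age-association contrasts; the per-protein model is exactly the
  one described above.
* Category summaries count curated labels; they are not enrichment
  tests.
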