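---
title: "Auditing the interchangeability of impairment and botheredness ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the interchangeability of impairment and botheredness ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bothaudit)
```

## The question and the data

A modified Work and Social Adjustment Scale asks, for each of five areas
of functioning (home management, private leisure, close relationships,
social leisure, work), two questions: how *impaired* the respondent is
(0 = not at all, 8 = very severely) and how *bothered* they are about
that level of impairment (0–8). If services may substitute the first
rating for the second, the paired difference `d = impaired − bothered`
should behave as if the two pair members were exchangeable. `bothaudit`
formalizes that audit: tie-aware rank correlation quantifies how strongly
the two kinds of ratings travel together, and a paired sign-flip
randomization test asks whether their mean difference is consistent with
exchangeability. Both analyses are run per item and on the pooled set of
pairs, and both are resampling tests, appropriate for bounded, heavily
tied, non-normal ordinal data.

## The two tests

**Permutation test for Spearman's rho.** Ratings 0–8 produce many ties,
so rho is computed as the Pearson correlation of average-rank vectors;
the classical `6Σd²` formula is biased under ties and is not used. Under
the null of no association, the pairing carries no information, so one
vector is shuffled without replacement and rho recomputed; over B
shuffles the p-value is the proportion of coefficients *as large or
larger* than the observed one. That counting rule is one-sided, and is
the package default (`tail = "one_sided_greater"`); the observed
coefficients that motivate the audit are all positive, and a two-sided
absolute-value rule (`"two_sided_absolute"`) is available when negative
association is plausible. For n ≤ `exact_threshold` (default 7, i.e.
5,040 permutations) the test enumerates all n! permutations and reports
the exact fraction.

**Sign-flip test of interchangeability.** If pair members are
exchangeable, flipping the sign of any difference is distribution
preserving. Each resample draws n independent signs ±1 with probability
1/2, multiplies them into `d`, and recomputes the mean; `p` is the
proportion of resampled means with `|mean| ≥ |observed mean|` — a
two-sided rule, with ties counted as extreme, mirroring the "as large or
larger" correlation rule applied symmetrically. For n ≤ 20 all 2^n sign
assignments are enumerated (`signflip_exact()`), and zero differences are
handled naturally as duplicate assignments.

**p-value conventions.** Monte Carlo tests default to the add-one
convention `(b+1)/(B+1)`: it is a valid test (never reports p = 0), and
at B = 10,000 with no exceedances it reports 0.0001, matching how such
results are conventionally printed. The plug-in fraction `b/B` is
available for comparisons against exact enumerations, which always
report the exact fraction.

## Numerical choices

* **Exact tie counting.** Permutation counts compare the centered rank
  cross-product rather than rho itself: ranks are multiples of 1/2, so
  these sums are integer multiples of 1/4 and exactly representable, and
  `≥` comparisons cannot misclassify a tie through floating-point error.
  The sign-flip tests compare integer sums throughout.
* **Symmetry in the arguments.** Which of the two vectors is shuffled is
  statistically immaterial; the package chooses it canonically (the
  lexicographically larger rank vector), so swapping impaired and
  bothered reproduces the identical p-value at the same seed.
* **Seeding.** Every test invocation takes one seed for R's default
  Mersenne-Twister generator. The audit derives a distinct sub-seed per
  (row label, test) via a polynomial hash of the master seed, so results
  are bit-reproducible and adding an item never perturbs another row.
* **Degenerate inputs.** A constant rating vector makes rho undefined;
  the audit records that error in-row and continues. Skewness of a
  constant vector is reported as 0 with a warning rather than NaN.
* **Quartiles.** Medians and quartiles use linear interpolation between
  order statistics (the "type 7" convention). Boxplot hinge conventions
  differ across software, so any statement about central-50% ranges is
  tied to this documented choice.

## The synthetic-data generator

The patient data behind the motivating audit are not publicly deposited,
so every downstream stage is exercised against synthetic tables with the
same statistical structure. The generator is a Gaussian copula: per item,
a latent bivariate standard normal pair with correlation `ρ_latent`, a
location shift `δ` (latent SD units) added to the botheredness
coordinate, and both coordinates discretized through the standard-normal
quantiles of a nine-category marginal. This gives independent control of
rank correlation and marginal shape — a direct categorical sampler would
entangle them.

Two calibrations connect latent parameters to observable targets:

* `calibrate_shift()` solves for δ in closed form (the expected value of
  a thresholded shifted normal), because an integer-scale shift cannot
  hit fractional mean-difference targets such as −0.377.
* `calibrate_latent_correlation()` bisects on `ρ_latent`, evaluating the
  sample Spearman on `n_probe` draws with common random numbers, so the
  probe objective is deterministic and monotone. Discretization
  attenuates rank correlation, so the calibrated latent value weakly
  exceeds the target; an unattainable target (near-constant marginals)
  raises an error reporting the achievable range.

`study_like_config()` assembles the study-scale design: 61 respondents,
per-item latent correlations calibrated to the published per-item
Spearman values (0.5596–0.7558) and shifts calibrated to the published
mean differences (−1.2295 to +0.0328). The default marginal places mass
0.04, 0.07, 0.12, 0.15, 0.17, 0.16, 0.13, 0.09, 0.07 on ratings 0–8 — a
mildly skewed, unimodal shape consistent with "non-normal" being all
that is known about the real marginals. This default is a documented
modelling choice, made once; published sources give no per-item
distributions to match.

What the generator does *not* emulate: respondent-level covariates,
clustering of items within respondents beyond what the shared scale
induces (items are generated independently given their specs, whereas
real respondents correlate across items), longitudinal structure, or
informative missingness. Passing tests on synthetic data therefore show
that the *procedures* behave correctly under the published summary
structure, not that any conclusion about real patients is reproduced.

## Calibration studies and problem sizes

`type1_error()` and `power_curve()` estimate rejection rates by
replicated simulation, always reporting the binomial Monte Carlo
standard error and refusing designs with fewer than 100 replicates. The
package's own validation uses 2,000 null replicates at n = 61 with
B = 2,000 per test (3-SE binomial band 0.035–0.065 around the nominal
0.05), and `reproduce_study_pattern()` runs 500 full audits of
study-like tables at n = 61 and B = 10,000. Those sizes keep every rate's
standard error near or below 0.005 while completing in minutes on a
single core. The study pattern is framed as orderings and majorities —
which items reject interchangeability in most replicates — never as
matching specific published p-values, which depend on the unavailable
raw data.

## Design choices where the design was open

* **"Combined" rows.** The pooled analysis concatenates all item-level
  pairs (5 per respondent, so 305 pairs at n = 61). An alternative
  reading — correlating per-respondent scale totals — is implemented as
  `combined_mode = "sums"`, but pooling is the default and the two are
  not mixed in one report.
* **Difference orientation** is fixed as impaired − bothered; negative
  means say botheredness runs higher. A sign flip would change nothing
  statistically but would silently invert every table for a reader, so
  the orientation is fixed and stated in the documentation.
* **Strictness.** The motivating data had no missing values, so strict
  mode (the default) errors on any violation; lenient mode drops invalid
  records, reports the exclusion counts, and analyses complete pairs.
* **alpha = 0 is admitted** in simulation designs as a boundary case: the
  add-one convention guarantees p > 0, so the rejection rate is exactly
  0 there, a useful self-check on the convention.

## Limitations

Exact enumeration is capped (n! beyond 7 and 2^n beyond 20 by default)
and Monte Carlo error at B = 10,000 is about 0.005 near p = 0.5 — small
p-values are far more precise. The generator's marginals are a
convention, and the calibrated latent correlations are specific to those
marginals: changing the marginal weights requires recalibration, which
`study_like_config()` performs on each call. No parametric competitors
(t-test, Wilcoxon) or equivalence-margin tests are provided; the audit
deliberately stays within the resampling framework it validates.
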