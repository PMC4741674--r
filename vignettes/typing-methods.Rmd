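---
title: "Reverse ABO typing from serum antibody profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse ABO typing from serum antibody profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotype)
```

## The typing model

Reverse ABO typing infers blood type from the antibodies present in serum
rather than from antigens on red cells. The underlying immunology is the
Landsteiner rule: antibodies are raised against the A and B blood-group
determinants *absent* from a person's own cells, so elevated anti-A
implies type B or O, elevated anti-B implies type A or O, both imply O and
neither implies AB.

On a glycan microarray, "anti-A evidence" is a fluorescence signal to one
or more synthetic A-determinant glycans, analyzed throughout this package
on a log base 2 scale of relative fluorescence units (log2 RFU). A
`threshold_rule` partitions that signal into three bands with two
thresholds `lower <= upper`:

* **positive** — signal strictly above `upper`;
* **negative** — signal strictly below `lower`;
* **unclassified** — in between, *including both boundary values*.

The boundary convention is deliberately conservative: a sample sitting
exactly on a threshold yields no call rather than an arbitrary one,
consistent with preferring accuracy over classification rate. Banding one
anti-A and one anti-B rule and combining them gives the blood-type call;
any unclassified band propagates to an unclassified call.

Three combination schemes are provided:

* **pairwise** — one rule per determinant (the simplest two-component
  systems);
* **all_agree** — several rules per determinant; a determinant band is
  accepted only when *every* rule for it returns the same non-unclassified
  band. Agreement requirements raise accuracy at the cost of more
  unclassified samples;
* **flowchart** — the 10-component two-stage method. Stage 1 evaluates,
  per determinant, the arithmetic mean of the log2 IgG signals over four
  glycans plus one IgM signal, all-agree. Samples left unclassified are
  re-evaluated in a stage 2 that uses *fewer glycans and stricter
  thresholds*: only the IgG-average rules, with the unclassified band
  widened by a stringency `s` (default 1 log2 unit) on each side. Dropping
  the IgM agreement requirement is what lets stage 2 classify samples
  stage 1 could not, while the wider band keeps those extra calls
  conservative. Stage-1 calls are final; samples unclassified at both
  stages stay unclassified.

Averaging happens *before* banding for the IgG quadruplets (the average
signal is the decision variable, not a vote of four bands). Component
names are matched exactly and case-sensitively after removing whitespace,
because published component tables contain spacing variants of the same
name (`"BG-B2-Sp - 05"` vs `"BG-B2-Sp-05"`); no fuzzy matching is
attempted. Two published spellings exist for one member of the A-side IgG
quadruplet (`BG-A2-Oct-16` vs `BG-A2-Oct-17`); the package defaults to the
former and accepts the latter with a warning when only it is present.

## Threshold fitting

`grid_search_two_component()` is exhaustive: every (anti-A candidate,
anti-B candidate, `lower_a <= upper_a`, `lower_b <= upper_b`) combination
over the grid is evaluated; methods classifying fewer than
`min_classification_rate` of the training samples (default 0.80) are
discarded, and survivors are ranked by accuracy among classified samples,
then classification rate, then smaller total band width, then
lexicographic target names and lower thresholds. The final keys exist only
to make the output deterministic.

The 10 flow-chart thresholds cannot be searched jointly (the product grid
is combinatorially infeasible), so `fit_flowchart_thresholds()` uses
coordinate ascent: rules are optimized one at a time by exhaustive search
over their own grid pairs with the others fixed, in the fixed order anti-A
IgG, anti-A IgM, anti-B IgG, anti-B IgM, for two full sweeps. The
objective is the same accuracy-then-rate order, evaluated on the full
two-stage method. Equivalence with exhaustive joint search is asserted on
small instances in the test suite rather than assumed. Each rule's grid
uses 0.25 log2-unit steps spanning that target's observed range, extended
one step past each end; 0.25 resolves threshold bands of the width typical
for these signals without inflating the search space.

Initialization is deterministic: each rule starts with a degenerate band
at the grid point nearest the midpoint between the class-conditional means
(foreign vs self for its determinant). Note that the rate component of the
objective can legitimately drive a rule's band to a degenerate width or to
an extreme grid value that effectively defers a decision to the other rule
of its determinant; this is an admissible optimum, not a failure mode.

Mislabel screening (`flag_suspected_mislabels()`) reports samples whose
*stage-1* call is a definite type different from the recorded label,
ranked by the minimum distance of any contributing (averaged) signal to
its nearest threshold. Stage-2 and unclassified calls never generate
flags: a suspect must be confidently typed to be worth re-checking.

## Evaluation conventions

`evaluate_calls()` reports the classification rate (classified / total)
and the accuracy *among classified samples only* — unclassified samples
are excluded from the accuracy denominator. Both an uncorrected accuracy
(against the labels as recorded) and a corrected one (after an optional
relabel map representing re-typed samples) are supported; a
total-denominator accuracy is also emitted for transparency. With nothing
classified, accuracy is reported as `NaN` with a warning rather than 0.

## Component ranking

`anova_rank()` runs a one-way fixed-effects ANOVA of each component's
log2 signal on the blood-type factor, by default the full four-level ABO
factor (a collapsed A/AB vs B/O factor is available via `collapse = TRUE`;
the four-level default makes the weakest assumption about which contrasts
matter). Components are ordered by ascending raw p-value; no multiplicity
correction enters the ranking itself, since ranking is invariant to any
monotone adjustment, but a Bonferroni column is emitted for reference.
Degenerate inputs are handled explicitly: a constant signal returns
F = 0, p = 1; exact within-group constancy with distinct means returns
F = Inf with the p-value floored at 1e-300, the floor applied everywhere
so sorted output never underflows to ties at zero.

## The synthetic-data generator

`simulate_profiles()` draws, for each sample of true type *t* and each
component with determinant *d*:

    signal ~ Normal(mu, sigma^2)
    mu = baseline_mu
       + incompat_delta * isotype_scale[iso] * density_effect[iso, dens] * [d foreign to t]
       + crossreact_epsilon * [d self to t]

with foreignness given by the Landsteiner rule. Defaults (log2 RFU):
`baseline_mu = 8`, `incompat_delta = 4`, `sigma = 1`,
`crossreact_epsilon = 0.3`, chosen to keep signals in the range where
published illustration thresholds (bands around 8–9, IgM medians near
10–12.5) are meaningful. The isotype and density multipliers encode the
empirical ordering that IgG separates blood types more strongly than IgM
(`isotype_scale`: IgG 1, IgM 0.7) and that IgG does best on high-density
glycans while IgM does relatively better on low-density ones
(`density_effect`: IgG high 1 / low 0.7; IgM low 1 / high 0.85). Recorded
blood types equal the truth except with probability `mislabel_rate`
(default 0), mirroring vendor labelling errors. Blood-type frequencies
default to an approximate U.S. distribution (O 0.45, A 0.40, B 0.11,
AB 0.04) and are fully configurable.

`simulate_cohort()` draws overall survival from a lognormal law (an
exponential option exists) whose median is `baseline_median = 16.3`
months, multiplied by `vaccine_bo_multiplier` (default 30/16.3) only for
vaccine-arm B/O patients and further by `forssman_multiplier` (default
1.5) when such a patient is also a Forssman responder. Two structural
invariants are built in because the analyses downstream test exactly them:
the control-arm survival law is identical across blood types, and the
Forssman response rate (default 0.5) does not depend on blood type.
Model-predicted survival is `baseline_median` times lognormal noise
independent of blood type (`hps_noise_sd`, default 6 months, mapped to the
log scale by the delta method), so OS minus prediction isolates the
treatment-by-type effect. The lognormal shape `os_sdlog = 0.8` reflects
the wide survival heterogeneity typical of advanced prostate-cancer
cohorts. Censoring is off by default (medians of largely complete
follow-up); a `censor_rate` is available.

What the generator does **not** emulate: batch and array-position
artifacts, day-to-day drift, ABO subgroups (A1/A2), secretor status,
non-Gaussian signal tails, and correlated noise across components. Passing
tests on synthetic data therefore demonstrate the correctness of the
decision logic, the optimizer and the statistics — not the field
performance of any particular threshold set on real sera, which must be
established on profiled samples of known type.

## Survival statistics

The Kaplan-Meier estimator, log-rank test and odds ratio are implemented
from first principles (and cross-checked against an independent survival
library in the tests): product-limit estimation with deaths processed
before censorings at tied times; the k-group log-rank chi-square from the
observed-minus-expected vector and its hypergeometric covariance (1 df for
two groups); medians as the smallest time with survival at or below 0.5,
undefined when the curve never reaches it — this KM convention is used
even without censoring, where it coincides with an empirical-median
convention, to keep one code path. Odds ratios use the cross-product with
a Woolf (log-scale normal) 95% interval and a two-sided Wald p; when any
cell is zero the Haldane-Anscombe correction adds 0.5 to every cell.
Fisher's exact p is emitted alongside, since the choice between Wald and
exact inference on small 2x2 tables is a judgment call. Group differences
in OS-minus-prediction are reported with a two-tailed t-test (the
conventional report, though it compares means) and a Mann-Whitney
rank-sum test side by side, because the quantity summarized per group is a
median.

Stratification pools types by whether blood group A is self (A/AB) or
foreign (B/O) — the contrast with an immunological rationale and workable
group sizes — and marks Forssman responders by a rise of at least 2 log2
units (4-fold, boundary inclusive) between the pre-treatment and
2–3-month draws. Patients with unknown or unclassified blood type are
excluded from stratified analyses with a logged count.

## Problem sizes and tolerances in the test suite

The suite mirrors a 60/40/120 training/test/validation design for
parameter-recovery runs, uses 100 random 20 x 10 matrices for the ANOVA
oracle at 1e-10 relative tolerance, a 10,000-permutation oracle for the
log-rank p on a 2 x 20 fixture (compared within 3 Monte-Carlo standard
errors, on a fixture with a moderate p-value where Monte-Carlo error
dominates the chi-square continuity gap), 1000 replicate cohorts of n = 80
for log-rank type-I calibration against the 0.05 level, 500 for the power
check, and exact 1e-12 checks for closed-form quantities. Exhaustive
truth-table enumeration covers all 9 pairwise band combinations, all 81
four-rule all-agree combinations, and every distinct signal region of the
two-stage flow chart including threshold boundaries.

## Known limitations

* Thresholds are fitted, never transcribed: published flow-chart threshold
  values exist only in figure form, so a fitted method's numeric bands are
  data-dependent and should be re-fitted per array platform and
  normalization.
* The per-array normalization that precedes the log2 scale is outside the
  package's scope; `log2_normalize()` exposes a pluggable hook rather than
  guessing a procedure.
* No probabilistic calls: the classifier is banded by design, and
  borderline samples are reported as unclassified rather than scored.
* Coordinate ascent is exact only on separable or small instances;
  pathological threshold landscapes could in principle hold it at a local
  optimum. Two sweeps have been sufficient on all tested instances.
* The cohort analyses are univariate by design (no Cox regression or
  multivariable adjustment); the predicted-survival covariate is consumed
  as given.
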