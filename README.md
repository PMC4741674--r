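# glycotype

Reverse ABO blood typing from glycan-microarray serum antibody profiles,
with the downstream survival analyses used to relate blood type to
treatment benefit in vaccine-therapy cohorts.

## The problem

ABO blood type can be read out of serum alone: a person carries antibodies
against the A and B blood-group antigens absent from their own red cells
(type O sera hold anti-A and anti-B, type A holds anti-B, type B holds
anti-A, type AB neither). A glycan microarray measures IgG and IgM binding
to dozens of synthetic blood-group glycans — varying the carrier chain type
(1–6), the conjugation linker, and the glycan density on the carrier
protein — from a few microliters of serum. That makes retrospective typing
possible for banked cohorts where red cells are gone and serum is nearly
exhausted, provided the right components and decision thresholds are
chosen.

`glycotype` implements that pipeline for biostatisticians and array labs:

* **Banded-threshold classifiers.** Each rule partitions a log2
  relative-fluorescence signal into *positive* (above the upper threshold),
  *negative* (below the lower), and *unclassified* between them. Anti-A and
  anti-B bands combine into a call: (+,+) → O, (−,+) → A, (+,−) → B,
  (−,−) → AB, anything unclassified → no call. Supported combinations are a
  single pair of components, all-agree multi-component panels, and a
  two-stage 10-component flow chart (per-determinant averaged IgG over four
  glycans plus one IgM component; a stricter IgG-only second stage
  re-evaluates samples the first stage leaves unclassified).
* **Threshold optimization.** Exhaustive two-component grid search under a
  minimum-classification-rate constraint, and coordinate-ascent fitting of
  the 10 flow-chart thresholds, both maximizing accuracy among classified
  samples first and classification rate second.
* **Component ranking and quality control.** Per-component one-way ANOVA of
  signal on the ABO factor, ordered heat-map export, and flagging of
  samples whose confident typing call contradicts the recorded label
  (mislabel suspects).
* **Survival analysis.** First-principles Kaplan-Meier estimation, log-rank
  tests (two or more groups), cross-product odds ratios with Woolf
  intervals and Haldane-Anscombe correction, overall survival minus
  model-predicted survival, and stratification by A/AB vs B/O and by
  Forssman response (a ≥ 4-fold rise in total Ig to the Forssman
  disaccharide, i.e. ≥ 2 log2 units).
* **Synthetic data.** A generator for blood-type-conditional antibody
  profiles (isotype- and density-dependent separation, cross-reactivity,
  label errors) and two-arm survival cohorts with a configurable B/O
  vaccine-arm benefit, so the whole pipeline is testable without patient
  data.

## Worked example

```r
library(glycotype)

# training sera with known blood types, then the fitted flow chart
sim    <- simulate_profiles(60, seed = 42)
method <- default_flowchart_method(sim$profiles, sim$truth)

# held-out validation sera
valid <- simulate_profiles(120, seed = 43)
evaluate_calls(classify_all(valid$profiles, method), valid$truth)
#> classified 117/120 (97.5%); accuracy among classified 117/117 (100.0%)
#>     called
#> true  A  B AB  O
#>   A  44  0  0  0
#>   B   0 12  0  0
#>   AB  0  0  4  0
#>   O   0  0  0 57
```

117 of 120 sera receive a definite call (97.5% classification rate); all
117 calls match the true type. The three remaining sera fall inside an
unclassified band at both stages and are reported as such rather than
guessed — the method trades classification rate for accuracy by design.

Typing a simulated two-arm cohort and comparing survival of patients for
whom blood group A is foreign (B/O) against those for whom it is self
(A/AB):

```r
co     <- simulate_cohort(80, 37, seed = 44, profiles = TRUE)
cohort <- co$cohort
calls  <- classify_all(co$profiles, method)
cohort$blood_type <- calls$call[match(cohort$patient_id, calls$sample_id)]
cohort$blood_type[cohort$blood_type == "unclassified"] <- NA
cohort <- stratify_cohort(cohort)

vac <- subset(cohort, arm == "vaccine" & !is.na(abo_group))
logrank_test(vac$os_months, vac$event, vac$abo_group)
#> log-rank chi-square = 18.27 on 1 df, p = 1.913e-05
#>       n observed expected   median
#> A/AB 28       28 14.13445 13.87620
#> B/O  51       51 64.86555 29.38569
```

B/O vaccine-arm patients show the longer Kaplan-Meier median (29.4 vs 13.9
months here), reflecting the benefit built into the simulated cohort; the
same analysis on the control arm shows no difference, as the control-arm
survival law is blood-type-independent by construction.

A command-line wrapper covers the same steps
(`glycotype simulate|convert|rank|fit|type|evaluate|survival`); see
`?glycotype_cli`.

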