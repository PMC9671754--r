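---
title: "Methods: a summed-PMR methylation triage test for endometrial cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a summed-PMR methylation triage test for endometrial cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(widqec)
```

## The problem

Endometrial cancer is usually signalled by abnormal bleeding, and the
standard initial triage — transvaginal ultrasound of endometrial thickness
— has poor specificity, sending many healthy women to invasive
hysteroscopy and biopsy. Tumour DNA is shed into the cervicovaginal canal,
where its regional hypermethylation can be read out by methylation-specific
qPCR on an ordinary smear, vaginal swab, or self-collected sample. This
package implements the complete development-and-evaluation pipeline for
such a test: an epigenome-wide discovery screen, MethyLight-style PMR
quantitation summed over a three-reaction panel, prespecified dual
decision thresholds, and the full diagnostic-accuracy analysis.

Because the clinical specimens themselves are not distributable, the
package ships a synthetic-cohort generator that reproduces the *structure*
of the data — cell mixtures, planted marker regions, Ct-space qPCR
measurements, DNA-insufficiency dropout — so that every stage of the
pipeline is exercised end to end, and recomputes the published
cohort-level statistics directly from the printed counts, which are fully
determined by cohort sizes and operating points.

## The cell-mixture model

A cervicovaginal specimen is modelled as a two-compartment mixture of
epithelial cells (fraction $1-f_i$) and infiltrating immune cells
(fraction $f_i$). For sample $i$ and CpG $j$ the observed methylation
fraction (beta value) is

$$\beta_{ij} = \mathrm{clip}\!\left[(1-f_i)\,\epsilon_{ij}
  + f_i\,\mu_j + e_{ij},\; 0, 1\right],$$

where $\mu_j$ is the immune reference methylation, $e_{ij}$ is additive
Gaussian noise with standard deviation `noise_sd`, and the epithelial mean
$\epsilon_{ij}$ equals the reference epithelial methylation plus
`effect_size` for cases at planted marker CpGs. Tumour hypermethylation
lives only in the epithelial compartment, so a heavily
immune-contaminated case sample has a *diluted* signal — exactly the
confounding the discovery screen must handle.

The immune fraction is estimated per sample by constrained least squares:
the closed-form minimiser of
$\sum_j (\beta_j - (1-f)\epsilon_j - f\mu_j)^2$ projected onto $[0,1]$.
On noise-free exact mixtures the estimator is exact; it is flagged `NA`
when the two reference profiles coincide (the mixture is then
unidentifiable).

## Discovery: immune-aware ranking and proximity regions

A usable MethyLight marker must be silent in everything except tumour
epithelium. A CpG is therefore *eligible* only if its immune reference
methylation and its control epithelial methylation (obtained by inverting
the mixture in control samples) are both at most 0.2 — defaults chosen to
encode "essentially unmethylated", configurable per run. Each eligible
CpG is scored by the case-indicator $t$-statistic of the per-CpG linear
model

$$\beta_j \sim \text{intercept} + \text{case} + f,$$

which adjusts the case/control contrast for immune contamination, and
CpGs are ranked by descending statistic (ties broken by genomic order;
constant CpGs score 0 and are unranked). The top 30 ranked CpGs seed
clusters of ranked CpGs within ±500 bp; clusters sharing members merge
transitively; clusters with at least 3 CpGs become candidate regions with
BED-style 0-based half-open coordinates. Each candidate's per-sample
score is its mean beta (the array surrogate for a qPCR reaction), and
candidates are ranked by empirical AUC; the top three form the panel,
mirroring a three-reaction assay targeting one region of *ZSCAN12* and
two of *GYPC*.

## MethyLight quantitation

With amplification efficiency $E$ (fixed at 2, perfect doubling, with a
config override — no efficiency model is claimed beyond this standard
assumption), a well at cycle threshold $c$ carries relative quantity
$E^{-c}$, and an undetermined well carries 0. The percentage of
methylated reference is

$$\mathrm{PMR} = 100 \times
  \frac{Q(\text{target})/Q(\text{reference})\big|_{\text{sample}}}
       {Q(\text{target})/Q(\text{reference})\big|_{\text{calibrator}}}
  = 100 \times E^{-(\Delta Ct_{\text{sample}} -
                    \Delta Ct_{\text{calibrator}})},$$

with the fully methylated calibrator run on every assay. PMR is invariant
to DNA input amount (a constant added to both sample Cts cancels), is 0
for undetermined targets, and is deliberately *not* capped at 100: the
summed score is a risk score, and truncation would need a justification
the assay design does not supply. The test statistic is the exact sum of
the three panel PMRs.

Replicate wells are averaged per (sample, assay) before PMR; a mix of
undetermined and numeric replicates uses the numeric ones with a warning
(a deterministic rule is required and this is the permissive one).
Specimens whose methylation-independent reference assay exceeds 38 cycles
(inclusive boundary: 38.0 is valid) or fails entirely are
DNA-insufficient and excluded from all performance denominators — the
generator plants such dropouts at rate 0.137, the self-collection failure
rate reported in practice.

## Dual decision thresholds

Two cutoffs on the summed PMR are fixed once on a small pilot
(development) set and never revisited; classification is
`score >= cutoff` everywhere (the boundary is positive — a convention
that must simply be fixed and tested). Candidate cutoffs are midpoints
between adjacent distinct scores plus sentinels below the minimum and
above the maximum, so "call everything" and "call nothing" are always
available:

* **Threshold 1** (high sensitivity; symptomatic and high-risk triage)
  maximizes specificity subject to sensitivity ≥ 95%.
* **Threshold 2** (high specificity; lower-risk screening) maximizes
  sensitivity subject to specificity ≥ 95%, searching only cutoffs at or
  above threshold 1.

The restriction in the second rule is a genuine design choice: on noisy
development sets the two unconstrained optima can cross (each constraint
region is individually loose), but the high-specificity cutoff serves the
stricter setting and must not sit below the high-sensitivity one.
Specificity is non-decreasing in the cutoff, so the restriction never
destroys feasibility; on cleanly separated pilot sets both thresholds
coincide at the class gap. Ties resolve toward the lower cutoff.
Thresholds are persisted as JSON with provenance (rule parameters,
development-set size and score digest).

## Evaluation statistics

All intervals for proportions are exact two-sided Clopper–Pearson, from
beta quantiles: the convention is identifiable from printed bounds — 8/8
correct gives a lower bound of $0.025^{1/8} = 63.1\%$. PPV/NPV come from
Bayes' rule at an *assumed* prevalence (9% by default for symptomatic
settings), with a prevalence sweep exposing how strongly PPV depends on
that assumption while NPV does not. The empirical AUC is the
tie-corrected Mann–Whitney pair count (equal to the trapezoidal area of
the ≥-convention ROC curve); paired AUCs are compared with DeLong's
placement-value test using midrank ties, appropriate because comparator
scores (mutation counts, thickness in mm) are heavily tied. Paired binary
modalities are compared with the exact McNemar binomial test. Reported
percentages follow the convention: proportions to one decimal in percent,
predictive values to the nearest integer percent.

For predictive (pre-diagnosis) settings, cases are split at 12 months
between sampling and diagnosis, with exact intervals per group and a
Fisher exact comparison of the two detection proportions — a documented
stand-in, since no specific test is prescribed for this contrast.

## What the generator emulates, and what it does not

Defaults are the package's standard study conditions, fixed once:
100 cases and 100 controls at 2,000 CpGs; three planted regions of five
CpGs each within 500 bp; `effect_size` 0.3 on the epithelial scale;
`noise_sd` 0.05; immune fractions Beta(2, 5) (broad, mean 0.29 — most
specimens are epithelium-dominated but heavy contamination occurs);
dropout rate 0.137; reference Cts uniform on 24–30 cycles; qPCR cycle
noise 0.1 in the pipeline. The pilot set is 20 + 20, matching the scale
of a small test-development set. Ground-truth PMR for a cohort is 100 ×
the region's mean beta; simulated marker Cts sit $\log_2(\mathrm{PMR}/100)$
cycles from the reference Ct, so zero-noise scoring round-trips exactly —
the identity the scoring tests exploit. In predictive cohorts the planted
effect halves for every 12 months of lead time before diagnosis, giving
the time-stratified analysis real structure; the decay scale is an
emulation choice, not an estimate.

The generator does **not** emulate array chemistry, probe types, batch
effects, copy number, multi-lineage immune composition (controls are one
homogeneous group), or primer behaviour. Passing tests therefore
demonstrate that the pipeline's inference machinery is correct under the
stated mixture model — not that the markers would be rediscovered from
real arrays, where unmodelled artefacts could dominate.

## Numerical choices and degenerate inputs

* Per-CpG model fits are vectorised through one QR/cross-product solve; a
  constant immune-fraction vector is dropped from the design (it would be
  collinear with the intercept), and fits with residual standard error
  below $10^{-8}$ score 0 (nothing to explain).
* Zero-PMR wells map to "undetermined" and back to PMR 0; an undetermined
  calibrator is an assay failure (error), and an undetermined sample
  reference is a QC failure, never silently scored.
* All tie-breaks (CpG ranking, reaction ranking, threshold candidates)
  resolve by genomic order or toward the lower cutoff, making every stage
  deterministic at fixed seed; one master seed derives fixed per-stage
  sub-seeds.
* Problem sizes in the test suite are the package's chosen study
  conditions: the full 200 × 2,000 recovery run, 100 random ROC
  instances against exhaustive pair counting, a 2,000-resample bootstrap
  check of the DeLong variance, and 2,000 simulated binomials for
  interval coverage.

## Known limitations

The discovery statistic is a transparent adjusted-association score, one
defensible choice among several that an assay-development team could
make; the
numeric thresholds are derived from development data by the documented
rule rather than copied from an assay protocol; and the published-count
reconstructions cover cohort-level operating points only — per-sample
scores, and hence the real-data ROC curves, are not reproducible without
the specimens. PPV/NPV inherit the prevalence assumption; both are
reported with it attached.
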