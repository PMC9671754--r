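# widqec

Development and evaluation pipeline for a three-marker DNA-methylation
triage test for endometrial cancer in cervicovaginal specimens.

Abnormal bleeding is the lead symptom of endometrial cancer, and the
standard triage (transvaginal ultrasound) has low specificity, so many
healthy women undergo invasive hysteroscopy and biopsy. Tumour-derived
DNA shed into the cervicovaginal canal carries regional hypermethylation
that methylation-specific qPCR (MethyLight) can quantify from a smear,
swab, or self-collected sample. This package implements the full
development pipeline for such a test, for methods researchers in cancer
early detection and diagnostic-accuracy statistics:

* **Synthetic cohorts** — beta-value matrices generated under a
  two-compartment cell mixture,
  `beta = clip((1 - f)·epithelial + f·immune + noise)`, with cancer
  hypermethylation planted only in the epithelial compartment, plus
  matching qPCR plates with cycle noise, "Undetermined" wells and
  DNA-insufficiency dropout.
* **Marker discovery** — per-sample immune-fraction estimation by
  constrained least squares; per-CpG ranking by the case-indicator
  t-statistic of `beta ~ case + immune_fraction`, restricted to CpGs
  unmethylated in immune cells and control epithelium; proximity
  clustering of top CpGs within ±500 bp; panel selection of the top three
  regions by AUC.
* **MethyLight scoring** — PMR (percentage of methylated reference),
  `PMR = 100 · E^-(ΔCt_sample − ΔCt_calibrator)` with efficiency `E = 2`,
  summed over the three-reaction panel into the test score Σ PMR, with
  reference-assay QC (Ct ≤ 38).
* **Dual thresholds** — a high-sensitivity cutoff (threshold 1, for
  symptomatic/high-risk triage) and a high-specificity cutoff
  (threshold 2, for screening-like settings), fixed once on a pilot set
  by constrained search; classification is `score ≥ cutoff`.
* **Diagnostic evaluation** — confusion counts; sensitivity/specificity
  with exact Clopper–Pearson intervals; PPV/NPV at assumed prevalence
  with prevalence sweeps; empirical ROC/AUC; DeLong paired AUC
  comparison; exact McNemar tests; covariate- and time-to-diagnosis-
  stratified summaries.

## Worked example

```r
library(widqec)

# printed cohort statistics follow from the cohort counts alone:
# 69 of 71 cases positive, 50 of 66 controls negative
ss <- sensitivity_specificity(confusion_from_counts(tp = 69, fp = 16,
                                                    tn = 50, fn = 2))
pct(ss)
#> sensitivity specificity
#>        97.2        75.8
pct(clopper_pearson(69, 71))   # exact 95% CI for sensitivity
#> lower upper
#>  90.2  99.7
round(100 * predictive_values(69/71, 50/66, prevalence = 0.09))
#> ppv npv
#>  28 100
```

At an assumed 9% prevalence among symptomatic women, a positive test
raises the cancer probability to 28% while a negative test leaves
essentially none (NPV 100%), which is what makes the test useful for
ruling out malignancy without referral.

The end-to-end synthetic run:

```r
res <- run_pipeline(wq_config(seed = 7), out_dir = "results/run")
res$panel[, c("region_id", "chrom", "start", "end", "auc")]
#>   region_id chrom  start    end    auc
#> 1 region_13  chr3 613034 613857 1.0000
#> 2 region_15  chr4  64265  64987 0.9995
#> 3 region_08  chr2 633032 633768 0.9944
```

The three discovered reactions coincide with the three planted marker
regions, and the validation report in `res$report` carries the
sensitivity/specificity with exact CIs, the AUC comparison against
endometrial thickness and mutation count, and the time-stratified
sensitivity of the predictive cohort.

## Analysis workflow

The numbered drivers under `analysis/` run the study as a narrative
sequence, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R --seed 1   # cohorts + ground truth
Rscript analysis/02_discover_markers.R            # screen, regions, panel
Rscript analysis/03_score_samples.R --seed 1      # plates, PMR, QC
Rscript analysis/04_define_test.R                 # dual thresholds
Rscript analysis/05_evaluate_performance.R        # full evaluation
Rscript analysis/06_published_counts.R            # printed-count statistics
```

Each stage reads only the previous stage's files, so any prefix can be
rerun alone.

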