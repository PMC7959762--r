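# hrvtda

Topological persistence statistics for heart-rate-variability analysis
and sleep staging.

Clinically, sleep stages (wake / REM / NREM) are scored from EEG in 30-s
epochs.  The heart, however, is read far more easily than the brain, and
the autonomic nervous system makes the heart rhythm stage-dependent:
faster and less stable awake, slow and respiration-locked in NREM.
`hrvtda` classifies sleep stages from nothing but R-peak times by
summarizing the *shape* of the instantaneous-heart-rate (IHR) signal
with persistent homology.

## The method

For each scored epoch the pipeline forms a 90-s, 4 Hz, median-centered
IHR window **x** ∈ ℝ³⁶⁰ (the epoch plus its two predecessors) and
computes three persistence diagrams:

- **P₀(x)** of the sub-level set filtration {t : x(t) ≤ h} — each point
  is a min–max pair of the signal (oscillation structure);
- **P₀ and P₁ of VR(R₁₂₀,₁(x))** — the Vietoris–Rips filtration of the
  Takens delay embedding t ↦ (x(t), x(t−1), …, x(t−119)), whose
  components and loops capture the recurrence of the dynamics.  A
  simplex enters at ε = diam/2 (radius scale).

Each diagram P is condensed into the multisets

    M = { (b + d)/2 : (b, d) ∈ P },   L = { d − b : (b, d) ∈ P }

over its finite points, and each multiset into eight statistics — mean,
sd, skewness, kurtosis, the three quartiles, and the persistent entropy
E = Σ −(v/S) log(v/S), S = Σ v.  That is 16 *persistence statistics* per
diagram and a 48-vector per epoch, classified by a linear SVM trained on
class-balanced (majority-down-sampled, seeded) epochs and evaluated on
the full test set with SE/+P/F1 per class, accuracy, Cohen's kappa and
AUC, per subject (mean ± sd) and pooled.

Everything runs offline: a seeded integrate-and-fire generator produces
stage-labeled synthetic R-peak recordings, so the entire pipeline is
testable without clinical data.

## A worked example

```r
library(hrvtda)

# the classic worked filtration: 4 vertices, 5 steps
flt <- worked_filtration()
drop_zero_persistence(compute_persistence(flt, max_dim = 1))
#>   dimension birth death
#> 1         0     1   Inf      # one component, born at step 1, never dies
#> 2         1     3     5      # the loop closes at step 3, is filled at step 5

betti_numbers(flt, at_value = 3)
#> [1] 1 1                      # one component, one loop at step 3

# end to end on synthetic subjects: train on 4, test on 2 held out
cohort <- synthetic_cohort(6, 20, seed = 1)
res <- run_pipeline(cohort[1:4], cohort[5:6], pipeline_config(task = "ws"))
res$report$summary
#>   metric  mean      sd
#> 1 acc    0.889 0.0786
#> 2 kappa  0.675 0.289
#> 3 se_W   0.833 0.236
#> 4 ppv_W  0.708 0.295
#> 5 f1_W   0.764 0.272
#> 6 se_S   0.862 0.00673
#> 7 ppv_S  0.964 0.0505
#> 8 f1_S   0.910 0.0188
#> 9 auc    0.794 0.181
res$report$confusion
#>     predicted
#> true  W  S
#>    W 13  1
#>    S  3 19
```

Mean held-out accuracy 0.889 with wake sensitivity 0.833 and sleep
sensitivity 0.862: the wake/sleep signal planted by the generator (wake
faster and more variable) is recovered on subjects the model never saw.
Numbers are exactly reproducible — every random draw is seeded.

A thin CLI wraps the same functions
(`inst/cli/tdahrv simulate | preprocess | train | evaluate | run`), e.g.

```sh
tdahrv=$(Rscript -e 'cat(system.file("cli", "tdahrv", package = "hrvtda"))')
Rscript $tdahrv simulate --subjects 4 --epochs 40 --seed 1 --out-dir data/
Rscript $tdahrv preprocess --rpeaks data/s01_rpeaks.csv --labels data/s01_labels.csv \
        --subject s01 --out s01_features.csv
```

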