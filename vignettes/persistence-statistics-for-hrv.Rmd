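---
title: "Persistence statistics for heart-rate-variability sleep staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistence statistics for heart-rate-variability sleep staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvtda)
```

## The problem and the approach

Sleep stages (wake, REM, NREM) are scored clinically from EEG in 30-second
epochs, but the autonomic nervous system leaves a readable imprint on the
heart rhythm: wake is faster and less stable, NREM is slow and strongly
modulated by respiration, REM sits in between.  `hrvtda` classifies sleep
stages from nothing but the R-peak times of an ECG, by summarizing the
*shape* of the instantaneous-heart-rate (IHR) signal with persistent
homology instead of hand-picked spectral or time-domain HRV indices.

For every scored epoch the pipeline builds a 90-second IHR window (the
epoch plus its two predecessors, 360 samples at 4 Hz, median-centered) and
computes three persistence diagrams:

1. **P0 of the sub-level set filtration** of the window.  Growing a
   threshold $h$ over the signal values, connected components of
   $\{t : x(t) \le h\}$ appear at local minima and merge at local maxima
   (the elder rule keeps the older component).  Each finite point $(b, d)$
   is a min–max pair of the signal: its oscillation structure.
2. **P0 and P1 of the Vietoris–Rips filtration** of the Takens delay
   embedding $t \mapsto (x(t), x(t-\tau), \ldots, x(t-(p-1)\tau))$ with
   $(p, \tau) = (120, 1)$, i.e. each embedded point is a sliding 30-s
   snapshot.  Connected components (P0) and loops (P1) of this cloud
   capture recurrence and quasi-periodicity of the dynamics.

Each diagram is then reduced to the multisets
$M = \{(b+d)/2\}$ and $L = \{d-b\}$ over its finite points and summarized
by 16 *persistence statistics*: mean, standard deviation, skewness,
kurtosis, the three quartiles and the persistent entropy of $M$, and the
same eight for $L$.  Three diagrams × 16 statistics give a 48-vector per
epoch, which feeds a class-balanced linear SVM.

```{r example}
rec <- synthetic_recording(rep(c("N", "W"), c(4, 4)), seed = 1)
cleaned <- clean_rpeaks(rec$rpeaks)
ihr <- compute_ihr(cleaned)
windows <- extract_windows(ihr, rec$labels, cleaned)
f <- epoch_features(windows$values[[1]])
round(f[1:8], 3)
```

## Conventions that pin the numbers down

Persistence at this level of detail involves several conventions the
underlying theory leaves open.  The package fixes them as follows; every
one is covered by a unit test.

**Scale of Rips diagrams.**  A simplex enters the Rips filtration when its
diameter is at most $2\varepsilon$; all births and deaths are reported on
the $\varepsilon$ (radius) scale, i.e. half the diameter.  Two points at
distance $d$ merge at $d/2$; the compiled backend works in diameters and
the wrapper divides by two.

**Tie-breaking.**  Simplexes entering at the same value are ordered by
dimension, then lexicographically by vertex tuple.  This fixes the
reduction pairing, making every diagram deterministic; the diagram itself
(as a multiset) is independent of such choices.

**Zero-persistence points.**  The generic engine
(`compute_persistence()`) reports simplex-level pairs including those with
equal birth and death; `drop_zero_persistence()` removes them, which
recovers the diagram of the value-indexed filtration (a class born and
dead at the same index never exists in any complex of the sequence).
`vr_diagrams()` omits such dim-1 pairs (an edge filled by an
equal-diameter coface, e.g. the closing edge of an equilateral triangle)
but keeps *all* $n-1$ dim-0 merge deaths, zero-length ones included, so
that the multiset of dim-0 deaths always equals half the Euclidean MST
edge weights.  The featurizer keeps zero-lifespan points: short-lived
classes are treated as signal, not noise.

**Essential classes.**  Every diagram of a connected filtration carries
one point with infinite death (for the sub-level filtration it is the
global minimum, for Rips it is $(0, \infty)$).  `diagram_to_multisets()`
discards all infinite-death points: they are structural, not
discriminative.  The bottleneck distance compares essential points
separately by birth and returns `Inf` when the two diagrams disagree in
their number — such diagrams are topologically incomparable.

**Moments and quantiles.**  Statistics use population (biased) variance,
skewness $m_3/m_2^{3/2}$, non-excess kurtosis $m_4/m_2^2$ (normal
$\approx 3$), and type-7 (linearly interpolated) quantiles.  Degenerate
inputs have fixed fallbacks: statistics of an empty multiset are 0, and
skewness/kurtosis of a zero-spread multiset are 0, so feature vectors are
always finite.

**Entropy of M.**  Persistent entropy is Shannon entropy of a multiset
normalized by its sum, which requires non-negative mass.  Lifespans are
non-negative by construction, but midpoints of a *median-centered* window
are signed.  The package therefore computes the entropy of $M$ on
absolute midpoints — a symmetric choice that preserves the intended
"complexity of hole locations" reading — and leaves $L$ untouched.

**Sub-level ties.**  Equal consecutive samples form one flat critical
region; merges inside a flat region emit no pair, and value ties between
components are broken by the earlier index.

## Preprocessing choices

The 5-beat median filter compares every RR interval with the running
median of its five surrounding intervals; an interval below $0.7\times$
the median marks a spurious beat (removed), one above $1.4\times$ marks
missed beats (the gap is filled with evenly spaced beats, one fewer than
the rounded gap-to-median ratio).  The $0.7/1.4$ band is the conventional
HRV artifact bound and is configurable; passes repeat to a fixed point so
the filter is idempotent.

IHR knots are $60/\mathrm{RR}$ at each beat; interpolation is
shape-preserving piecewise cubic (monotone Hermite, `signal::pchip`),
which cannot overshoot the surrounding knots — a desirable property for a
rate signal.  The first beat carries the first interval's rate so the
grid can span the whole recording.  The 4 Hz grid is aligned to multiples
of the sample period from recording time zero, which makes the 360 window
samples land exactly on grid points.

Epochs are dropped when their 30-s span holds fewer than 5 cleaned R
peaks (the rule is evaluated on the scored epoch, not the 90-s window)
and when no full 90-s history exists (the first two epochs, or windows
reaching before the first IHR sample).

## Classification protocol

Class imbalance is handled by down-sampling the majority classes of the
*training* set to the minority size, with a fixed seed (default 1); the
test set is never balanced and every test epoch is evaluated.  The model
is a linear-kernel SVM at cost 1 without internal standardization —
deliberately plain defaults; both are configurable.  Whether features
should be z-scored per subject before classification is genuinely open
(the normalization is defined here for the screening analysis, not the
classifier); the default is raw features, with `svm_standardize` and
`zscore_by_subject()` available to explore the alternative.  Three-class
problems use the one-versus-one construction (three pairwise linear
SVMs, majority vote).  The REM/NREM task is posed within sleep: wake
epochs are excluded from both training and evaluation pools.

Evaluation reports sensitivity, positive predictivity and F1 per class,
accuracy, expected accuracy, Cohen's kappa and (two-class) rank-based
AUC — each computed per subject and summarized as mean ± across-subject
sd, alongside pooled-epoch versions, since the two disagree when subjects
contribute unequal epoch counts.  Degenerate $0/0$ rates are reported as
0 and flagged, so an all-majority classifier scores zero sensitivity on
the minority class rather than `NaN`.  Feature screening z-scores each
feature within subject, applies the Wilcoxon rank-sum test per feature,
and Bonferroni-corrects over the family actually tested.

## Algorithms and numerics

`compute_persistence()` is the textbook $\mathbb{Z}_2$ column reduction
of the filtration-ordered boundary matrix, in R — transparent, and
feasible for the desk-scale complexes it serves.  `betti_numbers()`
deliberately does *not* share that code path: it computes
$\beta_q = \dim\ker\partial_q - \operatorname{rank}\partial_{q+1}$ by
Gaussian elimination, so the two routes cross-check each other on random
filtrations.

`vr_diagrams()` is compiled.  Dim 0 is Kruskal union-find over the sorted
edges.  Dim 1 runs persistent cohomology: the coboundary columns of the
edges are reduced in reverse filtration order with two standard
optimizations — *clearing* (MST edges are dim-0 death simplexes and are
skipped) and *lazy heap columns* (additions push entries onto a binary
heap; duplicates cancel mod 2 when the pivot is popped, so columns are
never materialized).  A reduced column is reconstructed on demand and
memoized.  The barcode is provably identical to boundary-matrix
reduction, and the suite verifies this against `compute_persistence()`
on random clouds.  A 241-point cloud in $\mathbb{R}^{120}$ — one
epoch — takes well under a second; homology dimension $\ge 2$ is
deliberately unsupported (its cost grows too steeply with cloud size to
be worth it here).

`bottleneck_distance()` is exact: binary search over the finitely many
candidate radii with bipartite-matching feasibility checks.  It exists to
validate stability (diagrams move no more than the sup-norm perturbation
of the signal), not for production use, and is quadratic-ish in diagram
size.

CSV round-trips are bit-exact: doubles are written with 17 significant
digits and re-parsed with base R's correctly rounded parser (the fast
parser in the CSV reader can be one ulp off, which matters for
byte-identical reruns).

## The synthetic generator

`synthetic_recording()` produces stage-labeled beat trains by
integrate-and-fire: the next interval is the stage's mean RR plus a
respiratory sinusoid plus Gaussian jitter, with transient accelerations
(RR scaled by 0.7–0.9 for a run of beats) injected at random during wake.
Defaults place wake at mean RR 0.8 s with sd 0.06 s and weak respiratory
modulation, NREM at 1.0 s, sd 0.02 s with pronounced 0.25 Hz modulation,
and REM in between — textbook sleep-cardiology orderings, *not* estimates
fitted to any clinical dataset.

What this emulates well: stage-dependent rate and variability, reflex
respiratory coupling, artifact-free trains at realistic rates, and a
planted, recoverable class signal — enough to exercise every pipeline
stage and the classifier end to end.  What it does not emulate: ectopic
beats and detector artifacts (the median filter is tested on synthetic
insertions/deletions instead), apnea-driven oscillations, circadian
drift, realistic stage-transition grammar, and inter-subject variability
beyond seed-to-seed variation.  A green end-to-end suite therefore
demonstrates that the machinery is correct and recovers a known signal;
it says nothing about clinical performance, which depends on real
recordings.

Test and example problem sizes were chosen to keep the full suite fast
while exercising every rule: cohorts of about six subjects at 20–30
epochs each for end-to-end runs, and clouds up to a few dozen points
where an exact independent oracle (brute-force rank computations, MST,
explicit filtrations) is feasible.

## Known limitations

- R-peak *detection* is out of scope: the contract starts at beat times.
- The Rips backend is exact but in-memory; recordings produce one
  241-point cloud per epoch, which is the intended operating point.
  Clouds beyond a few thousand points need `vr_max_scale` capping.
- `bottleneck_distance()` is for diagrams of tens of points.
- The linear SVM is the reference model by design; no tuning, kernels or
  calibration are provided.
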