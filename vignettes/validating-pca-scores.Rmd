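---
title: "Validating PCA scores with the partial bootstrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating PCA scores with the partial bootstrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(pcboot)
library(dplyr)
```

## The model

`fit_pca()` performs correlation-matrix PCA through the singular value
decomposition. The raw objects-by-variables matrix is standardized column
by column (mean 0, sample SD 1 with the n−1 denominator) and decomposed as
X = U D Vᵀ. The columns of V are the loadings; the scores are Z = X V =
U D; and the eigenvalues of the correlation matrix are d²/(n−1), so they
sum to the number of variables p. The percent of variance carried by the
first m axes is the ratio of the first m eigenvalues to the trace. We
compute explained variance on these **eigenvalues** (squared singular
values over n−1), not on the singular values themselves: only that choice
makes the variance decomposition additive on the correlation trace.

Two conventions make fits reproducible and comparable:

* **Sign.** SVD column signs are arbitrary. Each loading column is flipped
  so its largest-magnitude entry is positive (first such entry on ties).
  Any all-negative "size" component therefore appears here with positive
  loadings; nothing of substance changes.
* **Ties.** Exactly degenerate eigenvalues leave the corresponding axes
  non-identifiable; the order produced by the decomposition is kept as is.

When there are fewer objects than variables the correlation matrix is
rank-deficient and a plain SVD cannot supply a full p×p basis; the basis
is then completed from the eigendecomposition of the Gram matrix, with
trailing eigenvalues exactly zero.

## The partial bootstrap

Resampling the rows of X with replacement R times and refitting PCA gives
replicate axes that are reflected/rotated relative to the original ones.
Instead of re-aligning them, the partial bootstrap keeps the original V
and projects each re-standardized replicate matrix onto it as
supplementary points, `bootstrap_scores()`. Stacking all replicates gives
nR points in the fixed plane — n clouds of (on average) exactly R points,
because every drawn row contributes one projected point and the draw
counts sum to nR by construction.

Two choices deserve comment:

* **Replicate standardization.** Each replicate is standardized with *its
  own* column means and SDs (the default), because the replicate is meant
  to impersonate a fresh sample that would be standardized on its own
  terms. Standardizing with the training moments is available
  (`standardize = "original"`) for sensitivity checks.
* **Degenerate replicates.** A replicate in which some column is constant
  cannot be standardized. Such replicates are dropped — with a warning
  listing their ids and a recorded reduced effective R — rather than
  patched, since silently inflating a zero variance would bias every
  downstream band. With continuous data this is practically impossible at
  realistic n; it matters only for tiny or discrete inputs.

`bootstrap_eigenvalues()` decomposes every re-standardized replicate on
its own and keeps the eigenvalue vector per replicate (each row sums to p,
padded with zeros when a replicate is rank-deficient). The RNG is fully
deterministic: a plan built by `resample_plan(n, R, seed)` derives
replicate r from `seed + r`, so any single replicate can be regenerated in
isolation and results are identical across platforms given the seed.

Percentile intervals (`percentile_ci()`) use the 1-based order-statistic
convention lo = ⌈Rα/2⌉, hi = R − ⌈Rα/2⌉ + 1; at R = 1000 and α = 0.05
that selects the 25th and 976th sorted values. α = 0 returns the full
range (min/max), the 100% bands used by the dimensionality criterion.

## Confidence polygons and centroids

Each object's replicate cloud is summarised by its convex hull
(`confidence_polygons()`): the minimal convex region containing the
retained points. Areas come from the shoelace formula (half the absolute
sum of consecutive 2×2 cross products), centroids from the standard
signed-area-weighted polygon centroid — with *signed* area in the
denominator, so the result is winding-independent; hulls are emitted
counter-clockwise internally. A collinear cloud yields area 0 and the
vertex mean as centroid, flagged `degenerate` rather than raising, since
real clouds can collapse only in pathological inputs.

The trim level α interpolates between two uses: α = 0 keeps every point,
so outlying replicates remain visible as long hull edges (the most useful
setting for outlier screening, and the default); α ≈ 0.10 gives a central
region robust to extreme replicates. Since the trimming rule is not
uniquely determined by that description, the package implements
**convex-hull peeling** — repeatedly deleting whole hull layers while at
least ⌈(1−α)M⌉ points would remain, then removing the farthest vertices of
the last layer one at a time down to exactly that count. Peeling is
distribution-free and affine-equivariant in the ways that matter for a
score plane; Mahalanobis-distance trimming is available behind
`method = "mahalanobis"` for elliptically-minded users.

Polygon overlap (`polygons_overlap()`) is decided by Sutherland–Hodgman
clipping of one convex polygon by the other; the flag is true when the
interiors intersect *or* boundaries merely touch (intersection area 0).
Overlapping polygons mean the two objects' score positions are not
distinguishable under resampling; widespread polygons mean unstable
scores. The polygon centroid is the bootstrap estimate of the score
itself, and the centroid set serves as a validation set for clustering.

## Dimensionality from eigenvalue bands

With α = 0 bands, rank k is *separated* from rank k+1 when the smallest
replicate eigenvalue of rank k exceeds the largest of rank k+1.
`nonoverlap_dimension()` reports:

* `n_separated` — the count of leading consecutive separated ranks; and
* `m_star = n_separated + 1` — the largest m whose leading gaps 1…m−1 are
  all positive, the retention count under the criterion's own convention
  (floored at 1 when nothing separates, since one axis is always kept).

The off-by-one between the two is intrinsic to the criterion, not a bug:
a design with exactly one real factor has one separated gap (the first
eigenvalue band sits clear of the noise ranks), and the criterion then
licenses retaining the first *two* axes. In a planted-factor recovery
experiment the quantity that estimates the number of factors is
`n_separated`; when choosing how many axes to keep for display or
downstream modelling, `m_star` is the criterion's answer. Both appear in
the report and in the pipeline log precisely so the distinction is never
silent. Percentile bands at user α may drive the same rule
(`alpha` argument); min/max bands are the default but become more
conservative as R grows, since the minimum of R draws keeps falling —
hence the invariance checks in the test suite run at fixed R.

The scree table (`scree_table()`) marks an optional elbow at the rank
maximising the second difference of the eigenvalue profile, labelled a
heuristic; flat profiles flag nothing. The report deliberately presents
the bootstrap answer and the scree profile side by side without
adjudicating disagreements.

## Clustering comparison

`average_linkage()` is UPGMA on Euclidean distances between score (or
centroid) coordinates, delegated to `stats::hclust`; merge heights are
means of all inter-point distances, hence nondecreasing. `suggest_cut()`
returns the midpoint of the largest gap between consecutive merge heights
(earliest on ties) — a reading aid, matching what one would do by eye on
a dendrogram, not an inferential rule. Partitions from cutting the
original-score tree and the centroid tree are compared by pair-counting
(`compare_partitions()`: Rand and adjusted Rand plus the cross-table).
Dendrograms export to Newick with branch lengths equal to height
differences, so leaf depths reproduce merge heights exactly.

Clustering operates on the m retained score dimensions (2 by default,
matching the plotted plane), not on all p.

## EEG front end

The feature extractor reproduces a standard single-channel resting-EEG
variable set. Defaults, with units:

| parameter | default | meaning |
|---|---|---|
| band edges | theta 4–8, alpha 8–13, beta 13–30 Hz | shared endpoints: a boundary peak (e.g. 8 Hz) belongs to both bands |
| filter | Butterworth order 4, 1–40 Hz, forward–reverse | zero phase; doubled roll-off |
| epoch | 1 s, zero-mean, non-overlapping | 400 samples at fs = 400 Hz |
| epochs used | first 150 surviving | recordings with fewer are excluded |
| trapezoid half-width | 1 Hz | smallest symmetric window at 1 Hz resolution |
| skewness | moment coefficient g1 | adjusted variant via `skew_type = 2` |
| artifact rule | reject epoch if max abs amplitude > k·SD | plain placeholder, `reject_k`, off by default |

The Bartlett estimator averages rectangular-window periodograms across
epochs; the normalization conserves energy (the integrated one-sided PSD
equals the mean squared signal), and averaging shrinks the estimator
variance as 1/E at unchanged 1 Hz resolution. Band maxima are log10 PSD
values (power per Hz); band powers are log10 trapezoidal areas centred on
the band peak. RMS and SD per zero-mean epoch differ only by
√((L−1)/L), which is why these two feature columns are always perfectly
rank-correlated. Per-epoch statistics are summarised by their median
across epochs; when more epochs survive than are used, the earliest are
kept (temporal order), an arbitrary but reproducible choice. Subjects
missing any condition, or under the epoch minimum in any condition, are
excluded entirely so the assembled matrix stays paired across conditions.

Raw amplitudes are treated as microvolts throughout; since the spectral
features are log10-scaled, a uniform unit change shifts those columns
additively and leaves every correlation-based result untouched.

## What the generators emulate — and what they do not

`synth_feature_matrix()` plants a single common factor across all ten
feature columns, calibrated (by root-finding on the population
correlation matrix, duplicates included) so the leading eigenvalue is a
chosen fraction of the trace — default 0.84, the regime of strongly
inter-correlated EEG features where one "overall amplitude" component
dominates. Two column pairs are exact duplicates (alpha power/peak and
RMS/SD), reproducing the perfectly rank-correlated redundant pairs such
feature sets contain. An optional second factor loads positively on the
beta columns and negatively on the theta columns — the canonical
beta-versus-theta contrast shape of a second component — with default
strength 2.4 in the two-factor test design, chosen so the second
eigenvalue band separates cleanly from the noise ranks at n = 48.
Per-subject seed substreams make the generator extensible: adding
subjects never changes existing rows.

`synth_eeg()` sums 1/f-shaped background noise and an alpha oscillation
whose amplitude is larger in the eyes-closed condition (alpha blocking),
all scaled by a lognormal per-subject gain; a small gain-proportional
quadratic asymmetry gives skewness that *increases* with overall
amplitude, so even the scale-invariant skewness column shares the gain
factor and all ten features correlate positively across subjects, as in
real single-channel data. A configurable fraction of subjects receives an
exactly-8-Hz peak to exercise the band-boundary code path.

Passing tests on these generators shows the machinery is correct under a
known factor structure with Gaussian noise and stationary signals. It
does **not** show robustness to what real EEG adds: non-stationarity,
artifacts, heavy-tailed amplitude distributions, inter-channel structure,
or non-sinusoidal oscillations. The generators are calibration targets,
not physiological models, and no claim about real-data effect sizes
should be read off them.

## Numerical choices and problem sizes

Tolerances: orthonormality and score identities at 1e−8; trace identity
at 1e−6; geometric oracles (fan-triangulation centroids) at 1e−9;
degenerate-polygon threshold 1e−12 on the signed area; boundary tolerance
1e−9 in point-in-hull tests. Distance ties in clustering resolve by the
underlying implementation's first-minimum rule; merge sequences are
validated against a brute-force recomputation on continuous data, where
ties have probability zero.

The test suite exercises the study-scale configuration (48 × 10, R =
1000) for the exact bookkeeping identities, and scaled-down configurations
elsewhere — R = 200 across 20 seeds for dimensionality recovery, R = 200
across 5 seeds for containment/trimming, 200 random UPGMA instances at
q ≤ 12, 100 random polygons against a 10⁶-sample Monte-Carlo area oracle —
sizes chosen to keep the full suite around a minute on one core while
leaving the stochastic bands meaningful.

## Known limitations

* Confidence regions are computed in two dimensions only; higher-
  dimensional polytopes are out of scope (the plane is where the method's
  interpretation — overlap and spread — lives).
* Min/max (α = 0) eigenvalue bands are R-sensitive; treat `m_star` at
  very large R with the percentile-band variant as a cross-check.
* The per-object clouds are summarised by convex hulls, which are
  sensitive to single extreme replicates at α = 0 by design; use the trim
  level, not post-hoc vertex deletion, when robustness is wanted.
* The artifact rejector is a deliberate placeholder (amplitude threshold);
  serious EEG work should substitute a validated procedure upstream and
  feed clean epochs in.
* `compare_partitions()` corrects for chance only through the adjusted
  Rand; with very small object counts all pair-counting indices are
  coarse.
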