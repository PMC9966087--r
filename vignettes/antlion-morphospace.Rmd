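---
title: "Outline morphospaces for long-nosed antlion larvae: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outline morphospaces for long-nosed antlion larvae: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvamorph)
```

## The scientific problem

Larvae of silky lacewings (Psychopsidae), the "long-nosed antlions", are
recognisable across 100 million years of amber by a forward-protruding
labrum, toothless stylets and trumpet-shaped empodia.  Because fossil
larvae rarely carry taxonomic names, comparisons across time work on
*shape*: head-capsule and body outlines are digitized, decomposed into
elliptic Fourier coefficients, and projected into a principal-component
morphospace.  The area a fauna occupies in that space is a proxy for its
morphological disparity, and the way that area grows as specimens are
added (an accumulation curve) tells whether sampling has approached the
true disparity — a flattening curve means saturation, a still-rising one
means the known material underestimates the original diversity.

`larvamorph` implements that chain end to end: outline ingestion,
elliptic Fourier analysis (EFA), PCA morphospaces, convex-hull
occupation statistics, and a parametric generator of antlion-like
outlines that provides ground truth for validating every stage.

## Elliptic Fourier analysis

A closed outline is parametrized by arc length $t \in [0, T)$ and each
coordinate expanded in a Fourier series,

$$x(t) = A_0 + \sum_{n=1}^{N} a_n \cos\frac{2\pi n t}{T} +
  b_n \sin\frac{2\pi n t}{T}, \qquad
  y(t) = C_0 + \sum_{n=1}^{N} c_n \cos\frac{2\pi n t}{T} +
  d_n \sin\frac{2\pi n t}{T}.$$

For a polygonal contour the coefficient integrals have closed forms as
sums over segments (the classical chain-code formulation); the package
evaluates these exactly rather than via FFT, so coefficients are
independent of point density up to the polygonal approximation itself.
The default harmonic count is 20, configurable from 1 to 64; 20
harmonics reproduce head-capsule outlines with sub-percent radial error
while suppressing digitization jitter.

### Normalization

Coefficients are standardized by the first-harmonic ellipse: the
outline is centred ($A_0 = C_0 = 0$), the parametrization start moved to
the semi-major axis, the shape rotated so that axis lies along $+x$, and
all coefficients divided by the semi-major length.  After normalization
$a_1 = 1$ exactly and $b_1 = c_1 = 0$ to machine precision, so two
outlines differing only by position, size, rotation and tracing start
map to the same coefficient vector (verified to $10^{-9}$ and better in
the tests).

Two genuine ambiguities require conventions:

* **Starting point ($\pm\pi$).**  The first-harmonic phase is defined
  only modulo $\pi$ — either end of the semi-major axis is a valid
  start.  The two candidates differ exactly in the sign of every
  even-numbered harmonic.  The package requires the largest-magnitude
  even-harmonic coefficient to be positive.  Using the *argmax*
  coefficient (rather than, say, the sign of $a_2$) matters: for the
  near-bilaterally-symmetric shapes of larval heads, individual even
  coefficients straddle zero within a morphotype, and a tie-break based
  on one of them splits a homogeneous sample into two artificial
  mirror-normalized clusters.  The argmax is stable under small shape
  perturbations, so neighbouring shapes normalize consistently.
* **Reflection.**  Ingestion orients every contour counter-clockwise,
  which forces $d_1 > 0$ for every normalized outline — chirality
  therefore lives in the higher harmonics, not in the sign of $d_1$.
  Mirroring a CCW outline (flip plus traversal reversal) negates
  exactly the $b_n$ and $c_n$ coefficients.  With `reflect = TRUE`,
  normalization additionally requires the largest-magnitude
  odd-harmonic $b/c$ coefficient to be positive, mapping mirror-image
  pairs (e.g. dorsal vs ventral tracings of the same head) to identical
  vectors.  The flag is off by default: left-right asymmetry can be
  real signal, and whether published analyses mixed dorsal and ventral
  views is not knowable, so both behaviours are first-class.

A `norm_params` record (scale, rotation, phase, reflection, centroid)
accompanies every normalization and inverts it exactly
(`efa_denormalize`), so no information is discarded.

### What a round trip can and cannot promise

`efa_decompose` followed by `efa_reconstruct` is not an exact identity
at finite harmonic count: the truncated series traces the outline at
non-constant speed, so re-decomposing the reconstruction re-parametrizes
by arc length and perturbs coefficients at second order in the shape's
deviation from a circle (about $10^{-6}$ for a 1%-perturbed circle,
about $10^{-2}$ for a strongly sculptured larval outline).  The tests
assert the mathematically guaranteed properties instead: the round trip
contracts under iteration, and pointwise reconstruction error is
monotone non-increasing in the harmonic count.

The same arc-length geometry limits `resample_contour`: equal-arc
resampling of a polygon cuts corners, so repeating it moves points by an
amount that shrinks roughly linearly with the point count rather than
being exactly idempotent.  The square at $n$ divisible by 4 is exactly
idempotent; the general case is asserted as monotone convergence.

## Morphospace construction

PCA is performed on the covariance matrix of the normalized coefficient
rows — not the correlation matrix, because after normalization all
coefficients share one scale and rescaling them would inflate the noise
harmonics.  The constant columns $a_1, b_1, c_1$ are dropped before the
decomposition and reinserted on reconstruction.  The eigendecomposition
uses the deterministic symmetric solver, and each eigenvector's sign is
fixed by making its largest-magnitude loading positive, so repeated runs
are bit-identical.

**Effective components.**  Two selection rules are provided.  The
default, `proportion_ge(0.02)`, retains every component explaining at
least 2% of total variance; applied to the published per-component
percentages of the head-with-stylets analysis
(52.5/24.8/7.5/3.9/3.0/2.5%) it retains exactly six components, matching
the published count, which is why it is the default.  The
Kaiser–Guttman-style `gt_mean` rule (eigenvalue above the mean) is
offered as the alternative; the criterion actually used by the original
SHAPE-style software is not documented, so the choice is exposed rather
than hidden.

Each of the five structure classes (head with stylets, head capsule,
stylets, body with and without stylets) is fitted as its own
morphospace; no joint fit is attempted, because the five analyses answer
different anatomical questions and mixing them would entangle their
variance budgets.

`reconstruct_along_pc` rebuilds the outline at mean $\pm k$ SD along a
component.  Note one coupling effect: because size is normalized away by
the first-harmonic semi-major axis, a change concentrated in one
anatomical region (e.g. labrum length) also rescales the rest of the
outline slightly; shape change along a PC is therefore *concentrated*
in, not perfectly confined to, the driving region.

## Occupation, overlap and saturation

Disparity is measured in the PC1 × PC2 plane — the plane shown in
published scatterplots — as the area of each epoch's convex hull
(shoelace formula on `chull` vertices).  Convex hulls rather than alpha
shapes match the published figures' shaded regions; alpha shapes would
be a natural extension but are deliberately out of scope.  Hull overlap
uses Sutherland–Hodgman convex clipping, so claims like "the Eocene area
lies entirely inside the modern area" become the testable identity
`overlap(E, M) == area(E)`.

Accumulation curves resample accumulation *orders* (random permutations)
and take hull areas of the growing prefixes; this makes the mean curve
non-decreasing in subset size for every seed, not just in expectation,
and makes the value at $k = n$ exactly the full-group area with a
zero-width interval.  Confidence bands are 2.5/97.5 percentiles of the
resample distribution — no distributional assumption.  The saturation
statistic is the least-squares slope of the mean curve over its final
20%, normalized by the full-group area; a group is labelled saturated
below 0.005 (a reporting label only, configurable).  Bounded score
clouds (uniform square, n = 200) fall well below this threshold while
heavy-tailed clouds (bivariate t, df = 2, n = 60) stay above it — the
logic behind reading a still-rising Cretaceous curve as evidence that
sampling has not yet exhausted the original diversity.

All resampling uses one caller-supplied seed and restores the caller's
RNG state afterwards; no global state leaks.

## The synthetic generator

No outline coordinates are deposited for the real material (only
photographs and redrawn figures), so validation rests on a parametric
generator that emulates head-with-stylets outlines in polar form: a
head-capsule ellipse of configurable width/length aspect, labrum prongs
in the anterior sector, and two stylet lobes.  The six labrum
morphotypes described for these larvae map to prong counts — triangular,
pentagonal and broad carry one increasingly wide apex; trident carries
3 prongs, pentadent 5, and the bifid trident 3 with the middle prong
split (4 local maxima).  Multiplicative radial noise is a low-order
random Fourier perturbation, so contours stay smooth and closed.

Defaults follow the study system: three epochs with specimen counts
64/13/12 (the analysable Cretaceous/Eocene/extant inventory), dispersion
multipliers 3:2:1 so the Cretaceous is the most disparate, and
epoch-specific morphotype mixtures in which the trident/pentadent family
occurs only in the Cretaceous — mirroring the restriction of
trident-bearing larvae to Cretaceous amber.  Base template parameters
were chosen once so that the six morphotypes are cleanly separable in
shape space (nearest-centroid recovery ≥ 99% at low noise), bracketing
the described range from very slender to very broad heads.

Being star-convex by construction, generated outlines cannot
self-intersect — and also cannot reproduce genuinely non-star-shaped
features of real larvae (strongly hooked stylet tips, overlapping
appendages).  Passing the simulation studies therefore demonstrates
that the *pipeline* recovers known structure from smooth star-shaped
outlines; it does not certify digitization of arbitrarily complex real
material.

Each specimen derives its own RNG substream from the cohort seed by
counter, so cohorts are reproducible regardless of generation order.

## Specimen inventory

The packaged table carries all 98 known long-nosed antlion larvae: 52
prior-literature records (12 extant, 12 Eocene, 28 Cretaceous — epoch
and provenance only, since per-specimen details were not republished;
their inventory numbering here is bookkeeping, not historical order) and
46 newly described specimens with repository numbers, body lengths and
labrum morphotypes.  Lengths printed as ranges are stored as midpoints
with an estimate flag; where a measured and an estimated length coexist
the estimate is stored and the measurement kept in the notes.  Nine new
records are excluded from analysis: eight Cretaceous specimens whose
outlines are too concealed, deformed or incomplete to digitize, plus the
first Baltic-amber specimen, known only from a small literature
photograph partly hidden by a bubble — its exclusion, and the assumption
that the second Baltic-amber specimen (photographed at high quality)
enters head-based analyses only, are recorded as assumption flags in the
table's notes.  A checksum file guards the fixture against silent
corruption.

## Problem sizes and numerical choices

Simulation-based tests and the acceptance script run at deliberately
modest sizes — 128-point contours, 12 harmonics, cohorts of ~60–90
specimens, 100-seed ensembles — chosen so the full validation suite
completes in about a minute while every recovery criterion is met with
margin (epoch-area ordering recovered in ≥ 95/100 seeds; the
equal-dispersion null shows no pair preferred in more than ~60/100).
Key tolerances: normalization invariance 1e-9 (observed ~1e-15);
quadrature-oracle agreement 1e-6; hull area vs Monte-Carlo rejection
2%; eigenvalue recovery on a known spectrum ±15%.  Degenerate inputs
are first-class: fewer than three distinct points, zero perimeter or
collinear (zero-area) contours are rejected at ingestion; groups with
fewer than three specimens get area 0 and a degenerate flag rather than
an error; identical-row coefficient matrices yield zero eigenvalues and
zero effective components.

## Known limitations

* Occupation is measured in PC1 × PC2 only; higher-dimensional
  hypervolumes are out of scope.
* Convex hulls overestimate occupation for non-convex point clouds.
* The generator's star-convex shapes cannot probe self-intersecting or
  occluded outlines.
* No statistical test of disparity differences is provided — the
  ordering claims are descriptive, as in the source analyses this
  package generalizes.
* Published per-analysis variance percentages depend on hand-traced
  outlines that are not deposited and are therefore not recomputable;
  only their bookkeeping (component counts under the 2% rule) is
  reproduced.
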