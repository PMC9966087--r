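# larvamorph

Outline morphometrics and morphospace disparity for long-nosed antlion
larvae (Psychopsidae, the silky lacewings).

Fossil insect larvae rarely carry species names, so comparing faunas
across geological time works on shape instead: digitized outlines of
head capsules, stylets and whole bodies are decomposed by elliptic
Fourier analysis (EFA), projected into a principal-component
morphospace, and each epoch's disparity is measured as the area its
specimens occupy there.  `larvamorph` provides that pipeline for the
people who run such analyses — palaeoentomologists and morphometricians
working with amber inclusions and extant material — together with the
statistics needed to interpret it: per-epoch convex-hull areas and
overlaps, old-versus-expanded subset comparisons, and specimen
accumulation (saturation) curves.

## The method in brief

A closed outline parametrized by arc length $t \in [0, T)$ is expanded
per coordinate as

$$x(t) = A_0 + \sum_{n=1}^{N}\Big(a_n \cos\tfrac{2\pi nt}{T} + b_n \sin\tfrac{2\pi nt}{T}\Big),\qquad
y(t) = C_0 + \sum_{n=1}^{N}\Big(c_n \cos\tfrac{2\pi nt}{T} + d_n \sin\tfrac{2\pi nt}{T}\Big),$$

with coefficients computed by exact closed-form sums over polygon
segments.  Normalization by the first-harmonic ellipse removes
position, size, rotation and tracing start ($a_1 = 1$,
$b_1 = c_1 = 0$), after which covariance-matrix PCA yields the
morphospace; components explaining ≥ 2% of variance count as
"effective".  Disparity per group is the shoelace area of the convex
hull in PC1 × PC2; saturation is judged from the normalized tail slope
of a hull-area accumulation curve under resampled accumulation orders.

Because no outline coordinates are deposited for the real material, the
package also ships a parametric generator of antlion-like outlines
(head capsule + labrum prongs + stylet lobes, six labrum morphotypes,
per-epoch dispersion control) that provides ground truth for every
pipeline stage, plus the transcribed 98-specimen inventory of all known
long-nosed antlion larvae.

## Worked example

Simulate a three-epoch cohort under the default study conditions
(64/13/12 specimens, dispersion 3:2:1, trident-type labra confined to
the Cretaceous mixture), run EFA → PCA → occupation:

```r
library(larvamorph)

specimen_counts(load_paper_metadata())
#>             provenance
#> epoch        prior_study this_study
#>   Cretaceous          28         44
#>   Eocene              12          2
#>   extant              12          0

coh    <- generate_cohort(cohort_config(seed = 1, n_points = 128,
                                        n_harmonics = 12))
coefs  <- lapply(coh$contours, function(ct)
            efa_normalize(efa_decompose(ct, 12))$coeffs)
model  <- fit_morphospace(coef_matrix(coefs))
model
#> <morphospace> head_with_stylets | 89 specimens | 5 effective PCs (94.0% variance)

for (o in group_occupation(model$scores, coh$metadata$epoch)) print(o)
#> <occupation> Cretaceous | n = 64 | hull area 0.604
#> <occupation> Eocene | n = 13 | hull area 0.05183
#> <occupation> extant | n = 12 | hull area 0.01579

cret <- model$scores[coh$metadata$epoch == "Cretaceous", ]
saturation_slope(accumulation_curve(cret, n_resamples = 200, seed = 1))$slope
#> [1] 0.001887392
```

The hull areas recover the simulated disparity ordering — Cretaceous
largest, Eocene smaller, extant smallest — and the saturation slope
(fraction of total area still gained per added specimen over the curve's
tail) is far below the 0.005 reporting threshold, as expected for a
bounded synthetic cloud of this size.  `run_pipeline()` wraps the same
chain with TSV/JSON artifacts, figures and a reproducibility manifest;
`plot_morphospace()` draws the PC1 × PC2 scatter with shaded per-epoch
hulls.  A command-line wrapper lives at `inst/cli/larvamorph.R`
(subcommands `simulate` and `run`).

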