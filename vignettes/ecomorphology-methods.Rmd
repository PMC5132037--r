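---
title: "Methods: quantifying trophic ecomorphology in a fish radiation"
author: "ecomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying trophic ecomorphology in a fish radiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecomorph)
```

`ecomorph` implements the quantitative toolkit of an integrated
ecomorphological study design: landmark-based shape analysis of body and
pharyngeal-jaw form, stable-isotope niche metrics, diet statistics,
ancestral reconstruction on a molecular phylogeny, and the
cross-dataset tests that link phenotype, ecology, and genome. This
vignette explains each model, its assumptions, the tunable parameters,
and the numerical and design choices behind the implementation.

## Geometric morphometrics

### Superimposition

Shape is what remains of a landmark configuration after location,
scale, and orientation are removed. `gpa()` performs generalized
Procrustes analysis: every configuration is centred, scaled to unit
centroid size (`centroid_size()`, the root summed squared deviation of
landmarks from their centroid), and rotated onto the running consensus
by the closed-form SVD solution; the consensus is recomputed and the
cycle repeats until it moves by less than `tol` (default `1e-10`,
iteration cap 100; non-convergence is an error rather than a silent
partial fit). Reflections are disallowed throughout — the rotation
determinant is forced to +1 — because a mirror-image "fit" has no
biological meaning for lateral-view photographs. Aligned coordinates
are finally projected orthogonally onto the tangent space at the
consensus so Euclidean operations downstream (PCA, regression,
distance matrices) are consistent with the curved shape space.

Two numerical details matter for reproducibility. First, the output
orientation is made canonical by rotating the solution to the
principal axes of the consensus with a deterministic sign rule, so
results are invariant (to ~1e-8, verified in the tests) to arbitrary
similarity transforms of any input specimen. Second, residual sums of
squares about the consensus are tracked per iteration and are
non-increasing — a property the tests assert rather than assume.

### Allometry

Shape covaries with size in fish. Following standard practice the
pooled allometric component is removed by `regress_shape_on_size()`:
ordinary least squares of every Procrustes coordinate on log10 centroid
size, with the residuals used for all downstream analyses and
`percent_predicted` reporting the variance share explained by size.
Log base 10 is the package default (configurable) to match the log10
conventions used elsewhere in the pipeline (relative gut length). The
regression pools all specimens into a single slope; a per-group
analysis can be had by calling the function on subsets, but the pooled
slope is the default because the study design corrects the combined
sample once before ordination.

### Object symmetry

The lower pharyngeal jaw is a single bilaterally symmetric structure,
so its shape analysis must not count left/right noise as signal.
`symmetric_component()` implements the standard object-symmetry
construction: each configuration is mirrored (x negated), paired
landmark labels are swapped (`symmetry_map()`), GPA is run on the
doubled sample, and the symmetric component of a specimen is the mean
of its aligned original and mirror. The per-specimen distance between
the two copies is returned as an asymmetry score. Distance-based tests
that cannot model paired landmarks should be run after dropping one
member of each pair with `prune_landmarks()`.

### Semilandmarks and bending energy

Outline points on the jaw margin have no point-to-point homology; they
are semilandmarks allowed to slide along the outline during
superimposition. `slide_semilandmarks()` relaxes them against the
sample consensus by the minimum bending energy criterion over a fixed
number of cycles (default 10 in `sliding_scheme()`). Bending energy is
the thin-plate-spline deformation metric built from the kernel
`U(r) = r^2 log(r^2)`; `bending_energy_matrix()` returns the
upper-left block of the inverted bordered TPS system, which is
symmetric positive semidefinite and exactly annihilates affine
deformations. Each sliding cycle is: GPA; consensus becomes the TPS
reference; for every specimen the slide amounts of all semilandmarks
(along unit chords between their two neighbours, recomputed each
cycle; endpoints of open curves anchor to their single neighbour's
chord) are obtained by one closed-form linear solve, since the energy
is quadratic in the slide parameters. Because each cycle starts from
zero displacement, the minimization can never increase energy within a
cycle, and the returned energy trace lets users verify the
across-cycle trajectory. Sliding against the sample consensus (rather
than an external reference) is the package default, matching the
common tool behaviour for outline data.

The spacing and identity of retained semilandmarks is user-supplied:
a typical pharyngeal-jaw scheme digitizes 6 true landmarks plus 22
semilandmarks, slides, then prunes to 6 retained paired semilandmarks
for a 12-landmark dataset (`prune_landmarks()`); the package does not
hard-code any particular retention choice because it depends on the
digitization template.

## Ordination and permutation inference

`pca()` is a covariance-based principal component analysis with a
deterministic sign convention (largest-magnitude loading positive).
`cva()` first truncates to the informative PCA subspace (relative
eigenvalue threshold `1e-12`, since Procrustes shape data have rank at
most 2k−4), then solves the between- vs pooled-within-covariance
eigenproblem. Group separation is reported both as Mahalanobis
distance and as Euclidean distance between means, because the two
answer different questions (within-variance-scaled vs raw
morphospace separation); both get label-permutation p-values and
plain Bonferroni adjustment across pairs.

`npmanova()` implements distance-based permutational MANOVA: the
pseudo-F from sums of squared pairwise distances (total minus within),
with group labels permuted and the +1 correction so p is never zero.
With perfect separation (zero within-group distances) the statistic is
reported as `Inf` and treated as maximally significant, giving the
deterministic minimum p of `1/(n_perm+1)`. Pairwise tables use plain
Bonferroni (multiplication by the number of pairs), the convention of
the distance-based software this mirrors, while `holm_adjust()`
(sequential Bonferroni) is used where step-down adjustment is called
for (gut-length pairwise tests). The default permutation count is
10,000 in the analysis functions that mirror published tables; tests
use smaller counts purely to bound runtime, which affects p-value
resolution, not the statistics.

Equal-frequency ellipses (`equal_frequency_ellipse()`) are Mahalanobis
contours of the sample covariance scaled by the chi-square(2) quantile
at the chosen probability — at 0.9, the ellipse that contains 90% of
the population under bivariate normality, which is the convention for
ordination scatter summaries. Empirical coverage of a large simulated
normal sample is one of the package's acceptance checks
(100,000 points; observed coverage within half a percentage point
of 90%).

## Stable-isotope niche analysis

Isotope ratios are handled in delta notation (`delta_value()`, per
mille against the standard). Because lipid synthesis depletes 13C,
variable lipid content confounds dietary interpretation of raw
delta-13C; `lipid_correct()` applies the standard two-equation
arithmetic normalization driven by the C:N ratio (a lipid proxy):
lipid percentage `L = a / (1 + 1/(b*CN − c))`, then
`d13C' = d13C + D*(I + k1/(1 + k2/L))`. The parameters live in
`lipid_params()` with the published estimates of the fish-muscle
normalization model as documented defaults (`D = 7.018`, `I = 0.048`,
`a = 93`, `b = 0.246`, `c = 0.775`, `k1 = 3.90`, `k2 = 287`): they are
configuration, not constants, because studies may refit them. The
correction is the identity at `D = 0`, strictly monotone in C:N over
the calibrated range, and clamps the lipid percentage into [0, 100]
with a warning outside it.

Preservation effects are checked with paired tests
(`preservation_paired_test()`: paired t plus Wilcoxon signed-rank,
exact for n ≤ 25). No ethanol-preservation correction is applied after
lipid normalization — the design this package follows found the
preservation effect non-significant once lipid-normalized. Baseline
(trophic-level) standardization is deliberately not implemented:
without adequate baseline sampling, cross-site comparisons of absolute
values are not meaningful, so `within_site_tests()` compares species
within sites only (one-way ANOVA per site and element, with small
groups flagged).

The isotopic niche is summarized by the standard ellipse area
(`sea_seac()`: `SEA = pi*sqrt(lambda1*lambda2)` from the covariance
eigenvalues, with the small-sample correction
`SEAc = SEA*(n−1)/(n−2)`), and by pairwise ellipse overlap computed by
numerical polygon intersection (`ellipse_overlap()`, Sutherland–
Hodgman clipping of 720-vertex boundary polygons; relative
discretization error well below 1%). `isotopic_distance_matrix()`
treats (corrected delta-13C, delta-15N) as Cartesian coordinates, the
representation used by the Mantel stages.

## Diet and trait statistics

Stomach compositions are six percent-by-volume categories
(`diet_categories`); rows summing within [95, 105] are renormalized to
100, anything further off is rejected as a data error. Overlap uses
Schoener's index (`schoener_overlap()`,
`D = 1 − 0.5*sum(|p−q|)/100`), with `D > 0.6` flagged as substantial
by convention. Relative gut length is `log10(gut)/log10(SL)`;
`gut_model_comparison()` fits linear, exponential, logarithmic, and
quadratic mean functions for gut length with Gaussian error on a
common response scale and ranks them by small-sample AIC — AICc is the
package's documented choice where the underlying design says only that
simpler models fitted "as well or better", and "polynomial" is
interpreted as quadratic (the lowest-order nonlinearity). Model
ranking is invariant to length-unit rescaling, which the tests assert.
Gill-raker counts get a Pearson correlation against standard length
(size independence) and a one-way ANOVA across species
(`raker_tests()`).

## Phylogenetic comparative methods

Trees are `ape::phylo` objects read through `read_newick()` with
validation (single rooted tree, labelled tips, complete nonnegative
branch lengths). `prune_to_taxa()` takes the induced subtree with
additive collapsing of unifurcations, preserving root-to-tip path
lengths.

Ancestral shape reconstruction uses weighted squared-change parsimony
(`squared_change_parsimony()`): internal states minimize the sum over
branches of squared state change divided by branch length — squared
change weighted by the molecular change on each branch — solved as the
graph-Laplacian linear system, independently per trait dimension
(the criterion is separable, so multivariate traits need no
evolutionary covariance matrix). This solution is point-identical to
the Brownian-motion generalized-least-squares estimates, which the
test suite verifies against both a generic numerical minimizer and an
independent BM maximum-likelihood implementation. Zero-length branches
are replaced by `1e-8` times tree height to keep weights finite (and
the replacement reported); the solution is invariant to uniform
branch-length rescaling.

Uncertainty is summarized by `phenogram95()`: the BM rate `sigma2` is
estimated by REML (default; ML selectable) — REML is preferred for its
smaller small-sample bias, and the choice is exposed because either
could stand behind a published phenogram. Node conditional variances
come from the GLS formulation including the uncertainty of the
estimated root state, and the 95% interval is the state ±1.96 standard
deviations, plotted against node height. `phylomorphospace()` places
internal nodes in a 2-D ordination by the same solver and reports tree
edges as coordinate pairs.

## Integration

`two_block_pls()` is the SVD of the cross-covariance between two
column-centred blocks; per-axis strength is the correlation of paired
scores, tested by permuting specimen rows of the second block.
`mantel_test()` and `partial_mantel()` correlate lower-triangle
vectors of labeled distance matrices, permuting rows and columns of
the first matrix simultaneously; the partial variant residualizes both
tested matrices on the control by OLS and permutes the residualized
matrix. One-tailed positive association is the default (the usual
question is whether distances covary positively); a two-sided option
exists. `scale_to_unit()` divides by the maximum off-diagonal entry,
the convention for plotting morphological against genomic distances on
one axis.

SNP handling is deliberately simple and deterministic: `filter_snps()`
drops loci with missing genotypes, then keeps loci in a greedy
left-to-right walk per chromosome subject to a minimum physical
spacing (default 500 kb) — deterministic thinning is reproducible and
matches a "minimum distance between sites" rule exactly.
`genotype_pca()` centres the dosage matrix without scaling by default
(the common visualization convention; scaling is a flag). Pairwise
differentiation uses the Hudson estimator combined as a ratio of
averages across loci (`pairwise_fst()`), chosen for robustness to rare
alleles and unequal sample sizes; since any consistent estimator
serves the downstream Mantel stage, the raw (possibly slightly
negative) values are preserved as an attribute while the distance
matrix floors them at zero. A spherical-law-of-cosines great-circle
helper builds the geographic control matrix.

## The synthetic-data generator

No specimen data ship with the package; `sim_config()` and the
`simulate_*()` functions generate inputs with the statistical
structure the analyses assume, so the full pipeline is exercisable and
testable end to end. The defaults describe the study-like conditions
used throughout the tests, chosen once on biological grounds:

* **Landmarks** (`simulate_landmarks()`): a fixed 16-point fish
  template (`fish_template()`, an explicit coordinate constant), three
  species with mean-shape offsets of 0.05 Procrustes units in distinct
  mouth/body directions, landmark noise sd 0.01, n = 30 per group, and
  an allometry vector of norm 0.15 per log10 size unit over sizes
  10^1.6–10^2.2 mm. Offset and allometry directions are projected into
  pure shape space (orthogonal to translation and scaling of the
  template) so the planted quantities are exactly what superimposition
  can recover. Each specimen is then randomly rotated, translated, and
  scaled so GPA has real work to do.
* **Isotopes** (`simulate_isotopes()`): bivariate-normal niches, one
  species shifted in delta-13C only (−14 vs −20/−21 per mille, sd 1.5)
  with delta-15N shared (8.0 per mille, sd 0.8), n = 15 per species —
  the single-trophic-level, different-carbon-source geometry. C:N is
  3.2 (a lipid-free muscle floor) plus a gamma-distributed excess, and
  the raw delta-13C is back-computed through the inverse lipid
  correction so the corrected values match the drawn targets exactly.
* **Diet** (`simulate_diet()`): Dirichlet compositions with one
  cellulose-dominated species (43% plant / 30% algae pattern) against
  algae-dominated species (70–77% algae), concentration scaled so
  within-group variation is realistic for ~30 stomachs.
* **Traits on trees** (`simulate_bm()`): exact recursive BM.
* **Genotypes** (`simulate_genotypes()`): Balding–Nichols population
  structure (drift 0.1 per population by default), dosage genotypes,
  and locus positions with ~100 kb jitter so physical thinning has
  work to do.

Every generator is bit-reproducible given (seed, config); each forks a
deterministic sub-seed from the global seed under a fixed label, so
adding one generator never perturbs another's draws.

What the generators do **not** emulate: digitization error structure
(landmark noise is isotropic and independent, real digitization error
is not), within-species population structure in shape, isotope
baseline gradients across sites, linkage disequilibrium beyond
physical spacing, and any selection signal in the genotypes. Passing
tests on synthetic data therefore demonstrate that the estimators
recover what they claim under the stated models — not that real data
satisfy those models.

## Problem sizes and calibration checks

The test suite verifies, at sizes chosen to keep a full run in a few
minutes: type-I error of NPMANOVA, Mantel, and within-site ANOVA at
the nominal 5% over 500 null simulations (binomial 95% band); ≥95%
NPMANOVA detection of the planted 0.05-unit shape offsets over 100
simulated datasets; recovery of the planted allometry direction
(cosine > 0.95 at n = 100); BM rate recovery within 10% (500 REML
replicates on an 8-taxon tree); partial-Mantel recovery of a planted
partial correlation within 0.05; and the delta-13C-only niche
separation pattern in ≥90% of 200 runs. Exact checks cover the
12-landmark pruning bookkeeping, the 500 kb thinning walk, Schoener
and Holm arithmetic, the Hudson estimator, and closed-form phenogram
variances on a 3-taxon tree.

## Known limitations

Two-dimensional landmarks only; no Procrustes ANOVA of fluctuating
asymmetry; no parametric MANOVA; no Bayesian ellipse estimation or
isotope mixing models; no OU or multi-rate trait models; no
r²-based linkage pruning; and tree inference is out of scope — the
phylogeny is always an input.
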