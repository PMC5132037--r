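# ecomorph

Quantitative toolkit for trophic ecomorphology in fish adaptive
radiations — the kind of integrated study where landmark-based
morphometrics, stable-isotope niches, diet tables, a molecular
phylogeny, and population genomics are brought to bear on the same set
of species to ask whether ecological niche partitioning drives
morphological divergence. It is written for evolutionary ecologists
who need every stage of that pipeline reproducible in one place, from
raw TPS landmark files to the Mantel test linking shape to F\_ST.

## What it computes

* **Geometric morphometrics** — generalized Procrustes analysis
  (centring, unit centroid-size scaling, SVD rotations without
  reflection, tangent projection), object symmetry for bilaterally
  symmetric structures, thin-plate-spline bending energy
  (`U(r) = r² log r²`) with sliding semilandmarks by the minimum
  bending energy criterion, and allometric correction by OLS of
  Procrustes coordinates on log₁₀ centroid size.
* **Ordination and permutation inference** — covariance PCA, CVA with
  Mahalanobis distances (`D² = (m₁−m₂)ᵀ W⁻¹ (m₁−m₂)`), distance-based
  NPMANOVA (pseudo-F from sums of squared pairwise distances, label
  permutation with the +1 correction), equal-frequency ellipses at
  probability *p* via the χ²₂ quantile.
* **Isotope niches** — δ notation, C:N-driven arithmetic lipid
  normalization of δ¹³C, paired preservation tests, within-site
  ANOVAs, standard ellipse areas `SEA = π√(λ₁λ₂)` with the
  small-sample correction `SEAc = SEA·(n−1)/(n−2)`, ellipse overlap by
  polygon intersection, Euclidean isotopic distance matrices.
* **Diet and traits** — Schoener's overlap
  `D = 1 − ½Σ|pᵢ−qᵢ|/100`, composition summaries, relative gut length
  `log₁₀(gut)/log₁₀(SL)` with AICc model comparison, gill-raker tests.
* **Phylogenetic comparative methods** — tree pruning, ancestral
  states by squared-change parsimony weighted by branch lengths
  (minimizing `Σ (Δstate)²/length`, identical to Brownian-motion GLS
  estimates), 95% phenograms with REML-estimated σ², phylomorphospace
  projection.
* **Integration** — two-block PLS of shape against isotopes, simple
  and partial Mantel tests, distance scaling to unit maximum, greedy
  500 kb SNP thinning, genotype PCA, Hudson-estimator pairwise F\_ST.
* **Synthetic data** — seeded generators (landmarks with planted shape
  offsets and allometry, bivariate-normal isotope niches separated in
  δ¹³C only, Dirichlet diets, Brownian traits, Balding–Nichols
  genotypes) so the whole pipeline runs with no specimen data.

## Worked example

Three simulated sympatric species, end to end:

```r
library(ecomorph)
cfg <- sim_config(seed = 42)

## 1. body shape: superimpose, size-correct, test species separation
shapes  <- simulate_landmarks(cfg)
aligned <- gpa(shapes)
sizecor <- regress_shape_on_size(aligned)
print(sizecor)
#> Shape ~ log centroid size: 90 specimens; 15.19% of shape variance
#> predicted by size
set.seed(42)
shape_test <- npmanova(as.matrix(dist(sizecor$residuals)),
                       shapes$records$species, n_perm = 999)
cat(sprintf("body shape NPMANOVA: F = %.2f, p = %.4g\n",
            shape_test$statistic, shape_test$p_value))
#> body shape NPMANOVA: F = 25.15, p = 0.001

## 2. isotopes: lipid-correct, niche ellipses, within-site ANOVA
iso <- lipid_correct(simulate_isotopes(cfg))
niche_ellipses(iso)$areas
#>           group  n      sea     seac
#> 1   sp_alcalica 15 4.116157 4.432785
#> 2 sp_latilabris 15 4.193198 4.515752
#> 3  sp_ndalalani 15 4.415638 4.755303
within_site_tests(iso)[, c("site", "element", "F", "p")]
#>     site        element           F            p
#> 1 site05 d13C_corrected 101.2955878 8.530581e-17
#> 2 site05           d15N   0.4244763 6.568870e-01

## 3. diet overlap between species mean compositions
round(schoener_matrix(simulate_diet(cfg)), 2)
#>               sp_alcalica sp_latilabris sp_ndalalani
#> sp_alcalica          1.00          0.52         0.50
#> sp_latilabris        0.52          1.00         0.91
#> sp_ndalalani         0.50          0.91         1.00
```

Reading the output: size explains ~15% of shape variance and is
removed before testing; the NPMANOVA pseudo-F of 25 at the minimum
attainable permutation p (0.001 with 999 permutations) says the three
species occupy distinct regions of size-corrected morphospace. The
isotope ANOVAs show the planted niche structure — species differ
strongly in δ¹³C (carbon source) but not δ¹⁵N (trophic level) — and
Schoener's index flags substantial dietary overlap (0.91 > 0.6) only
between the two algae-dominated species, while the cellulose-feeder
overlaps neither (≈0.5).

See the methods vignette (`vignettes/ecomorphology-methods.Rmd`) for
the models, parameter defaults, and design decisions, and `?gpa`,
`?slide_semilandmarks`, `?squared_change_parsimony`, `?pairwise_fst`
etc. for per-function detail.

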