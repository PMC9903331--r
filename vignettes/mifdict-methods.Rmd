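---
title: "Discriminative dictionary learning for mIF point patterns: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative dictionary learning for mIF point patterns: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mifdict)
```

This vignette records the models behind `mifdict`, the assumptions they
make, and the design decisions taken where more than one reasonable
implementation exists.  It states no empirical results beyond what the test
suite and `scripts/acceptance.R` compute.

## 1. From cell tables to composite images

The input is one row per cell: position in microns, a phenotype label from
a fixed panel (default Epithelial, CTL, HelperT, Treg, APC), and image,
subject and class identifiers.  Each phenotype's cells in one image form a
spatial point pattern in a rectangular window.

`estimate_intensity()` turns a pattern into a gridded intensity surface
(points per µm²) using an isotropic Gaussian kernel evaluated at cell
centers and truncated at 4σ (truncation error below 1e−4 of kernel mass,
negligible against the 1% mass tolerance we test).  Assumptions: the
window is fully observed, and smoothing at a single global bandwidth is
appropriate — there is no adaptive or anisotropic estimation.

**Edge correction.**  Two standard corrections are implemented.  The
default, per-point (Diggle) correction, divides each cell's kernel by the
kernel mass falling inside the window at that cell's location; it conserves
total mass (sum × cell area ≈ cell count) exactly up to grid
discretization, which is the property the patch filter and the ℓ2
objective downstream implicitly rely on.  The per-location ("uniform")
correction — dividing each grid cell's estimate by the in-window kernel
mass centered at that cell — is also available, but it over- or
under-restores mass by a few percent for points near corners at moderate
bandwidths, so it is not the default.

**Bandwidth.**  Default σ = 1.5 grid cells (30 µm at the default 20 µm cell
size).  Smaller bandwidths approach binned counts and make the
low-intensity patch filter aggressive; larger ones blur the sub-patch
co-localization structure the dictionary is supposed to capture.  The
value is a configuration parameter, not an estimate.

**Grid.**  Default 70 rows × 50 columns regardless of window size, with the
cell size fitted to the window (`grid_for_window()`), so composites from
any cohort share one shape, `70 × 50 × c`.  Rows run along y with row 1 at
the bottom edge; values are sampled at cell centers.  Channels are stacked
in the declared phenotype order for every image of a cohort
(`build_composite()` enforces it), because the learner treats channel
index as meaningful.

No cross-channel normalization is applied by default: surfaces are kept in
physical units, so abundant phenotypes legitimately carry more ℓ2 weight.
An optional per-channel max normalization (`normalize_channels = TRUE`)
exists for panels where a dominant channel should not drown the rest; it
changes the objective's geometry and is therefore off unless requested.

## 2. Patches

`extract_patches()` takes every `n × n × c` block whose origin lies on a
stride lattice and that fits inside the image (no padding — padding would
inject zeros that interact with the emptiness filter).  Defaults `n = 20`,
stride 10, i.e. 50% overlap; the stride is a free parameter since only
"reasonable overlap" is required by the method.

A patch is dropped iff **strictly more than** 70% of its `n²c` values fall
below 1e−15; the boundary case (exactly 70%) is kept, and the rule is
applied identically before training and before test-time scoring.
Vectorization order is fixed and documented — channel slowest, row-major
within a channel — with `unvectorize_patch()` its exact inverse; any fixed
order gives identical classification, but the inverse must match for atom
visualization and the correlation stage.

## 3. The discriminative objective

For class matrices `Y` (own, N columns) and `Ȳ` (other), a dictionary `D`
with k unit-norm atoms minimizes

\[
\frac{1}{N}\min_{\|S\|_0\le L}\|Y-DS\|_F^2
\;-\;\frac{\rho}{N}\min_{\|\bar S\|_0\le L}\|\bar Y-D\bar S\|_F^2 .
\]

Both terms are divided by N — the printed form of the objective.  The
original DFDL formulation divides the second term by the other class's own
count; `normalize_by_own_N = TRUE` restores that behavior, which matters
when class sizes are very unbalanced (the default couples ρ's meaning to
the class ratio).

**Sparse coding.**  OMP with the ℓ0 constraint matches the objective as
written and is the default coder everywhere (training, classification,
activity analysis).  It is implemented in C++ (RcppArmadillo) as batch OMP
with a precomputed Gram matrix; at `L = 1` it provably coincides with
exhaustive single-atom least squares, which the tests exploit as an exact
oracle.  An experimental ℓ1 (lasso) coder behind the same interface
(`coder = "lasso"`, glmnet path with a least-squares refit on the support)
is available but off by default: its solutions are not ℓ0-constrained and
the two coders' codes are not interchangeable.

**Dictionary update.**  With codes fixed, the quadratic surrogate has
statistics `E = (1/N)·Y·Sᵀ − (ρ/N)·Ȳ·S̄ᵀ` and `F = (1/N)·S·Sᵀ −
(ρ/N)·S̄·S̄ᵀ`; atom j moves to `(e_j − D f_j + d_j F_jj)/F_jj`, then is
renormalized.  Because the discriminative term can make `F` indefinite, an
atom is updated only when `F_jj > δ` (default 1e−8); otherwise it is left
unchanged.  Atoms no in-class code selects in an iteration are re-seeded
from the worst-reconstructed in-class column — standard dictionary-learning
hygiene, and an addition relative to the bare update equations.
Initialization takes k distinct in-class columns chosen by the seed.  With
ρ = 0 the procedure is classical alternating minimization and the tests
assert its descent property; with ρ > 0 monotone descent is not guaranteed
(the coding step optimizes each term separately), so the stopping rule is
relative objective change below `rel_tol` (default 1e−4) or `max_iters`
(default 30).

**Defaults** k = 50 atoms per class and `L = 5`, `ρ = 0.1`: k matches the
100-atom combined dictionary the classification design assumes; `L` is a
deliberate choice in the absence of a published value (codes stay
interpretable and coding stays fast, and classification quality was not
sensitive to it in the tested range); ρ = 0.1 keeps reconstruction
dominant, with the grid {0.01, 0.05, 0.1, 0.5} worth scanning by inner
validation on new data.

## 4. Classification and evaluation

A test patch coded against `[D1 | D2]` is split into halves; ε_i is the
**squared** ℓ2 norm of `y − D_i S_i` (the residual is a vector; the scalar
compared is its squared norm, the standard reading), and ties break to
class 1, deterministically.  θ is the fraction of an entity's patches
labeled class 1 — an image's own patches, or all patches of all of a
subject's images pooled.  Entities left with no surviving patches are
excluded from metrics with a warning.

AUC is the rank/Mann–Whitney statistic on θ with ties credited 0.5.
Sensitivity and specificity use the θ ≥ 0.5 rule by default (no threshold
is canonical for this method), and the Youden-optimal operating point is
reported alongside.  Cross-validation is stratified over entities; in
subject mode all of a subject's images travel together, and the
no-subject-leakage property is asserted inside every fold.  Per-fold
metrics are summarized by their mean and min–max range (k small makes a
range more honest than a parametric interval).  k = 5 (80–20) is the
default; any k ≥ 2 that leaves both classes in every fold is accepted.

## 5. Atom interpretability

Every patch is coded against the combined dictionary; per-atom code values
are normalized across patches by the maximum absolute value — a
sign-preserving choice, so the subsequent binarization (active iff the
coefficient is strictly positive; zero and negative codes are inactive,
negative coefficients describing poorly represented bases) is unaffected
by the normalization constant.

**Atom selection.**  The natural "paired" comparison is not available —
the two classes contain different images — so significance is a per-atom
two-sample (Welch) t-test comparing per-image activation proportions
between the atom's own-class images and other-class images, both coded
against the same combined dictionary.  An atom is selected iff p < α
(default 0.05) and its own-class mean activation is the larger; the sign
and size of t order atoms by how class-specific they are.

**Spatially weighted partial correlation.**  Each selected atom is
reshaped to `n × n × c`; pixel i receives weight
\(w_i \propto \sum_j \exp(-\|x_i-x_j\|^2/\sigma^2)\) — the row sums of the
Gaussian kernel over the pixel lattice (computed separably), so central
pixels dominate and the weighted covariance is automatically positive
semidefinite, which the cross-pixel double-sum alternative does not
guarantee.  Default σ = n/2 cells.  Partial correlations come from the
normalized inverse of the weighted channel covariance; when the covariance
is near-singular it is shrunk toward its diagonal with the smallest
shrinkage in {1e−4, …, 0.1} that makes it invertible.  Constant channels
are reported as NA and excluded from downstream counts.  P-values are
two-sided permutation p-values (default 999 permutations, seeded),
permuting pixel assignments independently per channel: under spatial
weighting the effective sample size is far below the pixel count, so no
analytic null is appropriate.

Per class, the proportion of selected atoms in which a phenotype pair is
correlated (p < α) is compared between classes with the pooled
two-proportion z statistic and a two-sided normal p-value.  Raw p < 0.05
is the default throughout, matching the method's convention;
Benjamini–Hochberg is available via `stats::p.adjust` on the returned
tables if a user prefers FDR control across the 10 pairs.

## 6. The synthetic cohort generator

The simulator emulates exactly the statistical structure the pipeline
consumes: two classes of subjects, 1–20 images each, per-phenotype
homogeneous Poisson baselines, optional per-subject log-normal intensity
multipliers, and planted cross-phenotype coupling — a fraction of one
phenotype's points relocated to Gaussian offsets (sd
`offspring_dispersion_um`) around uniformly chosen parent points, with
out-of-window offsets resampled so per-phenotype counts are exactly
Poisson (an edge-deletion scheme would confound the edge-correction
tests).  `empirical_cross_coupling()` is the generator's own oracle: the
mean count of offspring points within r of parent points (minus-sampled to
kill border bias), normalized by the CSR expectation; its planted excess
is `frac · P(offset < r) / (λ_parent π r²)`.

Default study conditions: 20 subjects per class, 2 images per subject
(matching a TMA-style cohort of one to three cores per patient), a
1000 × 1400 µm window so the 70 × 50 grid has 20 µm cells, Epithelial
2·10⁻³ points/µm² with a sparser immune infiltrate (CTL and HelperT
8·10⁻⁴, APC 6·10⁻⁴, Treg 4·10⁻⁴), offspring dispersion 20 µm, and one
planted coupling (CTL → HelperT, 0.8 in class 1 only) as the class
difference.  These values were fixed once as a realistic dense-tissue
regime and drive both the acceptance tests and `scripts/acceptance.R`.

**What passing tests do and do not show.**  The generator produces
stationary Poisson/Thomas-like patterns with exactly known structure; real
mIF data adds segmentation and phenotyping error, tissue-scale intensity
gradients, holes and tears in the window, batch effects between slides,
and marker-intensity information the pipeline deliberately ignores.
Recovery of planted couplings here demonstrates the machinery is correct
and sensitive, not that any particular clinical effect size is detectable.

## 7. Numerical choices, degenerate inputs, problem sizes

* OMP stops early when the squared residual falls below (1e−10)²; repeated
  atom selection (a numerical-tie symptom) terminates the pursuit.
* All-zero initial atoms (possible when a sampled patch column is zero)
  are replaced by seeded random unit vectors; zero columns at coding time
  produce zero codes, residual = ‖y‖.
* Ties in the residual rule go to class 1; ties in AUC ranks are credited
  0.5; the Youden threshold search scans observed scores plus {0, 1, 1⁺}.
* One global seed drives every stochastic step; stage- and fold-specific
  seeds are derived as `(seed·7919 + offset) mod (2³¹ − 61)` so derived
  seeds stay valid 32-bit integers and stages are independently
  reproducible.
* Problem sizes used by the shipped tests and acceptance script: cohorts
  of 20 subjects per class × 2 images (≈1,900 surviving patches of
  dimension 2000), 5-fold CV, 50 + 50 atoms, 999 permutations per atom for
  the correlation p-values; the property suites run on deliberately small
  grids and dictionaries.  These sizes were chosen so a complete run is
  comfortable on a single CPU while keeping fold-level metrics meaningful.

## 8. Known limitations

* Patch-level class posterior is reduced to a vote (θ); residual margins
  are discarded after labeling.
* The t-test on per-image activation proportions treats images as
  independent even when a subject contributes several.
* Permutation p-values are granular at 1/(B+1); with B = 999 the smallest
  attainable p is 0.001.
* The lasso coder is a contract-compatible alternative, not an equivalent
  reimplementation of a path-wise ℓ1 solver's internals.
* Serialization uses CSV/JSON for tables and RDS for arrays and fitted
  objects; no HDF5 or TIFF export is provided.
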