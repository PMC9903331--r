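# mifdict

Interpretable two-class classification of multiplexed immunofluorescence
(mIF) tissue images, using only cell positions and phenotype labels.

Modern mIF panels give every segmented cell an (x, y) position and a
phenotype label (here: Epithelial/PanCK+, cytotoxic T lymphocytes, helper T
cells, regulatory T cells, antigen presenting cells).  Deep classifiers on
such data tend to be black boxes.  `mifdict` instead learns a *dictionary*
of prototype tissue patches per class: classification comes from which
class's prototypes reconstruct a patch better, and the prototypes themselves
can be inspected for the phenotype co-localization patterns that distinguish
the classes — for example, which pairs of immune phenotypes are spatially
coupled in responders versus non-responders to a therapy.

## The method

1. **Intensity surfaces.** Each phenotype's point pattern in an image is
   smoothed into a kernel intensity surface \(\hat\lambda(u)\) (isotropic
   Gaussian kernel, Diggle edge correction) on an `l x m` grid, and the `c`
   per-phenotype surfaces are stacked into an `l x m x c` composite image
   (default `70 x 50 x 5`).
2. **Patches.** Overlapping `n x n x c` patches (default `20 x 20 x 5`,
   stride 10) are extracted; near-empty patches (more than 70% of values
   below 1e-15) are dropped; survivors are vectorized to columns
   (`d = n^2 c = 2000`).
3. **Discriminative dictionary learning.** For each class a dictionary
   `D` (d x k, unit-norm atoms, default k = 50) minimizes

   ```
   (1/N)  min_{||S||_0 <= L} || Y    - D S    ||_F^2
   - (rho/N) min_{||S||_0 <= L} || Ybar - D Sbar ||_F^2
   ```

   so atoms reconstruct own-class patches well (first term) and other-class
   patches poorly (second term, weighted by `rho`).  Optimization
   alternates batch orthogonal matching pursuit (OMP, `L` nonzeros per
   code) with a block-coordinate atom update.
4. **Classification.** A test patch is coded against the concatenated
   dictionary `[D1 | D2]`; the code is split into class halves and the
   patch takes the class with the smaller squared reconstruction residual.
   An image's (or subject's) score is `theta`, the fraction of its patches
   labeled class 1; entity-level AUC, sensitivity and specificity come from
   grouped cross-validation in which a subject's images never straddle the
   train/test split.
5. **Atom interpretability.** Every patch's sparse code is binarized
   (active iff the coefficient is positive); atoms whose per-image
   activation is significantly higher in their own class (t-test, p < 0.05)
   are retained, reshaped back to `n x n x c` blocks, and each phenotype
   pair is tested for spatially weighted partial correlation (Gaussian
   kernel pixel weights, permutation p-values).  Per-pair proportions of
   correlated atoms are compared between classes with a pooled
   two-proportion z-test.

Because clinical cohorts of this kind are rarely shareable, the package
ships a seeded simulator (`simulate_cohort()`) producing two-class cohorts
of multi-phenotype point patterns with controllable per-class intensities
and cross-phenotype coupling (a fraction of one phenotype's cells placed as
Gaussian offspring of another's).

## Worked example

```r
library(mifdict)

spec <- cohort_spec(
  n_subjects_per_class = 10, images_per_subject = 2,
  coupling = tibble::tibble(class = 1L, parent = "CTL",
                            offspring = "HelperT", frac = 0.8),
  seed = 42)
cells <- simulate_cohort(spec)

cv <- cross_validate(cells, config = dfdl_config(seed = 42), k = 5, seed = 42)
glance(cv)
#> # A tibble: 1 × 7
#>   mode        k auc_mean auc_min auc_max sensitivity_mean specificity_mean
#>   <chr>   <int>    <dbl>   <dbl>   <dbl>            <dbl>            <dbl>
#> 1 subject     5    0.825     0.5       1              0.7              0.6
```

The two classes share identical per-phenotype abundances and differ only in
a planted spatial coupling (80% of helper T cells sit within ~20 um of a
CTL in class 1); 5-fold subject-grouped cross-validation on this small
cohort recovers that difference with a mean subject-level AUC of 0.825
(fold range 0.5–1 — folds hold only 2 test subjects per class, so per-fold
AUC is coarse).  Larger cohorts (20 subjects per class) reach mean AUCs
above 0.9; `autoplot(cv)` shows the per-subject theta scores, and
`analyze_atoms()` returns the significant-atom table and the per-pair
correlated-atom proportions with their between-class z-tests.

A full pipeline run (simulate → train → evaluate → atoms → report) is one
call, or one shell command via the bundled CLI:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "mifdict"),
             outdir = "demo_run")
```

```sh
Rscript inst/scripts/mifdict run --config inst/extdata/demo_config.yaml \
    --outdir demo_run
```

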