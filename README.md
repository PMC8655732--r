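# fmfs — Federated Morphometry Feature Selection

`fmfs` identifies which patches of a registered anatomical surface are
associated with a continuous pathology measure, when the subjects are spread
across institutions that cannot pool row-level data.  It was designed for
hippocampal surface morphometry: every subject carries two scalar fields on
one or two 100 × 150 vertex grids — radial distance (RD, local thickness
relative to the medial axis) and tensor-based morphometry (TBM, the
determinant of the registration Jacobian, i.e. local areal expansion or
atrophy) — and a response such as an amyloid centiloid or a regional tau
SUVR.  The intended users are neuroimaging statisticians who want
vertex-level associations with the statistical stability of grouped sparse
regression, without centralizing multi-site data.

## The model

Each surface is tiled into non-overlapping 2 × 3 vertex patches; the RD
values of a patch form one feature group, the TBM values another (2,500
patches and 5,000 groups per hemisphere; 60,000 features over both
hemispheres).  Feature selection is a group LASSO:

    min_beta  1/2 || y - sum_g X_g beta_g ||_2^2  +  lambda sum_g w_g ||beta_g||_2

with w_g = sqrt(p_g) by default, so whole patches enter or leave the model
together.  Three components make this practical and federated:

- **FBCD** (federated block coordinate descent): the objective decomposes
  over institutions' row blocks, so each proximal block update needs only
  the sum of per-site partial gradients `(X_g^i)' (X^i beta - y^i)`.  Sites
  exchange `p_g`-length aggregates and small Gram blocks — never subject
  rows (the "local query model").  Steps use the blockwise Lipschitz
  constant (largest eigenvalue of the aggregated group Gram), which
  guarantees monotone descent.
- **Federated safe screening**: along a decreasing regularization path
  anchored at `lambda_max = max_g ||X_g' y||_2 / w_g`, a dual-polytope
  projection test (EDPP family) discards groups that are provably zero at
  the next path point before solving.  All the test's inner products are
  sums of per-site terms.  Discards are *safe*: the retained set is a
  superset of the true active set, so the screened path equals the
  unscreened one while doing a small fraction of its work.
- **Stability selection**: solving at a grid of `lambda` values (default
  100 values from 1.0 to 0.1 of `lambda_max`) and counting how often each
  vertex's RD/TBM coefficients are nonzero yields a per-vertex selection
  frequency, normalized to 0–100, smoothed with a 2 × 3 averaging filter,
  and used to rank vertices.  The top-ranked vertices define an ROI whose
  frequency-weighted RD/TBM sums reduce (by PCA) to one scalar biomarker
  per subject.

## Worked example

```r
library(fmfs)

# a synthetic five-institution cohort: two 10 x 15 grids, 3 planted
# predictive patch groups, per-subject z-scored smooth fields
co <- generate_cohort(n_subjects = 100, grid_rows = 10, grid_cols = 15,
                      n_true_patches = 3, effect_scale = 1, noise_sd = 1,
                      n_sites = 3, seed = 5)
co$design
#> <grouped_design> 100 subjects x 600 features in 100 groups
#>   grid: left 10 x 15
#>   grid: right 10 x 15

path <- solve_path(co$shards, co$design$groups,
                   lambda_grid(1, 0.1, 20), solver_config(tol = 1e-9))
path
#> <lambda_path> 20 values in [0.1, 1] x lambda_max = 127.6; screening on
#>   retained groups: 2 .. 100; active at last value: 15; 6088 group updates

map <- smooth_map(count_selection(path, co$design))
head(patch_frequency(map, co$design), 4)
#>    hemisphere patch_row patch_col frequency
#> 50      right         4         4      50.0
#> 6        left         1         0      47.5
#> 12      left         2         1      32.5
#> 23      left         4         2      10.0

co$truth$patches   # the planted patches are the top-ranked ones
#>   hemisphere feature_type patch_row patch_col
#> 1       left           RD         1         0
#> 2       left          TBM         2         1
#> 3      right          TBM         4         4
```

The `frequency` column is the stability-selection score (0–100): the share
of (lambda, feature-type) pairs along the path in which the patch's
vertices carried nonzero coefficients.  The three planted patches rank
first.  `rank_and_select(map, top_k)` turns the map into an ROI feature
list, and `roi_scalar()` into a per-subject scalar; `export_map()` writes
the map as TSV or an ASCII PLY surface for rendering.

A thin command-line wrapper drives the same pipeline from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","fmfs.R",package="fmfs"))')" \
    simulate --subjects 200 --sites 5 --true-patches 10 --seed 42 -o fixture/
# ... select --matrix fixture/matrix.tsv --groups fixture/groups.tsv \
#            --response fixture/response.tsv --sites-file fixture/sites.tsv -o out/
```

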