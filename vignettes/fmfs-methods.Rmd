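---
title: "Federated morphometry feature selection: model, screening, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated morphometry feature selection: model, screening, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains what `fmfs` computes, the assumptions behind each
stage, the tunable parameters and the defaults we chose, and the limits of
what the synthetic test bed can show.

## The regression model

Subjects carry two scalar morphometry fields — radial distance (RD) and
tensor-based morphometry (TBM) — sampled on one or two registered
100 × 150 vertex grids.  Registration is assumed done: vertex `v` means the
same anatomical location for every subject, so a column of the feature
matrix is comparable across subjects.  Columns are standardized within each
subject and feature type (Z-scores with the sample, `n - 1`, divisor).
This removes per-subject scale differences between RD (a length) and TBM
(a unitless Jacobian determinant) and puts both feature types on a common
footing; a zero-variance block (a degenerate scan) is set to zero with a
warning rather than dropped, so shapes are preserved.

Associations with the continuous response `y` (an amyloid or tau burden
score, or any other scalar) are estimated by a group LASSO,

$$\min_{\beta} \tfrac12 \lVert y - \textstyle\sum_g X_g \beta_g \rVert_2^2
  + \lambda \sum_g w_g \lVert \beta_g \rVert_2 ,$$

where the groups are the RD (respectively TBM) values of one 2 × 3 vertex
patch.  Patch-level grouping trades a small loss of spatial resolution for
robustness: single-vertex selections on smooth fields are unstable, whereas
a six-vertex group must carry coherent signal to enter the model.  The
group weights are not prescribed by the problem; we use the standard
convention $w_g = \sqrt{p_g}$ so that groups of different sizes face
comparable penalties, and expose the weight as a column of the group table
for users who want non-uniform penalties.

## Federated solving

The squared loss decomposes over row blocks, so with subjects partitioned
across $I$ institutions the gradient for group $g$ is
$\sum_i (X_g^i)^\top (X^i \beta - y^i)$ — a sum of $p_g$-length site
aggregates.  The solver is a cyclic proximal block coordinate descent: for
each group the master aggregates the per-site partials (in ascending site
order, so floating-point results are reproducible), takes the step
$\beta_g \leftarrow S_{\lambda w_g / L_g}(\beta_g - \nabla_g f / L_g)$ with
$S_t$ the group soft-threshold, and broadcasts the update.  $L_g$ is the
largest eigenvalue of the aggregated group Gram matrix
$\sum_i (X_g^i)^\top X_g^i$ — the blockwise Lipschitz constant — which
makes every step a monotone descent step; the objective trace is asserted
non-increasing in the tests.  Convergence is declared when the relative
objective change over a full cycle falls below `tol` (default `1e-8`,
with `max_epochs = 1000` as a cap); the group cycle order is fixed
ascending by default, with an optional seeded shuffle.  No stopping rule is
prescribed by the method itself; an objective-change rule was chosen
because it is partition-invariant.  The reported KKT gap is a diagnostic:
an objective-change rule certifies objective precision, not gradient norms,
so the gap is small on the scale of $\lambda_{\max}$ rather than on the
scale of `tol`.

Federation is simulated in process.  The fast path runs the same
arithmetic in compiled code; a pure-R "logged" transport exchanges explicit
messages between master and worker objects and records every payload that
crosses a site boundary.  The test suite asserts the two transports agree
and that no logged message is longer than the largest group — the privacy
contract of the local query model: only aggregates, never rows, leave a
site.  Encryption, differential privacy, and real network transports are
out of scope; the message interface is transport-agnostic.

## Safe screening along the path

Stability selection needs the solution at many penalty levels, which is
where the cost lives.  The path is anchored at
$\lambda_{\max} = \max_g \lVert X_g^\top y \rVert_2 / w_g$, the smallest
penalty with an all-zero solution, and the grid is interpreted as fractions
of it (default 100 uniform values from 1.0 down to 0.1; absolute grids are
a flag away).  Before solving at each new value, a sequential
dual-polytope-projection test of the EDPP family discards groups that are
provably inactive: with $\theta_0$ the dual point of the previous exact
solution, the test builds a feasible direction $v_1$ (the gradient of the
single active dual constraint when the anchor is $\lambda_{\max}$ itself,
$y/\lambda_0 - \theta_0$ otherwise), the step $v_2 = y/\lambda_{\rm new} -
\theta_0$, its projection residual $v_2^\perp$, and discards $g$ when

$$\lVert X_g^\top (\theta_0 + v_2^\perp/2) \rVert_2
  < w_g - \tfrac12 \lVert v_2^\perp \rVert_2\, \lVert X_g \rVert_2 .$$

Every term is a sum of per-site pieces, so screening is as federated as the
solver.  Two numerical guards matter in practice.  First, the previous dual
point is rescaled into the feasible polytope and a small relative slack
(`1e-6` of $w_g$) is subtracted from the discard threshold, because the
solver's dual is exact only to its tolerance.  Second, at the
$\lambda_{\max}$ anchor the solution is forced to exactly zero before the
dual is formed: a one-ulp nonzero coefficient there would otherwise turn
$v_1$ into numerical noise and void the geometry.  If a path point's
solution fails its optimality check, the state is marked stale and the next
screening step is skipped (all groups retained) with a warning — safety is
never traded for speed.  The binding contract, enforced over hundreds of
randomized instances, is that no discarded group is active in an unscreened
high-accuracy solution; the work saved is reported as the ratio of group
updates with and without screening.

A centralized accelerated proximal-gradient solver (`prox_glasso`) is kept
in the package purely as an independent reference: it shares no code with
the federated path and is used in tests to certify objective agreement and
screening safety.

## Stability selection, maps, and the ROI scalar

For each vertex the package counts the (grid value, feature type) pairs
with a nonzero coefficient (|coefficient| > 1e-12, to ignore numerical
dust) and normalizes by twice the grid length, mapping counts to 0–100;
RD and TBM counts are summed by default, with a `merge = "max"` switch.
The map is smoothed by a 2 × 3 averaging filter whose window extends one
row forward and one column to each side of the vertex, clipped at grid
boundaries with the mean taken over surviving cells — values therefore stay
in [0, 100].  Vertices are ranked by smoothed frequency with ties broken by
row-major index, making the selection deterministic; the default
`top_k = 1500` vertices yield 3,000 ROI features (one RD and one TBM per
vertex).  The ROI is reduced to one scalar per subject by
frequency-weighting the selected RD values and summing, likewise for TBM,
and taking the first principal component of the two-column table
(centred and scaled; the sign is fixed so the RD loading is non-negative).
Zero-variance summaries raise an error rather than returning an arbitrary
direction.  Maps export as TSV and as ASCII PLY meshes (regular
triangulation, two triangles per grid cell, scalar in a `quality`
property).

## The synthetic test bed

The generator emulates the *structure* of registered morphometry data, not
its anatomy: per-subject Gaussian random fields smoothed with a separable
Gaussian kernel (reflecting boundaries) of correlation length
`smoothness = 0.75` vertices, then Z-scored per subject; a set of
`n_true_patches` planted patch groups (each one feature type on one patch)
with constant coefficients $\pm\,\mathrm{effect}/\sqrt{p_g}$; and
`y = X \beta + \varepsilon` with Gaussian noise.  One root seed derives
independent named streams for field, support, noise, and partition, so
cohorts are bit-reproducible and components can be varied in isolation.

The defaults are the package's study conditions, chosen once: 200 subjects
over five equal institutions on two 100 × 150 grids; `effect_scale = 0.15`
and `noise_sd = 1`, which puts the multivariate signal-to-noise in the
moderate range typical of imaging–pathology associations rather than in a
trivially separable regime; and a correlation length under one vertex,
which produces adjacent-vertex correlations near 0.6 (smooth enough to
resemble kernel-smoothed surface data, while keeping the planted patches'
design block well-enough conditioned that ordinary least squares restricted
to the true support meets its $3\sigma/\sqrt{n}$ consistency bound — the
generator's internal sanity contract).  Heavier smoothing is available but
raises within-patch collinearity quickly.

What the synthetic bed does *not* emulate: real anatomical covariance
(hippocampal fields have structured, nonstationary correlation), site
effects (shards here are exchangeable random splits; real institutions
differ in scanners and demographics), non-Gaussian responses, and
registration error.  Passing tests therefore demonstrate the correctness
and stability of the optimization, screening, and counting machinery — not
that a particular anatomical ROI would be recovered from real scans.  One
consequence of planting single-type groups is that a planted vertex's
frequency tops out near 50 on the summed 0–100 scale (the other feature
type at that vertex carries no signal), so null-control checks compare
support-vertex frequencies with and without permuting the response rather
than comparing absolute ceilings.

## Problem sizes used in the checks

The end-to-end checks run at the study scale the package documents: the
two-hemisphere 60,000-feature layout with 300 subjects for the
partition-invariance and work-reduction checks (grid of 100 values for the
latter), 500 subjects and 20 cohort replicates for planted-patch recovery
(grid of 20 values, all 10 planted patches required in the top 20 of
5,000 patch-averaged frequencies; the recovery cohorts use
`effect_scale = 0.2`, which realizes a multivariate R² of 0.55–0.65 —
the centre of what we call moderate SNR, R² between 0.5 and 0.7), and one
hundred randomized small
instances each for screening safety and solver-versus-oracle agreement.
These sizes were chosen as the smallest at which the properties are
meaningful at the documented geometry.

## Known limitations

- The screening state must come from the immediately preceding path point;
  jumping down the path in large steps weakens the rule sharply (the
  retained set approaches all groups below about 0.15 λ_max on dense
  problems), which is why the default grid is dense.
- Group weights, the 2 × 3 patch size, and the [1.0, 0.1] relative grid are
  conventions, not estimates; changing them changes which vertices rank
  highest, and the package deliberately exposes all three.
- The PCA reduction of the ROI summaries assumes the two feature types are
  positively aligned with the underlying atrophy process; with antagonistic
  signals the first component can mix them, and users may prefer the raw
  `s_rd`/`s_tbm` columns.
- `lambda_max = 0` (an identically zero response) makes the relative grid
  meaningless; the path refuses to run rather than guessing a scale.
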