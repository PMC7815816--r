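---
title: "Single-subject gray-matter networks: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-subject gray-matter networks: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method: the model behind
each stage, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, the numerical choices
made where the design was genuinely open, and the known limitations. The
package computes everything described here; no empirical claim is made that
the test suite or `scripts/acceptance.R` does not itself reproduce.

## 1. The single-subject network model

A structural covariance network is usually estimated across a cohort: one
correlation per region pair, over subjects. The single-subject variant
treats *intracortical similarity* within one scan as the coupling measure.
The assumptions are:

* Gray-matter density in a normalized scan is locally textured, and
  anatomically related patches share texture.
* A 3×3×3-voxel cube (6 mm side at 2 mm voxels) is large enough to carry
  texture and small enough to be anatomically specific.
* Correspondence between two cubes is defined up to orientation: one cube
  may be a rotated and/or mirrored version of the other. The similarity of
  nodes $i$ and $j$ is therefore
  $s_{ij} = \max_{T \in \mathcal{T}} \mathrm{corr}(v_i, T(v_j))$,
  with $v$ the 27 cube densities.

**The orientation set $\mathcal{T}$.** True 45°-step rotations of a
discrete 3×3×3 cube are not uniquely defined — off-lattice positions must
be resampled. The default set is therefore the 48 exact orthogonal cube
symmetries (24 proper rotations × optional reflection), which are value
permutations: exact, fast, and a group (so $s_{ij} = s_{ji}$ holds by
construction). An optional `"rot45"` set adds 45°-step rotations realized
by nearest-neighbour resampling; those maps duplicate some voxels and drop
others, both scan directions are evaluated to keep the measure symmetric,
and the mode is intended for fidelity experiments only.

**Edge threshold.** The null hypothesis for an edge is "no spatial
correspondence": a null sample is drawn by picking a random node pair and
randomly permuting one member's 27 values, which preserves each cube's
value distribution while destroying the voxel-to-voxel pairing, then
recording the orientation-maximized correlation. This null is demanding —
maximizing over 48 orientations lifts pure-noise correlations to ≈ 0.4 —
and it is exactly the right reference, because the observed similarities
were maximized the same way. Observed pairs get empirical p-values with
$(r+1)/(n+1)$ smoothing (no zero p-values); Benjamini–Hochberg across all
unordered pairs jointly at $q = 0.05$ yields the per-subject threshold.
One subtlety: the binarization rule is *strictly greater than* the
threshold, so the returned threshold is the largest **non**-significant
similarity (p-values are monotone in similarity), which makes the strict
rule retain exactly the significant set. Each subject gets its own null
and threshold.

**Degenerate cubes.** Zero-variance cubes (all-constant density, e.g. deep
in masked-out tissue) have undefined correlations. They are kept as nodes
— so node indexing is identical across subjects on one grid — but receive
similarity 0 to all partners; they can never exceed a positive threshold.

**Cube inclusion.** Tiling is non-overlapping, anchored at the mask
bounding box origin, and a cube becomes a node only if 100% of its voxels
are inside the mask (`min_inside_fraction`, configurable). This avoids
edge cubes dominated by non-GM zeros at the cost of discarding a rind of
partially masked tissue.

## 2. Graph metrics and small-world normalization

Nodal metrics on the binary graph: degree $k_i$ (row sums); clustering
$c_i$ (edges among neighbours over $k_i(k_i-1)/2$, set to 0 when
$k_i < 2$ where the ratio is undefined); characteristic path length $L_i$
(mean BFS shortest-path length to the other nodes); betweenness $BC_i$
(proportion of shortest paths through $i$, each unordered pair counted
once, no endpoint inclusion, no normalization — any normalization cancels
in group comparisons). Brandes' accumulation computes $BC$; the test suite
verifies it equals exhaustive path enumeration on all small graphs.

**Disconnected graphs.** Thresholded single-subject graphs can fragment.
$L_i$ averages only over nodes *reachable* from $i$; isolated nodes get
`NA` and are excluded from $L_{network}$. An alternative largest-component
mode (`path_mode = "largest"`) is provided; the default keeps every
connected node because fragment sizes themselves differ between groups and
discarding them biases $C_{network}$.

Global normalization uses $\mu = 5$ degree-preserving randomized
references per subject, built by Maslov–Sneppen double edge swaps: pick
two edges $(a,b), (c,d)$, rewire to $(a,d), (c,b)$ unless a self-loop or
duplicate would arise. Each reference accepts 10 swaps per edge
(`swaps_per_edge`), with an attempt cap of 100× the target so rigid graphs
(e.g. complete graphs, where no swap is ever accepted) terminate with a
warning and an unchanged copy — for which $\gamma = \lambda = \sigma = 1$
correctly results. Then $\gamma = C_{network}/\bar{C}_{random}$,
$\lambda = L_{network}/\bar{L}_{random}$, $\sigma = \gamma/\lambda$.
($\bar{L}_{random}$ is, of course, the mean of the references' *path
lengths*; the package reports the small-world coefficient under the name
`sigma` throughout.)

## 3. Metric maps

Each nodal metric is painted back onto the voxel grid (every voxel of a
cube receives its node's value; uncovered voxels are 0) and smoothed with
a Gaussian kernel of FWHM 10 mm — roughly double the 6-mm cube side, so
the block structure is blended into a continuous map. Smoothing is
separable with $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per axis
converted to voxels, kernel truncated at $4\sigma$ and renormalized.

Boundary handling is a genuine free choice; two modes are provided.
`"zero"` (default) pads with zeros: mass near the grid edge leaves the
image, which is appropriate for metric maps whose support sits inside the
mask. `"nearest"` distributes each source voxel's full kernel mass with
out-of-grid destinations folded onto the clamped edge voxel; columns of
the convolution matrix then sum to 1 and the image sum is conserved
exactly, which is the right mode for simulating fields on small grids.

## 4. Cohort statistics

* Demographics: unpaired pooled-variance t (Welch optional); Pearson χ²
  without continuity correction for sex-by-group tables.
* SUVR: mean of *positive* voxels in the target ROI over the mean of
  positive voxels in the reference ROI (negative reconstruction noise is
  excluded from both means). Partial-volume correction is out of scope.
* Global metrics: ANCOVA `metric ~ group + age + sex`, reporting the
  adjusted group effect.
* Global metric–SUVR association: partial correlation controlling age and
  sex, per group (the design deliberately fits the groups separately
  rather than a group×SUVR interaction), p from a t-distribution with
  $n - 2 - \#\text{covariates}$ df.
* Voxel-wise inference: per-voxel OLS with a t contrast (two-sample with
  nuisances, or per-group regression on SUVR with nuisances). Zero
  variance voxels are masked out. Pooled-variance OLS is used per voxel.
* Multiple comparisons: max-statistic permutation in the Freedman–Lane
  scheme — residualize the maps on the nuisance design, permute residual
  rows, add the nuisance fit back, refit the full model, record the
  maximum statistic; a voxel's corrected p is the smoothed rank of its
  observed statistic in that distribution. This replaces random-field
  theory: it is self-contained, assumption-light and exact under
  exchangeability, at the cost of runtime and of a different (slightly
  conservative at small $n$) null model. Clusters are 26-connected
  components (SPM convention; 6/18 available) above the height threshold,
  discarded below 50 voxels; conservative mode takes the height from the
  permutation distribution's 95th percentile, exploratory mode from
  uncorrected p < .001.

## 5. The synthetic-data generator

The generator exists to give every downstream stage a ground-truth
surface. Each subject's volume is built from three components:

1. **Cube-level latent texture field** (the structural backbone): 27
   independent white-noise fields on the *cube* grid, moving-average
   smoothed so that the textures of neighbouring cubes correlate at
   `local_texture_corr` (default 0.85, decaying as a Gaussian with cube
   distance). This is what makes nearby cubes genuinely similar — texture
   correspondence survives only when the voxel-to-voxel pairing is intact,
   exactly the signal the empirical-null FDR procedure is designed to
   detect — and it is why extracted networks are lattice-like and
   small-world.
2. **Voxel-level smooth intensity field**: white noise Gaussian-smoothed
   to `smoothness_fwhm_mm` (default 6 mm), mixed at variance share
   `smooth_intensity_share` (default 0.15). It adds the realistic smooth
   intensity autocorrelation of normalized GM maps. It cannot be the sole
   mechanism: a purely smooth field makes every cube a near-pure gradient,
   and the orientation-maximized correlation aligns any two gradients
   regardless of distance, leaving no usable contrast between neighbours
   and distant pairs.
3. **Planted regions** (`edge_block_specs`): inside each designated block
   of cubes, a single shared latent 27-vector is mixed into every cube at
   weight $\sqrt{s}$, planting a clique of true edges with pairwise
   correlation $\approx s$. Patients have $s$ multiplied by
   $1 - \texttt{group\_effect}$ (degraded local connectivity). A
   per-subject latent factor $f \sim N(0,1)$ modulates $s$ by
   $1 + \texttt{subject\_strength\_sd} \cdot f$ (clamped to $[0,1]$).

The final field is squashed affinely to $[0, 1]$ — affine maps leave every
Pearson correlation untouched, so planted similarities are exact (a
strength-1 block yields orientation-maximized similarity exactly 1).

**Covariates.** The SUVR-like scalar is drawn as
$\mathrm{SUVR} = m_g + s_g(\rho_g f + \sqrt{1-\rho_g^2}\,\varepsilon)$,
i.e. correlated at $\rho_g$ (`covariate_coupling`, default +0.6 in
controls, −0.6 in patients) with the same latent factor that modulates
planted connectivity. Group means and SDs default to 1.14 ± 0.17
(controls) and 1.49 ± 0.43 (patients); ages to 68.1 ± 6.5 and 69.5 ± 8.7;
sex is balanced. Age and sex are independent of the planted effects unless
`confound_covariates` links age to $f$ for exercising nuisance regression.

All randomness flows through one seed hierarchy (cohort seed → per-subject
seeds), so any subject is reproducible in isolation and cohorts are
bit-identical under a fixed configuration.

**What the generator does not emulate:** neuroanatomy (no template, no
tissue classes, no ventricles), registration error, scanner artifacts, PET
physics, or the empirical covariance structure of real GM maps. Passing
validation here demonstrates that the pipeline recovers planted structure
and controls its error rates under its own assumptions — not that those
assumptions hold in any given real dataset.

## 6. Validation design and problem sizes

The test-suite validation runs at sizes chosen for minutes-scale runtime
on one CPU; they are stated here as the package's reference conditions.

* *Metric correctness*: 500 random graphs on ≤ 7 nodes against an
  independent matrix-power path-counting oracle, exact equality, plus
  worked examples (path, star, cycle, complete) and an igraph cross-check.
* *Small-worldness of synthetic subjects*: 20 replicates of 18³-voxel
  volumes (216 nodes; the acceptance script uses 36³ → 1728 nodes) with a
  planted block at strength 0.6; γ > 1 and σ > 1 required in ≥ 95% of
  replicates.
* *Edge-FDR calibration*: 100 perfect-similarity pairs among 19 800
  independent-noise pairs (200 nodes), null of 10 000 samples, 50
  replicates; mean realized false-discovery proportion ≤ 5%.
* *Coupling recovery*: coupling ±0.6, n = 15/group on 21³ grids. The
  planted connectivity is spread over four disjoint 3³-cube blocks at
  staggered strengths 0.45/0.58/0.70/0.85 with `subject_strength_sd` 0.5:
  as the subject factor rises, successive blocks cross the edge-retention
  threshold, so regional degree responds as a smooth ramp rather than a
  single step (a lone clique saturates — every pair either passes or fails
  together — and carries little linear information about the factor). The
  sign of the region-mean degree–SUVR t must match the planted sign in
  ≥ 90% of 20 replicates.
* *Error control*: 100 null cohorts (no planted effects, coupling 0,
  n = 6/group, 12³ grids); ANCOVA rejections, exploratory cluster
  detections (p < .001, 50 voxels) and permutation-FWE detections must
  each stay ≤ 5% + 2 binomial SEs.

## 7. Numerical choices and degenerate inputs

* Similarity is computed on row-standardized values via one BLAS
  cross-product per orientation, with an element-wise running maximum;
  the matrix is symmetrized exactly by copying the upper triangle.
* Empirical p-values use $(r+1)/(n+1)$; the BH step is `stats::p.adjust`.
* `fdr_edge_threshold` returns `+Inf` when nothing is significant — the
  graph is empty and downstream global metrics are undefined
  (`gm_network` stores `NULL` global metrics in that case).
* Double-edge-swap determinism comes from R's RNG; seeds below $2^{31}$.
* Grids must allow ≥ 4 cube edges per axis (12 voxels); smaller inputs
  are a configuration error.
* `local_texture_corr` is capped at 0.9: the discrete moving-average
  kernel (radius 6 cubes) cannot realize arbitrarily high lag-1
  autocorrelation.

## 8. Known limitations

* The 45° orientation mode is a nearest-neighbour approximation; whether
  interpolated rotations beyond the orthogonal group are ever warranted on
  3×3×3 patches is an open question, and the default deliberately avoids
  them.
* Permutation FWE assumes exchangeability of residuals under the nuisance
  model; heteroscedastic groups at very small n weaken it.
* The per-subject FDR threshold adapts to each scan's null, so absolute
  edge densities are not comparable across subjects with very different
  texture spectra; the group statistics operate on normalized (γ, λ, σ)
  or voxel-standardized quantities for this reason.
* Cube tiling is anchored at the mask bounding box; a one-voxel shift of
  the mask can re-tile the volume. Real studies should fix one common
  mask for all subjects (the pipeline does).
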