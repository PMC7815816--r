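# graynet

Single-subject structural covariance networks from gray-matter density
volumes, with small-world graph metrics, voxel-space metric maps, and the
cohort statistics used to compare them between groups and relate them to a
PET-derived covariate (SUVR).

Structural covariance analysis usually needs a whole cohort to estimate one
network. The single-subject approach implemented here instead builds one
binary graph per scan from the *intracortical similarity* of small cortical
patches, so network properties become per-subject measurements that can be
entered into ordinary group statistics — of interest to researchers studying
network degeneration in dementia and to methodologists validating
graph-based biomarkers.

## The estimator

Given a gray-matter density volume *G* (values in [0, 1]) and a binary
analysis mask:

1. **Nodes.** The mask is tiled with non-overlapping 3×3×3-voxel cubes
   (6 mm side at 2 mm voxels); each fully-masked cube is one node.
2. **Similarity.** For nodes *i*, *j* the edge weight is
   max over orientations *T* of corr(v_i, T(v_j)), the maximal Pearson
   correlation over the 48 orthogonal cube symmetries (rotations by
   multiples of 90° and reflections; 45°-step rotations via
   nearest-neighbour resampling are available as an option).
3. **Threshold.** An empirical null is built by correlating randomly
   chosen node pairs after permuting one member's 27 values. Each observed
   similarity gets an empirical p-value with (r+1)/(n+1) smoothing;
   Benjamini–Hochberg across all pairs at q = 0.05 fixes the per-subject
   binarization threshold, so the expected proportion of spurious edges
   among those retained is at most 5%.
4. **Metrics.** Per node: degree *k*, clustering coefficient *c*,
   characteristic path length *L*, betweenness centrality *BC*. Per
   subject: C_network and L_network (means over nodes), normalized against
   μ = 5 degree-preserving randomized references (Maslov–Sneppen double
   edge swaps):

   γ = C_network / C̄_random,  λ = L_network / L̄_random,  σ = γ / λ.

   A small-world network has γ > 1, λ ≈ 1, σ > 1.
5. **Maps.** Nodal metrics are painted back onto the voxel grid
   (block-constant over each cube) and smoothed with a 10-mm FWHM Gaussian
   kernel, giving per-subject metric volumes for voxel-wise inference.

Cohort statistics: unpaired t and Pearson χ² for demographics; ANCOVA
(metric ~ group + age + sex) for global metrics; partial correlation with
SUVR controlling age and sex; voxel-wise GLM on metric maps with
max-statistic permutation FWE correction (Freedman–Lane) and cluster-extent
thresholding (height p < .05 FWE or exploratory p < .001 uncorrected,
extent 50 voxels, 26-connectivity).

## Worked example

```r
library(graynet)

# a synthetic subject: spatially structured GM density with a planted
# high-similarity block
cfg <- simulation_config(grid_shape = c(18, 18, 18), n_per_group = 3,
                         edge_block_specs = list(list(origin = c(2, 2, 2),
                                                      size = c(3, 3, 3),
                                                      strength = 0.6)),
                         seed = 3)
sub <- generate_subject(cfg, "control", subject_seed = 11)

net <- gm_network(sub$volume, q = 0.05, mu = 5, seed = 1)
net
#> Single-subject gray-matter network
#>   nodes: 216 ( 0 degenerate )
#>   edges: 1525 (density 0.066)
#>   FDR q: 0.05  threshold: 0.6716
#>   gamma 5.088  lambda 1.286  sigma 3.957  (mu = 5)
```

216 cube nodes were extracted from the 18³ volume; 1525 of the 23 220
possible edges survive the per-subject FDR threshold (similarity > 0.67).
The clustering coefficient is ~5× that of degree-matched random graphs
(γ = 5.09) while the path length is only mildly longer (λ = 1.29), giving a
small-world coefficient σ = 3.96 > 1 — the lattice-like local structure of
the simulated cortex is detected. `summary(net)` tabulates the nodal
metrics, `metric_maps(net)` returns the smoothed voxel maps, and
`run_pipeline()` drives the full simulate → extract → maps → stats chain
with a provenance manifest.

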