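---
title: "Methods: quantifying pipeline concordance in structural and functional connectivity outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying pipeline concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package answers

Cortical surface reconstruction is not unique: a unimodal reconstruction
(T1-weighted only) and a multimodal one (T1w plus T2w) of the same brain
produce slightly different surfaces, parcel boundaries, thickness and
gyrification estimates. Since resting-state functional connectivity (FC)
analyses are built *on top of* the reconstructed surface — vertex BOLD
series are pooled within parcels defined on it — the question is whether a
structural disagreement between two reconstruction pipelines propagates
into the functional results. `neuroconcord` implements the full comparison
battery as reusable, tested stages, driven by a synthetic paired-pipeline
generator in place of restricted human MRI data:

1. **Structural comparison** — per-parcel paired t-tests of thickness,
   gyrification and volume between pipelines (Bonferroni 0.05/34 per
   cortical hemisphere, 0.05/7 for the subcortical table), a vertex-level
   cluster-mass permutation comparison, and the Jaccard overlap of the two
   pipelines' vertex-to-parcel assignments.
2. **FC strength** — per-parcel mean (or median) of the suprathreshold
   (|r| ≥ 0.3) entries of the 68×68 Pearson matrix, compared between
   pipelines parcel-wise, with a smoothing-kernel sensitivity loop
   (4/5/6 mm FWHM) and seed-to-vertex network maps.
3. **Seed-map topology** — volumetric FC peak localisation, the Euclidean
   distance from each peak to its ROI's center of gravity, the
   delta-distance contrast between two ROIs, binarized error maps at
   thresholds 0.3–0.6, and TFCE with sign-flip permutation FWE on smoothed
   (sigma 2.12 mm) between-pipeline difference maps.
4. **Graph concordance** — binarized (r > 0.3) FC graphs, six node
   metrics, parcels × subjects matrices per metric, and the absolute
   Pearson correlation of first-principal-component scores between
   pipelines.

## Statistical model of the paired design

Every comparison is within-subject: pipeline A and pipeline B process the
same acquisition, so per-subject differences `d_s = x_s^B - x_s^A` are the
unit of inference. Parcel- and table-level tests use the exact paired
two-sided t distribution (not a normal approximation; at n = 20–58
subjects the difference matters in the Bonferroni tail). Vertex- and
voxel-level inference uses the exchangeability the paired design
guarantees under the null: flipping the sign of any subject's difference
map leaves the null distribution invariant, so the maximum cluster mass
(surface) or maximum TFCE score (volume) over sign-flip permutations
yields family-wise corrected p-values. Corrected p-values use the
`(1 + count)/(1 + n_perm)` convention and therefore never reach zero. When
`n_perm` exceeds the `2^n` distinct sign patterns the enumeration becomes
exhaustive.

This sign-flip construction deliberately replaces the Gaussian
random-field simulation used by common surface tools for cluster
correction: it targets the same quantity (cluster-wise FWE) but is fully
specifiable and reproducible from a seed. It is a stand-in with the same
inferential target, not a re-implementation of any particular tool.
Cluster connectivity on the surface is 1-ring mesh adjacency and the
cluster statistic is mass (sum of |t| over member vertices); the
minimum-area rule (50 mm², summed per-vertex Voronoi areas) applies only
to the seed-network stage, where small clusters are reported in an
excluded-clusters ledger instead of tested.

## Surface smoothing

Only the kernel FWHM is meaningful input; the implementation is iterated
graph diffusion. One step is `x <- x + alpha (A x - D x)` with
`alpha = 1/(max_degree + 1)`. Because this operator is symmetric with zero
row sums it preserves the vertex sum exactly on a closed mesh (so a
constant map is a fixed point and a point source conserves mass), while
equalling the familiar mean-of-self-and-neighbours step on a regular mesh.
The plain mean-of-neighbours form does *not* preserve the global mean on
an irregular closed mesh (an icosphere has twelve degree-5 vertices), which
is why the symmetric form was chosen. The iteration count is calibrated by
diffusion variance: one step adds about `h²/2` of spatial variance for mean
edge length `h`, and a Gaussian of full width `f` has variance
`(f/2.355)²`, giving

```
n_iter = round( (fwhm / 2.355)^2 / (mean_edge_length^2 / 2) )
```

The calibration is checked by the variance-additivity property (smoothing
twice at `f` ≈ once at `f√2`, 15% tolerance): exact kernel shape is not
claimed. Note the granularity: at the default mesh (subdivision-4
icospheres, 30 mm radius, mean edge ≈ 2.2 mm) the 4/5/6 mm kernels map to
1/2/3 iterations; on a coarser mesh neighbouring kernels can collapse onto
the same iteration count. Missing vertices are handled by diffusing the
masked values and the mask separately and renormalising.

Volume smoothing is a separable Gaussian (truncated at 4 sigma) with
mask renormalisation — value-times-mask and mask are convolved separately
and divided inside the mask — so constant maps stay exactly constant and
nothing bleeds across the mask boundary. Only isotropic grids are
supported; an anisotropic affine is an explicit error.

## TFCE

The enhanced value of voxel v integrates `extent^E · h^H` over thresholds
up to the voxel's own height, with the standard published defaults E = 0.5,
H = 2 and 6-connectivity (all exposed as arguments; the source analysis
names the method but no parameters). The threshold step defaults to
`max/100` per enhanced map; negative statistic values are enhanced by
applying the transform to the negated map and negating the result. A
single suprathreshold voxel of height h converges to `h^(H+1)/(H+1)` as
the step shrinks, which the tests verify at 2% with `dh = h/1000`, and
which fixes the integral's normalisation. The permutation loop calls a
compiled enhancement kernel; at the test grid sizes (8³–24³) 500–1000
permutations run in seconds.

## FC strength definitions

After removing the diagonal and all entries with |r| < 0.3 (correlations
that weak are unlikely to represent connections), the per-parcel strength
is the **mean over surviving entries** — "removal" is read as exclusion
from the average, not replacement by zero. Both readings are implemented
(`denominator = "survivors"` vs `"all"`); the survivor average is the
default. Surviving negative correlations keep their sign, since removal is
by absolute value only. A column with no survivors gets strength 0 and a
flag. The median variant uses the same survivor set.

## Graph metrics and PC1 concordance

Edges exist where raw r strictly exceeds 0.3 — the threshold is applied on
the correlation scale, with a z-scale option, because the source procedure
Fisher-transforms and then thresholds "r = 0.3" (atanh(0.3) ≈ 0.31, so the
two readings differ only for a narrow band). Fisher-z values of retained
edges are kept as weights for normalized strength (sum of retained weights
divided by n−1, with a binary-degree fallback), since "strength" on a
binarized graph is otherwise degenerate with degree.

Conventions chosen for the six node metrics: betweenness is normalised by
(n−1)(n−2)/2; closeness uses the component-scaled form
`((reachable−1)/distance_sum) · ((reachable−1)/(n−1))`, which is finite on
disconnected graphs and reduces to classical closeness on connected ones;
clustering is triangles over connected triples (0 where degree < 2);
degree is divided by n−1; eigenvector centrality is the dominant
adjacency eigenvector by power iteration on A + I (the shift makes the
dominant eigenvalue strictly largest in magnitude even on bipartite
graphs, without changing eigenvectors), unit norm, nonnegative
orientation, started from the uniform vector — on graphs whose dominant
eigenvalue is degenerate the limit is the projection of the uniform vector
onto the dominant eigenspace, and that convention is what the test oracle
checks. Shortest-path and triangle counting are delegated to igraph; all
six metrics are verified against independent brute-force oracles (path
enumeration, Floyd–Warshall, triple loops, full eigendecomposition) on
hundreds of small random graphs.

PC1 concordance treats parcels as observations and subjects as centered
variables, extracts the first-component *scores* (length = number of
parcels) per pipeline, and reports the absolute Pearson correlation —
the absolute value resolves the sign indeterminacy of principal
components; a loadings variant is available. Identical inputs give
exactly 1.

## The synthetic paired-pipeline generator

The generator emits, per subject, two bundles that share one cortical
mesh (two subdivided icospheres, left and right) and one vertex BOLD
acquisition, and differ the way two reconstructions of the same brain
differ:

* **Thickness**: pipeline B = A + 0.1 mm + per-subject-per-parcel noise
  (SD 0.1 mm). The offset magnitude is a calibration choice — the source
  analysis reports direction and significance, not millimetres — set so
  the per-subject effect size is 1.
* **Gyrification**: B = A − 0.1 (same noise model); B folds less.
* **Parcellation**: B's scheme relabels each parcel-boundary vertex with
  probability 0.13 to the majority neighbouring foreign label (ties to
  the lowest identifier). The default rate is calibrated so the mean
  parcel Jaccard between A and B is ≈ 0.90 on the default geometry,
  matching the reported overlap between real unimodal and multimodal
  parcellations. One uniform draw per boundary vertex is thresholded at
  the rate, so overlap decreases monotonically in the rate under a fixed
  seed.
* **BOLD**: parcel-level latent signals are drawn timepoint-wise from a
  block covariance (five networks in contiguous runs; within-network
  correlation ramps from 0.7× to 1.3× of 0.4 across blocks, between
  networks 0.1); each vertex receives its own parcel's latent plus white
  noise of SD 1. The ramp matters: with perfectly exchangeable parcels the
  parcels × subjects metric matrices have no stable parcel profile and
  first principal components are noise — the heterogeneity of real
  cortical networks is precisely what makes PC1 reproducible.
* **Runs**: 888 timepoints as three concatenated runs at TR 1 s (the
  post-scrub length of three 300-TR runs with four frames dropped);
  boundaries are recorded. Scripts use 300 timepoints where runtime
  matters.
* **Seed volumes**: per ROI, a Gaussian FC bump (amplitude 1, sigma 6 mm)
  at the ROI center — displaced by an injected shift for pipeline B —
  plus spatially smoothed noise rescaled to 5% of the amplitude, on a 24³
  grid of 3 mm isotropic voxels.

Ground truth (offsets, covariance, relabelled vertex sets, injected
shifts) is returned alongside the bundles, so every stage has a
parameter-recovery test.

What the generator does **not** emulate: physiological noise and motion,
temporal autocorrelation within runs, geometric cortical folding (spheres
stand in for folded cortex; gyrification is a supplied scalar, never
computed from the mesh), vertex-to-voxel registration (volumetric seed
maps are synthesised directly), and realistic parcel counts per vertex —
the meshes are scaled down (≈ 75 vertices per parcel at default, versus
thousands in real data). The last point has a visible consequence:
relabelling a boundary vertex moves a much larger fraction of a parcel
than in real data, so *unsmoothed* FC strength shows many more
significant parcels than the real study; at the standard 5 mm kernel the
count drops to the handful the study reports. Passing tests therefore
demonstrate correctness of the machinery and recoverability of injected
effects, not quantitative agreement with human cortex.

## Numerical and degenerate-input policy

* Missing values use `NA` throughout; operations document
  propagate-or-error, defaulting to propagation with a warning.
* A constant parcel timeseries yields missing correlations (with a
  warning naming the parcel), never an exception mid-batch.
* Identical paired samples give t = 0, p = 1; a nonzero zero-variance
  difference is flagged degenerate and no t is emitted.
* FC peak ties break to the lexicographically smallest 0-based (i, j, k).
* Error maps binarize on signed r ≥ threshold by default (the 0.3–0.6
  thresholds are positive FC levels); an absolute mode is provided. The
  error value is the exclusive-or mean over the mask, which lies in [0, 1].
* Graph threshold is strict (r > 0.3), making the boundary deterministic.
* Voxel indices are 0-based with world coordinates via the affine (RAS);
  R array access stays 1-based with converters at the boundary.

## Problem sizes and determinism

The shipped test suite and drivers use scaled sizes chosen as a
package-design decision: subdivision-2 or -3 spheres and 6–20 subjects in
unit tests; 100 replicates at 500 permutations for the family-wise error
checks; 200 draws for recovery rates; the end-to-end workflow check runs
12 subjects through all five stages twice and compares output checksums.
Every stochastic stage takes an explicit seed, reruns are bit-identical,
and the workflow manifest records seeds, parameters and per-file
checksums.

## Known limitations

* Betweenness centrality is the least stable metric at 68-node graph
  sizes: its PC1 concordance fluctuates widely across seeds (≈ 0.1–0.9)
  while the other five metrics sit at ≥ 0.96. This mirrors its known
  sensitivity to single-edge changes on dense thresholded graphs and
  disappears as graphs grow.
* The vertexwise cluster stand-in makes no claim of matching any specific
  surface tool's adjacency or statistic choices, which the source analysis
  does not specify.
* Whether seed-map group tests should re-smooth the correlation maps is
  unspecified in the source procedure; maps are not re-smoothed here.
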