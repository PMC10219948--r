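# neuroconcord

Does the choice of cortical surface-reconstruction pipeline change the
outcome of a resting-state functional-connectivity study? Two
reconstructions of the same brain — a unimodal one built from the
T1-weighted image alone and a multimodal one that also uses the
T2-weighted image — disagree measurably in cortical thickness,
gyrification and parcel boundaries. Because functional analyses pool
vertex BOLD signals within parcels defined on the reconstructed surface,
any structural disagreement can, in principle, propagate into every
downstream functional result. `neuroconcord` implements the full paired
comparison battery for this question as tested, reusable R stages, and
ships a synthetic paired-pipeline generator so the whole framework is
verifiable without access to restricted MRI data. It is written for
neuroimaging methodologists who want to quantify pipeline effects, and for
anyone who needs the component machinery (cluster-mass sign-flip
inference, TFCE with permutation FWE, thresholded FC strength, graph-PCA
concordance) with parameter-recovery tests behind it.

## The statistics at the core

All inference is within-subject on paired pipelines A and B:

* **Parcel-level tests.** For quantity x (thickness, gyrification, volume,
  FC strength) and parcel p: exact paired two-sided t-test of
  x<sub>s,p</sub><sup>B</sup> − x<sub>s,p</sub><sup>A</sup> across subjects
  s, Bonferroni-corrected at α/n (n = 34 cortical parcels per hemisphere,
  printed threshold 0.0014; n = 7 subcortical structures).
* **FC strength.** From each pipeline's 68×68 Pearson matrix with the
  diagonal removed and entries |r| < 0.3 discarded, the per-parcel
  strength is the mean (or median) over surviving entries.
* **Vertex/voxel-level FWE.** Per-location paired t-maps; clusters on the
  mesh scored by mass Σ|t| (surface) or TFCE-enhanced values with
  E = 0.5, H = 2 (volume); family-wise p from the max-statistic
  distribution over sign-flips of the subject difference maps,
  p = (1 + #{null ≥ obs}) / (1 + n_perm).
* **Topology.** Peak shift d = ‖peak(FC map) − COG(ROI)‖₂ per subject,
  ROI and pipeline; per-ROI paired tests of d; delta contrast
  |d<sub>A</sub> − d<sub>B</sub>| between two ROIs. Binarized error maps:
  mean over the mask of XOR(A ≥ τ, B ≥ τ) for τ ∈ {0.3, 0.4, 0.5, 0.6}.
* **Graph concordance.** Edges where r > 0.3 (Fisher-z weights retained);
  six node metrics (betweenness, closeness, clustering, degree,
  eigenvector, normalized strength); per metric, the parcels × subjects
  matrix per pipeline; concordance = |Pearson r| of the two PC1 score
  vectors.

## Worked example

```r
library(neuroconcord)

cfg <- synth_config(n_subjects = 12, n_timepoints = 300, rng_seed = 7L)
ds  <- generate_paired_dataset(cfg)

thick <- parcel_structural_comparison(ds$subjects, "thickness")
sum(thick$significant)                    # 35 of 68 parcels, all "B>A"

mean(sapply(ds$subjects, function(s)
  mean(sapply(1:68, function(p) jaccard(s$A$scheme, s$B$scheme, p)))))
# 0.899  -- vertex-assignment overlap between the two pipelines

fc <- compare_fc_strength(ds$subjects, stat = "mean", smoothing_fwhm = 5)
sum(fc$significant)                       # 3 of 68 parcels

round(graph_concordance(ds$subjects)$concordance, 3)
#  betweenness  closeness  clustering  degree  eigenvector  normalized_strength
#        0.790      0.996       0.993   0.998        1.000                0.999
```

Read: pipeline B reconstructs a thicker cortex in half the parcels
(direction always B>A, matching the injected +0.1 mm offset), the two
parcellations overlap at J ≈ 0.90, yet at the standard 5 mm kernel only 3
of 68 parcels differ in FC strength, and whole-brain graph organisation is
nearly identical between pipelines (PC1 r ≥ 0.99 for all metrics except
the noise-sensitive betweenness). Structural disagreement propagates only
weakly into functional outcomes — the pattern the framework is designed to
measure.

## Analysis workflow

The `analysis/` drivers run the four stages end to end on the default
synthetic cohort and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # cohort + ground truth + example bundle
Rscript analysis/02_structural.R        # parcel/vertex structural comparison, Jaccard
Rscript analysis/03_fc_strength.R       # FC strength + kernel/median sensitivity, seed maps
Rscript analysis/04_seed_topology.R     # peak shifts, error maps, TFCE p-FWE
Rscript analysis/05_graph_concordance.R # six metrics, PC1 concordance
```

`run_workflow()` chains the same stages programmatically and writes a
manifest with seeds, parameters and per-file checksums; reruns with the
same seed are bit-identical.

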