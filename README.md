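# cortexalign

Group-level fMRI studies of the visual system must bring many brains into a
common space before statistics can be pooled across subjects. `cortexalign`
implements, at desk scale and with fully synthetic data, the classical
three-arm comparison of alignment strategies for an attention-enhanced
visual field localizer:

* **VBA-analog** — a volumetric analysis: per-voxel GLM on a 3-mm grid with
  3D Gaussian smoothing and no cortical correspondence;
* **SBAV-analog** — a surface-based analysis (surface smoothing and readout
  on a shared spherical mesh) *without* macroanatomical alignment;
* **CBA** — the same surface analysis plus curvature-driven cortex-based
  alignment on the sphere.

The scientific core is the alignment algorithm: every subject's folding
(curvature) map lives on a standard-topology icosphere; subjects are first
rigidly rotated to a target (the rotation maximising the curvature
correlation, found by a 15° Euler grid plus Nelder–Mead refinement), then
morphed non-rigidly through four coarse-to-fine curvature smoothing levels
toward a *moving target* — the dynamically updated group-average curvature —
by minimising, per subject,

```
E(w) = Σ_v [ c_subj(w(v)) − c_target(v) ]²  +  λ Σ_e ( ℓ(e)/ℓ₀(e) − 1 )²
```

where `w` maps each group vertex to a position on the subject sphere, and
the second term penalises edge-length distortion. The whole procedure is run
twice: the first pass only manufactures an unbiased average rigid target for
the second (two-pass, moving-target alignment).

Because no scan data ship with the package, a first-class synthetic-cohort
generator produces template anatomies (ridge-based folding maps on the
sphere), per-subject smooth random warps with stored ground truth, and
quadrant-selective BOLD time series driven by the localizer paradigm
(144 × 2-s trials, 4 quadrant conditions, 11 prolonged ITIs, 340 s; TR 2 s,
170 volumes of which 4 are discarded; box-car ⊗ two-gamma design; AR(1)
noise). Every evaluation statistic of the study design is implemented:
random-effects t maps, Bonferroni thresholds, group ROIs with size-change
and asymmetry indices, probability maps (PMs), probability difference maps
(PDMs), peak-vertex distributions, detection rates and the
position-selectivity comparison across arms.

## A worked example

```r
library(cortexalign)

cfg <- experiment_config(master_seed = 42, n_subjects = 6,
                         mesh_subdivisions = 3,
                         cba = cba_params(updates_per_level = 2,
                                          iters_per_update = 12))
res <- run_experiment(cfg, verbose = FALSE)
res
#> <experiment_result> 6 subjects, arms: volume, surface_unaligned, surface_cba (40 s)
#>   max probability of activation overlap:  CBA 100%, SBAV-analog 100%, VBA-analog 100%

dplyr::filter(res$tables$pm_summary, quadrant == "LL")
#> # A tibble: 3 x 5
#>   quadrant arm         n_vertices   mpo mpo_vertex
#>   <chr>    <chr>            <int> <dbl>      <int>
#> 1 LL       SBAV-analog        223 100           33
#> 2 LL       CBA                172 100           33
#> 3 LL       VBA-analog         131  83.3         33
```

At this miniature size (6 subjects, 642 vertices) the surface arms saturate;
`pm_summary$n_vertices` (the spread of above-10% overlap) already shows CBA
focusing activation relative to the unaligned arm, and `pdm_summary` holds
the pairwise difference maps. At the analysis scale (20 subjects, 2,562
vertices, the default `experiment_config()`) the unaligned arm peaks around
75–85% overlap while CBA reaches ~100%, reproducing the qualitative ordering
of the three strategies. `write_report(res, "out/")` writes every table as
CSV plus a JSON manifest; `autoplot()` methods display probability maps,
difference maps, design matrices and alignment objective traces.

A thin command-line wrapper with `simulate`, `run` and `report` subcommands
is installed at `inst/scripts/cortexalign`.

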