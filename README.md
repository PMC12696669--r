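# funmodes

Multiscale probabilistic functional-mode decomposition of resting-state
fMRI, at desk scale, with everything needed to validate it end to end.

## The problem

Resting-state brain activity organises into functional modes at several
spatial scales simultaneously: a couple of dozen *distributed* networks
(default-mode, attention, motor, ...) and, nested inside them,
*localised* subsystems with temporally distinct dynamics. Decompositions
that commit to a single scale either miss the local detail or merge the
dynamics. This package is for methods researchers in functional
connectomics who want a fully inspectable, simulation-validated
implementation of a multiscale decomposition pipeline and its companion
analyses.

## What is inside

Each run of each subject is modelled as

    D = P H A + E,    D in R^(Nv x Nt)

with subject spatial maps `P` (double-Gaussian mixture prior around
group-level map means), non-negative amplitudes `H`, time courses `A`
(matrix-normal prior with a Wishart-linked precision hierarchy for
functional connectivity, plus a haemodynamic band-limitation penalty) and
Gaussian residuals. Fitting is stochastic: subjects are visited in
batches and the group model is blended with step size
`(t + tau)^(-beta)`, followed by full-batch consolidation.

* `simulate_modes()` / `sim_config()` — synthetic multiscale rfMRI with
  known ground truth: overlapping distributed modes (~1.3 modes per
  covered voxel), localised sub-modes, ~83% subject-group map overlap,
  Wishart-linked subject connectivity, low-frequency haemodynamic time
  courses, synthetic phenotypes with confound contamination.
* `pfm()` — the hierarchical decomposition (S3 object with `print`,
  `summary`, `coef`, `plot`, `fitted` methods; `qc_modes()` for mode QC).
* `icadr()` / `dual_regression()` — the group-ICA + dual-regression
  baseline, sharing the same incremental group-PCA basis.
* `tica_subcomponents()`, `winner_takes_all()`, `exclusive_temporal()`,
  `exclusive_spatial()`, `plant_subcomponent_scene()` — the within-mode
  temporal subcomponent analysis and its control variants.
* `snet()`, `tnet()`, `fisher_z()`, `pair_modes()`, `split_blocks()`,
  `svd_reduce()`, `consistency()` — connectivity features: spatial and
  Tikhonov-regularised partial temporal network matrices, Hungarian mode
  pairing with primary/secondary labelling, feature construction.
* `elasticnet_predict()`, `cca_permutation_test()` — fold-safe
  deconfounded, Gaussianised elastic-net prediction with nested
  cross-validation, and CCA with exchangeability-block permutation
  inference (family-wise error controlled).
* `score_recovery()`, `dice_similarity()` — the ground-truth recovery
  benchmark; `write_fmri()`, `read_fmri()`, `run_pipeline()` — plain-text
  and NIfTI I/O and a staged, resumable pipeline runner.

## Worked example

Simulate a small multiscale dataset, fit the hierarchical decomposition
and the ICA baseline, and score both against the ground truth:

```r
library(funmodes)

cfg <- sim_config(n_datasets = 1, n_subjects = 8, n_runs = 2,
                  n_voxels = 1200, n_timepoints = 200, seed = 7)
sim <- simulate_modes(cfg)
sim
#> Simulated multiscale resting-state dataset
#> Multiscale resting-state simulation configuration
#>   1 dataset(s): 8 subjects x 2 run(s)
#>   1200 voxels x 200 timepoints, TR 0.72 s
#>   12 modes (6 distributed + 6 localised)
#>   weights ~ Gamma(3, 0.5); coverage 0.11; warp 0.0063
#>   Wishart dof 50; obs noise SD 3; lowpass 0.1 Hz; seed 7
#>   overlap statistic: 1.438 distributed modes per covered voxel
#>   subject-group support Dice: 0.804

fit  <- pfm(sim$datasets, n_modes = 12, control = pfm_control(seed = 7))
base <- icadr(sim$datasets, n_modes = 12, seed = 7)

score_recovery(fit, sim$truth)
#> Ground-truth recovery (PFM): mean paired |r|
#>       element  mode_class accuracy
#>    group_maps distributed    0.831
#>    group_maps   localised    0.406
#>  subject_maps distributed    0.837
#>  subject_maps   localised    0.282
#>   timecourses distributed    0.946
#>   timecourses   localised    0.325
score_recovery(base, sim$truth)
#> Ground-truth recovery (ICA-DR): mean paired |r|
#>       element  mode_class accuracy
#>    group_maps distributed    0.675
#>    group_maps   localised    0.572
#>  subject_maps distributed    0.592
#>  subject_maps   localised    0.522
#>   timecourses distributed    0.853
#>   timecourses   localised    0.440
```

The `overlap statistic` and `support Dice` lines report the generator's
two calibration statistics (mean number of distributed modes covering a
covered voxel; mean Dice overlap between subject and group mode
supports). The recovery tables give the mean paired absolute correlation
between estimate and truth. At this deliberately tiny example scale the
hierarchical fit clearly beats the baseline on the distributed modes
(group maps 0.83 vs 0.68, subject maps 0.84 vs 0.59, time courses 0.95 vs
0.85); the nested localised modes are initialisation-limited with only 8
subjects and 1,200 voxels. At the benchmark scale used in the tests and
the acceptance script (20 subjects, 2,500 voxels, 3 datasets) the
hierarchical fit leads the baseline on nearly every element and class,
most clearly on the distributed modes.

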