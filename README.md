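# probatlas

Probabilistic functional atlases and individual neural markers from fMRI
localizer maps.

Functional regions — the language network being the motivating case — sit in
different voxels in different brains even after normalization to a common
template. `probatlas` builds voxelwise **probabilistic functional atlases**
from individual first-level statistical maps and extracts **individual-level
neural markers** from parcel-constrained functional ROIs (fROIs), for
researchers who work with single-subject localizer contrasts rather than
group-average maps.

The core quantity: given per-subject statistics $t_s(v)$ on a common grid and
an analysis mask $M$, each subject is reduced to a binary map $B_s$ — either
the top fraction $f$ of mask voxels by $t_s$ (default $f = 0.10$, pooled
across hemispheres, $k = \mathrm{round}(f|M|)$ exactly), or the voxels with
$t_s(v) > t_{\mathrm{crit}}(p,\nu)$ one-sided — and the atlas is

$$a(v) = \frac{1}{n}\sum_{s=1}^{n} \mathbf{1}[v \in B_s],$$

the proportion of individuals whose localizer-defined network contains voxel
$v$. Around it the package provides:

- **QC / session selection**: split-half (odd vs even runs) spatial
  correlation of the contrast within parcels; negative-mean-r sessions are
  excluded and each subject's most stable session is kept.
- **Neural markers** per parcel and hemisphere: leave-one-run-out
  cross-validated effect size (the fROI is defined on all-but-one run and
  read out on the left-out run, which removes selection bias), voxel counts
  at p < 0.001 (one-sided, uncorrected), Fisher-z split-half spatial
  correlation, and the lateralization index (LH−RH)/(LH+RH) on voxel counts.
- **Comparison utilities**: atlas–atlas and t-vs-contrast correlations,
  random-effects group t-maps, highest-overlap group ROIs, and atlas
  stability curves over sample size.
- **A synthetic cohort generator** with known ground truth (Gaussian
  activation blobs, inter-subject spatial jitter, lognormal amplitude
  scaling, run-level noise), so the entire pipeline is testable end to end.
- **A CLI** (`inst/cli/probatlas`) with subcommands
  `simulate | qc | build | markers | stability | compare | run`.

Volumes are NIfTI-1/2 via RNifti; cohort manifests and all tables are CSV;
surface data are handled as per-hemisphere overlay vectors.

## Worked example

```r
library(probatlas)

truth <- ground_truth()                       # blobs on the 4 mm MNI box
cfg   <- sim_config(n_subjects = 20, runs_per_subject = 4, seed = 7)
coh   <- simulate_cohort(truth, cfg)

mask  <- binary_map(rep(TRUE, n_sites(truth$grid)), truth$grid)
atlas <- build_atlas(lapply(coh$sessions, function(s)
           top_fraction_binarize(session_tmap(s, c("language", "control")),
                                 mask, 0.10)))
s <- atlas_summary(atlas, mask)
round(c(mask_mean = s$mask_mean,
        lh_max = unname(s$lh_range["max"]), rh_max = unname(s$rh_range["max"]),
        lh_fraction_mean = s$lh_fraction_mean), 4)
#>        mask_mean           lh_max           rh_max lh_fraction_mean
#>           0.1000           1.0000           0.8000           0.5337
```

`mask_mean` is exactly the selection fraction (each subject contributes
exactly k voxels — the conservation invariant). `lh_max`/`rh_max` are the
largest overlap proportions per hemisphere: all 20 subjects agree on the
best left-hemisphere voxel, and the left maximum exceeds the right because
the generator's right-hemisphere homologues are weaker (asymmetry 0.5). On
average 53% of each subject's selected voxels fall in the left hemisphere.

```r
parcels <- mirror_parcels(parcels_from_boxes(truth$grid,
  data.frame(name = "IFG", hemi = "L", xmin = -64, xmax = -36,
             ymin = 6, ymax = 34, zmin = -6, zmax = 22)))
crossval_effect_size(coh$sessions[[1]], parcels$parcels$L_IFG$mask,
                     c("language", "control"))
#> [1] 1.352388
```

— the subject's language−control response (input-map units) in their IFG
fROI, estimated without selection bias via leave-one-run-out
cross-validation (true blob peak: 2, scaled by this subject's amplitude
factor and diluted over the fROI).

## Documentation

The methods vignette (`vignettes/atlas-methods.Rmd`) documents the model,
conventions (hemisphere split, tie-breaking, Fisher-z clamping, quantile
type), the generative model behind the synthetic cohorts, and known
limitations.
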