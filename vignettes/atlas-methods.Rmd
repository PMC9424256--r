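---
title: "Probabilistic functional atlases and individual neural markers: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic functional atlases and individual neural markers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Functional regions — the language network in particular — occupy different
voxels in different brains, even after spatial normalization to a common
template. Group-average activation maps therefore blur individual topographies,
and a single fixed statistical threshold treats a strong responder and a weak
responder very differently. `probatlas` implements the complementary,
individual-first approach: each subject's localizer contrast map is reduced to
a *binary* membership map by a selection rule applied to that subject's own
statistics, and the binary maps are averaged voxelwise. The resulting
probabilistic functional atlas gives, at every voxel of the template space,
the proportion of individuals whose localizer-defined network includes that
voxel.

## Model and procedure

Let $t_s(v)$ be subject $s$'s statistic (a t-value, or an unscaled contrast
estimate) at voxel $v$, and let $M$ be the in-brain analysis mask with $|M|$
voxels. The stages are:

1. **QC (split-half stability).** Per session, the language$-$control
   contrast is averaged over the odd-numbered and over the even-numbered runs;
   the two half-maps are Pearson-correlated within each of a set of parcels
   (group-level masks marking the typical locations of the network's regions)
   and the per-parcel correlations are averaged. Sessions with a negative
   mean correlation are excluded; for subjects with several sessions the one
   with the highest mean correlation is kept, ties broken by the earliest
   session id so that selection is deterministic.
2. **Binarization.** Either *top-fraction*: the $k = \mathrm{round}(f\,|M|)$
   voxels with the largest $t_s(v)$, pooled across both hemispheres
   ($f = 0.10$ by default); or *fixed-p*: all voxels with
   $t_s(v) > t_{\mathrm{crit}}(p, \nu)$, the one-sided positive-tail Student-t
   critical value at the subject's degrees of freedom. The top-fraction rule
   equalizes the selected-network *size* across subjects and is therefore the
   default; the fixed-p rule instead equalizes the evidence threshold, letting
   network size vary.
3. **Aggregation.** The atlas value at $v$ is
   $\frac{1}{n}\sum_s \mathbf{1}[v \in B_s]$, exactly $k/n$-granular for
   top-fraction atlases. A per-subject laterality table records the fraction
   of each subject's selected voxels falling in the left hemisphere.

Individual **neural markers** are computed within parcel-constrained
functional ROIs (fROIs: the top 10% of a parcel's voxels by the subject's
statistic): the *cross-validated effect size* (leave-one-run-out: the fROI is
defined on all runs but one and the contrast is read out from the left-out
run, averaged over folds — the fold structure removes the selection bias that
would otherwise inflate the estimate), the *voxel count* above the one-sided
p < 0.001 uncorrected threshold, the *split-half spatial correlation*
(Fisher-z transformed), and the *lateralization index*
$(\mathrm{LH}-\mathrm{RH})/(\mathrm{LH}+\mathrm{RH})$ on hemisphere voxel
counts.

## Conventions and numerical choices

- **Hemispheres** are split in world coordinates: a voxel is left iff its
  centre has $x < 0$ (the affine maps 0-based voxel indices to mm). Voxels
  with $|x| < 10^{-6}$ are midline and belong to neither hemisphere summary;
  they stay in the denominator of the laterality fraction.
- **Analysis mask.** "Across the brain" needs an explicit voxel set. The
  default is the intersection of finite, nonzero voxels across all cohort
  maps, which is reproducible without any external template and strips
  zero-padded margins; an explicit mask file overrides it.
- **Ties.** Selection k is `round-half-up(f * |mask|)`; ties at the k-th
  order statistic are broken by ascending linear voxel index, so exactly k
  voxels are always selected and atlas conservation ($\sum_v a(v) = k$) is
  exact. The same policy applies to fROIs and group ROIs.
- **Fisher z.** Correlations are clamped to $\pm(1 - 10^{-7})$ before
  `atanh` so that identical halves (which occur in noise-free simulations)
  give a large finite z rather than infinity. Parcels with fewer than two
  usable voxels, or zero variance in either half, are omitted from the mean
  with a warning.
- **Z vs r ordering.** The Fisher transform is applied per parcel and the
  z-values averaged (the variance-stabilized aggregate); the exclusion rule
  is applied to the mean *raw* r, which is sign-equivalent. Both aggregates
  are emitted so either convention can be compared against.
- **Per-fold fROI statistic.** With $\ge 2$ held-in runs the fold statistic
  is the across-run one-sample t of the per-run contrasts; with a single
  held-in run it is that run's contrast map. Refitting a first-level GLM per
  fold is out of scope (the package consumes first-level outputs), and the
  across-run t is the natural in-scope ranking statistic; fold independence,
  and hence unbiasedness, is unaffected.
- **Degenerate inputs.** Zero-variance voxels in group t-maps become missing
  (never infinite); all-nonpositive t-maps legitimately produce empty
  fixed-p selections, whereas an empty top-fraction selection is an error;
  a zero/zero lateralization index is defined as 0 with a warning.
- **Quantiles** in marker summaries are type-7 (linear interpolation between
  order statistics), stated because cohort-table comparisons depend on it.
- **Sessions with one run** cannot be split-half-correlated or
  cross-validated; they are flagged for visual review in QC and contribute
  only voxel counts (when a precomputed t-map with dof is supplied) to the
  marker table.

## The synthetic-data generator

`ground_truth()` + `sim_config()` + `simulate_cohort()` generate cohorts in
which every pipeline quantity has a known (or Monte-Carlo-computable) truth.
The generative model:

- a population amplitude landscape $A(v)$: three Gaussian blobs (peak 2,
  sd 12 mm) at canonical left-hemisphere language-network foci — inferior
  frontal (−50, 20, 8), posterior temporal (−54, −40, 2), anterior temporal
  (−56, −10, −6) — each with a mirrored right-hemisphere homologue whose
  amplitude is multiplied by an asymmetry factor (default 0.5, making the
  network left-dominant);
- per subject: isotropic normal jitter of each blob centre (sd 6 mm,
  emulating residual inter-individual variability in region locations) and a
  lognormal amplitude scale (meanlog 0, sdlog 0.3, emulating trait/state
  differences in overall response strength);
- per run: "language" $= sA_j(v) + \varepsilon$, "control" $= \varepsilon$,
  with i.i.d. Gaussian noise of sd 0.5 (a quarter of the blob peak). The
  zero-mean control keeps the contrast equal to the activation landscape
  while still exercising every two-condition code path;
- the subject t-map is the across-run one-sample t of the per-run contrasts
  (dof = runs − 1). The default 6 runs per subject sits within the typical
  2–8-run range of localizer designs and gives the t-map enough degrees of
  freedom for p < 0.001 voxel counts to be non-trivial;
- defaults: 200 subjects on the 4 mm MNI bounding-box grid (46×55×46,
  116,380 voxels). Per-subject seeds are derived from the master seed plus
  the subject index, so cohorts are bitwise reproducible and any single
  subject can be regenerated alone.

What the generator does *not* emulate: spatially autocorrelated noise,
hemodynamic time series, physiological artefacts, motion, or surface meshes
(surface code paths are exercised with synthetic vertex vectors). Passing
tests therefore demonstrate the *statistical* correctness of the pipeline —
conservation, unbiasedness, probability recovery, monotonicity — not
robustness to scanner-specific artefact structure.

## Validation design and problem sizes

The test suite validates each operation against an independent oracle
(exhaustive sort-based selection, two-pass covariance, frozen `scipy`
inverse-survival critical values, textbook one-sample t) on fixtures of at
most 1,000 voxels, and the pipeline's statistical claims on simulated
cohorts: atlas values recover the Monte-Carlo selection probabilities
$q(v)$ within $3\sqrt{q(1-q)/n}$ at $\ge 99\%$ of voxels ($n = 500$
subjects, 9,600-voxel grid, 4,000-draw reference); cross-validated effect
sizes are unbiased under both null (500 simulated subjects) and signal (200
subjects, true effect 0.8) conditions; split-half z falls monotonically with
noise. These desk-scale sizes were chosen once as the smallest cohorts at
which the binomial and CLT bounds being tested are sharp.

`scripts/acceptance.R` re-runs the full default-scale study (200 subjects,
6 runs, 4 mm grid) from scratch and reports the headline quantities — mask
conservation, hemisphere overlap maxima, laterality, t-vs-contrast
correlation, marker medians, stability curve, and recovery rate — as JSON.

## Known limitations

- Percent-signal-change conversion of effect sizes is the caller's
  responsibility: markers are reported in the units of the input maps.
- Whether per-subject top-fraction selection should pool hemispheres or run
  per hemisphere is a genuine design fork; the package pools globally (which
  preserves hemispheric asymmetries in the atlas) for both volume and
  surface domains.
- The fixed-p atlas interpretation differs from the top-fraction one (the
  proportion *significant* vs the proportion in the *top decile*); the two
  rules cannot be mixed in one atlas and `build_atlas()` enforces this.
- Parcels written as a single NIfTI label volume lose overlap between
  parcels; overlapping parcel sets should be kept as in-memory objects or
  one mask per file.
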