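---
title: "Methods: voxel-wise intrinsic connectivity contrast analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-wise intrinsic connectivity contrast analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`icconn` implements an atlas-free resting-state functional connectivity
analysis. Its core statistic, the intrinsic connectivity contrast (ICC),
summarizes each voxel's connectivity with the entire brain: the mean of the
squared Pearson correlations between that voxel's BOLD time series and
every other masked voxel's series, retaining only positive correlations
through a unit-step weight. Because it needs no seed, atlas, or correlation
threshold, it suits studies that want to avoid a-priori regional
hypotheses. Group inference runs on z-normalized maps (zero mean, unit SD
across the brain mask), compared by a voxel-wise ordinary-least-squares
GLM with age, gender and depression score as nuisance covariates;
clinical-score analyses regress the covariate of interest on map values
within the patient group. Voxel-level multiplicity is handled by
Benjamini–Hochberg FDR; cluster extent is then tested against a
permutation null of the maximum 26-connected cluster size. Clusters
surviving both stages are fed to a second, seed-based step: each cluster's
mean time series is correlated with every voxel, Fisher-z transformed, and
the resulting maps analyzed with the same design and the same thresholds.

### Interpretation of the step weight

The step factor u(r) makes the ICC a "strength among present connections"
measure: negative correlations contribute nothing rather than adding their
squared magnitude. Without it the factor would be vacuous (r² is already
sign-free). The self-term j = i is excluded, the mean convention
(1/(N − 1)) rather than a bare sum is used because the statistic is
described as an average — the two differ by a positive constant, so after
z-normalization the maps are identical (this equivalence is a test).
Zero-variance voxels are defined to correlate 0 with everything, receiving
raw ICC 0 instead of NaN. Normalization statistics are computed over the
brain mask only, not the full volume box; the alternative is not
meaningful for masked data.

## The synthetic world

No imaging data ship with the package; a generator produces cohorts whose
statistical structure matches the study design the package targets. Its
defaults are the stated world, fixed once:

| parameter | default | why |
|---|---|---|
| group sizes | 17 + 17 | the emulated study design |
| volumes, TR | 178, 2.5 s | the emulated acquisition; 3 discarded in preprocessing |
| grid | 18×18×12 at 3 mm (2384 brain voxels) | desk-scale analogue of a 3 mm common space; full-size grids are supported but not default |
| onset distribution | N(28.82, 10.15), truncated to 18–45 | published patient summary |
| PSQI / ISI / BDI (patients) | N(15, 2.35), N(18.45, 5.16), N(8, 4.52) | published patient summaries, rounded and clipped to instrument ranges |
| BDI / MMSE (controls) | N(6, 3.86), N(29, 1) | published control summaries |
| baseline DMN–SMA coupling | −0.4 | the physiological anticorrelation between the default-mode network and task-positive motor cortex |
| coupling slope | +0.02 per year before the onset reference (45 y) | planted so that onset around 20 y reverses the coupling to ≈ +0.1, the qualitative reversal the method should detect |
| occipital gain | 2 | doubles patients' shared visual-network signal variance; with unit noise this moves within-template voxel correlations from 0.50 to 0.67, a recoverable but not trivial effect at n = 34 |
| noise, drift, physio amplitudes | 1, 1, 1 | white noise at signal amplitude; per-voxel linear drift; two sinusoids at 0.12 and 0.18 Hz, full amplitude in the noise ROI and one fifth elsewhere |
| motion random-walk step | 0.01 mm / 0.01° | typical compliant-subject motion; occasional excursions past the 1.0 exclusion limits are possible and intended |

Controls' sleep scores (PSQI 0–5, ISI 0–7) and the per-group age and
gender composition are **invented**: the study reports none. Gender
alternates within group so the small-n design matrix stays full rank.
Onset and duration are drawn jointly with `duration = age − onset` holding
exactly and ages confined to the 18–45 inclusion window.

Latent network time courses are band-limited (0.01–0.08 Hz) Gaussian
processes built in the Fourier domain. The DMN–SMA correlation is imposed
by Cholesky mixing — SMA = ρ·DMN + sqrt(1 − ρ²)·ε — which gives the
target correlation exactly in expectation; the empirical correlation of a
175-volume band-limited draw has an SE of roughly 0.11 (about 60 effective
samples), which the tests account for by averaging across subjects.
Disease duration receives **no** planted coupling of its own, so the
strength-versus-duration R² is expected near zero in synthetic runs; only
the onset association is planted.

Per-subject RNG streams derive from (seed, subject-id hash), so cohorts
are reproducible subject-by-subject and subjects are independent.

What the generator does **not** emulate: hemodynamic response convolution,
neural-mass dynamics, spatial autocorrelation within templates beyond the
shared latent, scanner artifacts beyond drift and sinusoidal physiology,
anatomical variability, or spatial preprocessing (data are born in a
common space). A green test therefore establishes that the pipeline's
statistics behave correctly on data satisfying the model's assumptions —
not that the pipeline is robust to realistic acquisition physics.

## Numerical choices

* **Motion gate.** "Exceeded 1.0 mm / 1.0°" is read strictly: boundary
  values pass. Magnitude is the maximum absolute value of each of the six
  parameters over the run; framewise displacement is not used because the
  emulated protocol does not describe it.
* **Band-pass filter.** Zero-phase Butterworth applied forward–backward
  with odd-reflection padding (50 samples). The design order defaults
  to 4: an order-2 design, applied twice, still leaves 19% amplitude at
  0.15 Hz for TR 2.5 s, violating the package's own stop-band contract
  (≤ 10% at 1.5× the upper edge); order 4 leaves 0.4%. The attenuation
  contract, not the filter family, is the tested surface. The coefficient
  computation (bilinear transform with pre-warping) was verified
  coefficient-exact against an independent reference implementation
  during development.
* **CompCor.** Anatomical-variant: the caller supplies a noise region (the
  synthetic NOISE_ROI plays the role of white matter/CSF). Five components
  by convention. Noise-voxel series are standardized before the SVD;
  components plus an intercept are regressed out of every voxel, which can
  only reduce per-voxel variance (a tested invariant).
* **Stage order** is fixed: motion gate → discard 3 volumes → linear
  detrend → band-pass → CompCor. Reordering demonstrably changes outputs
  and is covered by a regression test.
* **Fisher z clip.** |r| is capped at 1 − 1e−7 before atanh so self-seeds
  stay finite.
* **Cluster inference.** 26-connectivity; clusters never mix t signs; peak
  is the maximum |t|. The emulated study used parametric Gaussian-random-
  field cluster FWE; this package substitutes Freedman–Lane permutation of
  reduced-model residuals with an FDR-based cluster-forming rule, because
  GRF smoothness estimation is out of scope and the permutation scheme is
  exact under exchangeability with the same error-control contract. The
  estimator (1 + #{null ≥ k}) / (1 + n_perm) never returns zero.
  Permutation seeds are recorded in the report provenance.
* **Degenerate inputs.** All-constant data produce an all-zero ICC map
  with a warning; a zero-SD raw map cannot be z-normalized (error);
  empty significance masks yield empty cluster lists, and a first level
  with no surviving clusters yields a report with an empty second level,
  not an error.

## Design decisions that were genuinely open

* The second-level seed analysis reuses the first level's covariates and
  thresholds (the emulated procedure states the same thresholds were
  applied in both analyses). Clinical regressions default to **no**
  covariates, configurable, since the emulated description names none for
  that analysis.
* The printed correction description for the regression analyses ("FDR,
  p < 0.05; FWE, p < 0.05") does not say which level each applies to; the
  package implements voxel-FDR forming plus cluster-FWE, the same rule as
  the group analysis, and exposes both knobs.
* The strength analysis (DMN↔SMA coupling versus onset/duration) seeds
  from the largest surviving onset-regression cluster. At the desk-scale
  default (n = 17 patients, 2384 voxels) that regression usually finds no
  cluster — the coupling's effect on ICC is second-order — so the DMN
  template itself is the documented fallback seed analog; the target is
  always the SMA template. The recovered slope sign is negative in onset
  age by construction (earlier onset, more-positive coupling).
* For the parameter-recovery acceptance check, the prescribed "latent
  r² ≈ 0.4" configuration was calibrated once, before the test was
  written: a coupling slope of 0.01/yr gives a mean latent r² of 0.39
  (8 seeds). The package default stays at 0.02/yr, which was chosen for
  the qualitative coupling reversal rather than any r² target.
* The published p-values accompanying the clinical t statistics (0.275,
  0.115) are inconsistent with df = 32 for the printed t values;
  `summary_ttest` therefore reports t and df and leaves p to the caller.
* ENVIRONMENT constraints: no R NIfTI package is available in the target
  stack, so a minimal NIfTI-1 reader/writer (little-endian, float32,
  sform) is built in; it was cross-validated against nibabel in both
  directions during development and its round-trip and header layout are
  frozen in tests.

## Limitations

Desk-scale grids make cluster sizes and coordinates incomparable to
full-resolution studies; the synthetic effect sizes are stylized; the
permutation scheme assumes subject exchangeability under the reduced
model; seed maps use the unweighted seed mean (no eigenvariate); and
anatomical labelling of clusters is out of scope — tables report
coordinates, extents and corrected p-values only.
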