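# icconn

Voxel-wise resting-state fMRI functional connectivity analysis built around
the **intrinsic connectivity contrast (ICC)**, with a two-step
voxel-wise-then-seed-based procedure, covariate-adjusted group and
clinical-score inference, and a synthetic BOLD cohort generator that makes
the whole chain testable without any acquired data.

## Who this is for

Researchers studying group differences in whole-brain resting-state
connectivity (the motivating use case is primary insomnia patients versus
matched controls) who want an atlas-free, threshold-free voxel-to-brain
connectivity metric, principled multiple-comparison control, and a fully
reproducible synthetic test bed for their analysis code.

## The statistic

For masked voxels *i*, *j* with Pearson correlation *r*<sub>ij</sub>, the
ICC of voxel *i* is the mean strength of its positive connections to the
rest of the brain:

    ICC_i = (1 / (N - 1)) * sum_{j != i} r_ij^2 * u(r_ij),   u(r) = 1 if r > 0 else 0

Raw maps are z-normalized over the brain mask (zero mean, unit SD) for
group statistics. The analysis then proceeds in two steps:

1. **Voxel-wise:** per-subject ICC z maps are compared across groups with an
   ANCOVA-style GLM (covariates: age, gender, BDI), or regressed on clinical
   variables (age of onset, disease duration, ISI) within patients.
   Voxel-level significance is Benjamini–Hochberg FDR at p < 0.05; cluster
   extent is tested against a max-extent null built by Freedman–Lane
   permutation (cluster-level FWE).
2. **Seed-based:** every surviving cluster becomes a seed; Fisher-z
   seed-to-brain correlation maps are analyzed at the same thresholds,
   describing *where* connectivity differs.

The synthetic cohort plants two effects to recover: doubled shared-signal
variance in a bilateral visual template for patients (occipital
hyperconnectivity), and a latent DMN–SMA coupling that rises linearly with
earlier insomnia onset, reversing the physiological anticorrelation for
early-onset patients.

## Worked example

```r
library(icconn)
cfg <- pipeline_config(1, n_perm = 200L, second_level = FALSE,
                       regression_outcomes = "age_of_onset")
report <- run_two_step(cfg)
print(report)
head(cluster_table(report$group$clusters), 4)
```

prints (exact output of this code):

```
<icconn_report> seed 1, 34 subjects included (0 excluded)
  group contrast: 15 FWE-surviving cluster(s)
  regression on age_of_onset: 0 cluster(s)
  DMN-analog/SMA strength: R2 vs onset = 0.494, vs duration = 0.0079
      x     y    z  k        p_fdr       p_fwe direction
1 -10.5 -16.5 -1.5 81 3.042253e-10 0.004975124  increase
2  10.5 -19.5 -1.5 80 1.399320e-10 0.004975124  increase
3   7.5  10.5  7.5 51 6.705424e-05 0.004975124  decrease
4   4.5  -4.5  7.5 28 7.473485e-04 0.004975124  decrease
```

Reading this: the two largest `increase` clusters (k = 81 and 80) are the
two halves of the planted bilateral visual template, recovered with
cluster-level FWE p ≈ 0.005; the `decrease` clusters are the relative
shift forced elsewhere by per-subject z-normalization. The strength branch
reports that the DMN-analog seed's mean Fisher-z connectivity with the SMA
template explains 49% of variance in age of onset (the planted
association) and, as planted, essentially none in disease duration. The
onset regression finds no voxel-level cluster at n = 17 — an honest
desk-scale outcome.

Clinical worked example, recomputed from published summary statistics:

```r
summary_ttest(8, 4.52, 17, 6, 3.86, 17)$t   # 1.3873 (BDI)
summary_ttest(29, 1, 17, 28, 2, 17)$t       # 1.8439 (MMSE)
```

## Command line

```sh
Rscript -e 'icconn::icconn_cli()' simulate --seed 1 --out data/
Rscript -e 'icconn::icconn_cli()' analyze  --seed 1 --n-perm 300 --out results/
```

Subcommands: `simulate`, `preprocess`, `icc`, `analyze`, `report`;
configuration via `--config config.json` (see `read_pipeline_config`).

## Documentation

See the methods vignette (`vignettes/icconn-methods.Rmd`) for the model,
the synthetic world's assumptions, numerical choices and limitations.
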