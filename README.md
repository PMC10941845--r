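# phenomap

Comparative phenotyping of chronic obstructive pulmonary disease (COPD)
on paired inspiratory and registered expiratory chest CT, for
quantitative-imaging researchers who want the three standard analysis
lenses — and the statistics that compare them — in one tested R package:

1. **Parametric response mapping (PRM)**: each lung voxel is classified
   jointly by its inspiratory/expiratory attenuation into normal lung
   (insp (−950, −810] HU, exp [−856, −500] HU), functional small-airway
   disease (fSAD: insp (−950, −810], exp [−1000, −856)), emphysema
   (insp [−1000, −950], exp [−1000, −856)), or excluded, with relative
   class volumes and LAA-950 / LAA-856 metrics.
2. **Regional anomaly scoring**: overlapping 50³-voxel patches are
   embedded into fixed-length feature vectors; a reference density
   (Gaussian mixture, BIC-selected) is fitted to patches with <1%
   emphysema from subjects without airflow obstruction, and every patch
   is scored by its negative log-likelihood under that reference.
   Patient scores aggregate patch scores; anomaly maps are normalized
   by the cohort's 5th/95th score percentiles.
3. **Latent-structure analysis**: PCA with Horn's parallel analysis and
   Kaiser retention, mini-batch k-means and Gaussian-mixture clustering
   selected by Silhouette / Davies–Bouldin / Calinski–Harabasz rank
   aggregation, per-subject cluster volumes, cluster maps, and t-SNE
   visualization with an out-of-sample transform.

A statistics layer compares the three: Jonckheere–Terpstra ordered
trend tests across GOLD stages, Tukey post-hoc contrasts, bootstrap
Pearson confidence intervals with interpretive bands, Zou's CI for
differences of dependent overlapping correlations, Holm–Bonferroni
adjustment, linear mixed models (random study-site intercept, ML fits,
likelihood-ratio tests, adjusted conditional R²), and regression-based
Bland–Altman limits of agreement for non-constant bias.

Because real paired-CT cohorts are not redistributable, the package
ships a synthetic cohort generator with voxel-level ground truth:
stage-graded emphysema/fSAD lesion burdens calibrated to published
per-GOLD-class PRM volumes, truncated-normal HU models that place each
tissue class inside its PRM box, clinical covariates linearly linked to
lesion burden, and a random site effect. Every pipeline stage is tested
against it end to end.

## Worked example

```r
library(phenomap)

cfg <- cohort_config(n_per_stage = 5, seed = 7)
cohort <- generate_cohort(cfg)
#> <phenomap cohort> 30 subjects (5 per stage), grid 64x64x48

compute_prm(cohort$subjects[[25]]$study)   # a GOLD3 subject
#> <PRM> Normal 40.4% | fSAD 41.2% | Emph 18.4% (excluded 0.00% of lung)

feats <- embed_cohort(cohort, d = 128)
#> <latent features> 120 patches x 128 dims (histogram) from 30 subjects

an <- anomaly_stage(feats, k_range = 1:2)
#> <anomaly stage> 120 patches (37 reference), 30 subjects, bounds [20.79, 1376743.90]

pt <- an$patient
round(tapply(pt$patient_score, factor(pt$stage,
      c("control", paste0("GOLD", 0:4))), mean), 1)
#>   control     GOLD0     GOLD1     GOLD2     GOLD3     GOLD4
#>      22.3      33.0   20693.0   12243.1  202716.8 1297250.1

jonckheere_terpstra(split(pt$patient_score,
      factor(pt$stage, c("control", paste0("GOLD", 0:4)))))
#> Jonckheere-Terpstra: JT = 352.0 (E = 187.5, z = 5.97), p = 1.363e-09 [increasing, normal]
```

Reading the output: the GOLD3 subject's lung is 18.4% emphysema and
41.2% fSAD by PRM; patient-level anomaly scores (mean patch NLL in
nats; larger = further from the healthy-lung reference) rise over
severity stages by several orders of magnitude, and the
Jonckheere–Terpstra test confirms the ordered trend (JT = 352 against a
null expectation of 187.5, one-sided p ≈ 1.4 × 10⁻⁹).

The full pipeline — simulate → PRM → features → anomaly → cluster →
stats, with CSV outputs per stage and a Markdown report — runs from one
configuration object:

```r
res <- run_pipeline(analysis_config(n_per_stage = 10, seed = 42), "results_dir")
make_report("results_dir")
```

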