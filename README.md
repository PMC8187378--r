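# metlink

Multi-omic correlation selection and metabolic subtype discovery for
paired tumor studies.

## The problem

In liver-cancer cohorts profiled at three molecular levels — metabolic
gene expression in tumor tissue, tissue metabolite abundances (tumor and
adjacent non-tumor, paired per patient), and serum metabolite abundances —
a natural question is which serum metabolites are downstream read-outs of
tumor metabolism, and whether they stratify patients into subtypes with
different prognosis.  `metlink` implements a permutation-calibrated
**two-step correlation analysis** answering that question, plus the
downstream subtype machinery:

1. **Screen.** Features are tested tumor vs adjacent non-tumor with a
   paired t-test; Benjamini–Hochberg FDR < 0.05 keeps tumor-specific
   candidates.
2. **Step 1 (genes ↔ tissue metabolites).** Spearman correlations
   `c_ij` are computed on tumor samples.  Per-feature selection scores are
   the mean absolute correlations
   `G_i = Σ_j |c_ij| / J` and `T_j = Σ_i |c_ij| / I`.
   The selection threshold is not fixed a priori: it is the intersection
   of the observed coefficient density with the average density under
   permutations that destroy the sample linkage between the two matrices.
   Features with `G` (or `T`) strictly above the threshold are kept.
3. **Tumor specificity.** Selected tissue metabolites must additionally
   pass a two-sided 1.5 fold-change between tumor and non-tumor tissue.
4. **Step 2 (tissue ↔ serum).** The tumor-specific metabolite panel is
   correlated with serum metabolites on patient-matched samples; serum
   metabolites with mean absolute correlation `S_k = Σ_m |c_km| / M` above
   the step-2 threshold (fixed ±0.15 or re-derived by permutation) form
   the serum panel.
5. **Subtypes.** Each panel (genes / tissue metabolites / serum
   metabolites) is clustered by subsampled consensus clustering (80% item
   subsampling, Ward linkage on 1 − Spearman, k chosen by the CDF
   delta-area rule or fixed at 3), yielding MetGene / TissueMet / SerumMet
   patient clusters.
6. **Prognosis and validation.** Kaplan–Meier curves, log-rank tests, a
   Cox worst-vs-rest hazard ratio with 95% CI and a proportional-hazards
   check per layer; Fisher's exact association with clinical covariates;
   and a centroid-correlation permutation test matching clusters across
   independent cohorts.

Because the motivating cohort is not public, the package ships a
first-class **synthetic cohort generator** (`generate_cohort()`) with
planted gene–metabolite correlation blocks, latent patient subtypes and
subtype-dependent exponential survival; every stage is validated by
recovery and null-calibration experiments against this ground truth.

## Worked example

```r
library(metlink)

co  <- generate_cohort(cohort_config(seed = 1))   # 60 patients, 3 subtypes
res <- two_step_select(co$gene_matrix, co$tissue_met_matrix,
                       co$serum_met_matrix, co$pairing,
                       two_step_params(n_permutations = 1000, seed = 101,
                                       step2_method = "permutation"))
res
#> two_step_result: 50 genes, 20 tissue metabolites (20 tumor-specific), 15 serum metabolites
#>   step-1 thresholds [-0.2587, 0.2289] (degenerate); step-2 thresholds [-0.2587, 0.3483] (degenerate)

mean(co$truth$planted_gene_ids %in% res$gene_panel)        # 1    (50/50 recovered)
mean(co$truth$planted_serum_met_ids %in% res$serum_panel)  # 1    (15/15, no background)

m  <- log2(co$serum_met_matrix[res$serum_panel, co$pairing$patient_id])
cc <- run_consensus(m, consensus_params(n_resamples = 250, k_override = 3))
adjusted_rand_index(cc$labels, co$truth$subtype_label)     # 0.896 vs planted subtypes

sv <- co$clinical
cox_worst_vs_rest(sv$time_months, sv$event, cc$labels[sv$patient_id])
#> Cox worst-vs-rest: group '3', HR 3.63 [1.92-6.86], log-rank p = 2.41e-05
```

The step-1 upper threshold (0.23 here) is the point where the observed
gene–metabolite correlation density rises above the permutation null and
stays above it — on the real cohort the analogous values were ±0.165.
The `(degenerate)` tag reports that the negative side found no crossing
(this generator plants only positively correlated blocks) and fell back
to the 0.95 null quantile; selection uses the positive threshold.
The hazard ratio shows the recovered worst-prognosis cluster (planted
hazard ratio 3) is detected with a confidence interval excluding 1.

The same flow is scriptable end to end:

```sh
Rscript inst/cli/metlink.R simulate --seed 7 --out cohort/
Rscript inst/cli/metlink.R run-all --config run.json --out results/
```

where `run.json` holds the `pipeline_config()` blocks (see
`?pipeline_config`).  `run-all` writes panels, cluster labels, k-selection
tables, KM curves, Cox and Fisher tables, cross-layer agreement, and a
`manifest.json` with an MD5 digest per output — identical config + seed
reproduces byte-identical digests.

## Documentation

The methods vignette (`vignettes/metlink-methods.Rmd`) describes the
model assumptions, the threshold-calibration numerics, what the synthetic
generator does and does not emulate, and known limitations.
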