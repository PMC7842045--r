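# methcorr

Infer gene expression from Illumina 450K/EPIC DNA methylation profiles.

RNA in archival (FFPE) tumour tissue is often too degraded for reliable
sequencing, while DNA methylation is measured robustly on BeadChip arrays
even from fixed material. For many genes, expression is tracked by the
methylation state of CpG sites across the genome — positively by some,
negatively by others. methcorr trains, per gene, a regression model that
exploits this: it screens genome-wide CpG–gene Spearman correlations in
two discovery sample sets, keeps up to 100 positively and 100 negatively
expression-correlated CpG sites per gene, summarises their β-values into a
single **MethCORR score**

```
MCS = ( Σ_pos β  +  Σ_neg (1 − β) ) / n_available ,
```

and fits `RNA = B₀ + B₁·MCS + … + Bₙ·MCSⁿ` (n = 1–4, chosen by
10×-repeated 10-fold cross-validated RMSE with a ≥ 5% improvement rule).
Genes whose models reach R² > 0.16 in both the discovery and an
independent validation set ("MethCORR genes") are kept in a portable model
store that can then be applied to new methylation matrices — fresh-frozen
or FFPE, 450K or EPIC (missing probes are tolerated through an adaptive
score denominator) — to produce inferred expression (iRNA) profiles.

A fully seeded synthetic cohort generator with known ground truth
(latent methylation signals, readout probes, true coefficients) makes
every stage testable without any external download.

## Worked example

```r
library(methcorr)

spec   <- synthetic_spec(n_samples = 120, n_signal_genes = 30,
                         n_null_genes = 20, seed = 42)
cohort <- generate_cohort(spec)        # matched beta + expression matrices

store <- train(cohort$meth, cohort$expr, methcorr_config(seed = 7))
store
#> MethCORR model store
#>   genes:       30
#>   CpG sites:  601 (601 unique probes)
#>   platform:    450K
#>   rejected:   20 genes

glance(store)
#>   n_genes n_cpg_sites n_rejected median_r2_discovery median_r2_validation
#> 1      30         601         20               0.584                0.602
```

All 30 genes with a planted methylation–expression link were modelled and
all 20 unlinked null genes were rejected; the median validation R² of
about 0.60 matches the generator's signal fraction (60% of expression
variance carried by the latent methylation signal). Applying the store to
the held-out validation samples and comparing inferred with observed
expression:

```r
held_out <- split_samples(colnames(cohort$meth), 7)$validation
res  <- infer(store, cohort$meth[, held_out])
conc <- evaluate_concordance(res$irna, cohort$expr[, held_out])
glance(conc)
#>   n_samples n_genes median_r2 median_rmse
#> 1        24      30     0.869       0.738

recovery_report(store, cohort)
#>   sensitivity null_flag_rate probe_recall degree_accuracy median_r2_validation
#> 1           1              0            1               1                0.602
```

Each held-out sample's inferred profile correlates with its observed
profile at a median intra-sample R² of 0.87, and every true readout CpG
was recovered into the selected site lists. `autoplot(conc)`,
`autoplot(store)` and `plot_gene_fit()` give the corresponding figures;
`tidy(store)` returns the per-gene model table.

A command-line front end is installed with the package
(`system.file("exec/methcorr", package = "methcorr")`) with subcommands
`train`, `infer`, `evaluate` and `simulate` over TSV matrices and model
store directories.

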