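# originatlas

Tracing the cell-of-origin of bulk tumors from a single-cell chromatin
accessibility atlas.

Papillary renal cell carcinoma (pRCC) is heterogeneous: tumors seeded by
different normal kidney cell types — proximal tubule (PT) cells versus
collecting-duct principal cells (CD_PC) — retain the accessible-chromatin
signature of that originating cell and follow different clinical courses.
`originatlas` implements, as reusable and fully tested R functions, the
analysis chain that makes this tracing possible:

1. **Barcode quality control** for scATAC-seq fragment files: total-fragment
   counts, the fraction of fragments within ±1 kb of a TSS, and a
   *nucleosome banding score* — the summed spectral density of the
   insert-size histogram at periods of 100–300 bp, computed with
   `spec.pgram` (detrend, split-cosine-bell taper 0.5, 30% padding,
   modified Daniell smoother of span 20). Cutoffs are fitted as 2-component
   Gaussian mixtures and floored at the standard defaults
   (log10 fragments > 3.4, TSS ratio > 0.15, log10 banding > −1.75),
   keeping the stricter of the two.
2. **LSA clustering**: binary 5 kb window-by-cell matrix, zero/top-5%
   window filtering, log TF-IDF `ln(1 + 10^4·tf·idf)`, truncated SVD
   (components 2–40), shared-neighbor-weighted KNN graph (k = 15), Louvain
   modularity at resolution 1, clusters of ≤ 50 cells unassigned.
3. **Peak specificity**: master-peak merging, high-quality peaks (> 5% of
   cells accessible in some cluster), vst-style variable peaks, and
   Jensen–Shannon specificity `s = 1 − √JSD(q, e_t)` (base-2) with final
   score `s²` times the scaled proportion; the top 20,000 entries give the
   cell-type-specific peak set.
4. **Origin mapping** by three independent statistics: peak-overlap
   permutation tests (1,000 draws from the pooled specific peaks, one-sided
   binomial tail, BH adjustment); Pearson correlation of log-CPM +
   quantile-normalized profiles over shared variable peaks with a 2-cut
   hierarchical clustering of samples; and similarity scores from
   one-vs-rest L1 logistic models trained on a 50-cell × 20-replicate
   pseudo-bulk panel with per-class offset `log(f/(1−f))` and predicted at
   offset 0.
5. **Co-accessibility and gene activity**: genebody-anchored accessibility
   (−200/+100 bp around the TSS), KNN cell aggregation (k = 30), a
   distance-penalized graphical lasso within sliding 500 kb windows
   (250 kb constraint), partial-correlation scores, edges at ≥ 0.1, and
   per-cell-normalized gene activities.
6. **Origin-derived features and enrichment**: cell-type feature genes
   (pct.1 > 0.5, avg logFC > 0.5), subgroup feature genes from a
   negative-binomial exact test (|logFC| > 1, FDR < 0.05, logCPM > 5),
   their intersection as origin-derived features, expression-based
   2-cut subgrouping of a bulk cohort, and a bootstrap test for
   clinical-label (CIMP) enrichment in a subgroup, reported alongside the
   exact hypergeometric tail.

A synthetic-data module (`sim_config()`, `simulate_fragments()`,
`simulate_peak_matrix()`, `simulate_bulk_tumors()`,
`simulate_expression()`) generates every input with known ground truth, so
each stage's guarantees are checked end to end without any external
download.

## Worked example

```r
library(originatlas)

cfg <- pipeline_config(seed = 42,
                       sim = sim_config(seed = 42,
                                        cells_per_type = c(type1 = 120,
                                                           type2 = 120,
                                                           type3 = 120),
                                        n_background = 150))
res <- run_pipeline(cfg, outdir = "run", verbose = TRUE)

length(res$retained)                            # 360  (QC keeps the genuine cells)
mean(res$similarity$argmax == res$tumors$origins)  # 1   (similarity argmax = true origin)
mean(res$correlation$argmax == res$tumors$origins) # 1   (correlation argmax = true origin)
res$enrichment
#> Label enrichment: 8 of 8 labeled samples in a subgroup of 41 (cohort 255)
#>   bootstrap (10000 reps): mean 1.2815, sd 1.0159
#>   normal-tail p = 4.24e-11
#>   exact hypergeometric P(X >= 8) = 2.41e-07
```

On this synthetic atlas the QC filter retains all 360 genuine cells and
rejects the 150 background barcodes, both origin-mapping statistics assign
every purity-0.8 tumor to its true originating cell type, the expression
cohort splits into the planted 214/41 subgroups, and all 8 CIMP-labeled
samples land in the minority subgroup — an arrangement whose probability
under random subgroup draws is ~3e-11 (normal fit) and 2.4e-7 (exact
hypergeometric).

## Tests

```r
testthat::test_dir("tests/testthat", package = "originatlas",
                   load_package = "installed")
```

The suite covers every module with closed-form oracles (entropy arithmetic
for the Jensen–Shannon scores, exact binomial/hypergeometric tails, direct
matrix inversion for the graphical lasso) and property-based checks on the
synthetic atlas (AUROC, precision/recall, adjusted Rand index, type-I error
calibration), plus bit-reproducibility of the whole pipeline under a fixed
seed.
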