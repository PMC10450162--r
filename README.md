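# antisensePairs

Many eukaryotic genes are overlapped by a non-coding transcript running from
the opposite DNA strand — in budding yeast these include CUTs, SUTs and XUTs.
A recurring question is whether antisense transcription suppresses sense
transcription: if it does, perturbations that change antisense levels should
move sense levels the other way. A direct genome-wide way to ask this is to
catalog all gene/antisense pairs, measure differential expression of both
members of each pair between two conditions (e.g. a deletion mutant versus
wild type, in TT-seq or RNA-seq counts), and correlate the two fold-change
vectors. A strong *positive* Pearson correlation argues against widespread
antisense-mediated repression.

`antisensePairs` implements that analysis as a reusable, fully tested
pipeline:

1. **Pair catalog** — strand-aware interval overlap join of genes against
   ncRNAs (≥ 1 shared base, same chromosome), keep opposite-strand pairs,
   keep the longest ncRNA per gene (ties: smaller start, then smaller id).
2. **Differential expression** — a transparent negative-binomial Wald test,
   treatment versus control. With median-of-ratios size factors
   `s_j = median_i(K_ij / geomean_i(K_i.))`, method-of-moments dispersion
   `α̂_i = max(α_floor, (v_i − m_i)/m_i²)` (pooled within-condition variance
   `v_i`, grand mean `m_i`), condition means `μ̂_T`, `μ̂_C` of normalized
   counts and pseudocount `c₀ = 0.5`:

   ```
   log2FC = log2((μ̂_T + c₀)/(μ̂_C + c₀))
   Var(μ̂_c) = (μ̂_c + α̂ μ̂_c²)/n_c
   se = (1/ln 2) · sqrt(Var(μ̂_T)/(μ̂_T + c₀)² + Var(μ̂_C)/(μ̂_C + c₀)²)
   z = log2FC / se,   p = 2·Φ(−|z|),   q = Benjamini–Hochberg(p)
   ```

3. **Correlation** — among pairs whose *gene* q-value is below an FDR
   threshold (default 0.25), the Pearson correlation `r` of gene and ncRNA
   log2 fold-changes, with a two-sided p-value from
   `t = r·sqrt((n−2)/(1−r²))` on `n − 2` df.

A synthetic-data module generates yeast-like annotations and two-condition
NB count matrices in which the true sense/antisense effect correlation `ρ`
is planted, so the whole pipeline is validated by parameter recovery.

## Worked example

Simulate a 300-gene dataset with planted correlation ρ = 0.9 and run the
analysis:

```r
library(antisensePairs)

cfg <- sim_config(n_genes = 300, rho = 0.9, seed = 7)
ann <- simulate_annotation(cfg)
cnt <- simulate_counts(ann$genes, ann$ncrnas, ann$pairs, cfg)

catalog <- build_pair_catalog(ann$genes, ann$ncrnas)
catalog
#> PairCatalog: 300 sense/antisense pairs
#>   candidates 315 | opposite-strand 300 (300 ncRNAs x 300 genes)

de_genes  <- nb_wald_test(cnt$gene_counts)
de_ncrnas <- nb_wald_test(cnt$ncrna_counts)

correlate_pairs(catalog, de_genes, de_ncrnas, fdr_threshold = 0.25)
#> Sense/antisense log2FC correlation (gene FDR < 0.25)
#>   pairs retained: 287
#>   Pearson r = 0.923, p = 2.69e-120
```

All 300 genes received an antisense partner (`antisense_fraction = 1`); 287
of them are differentially expressed at gene-level FDR < 0.25, and their
sense and antisense fold-changes correlate at r = 0.923 — the pipeline
recovers the planted ρ = 0.9 up to sampling noise and the slight attenuation
expected from estimating both fold-change vectors.

The same analysis runs from the shell on files (BED6/GFF3/TSV annotations,
TSV counts and sample sheet) via the thin CLI:

```sh
exec/antisense-pairs simulate  --out sim/ --n-genes 300 --rho 0.9 --seed 7
exec/antisense-pairs run       --config run.yaml          # pairs -> DE x2 -> correlate
exec/antisense-pairs pairs     --genes sim/genes.bed --ncrnas sim/ncrnas.bed --out pairs.tsv
```

`run` writes the pair catalog, both DE tables, the per-pair fold-change
table and a versioned `summary.json` with every stage count.

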