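# phasic

Detection of cell-cycle **phasic gene expression** — genes whose mRNA
abundance differs between the G1 and G2/M phases — from DNA-content-sorted
RNA-seq. The package is aimed at analysts working with phase-sorted bulk
RNA-seq (including exon/intron total-RNA designs) and phase-sorted droplet
single-cell RNA-seq, e.g. across embryonic development where phasic
expression emerges lineage by lineage.

## What it implements

**Bulk:** a 5-CPM replicate-set expression filter, TMM normalization, a
per-gene negative binomial Wald test of phase on `log(library)`-offset counts
(dispersion by method of moments with a median floor; t reference on
residual + prior df), BH correction, and calls at adjusted *P* < 0.1. Phasic
genes are then decomposed with empirical-Bayes moderated t statistics on
exonic (expression), intronic (transcription) and exon−intron (stability)
log-CPM into TRANSCRIPTION / STABILITY / BOTH / UNRESOLVED classes,
exploiting the rapid turnover of introns.

**Single cell:** QC (≥5000 UMI, <5% mitochondrial, ≥40% relative gene
detection), a 20%-of-cells gene filter, pseudobulk aggregation of 10
same-phase (and same-lineage) cells, and a two-part **hurdle model** per gene
— logistic detection + Gaussian abundance on log2(CPM+1), tested jointly by
likelihood ratio under `~ cell_cycle_phase + fraction_of_detected_genes`.
Pseudobulk blocks are re-randomized 100 times; each gene's call uses the
**median BH-adjusted p across permutations** and an absolute fold-change gate
of 1.1 on the log2 scale. Phase × lineage interactions are tested as
per-lineage contrasts against a reference lineage, with a
**scrambled-lineage pseudobulk** (same-phase cells of mixed lineages, matched
sample counts) as the empirical negative control, and genotypes are compared
on equal numbers of cells per phase over 100 resamples. Canonical G1/S and
G2/M gene panels support co-expression cohort analysis in unsorted
populations, and a two-sample KS test calls phase-specific activity scores
at *P* < 1e-12.

**Synthetic data:** NB count generators with log-normal baselines and
library sizes, planted multiplicative phase effects (global or
lineage-restricted), exon/intron layers with transcription/stability
drivers, mitochondrial genes and planted QC failures — each with a
machine-readable truth table, so every pipeline is scored against ground
truth. See `vignettes/phasic-methods.Rmd` for the models, parameter choices
and limitations.

## Worked example

```r
library(phasic)

sim <- simulate_preset("sc-phasic", seed = 1)      # 2000 genes, 500 cells/phase,
qc  <- qc_filter_cells(sim$counts, sim$annotations) # 10% planted at |log2FC| = 1
counts <- filter_genes_sc(qc$counts)
res <- permuted_phasic_test(counts, qc$annotations,
                            alpha = 0.05, n_permutations = 100, seed = 1)
head(res[which(res$phasic_call), ])
```

```
          gene_id median_adj_p median_log2fc passes_fc phasic_call n_permutations_used
gene0038 gene0038 2.071264e-21    -1.0395588      TRUE        TRUE                 100
gene0059 gene0059 1.458649e-29    -1.1194595      TRUE        TRUE                 100
gene0074 gene0074 2.253201e-15     1.2102620      TRUE        TRUE                 100
gene0095 gene0095 4.292721e-33     0.9847096      TRUE        TRUE                 100
gene0100 gene0100 4.089107e-15    -0.9738561      TRUE        TRUE                 100
gene0103 gene0103 3.886647e-14     1.0164954      TRUE        TRUE                 100
```

Scored against the planted truth this run makes 209 calls with sensitivity
0.995 and observed FDR 0.048 at median adjusted *P* < 0.05; the recovered
log2 fold changes sit near the planted ±1. The numbered scripts under
`analysis/` run the full workflow the same way: simulation, bulk test and
exon/intron decomposition, single-cell calling, lineage-interaction testing
with the scrambled control, genotype comparison, and panel co-expression,
each printing its summary and writing tables under `results/`.

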