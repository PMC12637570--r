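# crtkit

Haploinsufficient neurodevelopmental disorders can in principle be treated
by *cis*-regulation therapy (CRT): using CRISPR activation (CRISPRa) at an
endogenous promoter or enhancer to boost expression of the intact allele.
Doing this at scale requires knowing, for each dose-sensitive risk gene,
which candidate cis-regulatory elements (cCREs) are active in neurons and
which guide RNAs upregulate the gene specifically. `crtkit` implements that
discovery pipeline as tested, reusable R code, for statistical geneticists
and functional genomicists building or evaluating CRT screens:

1. **Gene prioritization** — per-gene de novo variant expectations
   `E = 2·N·μ` under the trio Poisson mutation model, observed/expected
   ratios with one-sided Poisson tails, and the LoF `O/E > 1` selection
   rule for haploinsufficiency candidates.
2. **cCRE harmonization** — multi-source enhancer–gene predictions are
   center-extended to ≥ 500 bp, merged by single-linkage ≥ 1 bp overlap
   (union of sources and gene links), and filtered against 2 kb promoter
   windows and protein-coding exons. Coordinates are BED-convention
   0-based half-open throughout.
3. **MPRA analysis** — 270 bp tiles with 90 bp overlaps densely covering
   each cCRE; a per-tile negative-binomial test of RNA vs DNA barcode
   counts (median-of-ratios size factors, sequencing batch as covariate,
   Wald test on the modality coefficient); active = BH `q < 0.01` and
   `log2FC > 1`; empirical FDR from scrambled controls; cCRE validation by
   the top-10%-of-scores rule.
4. **gRNA design** — exhaustive NGG protospacer enumeration on both
   strands, polyT/GC/duplicate filters, CAGE-weighted TSS or
   enhancer-center distances, six rounds of threshold-relaxing selection
   of the top 4 gRNAs per target, `G + 19 nt` spacer finalization, and
   *S. aureus* NNGRRT PAM compatibility.
5. **Single-cell CRISPRa screen analysis** — cell QC (≤ 20% mito, ≥ 900
   UMIs), gRNA assignment at ≥ 5 UMIs, cis-pair construction within 1 Mb,
   a conditional randomization test (logistic model of gRNA presence on
   cell covariates; NB score statistic for the presence indicator; B
   resampled indicator vectors; one-sided `p = (1 + #{z* ≥ z})/(B + 1)`),
   BH hit calling at FDR 0.1, and 1 Mb specificity classification.
6. **Synthetic data** — generators for every input format (FASTA, BED,
   TSV, MTX) with planted ground truth: risk-gene LoF inflation, active
   MPRA tiles, effective gRNAs with known fold changes, so every stage is
   testable end to end without external downloads.

## Worked example

```r
library(crtkit)

## 1. Prioritize haploinsufficiency candidates from trio de novo counts
ref    <- gen_reference(seed = 1, chrom_length = 1e6, n_genes = 20)
cohort <- gen_denovo_cohort(ref, n_trios = 42320,
                            risk_genes = ref$genes$gene_id[1:5],
                            lof_inflation = 2.4, seed = 1)
rec <- prioritization_records(cohort$counts, ref$mutation_rates,
                              n_trios = 42320)
cohort_oe(rec, "lof")
#> $oe
#> [1] 1.418175
#> $observed
#> [1] 71
#> $expected
#> [1] 50.06435
#> $p
#> [1] 0.003059645
```

The cohort-level LoF burden is inflated (O/E 1.42, p = 0.003) because five
genes carry a planted 2.4-fold LoF excess. `prioritize()` then keeps
implicated genes with per-gene LoF O/E strictly greater than 1.

```r
## 2. Harmonize multi-source enhancer predictions into cCREs
preds <- gen_cre_predictions(ref, n_sources = 5, n_true_elements = 20,
                             jitter_sd = 50, dropout = 0.1, seed = 1)
ccres <- harmonize(preds$sources, ref$genes, ref$exons)
head(ccres, 3)
#>     ccre_id chrom  start    end                                      sources   genes support
#> 1 ccre00001  chr1  67621  68121                                     source03 gene002       1
#> 2 ccre00002  chr1  84570  85177                                     source03 gene002       1
#> 3 ccre00003  chr1 132222 132835 source01,source02,source03,source04,source05 gene004       5
```

Each merged cCRE records which prediction sources support it and which
genes it is linked to; intervals overlapping a promoter window or exon
have been removed.

```r
## 3. Tile the cCREs and call MPRA activity (one tile planted at 4x)
tiles <- design_tiles(ccres, ref = ref)
tiles <- add_scrambled_tiles(tiles, n = 40, seed = 1)
mpra  <- gen_mpra_counts(tiles[, c("tile_id", "class")],
                         barcodes_per_tile = 100,
                         planted_active = setNames(4, tiles$tile_id[1]),
                         seed = 1)
act <- activity_test(mpra$counts, mpra$association,
                     tiles = tiles[, c("tile_id", "class")])
act[act$active, c("tile_id", "log2fc", "q")]
#>          tile_id   log2fc             q
#> 1 ccre00001_t001 1.979547 1.245592e-211
```

The planted 4-fold tile is the only active call, with an estimated
log2 fold-change of 1.98 (truth: log2(4) = 2). `validate_ccres()` rolls
tile calls up to cCRE level, `empirical_fdr()` calibrates the active
thresholds against the scrambled controls, and the screen-side functions
(`qc_and_assign()`, `run_discovery()`, `call_hits_and_specificity()`,
`gene_summary()`) take the validated elements through gRNA-level hit
calling. See the methods vignette (`vignettes/crt-discovery.Rmd`) for the
models and parameter choices.

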