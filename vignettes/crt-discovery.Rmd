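---
title: "Models and design choices in the crtkit discovery pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in the crtkit discovery pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`crtkit` re-implements, as a tested pipeline, the computational route from
trio sequencing to CRISPRa reagents for haploinsufficient disease genes:
prioritize genes whose de novo loss-of-function (LoF) burden exceeds
mutational expectation, consolidate enhancer–gene predictions into
candidate cis-regulatory elements (cCREs), measure tile-level regulatory
activity with an MPRA, design guide RNAs, and call upregulation hits in a
multiplex single-cell CRISPRa screen. This vignette documents the models,
the parameters that matter, and the choices made where the design was
genuinely open. Everything quantitative asserted here is computed by the
package's test suite or by `scripts/acceptance.R`.

## Gene prioritization

The trio mutation model treats the number of de novo variants of class
$c$ in gene $g$ across $N$ offspring as Poisson with mean
$E_{gc} = 2 N \mu_{gc}$, where $\mu_{gc}$ is the per-haploid-genome
per-generation mutation probability (supplied as input; estimating it from
sequence context is out of scope). The enrichment test is the one-sided
Poisson upper tail $P(X \ge O_{gc})$, and the selection rule keeps
implicated genes with LoF $O/E$ strictly greater than 1 — a ratio filter,
not a significance filter, so no multiple-testing correction is applied to
selection; p-values are reported for diagnostics. The LoF class is the sum
of frameshift, canonical-splice and stop-gain counts.

Two boundary conventions are explicit: a gene with $E = 0$ and $O > 0$ is
"unratable" (ratio undefined); it is flagged, excluded from selection and
warned about rather than propagating an infinite ratio silently. Cohort
aggregate O/E is the ratio of summed observed to summed expected counts
over all genes, with the Poisson tail on the sums. Published cohort-level
O/E figures often differ slightly between analyses of the same cohorts
because the variant subsets entering the sums differ; this package commits
to the single summed-ratio definition above and reports exactly what its
inputs give.

## cCRE harmonization

All user-facing coordinates are BED-convention 0-based half-open, and
"overlap" always means an intersection of at least 1 bp. Promoter windows
are the `width` bp immediately upstream of each TSS: `[tss - width, tss)`
on the + strand, `[tss, tss + width)` on the −. Gene models therefore
store the TSS as the boundary coordinate of transcription start (equal to
`start` for + genes and `end` for − genes). Windows that would extend past
position 0 are clipped with a warning; overlapping isoform windows merge.

Harmonization extends each source interval from its center (floor
midpoint) to at least `min_width = 500` bp — clipping at 0 pads right to
preserve the width — then merges across sources by single-linkage on ≥ 1 bp
overlap. Bookended (touching, non-overlapping) intervals are *not* merged,
matching standard merge semantics at distance 0. A merged cCRE's sources
and gene links are the unions over its constituents; multi-gene cCREs are
allowed. Any merged interval overlapping a promoter window (default width
2000 bp; the exclusion width is an argument, since 500 bp windows are also
in common use) or a protein-coding exon is removed. The merge is implemented on `IRanges::reduce()`/`findOverlaps()`
and is checked in the tests against a brute-force union-find oracle.

## MPRA design and activity calling

Tiles are `tile_len = 270` bp at offsets stepping by
`tile_len − overlap = 180` bp; when the last step-aligned tile falls short
of the cCRE end one extra right-aligned tile `[end − 270, end)` is added,
and cCREs shorter than a tile get a single centered tile whose flanks come
from the reference sequence. Scrambled negative-control tiles are per-base
shuffles of randomly chosen test tiles.

The activity test aggregates barcode counts per tile × modality ×
replicate (barcode-level modeling stays available in principle but
aggregation is the default: it is stable at low barcode depth), normalizes
libraries with median-of-ratios size factors rescaled to geometric mean 1,
and fits a log-link regression of normalized count on modality (RNA vs
DNA) plus sequencing batch.

Two numerical choices matter here:

* **Point estimates solve the quasi-Poisson score equations** on
  normalized counts. This makes the log2 fold-change *exactly* invariant
  to rescaling any single library (the tests assert agreement to 1e-9
  under a 3× rescale), which an estimate reweighted by a re-estimated
  per-tile dispersion is not.
* **The Wald standard error uses a negative-binomial variance**
  (`var = μ + αμ²`) whose dispersion is pooled: with only
  2 × replicates observations and an intercept + modality + batch design,
  a per-tile method-of-moments estimate has 2–4 residual degrees of
  freedom and its noise badly miscalibrates the test. The pooled value
  solves the Pearson-moment equation across all tested tiles jointly,
  scaled per tile by barcode count (aggregating $n_b$ barcodes divides the
  effective dispersion by roughly $n_b$); a tile keeps its own
  df-corrected estimate only when it exceeds five times the pooled value
  (an outlier guard). The dispersion floor is 1e-4. Under all-null
  simulation the resulting p-values are approximately Uniform(0,1)
  (Kolmogorov–Smirnov checks in the test suite) and the false-active rate
  at the compound threshold is controlled.

A tile is *active* when BH `q < 0.01` **and** `log2FC > 1`: the test is
two-sided and the directional fold-change filter is applied afterwards,
matching the compound rule the call emulates. Tiles with no barcode or
with total count below `min_total = 10` are reported untested. The
empirical FDR of the active call is
`(scrambled pass rate × n_test) / n_test_passing` (0 when nothing passes);
several empirical-FDR estimators are in circulation, and this standard
scrambled-rate form is the documented definition here. Its threshold
curve is additionally monotonized q-value-style (running minimum from the
loosest threshold), because the raw ratio is not guaranteed monotone on
arbitrary data. cCRE validation uses the (1 − `top_fraction`) quantile of
model-estimated activity scores over all scored tiles, controls included;
both the score universe ("test only") and the score type (model estimate
vs raw mean ratio) are flags, since either reading is defensible.

## gRNA design

Enumeration scans both strands for 20-mers followed by NGG and records the
PAM and the 3′ 6 bp flank. Hard filters: a run of more than `max_polyT =
3` thymidines (a Pol III terminator), spacer GC outside `[0.25, 0.75]`,
and spacers occurring more than once in the provided sequence set — the
duplicate rule stands in for genome-wide off-target scoring, which is out
of scope. Promoter-target distances are signed (upstream negative in
transcript orientation) from the site midpoint to the CAGE-weighted mode
TSS, falling back to the annotated TSS with a warning when the profile is
empty; enhancer-target distances are absolute to the cCRE floor-midpoint
center.

Selection runs six rounds with strictly relaxing (min score,
max |distance|) thresholds, taking candidates per round ranked by score,
then |distance|, then leftmost coordinate, then + before − strand, until
`k = 4` per target. The round thresholds are explicit configuration with
documented defaults (scores 0.8 … 0, promoter distances 150 … ∞ bp,
enhancer center distances 25 … 135 … ∞ bp), not claims about any
particular published screen. The default on-target scorer is likewise a
documented deterministic heuristic (GC deviation and homopolymer
penalties, scaled to [0, 1]) behind a pluggable interface — the selection
algorithm, not the scorer, is the contribution captured here. Final
spacers are `G` + the PAM-proximal 19 nt, so every expressed spacer is
20 nt starting with G. *S. aureus* compatibility is an NNGRRT match of
the flank on the protospacer's strand, false (with a warning) when the
flank is truncated by the contig end.

## Single-cell screen analysis

QC keeps cells with mitochondrial fraction ≤ 0.20 and ≥ 900 gene UMIs
(a cell at exactly 900 is kept: the exclusion is strictly "< 900"). gRNA
assignment requires ≥ 5 gRNA UMIs ("a filter of 5" read as inclusive) and
is computed on QC-passing cells. Cis pairs connect a gRNA to every gene
whose TSS lies within an inclusive 1 Mb of the site midpoint on the same
chromosome; the pairing window (often 1 Mb up- and downstream, i.e. a 2 Mb
span) and the specificity window are separate arguments because the two
analyses need not share a radius.

The hypothesis test is a conditional randomization test implemented
directly; parity with any external implementation's exact numerics is a
non-goal — calibration and FDR behaviour are the acceptance surface:

1. a logistic model of gRNA assignment on cell covariates (log gene UMIs,
   log unique genes, mitochondrial fraction, lane, log gRNA-library UMIs)
   over QC-passing cells;
2. the observed statistic is the negative-binomial score statistic for
   the assignment indicator in a regression of the gene's UMI count on
   the covariates with a log total-UMI offset (per-gene dispersion by
   method of moments on the null fit, floored at 1e-4);
3. B indicator vectors are resampled as independent Bernoulli draws from
   the fitted assignment probabilities — drawn once per gRNA and shared
   across the genes tested for that gRNA, which cuts the dominant cost
   roughly tenfold without changing the per-test null;
4. the one-sided (upregulation) p-value is
   `(1 + #{z* ≥ z_obs}) / (B + 1)`, so `p ≥ 1/(B+1)` by construction.

Treated cells are those assigned the tested gRNA; all other QC-passing
cells, including multi-gRNA cells, are the comparison group — the
partitioning a multiplexed design implies. The average log2 fold-change is
`log2((mean normalized expression in treated + c)/(same in untreated +
c))` with pseudocount `c = 0.01`, a documented estimator choice. Hits are
BH
`q < 0.1` over intended-target tests; each hit gRNA is re-tested against
every gene within 1 Mb with BH applied *within that neighborhood family*
(a per-gRNA family is the natural local correction for a per-gRNA
question), and is "specific" when the
intended target is the only significant gene. Per-test reproducibility
under parallel or reordered execution comes from deriving each gRNA's
resampling seed by a stable string hash of the master seed and the gRNA
id.

## What the synthetic data emulates — and what it does not

The generators reproduce the statistical structure the pipeline must
survive: Poisson de novo counts at the study's 42,320-trio scale with
planted LoF inflation; multi-source cCRE predictions with boundary jitter,
dropout and decoys; negative-binomial barcode counts (variance
`μ + αμ²`, default `α = 0.2`, typical of UMI-scale count data) with
log-normal barcode abundances, replicate size factors and a shared
batch effect on the RNA modality; and a multiplexed screen with
zero-truncated-Poisson gRNA multiplicity (default mean 10.3), log-normal
cell size factors (sd 0.3), lane effects, a Beta mitochondrial fraction
with ~5% of cells pushed over the QC threshold, gRNA UMIs at NB mean 20
against sparse background mean 0.1 (so the threshold-5 rule is separative
but imperfect), and planted fold changes applied to carrier cells'
target-gene means. Genome sequence is i.i.d. uniform ACGT, so NGG PAM
availability arises at its natural ~1/16 per strand-position density.

Passing tests on these data show the statistics are calibrated and the
planted parameters recoverable *under the generating model*. Real data
add what the generators deliberately omit: linkage and haplotype
structure, sequence-composition-dependent mutation rates, chromatin
context and enhancer redundancy, guide-efficiency heterogeneity,
ambient-RNA contamination and doublets. Results on synthetic data bound
implementation correctness, not biological performance.

## Problem sizes and reproducibility

The test suite and acceptance script scale the study design down to sizes
a laptop-class CPU handles in minutes, chosen once as representative: up
to 10,000 tiles for null false-active control, 100 barcodes per tile and
3 replicates for recall of planted 4-fold tiles over 20 seeds, screens of
2,400–20,000 cells at the study's 10.3 gRNAs/cell with ~130 treated cells
per gRNA, 500 non-targeting tests at B = 500 for type-I calibration, and
ten seeds for the realized-FDP average. All generators and tests are
deterministic given their seed; identical seeds give identical outputs
byte for byte.

## Known limitations

* The MPRA test models library aggregates; barcode-level covariance
  (the same barcode observed in DNA and RNA) is absorbed into the pooled
  dispersion rather than modeled as pairing, which is slightly
  conservative for strongly heterogeneous barcode pools.
* The conditional randomization test's validity rests on the logistic
  presence model; covariates omitted from it that drive both assignment
  and expression would miscalibrate the null, as in any CRT.
* Duplicate-spacer exclusion is a weak proxy for off-target scoring;
  plug a real scorer into the scoring interface for production designs.
* Fold-change estimates use a pseudocount and are biased toward zero for
  very lowly expressed genes; the tests bound the bias (±0.3 log2) only
  at the simulated expression levels.
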