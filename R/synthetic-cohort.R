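## Synthetic trio cohort: per-gene observed de novo counts by class, drawn
## under the Poisson mutation model with a planted LoF inflation for risk
## genes.

#' Simulate de novo variant counts for a trio cohort
#'
#' Observed counts for each gene and variant class are Poisson with mean
#' `2 * n_trios * mu(gene, class)` (two haploid genomes per offspring). For
#' genes in `risk_genes`, the LoF mean is multiplied by `lof_inflation`,
#' emulating haploinsufficiency-driven enrichment.
#'
#' @param ref A `synthetic_reference`.
#' @param n_trios Number of offspring with parental data.
#' @param risk_genes Character vector of planted risk gene ids (may be
#'   empty).
#' @param lof_inflation Multiplier (>= 1) applied to the LoF rate of risk
#'   genes.
#' @param seed Integer seed.
#' @return List with `counts` (data.frame gene_id, lof, missense,
#'   synonymous) and `truth` (data.frame gene_id, lof_inflation; one row per
#'   planted risk gene).
#' @export
gen_denovo_cohort <- function(ref, n_trios, risk_genes = character(),
                              lof_inflation = 1, seed = 1L) {
  stopifnot(inherits(ref, "synthetic_reference"))
  if (lof_inflation < 1) stop("lof_inflation must be >= 1")
  if (length(risk_genes) > 0 &&
      !all(risk_genes %in% ref$mutation_rates$gene_id)) {
    stop("risk_genes contains ids absent from the reference")
  }
  set.seed(seed)
  mu <- ref$mutation_rates
  infl <- ifelse(mu$gene_id %in% risk_genes, lof_inflation, 1)
  n <- nrow(mu)
  counts <- data.frame(
    gene_id = mu$gene_id,
    lof = rpois(n, 2 * n_trios * mu$lof * infl),
    missense = rpois(n, 2 * n_trios * mu$missense),
    synonymous = rpois(n, 2 * n_trios * mu$synonymous),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(gene_id = risk_genes,
                      lof_inflation = rep(lof_inflation,
                                          length(risk_genes)),
                      stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}
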