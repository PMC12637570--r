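## Synthetic multiplex single-cell CRISPRa screen: cell x gene and
## cell x gRNA UMI matrices with covariates and planted upregulation effects.

#' Simulate a multiplex single-cell CRISPRa screen
#'
#' Cells receive a zero-truncated Poisson number of distinct gRNAs (the
#' study this emulates assigned a mean of 10.3 gRNAs per cell across 200,513
#' neurons; tests run scaled-down). Gene UMIs are negative binomial with
#' per-cell log-normal size factors, a lane effect, and a mitochondrial
#' fraction covariate with ~5% of cells pushed above the 20% QC threshold.
#' Cells carrying an effective gRNA have that gRNA's target-gene mean
#' multiplied by its fold change; non-targeting controls never have an
#' effect. gRNA UMI counts for present gRNAs are NB with mean
#' `guide_umi_mean` (default 20) so that the threshold-of-5 assignment rule
#' is separative but imperfect; absent gRNAs get sparse background counts
#' with mean 0.1.
#'
#' @param targets data.frame with columns `grna_id` and `target_gene`
#'   (targeting gRNAs only; NTCs are generated internally).
#' @param n_cells Number of cells.
#' @param mean_guides_per_cell Mean distinct gRNAs per cell (study: 10.3).
#' @param planted_effects Named numeric vector grna_id -> fold change (> 0);
#'   unnamed gRNAs have fold 1.
#' @param ntc_fraction Fraction of the final library that is non-targeting
#'   (in [0, 1)).
#' @param seed Integer seed.
#' @param n_background_genes Unlinked genes added to the expression matrix.
#' @param total_umis_per_cell Expected gene UMIs for a size-factor-1 cell.
#' @param nb_dispersion NB dispersion for gene UMIs.
#' @param guide_umi_mean NB mean UMI count of a present gRNA.
#' @param n_lanes Number of 10x lanes.
#' @return List with `gene_matrix` and `guide_matrix` (dgCMatrix, cells x
#'   features), `covariates` (cell_id, lane, mito_frac), `guide_meta`
#'   (grna_id, target_gene, ntc), and `truth` (grna_id, gene_id,
#'   fold_change).
#' @export
gen_screen <- function(targets, n_cells = 2000L, mean_guides_per_cell = 10.3,
                       planted_effects = numeric(), ntc_fraction = 0.1,
                       seed = 1L, n_background_genes = 50L,
                       total_umis_per_cell = 2500, nb_dispersion = 0.2,
                       guide_umi_mean = 20, n_lanes = 4L) {
  stopifnot(all(c("grna_id", "target_gene") %in% names(targets)))
  if (ntc_fraction < 0 || ntc_fraction >= 1) {
    stop("ntc_fraction must be in [0, 1)")
  }
  if (length(planted_effects) > 0) {
    if (any(planted_effects <= 0)) stop("fold changes must be > 0")
    if (!all(names(planted_effects) %in% targets$grna_id)) {
      stop("planted_effects names gRNAs absent from targets")
    }
  }
  set.seed(seed)

  n_ntc <- round(ntc_fraction / (1 - ntc_fraction) * nrow(targets))
  guide_meta <- rbind(
    data.frame(grna_id = targets$grna_id, target_gene = targets$target_gene,
               ntc = FALSE, stringsAsFactors = FALSE),
    if (n_ntc > 0) data.frame(grna_id = sprintf("NTC%04d", seq_len(n_ntc)),
                              target_gene = NA_character_, ntc = TRUE,
                              stringsAsFactors = FALSE)
  )
  guides <- guide_meta$grna_id
  n_guides <- length(guides)

  genes <- unique(c(targets$target_gene,
                    sprintf("bg%03d", seq_len(n_background_genes))))
  n_genes <- length(genes)
  base <- rlnorm(n_genes, meanlog = log(4), sdlog = 0.8)
  base <- base * total_umis_per_cell / sum(base)

  cells <- sprintf("cell%06d", seq_len(n_cells))
  size_fac <- rlnorm(n_cells, 0, 0.3)
  lane <- paste0("lane", sample.int(n_lanes, n_cells, replace = TRUE))
  lane_eff <- setNames(exp(rnorm(n_lanes, 0, 0.1)),
                       paste0("lane", seq_len(n_lanes)))
  mito <- rbeta(n_cells, 2, 38)
  high_mito <- runif(n_cells) < 0.05
  mito[high_mito] <- runif(sum(high_mito), 0.21, 0.45)

  ## gRNA complement per cell: zero-truncated Poisson multiplicity, distinct
  ## guides drawn uniformly.
  mult <- rztpois(n_cells, mean_guides_per_cell)
  mult <- pmin(mult, n_guides)
  carrier <- Matrix::sparseMatrix(
    i = rep(seq_len(n_cells), mult),
    j = unlist(lapply(mult, function(m) sample.int(n_guides, m))),
    x = 1, dims = c(n_cells, n_guides),
    dimnames = list(cells, guides)
  )

  ## Gene expression means with planted effects applied to carrier cells.
  mu <- outer(size_fac * lane_eff[lane], base)
  dimnames(mu) <- list(cells, genes)
  truth <- data.frame(grna_id = names(planted_effects),
                      gene_id = targets$target_gene[
                        match(names(planted_effects), targets$grna_id)],
                      fold_change = unname(planted_effects),
                      stringsAsFactors = FALSE)
  for (k in seq_len(nrow(truth))) {
    has <- carrier[, truth$grna_id[k]] > 0
    mu[has, truth$gene_id[k]] <- mu[has, truth$gene_id[k]] *
      truth$fold_change[k]
  }
  gene_counts <- matrix(
    rnbinom_md(length(mu), as.vector(mu), nb_dispersion),
    nrow = n_cells, dimnames = dimnames(mu)
  )
  gene_matrix <- methods::as(Matrix::Matrix(gene_counts, sparse = TRUE),
                             "CsparseMatrix")

  ## gRNA UMI counts: NB around guide_umi_mean where present, plus sparse
  ## Poisson(0.1) background elsewhere.
  pres <- Matrix::which(carrier > 0, arr.ind = TRUE)
  pres_counts <- rnbinom_md(nrow(pres), guide_umi_mean, nb_dispersion)
  n_slots <- as.numeric(n_cells) * n_guides
  n_bgpos <- rbinom(1, n_slots - nrow(pres), 1 - exp(-0.1))
  pres_lin <- (pres[, 2] - 1) * n_cells + pres[, 1]
  bg_lin <- setdiff(sample(n_slots, min(n_slots, n_bgpos + nrow(pres))),
                    pres_lin)
  bg_lin <- bg_lin[seq_len(min(n_bgpos, length(bg_lin)))]
  bg_counts <- rztpois(length(bg_lin), 0.1)
  guide_matrix <- Matrix::sparseMatrix(
    i = c(pres[, 1], ((bg_lin - 1) %% n_cells) + 1),
    j = c(pres[, 2], ((bg_lin - 1) %/% n_cells) + 1),
    x = c(pres_counts, bg_counts), dims = c(n_cells, n_guides),
    dimnames = list(cells, guides)
  )

  covariates <- data.frame(cell_id = cells, lane = lane, mito_frac = mito,
                           stringsAsFactors = FALSE)
  list(gene_matrix = gene_matrix, guide_matrix = guide_matrix,
       covariates = covariates, guide_meta = guide_meta, truth = truth)
}
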