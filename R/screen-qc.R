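## Single-cell screen preprocessing: cell QC and threshold-based gRNA
## assignment.

#' Cell QC and gRNA assignment
#'
#' Cells with mitochondrial fraction above `mito_max` or with fewer than
#' `min_umis` gene-expression UMIs are excluded (a cell at exactly
#' `min_umis` is kept, matching the strict "< min" exclusion). gRNA
#' assignments are computed on QC-passing cells only: a gRNA is assigned to
#' a cell when its UMI count is at least `umi_threshold`.
#'
#' @param gene_matrix Cells x genes UMI matrix (dgCMatrix or matrix).
#' @param guide_matrix Cells x gRNAs UMI matrix with identical row order.
#' @param covariates data.frame with cell_id, lane, mito_frac.
#' @param umi_threshold gRNA UMI assignment threshold (default 5).
#' @param mito_max Maximum tolerated mitochondrial fraction (default 0.20).
#' @param min_umis Minimum gene-expression UMIs (default 900).
#' @return List with `cells` (per-cell record incl. qc_pass), `assignments`
#'   (cell_id, grna_id, umi for assigned pairs), and `summary` (QC-passing
#'   cell count, assignment rate, mean gRNAs/cell, mean cells/gRNA).
#' @export
qc_and_assign <- function(gene_matrix, guide_matrix, covariates,
                          umi_threshold = 5, mito_max = 0.20,
                          min_umis = 900) {
  if (!identical(rownames(gene_matrix), rownames(guide_matrix)) ||
      !identical(rownames(gene_matrix), covariates$cell_id)) {
    stop("gene matrix, guide matrix and covariates must share cell ids")
  }
  total_umis <- Matrix::rowSums(gene_matrix)
  genes_detected <- Matrix::rowSums(gene_matrix > 0)
  guide_umis <- Matrix::rowSums(guide_matrix)
  cells <- data.frame(
    cell_id = covariates$cell_id,
    total_umis = as.vector(total_umis),
    genes_detected = as.vector(genes_detected),
    mito_frac = covariates$mito_frac,
    lane = covariates$lane,
    guide_umis = as.vector(guide_umis),
    stringsAsFactors = FALSE
  )
  cells$qc_pass <- cells$mito_frac <= mito_max & cells$total_umis >= min_umis

  keep <- which(cells$qc_pass)
  sub <- guide_matrix[keep, , drop = FALSE]
  hit <- Matrix::which(sub >= umi_threshold, arr.ind = TRUE)
  assignments <- data.frame(
    cell_id = rownames(sub)[hit[, 1]],
    grna_id = colnames(sub)[hit[, 2]],
    umi = sub[hit],
    stringsAsFactors = FALSE
  )
  n_pass <- length(keep)
  guides_per_cell <- table(factor(assignments$cell_id,
                                  levels = rownames(sub)))
  summary <- list(
    n_cells_qc = n_pass,
    assignment_rate = mean(guides_per_cell >= 1),
    mean_guides_per_cell = mean(guides_per_cell),
    mean_cells_per_guide = if (nrow(assignments) > 0)
      nrow(assignments) / length(unique(assignments$grna_id)) else 0
  )
  list(cells = cells, assignments = assignments, summary = summary)
}

#' Candidate cis (gRNA, gene) pairs within a genomic window
#'
#' A pair is included when the gene's TSS lies on the same chromosome and
#' within `half_window` bp (inclusive) of the gRNA site midpoint. The
#' default emulates the 2 Mb testing window (1 Mb up- and downstream).
#'
#' @param guide_sites data.frame: grna_id, chrom, start, end (site
#'   interval, 0-based half-open).
#' @param gene_tss data.frame: gene_id, chrom, tss.
#' @param half_window Half-window in bp (default 1e6).
#' @return data.frame: grna_id, gene_id, distance.
#' @export
cis_pairs <- function(guide_sites, gene_tss, half_window = 1e6) {
  mid <- (guide_sites$start + guide_sites$end) %/% 2
  out <- do.call(rbind, lapply(seq_len(nrow(guide_sites)), function(i) {
    same <- gene_tss$chrom == guide_sites$chrom[i]
    d <- abs(gene_tss$tss - mid[i])
    keep <- same & d <= half_window
    if (!any(keep)) return(NULL)
    data.frame(grna_id = guide_sites$grna_id[i],
               gene_id = gene_tss$gene_id[keep],
               distance = d[keep], stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(grna_id = character(), gene_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
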