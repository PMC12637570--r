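## Writers/readers for the interchange formats the pipeline consumes and
## emits: FASTA (Biostrings), BED (0-based half-open), TSV, MTX (Matrix)
## and a JSON run-metadata echo.

#' Write a synthetic dataset to disk in its interchange formats
#'
#' Emits the genome as FASTA, gene bodies and exons as BED, mutation rates,
#' gene models and CAGE profile as TSV, and echoes `params` to a JSON
#' run-metadata file.
#'
#' @param ref A `synthetic_reference`.
#' @param dir Output directory (created if needed).
#' @param params Named list echoed to `run_metadata.json`.
#' @return Invisibly, the directory.
#' @export
write_reference <- function(ref, dir, params = list()) {
  stopifnot(inherits(ref, "synthetic_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(ref$sequences),
    filepath = file.path(dir, "genome.fa")
  )
  write_bed(data.frame(chrom = ref$genes$chrom, start = ref$genes$start,
                       end = ref$genes$end, name = ref$genes$gene_id,
                       score = 0, strand = ref$genes$strand),
            file.path(dir, "genes.bed"))
  write_bed(data.frame(chrom = ref$exons$chrom, start = ref$exons$start,
                       end = ref$exons$end, name = ref$exons$gene_id),
            file.path(dir, "exons.bed"))
  write_tsv(ref$genes, file.path(dir, "gene_models.tsv"))
  write_tsv(ref$mutation_rates, file.path(dir, "mutation_rates.tsv"))
  write_tsv(ref$cage, file.path(dir, "cage_profile.tsv"))
  jsonlite::write_json(params, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Write a BED file (0-based half-open intervals)
#'
#' @param df data.frame whose first three columns are chrom, start, end;
#'   further columns are written as BED fields 4+.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  check_intervals(df, "BED table")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a 0-based half-open interval data.frame
#'
#' @param path BED path.
#' @param extra_names Names for columns beyond chrom/start/end.
#' @return data.frame with chrom, start, end (+ extras).
#' @export
read_bed <- function(path, extra_names = NULL) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(extra_names) && ncol(df) >= 3 + length(extra_names)) {
    names(df)[seq_along(extra_names) + 3] <- extra_names
  }
  df
}

#' Write a TSV with header
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with header
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a cell x feature matrix as MTX with row/column name files
#'
#' @param m Matrix (coerced to sparse).
#' @param prefix Path prefix; writes `<prefix>.mtx`, `<prefix>.rows.txt`,
#'   `<prefix>.cols.txt`.
#' @export
write_mtx <- function(m, prefix) {
  sm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(sm, paste0(prefix, ".mtx"))
  writeLines(rownames(sm), paste0(prefix, ".rows.txt"))
  writeLines(colnames(sm), paste0(prefix, ".cols.txt"))
  invisible(prefix)
}

#' Read a matrix written by [write_mtx()]
#'
#' @param prefix Path prefix used at write time.
#' @return dgCMatrix with dimnames restored.
#' @export
read_mtx <- function(prefix) {
  m <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  dimnames(m) <- list(readLines(paste0(prefix, ".rows.txt")),
                      readLines(paste0(prefix, ".cols.txt")))
  m
}
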