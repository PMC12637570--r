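## Synthetic reference: genome sequence, gene models, mutation rates and a
## pseudo-CAGE TSS profile. Everything downstream of the pipeline can be
## exercised against this object with planted ground truth.

#' Generate a synthetic reference genome with gene models
#'
#' Builds a deterministic (given `seed`) reference consisting of uniform
#' random ACGT chromosome sequence, non-overlapping gene models with strand,
#' TSS and exons, per-gene per-class de novo mutation probabilities and a
#' unimodal pseudo-CAGE 5' tag profile around each TSS. Coordinates are
#' 0-based half-open throughout. Mutation probabilities are per haploid
#' genome per generation and scale with gene length; classes are `lof`
#' (frameshift + canonical splice + stop gain), `missense` and `synonymous`.
#'
#' The TSS is stored as the boundary coordinate of transcription start:
#' equal to `start` for + strand genes and to `end` for - strand genes, so
#' the `width`-bp upstream window is `[tss - width, tss)` on + and
#' `[tss, tss + width)` on -.
#'
#' @param seed Integer seed; identical seeds give byte-identical objects.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp (>= 10000).
#' @param n_genes Total number of genes to place (>= 1).
#' @param gene_length_range Numeric length-2 vector of min/max gene lengths.
#' @param min_gap Minimum intergenic gap in bp (room for promoters and
#'   planted enhancers).
#' @return Object of class `synthetic_reference`: a list with
#'   `chrom_lengths`, `sequences` (named character), `genes`, `exons`,
#'   `mutation_rates` and `cage` data frames.
#' @export
gen_reference <- function(seed, n_chromosomes = 1L, chrom_length = 1e6,
                          n_genes = 20L,
                          gene_length_range = c(4000, 12000),
                          min_gap = 8000) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (chrom_length < 10000) stop("chrom_length must be >= 10000")
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chromosomes))
  chrom_lengths <- setNames(rep(as.integer(chrom_length), n_chromosomes),
                            chroms)
  sequences <- setNames(
    vapply(chroms, function(.) random_dna(chrom_length), character(1)),
    chroms
  )

  ## Distribute genes across chromosomes, then place them left to right
  ## with random gaps of at least min_gap.
  chrom_of <- sort(rep_len(seq_len(n_chromosomes), n_genes))
  genes <- vector("list", n_chromosomes)
  gi <- 0L
  for (ci in seq_len(n_chromosomes)) {
    n_here <- sum(chrom_of == ci)
    if (n_here == 0L) next
    lens <- round(runif(n_here, gene_length_range[1], gene_length_range[2]))
    needed <- sum(lens) + (n_here + 1L) * min_gap
    if (needed > chrom_length) {
      stop("cannot place ", n_here, " genes of total length ", sum(lens),
           " on a ", chrom_length, " bp chromosome with min_gap ", min_gap)
    }
    slack <- chrom_length - needed
    extra <- diff(c(0, sort(round(runif(n_here, 0, slack))), slack))
    pos <- min_gap + extra[1L]
    rows <- vector("list", n_here)
    for (k in seq_len(n_here)) {
      gi <- gi + 1L
      start <- pos
      end <- start + lens[k]
      strand <- sample(c("+", "-"), 1L)
      rows[[k]] <- data.frame(
        gene_id = sprintf("gene%03d", gi),
        chrom = chroms[ci], strand = strand,
        start = as.integer(start), end = as.integer(end),
        tss = as.integer(if (strand == "+") start else end),
        stringsAsFactors = FALSE
      )
      pos <- end + min_gap + extra[k + 1L]
    }
    genes[[ci]] <- do.call(rbind, rows)
  }
  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL

  ## Exons: split each gene body into 3-8 exons separated by introns.
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    n_ex <- sample(3:8, 1L)
    len <- g$end - g$start
    cuts <- sort(sample(seq_len(len - 1L), 2L * n_ex - 2L))
    bounds <- c(0L, cuts, len)
    starts <- g$start + bounds[seq(1L, length(bounds) - 1L, by = 2L)]
    ends <- g$start + bounds[seq(2L, length(bounds), by = 2L)]
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               start = as.integer(starts), end = as.integer(ends),
               stringsAsFactors = FALSE)
  }))
  rownames(exons) <- NULL

  ## Per-gene per-class mutation probabilities, proportional to gene length
  ## with log-normal gene-to-gene variation, bounded in (0, 1e-3).
  len <- genes$end - genes$start
  noise <- function() exp(rnorm(nrow(genes), 0, 0.3))
  rates <- data.frame(
    gene_id = genes$gene_id,
    lof = pmin(9e-4, len * 4e-9 * noise()),
    missense = pmin(9e-4, len * 1.6e-8 * noise()),
    synonymous = pmin(9e-4, len * 7e-9 * noise()),
    stringsAsFactors = FALSE
  )

  ## Pseudo-CAGE: unimodal (discretized Gaussian) 5' tag peak at each TSS.
  cage <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    offs <- -50:50
    pos <- g$tss + offs
    keep <- pos >= 0 & pos < chrom_lengths[[g$chrom]]
    counts <- round(400 * exp(-(offs^2) / (2 * 12^2)))[keep]
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               pos = as.integer(pos[keep]), count = as.integer(counts),
               stringsAsFactors = FALSE)[counts > 0, ]
  }))
  rownames(cage) <- NULL

  structure(
    list(chrom_lengths = chrom_lengths, sequences = sequences,
         genes = genes, exons = exons, mutation_rates = rates, cage = cage),
    class = "synthetic_reference"
  )
}

#' @export
print.synthetic_reference <- function(x, ...) {
  cat("synthetic_reference:", length(x$chrom_lengths), "chromosome(s),",
      sum(x$chrom_lengths), "bp,", nrow(x$genes), "genes\n")
  invisible(x)
}
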