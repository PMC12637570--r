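## Harmonization of multi-source enhancer-gene predictions into a
## non-redundant candidate CRE set. All user-facing coordinates are 0-based
## half-open (BED convention); overlap means an intersection of >= 1 bp.

#' Strand-aware merged promoter windows
#'
#' One `width`-bp window immediately upstream of every TSS: `[tss - width,
#' tss)` on the + strand, `[tss, tss + width)` on the - strand. Windows
#' extending past the chromosome start are clipped at 0 with a warning;
#' overlapping isoform windows are merged.
#'
#' @param gene_models data.frame with columns chrom, strand, tss (multiple
#'   rows per gene allowed, one per TSS).
#' @param width Promoter width in bp (> 0).
#' @return data.frame chrom, start, end of merged promoter intervals.
#' @export
define_promoters <- function(gene_models, width = 2000) {
  if (width <= 0) stop("width must be > 0")
  stopifnot(all(c("chrom", "strand", "tss") %in% names(gene_models)))
  start <- ifelse(gene_models$strand == "+", gene_models$tss - width,
                  gene_models$tss)
  end <- start + width
  if (any(start < 0)) {
    warning(sum(start < 0), " promoter window(s) clipped at position 0")
    start <- pmax(start, 0)
  }
  merge_by_chrom(data.frame(chrom = gene_models$chrom, start = start,
                            end = end, stringsAsFactors = FALSE))
}

#' Extend intervals from their center to a minimum width
#'
#' Intervals already at least `min_width` wide are unchanged. Shorter ones
#' are replaced by a centered interval of exactly `min_width`, where the
#' center is the floor midpoint `floor((start + end) / 2)`. Extension past
#' position 0 clips at 0 and pads on the right to preserve the width, with
#' a warning.
#'
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @param min_width Minimum interval width in bp.
#' @return The intervals, extended where needed (other columns preserved).
#' @export
extend_to_min_width <- function(intervals, min_width = 500) {
  check_intervals(intervals)
  w <- intervals$end - intervals$start
  short <- w < min_width
  if (any(short)) {
    center <- (intervals$start[short] + intervals$end[short]) %/% 2
    half <- min_width %/% 2
    new_start <- center - half
    new_end <- new_start + min_width
    clipped <- new_start < 0
    if (any(clipped)) {
      warning(sum(clipped), " interval(s) clipped at position 0")
      new_end[clipped] <- new_end[clipped] - new_start[clipped]
      new_start[clipped] <- 0
    }
    intervals$start[short] <- as.integer(new_start)
    intervals$end[short] <- as.integer(new_end)
  }
  intervals
}

#' Harmonize per-source CRE predictions into merged candidate CREs
#'
#' Extends every source interval to at least `min_width`, merges intervals
#' across sources by single-linkage on >= 1 bp overlap (unioning source
#' labels and gene links), and removes any merged interval that overlaps a
#' `promoter_width`-bp promoter window or an exon by >= 1 bp.
#'
#' @param per_source_predictions Named list of data.frames with columns
#'   chrom, start, end, gene_id.
#' @param gene_models data.frame with chrom, strand, tss (promoter
#'   definition) and gene ids.
#' @param exons data.frame chrom, start, end of protein-coding exons.
#' @param promoter_width Promoter exclusion width in bp.
#' @param min_width Minimum cCRE width in bp.
#' @return data.frame: ccre_id, chrom, start, end, sources (comma-joined),
#'   genes (comma-joined), support.
#' @export
harmonize <- function(per_source_predictions, gene_models, exons,
                      promoter_width = 2000, min_width = 500) {
  stopifnot(length(per_source_predictions) >= 1)
  if (is.null(names(per_source_predictions))) {
    names(per_source_predictions) <-
      paste0("source", seq_along(per_source_predictions))
  }
  known_genes <- unique(gene_models$gene_id)
  pooled <- do.call(rbind, lapply(names(per_source_predictions), function(s) {
    df <- per_source_predictions[[s]]
    if (nrow(df) == 0) return(NULL)
    check_intervals(df, paste0("source '", s, "'"))
    if (!all(df$gene_id %in% known_genes)) {
      stop("source '", s, "' links to unknown gene(s)")
    }
    df <- extend_to_min_width(df, min_width)
    data.frame(chrom = df$chrom, start = df$start, end = df$end,
               gene_id = df$gene_id, source = s, stringsAsFactors = FALSE)
  }))
  if (is.null(pooled) || nrow(pooled) == 0) {
    return(data.frame(ccre_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      sources = character(), genes = character(),
                      support = integer(), stringsAsFactors = FALSE))
  }

  promoters <- define_promoters(gene_models, promoter_width)
  check_intervals(exons, "exon table")
  excl <- rbind(promoters[c("chrom", "start", "end")],
                exons[c("chrom", "start", "end")])

  out <- lapply(split(pooled, pooled$chrom), function(p) {
    ir <- as_iranges0(p$start, p$end)
    merged <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, merged)
    mi <- S4Vectors::subjectHits(hit)
    srcs <- vapply(split(p$source, mi), function(x)
      paste(sort(unique(x)), collapse = ","), character(1))
    gns <- vapply(split(p$gene_id, mi), function(x)
      paste(sort(unique(x)), collapse = ","), character(1))
    supp <- vapply(split(p$source, mi), function(x)
      length(unique(x)), integer(1))
    co <- from_iranges0(merged)
    df <- data.frame(chrom = p$chrom[1], start = co$start, end = co$end,
                     sources = srcs[as.character(seq_along(merged))],
                     genes = gns[as.character(seq_along(merged))],
                     support = supp[as.character(seq_along(merged))],
                     stringsAsFactors = FALSE)
    ## Promoter/exon exclusion (>= 1 bp overlap).
    ex <- excl[excl$chrom == p$chrom[1], , drop = FALSE]
    if (nrow(ex) > 0) {
      drop <- IRanges::overlapsAny(merged, as_iranges0(ex$start, ex$end))
      df <- df[!drop, , drop = FALSE]
    }
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (nrow(out) > 0) {
    out <- cbind(ccre_id = sprintf("ccre%05d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
  } else {
    out <- cbind(ccre_id = character(0), out)
  }
  out
}

#' Source-support histogram for merged cCREs
#'
#' @param merged Output of [harmonize()].
#' @return List with `histogram` (data.frame support, n) and
#'   `fraction_at_least` (named numeric: fraction of cCREs with support >=
#'   k for each observed k).
#' @export
support_summary <- function(merged) {
  if (nrow(merged) == 0) stop("empty merged cCRE set")
  tab <- table(merged$support)
  hist <- data.frame(support = as.integer(names(tab)), n = as.vector(tab))
  ks <- seq_len(max(hist$support))
  frac <- vapply(ks, function(k) mean(merged$support >= k), numeric(1))
  list(histogram = hist,
       fraction_at_least = setNames(frac, paste0(">=", ks)))
}

## reduce()-merge of a chrom/start/end table (0-based half-open).
merge_by_chrom <- function(df) {
  out <- lapply(split(df, df$chrom), function(p) {
    m <- IRanges::reduce(as_iranges0(p$start, p$end), min.gapwidth = 0L)
    cbind(data.frame(chrom = p$chrom[1], stringsAsFactors = FALSE),
          from_iranges0(m))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
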