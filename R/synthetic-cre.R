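## Synthetic multi-source enhancer-gene predictions: planted true elements
## observed by several imperfect "datasets/strategies" with boundary jitter,
## dropout and decoy intervals.

#' Simulate multi-source candidate CRE prediction tables
#'
#' Plants `n_true_elements` intergenic true elements (each linked to its
#' nearest gene) and emits one prediction table per source. Each source
#' observes each true element with probability `1 - dropout`, with interval
#' boundaries jittered by N(0, jitter_sd), and additionally reports decoy
#' intervals. True elements are placed with a minimum mutual separation so
#' that, at moderate jitter, each one harmonizes into exactly one merged
#' cCRE.
#'
#' @param ref A `synthetic_reference`.
#' @param n_sources Number of prediction sources (>= 1).
#' @param n_true_elements Number of planted true elements.
#' @param jitter_sd Boundary jitter standard deviation in bp.
#' @param dropout Per-source probability of missing a true element.
#' @param seed Integer seed.
#' @param element_width_range Min/max width of planted elements in bp.
#' @param decoy_rate Expected number of decoys per source as a fraction of
#'   `n_true_elements`.
#' @param promoter_margin Minimum distance kept between planted elements and
#'   gene bodies/promoter windows, in bp.
#' @return List with `sources` (named list of data.frames chrom, start, end,
#'   gene_id) and `truth` (data.frame element_id, chrom, start, end,
#'   gene_id).
#' @export
gen_cre_predictions <- function(ref, n_sources = 5L, n_true_elements = 40L,
                                jitter_sd = 50, dropout = 0.1, seed = 1L,
                                element_width_range = c(150, 700),
                                decoy_rate = 0.2,
                                promoter_margin = 2500) {
  stopifnot(inherits(ref, "synthetic_reference"))
  if (n_sources < 1L) stop("n_sources must be >= 1")
  if (dropout < 0 || dropout > 1) stop("dropout must be in [0, 1]")
  set.seed(seed)

  ## Candidate intergenic slots: gaps between consecutive genes (and the
  ## chromosome flanks), shrunk by promoter_margin on both sides.
  slots <- do.call(rbind, lapply(names(ref$chrom_lengths), function(ch) {
    g <- ref$genes[ref$genes$chrom == ch, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    bounds <- c(0L, as.vector(rbind(g$start, g$end)),
                ref$chrom_lengths[[ch]])
    gap_start <- bounds[seq(1L, length(bounds) - 1L, by = 2L)]
    gap_end <- bounds[seq(2L, length(bounds), by = 2L)]
    data.frame(chrom = ch, start = gap_start + promoter_margin,
               end = gap_end - promoter_margin, stringsAsFactors = FALSE)
  }))
  slots <- slots[slots$end - slots$start >= max(element_width_range) + 200, ]
  if (nrow(slots) == 0) stop("no intergenic room to place elements")

  ## Place true elements in slots with >= 2 kb separation inside a slot.
  max_w <- max(element_width_range)
  sep <- 2000
  per_slot <- pmax(1L, floor((slots$end - slots$start) / (max_w + sep)))
  capacity <- sum(per_slot)
  if (n_true_elements > capacity) {
    stop("cannot place ", n_true_elements, " elements; capacity ", capacity)
  }
  slot_idx <- rep(seq_len(nrow(slots)), per_slot)
  within_idx <- unlist(lapply(per_slot, seq_len))
  pick <- sort(sample(length(slot_idx), n_true_elements))
  widths <- round(runif(n_true_elements, element_width_range[1],
                        element_width_range[2]))
  starts <- slots$start[slot_idx[pick]] +
    (within_idx[pick] - 1L) * (max_w + sep) +
    round(runif(n_true_elements, 0, 200))
  truth <- data.frame(
    element_id = sprintf("elem%03d", seq_len(n_true_elements)),
    chrom = slots$chrom[slot_idx[pick]],
    start = as.integer(starts),
    end = as.integer(starts + widths),
    stringsAsFactors = FALSE
  )
  ## Link each element to the nearest gene (by TSS) on its chromosome.
  truth$gene_id <- vapply(seq_len(nrow(truth)), function(i) {
    g <- ref$genes[ref$genes$chrom == truth$chrom[i], ]
    mid <- (truth$start[i] + truth$end[i]) / 2
    g$gene_id[which.min(abs(g$tss - mid))]
  }, character(1))

  sources <- lapply(seq_len(n_sources), function(s) {
    seen <- runif(nrow(truth)) >= dropout
    obs <- truth[seen, c("chrom", "start", "end", "gene_id")]
    if (nrow(obs) > 0 && jitter_sd > 0) {
      obs$start <- pmax(0L, as.integer(round(
        obs$start + rnorm(nrow(obs), 0, jitter_sd))))
      obs$end <- as.integer(round(obs$end + rnorm(nrow(obs), 0, jitter_sd)))
      bad <- obs$end <= obs$start
      obs$end[bad] <- obs$start[bad] + 100L
    }
    ## Decoys: extra intergenic intervals not tied to any planted element.
    n_decoy <- rpois(1, decoy_rate * n_true_elements)
    if (n_decoy > 0) {
      di <- sample(nrow(slots), n_decoy, replace = TRUE)
      dw <- round(runif(n_decoy, element_width_range[1],
                        element_width_range[2]))
      ds <- round(runif(n_decoy, slots$start[di],
                        pmax(slots$start[di] + 1, slots$end[di] - dw)))
      dg <- vapply(seq_len(n_decoy), function(k) {
        g <- ref$genes[ref$genes$chrom == slots$chrom[di[k]], ]
        g$gene_id[which.min(abs(g$tss - ds[k]))]
      }, character(1))
      obs <- rbind(obs, data.frame(chrom = slots$chrom[di],
                                   start = as.integer(ds),
                                   end = as.integer(ds + dw),
                                   gene_id = dg, stringsAsFactors = FALSE))
    }
    rownames(obs) <- NULL
    obs
  })
  names(sources) <- sprintf("source%02d", seq_len(n_sources))
  list(sources = sources, truth = truth)
}
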