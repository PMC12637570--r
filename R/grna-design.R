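## CRISPRa gRNA design: exhaustive NGG protospacer enumeration on both
## strands, hard filters (polyT, GC, duplicate spacers), target-distance
## annotation, iterative threshold-relaxing selection, spacer finalization
## (G + 19 nt) and S. aureus PAM compatibility.

#' Enumerate and filter NGG protospacer candidates
#'
#' Scans both strands of a region for every position where a 20-nt
#' protospacer is followed by an NGG PAM. Candidates are flagged (and
#' excluded from selection) when the spacer contains a run of more than
#' `max_polyT` consecutive T (a Pol III terminator), has GC fraction outside
#' `gc_bounds`, or occurs more than once across the provided sequence set.
#'
#' Genomic site intervals are 0-based half-open over the protospacer (PAM
#' excluded). The 3' 6-bp flank (PAM plus three further bases, read on the
#' protospacer's strand) is kept for cross-nuclease PAM checks and is NA
#' when truncated by the contig end.
#'
#' @param sequences Named character vector of contig sequences (the
#'   duplicate-spacer universe).
#' @param region Optional data.frame (chrom, start, end): restrict candidate
#'   protospacer sites to those fully inside this 0-based half-open region.
#' @param gc_bounds Inclusive GC-fraction bounds for the spacer.
#' @param max_polyT Longest tolerated run of consecutive T.
#' @return data.frame: protospacer, chrom, strand, start, end, pam, flank6,
#'   gc, flag_polyT, flag_gc, flag_duplicate, pass.
#' @export
enumerate_and_filter <- function(sequences, region = NULL,
                                 gc_bounds = c(0.25, 0.75), max_polyT = 3L) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  cands <- do.call(rbind, lapply(names(sequences), function(ch) {
    s <- sequences[[ch]]
    n <- nchar(s)
    if (n < 23L) {
      return(NULL)
    }
    chars <- strsplit(s, "")[[1]]
    ## + strand: protospacer at 1-based i..i+19, PAM N,G,G at i+20..i+22,
    ## so the GG dinucleotide sits at i+21..i+22.
    g <- which(chars == "G")
    g <- g[g + 1L <= n & chars[pmin(g + 1L, n)] == "G"]
    i_plus <- g - 21L                 # protospacer start (1-based)
    i_plus <- i_plus[i_plus >= 1L]
    plus <- if (length(i_plus)) data.frame(
      protospacer = substring(s, i_plus, i_plus + 19L),
      chrom = ch, strand = "+",
      start = i_plus - 1L, end = i_plus + 19L,
      pam = substring(s, i_plus + 20L, i_plus + 22L),
      flank6 = ifelse(i_plus + 25L <= n,
                      substring(s, i_plus + 20L, i_plus + 25L),
                      NA_character_),
      stringsAsFactors = FALSE) else NULL
    ## - strand: plus-strand "CC" at q..q+1 is the reverse-complement PAM;
    ## protospacer occupies plus coords q+3..q+22.
    q <- which(chars == "C")
    q <- q[chars[pmin(q + 1L, n)] == "C" & q + 1L <= n]
    q <- q[q + 22L <= n]
    minus <- if (length(q)) data.frame(
      protospacer = revcomp(substring(s, q + 3L, q + 22L)),
      chrom = ch, strand = "-",
      start = q + 2L, end = q + 22L,
      pam = revcomp(substring(s, q, q + 2L)),
      flank6 = ifelse(q - 3L >= 1L, revcomp(substring(s, q - 3L, q + 2L)),
                      NA_character_),
      stringsAsFactors = FALSE) else NULL
    rbind(plus, minus)
  }))
  if (is.null(cands) || nrow(cands) == 0) {
    return(empty_candidates())
  }
  if (!is.null(region)) {
    keep <- cands$chrom == region$chrom[1] &
      cands$start >= region$start[1] & cands$end <= region$end[1]
    cands <- cands[keep, , drop = FALSE]
    if (nrow(cands) == 0) return(empty_candidates())
  }
  gc <- vapply(strsplit(cands$protospacer, ""), function(x)
    mean(x %in% c("G", "C")), numeric(1))
  polyt <- grepl(strrep("T", max_polyT + 1L), cands$protospacer, fixed = TRUE)
  ## Duplicate = the spacer 20-mer occurs more than once across the whole
  ## provided sequence set (both strands, overlapping occurrences counted).
  all_hits <- spacer_occurrences(sequences, unique(cands$protospacer))
  dup <- all_hits[cands$protospacer] > 1L
  cands$gc <- gc
  cands$flag_polyT <- polyt
  cands$flag_gc <- gc < gc_bounds[1] | gc > gc_bounds[2]
  cands$flag_duplicate <- unname(dup)
  cands$pass <- !(cands$flag_polyT | cands$flag_gc | cands$flag_duplicate)
  rownames(cands) <- NULL
  cands
}

## Count occurrences of each 20-mer (both strands) across a sequence set.
spacer_occurrences <- function(sequences, spacers) {
  kmers <- unlist(lapply(sequences, function(s) {
    n <- nchar(s)
    if (n < 20L) return(character(0))
    c(substring(s, 1:(n - 19L), 20:n),
      substring(revcomp(s), 1:(n - 19L), 20:n))
  }), use.names = FALSE)
  tab <- table(factor(kmers[kmers %in% spacers], levels = spacers))
  setNames(as.integer(tab), spacers)
}

empty_candidates <- function() {
  data.frame(protospacer = character(), chrom = character(),
             strand = character(), start = integer(), end = integer(),
             pam = character(), flank6 = character(), gc = numeric(),
             flag_polyT = logical(), flag_gc = logical(),
             flag_duplicate = logical(), pass = logical(),
             stringsAsFactors = FALSE)
}

#' Annotate candidate gRNAs with target distances
#'
#' Promoter targets: signed distance from the candidate site midpoint to the
#' CAGE-weighted-mode TSS (position of maximal 5' tag count; ties broken
#' toward the annotated TSS), negative upstream in transcript orientation.
#' Falls back to the annotated TSS with a warning when the CAGE profile is
#' empty. Enhancer targets: absolute distance from the site midpoint to the
#' cCRE floor-midpoint center.
#'
#' @param candidates Candidate table from [enumerate_and_filter()].
#' @param target_kind "promoter" or "enhancer".
#' @param tss Annotated TSS position (promoter targets).
#' @param strand Gene strand (promoter targets).
#' @param cage_profile data.frame (pos, count) of 5' tag counts (promoter
#'   targets; may be empty).
#' @param ccre_interval data.frame (start, end) of the target cCRE
#'   (enhancer targets).
#' @return Candidates with a `distance` column (signed for promoters,
#'   absolute for enhancers) and `target_kind`.
#' @export
annotate_distances <- function(candidates, target_kind = c("promoter",
                                                           "enhancer"),
                               tss = NULL, strand = "+",
                               cage_profile = NULL, ccre_interval = NULL) {
  target_kind <- match.arg(target_kind)
  mid <- (candidates$start + candidates$end) %/% 2
  if (target_kind == "promoter") {
    if (is.null(tss)) stop("promoter targets need the annotated TSS")
    anchor <- tss
    if (!is.null(cage_profile) && nrow(cage_profile) > 0) {
      best <- cage_profile$count == max(cage_profile$count)
      cand_pos <- cage_profile$pos[best]
      anchor <- cand_pos[which.min(abs(cand_pos - tss))]
    } else {
      warning("empty CAGE profile; falling back to the annotated TSS")
    }
    d <- if (strand == "+") mid - anchor else anchor - mid
  } else {
    if (is.null(ccre_interval)) stop("enhancer targets need ccre_interval")
    center <- (ccre_interval$start[1] + ccre_interval$end[1]) %/% 2
    d <- abs(mid - center)
  }
  candidates$distance <- as.numeric(d)
  candidates$target_kind <- target_kind
  candidates
}

#' Default deterministic on-target score
#'
#' A documented heuristic in [0, 1]: 1 minus penalties for deviation of the
#' spacer GC fraction from 0.5 (weight 0.8) and for homopolymer runs beyond
#' 3 nt (0.08 per extra base), clamped to [0, 1]. Any scorer mapping a
#' spacer to a numeric score can be substituted.
#'
#' @param protospacer Character vector of 20-nt protospacers.
#' @return Numeric scores in [0, 1].
#' @export
default_on_target_score <- function(protospacer) {
  vapply(protospacer, function(sp) {
    x <- strsplit(sp, "")[[1]]
    gc <- mean(x %in% c("G", "C"))
    runs <- rle(x)$lengths
    pen <- 0.8 * abs(gc - 0.5) * 2 + 0.08 * max(0, max(runs) - 3)
    min(1, max(0, 1 - pen))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Iterative gRNA selection with relaxing thresholds
#'
#' Runs `n_rounds` selection rounds over one target's candidates. In each
#' round, still-unselected candidates that pass all hard filters and the
#' round's (min score, max |distance|) thresholds are ranked by score
#' (descending), then |distance| (ascending), then leftmost coordinate,
#' then + strand before -, and taken until `k` are held. Thresholds must
#' relax monotonically (scores non-increasing, distances non-decreasing).
#'
#' @param candidates Candidate table with `score`, `distance` and `pass`
#'   columns.
#' @param k Number of gRNAs to select per target (study design: 4).
#' @param round_thresholds data.frame with columns `min_score` and
#'   `max_distance`, one row per round.
#' @return List with `selected` (candidates plus a `round` column) and
#'   `shortfall` (TRUE when fewer than `k` candidates could be selected).
#' @export
iterative_select <- function(candidates, k = 4L,
                             round_thresholds = default_round_thresholds()) {
  rt <- round_thresholds
  stopifnot(all(c("min_score", "max_distance") %in% names(rt)))
  if (is.unsorted(-rt$min_score) || is.unsorted(rt$max_distance)) {
    stop("round thresholds must relax monotonically")
  }
  pool <- candidates[candidates$pass, , drop = FALSE]
  ## Global ranking key; within-round ranking is this order restricted to
  ## the round's passing, still-unselected candidates.
  pool <- pool[order(-pool$score, abs(pool$distance), pool$start,
                     match(pool$strand, c("+", "-"))), , drop = FALSE]
  taken <- integer(0)
  rounds <- integer(0)
  for (r in seq_len(nrow(rt))) {
    if (length(taken) >= k) break
    avail <- setdiff(which(pool$score >= rt$min_score[r] &
                             abs(pool$distance) <= rt$max_distance[r]),
                     taken)
    take <- head(avail, k - length(taken))
    taken <- c(taken, take)
    rounds <- c(rounds, rep(r, length(take)))
  }
  sel <- pool[taken, , drop = FALSE]
  sel$round <- rounds
  rownames(sel) <- NULL
  list(selected = sel, shortfall = nrow(sel) < k)
}

#' Default selection-round thresholds
#'
#' Six rounds of successively relaxing (min score, max |distance|) pairs;
#' explicit configuration, overridable per run.
#'
#' @param kind "promoter" (TSS distance in bp) or "enhancer" (center
#'   distance in bp).
#' @return data.frame with `min_score` and `max_distance`, one row per
#'   round.
#' @export
default_round_thresholds <- function(kind = c("promoter", "enhancer")) {
  kind <- match.arg(kind)
  data.frame(
    min_score = c(0.8, 0.7, 0.6, 0.5, 0.4, 0),
    max_distance = if (kind == "promoter") c(150, 250, 400, 600, 1000, Inf)
                   else c(25, 50, 75, 100, 135, Inf)
  )
}

#' Finalize a spacer for Pol III expression
#'
#' Returns `"G"` followed by the PAM-proximal 19 nt of the protospacer, so
#' every expressed spacer is 20 nt and starts with G.
#'
#' @param protospacer Character vector of 20-nt protospacers.
#' @return Character vector of final spacers.
#' @export
finalize_spacer <- function(protospacer) {
  stopifnot(all(nchar(protospacer) == 20L))
  paste0("G", substr(protospacer, 2L, 20L))
}

#' S. aureus Cas9 PAM compatibility
#'
#' TRUE when the candidate's 3' 6-bp flank matches NNGRRT (R = A or G) on
#' the protospacer's strand; FALSE (with a warning) when the flank is
#' truncated at the contig end.
#'
#' @param flank6 Character vector of 6-bp flanks (NA when truncated).
#' @return Logical vector.
#' @export
sa_pam_compatible <- function(flank6) {
  trunc <- is.na(flank6) | nchar(flank6) < 6L
  if (any(trunc)) {
    warning(sum(trunc), " flank(s) truncated at the contig end")
  }
  out <- !trunc & grepl("^..G[AG][AG]T$", flank6)
  out
}

#' Generate non-targeting control spacers
#'
#' Shuffles of random genomic 20-mers, re-drawn until absent (both strands)
#' from the provided sequence set.
#'
#' @param sequences Named character vector of contig sequences.
#' @param n Number of NTC spacers.
#' @param seed Integer seed.
#' @return Character vector of `n` spacers absent from the genome.
#' @export
generate_ntc_spacers <- function(sequences, n, seed = 1L) {
  set.seed(seed)
  genome <- paste(c(sequences, revcomp(sequences)), collapse = "N")
  out <- character(0)
  while (length(out) < n) {
    sp <- random_dna(20L)
    if (!grepl(sp, genome, fixed = TRUE)) out <- c(out, sp)
  }
  out
}
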