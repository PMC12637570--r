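## MPRA tile design: fixed-length tiles densely covering each candidate CRE
## with a fixed overlap, plus scrambled negative-control tiles.

#' Design fixed-length MPRA tiles over candidate CREs
#'
#' For each cCRE at least `tile_len` wide, tiles start at offsets 0,
#' `tile_len - overlap`, 2*(tile_len - overlap), ... as long as they fit;
#' if the last step-aligned tile does not reach the cCRE end, one extra
#' right-aligned tile `[end - tile_len, end)` is appended. A cCRE shorter
#' than `tile_len` gets a single tile centered on it (flanking sequence
#' drawn from the reference).
#'
#' @param ccres data.frame with ccre_id, chrom, start, end (0-based
#'   half-open).
#' @param tile_len Tile length in bp (study design: 270).
#' @param overlap Overlap between consecutive tiles in bp (study: 90).
#' @param ref Optional `synthetic_reference` (or any list with a
#'   `sequences` named character vector); when supplied, tile sequences are
#'   extracted and centered tiles may extend into flanking sequence. An
#'   error is raised if a centered tile needs flank but no reference is
#'   given.
#' @return data.frame: tile_id, ccre_id, chrom, start, end, offset, class
#'   ("test"), and `sequence` when `ref` is supplied.
#' @export
design_tiles <- function(ccres, tile_len = 270L, overlap = 90L, ref = NULL) {
  if (!(tile_len > overlap && overlap >= 0)) {
    stop("need tile_len > overlap >= 0")
  }
  check_intervals(ccres, "cCRE table")
  step <- tile_len - overlap
  rows <- lapply(seq_len(nrow(ccres)), function(i) {
    cc <- ccres[i, ]
    w <- cc$end - cc$start
    if (w < tile_len) {
      center <- (cc$start + cc$end) %/% 2
      s <- center - tile_len %/% 2
      if (s < 0) s <- 0
      if (is.null(ref) ) {
        stop("cCRE ", cc$ccre_id, " is shorter than tile_len and needs ",
             "flanking reference sequence; supply `ref`")
      }
      offs <- s - cc$start
      data.frame(ccre_id = cc$ccre_id, chrom = cc$chrom,
                 start = as.integer(s), end = as.integer(s + tile_len),
                 offset = as.integer(offs), stringsAsFactors = FALSE)
    } else {
      starts <- seq(0L, w - tile_len, by = step)
      if (max(starts) + tile_len < w) {
        starts <- c(starts, w - tile_len)
      }
      data.frame(ccre_id = cc$ccre_id, chrom = cc$chrom,
                 start = as.integer(cc$start + starts),
                 end = as.integer(cc$start + starts + tile_len),
                 offset = as.integer(starts), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- cbind(tile_id = sprintf("%s_t%03d", out$ccre_id,
                                 ave(seq_len(nrow(out)), out$ccre_id,
                                     FUN = seq_along)),
               out, class = "test", stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(ref)) {
    seqs <- ref$sequences
    if (is.null(seqs)) stop("`ref` has no sequences")
    out$sequence <- vapply(seq_len(nrow(out)), function(i) {
      s <- seqs[[out$chrom[i]]]
      if (out$end[i] > nchar(s)) {
        stop("tile ", out$tile_id[i], " extends past the chromosome end")
      }
      substr(s, out$start[i] + 1L, out$end[i])
    }, character(1))
  }
  out
}

#' Add base-shuffled scrambled control tiles to a design
#'
#' Scrambled controls are per-base shuffles of randomly chosen test tiles;
#' they carry no regulatory signal and calibrate the empirical FDR.
#'
#' @param tiles Output of [design_tiles()] (with or without sequences).
#' @param n Number of scrambled tiles.
#' @param seed Integer seed.
#' @return The design with `n` extra rows of class "scrambled".
#' @export
add_scrambled_tiles <- function(tiles, n, seed = 1L) {
  set.seed(seed)
  src <- tiles[sample(nrow(tiles), n, replace = n > nrow(tiles)), ]
  src$tile_id <- sprintf("scram%04d", seq_len(n))
  src$ccre_id <- NA_character_
  src$class <- "scrambled"
  if ("sequence" %in% names(src)) {
    src$sequence <- vapply(src$sequence, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  out <- rbind(tiles, src)
  rownames(out) <- NULL
  out
}
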