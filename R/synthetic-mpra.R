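## Synthetic MPRA counts: barcode-tile association plus DNA/RNA barcode
## counts with negative-binomial noise, replicate size factors and batch
## structure, and planted activity multipliers.

#' Simulate MPRA barcode association and DNA/RNA count tables
#'
#' Each tile receives a Poisson number of barcodes (at least one) around
#' `barcodes_per_tile`; each barcode has a log-normal abundance. DNA counts
#' are negative binomial around abundance x library size factor; RNA counts
#' are additionally multiplied by the tile's activity multiplier (1 for all
#' tiles not named in `planted_active`; scrambled tiles must not be planted).
#' Replicates are assigned to sequencing batches with a shared batch effect
#' on the RNA modality, exercising the batch covariate of the activity test.
#'
#' @param tiles data.frame with columns `tile_id` and `class` (one of
#'   "test", "scrambled", "external_control").
#' @param barcodes_per_tile Mean number of barcodes per tile. The study this
#'   emulates recovered a median of 163 DNA barcodes per element.
#' @param planted_active Named numeric vector: tile_id -> activity
#'   multiplier (> 0).
#' @param nb_dispersion NB dispersion alpha (var = mu + alpha mu^2).
#' @param n_replicates Number of transduction replicates (study design: 3).
#' @param seed Integer seed.
#' @param mean_abundance Mean barcode abundance (count scale).
#' @return List with `association` (barcode, tile_id), `counts` (barcode,
#'   modality, replicate, batch, count; long format) and `truth` (tile_id,
#'   multiplier for planted tiles).
#' @export
gen_mpra_counts <- function(tiles, barcodes_per_tile = 163,
                            planted_active = numeric(),
                            nb_dispersion = 0.2, n_replicates = 3L,
                            seed = 1L, mean_abundance = 50) {
  stopifnot(all(c("tile_id", "class") %in% names(tiles)))
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (length(planted_active) > 0) {
    if (any(planted_active <= 0)) stop("multipliers must be > 0")
    if (!all(names(planted_active) %in% tiles$tile_id)) {
      stop("planted_active names tiles absent from the design")
    }
    scr <- tiles$tile_id[tiles$class == "scrambled"]
    if (any(names(planted_active) %in% scr)) {
      stop("scrambled control tiles cannot carry a planted multiplier")
    }
  }
  set.seed(seed)

  n_tiles <- nrow(tiles)
  n_bc <- 1L + rpois(n_tiles, max(0, barcodes_per_tile - 1))
  association <- data.frame(
    barcode = sprintf("bc%07d", seq_len(sum(n_bc))),
    tile_id = rep(tiles$tile_id, n_bc),
    stringsAsFactors = FALSE
  )
  mult <- setNames(rep(1, n_tiles), tiles$tile_id)
  mult[names(planted_active)] <- planted_active
  bc_mult <- mult[association$tile_id]
  abundance <- rlnorm(nrow(association),
                      meanlog = log(mean_abundance) - 0.5^2 / 2, sdlog = 0.5)

  ## Replicates map to batches (two replicates per batch); the batch carries
  ## a shared RNA-side multiplier, a nuisance the model must absorb.
  batch_of <- paste0("batch", (seq_len(n_replicates) + 1L) %/% 2L)
  batch_rna_eff <- setNames(exp(rnorm(length(unique(batch_of)), 0, 0.1)),
                            unique(batch_of))
  sf <- matrix(rlnorm(2 * n_replicates, 0, 0.2), nrow = 2,
               dimnames = list(c("DNA", "RNA"), NULL))

  counts <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    dna_mu <- abundance * sf["DNA", r]
    rna_mu <- abundance * bc_mult * sf["RNA", r] *
      batch_rna_eff[[batch_of[r]]]
    data.frame(
      barcode = rep(association$barcode, 2L),
      modality = rep(c("DNA", "RNA"), each = nrow(association)),
      replicate = paste0("rep", r),
      batch = batch_of[r],
      count = c(rnbinom_md(nrow(association), dna_mu, nb_dispersion),
                rnbinom_md(nrow(association), rna_mu, nb_dispersion)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(counts) <- NULL

  truth <- data.frame(tile_id = names(planted_active),
                      multiplier = unname(planted_active),
                      stringsAsFactors = FALSE)
  list(association = association, counts = counts, truth = truth)
}
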