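## Observed/expected de novo variant statistics under the Poisson mutation
## model, and the O/E > 1 selection rule for haploinsufficiency candidates.

#' Expected de novo counts per gene and class
#'
#' Under the trio mutation model, the expected number of de novo variants of
#' a class in a cohort of `n_trios` offspring is `2 * n_trios * mu`, where
#' `mu` is the per-gene per-class mutation probability per haploid genome
#' per generation (two haploid genomes transmitted per offspring).
#'
#' @param rates data.frame with `gene_id` and one column per class (e.g.
#'   `lof`, `missense`, `synonymous`) of mutation probabilities.
#' @param n_trios Number of offspring with parental data (> 0).
#' @return data.frame of the same shape with expectations instead of rates.
#' @export
expected_counts <- function(rates, n_trios) {
  if (n_trios <= 0) stop("n_trios must be > 0")
  stopifnot("gene_id" %in% names(rates))
  classes <- setdiff(names(rates), "gene_id")
  if (any(vapply(rates[classes], function(x) any(x < 0), logical(1)))) {
    stop("mutation rates must be non-negative")
  }
  out <- rates
  out[classes] <- lapply(rates[classes], function(mu) 2 * n_trios * mu)
  out
}

#' Observed/expected ratio with Poisson upper-tail p-value
#'
#' `p = P(X >= observed)` for `X ~ Poisson(expected)` (one-sided enrichment
#' test). When `expected` is 0 but `observed` > 0 the gene is unratable: the
#' ratio is `Inf`, `p` is the 0 sentinel, and the record is flagged so that
#' selection can exclude it.
#'
#' @param observed Non-negative integer count vector.
#' @param expected Non-negative expectation vector.
#' @return data.frame with columns `oe`, `p`, `unratable`.
#' @export
oe_poisson <- function(observed, expected) {
  if (any(expected < 0)) stop("expected must be >= 0")
  if (any(observed < 0)) stop("observed must be >= 0")
  oe <- ifelse(expected > 0, observed / expected,
               ifelse(observed > 0, Inf, NaN))
  p <- ifelse(expected > 0,
              ppois(observed - 1, lambda = expected, lower.tail = FALSE),
              ifelse(observed > 0, 0, 1))
  unratable <- expected == 0 & observed > 0
  if (any(unratable)) {
    warning(sum(unratable),
            " record(s) have expected = 0 with observed > 0 (unratable)")
  }
  data.frame(oe = oe, p = p, unratable = unratable)
}

#' Build per-gene prioritization records
#'
#' Combines observed counts and expectations into the per-gene, per-class
#' record table (observed, expected, O/E, Poisson upper-tail p).
#'
#' @param counts data.frame `gene_id` + class columns of observed counts.
#' @param rates data.frame `gene_id` + class columns of mutation rates.
#' @param n_trios Cohort size.
#' @return Long data.frame: gene_id, class, observed, expected, oe, p,
#'   unratable.
#' @export
prioritization_records <- function(counts, rates, n_trios) {
  expect <- expected_counts(rates, n_trios)
  classes <- intersect(setdiff(names(counts), "gene_id"),
                       setdiff(names(rates), "gene_id"))
  if (length(classes) == 0) stop("counts and rates share no class columns")
  ord <- match(counts$gene_id, expect$gene_id)
  if (any(is.na(ord))) stop("counts contain genes with no mutation rate")
  do.call(rbind, lapply(classes, function(cl) {
    obs <- counts[[cl]]
    exp_ <- expect[[cl]][ord]
    cbind(data.frame(gene_id = counts$gene_id, class = cl, observed = obs,
                     expected = exp_, stringsAsFactors = FALSE),
          oe_poisson(obs, exp_))
  }))
}

#' Select haploinsufficiency candidate genes
#'
#' From a set of disorder-implicated genes, selects those whose de novo LoF
#' O/E ratio is strictly greater than 1. Unratable genes (expected 0 with
#' observed > 0) are excluded with a warning; ties at exactly 1 are
#' excluded by the strict inequality.
#'
#' @param implicated_genes Character vector of implicated gene ids.
#' @param records Record table from [prioritization_records()].
#' @param class Variant class the selection rule applies to.
#' @return Character vector of selected gene ids.
#' @export
prioritize <- function(implicated_genes, records, class = "lof") {
  rec <- records[records$class == class, ]
  missing <- setdiff(implicated_genes, rec$gene_id)
  if (length(missing) > 0) {
    stop("no record for implicated gene(s): ",
         paste(missing, collapse = ", "))
  }
  rec <- rec[match(implicated_genes, rec$gene_id), ]
  if (any(rec$unratable)) {
    warning("excluding unratable gene(s): ",
            paste(rec$gene_id[rec$unratable], collapse = ", "))
  }
  rec$gene_id[!rec$unratable & rec$oe > 1]
}

#' Cohort-level aggregate O/E and Poisson p
#'
#' Ratio of summed observed to summed expected counts across all genes for
#' one variant class, with the Poisson upper-tail p on the sums.
#'
#' @param records Record table from [prioritization_records()].
#' @param class Variant class.
#' @return List with `oe`, `observed`, `expected`, `p`.
#' @export
cohort_oe <- function(records, class = "lof") {
  rec <- records[records$class == class, ]
  if (nrow(rec) == 0) stop("no records for class ", class)
  O <- sum(rec$observed)
  E <- sum(rec$expected)
  if (E == 0) stop("total expected count is zero")
  list(oe = O / E, observed = O, expected = E,
       p = ppois(O - 1, lambda = E, lower.tail = FALSE))
}
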