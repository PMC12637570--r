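## Shared numerical helpers used across the pipeline modules.

#' Draw negative-binomial counts parameterized by mean and dispersion
#'
#' Counts have variance `mu + dispersion * mu^2` (the quadratic mean-variance
#' relationship typical of UMI and barcode count data). `dispersion = 0`
#' degenerates to Poisson.
#'
#' @param n Number of draws.
#' @param mu Mean vector (recycled).
#' @param dispersion Dispersion alpha >= 0 such that var = mu + alpha mu^2.
#' @return Integer vector of counts.
#' @export
rnbinom_md <- function(n, mu, dispersion) {
  stopifnot(dispersion >= 0)
  if (dispersion == 0) {
    return(rpois(n, lambda = mu))
  }
  rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Median-of-ratios size factors
#'
#' DESeq-style library size factors: per-row geometric means over all
#' libraries, then the per-library median of count/geometric-mean ratios,
#' computed over rows with all-positive counts. Factors are rescaled to have
#' geometric mean 1.
#'
#' @param counts Numeric matrix, rows = features, columns = libraries.
#' @return Numeric vector of size factors, one per column.
#' @export
size_factors_mor <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1L) stop("no libraries")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no feature has positive counts in every library")
  lc <- log(counts[pos, , drop = FALSE])
  gm <- rowMeans(lc)
  sf <- apply(lc, 2, function(x) exp(median(x - gm)))
  sf / exp(mean(log(sf)))
}

#' Method-of-moments negative-binomial dispersion
#'
#' Solves the moment identity sum((y - mu)^2 - mu) = alpha * sum(mu^2) for
#' alpha, floored at `floor`.
#'
#' @param y Observed counts.
#' @param mu Fitted means.
#' @param floor Lower bound for the returned dispersion.
#' @return Scalar dispersion estimate.
#' @export
mom_dispersion <- function(y, mu, floor = 1e-4) {
  denom <- sum(mu^2)
  if (denom <= 0) return(floor)
  max(floor, sum((y - mu)^2 - mu) / denom)
}

#' Derive a reproducible 31-bit seed from a master seed and a string label
#'
#' Stable polynomial string hash so per-unit seeds are independent of the
#' order units are processed in. Always returns a value in [1, 2^31 - 2].
#'
#' @param master Integer master seed.
#' @param label Character scalar identifying the unit of work.
#' @return Integer seed.
#' @export
derive_seed <- function(master, label) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector over the A/C/G/T alphabet.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Random DNA of given length.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Zero-truncated Poisson draws (>= 1) with rate lambda.
rztpois <- function(n, lambda) {
  u <- runif(n, min = ppois(0, lambda), max = 1)
  qpois(u, lambda)
}

## Validate a 0-based half-open interval data.frame with columns
## chrom/start/end.
check_intervals <- function(df, what = "interval table") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop(what, " must have columns chrom, start, end")
  }
  if (any(df$start < 0) || any(df$end <= df$start)) {
    stop(what, " has invalid coordinates (need 0 <= start < end)")
  }
  invisible(df)
}

## Convert 0-based half-open intervals to an IRanges (1-based closed).
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

## Back-convert an IRanges to 0-based half-open columns.
from_iranges0 <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}
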