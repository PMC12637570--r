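## MPRA activity calling: per-tile negative-binomial test of RNA vs DNA
## barcode counts with batch as a covariate, BH correction, the compound
## active call (q < fdr AND log2FC > 1), empirical FDR against scrambled
## controls, and roll-up of tile calls to cCRE validation.

#' Per-tile MPRA activity test
#'
#' Barcode counts are aggregated per tile x modality x replicate, libraries
#' are normalized with median-of-ratios size factors, and each tile is
#' tested with a log-link regression of normalized count on modality
#' (RNA vs DNA) plus sequencing batch. Coefficients solve the quasi-Poisson
#' score equations (so the log2 fold-change is exactly invariant to
#' rescaling any single library); the Wald standard error uses a per-tile
#' negative-binomial variance with method-of-moments dispersion floored at
#' 1e-4. P-values are BH-corrected across tested tiles and a tile is called
#' active when `q < fdr` and `log2FC > lfc_threshold`.
#'
#' Tiles with no associated barcode, or with total raw count below
#' `min_total`, are reported with NA statistics and `tested = FALSE`.
#'
#' @param counts Long data.frame: barcode, modality ("DNA"/"RNA"),
#'   replicate, batch, count.
#' @param association data.frame barcode -> tile_id (each barcode maps to
#'   exactly one tile).
#' @param tiles Optional design data.frame (tile_id, class); tiles absent
#'   from the association are then tracked as untested.
#' @param min_total Minimum total raw count across libraries for testing.
#' @param fdr BH q-value threshold of the active call.
#' @param lfc_threshold log2 fold-change threshold of the active call.
#' @return data.frame: tile_id, class, n_barcodes, base_mean, log2fc, se,
#'   p, q, active, tested.
#' @export
activity_test <- function(counts, association, tiles = NULL, min_total = 10,
                          fdr = 0.01, lfc_threshold = 1) {
  stopifnot(all(c("barcode", "modality", "replicate", "batch", "count")
                %in% names(counts)))
  if (anyDuplicated(association$barcode)) {
    stop("a barcode maps to more than one tile")
  }
  tile_of <- setNames(association$tile_id, association$barcode)
  if (!all(counts$barcode %in% names(tile_of))) {
    stop("counts contain barcodes absent from the association")
  }
  if (length(unique(counts$replicate)) < 1) stop("need >= 1 replicate")

  lib <- paste(counts$modality, counts$replicate, sep = ":")
  lib_levels <- sort(unique(lib))
  lib_meta <- unique(data.frame(lib = lib, modality = counts$modality,
                                replicate = counts$replicate,
                                batch = counts$batch,
                                stringsAsFactors = FALSE))
  lib_meta <- lib_meta[match(lib_levels, lib_meta$lib), ]
  tile <- tile_of[counts$barcode]
  tile_levels <- sort(unique(association$tile_id))
  K <- matrix(0, nrow = length(tile_levels), ncol = length(lib_levels),
              dimnames = list(tile_levels, lib_levels))
  agg <- tapply(counts$count, list(factor(tile, tile_levels),
                                   factor(lib, lib_levels)), sum)
  agg[is.na(agg)] <- 0
  K[] <- agg

  sf <- size_factors_mor(K)
  Z <- sweep(K, 2, sf, "/")

  ## Design: intercept + modality(RNA) + batch dummies.
  modality <- as.integer(lib_meta$modality == "RNA")
  batch <- factor(lib_meta$batch)
  X <- cbind(intercept = 1, rna = modality)
  if (nlevels(batch) > 1) {
    X <- cbind(X, stats::model.matrix(~batch)[, -1, drop = FALSE])
  }
  n_bc <- as.vector(table(factor(association$tile_id, tile_levels)))
  tested <- rowSums(K) >= min_total
  fit <- fit_loglink_batch(Z[tested, , drop = FALSE], X,
                           n_barcodes = n_bc[tested])

  res <- data.frame(tile_id = tile_levels,
                    n_barcodes = as.vector(table(
                      factor(association$tile_id, tile_levels))),
                    base_mean = rowMeans(Z), log2fc = NA_real_,
                    se = NA_real_, p = NA_real_, q = NA_real_,
                    active = FALSE, tested = tested,
                    stringsAsFactors = FALSE)
  res$log2fc[tested] <- fit$beta[, "rna"] / log(2)
  res$se[tested] <- fit$se_rna / log(2)
  res$p[tested] <- fit$p
  res$tested[which(tested)[is.na(fit$p)]] <- FALSE
  res$q[res$tested] <- p.adjust(res$p[res$tested], method = "BH")
  res$active <- !is.na(res$q) & res$q < fdr &
    !is.na(res$log2fc) & res$log2fc > lfc_threshold

  if (!is.null(tiles)) {
    res$class <- tiles$class[match(res$tile_id, tiles$tile_id)]
    missing <- setdiff(tiles$tile_id, res$tile_id)
    if (length(missing) > 0) {
      res <- rbind(res, data.frame(
        tile_id = missing, n_barcodes = 0L, base_mean = NA_real_,
        log2fc = NA_real_, se = NA_real_, p = NA_real_, q = NA_real_,
        active = FALSE, tested = FALSE,
        class = tiles$class[match(missing, tiles$tile_id)],
        stringsAsFactors = FALSE))
    }
  } else {
    res$class <- "test"
  }
  rownames(res) <- NULL
  res
}

## Batched log-link quasi-Poisson IRLS over many tiles sharing one design
## matrix, with NB method-of-moments Wald standard errors for the `rna`
## coefficient. y: tiles x libraries matrix (may be non-integer after
## normalization); X: libraries x p design. Per-tile dispersions use the
## residual-degrees-of-freedom correction and, because each tile has few
## libraries, are clamped from below at a pooled trend (the across-tile
## median of dispersion x barcode count, rescaled by each tile's barcode
## count) so that noisy per-tile underestimates do not inflate Wald z.
fit_loglink_batch <- function(y, X, n_barcodes = NULL, max_iter = 50L,
                              tol = 1e-12, disp_floor = 1e-4) {
  n_t <- nrow(y)
  p <- ncol(X)
  if (n_t == 0) {
    return(list(beta = matrix(numeric(0), 0, p,
                              dimnames = list(NULL, colnames(X))),
                se_rna = numeric(0), p = numeric(0),
                dispersion = numeric(0)))
  }
  ## Pairwise products of design columns, for per-tile information
  ## matrices via a single matrix multiplication per iteration.
  XX <- matrix(0, nrow(X), p * p)
  for (a in seq_len(p)) for (b in seq_len(p)) {
    XX[, (a - 1) * p + b] <- X[, a] * X[, b]
  }
  beta <- matrix(0, n_t, p, dimnames = list(NULL, colnames(X)))
  beta[, 1] <- log(pmax(rowMeans(y), 1e-8))
  ok <- rowSums(y) > 0
  for (it in seq_len(max_iter)) {
    eta <- beta %*% t(X)
    mu <- pmax(exp(eta), 1e-12)
    zwork <- eta + (y - mu) / mu
    info <- (mu %*% XX)                      # tiles x p^2
    rhs <- (mu * zwork) %*% X                # tiles x p
    new_beta <- beta
    for (t in which(ok)) {
      M <- matrix(info[t, ], p, p)
      bt <- tryCatch(solve(M, rhs[t, ]), error = function(e) NULL)
      if (!is.null(bt)) new_beta[t, ] <- bt
    }
    delta <- max(abs(new_beta - beta)[ok, , drop = FALSE], 0)
    beta <- new_beta
    if (delta < tol) break
  }
  eta <- beta %*% t(X)
  mu <- pmax(exp(eta), 1e-12)
  ## Per-tile MoM dispersion on the normalized scale, with the n/(n - p)
  ## residual-df correction, then the pooled lower clamp.
  n_lib <- ncol(y)
  dfc <- n_lib / max(1, n_lib - p)
  alpha_raw <- (dfc * rowSums((y - mu)^2) - rowSums(mu)) /
    pmax(rowSums(mu^2), 1e-12)
  if (is.null(n_barcodes)) n_barcodes <- rep(1, n_t)
  alpha <- pmax(alpha_raw, disp_floor)
  if (sum(ok) >= 5) {
    ## Pooled Pearson-moment dispersion across tiles: solve for the shared
    ## barcode-count-scaled dispersion a such that sum of squared Pearson
    ## residuals at alpha_t = a / n_barcodes_t equals the residual df.
    resid2 <- (y - mu)^2
    inv_nb <- 1 / n_barcodes
    target <- sum(ok) * (n_lib - p)
    pearson_gap <- function(a) {
      sum((resid2 / (mu + (a * inv_nb) * mu^2))[ok, , drop = FALSE]) -
        target
    }
    if (n_lib > p && pearson_gap(0) > 0) {
      hi <- 1
      while (pearson_gap(hi) > 0 && hi < 1e4) hi <- hi * 10
      a <- stats::uniroot(pearson_gap, c(0, hi))$root
      ## The pooled value replaces the noisy per-tile estimates (2-4
      ## residual df each); a tile keeps its own estimate only when it is a
      ## clear dispersion outlier.
      pooled <- pmax(a * inv_nb, disp_floor)
      alpha <- ifelse(alpha_raw > 5 * pooled, alpha_raw, pooled)
    }
  }
  w <- mu / (1 + alpha * mu)
  info_nb <- w %*% XX
  se <- rep(NA_real_, n_t)
  for (t in which(ok)) {
    M <- matrix(info_nb[t, ], p, p)
    v <- tryCatch(solve(M)[2, 2], error = function(e) NA_real_)
    se[t] <- sqrt(v)
  }
  zstat <- beta[, 2] / se
  pval <- 2 * pnorm(-abs(zstat))
  pval[!ok] <- NA_real_
  se[!ok] <- NA_real_
  list(beta = beta, se_rna = se, p = pval, dispersion = alpha)
}

#' Empirical FDR of the active call from scrambled controls
#'
#' The fraction of scrambled negative-control tiles passing the active
#' thresholds, scaled to the number of test tiles, divided by the number of
#' test tiles passing: `eFDR = (scrambled pass rate x n_test) /
#' n_test_passing`, and 0 when no test tile passes.
#'
#' @param test_calls Activity rows for test tiles (need column `active`).
#' @param scrambled_calls Activity rows for scrambled tiles (>= 1 row).
#' @return Proportion (scalar).
#' @export
empirical_fdr <- function(test_calls, scrambled_calls) {
  if (nrow(scrambled_calls) == 0) stop("need >= 1 scrambled tile")
  n_test <- nrow(test_calls)
  n_pass <- sum(test_calls$active)
  if (n_pass == 0) return(0)
  mean(scrambled_calls$active) * n_test / n_pass
}

#' Monotone empirical-FDR curve over activity-score thresholds
#'
#' Raw estimates `mean(scrambled >= t) / mean(test >= t)` are monotonized
#' q-value style (running minimum from the loosest to the strictest
#' threshold) so the reported eFDR never increases as the threshold is
#' raised.
#'
#' @param test_scores Activity scores of test tiles.
#' @param scrambled_scores Activity scores of scrambled tiles.
#' @param thresholds Increasing vector of score thresholds.
#' @return data.frame: threshold, raw, efdr (monotone).
#' @export
empirical_fdr_curve <- function(test_scores, scrambled_scores, thresholds) {
  if (length(scrambled_scores) == 0) stop("need >= 1 scrambled tile")
  thresholds <- sort(thresholds)
  raw <- vapply(thresholds, function(t) {
    n_pass <- sum(test_scores >= t)
    if (n_pass == 0) return(0)
    mean(scrambled_scores >= t) * length(test_scores) / n_pass
  }, numeric(1))
  data.frame(threshold = thresholds, raw = raw, efdr = cummin(raw))
}

#' Roll tile activity up to cCRE validation
#'
#' A cCRE is validated when at least one of its tiles scores in the top
#' `top_fraction` of activity scores. The score universe defaults to all
#' scored tiles (controls included); set `universe = "test"` to restrict to
#' test tiles.
#'
#' @param activity Output of [activity_test()] (needs `log2fc`, `tested`,
#'   `class`).
#' @param designs Tile design table (tile_id, ccre_id).
#' @param top_fraction Fraction defining "highly active" (default 0.10).
#' @param universe "all" or "test": tiles over which the score quantile is
#'   taken.
#' @return data.frame: ccre_id, best_score, validated.
#' @export
validate_ccres <- function(activity, designs, top_fraction = 0.10,
                           universe = c("all", "test")) {
  universe <- match.arg(universe)
  scored <- activity[activity$tested & !is.na(activity$log2fc), ]
  if (universe == "test") scored_u <- scored[scored$class == "test", ]
  else scored_u <- scored
  if (nrow(scored_u) < 10) stop("need >= 10 scored tiles")
  thr <- quantile(scored_u$log2fc, 1 - top_fraction, names = FALSE)
  sc <- scored[match(designs$tile_id, scored$tile_id), "log2fc"]
  best <- tapply(sc, designs$ccre_id, function(x) {
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  })
  data.frame(ccre_id = names(best), best_score = as.vector(best),
             validated = !is.na(best) & best >= thr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Odds ratio with Fisher's exact test for a 2x2 enrichment table
#'
#' The odds ratio is the cross-product `(a*d)/(b*c)` with the
#' Haldane-Anscombe 0.5 continuity correction applied to every cell when
#' any cell is zero; the two-sided p-value is Fisher's exact test
#' (hypergeometric enumeration).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `odds_ratio` and `p`.
#' @export
enrichment_odds_ratio <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (sum(table) == 0) stop("all-zero table")
  t2 <- table
  if (any(t2 == 0)) t2 <- t2 + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(odds_ratio = unname(or),
       p = fisher.test(table, alternative = "two.sided")$p.value)
}
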