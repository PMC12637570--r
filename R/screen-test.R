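## Conditional randomization testing of gRNA -> gene upregulation in a
## multiplex single-cell CRISPRa screen. For each gRNA a logistic model of
## assignment on cell covariates is fitted; the test statistic is the NB
## score statistic for the gRNA indicator in a regression of the gene's UMI
## count on covariates with a log library-size offset; the null distribution
## comes from B indicator vectors resampled from the fitted assignment
## probabilities. Resampled indicator matrices are drawn once per gRNA and
## shared across that gRNA's genes.

## Cell-level covariate design matrix (intercept, log totals, log unique
## genes, mito fraction, lane dummies) over QC-passing cells.
screen_design <- function(cells_qc) {
  X <- cbind(intercept = 1,
             log_umis = log(cells_qc$total_umis),
             log_genes = log(pmax(cells_qc$genes_detected, 1)),
             mito = cells_qc$mito_frac)
  lane <- factor(cells_qc$lane)
  if (nlevels(lane) > 1) {
    X <- cbind(X, stats::model.matrix(~lane)[, -1, drop = FALSE])
  }
  X
}

## Logistic model of gRNA assignment on covariates (plus log guide-library
## size); returns fitted probabilities clipped away from 0/1.
fit_presence <- function(has_guide, cells_qc) {
  X <- cbind(screen_design(cells_qc),
             log_guide = log1p(cells_qc$guide_umis))
  fit <- suppressWarnings(
    glm.fit(X, as.numeric(has_guide), family = binomial())
  )
  pmin(pmax(fit$fitted.values, 1e-8), 1 - 1e-8)
}

## NB null fit of one gene's counts on covariates with log total-UMI
## offset: Poisson IRLS, method-of-moments dispersion (floored), one NB
## reweighted refit. Returns quantities for the score statistic.
fit_gene_null <- function(y, X, offset, disp_floor = 1e-4, n_iter = 25L) {
  if (all(y == 0)) {
    return(list(degenerate = TRUE))
  }
  beta <- c(log(mean(y) + 1e-8) - mean(offset), rep(0, ncol(X) - 1))
  alpha <- 0
  for (round in 1:2) {
    for (it in seq_len(n_iter)) {
      eta <- drop(X %*% beta) + offset
      mu <- pmax(exp(eta), 1e-10)
      w <- mu / (1 + alpha * mu)
      z <- eta - offset + (y - mu) / mu
      fit <- tryCatch(
        qr.coef(qr(X * sqrt(w)), sqrt(w) * z),
        error = function(e) NULL
      )
      if (is.null(fit) || any(is.na(fit))) break
      if (max(abs(fit - beta)) < 1e-10) {
        beta <- fit
        break
      }
      beta <- fit
    }
    if (round == 1) {
      mu <- pmax(exp(drop(X %*% beta) + offset), 1e-10)
      alpha <- mom_dispersion(y, mu, floor = disp_floor)
    }
  }
  mu <- pmax(exp(drop(X %*% beta) + offset), 1e-10)
  w <- mu / (1 + alpha * mu)
  WX <- X * w
  M <- tryCatch(solve(crossprod(X, WX)), error = function(e) NULL)
  if (is.null(M)) return(list(degenerate = TRUE))
  list(degenerate = FALSE, mu = mu, alpha = alpha,
       r = (y - mu) / (1 + alpha * mu), w = w, WX = WX, M = M)
}

## Score statistic z for indicator vector(s). x: n-vector or n x B matrix.
score_stat <- function(x, null_fit) {
  x <- as.matrix(x)
  U <- drop(crossprod(x, null_fit$r))
  sumw <- drop(crossprod(x, null_fit$w))
  C <- crossprod(null_fit$WX, x)          # p x B
  V <- sumw - colSums(C * (null_fit$M %*% C))
  z <- ifelse(V > 1e-12, U / sqrt(V), Inf)
  z
}

#' Conditional randomization test of one gRNA against a set of genes
#'
#' One-sided (upregulation) resampling p-values: `p = (1 + #{resampled
#' statistic >= observed}) / (B + 1)`, so the smallest attainable p is
#' `1/(B+1)`. The average log2 fold-change compares size-factor-normalized
#' expression in treated vs untreated cells with pseudocount 0.01.
#'
#' @param grna_id The gRNA to test.
#' @param genes Character vector of genes to test it against.
#' @param assignments Assignment table from [qc_and_assign()].
#' @param gene_matrix Cells x genes UMI matrix (all cells; QC-passing rows
#'   are used).
#' @param cells Per-cell record table from [qc_and_assign()].
#' @param B Number of resamples (>= 100).
#' @param seed Master seed; the per-gRNA stream is derived from it.
#' @param min_treated Minimum number of treated cells to run a test.
#' @param null_cache Optional environment caching per-gene null fits across
#'   calls.
#' @return data.frame: grna_id, gene_id, n_treated, p, log2fc, B, tested,
#'   flagged (TRUE when the gene had zero counts in all cells).
#' @export
crt_test_grna <- function(grna_id, genes, assignments, gene_matrix, cells,
                          B = 1000L, seed = 1L, min_treated = 20L,
                          null_cache = NULL) {
  if (B < 100L) stop("B must be >= 100")
  cells_qc <- cells[cells$qc_pass, , drop = FALSE]
  gm <- gene_matrix[cells_qc$cell_id, , drop = FALSE]
  has <- cells_qc$cell_id %in%
    assignments$cell_id[assignments$grna_id == grna_id]
  n_treated <- sum(has)

  out <- data.frame(grna_id = grna_id, gene_id = genes,
                    n_treated = n_treated, p = NA_real_,
                    log2fc = NA_real_, B = as.integer(B), tested = FALSE,
                    flagged = FALSE, stringsAsFactors = FALSE)
  if (n_treated < min_treated) return(out)

  prob <- fit_presence(has, cells_qc)
  set.seed(derive_seed(seed, paste0("grna:", grna_id)))
  n <- nrow(cells_qc)
  S <- matrix(as.numeric(runif(n * B) < prob), n, B)

  X <- screen_design(cells_qc)
  offset <- log(pmax(cells_qc$total_umis, 1))
  sizefac <- cells_qc$total_umis / mean(cells_qc$total_umis)
  xs <- as.numeric(has)
  for (k in seq_along(genes)) {
    y <- as.vector(gm[, genes[k]])
    norm <- y / sizefac
    out$log2fc[k] <- log2((mean(norm[has]) + 0.01) /
                            (mean(norm[!has]) + 0.01))
    if (all(y == 0)) {
      out$p[k] <- 1
      out$log2fc[k] <- 0
      out$flagged[k] <- TRUE
      out$tested[k] <- TRUE
      next
    }
    nf <- if (!is.null(null_cache) && !is.null(null_cache[[genes[k]]])) {
      null_cache[[genes[k]]]
    } else {
      f <- fit_gene_null(y, X, offset)
      if (!is.null(null_cache)) null_cache[[genes[k]]] <- f
      f
    }
    if (nf$degenerate) {
      out$p[k] <- 1
      out$flagged[k] <- TRUE
      out$tested[k] <- TRUE
      next
    }
    z_obs <- score_stat(xs, nf)
    z_null <- score_stat(S, nf)
    out$p[k] <- (1 + sum(z_null >= z_obs)) / (B + 1)
    out$tested[k] <- TRUE
  }
  out
}

#' Run the discovery analysis over a (gRNA, gene) pair list
#'
#' Loops [crt_test_grna()] over gRNAs (one resample draw per gRNA, shared
#' across its genes) with a per-gene null-fit cache, so results are
#' independent of pair order.
#'
#' @param pairs data.frame with grna_id and gene_id.
#' @inheritParams crt_test_grna
#' @return Row-bound DEResult table.
#' @export
run_discovery <- function(pairs, assignments, gene_matrix, cells,
                          B = 1000L, seed = 1L, min_treated = 20L) {
  cache <- new.env(parent = emptyenv())
  by_grna <- split(pairs$gene_id, pairs$grna_id)
  res <- lapply(names(by_grna), function(g) {
    crt_test_grna(g, unique(by_grna[[g]]), assignments, gene_matrix, cells,
                  B = B, seed = seed, min_treated = min_treated,
                  null_cache = cache)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Calibration report from non-targeting-control tests
#'
#' Downsamples NTC p-values to the number of targeting cis tests, then
#' reports the Kolmogorov-Smirnov comparison against Uniform(0,1), the
#' empirical type-I error at alpha in {0.01, 0.05}, and a QQ table.
#'
#' @param ntc_pvalues Vector of NTC resampling p-values (>= 50).
#' @param n_targeting_tests Number of targeting cis tests to downsample to.
#' @param seed Integer seed for the downsampling.
#' @param alphas Type-I error levels to report.
#' @return List: n (downsampled count), ks_stat, ks_p, type1 (named by
#'   alpha), qq (data.frame expected/observed).
#' @export
calibrate_ntc <- function(ntc_pvalues, n_targeting_tests, seed = 1L,
                          alphas = c(0.01, 0.05)) {
  if (length(ntc_pvalues) < 50) stop("need >= 50 NTC tests")
  set.seed(derive_seed(seed, "ntc-downsample"))
  p <- if (length(ntc_pvalues) > n_targeting_tests) {
    sample(ntc_pvalues, n_targeting_tests)
  } else ntc_pvalues
  ks <- suppressWarnings(ks.test(p, "punif"))
  type1 <- vapply(alphas, function(a) mean(p <= a), numeric(1))
  sp <- sort(p)
  qq <- data.frame(expected = (seq_along(sp) - 0.5) / length(sp),
                   observed = sp)
  list(n = length(p), ks_stat = unname(ks$statistic), ks_p = ks$p.value,
       type1 = setNames(type1, alphas), qq = qq)
}

#' BH hit calling and 1 Mb specificity classification
#'
#' Benjamini-Hochberg correction over the intended-target discovery tests;
#' pairs with q below `fdr` are hits. Each hit gRNA is then re-tested
#' against every gene whose TSS lies within `specificity_window` of its
#' site, with BH within that neighborhood family: the hit is "specific"
#' when the intended target is the only significant gene, "non_specific"
#' otherwise, and "untested" when the neighborhood could not be tested.
#'
#' @param results Discovery DEResult table (intended-target pairs).
#' @param guide_sites data.frame grna_id, chrom, start, end of gRNA sites.
#' @param gene_tss data.frame gene_id, chrom, tss.
#' @param assignments,gene_matrix,cells As in [crt_test_grna()].
#' @param fdr BH threshold (default 0.1).
#' @param specificity_window Half-window for the neighborhood (default
#'   1e6).
#' @param B,seed,min_treated Resampling parameters for neighborhood tests.
#' @return List with `results` (q column added, hit flag) and `hits` (hit
#'   rows plus specificity class).
#' @export
call_hits_and_specificity <- function(results, guide_sites, gene_tss,
                                      assignments, gene_matrix, cells,
                                      fdr = 0.1, specificity_window = 1e6,
                                      B = 1000L, seed = 1L,
                                      min_treated = 20L) {
  results$q <- NA_real_
  tested <- results$tested & !is.na(results$p)
  results$q[tested] <- p.adjust(results$p[tested], method = "BH")
  results$hit <- !is.na(results$q) & results$q < fdr

  hits <- results[results$hit, , drop = FALSE]
  hits$specificity <- "untested"
  if (nrow(hits) > 0) {
    cache <- new.env(parent = emptyenv())
    neighborhoods <- cis_pairs(
      guide_sites[guide_sites$grna_id %in% hits$grna_id, , drop = FALSE],
      gene_tss, half_window = specificity_window)
    for (i in seq_len(nrow(hits))) {
      nb <- neighborhoods$gene_id[neighborhoods$grna_id == hits$grna_id[i]]
      if (length(nb) == 0) next
      r <- crt_test_grna(hits$grna_id[i], nb, assignments, gene_matrix,
                         cells, B = B, seed = seed,
                         min_treated = min_treated, null_cache = cache)
      if (!any(r$tested)) next
      r$q <- NA_real_
      r$q[r$tested] <- p.adjust(r$p[r$tested], method = "BH")
      sig <- r$gene_id[!is.na(r$q) & r$q < fdr]
      hits$specificity[i] <-
        if (setequal(sig, hits$gene_id[i])) "specific" else "non_specific"
    }
  }
  list(results = results, hits = hits)
}

#' Gene-level summary of screen hits
#'
#' Per-gene counts of activating promoter- and enhancer-targeting gRNAs,
#' the genes with at least one and at least two activating gRNAs, the
#' fraction of enhancer hits within 100 kb of their target TSS, and the
#' effective-cell multiplexing figure (mean assigned gRNAs per cell x
#' QC-passing cells).
#'
#' @param hits Hit table (grna_id, gene_id).
#' @param targets data.frame grna_id, target_gene, kind ("promoter" or
#'   "enhancer"), optionally `distance` (site-to-TSS bp).
#' @param qc_summary Summary list from [qc_and_assign()] (optional; enables
#'   the effective-cell figure).
#' @return List: per_gene table, n_genes_1plus, n_genes_2plus,
#'   frac_enhancer_within_100kb (NA without distances), effective_cells
#'   (NA without qc_summary).
#' @export
gene_summary <- function(hits, targets, qc_summary = NULL) {
  if (nrow(hits) == 0) {
    return(list(per_gene = data.frame(gene_id = character(),
                                      n_promoter = integer(),
                                      n_enhancer = integer()),
                n_genes_1plus = 0L, n_genes_2plus = 0L,
                frac_enhancer_within_100kb = NA_real_,
                effective_cells = if (is.null(qc_summary)) NA_real_ else
                  qc_summary$mean_guides_per_cell * qc_summary$n_cells_qc))
  }
  kind <- targets$kind[match(hits$grna_id, targets$grna_id)]
  per_gene <- do.call(rbind, lapply(split(kind, hits$gene_id), function(k) {
    data.frame(n_promoter = sum(k == "promoter"),
               n_enhancer = sum(k == "enhancer"))
  }))
  per_gene <- cbind(gene_id = rownames(per_gene), per_gene,
                    stringsAsFactors = FALSE)
  rownames(per_gene) <- NULL
  tot <- per_gene$n_promoter + per_gene$n_enhancer
  frac100 <- NA_real_
  if ("distance" %in% names(targets)) {
    d <- targets$distance[match(hits$grna_id[kind == "enhancer"],
                                targets$grna_id)]
    if (length(d) > 0) frac100 <- mean(abs(d) <= 1e5, na.rm = TRUE)
  }
  list(per_gene = per_gene,
       n_genes_1plus = sum(tot >= 1),
       n_genes_2plus = sum(tot >= 2),
       frac_enhancer_within_100kb = frac100,
       effective_cells = if (is.null(qc_summary)) NA_real_ else
         qc_summary$mean_guides_per_cell * qc_summary$n_cells_qc)
}
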