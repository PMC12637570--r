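# Cell QC boundaries, gRNA assignment, cis-pair construction, the
# conditional randomization test and its calibration, hit calling with
# specificity, and gene-level summaries.

test_that("QC applies the mito and UMI rules with the stated boundaries", {
  gm <- Matrix::Matrix(matrix(c(900, 0, 898, 1, 2000, 0), nrow = 3,
                              byrow = TRUE,
                              dimnames = list(paste0("c", 1:3),
                                              c("gA", "gB"))),
                       sparse = TRUE)
  gd <- Matrix::Matrix(matrix(c(7, 4, 5, 0, 0, 0), nrow = 3, byrow = TRUE,
                              dimnames = list(paste0("c", 1:3),
                                              c("g1", "g2"))),
                       sparse = TRUE)
  cov <- data.frame(cell_id = paste0("c", 1:3), lane = "lane1",
                    mito_frac = c(0.10, 0.10, 0.25))
  qa <- qc_and_assign(gm, gd, cov)
  ## exactly 900 UMIs kept; 899 excluded; mito 25% excluded despite UMIs
  expect_equal(qa$cells$qc_pass, c(TRUE, FALSE, FALSE))
  ## gRNA UMIs {7, 4} in the kept cell: 1 assignment at threshold >= 5
  expect_equal(nrow(qa$assignments), 1)
  expect_equal(qa$assignments$grna_id, "g1")
  ## {7, 4, 5} in one cell would give 2 assignments
  gd2 <- gd
  gd2["c1", "g2"] <- 5
  qa2 <- qc_and_assign(gm, gd2, cov)
  expect_equal(sort(qa2$assignments$grna_id), c("g1", "g2"))
  expect_error(qc_and_assign(gm, gd[c(2, 1, 3), ], cov), "cell ids")
})

test_that("cis pairs apply the inclusive 1 Mb window per chromosome", {
  sites <- data.frame(grna_id = "g1", chrom = "chr2",
                      start = 5e6 - 10, end = 5e6 + 10)
  tss <- data.frame(gene_id = paste0("t", 1:4),
                    chrom = c("chr2", "chr2", "chr2", "chr3"),
                    tss = c(4.2e6, 5.5e6, 6.2e6, 5.0e6))
  cp <- cis_pairs(sites, tss, half_window = 1e6)
  expect_equal(sort(cp$gene_id), c("t1", "t2"))
  ## exactly 1 Mb away: included
  cp2 <- cis_pairs(sites, data.frame(gene_id = "x", chrom = "chr2",
                                     tss = 6e6), 1e6)
  expect_equal(cp2$gene_id, "x")
  ## brute-force equivalence on a random instance
  set.seed(21)
  sites_r <- data.frame(grna_id = paste0("g", 1:40),
                        chrom = sample(c("c1", "c2"), 40, TRUE),
                        start = sample.int(2e7, 40))
  sites_r$end <- sites_r$start + 20
  tss_r <- data.frame(gene_id = paste0("t", 1:300),
                      chrom = sample(c("c1", "c2"), 300, TRUE),
                      tss = sample.int(2e7, 300))
  cp_r <- cis_pairs(sites_r, tss_r, 1e6)
  brute <- expand.grid(i = 1:40, j = 1:300)
  mid <- (sites_r$start + sites_r$end) %/% 2
  keep <- sites_r$chrom[brute$i] == tss_r$chrom[brute$j] &
    abs(tss_r$tss[brute$j] - mid[brute$i]) <= 1e6
  expect_equal(nrow(cp_r), sum(keep))
  expect_setequal(paste(cp_r$grna_id, cp_r$gene_id),
                  paste(sites_r$grna_id[brute$i[keep]],
                        tss_r$gene_id[brute$j[keep]]))
})

test_that("resampling p-values respect the 1/(B+1) lower bound", {
  scr <- make_screen(n_cells = 800, n_guides = 20, seed = 31,
                     effects = setNames(8, "g1"))
  qa <- qc_and_assign(scr$gene_matrix, scr$guide_matrix, scr$covariates)
  r <- crt_test_grna("g1", "tg1", qa$assignments, scr$gene_matrix,
                     qa$cells, B = 100, seed = 1)
  expect_gte(r$p, 1 / 101)
  expect_equal(r$p, 1 / 101)      # an 8-fold effect maxes out at the bound
  expect_gt(r$log2fc, 2)
  ## a gene with zero counts everywhere is flagged with p = 1, lfc = 0
  gm0 <- scr$gene_matrix
  gm0[, "tg2"] <- 0
  r0 <- crt_test_grna("g3", "tg2", qa$assignments, gm0, qa$cells,
                      B = 100, seed = 1)
  expect_equal(r0$p, 1)
  expect_equal(r0$log2fc, 0)
  expect_true(r0$flagged)
  ## too few treated cells: untested
  rt <- crt_test_grna("g1", "tg1", qa$assignments, scr$gene_matrix,
                      qa$cells, B = 100, seed = 1, min_treated = 1e6)
  expect_false(rt$tested)
  expect_error(crt_test_grna("g1", "tg1", qa$assignments,
                             scr$gene_matrix, qa$cells, B = 50), "B")
})

test_that("NTC tests are calibrated on null screens across seeds", {
  for (seed in 1:3) {
    scr <- make_screen(n_cells = 3000, n_guides = 40, seed = seed,
                       ntc_fraction = 0.35)
    qa <- qc_and_assign(scr$gene_matrix, scr$guide_matrix, scr$covariates)
    ntc <- scr$guide_meta$grna_id[scr$guide_meta$ntc]
    genes <- unique(scr$targets$target_gene)
    set.seed(seed)
    pairs <- data.frame(grna_id = rep(ntc[1:14], each = 14),
                        gene_id = as.vector(
                          replicate(14, sample(genes, 14))))
    res <- run_discovery(pairs, qa$assignments, scr$gene_matrix, qa$cells,
                         B = 300, seed = seed)
    cal <- calibrate_ntc(res$p, nrow(res), seed = seed)
    expect_gt(cal$ks_p, 0.01)
    expect_lt(abs(cal$type1[["0.05"]] - 0.05),
              3 * sqrt(0.05 * 0.95 / nrow(res)) + 1e-9)
  }
})

test_that("calibrate_ntc downsamples to the targeting test count", {
  set.seed(4)
  p <- runif(400)
  cal <- calibrate_ntc(p, 150, seed = 2)
  expect_equal(cal$n, 150)
  expect_equal(nrow(cal$qq), 150)
  expect_gt(cal$ks_p, 0.01)
  expect_error(calibrate_ntc(runif(10), 5), ">= 50")
})

test_that("hit calling BH-corrects and classifies specificity", {
  ## planted effect on g1 -> tg1; g2 targets tg1 too but has no effect
  scr <- make_screen(n_cells = 2500, n_guides = 30, seed = 77,
                     effects = setNames(3, "g1"))
  qa <- qc_and_assign(scr$gene_matrix, scr$guide_matrix, scr$covariates)
  pairs <- data.frame(grna_id = scr$targets$grna_id,
                      gene_id = scr$targets$target_gene)
  res <- run_discovery(pairs, qa$assignments, scr$gene_matrix, qa$cells,
                       B = 300, seed = 3)
  ## genomic layout: each target gene TSS 10 kb from its gRNAs' site,
  ## neighbours within 1 Mb
  genes <- unique(scr$targets$target_gene)
  gene_tss <- data.frame(gene_id = genes, chrom = "chr1",
                         tss = 2e6 + seq_along(genes) * 2e5)
  sites <- data.frame(grna_id = scr$targets$grna_id, chrom = "chr1")
  sites$start <- gene_tss$tss[match(scr$targets$target_gene,
                                    gene_tss$gene_id)] + 1e4
  sites$end <- sites$start + 20
  hs <- call_hits_and_specificity(res, sites, gene_tss, qa$assignments,
                                  scr$gene_matrix, qa$cells,
                                  B = 300, seed = 3)
  expect_true(all(hs$results$q[hs$results$tested] >=
                    hs$results$p[hs$results$tested]))
  expect_true("g1" %in% hs$hits$grna_id)
  g1row <- hs$hits[hs$hits$grna_id == "g1", ]
  expect_equal(g1row$gene_id, "tg1")
  expect_equal(g1row$specificity, "specific")
  ## BH arithmetic matches the brute-force step-up on these p-values
  tested <- hs$results$tested
  expect_equal(hs$results$q[tested], oracle_bh(hs$results$p[tested]))
})

test_that("gene summary counts promoter/enhancer hits and effective cells", {
  hits <- data.frame(grna_id = c("g1", "g2"), gene_id = "geneX")
  targets <- data.frame(grna_id = c("g1", "g2", "g3"),
                        target_gene = "geneX",
                        kind = c("promoter", "enhancer", "promoter"),
                        distance = c(500, 5e4, 100))
  qs <- list(mean_guides_per_cell = 10.3, n_cells_qc = 200513)
  gs <- gene_summary(hits, targets, qs)
  expect_equal(gs$per_gene$n_promoter, 1)
  expect_equal(gs$per_gene$n_enhancer, 1)
  expect_equal(gs$n_genes_2plus, 1)
  expect_equal(gs$frac_enhancer_within_100kb, 1)
  expect_equal(gs$effective_cells, 10.3 * 200513)
  expect_gt(gs$effective_cells, 2e6)
  empty <- gene_summary(hits[0, ], targets, qs)
  expect_equal(empty$n_genes_1plus, 0)
})
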