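# Generators: determinism, preconditions, structural invariants, planted
# truth bookkeeping, and null behaviour.

test_that("generators are deterministic under a fixed seed", {
  r1 <- gen_reference(7, n_chromosomes = 2, chrom_length = 2e5, n_genes = 6)
  r2 <- gen_reference(7, n_chromosomes = 2, chrom_length = 2e5, n_genes = 6)
  expect_identical(r1, r2)

  tiles <- make_tiles(20, 5)
  m1 <- gen_mpra_counts(tiles, barcodes_per_tile = 10, seed = 3)
  m2 <- gen_mpra_counts(tiles, barcodes_per_tile = 10, seed = 3)
  expect_identical(m1, m2)

  s1 <- make_screen(n_cells = 300, n_guides = 20, seed = 5)
  s2 <- make_screen(n_cells = 300, n_guides = 20, seed = 5)
  expect_equal(s1$gene_matrix, s2$gene_matrix)
  expect_equal(s1$guide_matrix, s2$guide_matrix)
  expect_identical(s1$covariates, s2$covariates)
})

test_that("gen_reference validates inputs and places genes cleanly", {
  expect_error(gen_reference(1, n_genes = 0), "n_genes")
  expect_error(gen_reference(1, chrom_length = 5000), "chrom_length")
  expect_error(gen_reference(1, chrom_length = 1e4, n_genes = 50,
                             gene_length_range = c(4000, 8000)),
               "cannot place")

  ref <- gen_reference(11, n_chromosomes = 1, chrom_length = 1e6,
                       n_genes = 10)
  expect_equal(nrow(ref$genes), 10)
  g <- ref$genes[order(ref$genes$start), ]
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))          # non-overlap
  expect_true(all(ref$exons$start >= 0 &
                    ref$exons$end <= ref$chrom_lengths[ref$exons$chrom]))
  mu <- as.matrix(ref$mutation_rates[, c("lof", "missense", "synonymous")])
  expect_true(all(mu > 0 & mu < 1e-3))
  expect_true(all(strsplit(ref$sequences[[1]], "")[[1]] %in%
                    c("A", "C", "G", "T")))
  ## pseudo-CAGE peak is unimodal with its mode at the TSS
  cg <- ref$cage[ref$cage$gene_id == ref$genes$gene_id[1], ]
  expect_equal(cg$pos[which.max(cg$count)], ref$genes$tss[1])
  expect_true(all(diff(cg$count[cg$pos <= ref$genes$tss[1]]) >= 0))
})

test_that("de novo cohorts follow the 2*N*mu Poisson model", {
  ref <- gen_reference(3, chrom_length = 1e6, n_genes = 40)
  ## linearity in n_trios (cohort totals, averaged over genes)
  c1 <- gen_denovo_cohort(ref, n_trios = 20000, seed = 1)
  c2 <- gen_denovo_cohort(ref, n_trios = 40000, seed = 2)
  expect_equal(sum(c2$counts$missense) / sum(c1$counts$missense), 2,
               tolerance = 0.15)

  ## planted risk gene with mu_lof = 1e-5, N = 42,320, inflation 2.4:
  ## mean observed ~ 2 * 42320 * 1e-5 * 2.4 = 2.03
  ref$mutation_rates$lof <- rep(1e-5, nrow(ref$mutation_rates))
  risk <- ref$mutation_rates$gene_id
  draws <- unlist(lapply(1:8, function(s) {
    gen_denovo_cohort(ref, 42320, risk_genes = risk, lof_inflation = 2.4,
                      seed = s)$counts$lof
  }))
  expect_equal(mean(draws), 2 * 42320 * 1e-5 * 2.4, tolerance = 0.06)

  ## null cohort: LoF O/E ~ 1
  cn <- gen_denovo_cohort(ref, 42320, seed = 9)
  rec <- prioritization_records(cn$counts, ref$mutation_rates, 42320)
  expect_equal(cohort_oe(rec, "lof")$oe, 1, tolerance = 0.1)

  expect_error(gen_denovo_cohort(ref, 1000, lof_inflation = 0.5),
               "lof_inflation")
  tr <- gen_denovo_cohort(ref, 1000, risk_genes = risk[1:3],
                          lof_inflation = 2, seed = 1)$truth
  expect_equal(nrow(tr), 3)                         # truth completeness
  expect_true(all(tr$gene_id %in% ref$genes$gene_id))
})

test_that("CRE prediction sources honour dropout and jitter settings", {
  ref <- gen_reference(5, chrom_length = 1e6, n_genes = 8)
  ## dropout 0, jitter 0, no decoys: all sources identical
  p0 <- gen_cre_predictions(ref, n_sources = 3, n_true_elements = 10,
                            jitter_sd = 0, dropout = 0, seed = 2,
                            decoy_rate = 0)
  expect_identical(p0$sources[[1]], p0$sources[[2]])
  expect_identical(p0$sources[[2]], p0$sources[[3]])
  expect_equal(nrow(p0$sources[[1]]), 10)
  ## dropout 1: empty tables
  p1 <- gen_cre_predictions(ref, n_sources = 2, n_true_elements = 10,
                            dropout = 1, seed = 2, decoy_rate = 0)
  expect_true(all(vapply(p1$sources, nrow, integer(1)) == 0))
  ## truth rows reference real genes and valid intervals
  expect_true(all(p0$truth$gene_id %in% ref$genes$gene_id))
  expect_true(all(p0$truth$start < p0$truth$end))
})

test_that("MPRA counts are null at multiplier 1 and scale with multiplier", {
  tiles <- make_tiles(60, 10)
  planted <- setNames(4, tiles$tile_id[1])
  sim <- gen_mpra_counts(tiles, barcodes_per_tile = 80,
                         planted_active = planted, n_replicates = 3,
                         seed = 13)
  act <- activity_test(sim$counts, sim$association, tiles = tiles)
  expect_equal(act$log2fc[act$tile_id == tiles$tile_id[1]], log2(4),
               tolerance = 0.2)
  null_lfc <- act$log2fc[act$tile_id != tiles$tile_id[1] & act$tested]
  expect_lt(max(abs(null_lfc)), 0.75)
  expect_equal(mean(null_lfc), 0, tolerance = 0.05)
  ## scrambled tiles cannot be planted; multipliers must be positive
  expect_error(gen_mpra_counts(tiles, planted_active = setNames(2, "s0001")),
               "scrambled")
  expect_error(gen_mpra_counts(tiles,
                               planted_active = setNames(-1,
                                                         tiles$tile_id[1])),
               "> 0")
  expect_equal(sim$truth,
               data.frame(tile_id = tiles$tile_id[1], multiplier = 4,
                          stringsAsFactors = FALSE))
})

test_that("screen generator matches its multiplexed design parameters", {
  scr <- make_screen(n_cells = 3000, n_guides = 50, seed = 8,
                     effects = setNames(1.6, "g1"))
  qa <- qc_and_assign(scr$gene_matrix, scr$guide_matrix, scr$covariates)
  ## mean distinct gRNAs per cell near the requested rate
  expect_equal(qa$summary$mean_guides_per_cell, 10.3, tolerance = 0.05)
  ## ~5% of cells pushed over the mito threshold
  expect_equal(mean(scr$covariates$mito_frac > 0.20), 0.05,
               tolerance = 0.5)
  ## NTC guides present at the requested fraction, with no target
  expect_equal(mean(scr$guide_meta$ntc), 0.1, tolerance = 0.1)
  expect_true(all(is.na(scr$guide_meta$target_gene[scr$guide_meta$ntc])))
  ## planted truth recorded exactly once
  expect_equal(scr$truth,
               data.frame(grna_id = "g1", gene_id = "tg1",
                          fold_change = 1.6, stringsAsFactors = FALSE))
  expect_error(gen_screen(scr$targets, planted_effects = setNames(1.5,
                                                                  "nope")),
               "absent")
  expect_error(gen_screen(scr$targets, ntc_fraction = 1), "ntc_fraction")
})
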