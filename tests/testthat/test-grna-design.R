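# Protospacer enumeration, hard filters, distance annotation, iterative
# selection, spacer finalization and Sa-PAM compatibility.

test_that("enumeration equals the brute-force regex-scan oracle", {
  set.seed(3)
  for (rep in 1:4) {
    s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
    got <- enumerate_and_filter(c(chrA = s))
    orc <- oracle_protospacers(s)
    key <- function(d) sort(paste(d$protospacer, d$strand, d$start))
    expect_equal(key(got), key(orc))
  }
})

test_that("a lone AGG PAM yields exactly one plus-strand candidate", {
  s <- paste0(strrep("AT", 10), "AGG", strrep("AT", 3), "A")
  expect_equal(nchar(s), 30)
  got <- enumerate_and_filter(c(toy = s))
  expect_equal(nrow(got), 1)
  expect_equal(got$strand, "+")
  expect_equal(c(got$start, got$end), c(0, 20))
  expect_equal(got$pam, "AGG")
  ## sub-23 bp regions yield no candidates
  expect_equal(nrow(enumerate_and_filter(c(tiny = substr(s, 1, 22)))), 0)
})

test_that("polyT, GC and duplicate filters flag candidates", {
  mk <- function(spacer) paste0("CAT", spacer, "TGGAGTCAT")
  g1 <- enumerate_and_filter(c(c1 = mk("GCGCGTTTTGCGCGCATGCG")))
  cand <- g1[g1$start == 3, ]
  expect_true(cand$flag_polyT)
  expect_false(cand$pass)
  ## low-GC spacer excluded at bounds [0.25, 0.75]
  g2 <- enumerate_and_filter(c(c1 = mk("ATATATATATATATATATAC")))
  cand2 <- g2[g2$start == 3, ]
  expect_lt(cand2$gc, 0.25)
  expect_true(cand2$flag_gc)
  ## duplicated spacer across the sequence set is flagged
  dup_seq <- paste0("CAT", "GCGATCGATCGTACGTAGCA", "TGG",
                    "AAA", "GCGATCGATCGTACGTAGCA", "TGG")
  g3 <- enumerate_and_filter(c(c1 = dup_seq))
  sp <- g3[g3$protospacer == "GCGATCGATCGTACGTAGCA", ]
  expect_true(all(sp$flag_duplicate))
})

test_that("distance annotation follows the sign and center conventions", {
  cand <- data.frame(protospacer = strrep("A", 20), chrom = "chr1",
                     strand = "+", start = 1290, end = 1310, pass = TRUE)
  ## enhancer: midpoint 1300 vs center of [1000, 1500) = 1250
  e <- annotate_distances(cand, "enhancer",
                          ccre_interval = data.frame(start = 1000,
                                                     end = 1500))
  expect_equal(e$distance, 50)
  ## promoter, + strand, site 150 bp upstream of the CAGE mode
  cage <- data.frame(pos = 1445:1455, count = c(1:5, 9, 5:1))
  p <- annotate_distances(cand, "promoter", tss = 1450, strand = "+",
                          cage_profile = cage)
  expect_equal(p$distance, -150)
  ## symmetric CAGE peak: mode equals the annotated TSS
  expect_equal(annotate_distances(cand, "promoter", tss = 1450,
                                  strand = "-",
                                  cage_profile = cage)$distance, 150)
  expect_warning(f <- annotate_distances(cand, "promoter", tss = 1450,
                                         strand = "+",
                                         cage_profile = cage[0, ]),
                 "CAGE")
  expect_equal(f$distance, -150)
})

test_that("iterative selection assigns rounds and is order-invariant", {
  cand <- data.frame(
    protospacer = strrep("A", 20), chrom = "chr1",
    strand = c("+", "+", "-", "+", "+", "-"),
    start = c(100, 200, 300, 400, 500, 600),
    end = c(120, 220, 320, 420, 520, 620),
    score = c(0.90, 0.85, 0.70, 0.65, 0.50, 0.90),
    distance = c(50, 80, 50, 150, 50, 180),
    pass = TRUE, stringsAsFactors = FALSE
  )
  rt <- data.frame(min_score = c(0.8, 0.6), max_distance = c(100, 200))
  sel <- iterative_select(cand, k = 4, round_thresholds = rt)
  expect_equal(sel$selected$round, c(1, 1, 2, 2))
  expect_equal(sel$selected$start, c(100, 200, 600, 300))
  expect_false(sel$shortfall)
  ## permuting the input never changes the selected set or rounds
  set.seed(5)
  for (rep in 1:5) {
    perm <- cand[sample(nrow(cand)), ]
    sel2 <- iterative_select(perm, k = 4, round_thresholds = rt)
    expect_equal(sel2$selected, sel$selected)
  }
  ## every selected candidate satisfies its round's thresholds
  with(sel$selected, {
    expect_true(all(score >= rt$min_score[round]))
    expect_true(all(abs(distance) <= rt$max_distance[round]))
  })
  ## shortfall when fewer than k candidates exist
  s1 <- iterative_select(cand[1, ], k = 4, round_thresholds = rt)
  expect_equal(nrow(s1$selected), 1)
  expect_true(s1$shortfall)
  expect_error(iterative_select(cand, k = 4, round_thresholds =
    data.frame(min_score = c(0.5, 0.8), max_distance = c(100, 200))),
    "monoton")
})

test_that("final spacers are 20 nt starting with G (PAM-proximal 19 kept)", {
  expect_equal(finalize_spacer("GTGCATGCATGCATGCATGC"),
               "GTGCATGCATGCATGCATGC")
  expect_equal(finalize_spacer("ATGCATGCATGCATGCATGC"),
               "GTGCATGCATGCATGCATGC")
  out <- finalize_spacer(c("CCCCCCCCCCCCCCCCCCCC", "AAAAAAAAAAAAAAAAAAAA"))
  expect_true(all(nchar(out) == 20))
  expect_true(all(substr(out, 1, 1) == "G"))
})

test_that("Sa-PAM compatibility matches NNGRRT with truncation warning", {
  expect_true(sa_pam_compatible("TGGAGT"))
  expect_false(sa_pam_compatible("TGGACC"))
  expect_true(sa_pam_compatible("AAGGGT"))
  expect_false(sa_pam_compatible("AATGGT"))   # pos 3 not G
  expect_warning(r <- sa_pam_compatible(c("TGGAGT", NA)), "truncated")
  expect_equal(r, c(TRUE, FALSE))
})

test_that("NGG site density on random sequence is near 2/16 per position", {
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE),
             collapse = "")
  got <- enumerate_and_filter(c(chr = s))
  expected <- 2 * (nchar(s) - 22) / 16
  expect_equal(nrow(got) / expected, 1, tolerance = 0.1)
})

test_that("NTC spacers are absent from the genome", {
  set.seed(2)
  seqs <- c(chr = paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                        collapse = ""))
  ntc <- generate_ntc_spacers(seqs, 5, seed = 3)
  expect_equal(length(ntc), 5)
  for (sp in ntc) {
    expect_false(grepl(sp, seqs[[1]], fixed = TRUE))
    expect_false(grepl(sp, revcomp(seqs[[1]]), fixed = TRUE))
  }
})

test_that("the default on-target score is deterministic and in [0, 1]", {
  sp <- c("GCGCATGCATGCATGCATGC", "AAAAAAAAAAAAAAAAAAAA",
          "GGGGGGGGGGGGGGGGGGGG")
  s <- default_on_target_score(sp)
  expect_true(all(s >= 0 & s <= 1))
  expect_identical(s, default_on_target_score(sp))
  expect_gt(s[1], s[2])   # balanced GC beats an A homopolymer
})
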