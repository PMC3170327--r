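# quality masking, pileup construction, consensus, coverage statistics

test_that("quality_mask applies both strict thresholds", {
  filt <- quality_filter()
  # base Q25, window mean 18: kept
  q <- c(rep(17, 5), 25, rep(17, 5))  # mean = (25 + 170)/11 = 17.7 > 15
  expect_true(quality_mask(rep("A", 11), q, filt)[6])
  # base exactly Q20: dropped (strict >)
  q2 <- c(rep(30, 5), 20, rep(30, 5))
  expect_false(quality_mask(rep("A", 11), q2, filt)[6])
  # window mean exactly 15: dropped (strict >)
  q3 <- c(rep(13.5, 5), 30, rep(13.5, 5))  # (30 + 135)/11 = 15
  expect_equal(mean(q3), 15)
  expect_false(quality_mask(rep("A", 11), q3, filt)[6])
  # window truncated at read ends
  q4 <- c(30, 30, 30, 30, rep(2, 18))
  m <- quality_mask(rep("A", 22), q4, filt)
  expect_true(m[1])   # truncated window = positions 1..6, mean 124/6 > 15
  expect_false(m[10]) # full window fails both thresholds
  expect_error(quality_mask("ACGT", c(30, 30), filt), "length")
  # absent qualities fail the filter
  expect_false(any(quality_mask(rep("A", 5), rep(NA, 5), filt)))
})

test_that("pileup counts kept non-N bases; depth conserves kept bases", {
  ref <- list(ref = strrep("A", 20))
  alns <- list(
    list(read_id = "r1", ref = "ref", ref_pos = 1:10, base = "AAAAAAAAAA",
         qual = 40L),
    list(read_id = "r2", ref = "ref", ref_pos = 1:10, base = "AAAANAAAAA",
         qual = 40L),
    list(read_id = "r3", ref = "ref", ref_pos = 3:12, base = "CCCCCCCCCC",
         qual = 40L),
    # r4 fails the base-quality filter everywhere
    list(read_id = "r4", ref = "ref", ref_pos = 1:10, base = "AAAAAAAAAA",
         qual = 10L))
  aln <- make_aln_set(alns, ref)
  pil <- build_pileup(aln, NULL, "ref")
  expect_equal(unname(pil$counts[1, "A"]), 2L)  # r1 + r2
  expect_equal(pil$counts[5, ], c(A = 1L, C = 1L, G = 0L, T = 0L)) # N excluded
  expect_equal(unname(pil$counts[3, "C"]), 1L)
  expect_equal(sum(pil$counts), 10L + 9L + 10L)  # conservation, r4 masked
  expect_equal(pileup_depth(pil)[13:20], rep(0L, 8))
})

test_that("deleted positions contribute nothing", {
  ref <- list(ref = strrep("G", 10))
  # read spans 1..10 but position 5 is deleted
  a <- list(read_id = "d1", ref = "ref", ref_pos = c(1:4, 6:10),
            base = "GGGGGGGGG", qual = 40L, n_del = 1L)
  pil <- build_pileup(make_aln_set(list(a), ref), NULL, "ref")
  expect_equal(pileup_depth(pil)[5], 0L)
  expect_equal(pileup_depth(pil)[4], 1L)
})

test_that("consensus: majority wins, ties prefer reference, depth 0 gives N", {
  ref <- list(ref = "GGGGG")
  alns <- list(
    list(read_id = "r1", ref = "ref", ref_pos = 1:2, base = "AA", qual = 40L),
    list(read_id = "r2", ref = "ref", ref_pos = 1:2, base = "AG", qual = 40L),
    list(read_id = "r3", ref = "ref", ref_pos = 1:2, base = "AG", qual = 40L),
    list(read_id = "r4", ref = "ref", ref_pos = 1:2, base = "CA", qual = 40L))
  pil <- build_pileup(make_aln_set(alns, ref), NULL, "ref")
  cons <- call_consensus(pil, ref$ref)
  expect_identical(cons$bases[1], "A")  # 3 A vs 1 C, majority (not ref G)
  expect_identical(cons$bases[2], "G")  # 2 A vs 2 G tie -> reference base
  expect_identical(cons$bases[3], "N")  # depth 0
  # tie with reference not among maxima -> fixed order A<C<G<T
  pil2 <- pil
  pil2$counts[4, ] <- c(A = 0L, C = 2L, G = 0L, T = 2L)
  cons2 <- call_consensus(pil2, "AAAAA")
  expect_identical(cons2$bases[4], "C")
})

test_that("consensus is idempotent on reads matching the consensus", {
  run <- run_small_pipeline(seed = 3)
  cons1 <- run$consensus
  # rebuild a pileup whose reads are error-free copies of the consensus
  covered <- which(cons1$bases != "N")
  a <- list(read_id = "c1", ref = "ref", ref_pos = covered,
            base = cons1$bases[covered], qual = 40L)
  refstr <- paste(run$sg$genome, collapse = "")
  pil2 <- build_pileup(make_aln_set(list(a), list(ref = refstr)),
                       NULL, "ref")
  cons2 <- call_consensus(pil2, refstr)
  expect_identical(cons2$bases[covered], cons1$bases[covered])
})

test_that("raising either quality threshold never increases depth", {
  run <- run_small_pipeline(n_reads = 150, seed = 9)
  base_depth <- pileup_depth(run$pileup)
  for (filt in list(quality_filter(min_base_quality = 28),
                    quality_filter(min_neighborhood_mean = 29))) {
    d <- pileup_depth(build_pileup(run$sim$alignments, NULL, "ref", filt))
    expect_true(all(d <= base_depth))
  }
})

test_that("coverage_stats computes the published summary columns", {
  ref <- list(ref = strrep("A", 30))
  gene <- gene_table("g1", "ref", 1, 12, "+", "core")[1, ]
  # depths: 6 positions at 6x, 6 at 0
  alns <- lapply(1:6, function(i)
    list(read_id = paste0("r", i), ref = "ref", ref_pos = 1:6,
         base = "AAAAAA", qual = 40L))
  pil <- build_pileup(make_aln_set(alns, ref), NULL, "ref")
  cs <- coverage_stats(pil, gene)
  expect_equal(cs$pct_ge_5x, 50)
  expect_equal(cs$pct_ge_1x, 50)
  expect_equal(cs$avg_depth, 3.0)
  # depths [5,5,4]: >=5 is inclusive
  gene2 <- gene_table("g2", "ref", 1, 3, "+", "core")[1, ]
  pil$counts[1:3, ] <- 0L
  pil$counts[1:3, "A"] <- c(5L, 5L, 4L)
  cs2 <- coverage_stats(pil, gene2)
  expect_equal(cs2$pct_ge_5x, 200 / 3, tolerance = 1e-10)
  expect_equal(cs2$avg_depth, 14 / 3, tolerance = 1e-10)
})
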