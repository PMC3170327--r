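# per-gene site/polymorphism counting, ratio conventions, windows,
# reference-based variant, and the oracle-equivalence property

# helper: uniform-depth pileup with chosen variant columns on a tiny genome
tiny_case <- function(genome, gene, reads) {
  refstr <- paste(genome, collapse = "")
  aln <- make_aln_set(reads, list(ref = refstr))
  pil <- build_pileup(aln, NULL, "ref")
  cons <- call_consensus(pil, refstr)
  list(pileup = pil, consensus = cons, aln = aln, refstr = refstr)
}

test_that("gene_site_counts sums codon enumerations over >=5x positions", {
  genome <- strsplit("TTTGGGATG", "")[[1]]
  gene <- gene_table("g", "ref", 1, 9, "+", "core")[1, ]
  reads <- lapply(1:5, function(i)
    list(read_id = paste0("r", i), ref = "ref", ref_pos = 1:9,
         base = "TTTGGGATG", qual = 40L))
  tc <- tiny_case(genome, gene, reads)
  sc <- gene_site_counts(tc$consensus, gene, tc$pileup, min_depth = 5)
  expect_equal(sc$ns_sites, 8 / 3 + 2 + 3)
  expect_equal(sc$s_sites, 1 / 3 + 1 + 0)
  expect_equal(sc$positions_counted, 9L)
  expect_equal(sc$ns_sites + sc$s_sites, sc$positions_counted)
  # all depths below 5 -> nothing counted
  sc4 <- gene_site_counts(tc$consensus, gene, tc$pileup, min_depth = 6)
  expect_equal(sc4$positions_counted, 0L)
  expect_true(is.nan(gene_dnds(sc4, list(ns_polys = 0L, s_polys = 0L))$dnds))
})

test_that("polymorphism counting distinguishes per-read and per-allele", {
  genome <- strsplit("GGGGGG", "")[[1]]
  gene <- gene_table("g", "ref", 1, 6, "+", "core")[1, ]
  # 6 reads; at position 3 two reads carry A (GGA is synonymous)
  reads <- lapply(1:6, function(i)
    list(read_id = paste0("r", i), ref = "ref", ref_pos = 1:6,
         base = if (i <= 2) "GGAGGG" else "GGGGGG", qual = 40L))
  tc <- tiny_case(genome, gene, reads)
  pr <- gene_polymorphism_counts(tc$pileup, tc$consensus, gene,
                                 multiplicity = "per-read")
  pa <- gene_polymorphism_counts(tc$pileup, tc$consensus, gene,
                                 multiplicity = "per-allele")
  expect_equal(pr$s_polys, 2L)
  expect_equal(pa$s_polys, 1L)
  expect_equal(pr$ns_polys, 0L)
  # depth 4 positions contribute nothing
  reads4 <- reads[1:4]
  tc4 <- tiny_case(genome, gene, reads4)
  p4 <- gene_polymorphism_counts(tc4$pileup, tc4$consensus, gene)
  expect_equal(p4$s_polys + p4$ns_polys, 0L)
})

test_that("gene_dnds honors the NaN/Inf conventions and dn_minus_ds", {
  sites <- list(ns_sites = 2, s_sites = 1, positions_counted = 3L)
  r <- gene_dnds(sites, list(ns_polys = 1L, s_polys = 1L))
  expect_equal(r$dN, 0.5); expect_equal(r$dS, 1.0)
  expect_equal(r$dnds, 0.5); expect_equal(r$dn_minus_ds, -0.5)
  expect_true(is.nan(gene_dnds(sites, list(ns_polys = 0L,
                                           s_polys = 0L))$dnds))
  expect_identical(gene_dnds(sites, list(ns_polys = 3L, s_polys = 0L))$dnds,
                   Inf)
  # dnds = 1 implies dn_minus_ds = 0
  r1 <- gene_dnds(sites, list(ns_polys = 2L, s_polys = 1L))
  expect_equal(r1$dnds, 1)
  expect_equal(r1$dn_minus_ds, 0)
  # ratio invariance under site rescaling
  s2 <- list(ns_sites = 2 * 7, s_sites = 1 * 7, positions_counted = 3L)
  expect_equal(gene_dnds(s2, list(ns_polys = 1L, s_polys = 1L))$dnds, 0.5)
})

test_that("minus-strand genes are handled by reverse complement", {
  # gene on the minus strand: genome CATCCCAAA -> gene TTTGGGATG
  genome <- strsplit("CATCCCAAA", "")[[1]]
  gene <- gene_table("gm", "ref", 1, 9, "-", "core")[1, ]
  reads <- lapply(1:5, function(i)
    list(read_id = paste0("r", i), ref = "ref", ref_pos = 1:9,
         base = "CATCCCAAA", qual = 40L))
  tc <- tiny_case(genome, gene, reads)
  sc <- gene_site_counts(tc$consensus, gene, tc$pileup)
  expect_equal(sc$ns_sites, 8 / 3 + 2 + 3)
  expect_equal(sc$s_sites, 1 / 3 + 1 + 0)
  # a genome-strand C variant at genome pos 4 = gene TTTGG[C->G]... :
  # gene position 6 alt G on GGG codon third base? complement: genome pos 4
  # is gene position 6 (codon 2 pos 3); genome alt A -> gene alt T: GGT syn
  reads2 <- c(reads, lapply(6:7, function(i)
    list(read_id = paste0("v", i), ref = "ref", ref_pos = 1:9,
         base = "CATACCAAA", qual = 40L)))
  tc2 <- tiny_case(genome, gene, reads2)
  p2 <- gene_polymorphism_counts(tc2$pileup, tc2$consensus, gene)
  expect_equal(p2$s_polys, 2L)  # GGG -> GGT synonymous, two reads
  expect_equal(p2$ns_polys, 0L)
})

test_that("codons containing N are skipped entirely", {
  genome <- strsplit("TTTGGGATG", "")[[1]]
  gene <- gene_table("g", "ref", 1, 9, "+", "core")[1, ]
  # no read covers position 5 -> consensus N there -> codon 2 skipped
  reads <- lapply(1:5, function(i)
    list(read_id = paste0("r", i), ref = "ref", ref_pos = c(1:4, 6:9),
         base = "TTTGGATG", qual = 40L, n_del = 1L))
  tc <- tiny_case(genome, gene, reads)
  expect_identical(tc$consensus$bases[5], "N")
  sc <- gene_site_counts(tc$consensus, gene, tc$pileup)
  expect_equal(sc$positions_counted, 6L)
  expect_equal(sc$ns_sites, 8 / 3 + 3)
})

test_that("reference-based dN/dS uses the reference as context and baseline", {
  genome <- strsplit("GGGGGGGGG", "")[[1]]
  gene <- gene_table("g", "ref", 1, 9, "+", "core")[1, ]
  # consensus differs from reference at position 3 (A fixed in population)
  reads <- lapply(1:6, function(i)
    list(read_id = paste0("r", i), ref = "ref", ref_pos = 1:9,
         base = "GGAGGGGGG", qual = 40L))
  tc <- tiny_case(genome, gene, reads)
  expect_identical(tc$consensus$bases[3], "A")
  vs_cons <- gene_selection_stats(tc$consensus, tc$pileup, gene)
  vs_ref <- dnds_vs_reference(tc$refstr, tc$pileup, gene)
  expect_true(is.nan(vs_cons$dnds))        # no read differs from consensus
  expect_equal(vs_ref$s_polys, 6L)         # every read differs from reference
  expect_equal(vs_ref$dnds, 0)
  # reads identical to reference -> NaN
  reads0 <- lapply(1:6, function(i)
    list(read_id = paste0("r", i), ref = "ref", ref_pos = 1:9,
         base = "GGGGGGGGG", qual = 40L))
  tc0 <- tiny_case(genome, gene, reads0)
  expect_true(is.nan(dnds_vs_reference(tc0$refstr, tc0$pileup, gene)$dnds))
})

test_that("sliding windows: layout, codon alignment, gene equivalence", {
  run <- run_small_pipeline(n_genes = 2, gene_length = 450, n_reads = 900,
                            seed = 5)
  g <- run$sg$genes[1, ]
  w <- sliding_window_dnds(run$consensus, run$pileup, g)
  full <- w[!w$truncated, ]
  expect_equal(nrow(full), 6L)  # offsets 0,48,...,240
  expect_equal(full$win_start - g$start, c(0L, 48L, 96L, 144L, 192L, 240L))
  expect_true(all((full$win_end - full$win_start + 1L) == 201L))
  expect_equal(sum(w$truncated), 1L)
  expect_true(all((w$win_start - g$start) %% 3 == 0))
  # a gene exactly one window long gives the whole-gene value
  g201 <- g; g201$end <- g201$start + 201L - 1L
  gene201 <- gene_table("w1", "ref", g201$start, g201$end, "+", "core")[1, ]
  w1 <- sliding_window_dnds(run$consensus, run$pileup, gene201)
  expect_equal(nrow(w1), 1L)
  whole <- gene_selection_stats(run$consensus, run$pileup, gene201)
  expect_equal(w1$dnds, whole$dnds)
  # minus-strand windows stay inside the gene and advance from its 3' end
  gm <- run$sg$genes[2, ]
  wm <- sliding_window_dnds(run$consensus, run$pileup, gm)
  expect_true(all(wm$win_start >= gm$start & wm$win_end <= gm$end))
  expect_equal(wm$win_end[1], gm$end)
})

test_that("windows tiling a gene exactly reproduce whole-gene counts", {
  run <- run_small_pipeline(n_genes = 2, gene_length = 450, n_reads = 900,
                            seed = 8)
  for (i in 1:2) {
    g <- run$sg$genes[i, ]
    w <- sliding_window_dnds(run$consensus, run$pileup, g,
                             window_length = 90, step = 90)
    expect_equal(nrow(w), 5L)
    expect_false(any(w$truncated))
    whole <- gene_selection_stats(run$consensus, run$pileup, g)
    expect_equal(sum(w$ns_polys), whole$ns_polys)
    expect_equal(sum(w$s_polys), whole$s_polys)
  }
})

test_that("internal stop codons in the backbone are skipped and flagged", {
  genome <- strsplit("ATGTAAGGGCCC", "")[[1]]  # codon 2 is a stop
  gene <- gene_table("g", "ref", 1, 12, "+", "core")[1, ]
  reads <- lapply(1:5, function(i)
    list(read_id = paste0("r", i), ref = "ref", ref_pos = 1:12,
         base = "ATGTAAGGGCCC", qual = 40L))
  tc <- tiny_case(genome, gene, reads)
  sc <- gene_site_counts(tc$consensus, gene, tc$pileup)
  expect_true(sc$internal_stop)
  expect_equal(sc$positions_counted, 9L)  # stop codon's 3 positions skipped
})

test_that("random small instances match the brute-force oracle exactly", {
  for (s in 1:6) {
    sg <- synthetic_genome(n_genes = sample(2:4, 1), gene_length = 150,
                           intergenic = 30, seed = 100 + s)
    cfg <- sim_config(n_reads = 250, read_length_mean = 60,
                      substitution_rate = 5e-3, quality_mean = 24,
                      quality_sd = 6, seed = 200 + s)
    sim <- simulate_reads(sg$genome, cfg)
    pil <- build_pileup(sim$alignments, NULL, "ref")
    cons <- call_consensus(pil, sg$genome)
    ocounts <- oracle_pileup(sim$alignments, length(sg$genome))
    expect_identical(unname(pil$counts), unname(ocounts))
    ocons <- oracle_consensus(ocounts, sg$genome)
    expect_identical(cons$bases, ocons)
    for (i in seq_len(nrow(sg$genes))) {
      g <- sg$genes[i, ]
      mine <- gene_selection_stats(cons, pil, g)
      orac <- oracle_gene(ocounts, ocons, g)
      expect_equal(mine$ns_sites, orac$ns_sites)
      expect_equal(mine$s_sites, orac$s_sites)
      expect_equal(mine$ns_polys, orac$ns_polys)
      expect_equal(mine$s_polys, orac$s_polys)
      expect_equal(mine$dnds, orac$dnds)
    }
  }
})
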