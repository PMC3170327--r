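# read simulator, population simulator, placement randomization

test_that("error-free simulation yields exact substrings and NaN dN/dS", {
  sg <- synthetic_genome(n_genes = 3, gene_length = 300, seed = 41)
  cfg <- sim_config(n_reads = 400, read_length_mean = 80,
                    substitution_rate = 0, seed = 42)
  sim <- simulate_reads(sg$genome, cfg)
  s <- sim$alignments$summary
  expect_true(all(s$n_matches == s$n_aligned_columns))
  pil <- build_pileup(sim$alignments, NULL, "ref")
  cons <- call_consensus(pil, sg$genome)
  st <- genes_selection_table(cons, pil, sg$genes)
  expect_true(all(is.nan(st$dnds)))
})

test_that("simulation is byte-identical under a fixed seed", {
  sg <- synthetic_genome(n_genes = 2, gene_length = 300, seed = 43)
  cfg <- sim_config(n_reads = 120, read_length_mean = 70,
                    substitution_rate = 2e-3, homopolymer_rate = 2e-3,
                    seed = 44)
  s1 <- simulate_reads(sg$genome, cfg)
  s2 <- simulate_reads(sg$genome, cfg)
  expect_identical(s1$alignments$summary, s2$alignments$summary)
  expect_identical(s1$alignments$bases, s2$alignments$bases)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_sim_fastq(s1, f1); write_sim_fastq(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # population generator and randomizer are seeded too
  omega <- stats::setNames(c(0.2, 1), sg$genes$locus)
  pc <- pop_config(n_haplotypes = 3, per_gene_omega = omega, seed = 45)
  p1 <- simulate_population(sg$genome, sg$genes, pc)
  p2 <- simulate_population(sg$genome, sg$genes, pc)
  expect_identical(p1$truth, p2$truth)
  r1 <- randomize_placements(rep(50L, 100), 2000L, sg$genes, 5, seed = 46)
  r2 <- randomize_placements(rep(50L, 100), 2000L, sg$genes, 5, seed = 46)
  expect_identical(r1$per_rep, r2$per_rep)
})

test_that("realized substitution rate converges (law of large numbers)", {
  sg <- synthetic_genome(n_genes = 10, gene_length = 900, intergenic = 50,
                         seed = 47)
  rate <- 0.01
  cfg <- sim_config(n_reads = 16000L, read_length_mean = 250,
                    substitution_rate = rate, seed = 48)
  sim <- simulate_reads(sg$genome, cfg)
  b <- sim$alignments$bases
  g <- sg$genome
  realized <- mean(b$base != g[b$ref_pos])
  expect_equal(nrow(b), 4e6)
  expect_lt(abs(realized - rate) / rate, 0.01)
})

test_that("homopolymer indels are recorded and read lengths adjust", {
  genome <- strsplit(paste0(strrep("A", 8), strrep("CGT", 40),
                            strrep("T", 8), strrep("GAC", 40)), "")[[1]]
  cfg <- sim_config(n_reads = 300, read_length_mean = 60,
                    substitution_rate = 0, homopolymer_rate = 0.3,
                    seed = 49)
  sim <- simulate_reads(genome, cfg)
  s <- sim$alignments$summary
  n_ins_total <- nrow(sim$insertions)
  n_del_total <- sum(s$n_aligned_columns - s$n_read_aligned)
  expect_gt(n_ins_total + n_del_total, 0)
  expect_true(all(s$read_length == s$n_read_aligned))
  # with no substitutions every reference-aligned base matches
  m_rows <- tabulate(sim$alignments$bases$read_uid, nbins = nrow(s))
  expect_equal(s$n_matches, m_rows)
  expect_true(all(s$n_aligned_columns >= s$n_matches))
})

test_that("population simulator respects per-gene omega in its truth table", {
  sg <- synthetic_genome(n_genes = 4, gene_length = 600, seed = 51)
  omega <- stats::setNames(c(0, 0.5, 1, 2), sg$genes$locus)
  pop <- simulate_population(sg$genome, sg$genes,
                             pop_config(n_haplotypes = 8,
                                        per_gene_omega = omega,
                                        target_divergence = 0.06,
                                        seed = 52))
  tt <- pop$truth
  # omega = 0 gene carries only synonymous mutations
  g0 <- sg$genes$locus[1]
  expect_true(all(tt$class[tt$locus == g0] == "S"))
  # all truth mutations are genuine substitutions of the reference
  expect_true(all(tt$ref != tt$alt))
  expect_true(all(pop$reference[tt$pos] == tt$ref))
  for (h in seq_along(pop$haplotypes)) {
    sel <- tt[tt$haplotype == h, ]
    expect_identical(pop$haplotypes[[h]][sel$pos], sel$alt)
    # untouched positions equal the reference
    untouched <- setdiff(seq_along(pop$reference), sel$pos)
    expect_identical(pop$haplotypes[[h]][untouched],
                     pop$reference[untouched])
  }
  expect_error(simulate_population(
    sg$genome, sg$genes,
    pop_config(per_gene_omega = c(nope = 1), seed = 1)), "unknown locus")
})

test_that("two haplotypes differing at one synonymous site give dnds 0", {
  sg <- synthetic_genome(n_genes = 1, gene_length = 300, intergenic = 60,
                         seed = 53)
  g <- sg$genes[1, ]
  # force exactly one synonymous mutation into haplotype 2 by hand
  view_pos <- g$start:g$end
  hap2 <- sg$genome
  # find a fourfold-degenerate third position on the plus-strand gene
  found <- FALSE
  for (ci in seq_len((g$end - g$start + 1) %/% 3)) {
    at <- g$start + 3 * ci - 1
    codon <- paste(sg$genome[(at - 2):at], collapse = "")
    if (!grepl("[^ACGT]", codon)) {
      for (alt in setdiff(c("A", "C", "G", "T"), sg$genome[at])) {
        if (classify_substitution(codon, 3, alt) == "S") {
          hap2[at] <- alt; found <- TRUE; break
        }
      }
    }
    if (found) break
  }
  expect_true(found)
  pop <- list(haplotypes = list(sg$genome, hap2), reference = sg$genome,
              genes = sg$genes,
              truth = data.frame())
  class(pop) <- "sim_population"
  cfg <- sim_config(n_reads = 200, read_length_mean = 60,
                    substitution_rate = 0, seed = 54)
  sim <- simulate_population_reads(pop, cfg)
  pil <- build_pileup(sim$alignments, NULL, "ref")
  cons <- call_consensus(pil, sg$genome)
  st <- gene_selection_stats(cons, pil, g)
  expect_gt(st$s_polys, 0)
  expect_equal(st$ns_polys, 0L)
  expect_equal(st$dnds, 0)
})

test_that("randomized placements conserve bases and have flat expectation", {
  sg <- synthetic_genome(n_genes = 6, gene_length = 300, intergenic = 100,
                         seed = 55)
  G <- length(sg$genome)
  lens <- rep(100L, 400)
  rp <- randomize_placements(lens, G, sg$genes, n_reps = 100, seed = 56)
  expect_equal(ncol(rp$per_rep), 100L)
  expect_equal(rp$genome_mean, sum(lens) / G)
  # exact analytic per-position expectation under uniform start placement
  L <- 100L; n <- length(lens)
  exp_depth <- function(p)
    n * (pmin(p, G - L + 1L) - pmax(1L, p - L + 1L) + 1L) / (G - L + 1L)
  for (i in seq_len(nrow(sg$genes))) {
    reps <- rp$per_rep[i, ]
    analytic <- mean(exp_depth(sg$genes$start[i]:sg$genes$end[i]))
    ci <- mean(reps) + c(-1, 1) * 4 * sd(reps) / sqrt(length(reps))
    expect_gt(analytic, ci[1])
    expect_lt(analytic, ci[2])
  }
  # within one replicate, total placed bases bound the depth integral
  depth_integral <- sum(rp$per_rep[, 1] *
                          (sg$genes$end - sg$genes$start + 1))
  expect_lte(depth_integral, sum(lens))
})
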