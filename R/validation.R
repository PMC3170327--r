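# Desk-scale validation experiments. Each function builds a fully synthetic
# stated world, runs the estimator end to end, and returns both the
# estimate and the independent expectation (analytic, or read off the
# simulation truth table), so callers can assert calibration. The
# acceptance tests and scripts/acceptance.R both run these.

# fractional NS/S site totals of a gene on a bare sequence (no depth
# restriction): used to turn truth-table mutation counts into rates
.full_gene_sites <- function(seq_chars_vec, gene) {
  zero <- structure(list(reference_id = "ref",
                         counts = matrix(0L, nrow = length(seq_chars_vec),
                                         ncol = 4L,
                                         dimnames = list(NULL, DNA_BASES))),
                    class = "pileup")
  gene_site_counts(seq_chars_vec, gene, zero, min_depth = 0L)
}

#' Neutral-null calibration experiment
#'
#' Simulates substitution-only sequencing errors on a synthetic genome and
#' compares each gene's estimated dN/dS with its analytic expectation
#' under neutral uniform errors. At position j with filtered depth d_j,
#' errors arrive as independent events at the substitution rate, a
#' fraction `nNS_j/3` of them non-synonymous; NS and S totals are thus
#' independent Poissons with means `lamN = r * sum(d_j nNS_j/3)` and
#' `lamS = r * sum(d_j nS_j/3)`, and
#' `E[dN/dS] ~ (lamN/ns_sites)/(lamS/s_sites) * (1 + 1/lamS)`
#' (second-order expansion of `E[1/S]`). The mean estimated ratio over
#' genes should sit inside the Monte-Carlo confidence band of the mean
#' expectation.
#'
#' @param n_genes,gene_length Synthetic genome layout (default approx
#'   100 kb: 110 genes of 801 bp with 100 bp spacers).
#' @param depth Target mean read depth (default 40).
#' @param substitution_rate Per-base error rate (default 2e-3).
#' @param read_length Read length in bp (default 250).
#' @param seed Integer seed.
#' @return List: `stats` (per-gene table), `expected` (per-gene analytic
#'   expectation), `mean_dnds`, `mean_expected`, `mc_halfwidth` (1.96 se
#'   of the mean paired difference), `n_used`.
#' @export
neutral_null_experiment <- function(n_genes = 110L, gene_length = 801L,
                                    depth = 40, substitution_rate = 2e-3,
                                    read_length = 250, seed = 1L) {
  sg <- synthetic_genome(n_genes = n_genes, gene_length = gene_length,
                         intergenic = 100L, seed = seed)
  G <- length(sg$genome)
  cfg <- sim_config(n_reads = round(G * depth / read_length),
                    read_length_mean = read_length,
                    substitution_rate = substitution_rate,
                    seed = seed + 1L)
  sim <- simulate_reads(sg$genome, cfg)
  pil <- build_pileup(sim$alignments, NULL, "ref")
  cons <- call_consensus(pil, sg$genome)
  st <- genes_selection_table(cons, pil, sg$genes)
  tb <- .codon_tables()
  expected <- vapply(seq_len(nrow(sg$genes)), function(i) {
    sc <- .gene_scan(cons, pil, sg$genes[i, ], min_depth = 5L)
    el <- which(sc$eligible)
    if (!length(el)) return(NA_real_)
    idx <- cbind(match(sc$codon_str[sc$codon_of[el]], rownames(tb$site_ns)),
                 sc$pos_in_codon[el])
    d <- sc$view$depth[el]
    lamN <- substitution_rate * sum(d * tb$site_ns[idx])
    lamS <- substitution_rate * sum(d * tb$site_s[idx])
    ns_sites <- sum(tb$site_ns[idx]); s_sites <- sum(tb$site_s[idx])
    (lamN / ns_sites) / (lamS / s_sites) * (1 + 1 / lamS)
  }, 1.0)
  ok <- is.finite(st$dnds) & is.finite(expected)
  diffs <- st$dnds[ok] - expected[ok]
  list(stats = st, expected = expected,
       mean_dnds = mean(st$dnds[ok]), mean_expected = mean(expected[ok]),
       mc_halfwidth = 1.96 * stats::sd(diffs) / sqrt(length(diffs)),
       n_used = sum(ok))
}

#' Parameter-recovery experiment for the population simulator
#'
#' Simulates a clonal population whose genes carry known omega values,
#' sequences it without read errors (isolating the estimator from the
#' error model, which [neutral_null_experiment()] covers), and compares
#' estimated dN/dS with the truth.
#'
#' @param omega_levels True omega values (default 0.1, 0.3, 1.0, 2.0).
#' @param genes_per_level Genes per omega level (default 20).
#' @param gene_length Gene length in bp (default 600).
#' @param depth Mean read depth (default 30).
#' @param n_haplotypes Population haplotypes (default 6).
#' @param divergence Synonymous divergence per haplotype (default 0.05).
#' @param seed Integer seed.
#' @return List: `truth_omega`, `estimate` (per gene), `spearman`,
#'   `level_means` (`data.frame`: omega, mean_estimate, n),
#'   `truth_realized` (per-gene ratio recomputed from the truth mutation
#'   table), `n_finite`.
#' @export
parameter_recovery_experiment <- function(omega_levels = c(0.1, 0.3, 1, 2),
                                          genes_per_level = 20L,
                                          gene_length = 600L, depth = 30,
                                          n_haplotypes = 6L,
                                          divergence = 0.05, seed = 1L) {
  n_genes <- length(omega_levels) * genes_per_level
  sg <- synthetic_genome(n_genes = n_genes, gene_length = gene_length,
                         intergenic = 60L, seed = seed)
  omega <- stats::setNames(rep(omega_levels, each = genes_per_level),
                           sg$genes$locus)
  pop <- simulate_population(sg$genome, sg$genes,
                             pop_config(n_haplotypes = n_haplotypes,
                                        per_gene_omega = omega,
                                        target_divergence = divergence,
                                        seed = seed + 1L))
  G <- length(sg$genome)
  cfg <- sim_config(n_reads = round(G * depth / 250), read_length_mean = 250,
                    substitution_rate = 0, seed = seed + 2L)
  sim <- simulate_population_reads(pop, cfg)
  pil <- build_pileup(sim$alignments, NULL, "ref")
  cons <- call_consensus(pil, sg$genome)
  st <- genes_selection_table(cons, pil, sg$genes)
  est <- st$dnds
  truth_realized <- vapply(seq_len(nrow(sg$genes)), function(i) {
    g <- sg$genes[i, ]
    tt <- pop$truth[!is.na(pop$truth$locus) & pop$truth$locus == g$locus, ]
    sc <- .full_gene_sites(sg$genome, g)
    nN <- sum(tt$class == "NS"); nS <- sum(tt$class == "S")
    if (nN == 0 && nS == 0) NaN
    else if (nS == 0) Inf
    else (nN / sc$ns_sites) / (nS / sc$s_sites)
  }, 1.0)
  ok <- is.finite(est)
  sp <- stats::cor(omega[ok], est[ok], method = "spearman")
  lm_rows <- lapply(omega_levels, function(w) {
    sel <- omega == w & ok
    data.frame(omega = w, mean_estimate = mean(est[sel]), n = sum(sel))
  })
  list(truth_omega = omega, estimate = est, spearman = sp,
       level_means = do.call(rbind, lm_rows),
       truth_realized = truth_realized, n_finite = sum(ok))
}

#' Purifying-dominance experiment
#'
#' Draws per-gene omega from a log-normal chosen so about 95 percent of
#' genes are under purifying selection (omega below 1), simulates the
#' population, and compares the estimated fraction of genes with
#' dN/dS below 1 against the same fraction computed from the simulation
#' truth table. Genes with an undefined ratio (NaN) are excluded on both
#' sides; Inf counts as above 1.
#'
#' @param n_genes Number of genes (default 60).
#' @param meanlog,sdlog Log-normal omega parameters (default
#'   `log(0.25)`, 0.85: about 95 percent of mass below 1).
#' @inheritParams parameter_recovery_experiment
#' @return List: `frac_below_1_est`, `frac_below_1_truth`, `omega`,
#'   `estimate`, `truth_realized`.
#' @export
purifying_experiment <- function(n_genes = 60L, meanlog = log(0.25),
                                 sdlog = 0.85, gene_length = 600L,
                                 depth = 30, n_haplotypes = 6L,
                                 divergence = 0.05, seed = 1L) {
  sg <- synthetic_genome(n_genes = n_genes, gene_length = gene_length,
                         intergenic = 60L, seed = seed)
  omega <- with_seed(seed + 10L,
                     stats::setNames(stats::rlnorm(n_genes, meanlog, sdlog),
                                     sg$genes$locus))
  pop <- simulate_population(sg$genome, sg$genes,
                             pop_config(n_haplotypes = n_haplotypes,
                                        per_gene_omega = omega,
                                        target_divergence = divergence,
                                        seed = seed + 1L))
  G <- length(sg$genome)
  cfg <- sim_config(n_reads = round(G * depth / 250), read_length_mean = 250,
                    substitution_rate = 0, seed = seed + 2L)
  sim <- simulate_population_reads(pop, cfg)
  pil <- build_pileup(sim$alignments, NULL, "ref")
  cons <- call_consensus(pil, sg$genome)
  est <- genes_selection_table(cons, pil, sg$genes)$dnds
  truth_realized <- vapply(seq_len(nrow(sg$genes)), function(i) {
    g <- sg$genes[i, ]
    tt <- pop$truth[!is.na(pop$truth$locus) & pop$truth$locus == g$locus, ]
    sc <- .full_gene_sites(sg$genome, g)
    nN <- sum(tt$class == "NS"); nS <- sum(tt$class == "S")
    if (nN == 0 && nS == 0) NaN
    else if (nS == 0) Inf
    else (nN / sc$ns_sites) / (nS / sc$s_sites)
  }, 1.0)
  def_e <- !is.nan(est) & !is.na(est)
  def_t <- !is.nan(truth_realized)
  list(frac_below_1_est = mean(est[def_e] < 1),
       frac_below_1_truth = mean(truth_realized[def_t] < 1),
       omega = omega, estimate = est, truth_realized = truth_realized)
}

#' Coverage-randomization null experiment
#'
#' Simulates neutral reads, computes per-gene dN - dS, re-places the same
#' reads uniformly 100 times for the null coverage distribution, and
#' regresses dN - dS on the null mean coverage. Under the null there is
#' no relationship: the slope should sit within two standard errors of
#' zero.
#'
#' @param n_genes Number of genes (default 40).
#' @param gene_length Gene length (default 600).
#' @param depth Mean depth (default 30).
#' @param substitution_rate Error rate (default 2e-3).
#' @param n_reps Randomization replicates (default 100).
#' @param seed Integer seed.
#' @return List: `fit` (a [regress()] result), `null_mean_depth`,
#'   `dn_minus_ds`, `slope_over_se`.
#' @export
coverage_null_experiment <- function(n_genes = 40L, gene_length = 600L,
                                     depth = 30, substitution_rate = 2e-3,
                                     n_reps = 100L, seed = 1L) {
  sg <- synthetic_genome(n_genes = n_genes, gene_length = gene_length,
                         intergenic = 100L, seed = seed)
  G <- length(sg$genome)
  cfg <- sim_config(n_reads = round(G * depth / 250), read_length_mean = 250,
                    substitution_rate = substitution_rate, seed = seed + 1L)
  sim <- simulate_reads(sg$genome, cfg)
  pil <- build_pileup(sim$alignments, NULL, "ref")
  cons <- call_consensus(pil, sg$genome)
  st <- genes_selection_table(cons, pil, sg$genes)
  null <- randomize_placements(sim$alignments$summary$read_length, G,
                               sg$genes, n_reps = n_reps, seed = seed + 2L)
  fit <- regress(null$mean_depth, st$dn_minus_ds)
  list(fit = fit, null_mean_depth = null$mean_depth,
       dn_minus_ds = st$dn_minus_ds,
       slope_over_se = abs(fit$slope) / fit$slope_se)
}
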