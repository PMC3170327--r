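# In-code fixture builders shared across test files.

# Minimal alignment_set from per-alignment descriptions. Each alignment is
# a list: read_id, ref, ref_pos (int vector of aligned columns), base,
# qual (recycled), read_length, n_ins/n_del gap columns, strand.
make_aln_set <- function(alns, references) {
  srows <- list(); brows <- list()
  for (i in seq_along(alns)) {
    a <- alns[[i]]
    nb <- length(a$ref_pos)
    qual <- rep_len(a$qual %||% 40L, nb)
    base <- a$base
    if (length(base) == 1L && nchar(base[1L]) > 1L)
      base <- strsplit(base, "", fixed = TRUE)[[1L]]
    base <- rep_len(base, nb)
    n_ins <- a$n_ins %||% 0L
    n_del <- a$n_del %||% 0L
    refseq <- references[[a$ref]]
    refchars <- strsplit(refseq, "", fixed = TRUE)[[1L]]
    n_matches <- a$n_matches %||% sum(base == refchars[a$ref_pos])
    srows[[i]] <- data.frame(
      read_uid = i, read_id = a$read_id, reference_id = a$ref,
      strand = a$strand %||% "+", ref_start = min(a$ref_pos),
      n_matches = n_matches,
      n_aligned_columns = nb + n_ins + n_del,
      n_read_aligned = nb + n_ins,
      read_length = a$read_length %||% (nb + n_ins))
    brows[[i]] <- data.frame(read_uid = i, ref_pos = a$ref_pos,
                             read_pos = seq_len(nb), base = base,
                             qual = qual)
  }
  alignment_set(do.call(rbind, srows), do.call(rbind, brows),
                references = vapply(references, nchar, 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random alignment_set against two references, for property tests
random_aln_set <- function(n_reads, seed) {
  set.seed(seed)
  refs <- list(
    refA = paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = ""),
    refB = paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = ""))
  alns <- list()
  for (i in seq_len(n_reads)) {
    for (r in names(refs)[runif(2) < 0.8]) {
      L <- sample(40:80, 1)
      start <- sample(1:(400 - L), 1)
      refchars <- strsplit(refs[[r]], "", fixed = TRUE)[[1L]]
      base <- refchars[start:(start + L - 1)]
      nmut <- rbinom(1, L, 0.1)
      if (nmut > 0) {
        at <- sample(L, nmut)
        base[at] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
      }
      unaligned <- sample(0:20, 1)
      alns[[length(alns) + 1L]] <- list(
        read_id = sprintf("r%04d", i), ref = r,
        ref_pos = start:(start + L - 1), base = base, qual = 40L,
        read_length = L + unaligned)
    }
  }
  if (!length(alns)) return(NULL)
  make_aln_set(alns, refs)
}

# small pipeline run: simulate neutral reads on a synthetic genome and
# return everything downstream tests need
run_small_pipeline <- function(n_genes = 4, gene_length = 300,
                               n_reads = 600, read_len = 80,
                               sub_rate = 3e-3, seed = 1) {
  sg <- synthetic_genome(n_genes = n_genes, gene_length = gene_length,
                         intergenic = 50, seed = seed)
  cfg <- sim_config(n_reads = n_reads, read_length_mean = read_len,
                    substitution_rate = sub_rate, seed = seed + 100)
  sim <- simulate_reads(sg$genome, cfg)
  pil <- build_pileup(sim$alignments, NULL, "ref")
  cons <- call_consensus(pil, sg$genome)
  list(sg = sg, sim = sim, pileup = pil, consensus = cons)
}
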