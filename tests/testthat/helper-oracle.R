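# Independent brute-force recomputation of the per-gene statistics,
# written deliberately as plain nested loops over reads, positions and
# codons, classifying amino-acid changes directly through
# Biostrings::GENETIC_CODE. It shares no code path with the package
# internals beyond the alignment_set accessors.

oracle_translate <- function(codon) Biostrings::GENETIC_CODE[[codon]]

oracle_mask <- function(quals, min_q = 20, w = 11, min_mean = 15) {
  n <- length(quals)
  keep <- logical(n)
  h <- (w - 1) / 2
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    keep[i] <- !is.na(quals[i]) && quals[i] > min_q &&
      mean(quals[lo:hi]) > min_mean
  }
  keep
}

# pileup by explicit per-read loops
oracle_pileup <- function(aln, ref_len, min_q = 20, w = 11, min_mean = 15) {
  counts <- matrix(0L, nrow = ref_len, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (uid in aln$summary$read_uid) {
    b <- as.data.frame(aln$bases[aln$bases$read_uid == uid])
    b <- b[order(b$read_pos), ]
    keep <- oracle_mask(b$qual, min_q, w, min_mean)
    for (k in seq_len(nrow(b))) {
      bb <- b$base[k]
      if (keep[k] && bb %in% c("A", "C", "G", "T"))
        counts[b$ref_pos[k], bb] <- counts[b$ref_pos[k], bb] + 1L
    }
  }
  counts
}

oracle_consensus <- function(counts, refchars) {
  n <- nrow(counts)
  out <- character(n)
  for (i in seq_len(n)) {
    if (sum(counts[i, ]) == 0) { out[i] <- "N"; next }
    mx <- max(counts[i, ])
    winners <- colnames(counts)[counts[i, ] == mx]
    out[i] <- if (refchars[i] %in% winners) refchars[i] else winners[1]
  }
  out
}

oracle_comp <- function(x) c(A = "T", C = "G", G = "C", T = "A", N = "N")[x]

# site + polymorphism counts + ratio for one gene, per-read multiplicity
oracle_gene <- function(counts, cons, gene, min_depth = 5) {
  pos <- gene$start:gene$end
  bases <- cons[pos]
  cmat <- counts[pos, , drop = FALSE]
  if (gene$strand == "-") {
    pos <- rev(pos)
    bases <- unname(oracle_comp(rev(bases)))
    cmat <- cmat[rev(seq_len(nrow(cmat))), , drop = FALSE]
    cmat <- cmat[, c("T", "G", "C", "A")]
    colnames(cmat) <- c("A", "C", "G", "T")
  }
  depth <- rowSums(cmat)
  ncod <- length(bases) %/% 3
  ns_sites <- 0; s_sites <- 0; np <- 0L; sp <- 0L; counted <- 0L
  for (ci in seq_len(ncod)) {
    at <- (3 * ci - 2):(3 * ci)
    codon <- paste(bases[at], collapse = "")
    if (grepl("[^ACGT]", codon)) next
    if (oracle_translate(codon) == "*") next
    for (j in 1:3) {
      p <- at[j]
      if (depth[p] < min_depth) next
      counted <- counted + 1L
      for (alt in setdiff(c("A", "C", "G", "T"), bases[p])) {
        mut <- strsplit(codon, "")[[1]]
        mut[j] <- alt
        syn <- oracle_translate(paste(mut, collapse = "")) ==
          oracle_translate(codon)
        if (syn) s_sites <- s_sites + 1 / 3 else ns_sites <- ns_sites + 1 / 3
        nreads <- unname(cmat[p, alt])
        if (nreads > 0) {
          if (syn) sp <- sp + nreads else np <- np + nreads
        }
      }
    }
  }
  dN <- np / ns_sites; dS <- sp / s_sites
  dnds <- if (np == 0 && sp == 0) NaN else if (sp == 0) Inf else dN / dS
  list(ns_sites = ns_sites, s_sites = s_sites, ns_polys = np, s_polys = sp,
       positions_counted = counted, dN = dN, dS = dS, dnds = dnds)
}
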