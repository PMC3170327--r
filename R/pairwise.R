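# NG86-style pairwise pN/pS between two codon-aligned sequences, used for
# (a) per-read comparisons against the consensus, averaged per gene, and
# (b) homolog comparisons between two genomes. This is a deliberate
# surrogate for PAML's yn00: proportions without multiple-hit correction
# (an optional Jukes-Cantor flag is provided), sites averaged over the two
# sequences, multi-hit codons resolved by averaging over all shortest
# mutational pathways that avoid stop codons.

# NS/S difference counts for one codon pair, averaged over pathways
.codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(ns = 0, s = 0))
  a1 <- strsplit(c1, "", fixed = TRUE)[[1L]]
  a2 <- strsplit(c2, "", fixed = TRUE)[[1L]]
  dpos <- which(a1 != a2)
  perm <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perm(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  paths <- perm(dpos)
  tally <- function(order, allow_stop) {
    cur <- a1
    ns <- 0; s <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- a2[p]
      nxt_cd <- paste(nxt, collapse = "")
      if (!allow_stop && .is_stop(nxt_cd) && !identical(nxt, a2))
        return(NULL)
      cls <- .mutation_class(paste(cur, collapse = ""), p, a2[p])
      if (cls == "NS") ns <- ns + 1 else s <- s + 1
      cur <- nxt
    }
    c(ns = ns, s = s)
  }
  res <- Filter(Negate(is.null), lapply(paths, tally, allow_stop = FALSE))
  if (!length(res)) res <- lapply(paths, tally, allow_stop = TRUE)
  m <- do.call(rbind, res)
  colMeans(m)
}

#' NG86 pairwise pN/pS between two codon-aligned sequences
#'
#' Sites are the average of the two sequences' fractional site counts over
#' the compared codons; differences are classified per codon, averaging
#' over all shortest mutational pathways for codons differing at 2-3
#' positions (pathways through intermediate stop codons excluded when any
#' stop-free pathway exists). Codon columns containing `N`, a gap
#' character, or a stop codon in either sequence are skipped. The ratio
#' follows the `NaN` (no differences) / `Inf` (only non-synonymous
#' differences) conventions.
#'
#' @param seq_a,seq_b Equal-length, codon-aligned nucleotide strings (gaps
#'   as `-`).
#' @param jc_correction Apply the Jukes-Cantor multiple-hit correction to
#'   the per-site proportions before forming the ratio (default `FALSE`).
#' @return List: `dn`, `ds`, `ratio`, `nd`, `sd`, `ns_sites`, `s_sites`,
#'   `codons_compared`.
#' @export
pairwise_dnds <- function(seq_a, seq_b, jc_correction = FALSE) {
  a <- seq_chars(seq_a); b <- seq_chars(seq_b)
  if (length(a) != length(b)) stop("sequences differ in length")
  if (length(a) %% 3L != 0L) stop("sequences are not codon-aligned")
  ncod <- length(a) %/% 3L
  nd <- 0; sd <- 0; nsit <- 0; ssit <- 0; used <- 0L
  for (i in seq_len(ncod)) {
    ca <- paste(a[(3L * i - 2L):(3L * i)], collapse = "")
    cb <- paste(b[(3L * i - 2L):(3L * i)], collapse = "")
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    if (.is_stop(ca) || .is_stop(cb)) next
    used <- used + 1L
    sa <- codon_site_counts(ca); sb <- codon_site_counts(cb)
    nsit <- nsit + (sa[["ns_sites"]] + sb[["ns_sites"]]) / 2
    ssit <- ssit + (sa[["s_sites"]] + sb[["s_sites"]]) / 2
    d <- .codon_pair_diffs(ca, cb)
    nd <- nd + d[["ns"]]; sd <- sd + d[["s"]]
  }
  if (used == 0L)
    return(list(dn = NA_real_, ds = NA_real_, ratio = NaN, nd = 0, sd = 0,
                ns_sites = 0, s_sites = 0, codons_compared = 0L))
  pn <- nd / nsit; ps <- sd / ssit
  if (jc_correction) {
    jc <- function(p) if (p < 0.75) -3 / 4 * log1p(-4 * p / 3) else NaN
    pn <- jc(pn); ps <- jc(ps)
  }
  ratio <- if (nd == 0 && sd == 0) NaN else if (sd == 0) Inf else pn / ps
  list(dn = pn, ds = ps, ratio = ratio, nd = nd, sd = sd,
       ns_sites = nsit, s_sites = ssit, codons_compared = used)
}

#' Mean per-read pairwise dN/dS for one gene
#'
#' Each read overlapping the gene is compared with the consensus over the
#' codons in which the read contributes at least one kept base (consensus
#' bases fill the rest of those codons — reads are unlinked, so the
#' consensus supplies context). Per-read ratios of 0/0 (`NaN`, read
#' identical to the consensus) and x/0 (`Inf`, only non-synonymous
#' differences) are excluded from the mean, and the exclusion counts are
#' reported.
#'
#' @param aln_set An [alignment_set()].
#' @param consensus A `consensus_seq` from [call_consensus()].
#' @param gene One row of a [gene_table()].
#' @param assignments Optional [recruit()] output restricting reads.
#' @param filter A [quality_filter()].
#' @return List: `mean_ratio` (`NA` when no finite per-read ratio exists),
#'   `n_reads`, `n_finite`, `n_nan`, `n_inf`, `per_read` (`data.frame`).
#' @export
gene_mean_pairwise <- function(aln_set, consensus, gene, assignments = NULL,
                               filter = quality_filter()) {
  stopifnot(inherits(aln_set, "alignment_set"),
            inherits(consensus, "consensus_seq"))
  s <- aln_set$summary
  uids <- s$read_uid[s$reference_id == consensus$reference_id]
  if (!is.null(assignments)) {
    ok <- assignments$read_id[assignments$assigned_reference ==
                                consensus$reference_id]
    uids <- intersect(uids, s$read_uid[s$read_id %in% ok])
  }
  b <- aln_set$bases[aln_set$bases$read_uid %in% uids &
                       aln_set$bases$ref_pos >= gene$start &
                       aln_set$bases$ref_pos <= gene$end]
  ratios <- numeric(0); ids <- character(0)
  if (nrow(b)) {
    b <- b[.bases_keep(b, filter) & b$base %in% DNA_BASES]
  }
  if (nrow(b)) {
    gpos <- gene$start:gene$end
    cons_gene <- consensus$bases[gpos]
    minus <- gene$strand == "-"
    if (minus) cons_gene <- complement_chars(rev(cons_gene))
    glen <- length(cons_gene)
    by_read <- split(b, b$read_uid)
    for (rb in by_read) {
      off <- rb$ref_pos - gene$start + 1L
      if (minus) off <- glen - off + 1L
      read_gene <- cons_gene
      read_gene[off] <- if (minus) complement_chars(rb$base) else rb$base
      cod <- unique((off - 1L) %/% 3L)
      keep_pos <- as.vector(outer(1:3, cod * 3L, `+`))
      pr <- pairwise_dnds(cons_gene[keep_pos], read_gene[keep_pos])
      ratios <- c(ratios, pr$ratio)
      ids <- c(ids, s$read_id[match(rb$read_uid[1L], s$read_uid)])
    }
  }
  fin <- is.finite(ratios)
  list(mean_ratio = if (any(fin)) mean(ratios[fin]) else NA_real_,
       n_reads = length(ratios), n_finite = sum(fin),
       n_nan = sum(is.nan(ratios)),
       n_inf = sum(is.infinite(ratios)),
       per_read = data.frame(read_id = ids, ratio = ratios))
}

#' dN/dS between homologous coding sequences of two genomes
#'
#' Applies [pairwise_dnds()] to each pair of pre-aligned homolog CDSs.
#' Pairs absent from either set are reported with marker `"nh"` (no
#' homolog); pairs with no differences with `"np"` (no polymorphisms).
#'
#' @param cds_a,cds_b Named character vectors (or `DNAStringSet`) of
#'   codon-aligned CDS sequences; names pair the homologs via `pairs`.
#' @param pairs `data.frame` with columns `a` and `b` naming homologs.
#' @param jc_correction Passed to [pairwise_dnds()].
#' @return `data.frame`: `a`, `b`, `dn`, `ds`, `ratio`, `marker` (`""`,
#'   `"nh"` or `"np"`).
#' @export
homolog_dnds <- function(cds_a, cds_b, pairs, jc_correction = FALSE) {
  if (inherits(cds_a, "DNAStringSet")) cds_a <- as.character(cds_a)
  if (inherits(cds_b, "DNAStringSet")) cds_b <- as.character(cds_b)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    an <- pairs$a[i]; bn <- pairs$b[i]
    if (is.na(bn) || !bn %in% names(cds_b) || !an %in% names(cds_a))
      return(data.frame(a = an, b = bn %||% NA_character_, dn = NA_real_,
                        ds = NA_real_, ratio = NA_real_, marker = "nh"))
    r <- pairwise_dnds(cds_a[[an]], cds_b[[bn]], jc_correction)
    data.frame(a = an, b = bn, dn = r$dn, ds = r$ds, ratio = r$ratio,
               marker = if (r$nd == 0 && r$sd == 0) "np" else "")
  })
  do.call(rbind, rows)
}
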