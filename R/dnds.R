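# Per-gene and sliding-window dN/dS (strictly speaking pN/pS: polymorphism
# counts over site counts) from a filtered pileup and a backbone sequence.
# The backbone is normally the majority-rule consensus; passing the
# reference genome instead gives the "dN/dS vs reference" variant.
#
# Counting scheme:
#   * sites are fractional (each codon totals 3), summed position-by-position
#     over gene positions with depth >= min_depth whose codon is N-free and
#     not a stop; site and polymorphism counts are restricted to the same
#     positions so numerator and denominator are matched
#   * a polymorphism is a kept read base differing from the backbone base;
#     per-read mode counts every such read base, per-allele mode counts each
#     distinct variant base once
#   * no multiple-substitution correction is applied (within-population
#     divergence is far too low for it to matter)

# shared scaffolding: positions eligible for counting, codon decomposition
.gene_scan <- function(backbone, pileup, gene, min_depth = 5L) {
  bb <- if (inherits(backbone, "consensus_seq")) backbone$bases
  else seq_chars(backbone)
  if (length(bb) != nrow(pileup$counts))
    stop("backbone length does not match the pileup")
  v <- .gene_view(bb, pileup, gene)
  glen <- length(v$bases)
  ncod <- glen %/% 3L
  codon_of <- rep(seq_len(ncod), each = 3L)
  pos_in_codon <- rep(1:3, times = ncod)
  codon_str <- vapply(seq_len(ncod), function(i)
    paste(v$bases[(3L * i - 2L):(3L * i)], collapse = ""), "")
  codon_clean <- !grepl("[^ACGT]", codon_str)
  codon_stop <- codon_clean & .is_stop(codon_str)
  usable_codon <- codon_clean & !codon_stop
  eligible <- v$depth >= min_depth & usable_codon[codon_of]
  list(view = v, codon_of = codon_of, pos_in_codon = pos_in_codon,
       codon_str = codon_str, eligible = eligible,
       internal_stop = any(codon_stop[-ncod]))
}

#' Non-synonymous and synonymous site counts for one gene
#'
#' Sums the fractional per-position site contributions of the backbone
#' codons over all gene positions with pileup depth at least `min_depth`
#' whose codon is free of `N` (and is not a stop codon — mid-gene backbone
#' stops are skipped and flagged).
#'
#' @param backbone A `consensus_seq` (or reference sequence) spanning the
#'   reference.
#' @param gene One row of a [gene_table()].
#' @param pileup Matching [build_pileup()] result.
#' @param min_depth Minimum filtered depth (default 5).
#' @return List: `ns_sites`, `s_sites`, `positions_counted`,
#'   `internal_stop`.
#' @export
gene_site_counts <- function(backbone, gene, pileup, min_depth = 5L) {
  sc <- .gene_scan(backbone, pileup, gene, min_depth)
  tb <- .codon_tables()
  el <- which(sc$eligible)
  if (!length(el))
    return(list(ns_sites = 0, s_sites = 0, positions_counted = 0L,
                internal_stop = sc$internal_stop))
  idx <- cbind(match(sc$codon_str[sc$codon_of[el]], rownames(tb$site_ns)),
               sc$pos_in_codon[el])
  list(ns_sites = sum(tb$site_ns[idx]), s_sites = sum(tb$site_s[idx]),
       positions_counted = length(el), internal_stop = sc$internal_stop)
}

#' Non-synonymous and synonymous polymorphism counts for one gene
#'
#' At each eligible position (same eligibility as [gene_site_counts()]),
#' every kept read base differing from the backbone base is classified by
#' substituting it into the backbone codon.
#'
#' @inheritParams gene_site_counts
#' @param multiplicity `"per-read"` (each differing read base counts once;
#'   default) or `"per-allele"` (each distinct variant base counts once).
#' @return List: `ns_polys`, `s_polys`.
#' @export
gene_polymorphism_counts <- function(pileup, backbone, gene, min_depth = 5L,
                                     multiplicity = c("per-read",
                                                      "per-allele")) {
  multiplicity <- match.arg(multiplicity)
  sc <- .gene_scan(backbone, pileup, gene, min_depth)
  el <- which(sc$eligible)
  ns <- 0L; s <- 0L
  if (length(el)) {
    counts <- sc$view$counts[el, , drop = FALSE]
    bb <- sc$view$bases[el]
    rows <- integer(0); alts <- character(0); nn <- integer(0)
    for (j in seq_along(DNA_BASES)) {
      alt <- DNA_BASES[j]
      hit <- which(counts[, j] > 0L & bb != alt)
      if (length(hit)) {
        rows <- c(rows, hit); alts <- c(alts, rep(alt, length(hit)))
        nn <- c(nn, counts[hit, j])
      }
    }
    if (length(rows)) {
      cls <- .mutation_class(sc$codon_str[sc$codon_of[el][rows]],
                             sc$pos_in_codon[el][rows], alts)
      wt <- if (multiplicity == "per-read") nn else rep(1L, length(nn))
      ns <- sum(wt[cls == "NS"]); s <- sum(wt[cls == "S"])
    }
  }
  list(ns_polys = ns, s_polys = s)
}

#' Combine site and polymorphism counts into dN, dS and dN/dS
#'
#' `dN = ns_polys/ns_sites`, `dS = s_polys/s_sites`,
#' `dnds = dN/dS` with the conventions: `NaN` when no polymorphism of
#' either kind was observed (0/0), `Inf` when only non-synonymous
#' polymorphisms were observed. `dn_minus_ds = dN - dS`.
#'
#' @param sites [gene_site_counts()] result.
#' @param polys [gene_polymorphism_counts()] result.
#' @return List: `dN`, `dS`, `dnds`, `dn_minus_ds`, `computable`.
#' @export
gene_dnds <- function(sites, polys) {
  if (sites$positions_counted == 0L)
    return(list(dN = NA_real_, dS = NA_real_, dnds = NaN,
                dn_minus_ds = NA_real_, computable = FALSE))
  dN <- polys$ns_polys / sites$ns_sites
  dS <- polys$s_polys / sites$s_sites
  dnds <- if (polys$ns_polys == 0L && polys$s_polys == 0L) NaN
  else if (polys$s_polys == 0L) Inf
  else dN / dS
  list(dN = dN, dS = dS, dnds = dnds, dn_minus_ds = dN - dS,
       computable = TRUE)
}

#' Full per-gene selection statistics
#'
#' Convenience wrapper running site counting, polymorphism counting, the
#' ratio arithmetic and coverage statistics for one gene.
#'
#' @inheritParams gene_polymorphism_counts
#' @return One-row `data.frame` with `locus`, `dN`, `dS`, `dnds`,
#'   `dn_minus_ds`, `ns_sites`, `s_sites`, `ns_polys`, `s_polys`,
#'   `positions_counted`, `pct_ge_5x`, `pct_ge_1x`, `avg_depth`,
#'   `category`, `internal_stop`.
#' @export
gene_selection_stats <- function(backbone, pileup, gene, min_depth = 5L,
                                 multiplicity = "per-read") {
  sites <- gene_site_counts(backbone, gene, pileup, min_depth)
  polys <- gene_polymorphism_counts(pileup, backbone, gene, min_depth,
                                    multiplicity)
  r <- gene_dnds(sites, polys)
  cov <- coverage_stats(pileup, gene)
  data.frame(locus = gene$locus, dN = r$dN, dS = r$dS, dnds = r$dnds,
             dn_minus_ds = r$dn_minus_ds, ns_sites = sites$ns_sites,
             s_sites = sites$s_sites, ns_polys = polys$ns_polys,
             s_polys = polys$s_polys,
             positions_counted = sites$positions_counted,
             pct_ge_5x = cov$pct_ge_5x, pct_ge_1x = cov$pct_ge_1x,
             avg_depth = cov$avg_depth,
             category = gene$category %||% "core",
             internal_stop = sites$internal_stop)
}

#' Per-gene selection statistics for a whole gene table
#'
#' @inheritParams gene_selection_stats
#' @param genes A [gene_table()].
#' @return `data.frame` with one row per gene (see
#'   [gene_selection_stats()]).
#' @export
genes_selection_table <- function(backbone, pileup, genes, min_depth = 5L,
                                  multiplicity = "per-read") {
  out <- lapply(seq_len(nrow(genes)), function(i)
    gene_selection_stats(backbone, pileup, genes[i, ], min_depth,
                         multiplicity))
  do.call(rbind, out)
}

#' dN/dS against the reference genome instead of the consensus
#'
#' Identical computation with the reference supplying both the codon
#' context and the mismatch baseline.
#'
#' @param reference Reference sequence (string/char vector/`DNAString`).
#' @inheritParams gene_selection_stats
#' @return As [gene_selection_stats()].
#' @export
dnds_vs_reference <- function(reference, pileup, gene, min_depth = 5L,
                              multiplicity = "per-read") {
  gene_selection_stats(seq_chars(reference), pileup, gene, min_depth,
                       multiplicity)
}

#' Sliding-window dN/dS along a gene
#'
#' Windows start at the gene's 5' end and advance by `step` (offsets are
#' floored to codon boundaries when `step` is not a multiple of 3). Full
#' windows are those fitting entirely inside the gene; when they do not
#' reach the gene's 3' end, one truncated terminal window is appended and
#' flagged. Each window is computed exactly like a gene; coordinates are
#' reported on the genome.
#'
#' @inheritParams gene_selection_stats
#' @param window_length Window size in nucleotides, multiple of 3
#'   (default 201).
#' @param step Step in nucleotides (default 48).
#' @return `data.frame`: `locus`, `win_start`, `win_end` (genome
#'   coordinates), `dnds`, `dN`, `dS`, `ns_polys`, `s_polys`,
#'   `truncated`.
#' @export
sliding_window_dnds <- function(backbone, pileup, gene, window_length = 201L,
                                step = 48L, min_depth = 5L,
                                multiplicity = "per-read") {
  window_length <- as.integer(window_length); step <- as.integer(step)
  if (window_length %% 3L != 0L) stop("window_length must be a multiple of 3")
  if (step < 1L) stop("step must be positive")
  glen <- gene$end - gene$start + 1L
  if (glen <= window_length) {
    offsets <- 0L
    truncated <- glen < window_length
  } else {
    offsets <- seq(0L, glen - window_length, by = step)
    offsets <- unique((offsets %/% 3L) * 3L)
    truncated <- rep(FALSE, length(offsets))
    last_end <- offsets[length(offsets)] + window_length
    if (last_end < glen) {
      nxt <- ((offsets[length(offsets)] + step) %/% 3L) * 3L
      if (nxt < glen) {
        offsets <- c(offsets, nxt)
        truncated <- c(truncated, TRUE)
      }
    }
  }
  rows <- lapply(seq_along(offsets), function(k) {
    off <- offsets[k]
    wlen <- min(window_length, glen - off)
    wlen <- (wlen %/% 3L) * 3L
    if (gene$strand == "+") {
      ws <- gene$start + off; we <- ws + wlen - 1L
    } else {
      we <- gene$end - off; ws <- we - wlen + 1L
    }
    wgene <- gene
    wgene$start <- ws; wgene$end <- we
    st <- gene_selection_stats(backbone, pileup, wgene, min_depth,
                               multiplicity)
    data.frame(locus = gene$locus, win_start = ws, win_end = we,
               dnds = st$dnds, dN = st$dN, dS = st$dS,
               ns_polys = st$ns_polys, s_polys = st$s_polys,
               truncated = truncated[k] || wlen < window_length)
  })
  do.call(rbind, rows)
}
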