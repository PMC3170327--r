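# Quality masking, filtered pileups, majority-rule consensus and per-gene
# coverage statistics. Both thresholds of the quality filter are strict
# inequalities: a base survives only if its own Phred score is above
# min_base_quality AND the mean over the centered neighborhood window is
# above min_neighborhood_mean.

#' Quality filter parameters
#'
#' @param min_base_quality Phred threshold for the base itself (strict `>`,
#'   default 20).
#' @param neighborhood_size Odd window length in nucleotides centered on the
#'   base, including the base, truncated at read ends (default 11).
#' @param min_neighborhood_mean Phred threshold for the window mean (strict
#'   `>`, default 15).
#' @return Object of class `quality_filter`.
#' @export
quality_filter <- function(min_base_quality = 20, neighborhood_size = 11,
                           min_neighborhood_mean = 15) {
  neighborhood_size <- as.integer(neighborhood_size)
  if (neighborhood_size < 1L || neighborhood_size %% 2L == 0L)
    stop("neighborhood_size must be odd and >= 1")
  structure(list(min_base_quality = min_base_quality,
                 neighborhood_size = neighborhood_size,
                 min_neighborhood_mean = min_neighborhood_mean),
            class = "quality_filter")
}

# truncated centered rolling mean of an integer vector
.window_mean <- function(q, w) {
  n <- length(q)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, q))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Per-base keep/drop mask from read qualities
#'
#' @param read_bases Character vector of bases (or a single string); only
#'   its length is used, to validate against the qualities.
#' @param read_qualities Integer Phred scores, same length; `NA` fails.
#' @param filter A [quality_filter()].
#' @return Logical vector, `TRUE` where the base is kept.
#' @export
quality_mask <- function(read_bases, read_qualities, filter = quality_filter()) {
  if (length(read_bases) == 1L && nchar(read_bases[1L]) > 1L)
    read_bases <- strsplit(read_bases, "", fixed = TRUE)[[1L]]
  if (length(read_bases) != length(read_qualities))
    stop("bases and qualities differ in length")
  q <- as.numeric(read_qualities)
  if (anyNA(q)) {
    keep <- rep(FALSE, length(q))
    ok <- !is.na(q)
    if (any(ok)) keep[ok] <- quality_mask(read_bases[ok], q[ok], filter)
    return(keep)
  }
  q > filter$min_base_quality &
    .window_mean(q, filter$neighborhood_size) > filter$min_neighborhood_mean
}

# keep flag for every row of an alignment_set bases table, computed per
# alignment in read-storage order (symmetric window, so reference
# orientation is equivalent to read orientation up to end truncation)
.bases_keep <- function(bases, filter) {
  if (nrow(bases) == 0L) return(logical(0))
  b <- data.table::copy(bases)
  b[, row__ := .I]
  data.table::setorder(b, read_uid, read_pos)
  b[, keep__ := {
    q <- qual
    if (anyNA(q)) rep(FALSE, .N)
    else q > filter$min_base_quality &
      .window_mean(q, filter$neighborhood_size) > filter$min_neighborhood_mean
  }, by = read_uid]
  data.table::setorder(b, row__)
  b$keep__
}

#' Build a filtered pileup for one reference
#'
#' Counts kept, non-N read bases per reference position for the reads
#' assigned to `reference_id`. Insertions never enter (they have no
#' reference position) and deletions contribute nothing at the deleted
#' positions.
#'
#' @param aln_set An [alignment_set()] with declared reference lengths.
#' @param assignments Output of [recruit()]; only reads assigned to
#'   `reference_id` contribute. `NULL` uses every alignment to the
#'   reference.
#' @param reference_id Name of the reference to pile.
#' @param filter A [quality_filter()].
#' @return Object of class `pileup`: list with `reference_id` and an
#'   integer `counts` matrix (positions x A,C,G,T).
#' @export
build_pileup <- function(aln_set, assignments = NULL, reference_id = NULL,
                         filter = quality_filter()) {
  stopifnot(inherits(aln_set, "alignment_set"))
  if (is.null(aln_set$references))
    stop("alignment_set lacks reference lengths")
  if (is.null(reference_id)) {
    reference_id <- names(aln_set$references)
    if (length(reference_id) != 1L)
      stop("reference_id required with multiple references")
  }
  L <- aln_set$references[[reference_id]]
  s <- aln_set$summary
  keep_uid <- s$read_uid[s$reference_id == reference_id]
  if (!is.null(assignments)) {
    ok <- assignments$read_id[assignments$assigned_reference == reference_id]
    keep_uid <- intersect(keep_uid, s$read_uid[s$read_id %in% ok])
  }
  b <- aln_set$bases[aln_set$bases$read_uid %in% keep_uid]
  if (nrow(b) && (min(b$ref_pos) < 1L || max(b$ref_pos) > L))
    stop("alignment references positions outside the reference")
  counts <- matrix(0L, nrow = L, ncol = 4L,
                   dimnames = list(NULL, DNA_BASES))
  if (nrow(b)) {
    keep <- .bases_keep(b, filter)
    b <- b[keep & b$base %in% DNA_BASES]
    if (nrow(b)) {
      tab <- b[, .N, by = .(ref_pos, base)]
      counts[cbind(tab$ref_pos, match(tab$base, DNA_BASES))] <- tab$N
    }
  }
  structure(list(reference_id = reference_id, counts = counts),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  d <- rowSums(x$counts)
  cat("pileup on", x$reference_id, "-", nrow(x$counts), "positions, mean depth",
      round(mean(d), 2), "\n")
  invisible(x)
}

#' Per-position depth of a pileup
#' @param pileup A [build_pileup()] result.
#' @return Integer vector of depths.
#' @export
pileup_depth <- function(pileup) rowSums(pileup$counts)

#' Majority-rule consensus from a pileup
#'
#' Positions with zero filtered depth become `N`; otherwise the base with
#' the maximal count wins. Ties prefer the reference base when it is among
#' the maxima, then fall back to the fixed order A < C < G < T. Reference
#' bases are never injected as evidence, only used for tie-breaking.
#'
#' @param pileup A [build_pileup()] result.
#' @param reference Reference sequence (string, `DNAString`, or char
#'   vector) of the same length.
#' @return Object of class `consensus_seq`: list with `reference_id` and
#'   `bases` (character vector over A/C/G/T/N).
#' @export
call_consensus <- function(pileup, reference) {
  rc <- seq_chars(reference)
  counts <- pileup$counts
  if (length(rc) != nrow(counts))
    stop("reference length does not match the pileup")
  depth <- rowSums(counts)
  maxn <- do.call(pmax, as.data.frame(counts))
  ref_idx <- match(rc, DNA_BASES)
  ref_count <- rep(-1L, length(rc))
  has <- !is.na(ref_idx)
  ref_count[has] <- counts[cbind(which(has), ref_idx[has])]
  first_max <- DNA_BASES[max.col(counts, ties.method = "first")]
  bases <- ifelse(depth == 0L, "N",
                  ifelse(ref_count == maxn, rc, first_max))
  structure(list(reference_id = pileup$reference_id, bases = bases),
            class = "consensus_seq")
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat("consensus for", x$reference_id, "-", length(x$bases), "bp,",
      sum(x$bases == "N"), "N positions\n")
  invisible(x)
}

#' @export
as.character.consensus_seq <- function(x, ...) paste(x$bases, collapse = "")

#' Coverage statistics over one gene
#'
#' @param pileup A [build_pileup()] result.
#' @param gene One row of a [gene_table()].
#' @return `data.frame` row: `locus`, `pct_ge_5x`, `pct_ge_1x`,
#'   `avg_depth`.
#' @export
coverage_stats <- function(pileup, gene) {
  if (gene$end < gene$start) stop("zero-length gene")
  if (gene$start < 1L || gene$end > nrow(pileup$counts))
    stop("gene outside the reference")
  d <- rowSums(pileup$counts[gene$start:gene$end, , drop = FALSE])
  data.frame(locus = gene$locus,
             pct_ge_5x = 100 * mean(d >= 5L),
             pct_ge_1x = 100 * mean(d >= 1L),
             avg_depth = mean(d))
}
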