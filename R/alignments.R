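# An alignment_set holds every read placement in two tables:
#   summary - one row per alignment (identity/coverage ingredients)
#   bases   - one row per reference-aligned read base (pileup ingredients),
#             in reference orientation (as SAM stores SEQ/QUAL)
# Insertion read bases carry no reference position and appear only in the
# summary counts; deletion columns likewise count as aligned columns only.

#' Construct an alignment set
#'
#' @param summary `data.frame` with columns `read_uid`, `read_id`,
#'   `reference_id`, `strand`, `ref_start`, `n_matches`, `n_aligned_columns`,
#'   `n_read_aligned`, `read_length`.
#' @param bases `data.frame` with columns `read_uid`, `ref_pos`, `read_pos`,
#'   `base`, `qual` (Phred integer, `NA` when the SAM record had no
#'   qualities).
#' @param references Named integer vector of reference lengths (optional but
#'   required for pileups).
#' @return An object of class `alignment_set`.
#' @export
alignment_set <- function(summary, bases, references = NULL) {
  summary <- data.table::as.data.table(summary)
  bases <- data.table::as.data.table(bases)
  need_s <- c("read_uid", "read_id", "reference_id", "strand", "ref_start",
              "n_matches", "n_aligned_columns", "n_read_aligned",
              "read_length")
  if (!all(need_s %in% names(summary)))
    stop("summary lacks columns: ",
         paste(setdiff(need_s, names(summary)), collapse = ", "))
  need_b <- c("read_uid", "ref_pos", "read_pos", "base", "qual")
  if (!all(need_b %in% names(bases)))
    stop("bases lacks columns: ",
         paste(setdiff(need_b, names(bases)), collapse = ", "))
  if (any(summary$n_matches > summary$n_aligned_columns))
    stop("n_matches exceeds n_aligned_columns")
  if (!is.null(references)) {
    rl <- references[summary$reference_id]
    if (anyNA(rl)) stop("alignment to undeclared reference")
    lim <- rl[match(bases$read_uid, summary$read_uid)]
    if (any(bases$ref_pos < 1L | bases$ref_pos > lim))
      stop("aligned base outside the reference bounds")
  }
  structure(list(summary = summary, bases = bases, references = references),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("alignment_set:", nrow(x$summary), "alignments,",
      length(unique(x$summary$read_id)), "reads,",
      nrow(x$bases), "aligned bases\n")
  invisible(x)
}

#' Read alignments from a SAM file
#'
#' Converts the SAM to BAM with `Rsamtools::asBam()` and expands every
#' mapped record into per-base rows. The reference FASTA is required: match
#' counting (for percent identity) compares each aligned read base with the
#' reference, and reference lengths are validated against the SAM header.
#' Records with quality `"*"` get `NA` qualities, which fail the quality
#' filter downstream.
#'
#' @param sam_path SAM file; the header must declare all references.
#' @param reference FASTA path, `DNAStringSet`, or named character vector of
#'   reference sequences.
#' @return An [alignment_set()].
#' @export
read_sam_alignments <- function(sam_path, reference) {
  refs <- .load_references(reference)
  bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  mapped <- !is.na(b$pos) & bitwAnd(b$flag, 4L) == 0L
  qname <- b$qname[mapped]; flag <- b$flag[mapped]
  rname <- as.character(b$rname)[mapped]; pos <- b$pos[mapped]
  cigar <- b$cigar[mapped]
  seqs <- as.character(b$seq)[mapped]
  quals <- as.character(b$qual)[mapped]
  n <- length(qname)
  if (n == 0L)
    return(alignment_set(
      summary = data.table::data.table(
        read_uid = integer(), read_id = character(),
        reference_id = character(), strand = character(),
        ref_start = integer(), n_matches = integer(),
        n_aligned_columns = integer(), n_read_aligned = integer(),
        read_length = integer()),
      bases = data.table::data.table(
        read_uid = integer(), ref_pos = integer(), read_pos = integer(),
        base = character(), qual = integer()),
      references = vapply(refs, length, 1L)))

  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  op_sum <- function(want) {
    vapply(seq_len(n), function(i) sum(lens[[i]][ops[[i]] %in% want]), 1L)
  }
  n_aligned_columns <- op_sum(c("M", "=", "X", "I", "D"))
  n_read_aligned <- op_sum(c("M", "=", "X", "I"))

  rref <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "=", "X"))
  rqry <- GenomicAlignments::cigarRangesAlongQuerySpace(
    cigar, ops = c("M", "=", "X"))
  uref <- unlist(rref, use.names = FALSE)
  uqry <- unlist(rqry, use.names = FALSE)
  blk_aln <- rep(seq_len(n), S4Vectors::elementNROWS(rref))
  w <- IRanges::width(uref)
  aln_of <- rep(blk_aln, w)
  ref_pos <- sequence(w, from = IRanges::start(uref))
  read_pos <- sequence(IRanges::width(uqry), from = IRanges::start(uqry))

  flat_seq <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]
  off <- cumsum(c(0L, nchar(seqs)))
  base <- toupper(flat_seq[off[aln_of] + read_pos])
  has_q <- quals != "*"
  qual <- rep(NA_integer_, length(base))
  if (any(has_q)) {
    # decode Phred+33 per record to keep offsets aligned with SEQ
    qflat <- rep(NA_integer_, sum(nchar(seqs)))
    for (i in which(has_q))
      qflat[(off[i] + 1L):(off[i] + nchar(seqs[i]))] <-
        as.integer(charToRaw(quals[i])) - 33L
    qual <- qflat[off[aln_of] + read_pos]
  }

  ref_chars <- lapply(refs, function(s) strsplit(as.character(s), "",
                                                 fixed = TRUE)[[1L]])
  ref_of_base <- rname[aln_of]
  match_flag <- logical(length(base))
  for (r in unique(rname)) {
    sel <- ref_of_base == r
    match_flag[sel] <- base[sel] == ref_chars[[r]][ref_pos[sel]]
  }
  n_matches <- tabulate(aln_of[match_flag], nbins = n)

  summary <- data.table::data.table(
    read_uid = seq_len(n), read_id = qname, reference_id = rname,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    ref_start = pos, n_matches = n_matches,
    n_aligned_columns = n_aligned_columns,
    n_read_aligned = n_read_aligned, read_length = nchar(seqs))
  bases <- data.table::data.table(
    read_uid = aln_of, ref_pos = ref_pos, read_pos = read_pos,
    base = base, qual = qual)
  alignment_set(summary, bases,
                references = vapply(ref_chars, length, 1L))
}

.load_references <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (inherits(reference, "DNAStringSet")) {
    out <- as.character(reference)
    names(out) <- sub("\\s.*$", "", names(reference))
    return(out)
  }
  if (is.character(reference) && !is.null(names(reference)))
    return(toupper(reference))
  stop("reference must be a FASTA path, DNAStringSet, or named character")
}
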