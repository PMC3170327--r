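# Plain-text writers mirroring the published supplementary-table layouts.
# Non-finite dN/dS values are emitted as the literal strings "NaN" and
# "Inf".

.fmt_ratio <- function(x) {
  ifelse(is.nan(x), "NaN", ifelse(is.infinite(x), "Inf",
                                  trimws(formatC(x, digits = 6,
                                                 format = "g"))))
}

#' Write read assignments as TSV
#' @param assignments [recruit()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments_tsv <- function(assignments, path) {
  write.table(assignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a per-position pileup as TSV
#' @param pileup [build_pileup()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  d <- data.frame(position = seq_len(nrow(pileup$counts)), pileup$counts,
                  depth = rowSums(pileup$counts))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-position pileup TSV back into a pileup object
#' @param path TSV written by [write_pileup_tsv()].
#' @param reference_id Reference name to attach.
#' @return A `pileup` object.
#' @export
read_pileup_tsv <- function(path, reference_id = "ref") {
  d <- read.table(path, header = TRUE, sep = "\t")
  counts <- as.matrix(d[, DNA_BASES])
  dimnames(counts) <- list(NULL, DNA_BASES)
  structure(list(reference_id = reference_id,
                 counts = matrix(as.integer(counts), ncol = 4L,
                                 dimnames = list(NULL, DNA_BASES))),
            class = "pileup")
}

#' Write a consensus sequence as FASTA
#' @param consensus [call_consensus()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(consensus, path) {
  x <- Biostrings::DNAStringSet(as.character(consensus))
  names(x) <- consensus$reference_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a per-gene selection table as TSV
#'
#' Columns mirror the published per-gene tables: locus, dN, dS, dN/dS,
#' coverage summaries and category, with literal `NaN`/`Inf` strings.
#'
#' @param stats [genes_selection_table()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_stats_tsv <- function(stats, path) {
  out <- data.frame(locus = stats$locus, dN = stats$dN, dS = stats$dS,
                    dnds = .fmt_ratio(stats$dnds),
                    dn_minus_ds = stats$dn_minus_ds,
                    pct_min5x_cov = stats$pct_ge_5x,
                    pct_min1x_cov = stats$pct_ge_1x,
                    avg_read_depth = stats$avg_depth,
                    category = stats$category)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sliding-window statistics as TSV
#' @param windows [sliding_window_dnds()] output (rows may span genes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_tsv <- function(windows, path) {
  out <- data.frame(locus = windows$locus, win_start = windows$win_start,
                    win_end = windows$win_end,
                    dnds = .fmt_ratio(windows$dnds),
                    truncated = windows$truncated)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
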