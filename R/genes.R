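#' Build a validated gene table
#'
#' Genes are coding regions on a reference, held with 1-based inclusive
#' coordinates. Genes whose annotated length is not a multiple of three are
#' trimmed at their 3' end (strand-aware) to a codon boundary and flagged in
#' the `trimmed` column, so downstream codon decomposition always has a
#' defined frame.
#'
#' @param locus Character vector of gene identifiers.
#' @param reference_id Reference sequence name(s).
#' @param start,end 1-based inclusive genome coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param category `"core"` or `"accessory"`.
#' @return A `data.frame` with class `gene_table`.
#' @export
gene_table <- function(locus, reference_id, start, end, strand = "+",
                       category = "core") {
  n <- length(locus)
  g <- data.frame(locus = as.character(locus),
                  reference_id = rep_len(as.character(reference_id), n),
                  start = as.integer(start), end = as.integer(end),
                  strand = rep_len(as.character(strand), n),
                  category = rep_len(as.character(category), n),
                  stringsAsFactors = FALSE)
  if (any(g$start > g$end)) stop("gene with start > end")
  if (!all(g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(g$category %in% c("core", "accessory")))
    stop("category must be 'core' or 'accessory'")
  if (anyDuplicated(g$locus)) stop("duplicate locus identifiers")
  len <- g$end - g$start + 1L
  over <- len %% 3L
  g$trimmed <- over != 0L
  # trim the 3' end in gene orientation
  plus <- g$strand == "+"
  g$end[plus] <- g$end[plus] - over[plus]
  g$start[!plus] <- g$start[!plus] + over[!plus]
  if (any(g$end - g$start + 1L < 3L)) stop("gene shorter than one codon")
  class(g) <- c("gene_table", "data.frame")
  g
}

#' Read gene models from GFF3
#'
#' Imports `CDS` features (falling back to `gene` if no CDS present). The
#' core/accessory label is read from a `category` attribute when present,
#' defaulting to `"core"`. Locus comes from `locus_tag`, `ID` or `Name`,
#' first available.
#'
#' @param path GFF3 file.
#' @return A [gene_table()].
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type == "CDS"
  if (!any(keep)) keep <- type == "gene"
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  pick <- function(col) if (col %in% names(md)) as.character(md[[col]]) else
    rep(NA_character_, length(gr))
  locus <- pick("locus_tag")
  locus <- ifelse(is.na(locus), pick("ID"), locus)
  locus <- ifelse(is.na(locus), pick("Name"), locus)
  category <- pick("category")
  category[is.na(category)] <- "core"
  gene_table(locus = locus,
             reference_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             category = category)
}

#' Read gene models from a simple TSV
#'
#' Columns: locus, reference_id, start, end, strand, category (1-based
#' inclusive coordinates).
#'
#' @param path TSV file with a header line.
#' @return A [gene_table()].
#' @export
read_genes_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  gene_table(d$locus, d$reference_id, d$start, d$end, d$strand, d$category)
}

# Gene-oriented views of a backbone sequence and pileup used by the
# estimator: positions ordered 5'->3' along the gene, bases complemented and
# count columns swapped for minus-strand genes.
.gene_view <- function(backbone_chars, pileup, gene) {
  if (gene$start < 1L || gene$end > length(backbone_chars))
    stop("gene ", gene$locus, " outside the reference bounds")
  pos <- gene$start:gene$end
  counts <- pileup$counts[pos, , drop = FALSE]
  bases <- backbone_chars[pos]
  if (gene$strand == "-") {
    pos <- rev(pos)
    bases <- complement_chars(rev(bases))
    counts <- counts[rev(seq_len(nrow(counts))), c("T", "G", "C", "A"),
                     drop = FALSE]
    colnames(counts) <- DNA_BASES
  }
  list(pos = pos, bases = bases, counts = counts, depth = rowSums(counts))
}
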