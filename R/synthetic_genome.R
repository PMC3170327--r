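#' Generate a synthetic genome with annotated genes
#'
#' Builds a random genome of alternating genes and intergenic spacers.
#' Gene bodies are random codons drawn uniformly from the 61 sense codons
#' (so the backbone never contains an internal stop), opened with ATG and
#' closed with TAA; spacers are uniform random bases. Strands alternate so
#' both orientations are exercised.
#'
#' @param n_genes Number of genes.
#' @param gene_length Gene length in bp, multiple of 3 (default 600).
#' @param intergenic Spacer length in bp (default 100).
#' @param seed Integer seed.
#' @param categories Optional character vector of per-gene categories
#'   (recycled); default half core, half accessory.
#' @return List: `genome` (character vector of bases), `genes`
#'   (a [gene_table()]).
#' @export
synthetic_genome <- function(n_genes = 20L, gene_length = 600L,
                             intergenic = 100L, seed = 1L,
                             categories = c("core", "accessory")) {
  gene_length <- as.integer(gene_length)
  if (gene_length %% 3L != 0L) stop("gene_length must be a multiple of 3")
  tb <- .codon_tables()
  sense <- setdiff(rownames(tb$site_ns), tb$stops)
  with_seed(seed, {
    pieces <- list()
    starts <- integer(n_genes); ends <- integer(n_genes)
    cursor <- 0L
    for (i in seq_len(n_genes)) {
      spacer <- sample(DNA_BASES, intergenic, replace = TRUE)
      ncod <- gene_length %/% 3L - 2L
      body <- sample(sense, ncod, replace = TRUE)
      gene_seq <- strsplit(paste(c("ATG", body, "TAA"), collapse = ""),
                           "", fixed = TRUE)[[1L]]
      if (i %% 2L == 0L) gene_seq <- complement_chars(rev(gene_seq))
      pieces[[length(pieces) + 1L]] <- spacer
      cursor <- cursor + intergenic
      starts[i] <- cursor + 1L
      pieces[[length(pieces) + 1L]] <- gene_seq
      cursor <- cursor + gene_length
      ends[i] <- cursor
    }
    pieces[[length(pieces) + 1L]] <- sample(DNA_BASES, intergenic,
                                            replace = TRUE)
    genome <- unlist(pieces)
    genes <- gene_table(
      locus = sprintf("gene_%03d", seq_len(n_genes)),
      reference_id = "ref", start = starts, end = ends,
      strand = ifelse(seq_len(n_genes) %% 2L == 0L, "-", "+"),
      category = rep_len(categories, n_genes))
    list(genome = genome, genes = genes)
  })
}
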