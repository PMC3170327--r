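# Codon mutation tables used by both the per-site estimator and the NG86
# pairwise surrogate. Stop codons translate to "*" and count as a distinct
# amino acid, so mutations to or from a stop are non-synonymous.

.codon_tables <- local({
  tbl <- NULL
  function() {
    if (!is.null(tbl)) return(tbl)
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)
    aa <- unname(gc)
    names(aa) <- codons

    # mutation class lookup: "CODON.pos.alt" -> "NS"/"S"
    keys <- character(64L * 9L)
    cls <- character(64L * 9L)
    site_ns <- matrix(0, nrow = 64L, ncol = 3L, dimnames = list(codons, NULL))
    site_s <- site_ns
    k <- 0L
    for (cd in codons) {
      cc <- strsplit(cd, "", fixed = TRUE)[[1L]]
      for (p in 1:3) {
        for (alt in setdiff(DNA_BASES, cc[p])) {
          mut <- cc
          mut[p] <- alt
          mcd <- paste(mut, collapse = "")
          k <- k + 1L
          keys[k] <- paste(cd, p, alt, sep = ".")
          syn <- aa[mcd] == aa[cd]
          cls[k] <- if (syn) "S" else "NS"
          if (syn) site_s[cd, p] <- site_s[cd, p] + 1 / 3
          else site_ns[cd, p] <- site_ns[cd, p] + 1 / 3
        }
      }
    }
    names(cls) <- keys
    tbl <<- list(aa = aa, class = cls, site_ns = site_ns, site_s = site_s,
                 stops = codons[aa == "*"])
    tbl
  }
})

#' Fractional non-synonymous and synonymous site counts of one codon
#'
#' Enumerates the nine possible single-base mutations of the codon and
#' classifies each as non-synonymous (amino-acid changing, with stop treated
#' as a distinct amino acid) or synonymous. Counts are divided by three so
#' every codon totals exactly three sites.
#'
#' @param codon Character scalar of three bases over A/C/G/T.
#' @return Named numeric vector `c(ns_sites=, s_sites=)` summing to 3.
#' @examples
#' codon_site_counts("TTT") # 8/3 NS, 1/3 S
#' codon_site_counts("GGG") # 2 NS, 1 S
#' @export
codon_site_counts <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("codon must be 3 bases over A/C/G/T (no N): ", codon)
  tb <- .codon_tables()
  c(ns_sites = sum(tb$site_ns[codon, ]), s_sites = sum(tb$site_s[codon, ]))
}

#' Classify a single-base substitution as non-synonymous or synonymous
#'
#' Substitutes `alt_base` into `codon` at `pos_in_codon` (the other two
#' positions keep the backbone context — reads are unlinked, so the consensus
#' or reference codon always supplies the context) and compares amino acids.
#'
#' @param codon Backbone codon, 3 bases over A/C/G/T.
#' @param pos_in_codon Position 1, 2 or 3 within the codon.
#' @param alt_base Observed base, must differ from the codon's base there.
#' @return `"NS"` or `"S"`.
#' @export
classify_substitution <- function(codon, pos_in_codon, alt_base) {
  codon <- toupper(codon); alt_base <- toupper(alt_base)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("codon must be N-free: ", codon)
  if (!pos_in_codon %in% 1:3) stop("pos_in_codon must be 1, 2 or 3")
  if (substr(codon, pos_in_codon, pos_in_codon) == alt_base)
    stop("alt_base equals the backbone base; not a polymorphism")
  if (!alt_base %in% DNA_BASES) stop("alt_base must be A/C/G/T")
  unname(.codon_tables()$class[paste(codon, pos_in_codon, alt_base, sep = ".")])
}

# Vectorized class lookup used by the pileup scanner.
.mutation_class <- function(codon, pos, alt) {
  unname(.codon_tables()$class[paste(codon, pos, alt, sep = ".")])
}

.translate_codon <- function(codon) unname(.codon_tables()$aa[codon])

.is_stop <- function(codon) codon %in% .codon_tables()$stops
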