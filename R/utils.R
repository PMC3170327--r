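#' @import data.table
#' @importFrom stats rnorm runif rpois lm coef
#' @importFrom utils head tail write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Coerce a genome to an uppercase character vector of single bases.
seq_chars <- function(x) {
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet")) {
    if (inherits(x, "DNAStringSet")) x <- x[[1L]]
    x <- as.character(x)
  }
  stopifnot(is.character(x), length(x) >= 1L)
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "", fixed = TRUE)[[1L]]
  toupper(x)
}

complement_chars <- function(x) chartr("ACGTN", "TGCAN", x)

revcomp_string <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

finite_vals <- function(x) x[is.finite(x)]
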