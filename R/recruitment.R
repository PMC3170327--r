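# Fragment recruitment: filter read placements at identity/coverage
# thresholds and competitively assign each read to the reference with the
# best surviving alignment (ties broken by a seeded uniform draw).

#' Percent identity of an alignment
#'
#' Matches over aligned columns; gap columns (insertions and deletions)
#' count in the denominator.
#'
#' @param aln A one-row `data.frame`/list with fields `n_matches` and
#'   `n_aligned_columns` (e.g. a row of `alignment_set$summary`).
#' @return Fraction in `[0, 1]`.
#' @export
alignment_identity <- function(aln) {
  if (is.null(aln$n_aligned_columns) || any(aln$n_aligned_columns < 1L))
    stop("malformed alignment record: no aligned columns")
  aln$n_matches / aln$n_aligned_columns
}

#' Coverage (length fraction) of an alignment
#'
#' Aligned read bases (gap columns on the read side excluded) over the full
#' read length.
#'
#' @param aln As for [alignment_identity()], with fields `n_read_aligned`
#'   and `read_length`.
#' @return Fraction in `[0, 1]`.
#' @export
alignment_coverage <- function(aln) {
  if (is.null(aln$read_length) || any(aln$read_length < 1L))
    stop("malformed alignment record: read_length must be positive")
  aln$n_read_aligned / aln$read_length
}

#' Competitively assign reads to references
#'
#' Per read, alignments failing either threshold are dropped; among the
#' survivors the best is chosen: higher identity first, then more aligned
#' columns, then a seeded uniform draw for byte-identical survivors (the
#' draw is flagged in `competing_equal`). Reads with no surviving alignment
#' are `"unassigned"`.
#'
#' @param aln_set An [alignment_set()].
#' @param min_identity,min_coverage Inclusive thresholds in `[0, 1]`
#'   (default 0.80/0.80).
#' @param seed Integer seed making tie-breaks reproducible.
#' @return `data.frame` with one row per read: `read_id`,
#'   `assigned_reference`, `identity`, `coverage`, `competing_equal`.
#' @export
recruit <- function(aln_set, min_identity = 0.80, min_coverage = 0.80,
                    seed = 1L) {
  stopifnot(inherits(aln_set, "alignment_set"))
  if (min_identity < 0 || min_identity > 1 || min_coverage < 0 ||
      min_coverage > 1)
    stop("thresholds must lie in [0, 1]")
  s <- data.table::copy(aln_set$summary)
  all_reads <- unique(s$read_id)
  if (length(all_reads) == 0L)
    return(data.frame(read_id = character(), assigned_reference = character(),
                      identity = numeric(), coverage = numeric(),
                      competing_equal = logical()))
  s[, identity := n_matches / n_aligned_columns]
  s[, coverage := n_read_aligned / read_length]
  surv <- s[identity >= min_identity & coverage >= min_coverage]
  picked <- with_seed(seed, {
    if (nrow(surv)) {
      surv[, tie_rand := runif(.N)]
      data.table::setorder(surv, read_id, -identity, -n_aligned_columns,
                           tie_rand)
      best <- surv[, {
        top <- .SD[1L]
        nbest <- sum(identity == top$identity &
                       n_aligned_columns == top$n_aligned_columns)
        list(assigned_reference = top$reference_id,
             identity = top$identity, coverage = top$coverage,
             competing_equal = nbest > 1L)
      }, by = read_id]
      best
    } else {
      data.table::data.table(read_id = character(),
                             assigned_reference = character(),
                             identity = numeric(), coverage = numeric(),
                             competing_equal = logical())
    }
  })
  out <- merge(data.table::data.table(read_id = all_reads), picked,
               by = "read_id", all.x = TRUE, sort = FALSE)
  out[is.na(assigned_reference),
      `:=`(assigned_reference = "unassigned", competing_equal = FALSE)]
  data.table::setorder(out, read_id)
  data.table::setDF(out)
  out
}

#' Recruitment curve over a threshold grid
#'
#' For each (identity, coverage) pair, counts reads with at least one
#' surviving alignment. The grid must be ordered from strict to permissive
#' (both thresholds non-increasing), so totals are non-decreasing by set
#' containment and `newly_recruited` is their first difference.
#'
#' @param aln_set An [alignment_set()].
#' @param grid `data.frame` with columns `identity` and `coverage`.
#' @return `data.frame`: `identity`, `coverage`, `total_recruited`,
#'   `newly_recruited`.
#' @export
recruitment_curve <- function(aln_set, grid) {
  stopifnot(inherits(aln_set, "alignment_set"))
  grid <- as.data.frame(grid)
  if (!all(c("identity", "coverage") %in% names(grid)))
    stop("grid needs columns identity, coverage")
  if (nrow(grid) > 1L) {
    did <- diff(grid$identity); dcv <- diff(grid$coverage)
    if (any(did > 0) || any(dcv > 0))
      stop("grid must be sorted from strict to permissive")
  }
  s <- aln_set$summary
  id <- s$n_matches / s$n_aligned_columns
  cv <- s$n_read_aligned / s$read_length
  total <- vapply(seq_len(nrow(grid)), function(k) {
    length(unique(s$read_id[id >= grid$identity[k] &
                              cv >= grid$coverage[k]]))
  }, 1L)
  data.frame(identity = grid$identity, coverage = grid$coverage,
             total_recruited = total,
             newly_recruited = c(total[1L], diff(total)))
}

#' Parse a "from:to:step" grid specification
#'
#' `"1.0:0.5:0.05"` yields the diagonal grid (1.0,1.0), (0.95,0.95), ...,
#' (0.5,0.5), strict to permissive.
#'
#' @param spec Character scalar.
#' @return `data.frame` with `identity` and `coverage`.
#' @export
parse_threshold_grid <- function(spec) {
  v <- as.numeric(strsplit(spec, ":", fixed = TRUE)[[1L]])
  if (length(v) != 3L || anyNA(v)) stop("grid spec must be from:to:step")
  th <- seq(v[1L], v[2L], by = -abs(v[3L]))
  data.frame(identity = th, coverage = th)
}
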