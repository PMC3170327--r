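# Cross-gene summaries and analyses: category means and histograms, OLS
# regressions (dN - dS against coverage; homolog comparisons after a
# square-root transform), and Kyte-Doolittle hydropathy profiles.

#' Summarize a per-gene selection table
#'
#' Mean dN/dS is taken over finite entries only (NaN = 0/0 genes and
#' Inf = no-synonymous-polymorphism genes are excluded and counted
#' separately). The fraction of genes with dN/dS below 1 is computed over
#' genes with a defined ratio, with Inf counting as above 1. Summaries are
#' reported overall and per category; empty categories are omitted.
#'
#' @param stats `data.frame` from [genes_selection_table()] (needs
#'   `dnds` and `category`).
#' @param breaks Histogram bin edges for the dN/dS distribution.
#' @param high_coverage_fold Report filter: genes with `avg_depth` above
#'   this are counted as highly represented (default 20).
#' @return List: `summary` (`data.frame` per category plus `"all"`),
#'   `histogram` (`data.frame` of bin counts over finite ratios).
#' @export
summarize_genes <- function(stats,
                            breaks = c(seq(0, 1, by = 0.1), 1.5, 2, Inf),
                            high_coverage_fold = 20) {
  if (nrow(stats) == 0L) stop("empty gene table")
  one <- function(d, label) {
    x <- d$dnds
    fin <- x[is.finite(x)]
    defined <- x[!is.nan(x) & !is.na(x)]
    data.frame(
      category = label, n_genes = nrow(d),
      mean_dnds = if (length(fin)) mean(fin) else NA_real_,
      frac_below_1 = if (length(defined)) mean(defined < 1) else NA_real_,
      n_nan = sum(is.nan(x)), n_inf = sum(is.infinite(x)),
      n_high_coverage = if ("avg_depth" %in% names(d))
        sum(d$avg_depth > high_coverage_fold) else NA_integer_)
  }
  rows <- list(one(stats, "all"))
  for (cat in sort(unique(stats$category)))
    rows[[length(rows) + 1L]] <- one(stats[stats$category == cat, ], cat)
  fin <- stats$dnds[is.finite(stats$dnds)]
  hist_counts <- if (length(fin))
    table(cut(fin, breaks = breaks, right = FALSE)) else
      table(cut(numeric(0), breaks = breaks, right = FALSE))
  list(summary = do.call(rbind, rows),
       histogram = data.frame(bin = names(hist_counts),
                              count = as.integer(hist_counts)))
}

#' Ordinary least squares regression
#'
#' Pairs with a non-finite member are dropped and counted. Used for
#' dN - dS against average read depth and for homolog-population
#' comparisons.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List of class `ols_fit`: `slope`, `intercept`, `r_squared`,
#'   `n_points`, `slope_se`, `n_dropped`.
#' @export
regress <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("fewer than 2 finite pairs")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = sm$r.squared, n_points = length(x),
                 slope_se = sm$coefficients[2L, 2L],
                 n_dropped = n_dropped),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS: y = %.4gx + %.4g, r^2 = %.3f, n = %d (slope se %.4g)\n",
              x$slope, x$intercept, x$r_squared, x$n_points, x$slope_se))
  invisible(x)
}

#' Compare homologous genes' dN/dS between two populations
#'
#' Joins the two per-gene tables on homolog pairs, square-root transforms
#' both ratios (stabilizing the skew before regression), fits population B
#' on population A by OLS, and reports genes under discordant selection
#' (ratio above 1 in exactly one population, Inf counting as above 1).
#' Pairs with NaN/NA in either population, or Inf in either (no synonymous
#' polymorphisms), are dropped from the regression and counted.
#'
#' @param stats_a,stats_b Per-gene tables (need `locus` and `dnds`).
#' @param homolog_pairs `data.frame` with columns `a` and `b` naming the
#'   loci pairs.
#' @return List: `paired` (`data.frame` with both ratios and their sqrt),
#'   `fit` ([regress()] result), `n_dropped_nan`, `n_dropped_inf`,
#'   `discordant` (`data.frame`).
#' @export
compare_homolog_populations <- function(stats_a, stats_b, homolog_pairs) {
  ia <- match(homolog_pairs$a, stats_a$locus)
  ib <- match(homolog_pairs$b, stats_b$locus)
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok)) stop("no homolog pair present in both tables")
  pa <- stats_a$dnds[ia[ok]]
  pb <- stats_b$dnds[ib[ok]]
  paired <- data.frame(a = homolog_pairs$a[ok], b = homolog_pairs$b[ok],
                       dnds_a = pa, dnds_b = pb,
                       sqrt_a = sqrt(pa), sqrt_b = sqrt(pb))
  nan_pair <- is.nan(pa) | is.nan(pb) | is.na(pa) | is.na(pb)
  inf_pair <- !nan_pair & (is.infinite(pa) | is.infinite(pb))
  usable <- !nan_pair & !inf_pair
  fit <- regress(paired$sqrt_a[usable], paired$sqrt_b[usable])
  gt1 <- function(x) !is.na(x) & !is.nan(x) & x > 1
  disc <- paired[xor(gt1(pa), gt1(pb)) & !nan_pair, , drop = FALSE]
  list(paired = paired, fit = fit,
       n_dropped_nan = sum(nan_pair), n_dropped_inf = sum(inf_pair),
       discordant = disc)
}

# Kyte-Doolittle hydropathy values
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding mean of per-residue hydropathy values over a centered window;
#' only positions with a full window are emitted.
#'
#' @param protein Amino-acid string or character vector (standard 20
#'   residues).
#' @param window Window size in residues, odd (default 19).
#' @return `data.frame`: `position` (window center, 1-based),
#'   `hydropathy`.
#' @export
hydropathy_profile <- function(protein, window = 19L) {
  p <- toupper(seq_chars(protein))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd")
  if (length(p) < window)
    stop("sequence shorter than the window (", length(p), " < ", window, ")")
  v <- .KD[p]
  if (anyNA(v)) stop("non-standard residue: ",
                     paste(unique(p[is.na(v)]), collapse = ", "))
  h <- (window - 1L) %/% 2L
  centers <- (h + 1L):(length(p) - h)
  cs <- cumsum(c(0, v))
  data.frame(position = centers,
             hydropathy = (cs[centers + h + 1L] - cs[centers - h]) / window)
}
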