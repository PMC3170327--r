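# Seeded generators for synthetic inputs:
#   simulate_reads        - 454-like reads from one genome (neutral null)
#   simulate_population   - clonal haplotypes diverged at controlled per-gene
#                           omega, with a truth mutation table
#   randomize_placements  - uniform re-placement coverage null
#
# 454 error model: uniform substitutions at substitution_rate (alt base
# uniform over the three others), plus homopolymer indels - each
# homopolymer run of length L overlapped by a read suffers a single-base
# insertion or deletion (equal odds) with probability
# min(1, homopolymer_rate * L^homopolymer_exponent). Qualities are
# Gaussian-rounded Phred scores clipped to [2, 40]. All outputs are
# byte-identical under a fixed seed.

#' Simulation configuration for 454-like reads
#'
#' Defaults mirror the scale of the published control simulation: reads
#' averaging 250 bp; 300000 reads is the full-scale count (pass `n_reads`
#' explicitly for desk-scale runs).
#'
#' @param n_reads Number of reads.
#' @param read_length_mean,read_length_sd Read length model in bp;
#'   `sd = 0` gives fixed-length reads.
#' @param substitution_rate Per-base substitution error probability.
#' @param homopolymer_rate Per-run base rate of a single-base indel.
#' @param homopolymer_exponent Run-length exponent of the indel rate.
#' @param quality_mean,quality_sd Phred quality model.
#' @param seed Integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_reads = 300000L, read_length_mean = 250,
                       read_length_sd = 0, substitution_rate = 1e-3,
                       homopolymer_rate = 0, homopolymer_exponent = 1,
                       quality_mean = 30, quality_sd = 5, seed = 1L) {
  stopifnot(n_reads >= 0, substitution_rate >= 0, substitution_rate <= 1,
            homopolymer_rate >= 0, homopolymer_rate <= 1,
            read_length_mean > 0)
  structure(list(n_reads = as.integer(n_reads),
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 substitution_rate = substitution_rate,
                 homopolymer_rate = homopolymer_rate,
                 homopolymer_exponent = homopolymer_exponent,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate 454-like reads from a genome
#'
#' Read start positions are uniform over the genome on both strands.
#' Substitution and homopolymer-indel errors are applied per the config;
#' the error-free placement is recorded as truth, so the result doubles as
#' a perfect alignment set (identity reflects only the injected errors).
#'
#' @param genome Genome sequence (string, char vector or `DNAString`).
#' @param config A [sim_config()].
#' @param reference_id Name used for the reference (default `"ref"`).
#' @return List of class `sim_reads`: `alignments` (an
#'   [alignment_set()] of the truth placements), `insertions`
#'   (`data.frame` of inserted read bases, for FASTQ/SAM export), and
#'   `reference_id`.
#' @export
simulate_reads <- function(genome, config, reference_id = "ref") {
  g <- seq_chars(genome)
  G <- length(g)
  n <- config$n_reads
  with_seed(config$seed, {
    L <- if (config$read_length_sd > 0)
      pmax(30L, pmin(G, as.integer(round(rnorm(n, config$read_length_mean,
                                               config$read_length_sd)))))
    else rep(min(as.integer(round(config$read_length_mean)), G), n)
    if (any(L > G)) stop("read length exceeds the genome length")
    start <- as.integer(floor(runif(n, 1, G - L + 1 + 1)))
    strand <- sample(c("+", "-"), n, replace = TRUE)

    tot <- sum(L)
    uid <- rep(seq_len(n), L)
    ref_pos <- sequence(L, from = start)
    base <- g[ref_pos]
    # substitution errors, alt uniform over the other three bases
    hit <- runif(tot) < config$substitution_rate
    if (any(hit)) {
      cur <- match(base[hit], DNA_BASES)
      shift <- sample.int(3L, sum(hit), replace = TRUE)
      base[hit] <- DNA_BASES[(cur - 1L + shift) %% 4L + 1L]
    }
    qual <- pmin(40L, pmax(2L, as.integer(round(rnorm(
      tot, config$quality_mean, config$quality_sd)))))

    keep_row <- rep(TRUE, tot)
    n_ins <- integer(n); n_del <- integer(n)
    ins <- list()
    if (config$homopolymer_rate > 0) {
      r <- rle(g)
      run_end <- cumsum(r$lengths)
      run_start <- run_end - r$lengths + 1L
      runs <- which(r$lengths >= 2L)
      p_run <- pmin(1, config$homopolymer_rate *
                      r$lengths[runs]^config$homopolymer_exponent)
      row_off <- cumsum(c(0L, L))
      for (i in seq_len(n)) {
        s0 <- start[i]; e0 <- s0 + L[i] - 1L
        inside <- runs[run_start[runs] >= s0 & run_end[runs] <= e0]
        if (!length(inside)) next
        ev <- runif(length(inside)) < p_run[match(inside, runs)]
        for (j in inside[ev]) {
          if (runif(1) < 0.5) {  # deletion of one run base
            del_pos <- run_start[j]
            keep_row[row_off[i] + (del_pos - s0 + 1L)] <- FALSE
            n_del[i] <- n_del[i] + 1L
          } else {               # insertion duplicating one run base
            ins[[length(ins) + 1L]] <- data.frame(
              read_uid = i, after_ref_pos = run_start[j],
              base = g[run_start[j]],
              qual = pmin(40L, pmax(2L, as.integer(round(rnorm(
                1, config$quality_mean, config$quality_sd))))))
            n_ins[i] <- n_ins[i] + 1L
          }
        }
      }
    }
    if (!all(keep_row)) {
      uid <- uid[keep_row]; ref_pos <- ref_pos[keep_row]
      base <- base[keep_row]; qual <- qual[keep_row]
    }
    n_M <- tabulate(uid, nbins = n)
    read_pos <- sequence(n_M)
    n_matches <- tabulate(uid[base == g[ref_pos]], nbins = n)
    summary <- data.table::data.table(
      read_uid = seq_len(n), read_id = sprintf("simread_%06d", seq_len(n)),
      reference_id = reference_id, strand = strand, ref_start = start,
      n_matches = n_matches,
      n_aligned_columns = n_M + n_ins + n_del,
      n_read_aligned = n_M + n_ins,
      read_length = n_M + n_ins)
    bases <- data.table::data.table(read_uid = uid, ref_pos = ref_pos,
                                    read_pos = read_pos, base = base,
                                    qual = qual)
    refs <- stats::setNames(G, reference_id)
    structure(list(alignments = alignment_set(summary, bases, refs),
                   insertions = if (length(ins)) do.call(rbind, ins)
                   else data.frame(read_uid = integer(),
                                   after_ref_pos = integer(),
                                   base = character(), qual = integer()),
                   reference_id = reference_id, genome_length = G),
              class = "sim_reads")
  })
}

# read sequence/qualities in reference orientation, insertions spliced in
.sim_read_seq <- function(sim, uid) {
  b <- sim$alignments$bases[sim$alignments$bases$read_uid == uid]
  sq <- b$base; ql <- b$qual; rp <- b$ref_pos
  ins <- sim$insertions[sim$insertions$read_uid == uid, , drop = FALSE]
  if (nrow(ins)) {
    for (k in order(ins$after_ref_pos, decreasing = TRUE)) {
      at <- max(which(rp <= ins$after_ref_pos[k]))
      sq <- append(sq, ins$base[k], after = at)
      ql <- append(ql, ins$qual[k], after = at)
      rp <- append(rp, NA_integer_, after = at)
    }
  }
  list(seq = sq, qual = ql, ref_pos = rp)
}

#' Write simulated reads as FASTQ (Sanger Phred+33)
#'
#' Sequences are emitted in read orientation (reverse-complemented for
#' minus-strand placements).
#'
#' @param sim A [simulate_reads()] result.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_sim_fastq <- function(sim, path) {
  s <- sim$alignments$summary
  con <- file(path, "w")
  on.exit(close(con))
  for (i in s$read_uid) {
    r <- .sim_read_seq(sim, i)
    sq <- paste(r$seq, collapse = "")
    ql <- intToUtf8(r$qual + 33L)
    if (s$strand[i] == "-") {
      sq <- revcomp_string(sq)
      ql <- paste(rev(strsplit(ql, "", fixed = TRUE)[[1L]]), collapse = "")
    }
    writeLines(c(paste0("@", s$read_id[i]), sq, "+", ql), con)
  }
  invisible(path)
}

#' Write simulated truth placements as SAM
#'
#' @param sim A [simulate_reads()] result.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sim_sam <- function(sim, path) {
  s <- sim$alignments$summary
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", sim$reference_id,
                       sim$genome_length)), con)
  for (i in s$read_uid) {
    r <- .sim_read_seq(sim, i)
    # CIGAR from the ref-position structure (NA = insertion, jump = deletion)
    ops <- character(0); lens <- integer(0)
    push <- function(op) {
      if (length(ops) && ops[length(ops)] == op)
        lens[length(lens)] <<- lens[length(lens)] + 1L
      else { ops <<- c(ops, op); lens <<- c(lens, 1L) }
    }
    prev <- NA_integer_
    for (p in r$ref_pos) {
      if (is.na(p)) push("I")
      else {
        if (!is.na(prev) && p > prev + 1L)
          for (k in seq_len(p - prev - 1L)) push("D")
        push("M")
        prev <- p
      }
    }
    cigar <- paste0(lens, ops, collapse = "")
    writeLines(paste(s$read_id[i], ifelse(s$strand[i] == "-", 16L, 0L),
                     sim$reference_id, s$ref_start[i], 60L, cigar, "*", 0L,
                     0L, paste(r$seq, collapse = ""),
                     intToUtf8(r$qual + 33L), sep = "\t"), con)
  }
  invisible(path)
}

#' Population configuration for the clonal-divergence simulator
#'
#' @param n_haplotypes Number of haplotype genomes drawn from the
#'   reference.
#' @param per_gene_omega Named numeric vector, locus -> true omega.
#' @param target_divergence Expected substitutions per synonymous site per
#'   haplotype.
#' @param intergenic_rate Per-base substitution probability outside genes.
#' @param seed Integer seed.
#' @return Object of class `pop_config`.
#' @export
pop_config <- function(n_haplotypes = 6L, per_gene_omega,
                       target_divergence = 0.05, intergenic_rate = 0,
                       seed = 1L) {
  stopifnot(all(per_gene_omega >= 0), target_divergence >= 0,
            n_haplotypes >= 1L)
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 per_gene_omega = per_gene_omega,
                 target_divergence = target_divergence,
                 intergenic_rate = intergenic_rate,
                 seed = as.integer(seed)),
            class = "pop_config")
}

#' Simulate a clonal population diverged at controlled per-gene omega
#'
#' Each haplotype independently accumulates substitutions: per gene,
#' `Poisson(target_divergence * s_sites)` synonymous and
#' `Poisson(omega * target_divergence * ns_sites)` non-synonymous
#' mutations, sampled without replacement from the gene's enumerated
#' mutation lists (classified in the reference codon context). Haplotypes
#' carry substitutions only, so reference coordinates are preserved.
#'
#' @param genome Reference genome sequence.
#' @param genes A [gene_table()] (every locus in
#'   `config$per_gene_omega` must appear; unknown loci error).
#' @param config A [pop_config()].
#' @return List of class `sim_population`: `haplotypes` (list of char
#'   vectors), `truth` (`data.frame`: haplotype, pos, ref, alt, locus,
#'   class), `genes`, `reference` (char vector).
#' @export
simulate_population <- function(genome, genes, config) {
  g <- seq_chars(genome)
  omega <- config$per_gene_omega
  unknown <- setdiff(names(omega), genes$locus)
  if (length(unknown))
    stop("omega requested for unknown locus: ",
         paste(unknown, collapse = ", "))
  tb <- .codon_tables()
  # enumerate every possible single-base mutation per gene, with class
  menu <- lapply(names(omega), function(lc) {
    gn <- genes[genes$locus == lc, ]
    pos <- gn$start:gn$end
    bb <- g[pos]
    if (gn$strand == "-") { pos <- rev(pos); bb <- complement_chars(rev(bb)) }
    ncod <- length(bb) %/% 3L
    cod <- vapply(seq_len(ncod), function(i)
      paste(bb[(3L * i - 2L):(3L * i)], collapse = ""), "")
    ok_cod <- !grepl("[^ACGT]", cod) & !.is_stop(cod)
    rows <- list()
    for (i in which(ok_cod)) {
      for (p in 1:3) {
        at <- 3L * (i - 1L) + p
        for (alt in setdiff(DNA_BASES, bb[at])) {
          cls <- unname(tb$class[paste(cod[i], p, alt, sep = ".")])
          genome_alt <- if (gn$strand == "-") complement_chars(alt) else alt
          rows[[length(rows) + 1L]] <- c(pos = pos[at], alt = genome_alt,
                                         class = cls)
        }
      }
    }
    m <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    m$pos <- as.integer(m$pos)
    m$locus <- lc
    # fractional site totals for the Poisson means
    idx <- which(ok_cod)
    m_ns <- sum(tb$site_ns[cod[idx], ]); m_s <- sum(tb$site_s[cod[idx], ])
    attr(m, "ns_sites") <- m_ns
    attr(m, "s_sites") <- m_s
    m
  })
  names(menu) <- names(omega)

  with_seed(config$seed, {
    truth <- list()
    haplotypes <- vector("list", config$n_haplotypes)
    for (h in seq_len(config$n_haplotypes)) {
      hg <- g
      for (lc in names(omega)) {
        m <- menu[[lc]]
        lamS <- config$target_divergence * attr(m, "s_sites")
        lamN <- omega[[lc]] * config$target_divergence * attr(m, "ns_sites")
        iS <- which(m$class == "S"); iN <- which(m$class == "NS")
        pick <- c(if (length(iS)) sample(iS, min(rpois(1, lamS), length(iS)))
                  else integer(0),
                  if (length(iN)) sample(iN, min(rpois(1, lamN), length(iN)))
                  else integer(0))
        if (length(pick)) {
          sel <- m[pick, , drop = FALSE]
          sel <- sel[!duplicated(sel$pos), , drop = FALSE]
          hg[sel$pos] <- sel$alt
          truth[[length(truth) + 1L]] <- data.frame(
            haplotype = h, pos = sel$pos, ref = g[sel$pos], alt = sel$alt,
            locus = sel$locus, class = sel$class,
            stringsAsFactors = FALSE)
        }
      }
      if (config$intergenic_rate > 0) {
        in_gene <- logical(length(g))
        for (i in seq_len(nrow(genes)))
          in_gene[genes$start[i]:genes$end[i]] <- TRUE
        ig <- which(!in_gene)
        hit <- ig[runif(length(ig)) < config$intergenic_rate]
        if (length(hit)) {
          cur <- match(g[hit], DNA_BASES)
          shift <- sample.int(3L, length(hit), replace = TRUE)
          hg[hit] <- DNA_BASES[(cur - 1L + shift) %% 4L + 1L]
          truth[[length(truth) + 1L]] <- data.frame(
            haplotype = h, pos = hit, ref = g[hit], alt = hg[hit],
            locus = NA_character_, class = "intergenic",
            stringsAsFactors = FALSE)
        }
      }
      haplotypes[[h]] <- hg
    }
    structure(list(haplotypes = haplotypes,
                   truth = if (length(truth)) do.call(rbind, truth)
                   else data.frame(haplotype = integer(), pos = integer(),
                                   ref = character(), alt = character(),
                                   locus = character(), class = character()),
                   genes = genes, reference = g),
              class = "sim_population")
  })
}

#' Draw reads from a simulated population
#'
#' Reads are drawn in equal expected proportion from each haplotype (the
#' haplotype of each read is multinomial) and carry the sequencing-error
#' model of `config`. Because haplotypes are substitution-only, all truth
#' placements live in reference coordinates and the merged alignment set
#' can be piled directly against the original reference.
#'
#' @param pop A [simulate_population()] result.
#' @param config A [sim_config()]; `config$seed` governs both the
#'   haplotype assignment and the read draws.
#' @param reference_id Name used for the reference (default `"ref"`).
#' @return A `sim_reads` object (see [simulate_reads()]).
#' @export
simulate_population_reads <- function(pop, config, reference_id = "ref") {
  H <- length(pop$haplotypes)
  with_seed(config$seed, {
    hap_of <- sample.int(H, config$n_reads, replace = TRUE)
    sims <- vector("list", H)
    sub_seeds <- sample.int(.Machine$integer.max, H)
    for (h in seq_len(H)) {
      nh <- sum(hap_of == h)
      cfg <- config
      cfg$n_reads <- nh
      cfg$seed <- sub_seeds[h]
      sims[[h]] <- simulate_reads(pop$haplotypes[[h]], cfg, reference_id)
    }
    # merge, renumbering read_uids
    off <- 0L
    summaries <- list(); bases <- list(); inserts <- list()
    for (h in seq_len(H)) {
      s <- data.table::copy(sims[[h]]$alignments$summary)
      b <- data.table::copy(sims[[h]]$alignments$bases)
      i <- sims[[h]]$insertions
      s[, read_uid := read_uid + off]
      s[, read_id := sprintf("simread_h%d_%06d", h, .I)]
      b[, read_uid := read_uid + off]
      if (nrow(i)) i$read_uid <- i$read_uid + off
      off <- off + nrow(s)
      summaries[[h]] <- s; bases[[h]] <- b; inserts[[h]] <- i
    }
    summary <- data.table::rbindlist(summaries)
    # identity/matches are measured against the true reference, not the
    # haplotype the read came from
    g <- pop$reference
    ab <- data.table::rbindlist(bases)
    mt <- ab[, .(n = sum(base == g[ref_pos])), by = read_uid]
    summary[mt, n_matches := i.n, on = "read_uid"]
    summary[!mt, n_matches := 0L, on = "read_uid"]
    refs <- stats::setNames(length(g), reference_id)
    structure(list(alignments = alignment_set(summary, ab, refs),
                   insertions = do.call(rbind, inserts),
                   reference_id = reference_id, genome_length = length(g),
                   haplotype_of_read = hap_of),
              class = "sim_reads")
  })
}

#' Placement-randomization coverage null
#'
#' Re-places reads of the given lengths uniformly on the genome `n_reps`
#' times and records the mean depth per gene for each replicate, plus the
#' across-replicate mean - the null distribution of per-gene coverage
#' under no recruitment preference.
#'
#' @param read_lengths Integer vector of read lengths to re-place.
#' @param genome_length Genome length in bp.
#' @param genes A [gene_table()].
#' @param n_reps Number of randomizations (default 100).
#' @param seed Integer seed.
#' @return List: `per_rep` (genes x reps matrix of mean depths),
#'   `mean_depth` (named vector), `genome_mean` (expected depth
#'   anywhere).
#' @export
randomize_placements <- function(read_lengths, genome_length, genes,
                                 n_reps = 100L, seed = 1L) {
  read_lengths <- as.integer(read_lengths)
  if (any(read_lengths > genome_length))
    stop("read length exceeds the genome length")
  G <- as.integer(genome_length)
  n <- length(read_lengths)
  idx <- lapply(seq_len(nrow(genes)), function(i) genes$start[i]:genes$end[i])
  per_rep <- matrix(0, nrow = nrow(genes), ncol = n_reps,
                    dimnames = list(genes$locus, NULL))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      start <- as.integer(floor(runif(n, 1, G - read_lengths + 1 + 1)))
      delta <- integer(G + 1L)
      dt <- data.table::data.table(s = start, e = start + read_lengths)
      add <- dt[, .N, by = s]; sub <- dt[, .N, by = e]
      delta[add$s] <- delta[add$s] + add$N
      delta[sub$e] <- delta[sub$e] - sub$N
      depth <- cumsum(delta)[seq_len(G)]
      per_rep[, r] <- vapply(idx, function(p) mean(depth[p]), 1.0)
    }
  })
  list(per_rep = per_rep, mean_depth = rowMeans(per_rep),
       genome_mean = sum(read_lengths) / G)
}
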