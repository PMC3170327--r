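---
title: "Estimating within-population dN/dS from metagenomic read pileups"
author: "metadnds authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating within-population dN/dS from metagenomic read pileups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Environmental shotgun metagenomes of a microbial population deliver short,
unlinked reads: each read samples one cell's genome at one place, and no
two reads can be assumed to come from the same cell. Classical dN/dS
machinery (codon models over an alignment block of full-length sequences)
does not apply. `metadnds` implements the site-wise alternative: tile reads
onto a reference genome, call a majority-rule consensus as the population's
modal sequence, and treat every read base that differs from the consensus
as one observed polymorphism.

For a gene (or window) the statistic is

$$\frac{dN}{dS} \;=\; \frac{\text{NS polys} / \text{NS sites}}
                           {\text{S polys} / \text{S sites}}$$

where *sites* are counted from the consensus by enumerating, for every
codon position, the three possible single-base mutations and classifying
each as non-synonymous (amino-acid changing; mutations creating or
destroying a stop codon count as non-synonymous) or synonymous. Counts are
fractional — each codon contributes exactly 3 sites — which keeps dN and
dS on a per-site scale; the ratio itself is invariant to fractional versus
raw counting, and the test suite asserts that invariance. Because the
quantity is computed from segregating polymorphisms rather than fixed
differences it is strictly a pN/pS, and because within-population
divergence is tiny no multiple-hit correction (e.g. Jukes–Cantor) is
applied to the per-gene estimator.

Genes with zero polymorphisms of both kinds report `NaN` (0/0); genes with
only non-synonymous polymorphisms report `Inf`. Both are first-class values
throughout the package, written as literal `NaN`/`Inf` strings in the TSV
outputs, and excluded from means (the same exclusion rule the pairwise
estimator states explicitly). When the ratio's denominator is fragile the
difference statistic `dN - dS` is provided, with 0 as the neutral
reference.

## Pipeline stages and the parameters that matter

**Recruitment.** Reads may align to several references; alignments are
filtered at minimum percent identity and minimum coverage ("length
fraction"), both defaulting to 0.80 and compared inclusively (a read at
exactly 80% passes). Identity is matches over aligned columns *including*
gap columns; coverage is aligned read bases over read length. Among
surviving alignments the best one wins: higher identity, then more aligned
columns, then a seeded uniform draw, with the draw flagged
(`competing_equal`) so equally-hitting reads can be counted. The identity
denominator choice is our own (the originating aligner's formula is
unpublished); it only matters for gapped alignments, and indels are
discarded downstream anyway.

**Quality masking.** A read base enters the pileup only if its Phred
quality is strictly above 20 *and* the mean quality of the 11-nucleotide
window centred on it (truncated at read ends) is strictly above 15. We read
"the surrounding 11 nucleotides" as the centred window including the focal
base — the conventional reading; the thresholds are parameters of
`quality_filter()`. SAM records with `*` qualities fail the filter, since
the filter is mandatory in this pipeline. The window is computed in the
read's stored (reference) orientation; because the window is symmetric
this equals the read-orientation window except at clip boundaries.

**Pileup and consensus.** Per reference position the filtered A/C/G/T
counts are tabulated; `N` read bases and indel columns contribute nothing.
Positions with zero filtered depth become `N` in the consensus; otherwise
the maximal count wins, with ties resolved first toward the reference base
(when it is among the maxima) and then by the fixed order A &lt; C &lt; G
&lt; T. Reference bases are never injected as evidence — the consensus is
derived from the reads alone; the reference only breaks exact ties
deterministically.

**Counting.** Polymorphisms and sites are accumulated only at gene
positions with filtered depth of at least 5 (inclusive) whose consensus
codon is free of `N`. Restricting the *site* denominator to the same
positions as the polymorphism numerator is a deliberate choice: the source
method states the depth rule only for polymorphisms, but an unmatched
denominator would deflate the ratio for partially covered genes, so the
matched restriction is the default here. A consensus codon that is itself
a mid-gene stop is skipped and the gene flagged. Polymorphism multiplicity
defaults to per-read (each differing read base counts once), with
per-allele (each distinct variant base once) as a switch. Codon context
for classification is always the consensus (or reference) codon, never a
read's own neighbours — reads are unlinked, so a read's bases cannot be
phased together.

**Coordinates and strand.** The package uses 1-based inclusive coordinates
internally (the R/Bioconductor idiom; GFF3 I/O is 1-based inclusive
either way). Minus-strand genes are reverse-complemented before codon
decomposition, and variant bases complemented accordingly. Genes whose
annotated length is not a multiple of 3 are trimmed at their 3' end to a
codon boundary and flagged.

**Windows.** Sliding windows default to 201 nt advanced in 48-nt steps,
starting at the gene's 5' end; offsets are floored to codon boundaries,
full windows require `offset + 201 <= gene length`, and when they fail to
reach the gene's 3' end one truncated terminal window is appended and
flagged. Window coordinates are reported on the genome. Whether the
original analysis emitted terminal partial windows is unstated; emitting
them flagged loses nothing.

**Reference-based variant.** `dnds_vs_reference()` repeats the computation
with the reference genome supplying both codon context and the mismatch
baseline, so a gene fixed away from the reference but monomorphic within
the population shows the characteristic pattern: consensus-based `NaN` (or
&lt; 1) with reference-based values possibly &gt; 1.

**Pairwise surrogate.** The per-read cross-check averages NG86-style
pairwise ratios of each read against the consensus over the codons the
read touches, excluding 0/0 (`NaN`) and x/0 (`Inf`) reads from the mean as
stated. PAML's yn00 is deliberately *not* re-implemented: its
transition/transversion and codon-frequency machinery is out of proportion
to its role as a cross-check, so an equal-weight NG86 proportion estimator
without distance correction (optional Jukes–Cantor flag) stands in.
Multi-hit codons average over all shortest mutational pathways, excluding
pathways through stop codons unless none avoids them; codon columns
containing a stop or `N` in either sequence are skipped.

## The synthetic world

The generators in `sim454` are first-class, tested code; they emulate:

* **454-like reads** (`simulate_reads`): uniform start positions on both
  strands, fixed or Gaussian length (default 250 bp, the published
  simulation's read length; 300,000 reads is the published full-scale
  count), uniform substitution errors (default 1e-3), and a two-parameter
  homopolymer-indel model — each homopolymer run of length $L$ overlapped
  by a read suffers a single-base insertion or deletion with probability
  $\min(1, r_h L^{e})$ (defaults $r_h$ = 0, exponent 1; indels are
  discarded by the pipeline, so the substitution behaviour dominates any
  null). Qualities are Gaussian Phred scores (mean 30, sd 5) clipped to
  [2, 40], so a realistic few percent of bases fail the Q20 filter. The
  error-free placement is retained as truth, exportable as SAM alongside
  Sanger-encoded FASTQ; all outputs are byte-identical under a fixed seed.
  The simulator does not model flowgram-level 454 chemistry or
  amplification bias; its parameterization is explicit rather than
  calibrated to any particular simulator.

* **A clonal population** (`simulate_population`): `n_haplotypes`
  (default 6) genomes independently diverged from the reference, each gene
  receiving `Poisson(divergence x s_sites)` synonymous and
  `Poisson(omega x divergence x ns_sites)` non-synonymous substitutions
  drawn from the gene's enumerated mutation menu, so the realized NS:S
  mutation ratio matches $\omega \cdot (\text{NS sites}/\text{S sites})$
  in expectation. Every mutation is logged with its class in a truth
  table, the independent yardstick for parameter-recovery checks. The
  default divergence of 0.05 substitutions per synonymous site per
  haplotype gives genes of ~600 bp a few dozen segregating synonymous
  sites — enough for a stable denominator, comparable to a diverse wild
  population near the recruitment identity floor. Haplotypes carry
  substitutions only, so reference coordinates are preserved (real
  populations also carry indels, which this pipeline ignores by design).

* **Placement randomization** (`randomize_placements`): the observed read
  lengths re-placed uniformly 100 times (the published replicate count),
  yielding each gene's null mean coverage.

What a green test establishes: the estimator is internally consistent
(exact agreement with brute-force recounting), calibrated under neutral
sequencing error, and able to rank and recover per-gene $\omega$ from
unlinked reads at 30x depth. What it does not establish: behaviour under
real 454 flowgram error structure, under recruitment from mixed clades, or
under recombination/linkage — none of which the synthetic world attempts
to emulate.

Parameter recovery is run with the sequencing-error rate set to zero: it
isolates the estimator from the error model, whose effect is measured
separately by the neutral null. With errors on, low-$\omega$ genes would be
inflated toward the error ratio — exactly the confounding the two separate
experiments are designed to distinguish.

A note on reading the recovery statistic: true $\omega$ takes only four
values, so the Spearman correlation is computed against heavily tied
ranks; its maximum attainable value with 20 genes per level is about
0.968, which is what perfect level separation reports.

## Numerical choices and degenerate inputs

* Strict inequalities in the quality filter (a Q20 base is dropped; a
  window mean of exactly 15 is dropped); inclusive thresholds in
  recruitment (80% passes) and depth (5x passes) — both as stated by the
  source method.
* Ties: recruitment ties broken by a seeded uniform draw and flagged;
  consensus ties broken toward the reference, then A &lt; C &lt; G &lt; T.
  All randomness flows through explicit integer seeds; identical inputs
  and seeds give byte-identical outputs.
* Degenerate inputs: empty alignment records and zero-length reads error
  as malformed; zero-length genes error; a gene with no eligible position
  reports `positions_counted = 0` and `NaN`; an empty recruitment input
  yields an empty assignment table.
* Mean dN/dS summaries exclude `NaN` and `Inf` genes; the fraction of
  genes below 1 is computed over defined ratios with `Inf` counting as
  above 1.

## Known limitations

* No indel calling, no diploid/ambiguity consensus codes, no
  phylogeny-aware or ML codon models, no site-specific positive-selection
  tests, no recombination inference — all outside this pipeline's scope.
* Read mapping itself is upstream: the package consumes SAM from any
  mapper and begins at the recruitment filter.
* The full-scale published numbers (recruitment counts, per-population
  mean ratios, the homolog regression) require the real reference genomes
  and the deposited metagenome and are not reproduced offline; the
  validation experiments are their desk-scale analogues.
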