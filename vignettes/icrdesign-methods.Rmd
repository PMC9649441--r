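---
title: "Methods: constrained ICR sequence design and single-molecule methylation calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained ICR sequence design and single-molecule methylation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icrdesign)
```

# The problem

Imprinting control regions (ICRs) can stably propagate either of two
opposite DNA methylation states on the same sequence. To separate the
contribution of the primary DNA sequence from that of bulk composition
(length, GC%, CpG number and spacing), one needs sequence variants that
scramble the inter-CpG text while holding composition fixed, plus a
single-molecule readout of the methylation patterns that result. This
vignette documents the models, algorithms, parameter choices and known
limitations of the package's implementation of that programme.

# Coordinates and conventions

Every coordinate in the package is 0-based and half-open: a CpG "at 10"
occupies offsets 10 and 11; a window `[0, 1000)` is the first kilobase.
BED and TSV outputs use the same convention natively. GC fraction excludes
N bases from both numerator and denominator; CpG density per 100 bp uses
the total length.

# Constrained inter-CpG shuffling

## Model

The shuffled variant is an exact permutation of the input bases subject to:

1. **Grid preservation.** Bases at CpG dinucleotide positions are never
   moved: `cpg_positions(shuffled) == cpg_positions(original)` byte for
   byte.
2. **Local GC preservation.** Bases are only permuted *within* tiles of
   `local_gc_window` bp (default 100 bp), so each tile's base multiset —
   hence its GC content — is preserved exactly. The `local_gc_tolerance`
   parameter (default 0) only becomes meaningful if cross-tile moves are
   ever enabled; with the default algorithm the audit always reports a
   maximal per-tile deviation of exactly 0.
3. **No new CpGs.** No CG dinucleotide may appear outside the original
   grid (`forbid_new_cpg`, default on).
4. **No forbidden motifs.** By default the ZFP57 hexanucleotide TGCCGC and
   its reverse complement GCGGCA may not occur in the output, so motif
   disruption is guaranteed by construction rather than by chance.

## Algorithm

Per-tile Fisher–Yates permutation of the inter-CpG positions, then a repair
phase (bounded at 2,000 attempts) that removes any constraint violation by
within-tile swaps, then hill-climbing: random within-tile pair swaps are
accepted only when they strictly increase the number of positions differing
from the original and keep the sequence violation-free. The mismatch
trajectory is therefore non-decreasing by construction, and termination is
by target reached, proposal budget (`max_iterations`, default 200,000),
5,000-proposal stall, or saturation (every inter-CpG position already
differs). An infeasible target yields an explicit `target_not_reached`
status with the best result found — never a silent partial result.

Whether a published mismatch threshold such as 78% refers to inter-CpG
positions or the whole sequence is ambiguous in the field's usage; the
package optimises and reports the inter-CpG fraction (`mismatch_inter_cpg`,
the positions actually permuted) and reports `mismatch_total` alongside for
transparency. On the package's reference synthetic element (3 kb, GC 0.60,
120 CpGs) MAXIMIZE mode saturates near 100% inter-CpG mismatch, comfortably
above the 78% design target; whether one resamples random permutations until
a target or performs a directed search is an implementation freedom — the
hill-climb is this package's choice, made for determinism and speed.

## Motif reconstitution

`reconstitute_motifs()` byte-copies motif spans (hit coordinates on the
original) back into the shuffled variant. Which spans to restore is a user
decision — exact hexanucleotide hits are the default scan, but any hit
table can be supplied (e.g. extended footprints from a trained model). If
copying creates a CG dinucleotide straddling a splice junction that neither
input carried, the junction base on the *shuffled* side is substituted
(C→T before a span, G→A after), because motif bases must stay intact; the
repaired offsets are reported and a post-scan asserts a hit at every
requested coordinate.

# Sequence twins

`find_twins()` scans a genome at the query's length and ranks windows by

\[ d = w_1\,|\Delta GC| + w_2\,\frac{|\Delta n_{CpG}|}{\max(n_{CpG})} +
     w_3\,KS(\text{spacings}) \]

with default weights 1:1:1. The spacing term is the two-sample
Kolmogorov–Smirnov statistic between the CpG-spacing distributions —
chosen because "similar distribution" is otherwise unoperationalised, KS is
scale-free, bounded in [0, 1] like the other two terms, and sensitive to
the short/long gap mixture that distinguishes clustered ICR-like elements.
The distance is a pseudo-metric: non-negative, symmetric, zero on identical
profiles. Published selections of composition-matched elements do not state
their metric or tolerances; this weighted distance is a reasoned stand-in
and ranked output should be treated as a candidate list, not a significance
statement.

Exactness/efficiency trade-off: the GC and CpG-count terms are computed for
every window from cumulative arrays; the spacing term only for a candidate
pool (default 2,000 windows) preselected by the cheap partial distance,
which lower-bounds the full distance. A greedy non-overlapping sweep is
added to the pool so at least `top_k` mutually non-overlapping candidates
are always scored. Overlapping hits are merged to the best-scoring offset;
ties break lexicographically on (contig, start), so output order is a
deterministic contract. Windows with more than 10% Ns are skipped and
counted (the choice of 10% is this package's; genome scans rarely hinge on
it at amplicon/toy scale).

# Walking-swap contribution scan

`walking_swap_scan()` implements the saturation replacement scheme: a
`window` (default 10 nt) of the base sequence is replaced by the
same-coordinate window of a donor and shifted by `step` (default 1 bp),
giving L − w + 1 variants at step 1. The scorer is pluggable; the built-ins
(both-strand exact motif count; PWM log-odds sum against the sequence's own
base frequencies with a 0.5 pseudo-count per base) are desk-scale stand-ins
for a trained sequence-to-binding model, which is out of scope. A caveat
that matters when interpreting profiles: a swapped window can create a
motif *straddling* the splice boundary; the tests therefore verify the
profile against brute-force enumeration of every variant rather than
against naive span logic.

# Single-molecule bisulfite analysis

## Conversion model

On the original-top (OT) strand every unmethylated cytosine — all non-CpG
Cs, and CpG Cs in the UNMETH state — converts to T with probability
`conversion_rate`; methylated CpG Cs are retained. The original-bottom (OB)
strand applies the same rule to the reverse complement, treating CpG
methylation as symmetric. Sequencing errors are independent uniform
substitutions applied after conversion. CHH/CHG methylation is not
modelled (the analysis concerns CpG methylation only).

## Alignment and calling

Reads are aligned to the amplicon reference with Needleman–Wunsch-style
global-in-read alignment (`Biostrings::pairwiseAlignment`, type
"global-local"; match +1, mismatch −1, linear gap −2) in
bisulfite-collapsed space: both read and reference collapsed C→T (OT-type
forms) or G→A (OB-type forms), so conversion never penalises the
alignment. Directional mode tries the OT and OB forms; non-directional mode
additionally tries CTOT and CTOB (the complement strands), with score ties
broken by the fixed priority OT > OB > CTOT > CTOB (logged per read). Calls
are made from the read's *original* base at the informative column: the CpG
C (C = METH, T = UNMETH) on C→T forms, the CpG G (G = METH, A = UNMETH) on
G→A forms; gaps, Ns and uncovered sites are MISSING, never imputed.

## QC and summaries

Per-read QC: conversion rate measured on non-CpG cytosines (guanines for
OB-type forms) and collapsed-space identity; defaults `min_conversion`
0.95, `min_identity` 0.90 are QUMA-style stand-ins — the thresholds used in
published amplicon analyses are typically not stated — and are
configurable. Summaries report per-site METH/(METH+UNMETH) over non-missing
calls and an unweighted mean over sites passing the coverage filter;
`min_coverage` 500 reproduces the targeted-amplicon rule ("exclude CpGs
covered less than 500 times"), 10 the whole-genome-scale rule.

# Synthetic data: the stated world

`generate_sequence()` places exactly `n_cpg` CG dinucleotides (uniform or
clustered spacing), fills inter-CpG positions with an exact base count
hitting the GC target (realised GC within one base of target, always within
the ±0.02 contract), and repairs accidental CGs by composition-preserving
swaps. The clustered spacing model is a two-component geometric gap mixture
— short gaps with mean 10 bp (probability 0.7) and long gaps with mean
60 bp — mimicking the visual clustering of CpGs in ICR elements; the
parameters are configurable and are a modelling choice, not a measured
property of any specific locus.

`generate_reads()` simulates full-length amplicon molecules (no
fragmentation — the bisulfite-PCR setting), drawing molecule states from
BIMODAL (fraction `f` fully methylated — the maintained, imprint-like
population), DISORDERED (each CpG independently methylated with probability
`p` per molecule — the intermediate state observed when sequence
information is removed; 0.403 and 0.235 are the study-scale scenario
values), or PER_SITE (explicit per-CpG probabilities). Defaults
`conversion_rate` 0.99 and `error_rate` 0.001 reflect routine bisulfite
amplicon practice (near-complete conversion controls; Illumina-scale
substitution error). Ground truth is always returned with the data.

What the generator does **not** emulate: PCR amplification bias (the
two-annealing-temperature protocol is summarised as uniform sampling),
strand-specific conversion failure, real genomic repeat structure and k-let
composition beyond GC/CpG, and real ICR sequences themselves (no genome
download). A green recovery test therefore establishes the pipeline's
correctness on its stated model, not performance on any particular real
locus.

# Numerical and degenerate-input choices

- A CpG-only sequence (no inter-CpG base) shuffles to itself with status
  `degenerate`; Ns are rejected for shuffling (permuting Ns is undefined).
- `mismatch()` on an empty mask returns 0 with a warning rather than NaN.
- An all-N sequence has undefined GC and is rejected explicitly.
- Empty spacing sets in the KS term: both empty → 0; exactly one empty → 1.
- The binomial consistency checks in the tests use pooled exact binomial
  tests at α = 0.01 and 99% normal-approximation intervals at n = 2,000
  molecules; at those sizes the ~1% conversion-failure bias
  (≈ (1−p)·0.01 upward) stays well inside the interval.
- Property sweeps are sized to keep the default suite inside a desk-scale
  budget (e.g. 250 generator specs, 500 shuffle audits, 1,000 CpG-scan
  comparisons); each is a fixed-seed loop and scales up by editing one
  constant.

# Known limitations

- The twin-search pool preselection is exact for the GC/CpG terms but
  bounds the spacing term only through pool membership; pathological
  genomes where thousands of windows tie on composition but differ in
  spacing could in principle displace a true twin from a small pool
  (increase `pool_size` if in doubt).
- The hill-climb maximises mismatch greedily; it is not guaranteed to find
  the global constrained optimum (it demonstrably exceeds the 78% design
  target with large margin on realistic compositions).
- The aligner is an amplicon-scale tool: quadratic alignment per read, no
  indexing, no paired-end awareness; it is not a WGBS aligner.
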