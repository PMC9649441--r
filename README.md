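# icrdesign

Tools for asking whether the DNA sequence of an imprinting control region
(ICR) — beyond its size, GC content and CpG arrangement — carries the
information needed for epigenetic memory, and for reading out the answer in
single-molecule bisulfite data.

ICRs such as the *Airn* element maintain two opposite, heritable DNA
methylation states on an identical sequence. Dissecting what the sequence
itself contributes requires designed variants that change the sequence while
holding its composition fixed, and assays that measure per-molecule
methylation patterns. `icrdesign` implements the computational side of that
programme:

- **Constrained inter-CpG shuffling** — permute only the bases *between*
  CpGs, preserving the exact number and position of every CG dinucleotide
  and the local GC content (exact, per tile), while hill-climbing the
  positionwise mismatch to the original above a target (e.g. 78%). Variants
  are guaranteed free of new CpGs and of ZFP57 binding motifs.
- **ZFP57 motif tools** — scan for the hexanucleotide `TGCCGC` (bound by
  ZFP57 when the internal CpG is methylated) on both strands, report
  disruption, and splice the original motif spans back into a shuffled
  variant (`reconstitute_motifs`), with junction repair so no spurious CpG
  appears at splice boundaries.
- **Sequence-twin search** — scan a genome in windows of the query's length
  and rank windows by a weighted distance on GC%, CpG count and the
  Kolmogorov–Smirnov distance between CpG-spacing distributions: find
  elements "highly similar in size, GC%, CpG number and distribution".
- **Walking-swap contribution scan** — replace a sliding 10-bp window of one
  sequence with the same-coordinate window of another, score every variant
  with a pluggable scorer (motif count or PWM log-odds stand-ins for a
  trained sequence model), and profile the score deltas.
- **Single-molecule bisulfite analysis** — QUMA-style amplicon pipeline:
  in-silico conversion, global alignment in bisulfite-collapsed space
  (directional or non-directional, four strand forms OT/OB/CTOT/CTOB),
  per-CpG METH/UNMETH/MISSING calls per molecule, conversion/identity QC,
  and coverage-filtered summaries (e.g. exclude CpGs covered < 500×).
- **Synthetic data** — generators for CpG-island-like sequences with exact
  CpG counts and target GC, toy genomes with planted twins, and bisulfite
  read sets under bimodal (maintained) or disordered (intermediate, e.g.
  per-CpG probability 0.403 or 0.235) epiallele scenarios, always with
  ground truth attached.

All coordinates are 0-based, half-open, everywhere (functions, TSV, BED).

## Worked example

```r
library(icrdesign)

## an ICR-like element: 3 kb, GC 0.60, 120 CpGs in clustered spacing
gs <- generate_sequence(sequence_spec(3000, 0.60, 120, "clustered", seed = 7),
                        id = "icr_like")
profile_sequence(gs)
#> sequence_profile: 3000 bp, GC 0.600, 120 CpGs (4.00 / 100 bp), 30 local-GC tiles

## shuffle the inter-CpG sequence, maximizing mismatch under all constraints
res <- shuffle_inter_cpg(gs, shuffle_constraints(seed = 7))
res
#> shuffle_result 'icr_like' (ok): inter-CpG mismatch 100.0%, total 92.0%
#>   grid identical: TRUE; permutation: TRUE; novel CpGs: 0; forbidden hits: 0

disruption_report(gs, res$shuffled)$fully_disrupted   # all ZFP57 motifs gone
#> TRUE

## simulate a disordered epiallele population and call it back
ref <- generate_sequence(sequence_spec(300, 0.55, 15, "clustered", seed = 3),
                         id = "amplicon")
sim <- generate_reads(ref, epiallele_scenario("DISORDERED", p = 0.403,
                                              n_molecules = 200,
                                              conversion_rate = 0.99,
                                              error_rate = 0.001, seed = 8))
mat <- call_matrix(sim$reads, ref, mode = "directional")
mat
#> methylation_calls on 'amplicon': 199 molecules x 15 CpG sites (1 reads failed QC)
summarize_methylation(mat, min_coverage = 10)
#> methylation_summary: 15/15 sites retained (min coverage 10), aggregate 0.403
```

The shuffle result says: every CpG of the original is still a CpG at the
same offset, the variant is an exact permutation of the original's bases
(local GC untouched), no CpG or ZFP57 motif was created, and every inter-CpG
base differs from the original. The bisulfite run recovers the simulated
disordered methylation level (0.403) from the called molecules.

## Command line

```sh
exec/icrdesign shuffle --fasta icr.fa --out shuffled.fa --maximize \
    --seed 7 --report audit.json
exec/icrdesign twins --fasta genome.fa --query icr.fa --out twins.tsv \
    --top-k 5
exec/icrdesign bs-call --reference amp.fa --reads reads.fq \
    --matrix lollipop.tsv --summary summary.tsv --min-coverage 500
exec/icrdesign simulate-sequence --out synth.fa --length 3000 --gc 0.6 \
    --n-cpg 120 --seed 7
```

Every subcommand with a fixed `--seed` is byte-identical across runs; data
go to files, logs to stderr; `--manifest run.json` records the effective
configuration.

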