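Package: icrdesign
Title: Sequence Design and Single-Molecule Methylation Analysis for
    Imprinting Control Regions
Version: 0.1.0
Authors@R:
    person("ICR", "Design Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing imprinting control region
    (ICR) sequence variants: constrained shuffling of inter-CpG sequence
    that preserves local GC content and the exact number and position of
    CpG dinucleotides, disruption and reconstitution of ZFP57 binding
    motifs (TGCCGC), genome-window scans for "sequence twins" matching a
    query in size, GC content, CpG number and CpG spacing distribution,
    walking-window sequence-swap contribution scans with pluggable
    scorers, and QUMA-style single-molecule bisulfite amplicon analysis
    (in-silico conversion, bisulfite-space alignment, per-CpG calling,
    QC and coverage-filtered summaries).  A synthetic-data module
    generates CpG-island-like sequences, toy genomes with planted twins,
    and bisulfite read sets under bimodal or disordered epiallele
    scenarios, so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
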