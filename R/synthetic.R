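#' Specification for a CpG-island-like synthetic sequence
#'
#' @param length Sequence length in bp.
#' @param gc_fraction Target overall GC fraction in (0, 1); the realised value
#'   is exact to within one base in the inter-CpG fill (always within 0.02).
#' @param n_cpg Exact number of CG dinucleotides to place (`2 * n_cpg <=
#'   length`).
#' @param spacing_model `"uniform"` (CpGs placed uniformly at random) or
#'   `"clustered"` (two-component gap mixture, short gaps around
#'   `short_gap` bp and long gaps around `long_gap` bp, mimicking the CpG
#'   clustering of ICRs).
#' @param short_gap,long_gap,p_short Clustered-model parameters: mean short
#'   and long inter-CpG gap (bp) and the probability of a short gap.
#' @param seed Integer seed.
#' @return A `sequence_spec` list.
#' @export
sequence_spec <- function(length, gc_fraction, n_cpg,
                          spacing_model = c("uniform", "clustered"),
                          short_gap = 10, long_gap = 60, p_short = 0.7,
                          seed = 1L) {
  spacing_model <- match.arg(spacing_model)
  length <- as.integer(length); n_cpg <- as.integer(n_cpg)
  if (length < 1L) stop("'length' must be >= 1")
  if (n_cpg < 0L || 2L * n_cpg > length)
    stop("need 2 * n_cpg <= length")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("'gc_fraction' must be in (0, 1)")
  structure(list(length = length, gc_fraction = gc_fraction, n_cpg = n_cpg,
                 spacing_model = spacing_model, short_gap = short_gap,
                 long_gap = long_gap, p_short = p_short,
                 seed = as.integer(seed)),
            class = "sequence_spec")
}

#' Generate a CpG-island-like sequence
#'
#' Places exactly `n_cpg` CG dinucleotides according to the spacing model,
#' fills the inter-CpG positions with an exact base composition chosen to hit
#' the target GC fraction, then repairs accidental CG dinucleotides created by
#' the fill (base swaps among inter-CpG positions, preserving composition).
#' Deterministic under the spec's seed.
#'
#' @param spec A [sequence_spec()].
#' @param id Sequence id.
#' @return A `genomic_sequence` with exactly `spec$n_cpg` CpGs and realised GC
#'   within 0.02 of the target.
#' @export
generate_sequence <- function(spec, id = "synthetic") {
  if (!inherits(spec, "sequence_spec")) stop("'spec' must be a sequence_spec")
  set.seed(spec$seed)
  n <- spec$length; k <- spec$n_cpg
  n_inter <- n - 2L * k
  ## feasibility: CpGs alone contribute 2k GC bases
  gc_total <- round(spec$gc_fraction * n)
  gc_inter <- gc_total - 2L * k
  if (gc_inter < 0L)
    stop(sprintf(
      "infeasible spec: %d CpGs force GC fraction >= %.3f (target %.3f)",
      k, 2 * k / n, spec$gc_fraction))
  if (gc_inter > n_inter)
    stop(sprintf(
      "infeasible spec: GC target %.3f needs %d GC bases among %d inter-CpG positions",
      spec$gc_fraction, gc_inter, n_inter))
  starts <- place_cpgs(n, k, spec)
  ch <- rep(NA_character_, n)
  if (k > 0L) { ch[starts + 1L] <- "C"; ch[starts + 2L] <- "G" }
  inter <- which(is.na(ch))
  bases <- character(0)
  if (n_inter > 0L) {
    n_c <- gc_inter %/% 2L; n_g <- gc_inter - n_c
    n_a <- (n_inter - gc_inter) %/% 2L; n_t <- n_inter - gc_inter - n_a
    bases <- sample(c(rep("C", n_c), rep("G", n_g),
                      rep("A", n_a), rep("T", n_t)))
    ch[inter] <- bases
  }
  ## repair accidental CGs (both members always inter-CpG positions)
  grid_target <- starts
  for (pass in 1:200) {
    s <- paste(ch, collapse = "")
    extra <- setdiff(cpg_positions(s), grid_target)
    if (length(extra) == 0L) break
    for (p0 in extra) {
      i <- p0 + 1L  # the C (1-based); inter by construction
      cand <- inter[ch[inter] != "C"]
      if (length(cand) == 0L) break
      j <- cand[sample.int(length(cand), 1L)]
      tmp <- ch[i]; ch[i] <- ch[j]; ch[j] <- tmp
    }
  }
  s <- paste(ch, collapse = "")
  extra <- setdiff(cpg_positions(s), grid_target)
  if (length(extra) > 0L)
    stop("could not repair accidental CpGs; spec too dense")
  out <- genomic_sequence(id, s)
  realized <- profile_sequence(s)$gc_fraction
  if (abs(realized - spec$gc_fraction) > 0.02)
    stop(sprintf("realised GC %.4f deviates from target %.4f by > 0.02",
                 realized, spec$gc_fraction))
  out
}

## choose 0-based CpG start positions with pairwise gaps >= 2
place_cpgs <- function(n, k, spec) {
  if (k == 0L) return(integer(0))
  if (spec$spacing_model == "uniform") {
    ## non-decreasing draws q from 0..n-2k map to starts with pairwise gap >= 2
    q <- sort(sample.int(n - 2L * k + 1L, k, replace = TRUE) - 1L)
    return(q + 2L * (seq_len(k) - 1L))
  }
  ## clustered: gaps from a two-component geometric mixture, min gap 2
  for (try in 1:100) {
    short <- stats::rgeom(k, 1 / spec$short_gap)
    long <- stats::rgeom(k, 1 / spec$long_gap)
    gaps <- ifelse(stats::runif(k) < spec$p_short, short, long) + 2L
    pos <- cumsum(gaps) - gaps[1L]
    if (pos[k] + 2L <= n) {
      shift <- sample.int(n - (pos[k] + 2L) + 1L, 1L) - 1L
      return(pos + shift)
    }
  }
  ## dense spec: fall back to a compact centred block (feasible since 2k <= n)
  2L * (seq_len(k) - 1L) + (n - 2L * k) %/% 2L
}

#' Plant a twin of a query sequence in a toy genome
#'
#' Builds a random genome (uniform base composition at a given GC fraction)
#' and inserts either the query verbatim or a "disguised twin": a
#' shuffle-module output with the same CpG grid and local GC but different
#' inter-CpG text.  Returns the genome and the planted coordinates for
#' recovery experiments.
#'
#' @param genome_length Total genome length in bp (>= query length).
#' @param n_contigs Number of equally sized contigs.
#' @param query A `genomic_sequence`.
#' @param disguise `"VERBATIM"` or `"KEEP_GRID_RESHUFFLE"`.
#' @param gc Background genome GC fraction.
#' @param seed Integer seed.
#' @param position Optional forced 0-based insert offset within the chosen
#'   contig (e.g. 0 to test the edge); default random.
#' @return List with `genome` (list of `genomic_sequence`), `contig`, `start`,
#'   `end` (0-based half-open planted coordinates) and `planted`
#'   (the inserted `genomic_sequence`).
#' @export
plant_twin <- function(genome_length, query,
                       disguise = c("KEEP_GRID_RESHUFFLE", "VERBATIM"),
                       n_contigs = 1L, gc = 0.5, seed = 1L, position = NULL) {
  disguise <- match.arg(disguise)
  query <- as_genomic_sequence(query, id = "query")
  qlen <- nchar(query$seq)
  genome_length <- as.integer(genome_length)
  n_contigs <- as.integer(n_contigs)
  clen <- genome_length %/% n_contigs
  if (clen < qlen) stop("contigs shorter than the query")
  set.seed(seed)
  insert <- if (disguise == "VERBATIM") query$seq else {
    res <- shuffle_inter_cpg(query, shuffle_constraints(
      seed = seed + 1L, max_iterations = 5000L, forbid_motifs = NULL))
    res$shuffled$seq
  }
  genome <- vector("list", n_contigs)
  for (i in seq_len(n_contigs)) {
    b <- sample(c("A", "C", "G", "T"), clen, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    genome[[i]] <- genomic_sequence(sprintf("contig%02d", i),
                                    paste(b, collapse = ""))
  }
  ci <- sample.int(n_contigs, 1L)
  pos0 <- if (!is.null(position)) as.integer(position)
          else sample.int(clen - qlen + 1L, 1L) - 1L
  s <- genome[[ci]]$seq
  genome[[ci]]$seq <- paste0(substr(s, 1L, pos0),
                             insert,
                             substr(s, pos0 + qlen + 1L, clen))
  list(genome = genome, contig = genome[[ci]]$id,
       start = pos0, end = pos0 + qlen,
       planted = genomic_sequence("planted", insert))
}

#' Epiallele simulation scenario
#'
#' Describes the distribution of single-molecule methylation patterns:
#' `BIMODAL` (a fraction `f` of molecules fully methylated, the rest fully
#' unmethylated — the maintained, imprinted-like state), `DISORDERED` (every
#' CpG methylated independently with probability `p` on each molecule — the
#' intermediate, disordered state observed when sequence information is
#' removed; study-scale values 0.403 and 0.235) or `PER_SITE` (an explicit
#' per-CpG probability vector).
#'
#' @param mode `"BIMODAL"`, `"DISORDERED"` or `"PER_SITE"`.
#' @param f Fully-methylated fraction (BIMODAL).
#' @param p Per-CpG methylation probability (DISORDERED).
#' @param per_site Numeric probability vector (PER_SITE).
#' @param n_molecules Number of molecules (>= 1).
#' @param conversion_rate,error_rate Passed to [convert_in_silico()].
#' @param ot_fraction Fraction of molecules read from the OT strand.
#' @param seed Integer seed.
#' @return An `epiallele_scenario` list.
#' @export
epiallele_scenario <- function(mode = c("DISORDERED", "BIMODAL", "PER_SITE"),
                               f = 0.5, p = 0.5, per_site = NULL,
                               n_molecules = 100L, conversion_rate = 0.99,
                               error_rate = 0.001, ot_fraction = 0.5,
                               seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(f >= 0, f <= 1, p >= 0, p <= 1,
            conversion_rate >= 0, conversion_rate <= 1,
            error_rate >= 0, error_rate <= 1,
            ot_fraction >= 0, ot_fraction <= 1, n_molecules >= 1)
  if (mode == "PER_SITE" &&
      (is.null(per_site) || any(per_site < 0) || any(per_site > 1)))
    stop("PER_SITE mode needs a probability vector 'per_site'")
  structure(list(mode = mode, f = f, p = p, per_site = per_site,
                 n_molecules = as.integer(n_molecules),
                 conversion_rate = conversion_rate, error_rate = error_rate,
                 ot_fraction = ot_fraction, seed = as.integer(seed)),
            class = "epiallele_scenario")
}

#' Simulate a bisulfite read set under an epiallele scenario
#'
#' Draws per-molecule methylation states from the scenario, converts each
#' molecule in silico (full-length amplicon reads; OT or OB strand per
#' molecule) and returns the reads together with the ground-truth state
#' matrix, so recovery tests never have to infer truth from the data.
#'
#' @param reference A `genomic_sequence` or string.
#' @param scenario An [epiallele_scenario()].
#' @return List with `reads` (list of `bisulfite_read`), `states` (logical
#'   matrix molecules x CpGs, TRUE = methylated), `strands`.
#' @export
generate_reads <- function(reference, scenario) {
  if (!inherits(scenario, "epiallele_scenario"))
    stop("'scenario' must be an epiallele_scenario")
  ref <- as_genomic_sequence(reference, id = "reference")
  grid0 <- cpg_positions(ref$seq)
  k <- length(grid0)
  set.seed(scenario$seed)
  m <- scenario$n_molecules
  states <- switch(scenario$mode,
    BIMODAL = {
      full <- stats::runif(m) < scenario$f
      matrix(rep(full, each = k), nrow = m, ncol = k, byrow = TRUE)
    },
    DISORDERED = matrix(stats::runif(m * k) < scenario$p, nrow = m),
    PER_SITE = {
      if (length(scenario$per_site) != k)
        stop("'per_site' must have one probability per CpG (", k, ")")
      t(vapply(seq_len(m),
               function(i) stats::runif(k) < scenario$per_site,
               logical(k)))
    })
  if (k == 0L) states <- matrix(logical(0), nrow = m, ncol = 0L)
  strands <- ifelse(stats::runif(m) < scenario$ot_fraction, "OT", "OB")
  reads <- vector("list", m)
  for (i in seq_len(m)) {
    reads[[i]] <- convert_in_silico(
      ref, states[i, ], conversion_rate = scenario$conversion_rate,
      strand = strands[i], error_rate = scenario$error_rate,
      id = sprintf("mol%05d", i))
  }
  list(reads = reads, states = states, strands = strands)
}
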