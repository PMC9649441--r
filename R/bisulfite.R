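#' Bisulfite reads
#'
#' A bisulfite read is a converted amplicon sequence with an optional library
#' strand label: OT/OB (original top/bottom converted strands) or CTOT/CTOB
#' (their complements, seen in non-directional libraries).
#'
#' @param id Read id.
#' @param seq DNA string over ACGTN.
#' @param library_strand One of OT, OB, CTOT, CTOB, UNKNOWN (informational;
#'   alignment decides the strand form from the data).
#' @return A `bisulfite_read` object.
#' @export
bisulfite_read <- function(id, seq, library_strand = "UNKNOWN") {
  gs <- genomic_sequence(id, seq)
  if (!library_strand %in% c("OT", "OB", "CTOT", "CTOB", "UNKNOWN"))
    stop("invalid library_strand")
  structure(list(id = gs$id, seq = gs$seq, library_strand = library_strand),
            class = "bisulfite_read")
}

#' QC thresholds for bisulfite reads
#'
#' QUMA-style defaults: a read passes when its non-CpG conversion rate is at
#' least `min_conversion` and its collapsed-space alignment identity at least
#' `min_identity`.
#'
#' @param min_conversion,min_identity Fractions in \[0, 1\].
#' @return A `bs_qc_thresholds` list.
#' @export
bs_qc_thresholds <- function(min_conversion = 0.95, min_identity = 0.90) {
  stopifnot(min_conversion >= 0, min_conversion <= 1,
            min_identity >= 0, min_identity <= 1)
  structure(list(min_conversion = min_conversion, min_identity = min_identity),
            class = "bs_qc_thresholds")
}

#' Simulate bisulfite conversion of one molecule
#'
#' Applies in-silico bisulfite chemistry to a reference molecule with known
#' per-CpG methylation states.  On the original top (OT) strand every
#' unmethylated cytosine (all non-CpG Cs, and CpG Cs whose state is UNMETH)
#' converts to T with probability `conversion_rate`; methylated CpG Cs are
#' retained.  The OB strand applies the symmetric rule to the reverse
#' complement (CpG methylation is treated as symmetric).  Independent uniform
#' substitution errors are applied afterwards at `error_rate`.
#'
#' @param reference A `genomic_sequence` or string (no Ns for simulation).
#' @param molecule_states Character (`"METH"`/`"UNMETH"`) or logical vector,
#'   one state per CpG of the reference.
#' @param conversion_rate,error_rate Probabilities in \[0, 1\].
#' @param strand `"OT"` or `"OB"`.
#' @param id Read id.
#' @return A `bisulfite_read` (5'->3' in its own orientation).
#' @export
convert_in_silico <- function(reference, molecule_states, conversion_rate = 1,
                              strand = c("OT", "OB"), error_rate = 0,
                              id = "read") {
  strand <- match.arg(strand)
  if (conversion_rate < 0 || conversion_rate > 1 ||
      error_rate < 0 || error_rate > 1)
    stop("'conversion_rate' and 'error_rate' must be in [0, 1]")
  ref <- seq_string(reference)
  grid0 <- cpg_positions(ref)
  if (is.logical(molecule_states))
    molecule_states <- ifelse(molecule_states, "METH", "UNMETH")
  if (length(molecule_states) != length(grid0))
    stop("'molecule_states' must cover every CpG of the reference (",
         length(grid0), " sites)")
  work <- if (strand == "OT") ref else reverse_complement(ref)
  ch <- strsplit(work, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  ## positions (1-based, in working orientation) of methyl-protected CpG Cs
  meth_c <- if (strand == "OT") grid0[molecule_states == "METH"] + 1L
            else (n - 1L) - grid0[molecule_states == "METH"]  # bottom C of CpG
  is_c <- which(ch == "C")
  unprotected <- setdiff(is_c, meth_c)
  conv <- unprotected[stats::runif(length(unprotected)) < conversion_rate]
  ch[conv] <- "T"
  if (error_rate > 0) {
    err <- which(stats::runif(n) < error_rate)
    for (i in err) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  bisulfite_read(id, paste(ch, collapse = ""), library_strand = strand)
}

## the four strand forms: orientation of the read and collapse direction
BS_FORMS <- list(
  OT   = list(revcomp = FALSE, collapse = "CT"),
  OB   = list(revcomp = TRUE,  collapse = "GA"),
  CTOT = list(revcomp = TRUE,  collapse = "CT"),
  CTOB = list(revcomp = FALSE, collapse = "GA"))

collapse_seq <- function(s, collapse) {
  if (collapse == "CT") chartr("C", "T", s) else chartr("G", "A", s)
}

#' Align a bisulfite read to an amplicon reference and call methylation
#'
#' Performs a global-in-read alignment in bisulfite-collapsed space (read and
#' reference both collapsed C->T or G->A depending on the strand form) with
#' Needleman-Wunsch style scoring, and calls each reference CpG site from the
#' read's original base at the informative column: on C->T forms the CpG
#' cytosine (C = methylated, T = unmethylated), on G->A forms the CpG guanine
#' (G = methylated, A = unmethylated); anything else (gap, N, off-read) is
#' MISSING.  Directional mode tries the OT and OB forms; non-directional mode
#' additionally tries CTOT and CTOB (four-form search as in
#' non-directional amplicon aligners).  Score ties break by the fixed priority
#' OT > OB > CTOT > CTOB.
#'
#' @param read A `bisulfite_read` (or string).
#' @param reference A `genomic_sequence` or string.
#' @param mode `"directional"` or `"non_directional"`.
#' @param scoring List with `match`, `mismatch`, `gap` (per-base linear gap).
#' @param qc A [bs_qc_thresholds()] object.
#' @return A `bs_alignment` list: `form`, `score`, `identity`,
#'   `conversion_rate`, `pass`, `calls` (character vector METH/UNMETH/MISSING
#'   per reference CpG), `ref_start` (0-based), `n_cpg_covered`.
#' @export
align_bisulfite <- function(read, reference,
                            mode = c("non_directional", "directional"),
                            scoring = list(match = 1, mismatch = -1, gap = -2),
                            qc = bs_qc_thresholds()) {
  mode <- match.arg(mode)
  rs <- if (inherits(read, "bisulfite_read")) read$seq else seq_string(read)
  ref <- seq_string(reference)
  if (nchar(ref) < nchar(rs) / 2)
    stop("reference shorter than half the read: not an amplicon setting")
  grid0 <- cpg_positions(ref)
  forms <- if (mode == "directional") c("OT", "OB")
           else c("OT", "OB", "CTOT", "CTOB")
  best <- NULL
  for (f in forms) {
    spec <- BS_FORMS[[f]]
    oriented <- if (spec$revcomp) reverse_complement(rs) else rs
    al <- bs_form_alignment(oriented, ref, spec$collapse, grid0, scoring)
    al$form <- f
    if (is.null(best) || al$score > best$score) best <- al
  }
  thr <- qc
  conv_ok <- is.na(best$conversion_rate) ||
    best$conversion_rate >= thr$min_conversion
  best$pass <- best$identity >= thr$min_identity && conv_ok
  best$read_id <- if (inherits(read, "bisulfite_read")) read$id else "read"
  class(best) <- "bs_alignment"
  best
}

bs_form_alignment <- function(oriented, ref, collapse, grid0, scoring) {
  cread <- collapse_seq(oriented, collapse)
  cref <- collapse_seq(ref, collapse)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(cread),
    subject = Biostrings::DNAString(cref),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE,
      type = "DNA"),
    gapOpening = 0, gapExtension = -scoring$gap)
  ap <- strsplit(as.character(Biostrings::pattern(al)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::subject(al)), "")[[1L]]
  ref_pos <- Biostrings::start(Biostrings::subject(al))  # 1-based in cref
  read_pos <- Biostrings::start(Biostrings::pattern(al))
  och <- strsplit(oriented, "", fixed = TRUE)[[1L]]
  rch <- strsplit(ref, "", fixed = TRUE)[[1L]]
  ## map: reference 1-based position -> original read base at that column
  read_base_at <- rep(NA_character_, nchar(ref))
  rp <- ref_pos; qp <- read_pos
  for (k in seq_along(ap)) {
    if (ap[k] != "-" && as_[k] != "-") {
      read_base_at[rp] <- och[qp]
      rp <- rp + 1L; qp <- qp + 1L
    } else if (ap[k] == "-") {
      rp <- rp + 1L
    } else {
      qp <- qp + 1L
    }
  }
  identity <- if (length(ap)) mean(ap == as_ & ap != "-") else 0
  ## methylation calls at CpG sites
  calls <- rep("MISSING", length(grid0))
  if (length(grid0)) {
    if (collapse == "CT") {
      b <- read_base_at[grid0 + 1L]
      calls[!is.na(b) & b == "C"] <- "METH"
      calls[!is.na(b) & b == "T"] <- "UNMETH"
    } else {
      b <- read_base_at[grid0 + 2L]
      calls[!is.na(b) & b == "G"] <- "METH"
      calls[!is.na(b) & b == "A"] <- "UNMETH"
    }
  }
  ## conversion QC on non-CpG cytosines (C->T forms) / guanines (G->A forms)
  if (collapse == "CT") {
    qc_pos <- setdiff(which(rch == "C"), grid0 + 1L)
    b <- read_base_at[qc_pos]
    n_conv <- sum(b == "T", na.rm = TRUE)
    n_tot <- sum(b %in% c("C", "T"), na.rm = TRUE)
  } else {
    qc_pos <- setdiff(which(rch == "G"), grid0 + 2L)
    b <- read_base_at[qc_pos]
    n_conv <- sum(b == "A", na.rm = TRUE)
    n_tot <- sum(b %in% c("G", "A"), na.rm = TRUE)
  }
  list(score = Biostrings::score(al),
       identity = identity,
       conversion_rate = if (n_tot > 0L) n_conv / n_tot else NA_real_,
       calls = calls,
       ref_start = ref_pos - 1L,
       n_cpg_covered = sum(calls != "MISSING"))
}

#' Build the single-molecule methylation call matrix
#'
#' Aligns every read to the reference, applies read QC, and assembles the
#' molecules x CpG-sites "lollipop" matrix: 1 = methylated, 0 = unmethylated,
#' NA = missing.  One row per passing read; QC failures are logged with their
#' statistics in the `qc` table.
#'
#' @param reads List of `bisulfite_read` (or strings).
#' @param reference A `genomic_sequence` or string.
#' @param qc A [bs_qc_thresholds()] object.
#' @param mode Alignment mode, see [align_bisulfite()].
#' @return A `methylation_calls` object: `reference_id`, `cpg_sites` (0-based
#'   grid), `calls` (integer matrix with NA for missing), `qc` (per-read
#'   data.frame), `status` (`"ok"` or `"no_passing_reads"`).
#' @export
call_matrix <- function(reads, reference, qc = bs_qc_thresholds(),
                        mode = c("non_directional", "directional")) {
  mode <- match.arg(mode)
  if (length(reads) == 0L) stop("need at least one read")
  ref <- as_genomic_sequence(reference, id = "reference")
  grid0 <- cpg_positions(ref$seq)
  rows <- list(); qcl <- list()
  for (i in seq_along(reads)) {
    al <- align_bisulfite(reads[[i]], ref, mode = mode, qc = qc)
    qcl[[i]] <- data.frame(
      read_id = al$read_id, form = al$form, score = al$score,
      identity = al$identity, conversion_rate = al$conversion_rate,
      pass = al$pass)
    if (al$pass)
      rows[[length(rows) + 1L]] <-
        ifelse(al$calls == "METH", 1L, ifelse(al$calls == "UNMETH", 0L, NA))
  }
  qcdf <- do.call(rbind, qcl)
  if (length(rows) == 0L) {
    calls <- matrix(NA_integer_, nrow = 0L, ncol = length(grid0))
    status <- "no_passing_reads"
  } else {
    calls <- do.call(rbind, rows)
    status <- "ok"
  }
  colnames(calls) <- grid0
  rownames(calls) <- qcdf$read_id[qcdf$pass][seq_len(nrow(calls))]
  structure(list(reference_id = ref$id, cpg_sites = grid0, calls = calls,
                 qc = qcdf, status = status), class = "methylation_calls")
}

#' @export
print.methylation_calls <- function(x, ...) {
  cat(sprintf(
    "methylation_calls on '%s': %d molecules x %d CpG sites (%d reads failed QC)\n",
    x$reference_id, nrow(x$calls), length(x$cpg_sites), sum(!x$qc$pass)))
  invisible(x)
}

#' Summarise a methylation call matrix
#'
#' Per-site methylation fraction METH / (METH + UNMETH) over non-missing
#' calls, with a coverage filter: sites covered by fewer than `min_coverage`
#' informative calls are excluded from the aggregate and enumerated.  The
#' aggregate is the unweighted mean over retained sites.  The study-scale
#' defaults for `min_coverage` are 500 for targeted amplicon data and 10 for
#' whole-genome-scale data.
#'
#' @param x A `methylation_calls` object.
#' @param min_coverage Minimum informative calls per site (>= 1).
#' @return A `methylation_summary`: data.frame `sites` (site, coverage,
#'   meth_fraction, retained), `aggregate` (NA when no site is retained,
#'   flagged by `all_excluded`), `excluded_sites`, `min_coverage`.
#' @export
summarize_methylation <- function(x, min_coverage = 1L) {
  if (!inherits(x, "methylation_calls")) stop("'x' must be methylation_calls")
  min_coverage <- as.integer(min_coverage)
  if (min_coverage < 1L) stop("'min_coverage' must be >= 1")
  coverage <- colSums(!is.na(x$calls))
  meth <- colSums(x$calls == 1L, na.rm = TRUE)
  frac <- ifelse(coverage > 0L, meth / coverage, NA_real_)
  retained <- coverage >= min_coverage
  sites <- data.frame(site = x$cpg_sites, coverage = as.integer(coverage),
                      meth_fraction = frac, retained = retained)
  aggregate <- if (any(retained)) mean(frac[retained]) else NA_real_
  structure(list(sites = sites,
                 aggregate = aggregate,
                 all_excluded = !any(retained),
                 excluded_sites = x$cpg_sites[!retained],
                 min_coverage = min_coverage),
            class = "methylation_summary")
}

#' @export
print.methylation_summary <- function(x, ...) {
  cat(sprintf(
    "methylation_summary: %d/%d sites retained (min coverage %d), aggregate %s\n",
    sum(x$sites$retained), nrow(x$sites), x$min_coverage,
    if (is.na(x$aggregate)) "undefined (all sites excluded)"
    else sprintf("%.3f", x$aggregate)))
  invisible(x)
}
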