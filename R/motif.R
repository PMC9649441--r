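#' Motif definitions
#'
#' A motif is either an exact/IUPAC pattern string or a position weight matrix
#' (rows A, C, G, T over the motif length, columns summing to 1).  The default
#' is the ZFP57 binding hexanucleotide TGCCGC, which ZFP57 binds when the
#' internal CpG is methylated; scanning operates on the unmethylated text.
#'
#' @param id Motif name.
#' @param pattern IUPAC DNA string (length >= 2), or `NULL` when `pwm` given.
#' @param pwm Optional 4 x L probability matrix with rownames A, C, G, T.
#' @param scan_both_strands Scan the reverse complement as well (default TRUE).
#' @return A `motif_def` object.
#' @export
motif_def <- function(id, pattern = NULL, pwm = NULL, scan_both_strands = TRUE) {
  if (is.null(pattern) == is.null(pwm))
    stop("give exactly one of 'pattern' or 'pwm'")
  if (!is.null(pattern)) {
    pattern <- toupper(pattern)
    if (nchar(pattern) < 2L) stop("pattern length must be >= 2")
    if (grepl(sprintf("[^%s]", paste(names(IUPAC_TABLE), collapse = "")), pattern))
      stop("pattern contains non-IUPAC characters")
  } else {
    if (!is.matrix(pwm) || nrow(pwm) != 4L ||
        !identical(rownames(pwm), c("A", "C", "G", "T")))
      stop("'pwm' must be a 4 x L matrix with rownames A, C, G, T")
    if (any(abs(colSums(pwm) - 1) > 1e-9))
      stop("PWM columns must sum to 1")
  }
  structure(list(id = id, pattern = pattern, pwm = pwm,
                 scan_both_strands = isTRUE(scan_both_strands)),
            class = "motif_def")
}

#' @rdname motif_def
#' @export
zfp57_motif <- function() motif_def("ZFP57", "TGCCGC")

IUPAC_TABLE <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_regex <- function(pattern) {
  paste(IUPAC_TABLE[strsplit(pattern, "", fixed = TRUE)[[1L]]], collapse = "")
}

## all 0-based starts of IUPAC pattern occurrences (overlaps included)
iupac_starts <- function(seq, pattern) {
  rx <- sprintf("(?=%s)", iupac_regex(pattern))
  m <- gregexpr(rx, seq, perl = TRUE)[[1L]]
  if (m[1L] < 0L) integer(0) else as.integer(m) - 1L
}

#' Scan a sequence for motif occurrences
#'
#' Exact/IUPAC mode reports every occurrence on the plus strand and, when
#' enabled, every occurrence of the reverse complement, all in plus-strand
#' 0-based half-open coordinates with the matched text as read on the plus
#' strand.  PWM mode reports windows whose log-odds score (against a
#' background of the sequence's own base frequencies with a 0.5 pseudo-count
#' per base) reaches `pwm_threshold`.  Overlapping hits are all reported.
#'
#' @param x A `genomic_sequence` or DNA string.
#' @param motif A `motif_def` (default the ZFP57 hexanucleotide).
#' @param pwm_threshold Log-odds cutoff, required in PWM mode.
#' @return A data.frame (class `motif_hits`): motif_id, start, end, strand,
#'   matched_text, contains_cpg (and score in PWM mode), sorted by start then
#'   strand (+ before -).
#' @examples
#' find_motifs("TGCCGC")            # one + hit at 0
#' find_motifs("GCGGCA")            # one - hit at 0
#' @export
find_motifs <- function(x, motif = zfp57_motif(), pwm_threshold = NULL) {
  s <- seq_string(x)
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' at 0-based offset %d",
                 substr(s, bad, bad), as.integer(bad) - 1L))
  if (!inherits(motif, "motif_def")) stop("'motif' must be a motif_def")
  if (is.null(motif$pwm)) {
    w <- nchar(motif$pattern)
    plus <- iupac_starts(s, motif$pattern)
    minus <- if (motif$scan_both_strands)
      iupac_starts(s, reverse_complement(motif$pattern)) else integer(0)
    hits <- data.frame(
      motif_id = rep(motif$id, length(plus) + length(minus)),
      start = c(plus, minus),
      strand = rep(c("+", "-"), c(length(plus), length(minus))),
      stringsAsFactors = FALSE)
    ## the palindromic case double-reports; keep both strands as distinct hits
    hits$end <- hits$start + w
  } else {
    if (is.null(pwm_threshold)) stop("'pwm_threshold' is required in PWM mode")
    w <- ncol(motif$pwm)
    lo <- pwm_logodds_matrix(motif$pwm, s)
    sc_p <- pwm_window_scores(s, lo)
    st_p <- which(sc_p >= pwm_threshold) - 1L
    hits <- data.frame(motif_id = rep(motif$id, length(st_p)),
                       start = st_p,
                       strand = rep("+", length(st_p)),
                       score = sc_p[sc_p >= pwm_threshold],
                       stringsAsFactors = FALSE)
    if (motif$scan_both_strands) {
      sc_m <- pwm_window_scores(reverse_complement(s), lo)
      st_m <- which(sc_m >= pwm_threshold) - 1L
      hits <- rbind(hits, data.frame(
        motif_id = rep(motif$id, length(st_m)),
        start = nchar(s) - w - st_m, strand = rep("-", length(st_m)),
        score = sc_m[sc_m >= pwm_threshold], stringsAsFactors = FALSE))
    }
    hits$end <- hits$start + w
  }
  if (nrow(hits) > 0L) {
    hits$matched_text <- substr(rep(s, nrow(hits)), hits$start + 1L, hits$end)
    hits$contains_cpg <- grepl("CG", hits$matched_text, fixed = TRUE)
    hits <- hits[order(hits$start, hits$strand), ]
  } else {
    hits$matched_text <- character(0)
    hits$contains_cpg <- logical(0)
  }
  first <- c("motif_id", "start", "end", "strand", "matched_text", "contains_cpg")
  hits <- hits[, c(first, setdiff(names(hits), first)), drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("motif_hits", "data.frame")
  hits
}

pwm_logodds_matrix <- function(pwm, seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(ch == b) + 0.5, 0)
  bg <- counts / sum(counts)
  log2(pwm / bg)
}

pwm_window_scores <- function(seq, lo) {
  w <- ncol(lo)
  n <- nchar(seq)
  if (n < w) return(numeric(0))
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
  sc <- numeric(n - w + 1L)
  for (k in seq_len(w)) {
    v <- lo[cbind(idx[k:(n - w + k)], k)]
    v[is.na(v)] <- -Inf  # N in window: never a hit
    sc <- sc + v
  }
  sc
}

#' Motif disruption report
#'
#' Compares motif occurrences between an original sequence and a variant
#' (e.g. a constrained shuffle) of the same length.  `fully_disrupted` is TRUE
#' iff the variant has zero hits; when the original itself has no hits the
#' result is vacuously TRUE with a warning.
#'
#' @param original,variant Same-length sequences.
#' @param motif A `motif_def`.
#' @return List with `hits_original`, `hits_variant`, `fully_disrupted`.
#' @export
disruption_report <- function(original, variant, motif = zfp57_motif()) {
  so <- seq_string(original); sv <- seq_string(variant)
  if (nchar(so) != nchar(sv)) stop("sequences must have the same length")
  ho <- find_motifs(so, motif)
  hv <- find_motifs(sv, motif)
  if (nrow(ho) == 0L)
    warning("original sequence has no motif hits; disruption is vacuous")
  list(hits_original = ho, hits_variant = hv,
       fully_disrupted = nrow(hv) == 0L)
}

#' Walking-window sequence-swap contribution scan
#'
#' For each offset, a window of `window` bp in `base` is replaced by the
#' same-coordinate window of `donor` and the variant is scored; the profile of
#' score deltas localises which parts of the donor sequence change the score.
#' This is the saturation "walking replacement" scheme (default 10 nt windows
#' shifted by 1 bp) with a pluggable scorer standing in for a trained
#' sequence-to-activity model.
#'
#' @param base,donor Same-length sequences; `base` is modified, `donor`
#'   supplies the replacement windows.
#' @param window Swap window in bp (default 10), `window <= length`.
#' @param step Offset step in bp (default 1).
#' @param scorer Function mapping a DNA string to a numeric score.
#' @return A `contribution_profile` data.frame (offset, variant_score, delta)
#'   with attributes `baseline_score`, `window`, `step`.
#' @export
walking_swap_scan <- function(base, donor, window = 10L, step = 1L,
                              scorer = motif_count_scorer()) {
  sb <- seq_string(base); sd <- seq_string(donor)
  if (nchar(sb) != nchar(sd)) stop("'base' and 'donor' must have equal length")
  window <- as.integer(window); step <- as.integer(step)
  n <- nchar(sb)
  if (window < 1L || window > n) stop("'window' must be in [1, length]")
  if (step < 1L) stop("'step' must be >= 1")
  baseline <- tryCatch(scorer(sb), error = function(e)
    stop("scorer failed on the baseline sequence: ", conditionMessage(e)))
  offsets <- seq.int(0L, n - window, by = step)
  scores <- numeric(length(offsets))
  for (i in seq_along(offsets)) {
    o <- offsets[i]
    variant <- paste0(substr(sb, 1L, o),
                      substr(sd, o + 1L, o + window),
                      substr(sb, o + window + 1L, n))
    sc <- tryCatch(scorer(variant), error = function(e)
      stop(sprintf("scorer failed at offset %d: %s", o, conditionMessage(e))))
    scores[i] <- sc
  }
  res <- data.frame(offset = offsets, variant_score = scores,
                    delta = scores - baseline)
  attr(res, "baseline_score") <- baseline
  attr(res, "window") <- window
  attr(res, "step") <- step
  class(res) <- c("contribution_profile", "data.frame")
  res
}

#' Built-in scorers for the walking-swap scan
#'
#' `motif_count_scorer` counts exact motif occurrences on both strands;
#' `pwm_logodds_scorer` sums per-window log-odds scores at or above a
#' threshold.  Both return a closure usable as the `scorer` argument of
#' [walking_swap_scan()].
#'
#' @param motif A `motif_def`.
#' @param pwm_threshold Log-odds cutoff for the PWM scorer.
#' @return A function `seq -> numeric score`.
#' @export
motif_count_scorer <- function(motif = zfp57_motif()) {
  force(motif)
  function(seq) {
    s <- seq_string(seq)
    if (nchar(s) == 0L) { warning("empty sequence: score 0"); return(0) }
    nrow(find_motifs(s, motif))
  }
}

#' @rdname motif_count_scorer
#' @export
pwm_logodds_scorer <- function(motif, pwm_threshold = 0) {
  if (is.null(motif$pwm)) stop("pwm_logodds_scorer needs a PWM motif")
  force(motif); force(pwm_threshold)
  function(seq) {
    s <- seq_string(seq)
    if (nchar(s) == 0L) { warning("empty sequence: score 0"); return(0) }
    h <- find_motifs(s, motif, pwm_threshold = pwm_threshold)
    if (nrow(h) == 0L) 0 else sum(h$score)
  }
}
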