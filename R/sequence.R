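#' Genomic sequence objects
#'
#' A `genomic_sequence` is a named DNA string over the alphabet A, C, G, T, N,
#' optionally carrying the genomic source (contig, 0-based start) it was
#' extracted from.  All coordinates in this package are 0-based, half-open.
#'
#' @param id Single non-empty string naming the sequence.
#' @param seq Single DNA string; lowercase input is uppercased.
#' @param contig,start Optional source coordinates for windows cut out of a
#'   genome (`start` is 0-based).
#' @return An object of class `genomic_sequence` with fields `id`, `seq` and
#'   `source` (either `NULL` or `list(contig, start)`).
#' @examples
#' gs <- genomic_sequence("icr", "ACGTACGT")
#' cpg_positions(gs)
#' @export
genomic_sequence <- function(id, seq, contig = NULL, start = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a single non-empty string")
  if (!is.character(seq) || length(seq) != 1L)
    stop("'seq' must be a single string")
  seq <- toupper(seq)
  if (nchar(seq) < 1L) stop("sequence '", id, "' is empty")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' at 0-based offset %d in sequence '%s'",
                 substr(seq, bad, bad), as.integer(bad) - 1L, id))
  source <- NULL
  if (!is.null(contig)) {
    if (is.null(start)) stop("'start' is required when 'contig' is given")
    source <- list(contig = as.character(contig), start = as.integer(start))
  }
  structure(list(id = id, seq = seq, source = source),
            class = "genomic_sequence")
}

#' Coerce to a genomic_sequence
#'
#' @param x A `genomic_sequence`, or a single DNA string.
#' @param id Id to use when `x` is a bare string.
#' @return A `genomic_sequence`.
#' @export
as_genomic_sequence <- function(x, id = "seq") {
  if (inherits(x, "genomic_sequence")) return(x)
  genomic_sequence(id, x)
}

#' @export
print.genomic_sequence <- function(x, ...) {
  n <- nchar(x$seq)
  head <- substr(x$seq, 1L, min(40L, n))
  cat(sprintf("genomic_sequence '%s': %d bp%s\n  %s%s\n", x$id, n,
              if (is.null(x$source)) ""
              else sprintf(" [%s:%d]", x$source$contig, x$source$start),
              head, if (n > 40L) "..." else ""))
  invisible(x)
}

seq_string <- function(x) {
  if (inherits(x, "genomic_sequence")) x$seq
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a genomic_sequence or a single string")
}

#' Reverse complement of a DNA string
#'
#' @param x A `genomic_sequence` or DNA string.
#' @return The reverse complement as a plain string.
#' @export
reverse_complement <- function(x) {
  s <- seq_string(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' CpG dinucleotide positions
#'
#' Returns the ordered 0-based start offsets of every "CG" dinucleotide in a
#' sequence (the CpG grid).  Ns never take part in a CpG.
#'
#' @param x A `genomic_sequence` or DNA string.
#' @return Strictly increasing integer vector of 0-based offsets; `integer(0)`
#'   when the sequence has no CpG.
#' @examples
#' cpg_positions("CGCGCG")  # 0 2 4
#' @export
cpg_positions <- function(x) {
  s <- seq_string(x)
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' at 0-based offset %d",
                 substr(s, bad, bad), as.integer(bad) - 1L))
  m <- gregexpr("CG", s, fixed = TRUE)[[1L]]
  if (m[1L] < 0L) return(integer(0))
  as.integer(m) - 1L
}

## 1-based indices of all bases belonging to CpG dinucleotides
cpg_base_index <- function(grid0) {
  if (length(grid0) == 0L) return(integer(0))
  sort(unique(c(grid0 + 1L, grid0 + 2L)))
}
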