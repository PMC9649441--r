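#' Read a FASTA file
#'
#' Multi-record, wrapped or unwrapped, case-insensitive (lowercase bases are
#' uppercased with a message).
#'
#' @param path Path to a FASTA file.
#' @return List of `genomic_sequence`; empty list with a warning on an empty
#'   file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e)
      stop("failed to read FASTA '", path, "': ", conditionMessage(e)))
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  raw <- unname(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  ## Biostrings uppercases on read; flag lowercase from the raw lines
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("[a-z]", lines[!startsWith(lines, ">")])))
    message("lowercase bases in '", path, "' uppercased")
  out <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    out[[i]] <- tryCatch(genomic_sequence(ids[i], raw[i]),
                         error = function(e)
                           stop("record '", ids[i], "' in '", path, "': ",
                                conditionMessage(e)))
  }
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A `genomic_sequence` or list thereof.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "genomic_sequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$seq, ""))
  names(set) <- vapply(seqs, function(s) s$id, "")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read bisulfite reads from FASTQ or FASTA
#'
#' Qualities are parsed but not used beyond format validation.
#'
#' @param path Path to a FASTQ (or FASTA) file.
#' @param format `"fastq"` or `"fasta"` (guessed from the extension by
#'   default).
#' @return List of `bisulfite_read`.
#' @export
read_reads <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e)
      stop("failed to read reads '", path, "': ", conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(set))
  mapply(bisulfite_read, ids, as.character(set),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write motif hits or twin candidates as BED6
#'
#' Coordinates are written 0-based half-open, the native BED convention used
#' throughout the package.  For twin candidates `name` is the rank and
#' `score` the distance scaled to 0-1000 (capped); for motif hits `name` is
#' the motif id and `score` 0 (or the PWM score when present).
#'
#' @param x A `motif_hits` or `twin_candidates` data.frame.
#' @param path Output path.
#' @param chrom Chromosome name for motif hits (default the literal id
#'   `"seq"`), ignored for twin candidates (which carry contigs).
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, chrom = "seq") {
  if (inherits(x, "twin_candidates")) {
    bed <- data.frame(chrom = x$contig, start = x$start, end = x$end,
                      name = x$rank,
                      score = pmin(1000L, as.integer(round(x$distance * 1000))),
                      strand = ".")
  } else {
    score <- if ("score" %in% names(x)) round(x$score, 3)
             else rep(0L, nrow(x))
    bed <- data.frame(chrom = rep(chrom, nrow(x)), start = x$start,
                      end = x$end, name = x$motif_id, score = score,
                      strand = x$strand)
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a table as TSV with a single header line
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a methylation call matrix as a lollipop TSV
#'
#' Rows are molecules, columns the 0-based CpG reference offsets; values are
#' 1 (methylated), 0 (unmethylated) or "." (missing).
#'
#' @param x A `methylation_calls` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_call_matrix <- function(x, path) {
  m <- x$calls
  chr <- matrix(as.character(m), nrow = nrow(m))
  chr[is.na(chr)] <- "."
  df <- as.data.frame(chr, stringsAsFactors = FALSE)
  names(df) <- as.character(x$cpg_sites)
  df <- cbind(molecule = rownames(m) %||% seq_len(nrow(m)), df)
  write_tsv(df, path)
}

#' Write a JSON run manifest
#'
#' Captures the effective configuration, every seed and threshold, and
#' package/R versions; deterministic apart from the timestamp.
#'
#' @param config Named list: the effective run configuration.
#' @param path Output path.
#' @param timestamp Include a timestamp (default TRUE; disable for
#'   byte-identical reruns).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, timestamp = TRUE) {
  manifest <- list(
    tool = "icrdesign",
    version = as.character(utils::packageVersion("icrdesign")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config)
  if (timestamp) manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
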