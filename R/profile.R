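#' Sequence composition profile
#'
#' Computes the composition statistics used throughout the package to compare
#' a query element against genomic windows: length, GC fraction, CpG count and
#' density per 100 bp, a local-GC track on tiling windows, and the empirical
#' distribution of gaps between consecutive CpGs.
#'
#' GC fraction is (#C + #G) / (length - #N): N bases are excluded from both
#' numerator and denominator.  `cpg_per_100bp` uses the total length.  Local GC
#' is computed on half-open tiles of `local_window` bp advanced by
#' `local_step`; a final partial tile is included and flagged.
#'
#' @param x A `genomic_sequence` or DNA string.
#' @param local_window,local_step Tile size and step in bp for the local GC
#'   track (both >= 1).
#' @return A `sequence_profile`: list with fields `length`, `gc_fraction`,
#'   `cpg_count`, `cpg_per_100bp`, `local_gc` (data.frame: start, end, gc,
#'   partial), `cpg_spacings`, `local_window`, `local_step`.
#' @examples
#' p <- profile_sequence(strrep("CG", 50))
#' p$gc_fraction  # 1
#' p$cpg_count    # 50
#' @export
profile_sequence <- function(x, local_window = 100L, local_step = local_window) {
  s <- seq_string(x)
  local_window <- as.integer(local_window); local_step <- as.integer(local_step)
  if (local_window < 1L || local_step < 1L)
    stop("'local_window' and 'local_step' must be >= 1")
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  is_gc <- ch == "C" | ch == "G"
  is_n <- ch == "N"
  n_valid <- n - sum(is_n)
  if (n_valid == 0L)
    stop("GC fraction undefined: sequence consists entirely of N")
  grid <- cpg_positions(s)
  cs_gc <- c(0L, cumsum(is_gc))
  cs_n <- c(0L, cumsum(is_n))
  starts <- seq.int(0L, max(0L, n - 1L), by = local_step)
  ends <- pmin(starts + local_window, n)
  width <- ends - starts
  keep <- width > 0L
  starts <- starts[keep]; ends <- ends[keep]; width <- width[keep]
  tile_gc_n <- cs_gc[ends + 1L] - cs_gc[starts + 1L]
  tile_n_n <- cs_n[ends + 1L] - cs_n[starts + 1L]
  denom <- width - tile_n_n
  local_gc <- data.frame(
    start = starts, end = ends,
    gc = ifelse(denom > 0L, tile_gc_n / denom, NA_real_),
    partial = width < local_window)
  structure(list(
    length = n,
    gc_fraction = sum(is_gc) / n_valid,
    cpg_count = length(grid),
    cpg_per_100bp = length(grid) * 100 / n,
    local_gc = local_gc,
    cpg_spacings = if (length(grid) >= 2L) diff(grid) else integer(0),
    local_window = local_window,
    local_step = local_step), class = "sequence_profile")
}

#' @export
print.sequence_profile <- function(x, ...) {
  cat(sprintf(
    "sequence_profile: %d bp, GC %.3f, %d CpGs (%.2f / 100 bp), %d local-GC tiles\n",
    x$length, x$gc_fraction, x$cpg_count, x$cpg_per_100bp, nrow(x$local_gc)))
  invisible(x)
}

## cheap per-contig scan machinery shared by genome_window_scan / find_twins
contig_scan_arrays <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  list(n = nchar(seq),
       cs_gc = c(0L, cumsum(ch == "C" | ch == "G")),
       cs_n = c(0L, cumsum(ch == "N")),
       cpg = cpg_positions(seq))
}

#' Fixed-window genome scan
#'
#' Slides a fixed window over every contig of a genome and emits one profile
#' row per window (full windows only), in deterministic order: contigs in
#' input order, windows left to right.  Windows whose N fraction exceeds
#' `max_n_fraction` are skipped and counted, as are contigs shorter than the
#' window.
#'
#' @param genome A list of `genomic_sequence` (e.g. from [read_fasta()]) or a
#'   path to a FASTA file.
#' @param window Window size in bp (>= 2); the study-scale default is 1 kb.
#' @param step Step in bp (>= 1); defaults to `window` (a partition).
#' @param max_n_fraction Windows with a larger fraction of Ns are skipped.
#' @return A data.frame with columns contig, start, end, length, gc_fraction,
#'   cpg_count, cpg_per_100bp, and attributes `skipped_n_windows` and
#'   `skipped_short_contigs`.
#' @export
genome_window_scan <- function(genome, window = 1000L, step = window,
                               max_n_fraction = 0.1) {
  window <- as.integer(window); step <- as.integer(step)
  if (window < 2L) stop("'window' must be >= 2")
  if (step < 1L) stop("'step' must be >= 1")
  genome <- as_genome(genome)
  out <- vector("list", length(genome))
  skipped_n <- 0L; skipped_short <- 0L
  for (i in seq_along(genome)) {
    gs <- genome[[i]]
    a <- contig_scan_arrays(gs$seq)
    if (a$n < window) { skipped_short <- skipped_short + 1L; next }
    starts <- seq.int(0L, a$n - window, by = step)
    ends <- starts + window
    gc_n <- a$cs_gc[ends + 1L] - a$cs_gc[starts + 1L]
    n_n <- a$cs_n[ends + 1L] - a$cs_n[starts + 1L]
    cpg_n <- findInterval(ends - 2L, a$cpg) - findInterval(starts - 1L, a$cpg)
    ok <- n_n / window <= max_n_fraction
    skipped_n <- skipped_n + sum(!ok)
    denom <- window - n_n
    out[[i]] <- data.frame(
      contig = gs$id, start = starts[ok], end = ends[ok], length = window,
      gc_fraction = (gc_n / pmax(denom, 1L))[ok],
      cpg_count = cpg_n[ok],
      cpg_per_100bp = (cpg_n * 100 / window)[ok])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      gc_fraction = numeric(0), cpg_count = integer(0),
                      cpg_per_100bp = numeric(0))
  rownames(res) <- NULL
  attr(res, "skipped_n_windows") <- skipped_n
  attr(res, "skipped_short_contigs") <- skipped_short
  res
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) genome <- read_fasta(genome)
  if (inherits(genome, "genomic_sequence")) genome <- list(genome)
  if (!is.list(genome) || !all(vapply(genome, inherits, TRUE, "genomic_sequence")))
    stop("'genome' must be a FASTA path or a list of genomic_sequence objects")
  genome
}

## two-sample Kolmogorov-Smirnov statistic between CpG spacing sets;
## both empty -> 0, exactly one empty -> 1 (maximal divergence)
spacing_ks <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(0)
  if (length(a) == 0L || length(b) == 0L) return(1)
  pts <- sort(unique(c(a, b)))
  fa <- findInterval(pts, sort(a)) / length(a)
  fb <- findInterval(pts, sort(b)) / length(b)
  max(abs(fa - fb))
}

#' Distance between two sequence profiles
#'
#' Weighted sum of the absolute GC-fraction difference, the CpG-count
#' difference relative to the first profile's CpG count, and the
#' Kolmogorov-Smirnov statistic between the two CpG-spacing distributions.
#' It is non-negative, symmetric up to the CpG normalisation (which uses
#' `max(cpg_count)` so the distance is symmetric in its arguments) and zero on
#' identical profiles.
#'
#' @param p,q `sequence_profile` objects.
#' @param weights Numeric length-3 vector of non-negative weights for
#'   (GC, CpG count, spacing) terms.
#' @return Non-negative scalar distance.
#' @export
profile_distance <- function(p, q, weights = c(1, 1, 1)) {
  if (length(weights) != 3L || any(weights < 0))
    stop("'weights' must be three non-negative numbers")
  cpg_ref <- max(p$cpg_count, q$cpg_count, 1L)
  weights[1L] * abs(p$gc_fraction - q$gc_fraction) +
    weights[2L] * abs(p$cpg_count - q$cpg_count) / cpg_ref +
    weights[3L] * spacing_ks(p$cpg_spacings, q$cpg_spacings)
}

#' Find "sequence twins" of a query profile in a genome
#'
#' Scans the genome in windows of the query's length and ranks windows by
#' [profile_distance()] to the query: similarity in GC%, CpG number and CpG
#' spacing distribution at matched size.  Candidate windows are preselected by
#' the cheap GC + CpG-count part of the distance (a lower bound on the full
#' distance, since the spacing term is non-negative) and the full distance is
#' evaluated on that pool; overlapping hits are merged to the best-scoring
#' offset.  Ties break lexicographically on (contig, start).
#'
#' @param query A `sequence_profile` (or a `genomic_sequence`/string, which is
#'   profiled first).
#' @param genome FASTA path or list of `genomic_sequence`.
#' @param top_k Number of non-overlapping candidates to return (> 0).
#' @param weights Distance weights, see [profile_distance()].
#' @param step Scan step in bp (default 1).
#' @param max_n_fraction Skip windows with more Ns than this fraction.
#' @param pool_size Size of the candidate pool scored with the full distance.
#' @return A `twin_candidates` data.frame (contig, start, end, distance,
#'   gc_fraction, cpg_count, rank), sorted by ascending distance.
#' @export
find_twins <- function(query, genome, top_k = 5L, weights = c(1, 1, 1),
                       step = 1L, max_n_fraction = 0.1, pool_size = 2000L) {
  top_k <- as.integer(top_k)
  if (top_k <= 0L) stop("'top_k' must be > 0")
  if (!inherits(query, "sequence_profile")) query <- profile_sequence(query)
  genome <- as_genome(genome)
  if (length(genome) == 0L) {
    warning("empty genome: no twin candidates")
    return(empty_twins())
  }
  window <- query$length
  step <- as.integer(step)
  cand <- list()
  for (i in seq_along(genome)) {
    gs <- genome[[i]]
    a <- contig_scan_arrays(gs$seq)
    if (a$n < window) next
    starts <- seq.int(0L, a$n - window, by = step)
    ends <- starts + window
    gc_n <- a$cs_gc[ends + 1L] - a$cs_gc[starts + 1L]
    n_n <- a$cs_n[ends + 1L] - a$cs_n[starts + 1L]
    cpg_n <- findInterval(ends - 2L, a$cpg) - findInterval(starts - 1L, a$cpg)
    ok <- n_n / window <= max_n_fraction
    denom <- pmax(window - n_n, 1L)
    partial <- weights[1L] * abs(gc_n / denom - query$gc_fraction) +
      weights[2L] * abs(cpg_n - query$cpg_count) /
        pmax(pmax(cpg_n, query$cpg_count), 1L)
    cand[[i]] <- data.frame(ci = i, contig = gs$id, start = starts[ok],
                            end = ends[ok], partial = partial[ok])
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0L) {
    warning("no scannable windows (all contigs shorter than the query?)")
    return(empty_twins())
  }
  ## deterministic pool: ascending partial distance, ties on (contig, start);
  ## a greedy non-overlapping sweep is added so the pool always carries at
  ## least top_k mutually non-overlapping candidates (when the genome has
  ## that many windows)
  ord <- order(cand$partial, cand$contig, cand$start)
  take <- ord[seq_len(min(nrow(cand), max(pool_size, 10L * top_k)))]
  nonov <- integer(0)
  for (j in ord) {
    ok <- TRUE
    for (k in nonov) {
      if (cand$contig[j] == cand$contig[k] &&
          cand$start[j] < cand$end[k] && cand$end[j] > cand$start[k]) {
        ok <- FALSE; break
      }
    }
    if (ok) nonov <- c(nonov, j)
    if (length(nonov) >= 5L * top_k) break
  }
  pool <- cand[sort(unique(c(take, nonov))), ]
  full <- numeric(nrow(pool)); gcv <- numeric(nrow(pool)); cpv <- integer(nrow(pool))
  for (j in seq_len(nrow(pool))) {
    gs <- genome[[pool$ci[j]]]
    sub <- substr(gs$seq, pool$start[j] + 1L, pool$end[j])
    pr <- profile_sequence(sub, query$local_window, query$local_step)
    full[j] <- profile_distance(query, pr, weights)
    gcv[j] <- pr$gc_fraction; cpv[j] <- pr$cpg_count
  }
  pool$distance <- full; pool$gc_fraction <- gcv; pool$cpg_count <- cpv
  pool <- pool[order(pool$distance, pool$contig, pool$start), ]
  ## greedy non-overlap selection (merges overlapping self-hits to best offset)
  sel <- integer(0)
  for (j in seq_len(nrow(pool))) {
    overlaps <- FALSE
    for (k in sel) {
      if (pool$contig[j] == pool$contig[k] &&
          pool$start[j] < pool$end[k] && pool$end[j] > pool$start[k]) {
        overlaps <- TRUE; break
      }
    }
    if (!overlaps) sel <- c(sel, j)
    if (length(sel) >= top_k) break
  }
  res <- pool[sel, c("contig", "start", "end", "distance",
                     "gc_fraction", "cpg_count")]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("twin_candidates", "data.frame")
  res
}

empty_twins <- function() {
  res <- data.frame(contig = character(0), start = integer(0),
                    end = integer(0), distance = numeric(0),
                    gc_fraction = numeric(0), cpg_count = integer(0),
                    rank = integer(0))
  class(res) <- c("twin_candidates", "data.frame")
  res
}
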