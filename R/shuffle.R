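#' Constraints for inter-CpG shuffling
#'
#' The shuffler is a pure permutation of the input bases that never touches a
#' base belonging to a CpG dinucleotide and only moves bases within local GC
#' tiles, so per-tile base composition (hence local GC content) is preserved
#' exactly by construction.  Optional constraints forbid creating CG
#' dinucleotides outside the original grid and forbid re-creating a list of
#' motifs (default: the ZFP57 hexanucleotide on both strands).
#'
#' @param target_mismatch Fraction in (0, 1] of inter-CpG positions that must
#'   differ from the original, or `NULL` for MAXIMIZE mode (hill-climb as far
#'   as the constraints allow within `max_iterations`).
#' @param local_gc_window Tile size in bp within which bases may be permuted.
#' @param local_gc_tolerance Allowed absolute per-tile GC deviation; the
#'   default 0 is met exactly because permutation is within-tile.
#' @param forbid_new_cpg Disallow CG dinucleotides outside the original grid.
#' @param forbid_motifs Character vector of exact motifs whose occurrence (on
#'   either strand) is disallowed in the shuffled sequence, or a `motif_def`.
#'   `NULL` disables the check.
#' @param max_iterations Hill-climb proposal budget.
#' @param seed Mandatory integer seed; all randomness derives from it.
#' @return A `shuffle_constraints` object.
#' @export
shuffle_constraints <- function(target_mismatch = NULL,
                                local_gc_window = 100L,
                                local_gc_tolerance = 0,
                                forbid_new_cpg = TRUE,
                                forbid_motifs = zfp57_motif(),
                                max_iterations = 200000L,
                                seed = 1L) {
  if (!is.null(target_mismatch) &&
      (target_mismatch <= 0 || target_mismatch > 1))
    stop("'target_mismatch' must be in (0, 1] or NULL for MAXIMIZE")
  if (local_gc_tolerance < 0 || local_gc_tolerance >= 0.5)
    stop("'local_gc_tolerance' must be in [0, 0.5)")
  if (inherits(forbid_motifs, "motif_def")) forbid_motifs <- forbid_motifs$pattern
  if (!is.null(forbid_motifs)) {
    forbid_motifs <- toupper(forbid_motifs)
    forbid_motifs <- unique(c(forbid_motifs,
                              vapply(forbid_motifs, reverse_complement, "")))
  }
  structure(list(target_mismatch = target_mismatch,
                 local_gc_window = as.integer(local_gc_window),
                 local_gc_tolerance = local_gc_tolerance,
                 forbid_new_cpg = isTRUE(forbid_new_cpg),
                 forbid_motifs = forbid_motifs,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "shuffle_constraints")
}

#' Positionwise mismatch fraction
#'
#' Fraction of positions at which two equal-length strings differ, either over
#' all positions or over inter-CpG positions only (positions not belonging to
#' a CpG dinucleotide of `a`).
#'
#' @param a,b Equal-length sequences.
#' @param mask `"ALL"` or `"INTER_CPG"` (grid taken from `a`).
#' @return Mismatch fraction in \[0, 1\]; 0 with a warning on an empty mask.
#' @export
mismatch <- function(a, b, mask = c("ALL", "INTER_CPG")) {
  mask <- match.arg(mask)
  sa <- seq_string(a); sb <- seq_string(b)
  if (nchar(sa) != nchar(sb)) stop("length mismatch between 'a' and 'b'")
  ca <- strsplit(sa, "", fixed = TRUE)[[1L]]
  cb <- strsplit(sb, "", fixed = TRUE)[[1L]]
  idx <- seq_along(ca)
  if (mask == "INTER_CPG")
    idx <- setdiff(idx, cpg_base_index(cpg_positions(sa)))
  if (length(idx) == 0L) {
    warning("empty mask: mismatch reported as 0")
    return(0)
  }
  mean(ca[idx] != cb[idx])
}

## 0-based starts (within chars[lo..hi], 1-based bounds) of constraint
## violations: CGs outside the grid, and forbidden motifs on either strand
local_violations <- function(chars, lo, hi, grid0, forbid_new_cpg, motifs) {
  s <- paste(chars[lo:hi], collapse = "")
  viol <- list()
  if (forbid_new_cpg) {
    m <- gregexpr("CG", s, fixed = TRUE)[[1L]]
    if (m[1L] > 0L) {
      abs0 <- as.integer(m) - 1L + (lo - 1L)
      abs0 <- abs0[!(abs0 %in% grid0)]
      if (length(abs0)) viol$cpg <- cbind(abs0, abs0 + 1L)
    }
  }
  for (p in motifs) {
    st <- iupac_starts(s, p)
    if (length(st))
      viol[[p]] <- cbind(st + (lo - 1L), st + (lo - 1L) + nchar(p) - 1L)
  }
  if (length(viol)) do.call(rbind, viol) else NULL
}

count_violations <- function(chars, grid0, forbid_new_cpg, motifs) {
  v <- local_violations(chars, 1L, length(chars), grid0, forbid_new_cpg, motifs)
  if (is.null(v)) 0L else nrow(v)
}

#' Shuffle the inter-CpG sequence of an element
#'
#' Produces a permutation of the input in which every CpG dinucleotide stays
#' byte-identical in place, local GC content is preserved (within-tile
#' permutation), no new CpG is created and no forbidden motif reappears, while
#' the positionwise mismatch to the original over inter-CpG positions is
#' driven to `target_mismatch` (or maximised by hill-climbing pair swaps).
#'
#' The algorithm: per-tile Fisher-Yates permutation of the inter-CpG
#' positions, a repair phase removing constraint violations by within-tile
#' swaps, then hill-climbing: random within-tile pair swaps accepted only when
#' they strictly increase mismatch and keep the sequence violation-free, so
#' the logged mismatch trajectory is non-decreasing.
#'
#' @param x A `genomic_sequence` or DNA string (no Ns).
#' @param constraints A [shuffle_constraints()] object.
#' @return A `shuffle_result`: original and shuffled `genomic_sequence`,
#'   `mismatch_inter_cpg`, `mismatch_total`, `iterations_used`, `status`
#'   (`"ok"`, `"degenerate"`, `"target_not_reached"` or
#'   `"constraints_not_met"`), `trajectory`, `seed` and an `audit` list
#'   (grid_identical, permutation, novel_cpgs, forbidden_hits,
#'   max_tile_gc_dev, tile_gc_dev).
#' @examples
#' r <- shuffle_inter_cpg("ATGCGATTACGGATCCGTAA",
#'                        shuffle_constraints(seed = 1, max_iterations = 500))
#' r$audit$grid_identical
#' @export
shuffle_inter_cpg <- function(x, constraints = shuffle_constraints()) {
  gs <- as_genomic_sequence(x)
  if (grepl("N", gs$seq, fixed = TRUE))
    stop("sequence contains N: shuffling Ns is undefined")
  cn <- constraints
  set.seed(cn$seed)
  ch <- strsplit(gs$seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  grid0 <- cpg_positions(gs$seq)
  fixed <- cpg_base_index(grid0)
  inter <- setdiff(seq_len(n), fixed)
  motifs <- cn$forbid_motifs %||% character(0)
  if (length(inter) == 0L) {
    return(finish_shuffle(gs, ch, ch, grid0, inter, cn, 0L,
                          status = "degenerate", trajectory = numeric(0)))
  }
  orig <- ch
  tile_of <- (inter - 1L) %/% cn$local_gc_window
  tiles <- split(inter, tile_of)
  ## initial within-tile permutation
  sh <- ch
  for (tl in tiles) {
    if (length(tl) > 1L) sh[tl] <- sh[sample(tl)]
  }
  ## repair: remove violations by within-tile swaps
  repair_budget <- 2000L
  tries <- 0L
  repeat {
    v <- local_violations(sh, 1L, n, grid0, cn$forbid_new_cpg, motifs)
    if (is.null(v)) break
    tries <- tries + 1L
    if (tries > repair_budget) break
    span <- v[1L, ]
    span_pos <- intersect((span[1L] + 1L):(span[2L] + 1L), inter)
    if (length(span_pos) == 0L) break  # violation entirely on fixed bases
    i <- if (length(span_pos) == 1L) span_pos else sample(span_pos, 1L)
    tl <- tiles[[as.character((i - 1L) %/% cn$local_gc_window)]]
    cand <- tl[sh[tl] != sh[i]]
    if (length(cand) == 0L) next
    j <- if (length(cand) == 1L) cand else sample(cand, 1L)
    before <- pair_violation_count(sh, i, j, grid0, cn$forbid_new_cpg, motifs)
    tmp <- sh[i]; sh[i] <- sh[j]; sh[j] <- tmp
    after <- pair_violation_count(sh, i, j, grid0, cn$forbid_new_cpg, motifs)
    if (after > before) { tmp <- sh[i]; sh[i] <- sh[j]; sh[j] <- tmp }
  }
  if (!is.null(local_violations(sh, 1L, n, grid0, cn$forbid_new_cpg, motifs)))
    return(finish_shuffle(gs, orig, orig, grid0, inter, cn, tries,
                          status = "constraints_not_met",
                          trajectory = numeric(0)))
  ## hill-climb: within-tile pair swaps that strictly increase mismatch
  mm <- sum(sh[inter] != orig[inter])
  target_mm <- if (is.null(cn$target_mismatch)) Inf
               else ceiling(cn$target_mismatch * length(inter))
  trajectory <- mm / length(inter)
  multi <- tiles[vapply(tiles, length, 1L) > 1L]
  iterations <- 0L
  stall <- 0L
  if (length(multi) > 0L) {
    tile_w <- vapply(multi, length, 1L)
    while (iterations < cn$max_iterations && mm < target_mm &&
           stall < 5000L && mm < length(inter)) {
      iterations <- iterations + 1L
      tl <- multi[[sample.int(length(multi), 1L, prob = tile_w)]]
      ij <- tl[sample.int(length(tl), 2L)]
      i <- ij[1L]; j <- ij[2L]
      if (sh[i] == sh[j]) { stall <- stall + 1L; next }
      cur <- (sh[i] == orig[i]) + (sh[j] == orig[j])
      new <- (sh[j] == orig[i]) + (sh[i] == orig[j])
      if (new >= cur) { stall <- stall + 1L; next }
      before <- pair_violation_count(sh, i, j, grid0, cn$forbid_new_cpg, motifs)
      tmp <- sh[i]; sh[i] <- sh[j]; sh[j] <- tmp
      after <- pair_violation_count(sh, i, j, grid0, cn$forbid_new_cpg, motifs)
      if (after > before) {
        tmp <- sh[i]; sh[i] <- sh[j]; sh[j] <- tmp
        stall <- stall + 1L
      } else {
        mm <- mm + (cur - new)
        trajectory <- c(trajectory, mm / length(inter))
        stall <- 0L
      }
    }
  }
  status <- if (is.finite(target_mm) && mm < target_mm) "target_not_reached"
            else "ok"
  finish_shuffle(gs, orig, sh, grid0, inter, cn, iterations, status, trajectory)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## violations touching the +/- 6 bp neighbourhoods of two changed positions
pair_violation_count <- function(chars, i, j, grid0, forbid_new_cpg, motifs) {
  n <- length(chars)
  w <- 6L
  r1 <- c(max(1L, i - w), min(n, i + w))
  r2 <- c(max(1L, j - w), min(n, j + w))
  if (r1[1L] > r2[1L]) { tmp <- r1; r1 <- r2; r2 <- tmp }
  cnt <- function(lo, hi) {
    v <- local_violations(chars, lo, hi, grid0, forbid_new_cpg, motifs)
    if (is.null(v)) 0L else nrow(v)
  }
  if (r2[1L] <= r1[2L] + 1L) cnt(r1[1L], max(r1[2L], r2[2L]))
  else cnt(r1[1L], r1[2L]) + cnt(r2[1L], r2[2L])
}

finish_shuffle <- function(gs, orig, sh, grid0, inter, cn, iterations,
                           status, trajectory) {
  shuffled_seq <- paste(sh, collapse = "")
  shuffled <- genomic_sequence(paste0(gs$id, "_shuffled"), shuffled_seq)
  grid_new <- cpg_positions(shuffled_seq)
  novel <- length(setdiff(grid_new, grid0))
  forb <- 0L
  for (p in cn$forbid_motifs %||% character(0))
    forb <- forb + length(iupac_starts(shuffled_seq, p))
  po <- profile_sequence(paste(orig, collapse = ""),
                         local_window = cn$local_gc_window)
  ps <- profile_sequence(shuffled_seq, local_window = cn$local_gc_window)
  dev <- abs(po$local_gc$gc - ps$local_gc$gc)
  mm_inter <- if (length(inter) == 0L) 0 else mean(sh[inter] != orig[inter])
  audit <- list(
    grid_identical = identical(grid_new, grid0),
    permutation = identical(sort(orig), sort(sh)),
    novel_cpgs = novel,
    forbidden_hits = forb,
    tile_gc_dev = dev,
    max_tile_gc_dev = if (length(dev)) max(dev) else 0,
    gc_within_tolerance = all(dev <= cn$local_gc_tolerance + 1e-12))
  structure(list(
    original = gs,
    shuffled = shuffled,
    mismatch_inter_cpg = mm_inter,
    mismatch_total = mean(sh != orig),
    iterations_used = iterations,
    status = status,
    trajectory = trajectory,
    seed = cn$seed,
    constraints = cn,
    audit = audit), class = "shuffle_result")
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat(sprintf(paste0(
    "shuffle_result '%s' (%s): inter-CpG mismatch %.1f%%, total %.1f%%\n",
    "  grid identical: %s; permutation: %s; novel CpGs: %d; forbidden hits: %d\n"),
    x$original$id, x$status, 100 * x$mismatch_inter_cpg,
    100 * x$mismatch_total, x$audit$grid_identical, x$audit$permutation,
    x$audit$novel_cpgs, x$audit$forbidden_hits))
  invisible(x)
}

#' Restore motif spans from the original sequence into a shuffled variant
#'
#' Byte-copies the spans of the given motif hits (coordinates on the ORIGINAL
#' sequence) from the original into the shuffled sequence, reconstituting the
#' motifs that shuffling disrupted.  If copying creates a CG dinucleotide at a
#' splice junction that exists in neither input, the junction base on the
#' shuffled side is substituted (C before a span -> T; G after a span -> A)
#' and the repaired positions are reported.  A post-check asserts that a motif
#' scan of the output finds a hit at every requested position.
#'
#' @param shuffled,original Same-length `genomic_sequence`s or strings.
#' @param hits A `motif_hits` data.frame (or any data.frame with 0-based
#'   `start`, `end`) located on the original sequence; spans must be
#'   non-overlapping and in bounds.
#' @param motif The `motif_def` used for the post-check scan; `NULL` skips it.
#' @return A `genomic_sequence` with attribute `repaired_junctions` (0-based
#'   positions whose base was substituted during junction repair).
#' @export
reconstitute_motifs <- function(shuffled, original, hits,
                                motif = zfp57_motif()) {
  ss <- seq_string(shuffled); so <- seq_string(original)
  if (nchar(ss) != nchar(so)) stop("sequences must have the same length")
  id <- if (inherits(shuffled, "genomic_sequence"))
    paste0(shuffled$id, "_reconstituted") else "reconstituted"
  if (nrow(hits) == 0L) {
    out <- genomic_sequence(id, ss)
    attr(out, "repaired_junctions") <- integer(0)
    return(out)
  }
  h <- hits[order(hits$start), , drop = FALSE]
  bad_bounds <- which(h$start < 0L | h$end > nchar(so) | h$end <= h$start)
  if (length(bad_bounds))
    stop("out-of-bounds hit spans at rows: ",
         paste(bad_bounds, collapse = ", "))
  if (nrow(h) > 1L) {
    ov <- which(h$start[-1L] < h$end[-nrow(h)])
    if (length(ov))
      stop("overlapping hit spans (0-based starts): ",
           paste(h$start[c(ov, ov + 1L)], collapse = ", "))
  }
  ch <- strsplit(ss, "", fixed = TRUE)[[1L]]
  co <- strsplit(so, "", fixed = TRUE)[[1L]]
  for (k in seq_len(nrow(h)))
    ch[(h$start[k] + 1L):h$end[k]] <- co[(h$start[k] + 1L):h$end[k]]
  ## junction repair: CG straddling a span boundary that neither input had
  allowed <- union(cpg_positions(so), cpg_positions(ss))
  repaired <- integer(0)
  n <- length(ch)
  for (k in seq_len(nrow(h))) {
    for (p0 in c(h$start[k] - 1L, h$end[k] - 1L)) {  # 0-based CG start cands
      if (p0 < 0L || p0 + 1L >= n) next
      if (ch[p0 + 1L] == "C" && ch[p0 + 2L] == "G" && !(p0 %in% allowed)) {
        if (p0 + 1L >= h$start[k] + 1L && p0 + 1L <= h$end[k]) {
          ch[p0 + 2L] <- "A"; repaired <- c(repaired, p0 + 1L)  # G outside
        } else {
          ch[p0 + 1L] <- "T"; repaired <- c(repaired, p0)       # C outside
        }
      }
    }
  }
  out_seq <- paste(ch, collapse = "")
  if (!is.null(motif)) {
    found <- find_motifs(out_seq, motif)
    missing <- setdiff(h$start, found$start)
    if (length(missing))
      warning("post-check: no motif hit at reconstituted 0-based starts: ",
              paste(missing, collapse = ", "))
  }
  out <- genomic_sequence(id, out_seq)
  attr(out, "repaired_junctions") <- repaired
  out
}
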