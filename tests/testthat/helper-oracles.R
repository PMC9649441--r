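## Independent brute-force oracles.  These deliberately share no code with
## the package internals they check.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## sliding two-character scan
oracle_cpg <- function(seq) {
  n <- nchar(seq)
  if (n < 2L) return(integer(0))
  out <- integer(0)
  for (i in seq_len(n - 1L))
    if (substr(seq, i, i + 1L) == "CG") out <- c(out, i - 1L)
  out
}

## per-position tally
oracle_gc <- function(seq) {
  ch <- strsplit(seq, "")[[1L]]
  sum(ch %in% c("C", "G")) / sum(ch != "N")
}

oracle_mismatch <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  n <- 0L
  for (i in seq_along(ca)) if (ca[i] != cb[i]) n <- n + 1L
  n / length(ca)
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
}

## exact-substring scan on both strands; returns data.frame(start, strand)
oracle_motif_starts <- function(seq, pattern) {
  w <- nchar(pattern)
  rc <- oracle_revcomp(pattern)
  out <- list()
  for (i in seq_len(max(0L, nchar(seq) - w + 1L))) {
    s <- substr(seq, i, i + w - 1L)
    if (s == pattern) out[[length(out) + 1L]] <- c(i - 1L, "+")
    if (s == rc) out[[length(out) + 1L]] <- c(i - 1L, "-")
  }
  if (!length(out)) return(data.frame(start = integer(0), strand = character(0)))
  m <- do.call(rbind, out)
  df <- data.frame(start = as.integer(m[, 1L]), strand = m[, 2L])
  df[order(df$start, df$strand), ]
}

## semi-global DP (read global, free end gaps in the reference), linear gaps
oracle_semiglobal <- function(read, ref, match = 1, mis = -1, gap = -2) {
  a <- strsplit(read, "")[[1L]]; b <- strsplit(ref, "")[[1L]]
  n <- length(a); m <- length(b)
  D <- matrix(-Inf, n + 1L, m + 1L)
  D[1L, ] <- 0                      # free leading gap in reference
  for (i in seq_len(n)) D[i + 1L, 1L] <- i * gap
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (a[i] == b[j]) match else mis
    D[i + 1L, j + 1L] <- max(D[i, j] + s, D[i, j + 1L] + gap,
                             D[i + 1L, j] + gap)
  }
  max(D[n + 1L, ])                  # free trailing gap in reference
}

## manual string splice of hit spans from original into shuffled
oracle_splice <- function(shuffled, original, starts0, ends0) {
  out <- shuffled
  for (k in seq_along(starts0)) {
    substr(out, starts0[k] + 1L, ends0[k]) <-
      substr(original, starts0[k] + 1L, ends0[k])
  }
  out
}

## independent audit of a shuffle result
oracle_shuffle_audit <- function(orig, shuf, tile = 100L,
                                 forbidden = c("TGCCGC", "GCGGCA")) {
  stopifnot(nchar(orig) == nchar(shuf))
  co <- strsplit(orig, "")[[1L]]; cs <- strsplit(shuf, "")[[1L]]
  grid_o <- oracle_cpg(orig); grid_s <- oracle_cpg(shuf)
  tiles_dev <- numeric(0)
  n <- nchar(orig)
  for (s in seq(1L, n, by = tile)) {
    e <- min(s + tile - 1L, n)
    go <- sum(co[s:e] %in% c("C", "G")) / (e - s + 1L)
    gs <- sum(cs[s:e] %in% c("C", "G")) / (e - s + 1L)
    tiles_dev <- c(tiles_dev, abs(go - gs))
  }
  fixed <- unique(c(grid_o + 1L, grid_o + 2L))
  forb <- 0L
  for (p in forbidden)
    forb <- forb + nrow(oracle_motif_starts(shuf, p)[
      oracle_motif_starts(shuf, p)$strand == "+", , drop = FALSE])
  list(grid_identical = identical(grid_s, grid_o),
       permutation = identical(sort(co), sort(cs)),
       cpg_bases_untouched = all(co[fixed] == cs[fixed]),
       novel_cpgs = length(setdiff(grid_s, grid_o)),
       forbidden_plus_hits = forb,
       max_tile_gc_dev = if (length(tiles_dev)) max(tiles_dev) else 0)
}
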