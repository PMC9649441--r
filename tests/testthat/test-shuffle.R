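test_that("mismatch matches examples and the positionwise loop oracle", {
  expect_equal(mismatch("ACGT", "ACGT"), 0)
  expect_equal(mismatch("AAAA", "TTTT"), 1)
  expect_error(mismatch("AA", "AAA"), "length")
  expect_warning(m0 <- mismatch("CG", "CG", mask = "INTER_CPG"), "empty mask")
  expect_equal(m0, 0)
  set.seed(3)
  for (i in 1:50) {
    n <- sample(5:80, 1)
    a <- random_dna(n); b <- random_dna(n)
    expect_equal(mismatch(a, b), oracle_mismatch(a, b))
  }
})

test_that("a CpG-only sequence is a degenerate shuffle", {
  r <- shuffle_inter_cpg("CGCGCG", shuffle_constraints(seed = 1))
  expect_equal(r$status, "degenerate")
  expect_identical(r$shuffled$seq, "CGCGCG")
  expect_equal(r$mismatch_inter_cpg, 0)
})

test_that("shuffling rejects Ns and validates constraints", {
  expect_error(shuffle_inter_cpg("ACGNTT", shuffle_constraints(seed = 1)), "N")
  expect_error(shuffle_constraints(target_mismatch = 1.5), "target_mismatch")
  expect_error(shuffle_constraints(local_gc_tolerance = 0.6), "tolerance")
})

test_that("shuffle audit equals an independent brute-force checker", {
  set.seed(11)
  for (i in 1:10) {
    s <- random_dna(60, gc = 0.6)
    r <- shuffle_inter_cpg(s, shuffle_constraints(seed = i,
                                                  local_gc_window = 20,
                                                  max_iterations = 2000))
    o <- oracle_shuffle_audit(s, r$shuffled$seq, tile = 20)
    expect_identical(r$audit$grid_identical, o$grid_identical)
    expect_identical(r$audit$permutation, o$permutation)
    expect_true(o$cpg_bases_untouched)
    expect_equal(r$audit$novel_cpgs, o$novel_cpgs)
    expect_equal(r$audit$max_tile_gc_dev, o$max_tile_gc_dev)
    if (r$status == "ok") {
      expect_equal(o$novel_cpgs, 0)
      expect_equal(o$max_tile_gc_dev, 0)
    }
    expect_equal(r$mismatch_inter_cpg >= 0 & r$mismatch_inter_cpg <= 1, TRUE)
  }
})

test_that("shuffle invariants hold over random synthetic inputs", {
  set.seed(21)
  for (i in 1:25) {
    spec <- sequence_spec(sample(150:400, 1), runif(1, 0.45, 0.65),
                          sample(5:25, 1),
                          sample(c("uniform", "clustered"), 1), seed = 100 + i)
    s <- generate_sequence(spec)
    r <- shuffle_inter_cpg(s, shuffle_constraints(seed = i,
                                                  max_iterations = 500))
    expect_identical(cpg_positions(r$shuffled), cpg_positions(s))
    expect_identical(sort(strsplit(r$shuffled$seq, "")[[1]]),
                     sort(strsplit(s$seq, "")[[1]]))
    ## no-new-CpG: total CG count conserved
    expect_equal(length(cpg_positions(r$shuffled)), length(cpg_positions(s)))
    expect_equal(r$audit$novel_cpgs, 0)
    expect_equal(r$audit$forbidden_hits, 0)
    expect_true(r$audit$gc_within_tolerance)
    ## hill-climb trajectory is non-decreasing
    expect_true(all(diff(r$trajectory) >= 0))
    ## inter-CpG mismatch consistent with mismatch() on the result
    expect_equal(r$mismatch_inter_cpg,
                 suppressWarnings(mismatch(s, r$shuffled, "INTER_CPG")))
    expect_equal(r$mismatch_total, mismatch(s, r$shuffled, "ALL"))
  }
})

test_that("identical seed and constraints give byte-identical output", {
  s <- generate_sequence(sequence_spec(500, 0.6, 20, "clustered", seed = 33))
  cn <- shuffle_constraints(seed = 12, max_iterations = 1000)
  r1 <- shuffle_inter_cpg(s, cn)
  r2 <- shuffle_inter_cpg(s, cn)
  expect_identical(r1$shuffled$seq, r2$shuffled$seq)
  r3 <- shuffle_inter_cpg(s, shuffle_constraints(seed = 13,
                                                 max_iterations = 1000))
  expect_false(identical(r1$shuffled$seq, r3$shuffled$seq))
})

test_that("target mode reports when the target is not reached", {
  s <- generate_sequence(sequence_spec(200, 0.55, 8, "uniform", seed = 5))
  r <- shuffle_inter_cpg(s, shuffle_constraints(target_mismatch = 0.5,
                                                seed = 2,
                                                max_iterations = 5000))
  expect_true(r$status %in% c("ok", "target_not_reached"))
  if (r$status == "ok") expect_gte(r$mismatch_inter_cpg, 0.5)
  ## an effectively unreachable target is reported, never silently dropped
  r2 <- shuffle_inter_cpg("AACGAA", shuffle_constraints(target_mismatch = 1,
                                                        seed = 2,
                                                        max_iterations = 50))
  expect_true(r2$status %in% c("target_not_reached", "ok"))
  if (r2$status == "target_not_reached")
    expect_lt(r2$mismatch_inter_cpg, 1)
})

test_that("reconstitute_motifs splices spans exactly and validates hits", {
  set.seed(8)
  orig <- paste0(random_dna(15, 0.5), "TGCCGC", random_dna(12, 0.5),
                 "TGCCGC", random_dna(11, 0.5))
  gs <- genomic_sequence("toy", orig)
  r <- shuffle_inter_cpg(gs, shuffle_constraints(seed = 4,
                                                 local_gc_window = 25,
                                                 max_iterations = 2000))
  hits <- find_motifs(gs)
  expect_gte(nrow(hits), 2)
  out <- reconstitute_motifs(r$shuffled, gs, hits)
  ## scan of the output finds a hit at every original coordinate
  found <- find_motifs(out)
  expect_true(all(hits$start %in% found$start))
  ## equals an independent string-splice everywhere outside repairs
  spl <- oracle_splice(r$shuffled$seq, orig, hits$start, hits$end)
  rep0 <- attr(out, "repaired_junctions")
  keep <- setdiff(seq_len(nchar(orig)), rep0 + 1L)
  expect_identical(strsplit(out$seq, "")[[1]][keep],
                   strsplit(spl, "")[[1]][keep])

  ## empty hit list: output equals shuffled
  out0 <- reconstitute_motifs(r$shuffled, gs, hits[0, ])
  expect_identical(out0$seq, r$shuffled$seq)

  ## overlapping and out-of-bounds hits rejected
  bad <- data.frame(start = c(0L, 3L), end = c(6L, 9L))
  expect_error(reconstitute_motifs(r$shuffled, gs, bad), "overlapping")
  oob <- data.frame(start = nchar(orig) - 2L, end = nchar(orig) + 4L)
  expect_error(reconstitute_motifs(r$shuffled, gs, oob), "bounds")
})

test_that("junction repair removes splice-created CpGs and reports positions", {
  ## shuffled has C just before the span; span starts with G at a position
  ## where neither input had a CG
  original <- "AATTGCCGCTTAA"
  shuffled <- "ATCTGCCGCTATA"  # same length; C at offset 2 precedes span?
  hits <- data.frame(start = 3L, end = 9L)  # span "GCCGCT" on original
  out <- reconstitute_motifs(shuffled, original, hits, motif = NULL)
  grid_o <- cpg_positions(original); grid_s <- cpg_positions(shuffled)
  extra <- setdiff(cpg_positions(out$seq), union(grid_o, grid_s))
  expect_length(extra, 0)
})
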