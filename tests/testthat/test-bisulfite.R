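make_ref <- function(seed = 3, len = 120, n_cpg = 8)
  generate_sequence(sequence_spec(len, 0.55, n_cpg, "clustered", seed = seed),
                    id = "amp")

test_that("convert_in_silico applies bisulfite chemistry deterministically", {
  ref <- make_ref()
  k <- length(cpg_positions(ref$seq))
  set.seed(1)
  r_meth <- convert_in_silico(ref, rep("METH", k), conversion_rate = 1,
                              strand = "OT")
  ## all non-CpG Cs converted; C retained exactly at CpG-C positions
  expect_identical(which(strsplit(r_meth$seq, "")[[1]] == "C") - 1L,
                   cpg_positions(ref$seq))
  set.seed(1)
  r_unmeth <- convert_in_silico(ref, rep("UNMETH", k), conversion_rate = 1,
                                strand = "OT")
  expect_false(grepl("C", r_unmeth$seq, fixed = TRUE))
  ## OB strand: symmetric on the reverse complement
  set.seed(1)
  b_meth <- convert_in_silico(ref, rep("METH", k), conversion_rate = 1,
                              strand = "OB")
  rc <- reverse_complement(ref$seq)
  bottom_c <- (nchar(ref$seq) - 2L) - cpg_positions(ref$seq)
  expect_identical(which(strsplit(b_meth$seq, "")[[1]] == "C") - 1L, rev(bottom_c))
  expect_error(convert_in_silico(ref, rep("METH", k), conversion_rate = 2),
               "\\[0, 1\\]")
  expect_error(convert_in_silico(ref, rep("METH", k - 1)), "every CpG")
})

test_that("observed conversion matches the nominal rate binomially", {
  ref <- make_ref(seed = 9, len = 60, n_cpg = 3)
  rch <- strsplit(ref$seq, "")[[1]]
  non_cpg_c <- setdiff(which(rch == "C"), cpg_positions(ref$seq) + 1L)
  n_c <- length(non_cpg_c)
  set.seed(99)
  n_mol <- 10000L
  conv <- 0L
  for (i in seq_len(n_mol)) {
    r <- convert_in_silico(ref, rep("METH", length(cpg_positions(ref$seq))),
                           conversion_rate = 0.99, strand = "OT")
    conv <- conv + sum(strsplit(r$seq, "")[[1]][non_cpg_c] == "T")
  }
  p_hat <- conv / (n_mol * n_c)
  se <- sqrt(0.99 * 0.01 / (n_mol * n_c))
  expect_lt(abs(p_hat - 0.99), 3 * se)
})

test_that("alignment score equals the semi-global DP oracle in collapsed space", {
  set.seed(41)
  for (i in 1:10) {
    ref <- random_dna(60, 0.5)
    read <- substr(ref, 11, 40)
    ## mutate a couple of bases
    ch <- strsplit(read, "")[[1]]
    pos <- sample(30, 2)
    ch[pos] <- sample(c("A", "C", "G", "T"), 2, replace = TRUE)
    read <- paste(ch, collapse = "")
    al <- align_bisulfite(bisulfite_read("r", read), ref,
                          mode = "directional",
                          qc = bs_qc_thresholds(0, 0))
    best_oracle <- max(
      oracle_semiglobal(chartr("C", "T", read), chartr("C", "T", ref)),
      oracle_semiglobal(chartr("G", "A", oracle_revcomp(read)),
                        chartr("G", "A", ref)))
    expect_equal(al$score, best_oracle)
  }
})

test_that("error-free simulated reads are recovered exactly (round trip)", {
  ref <- make_ref(seed = 6, len = 150, n_cpg = 10)
  k <- 10L
  set.seed(2)
  states <- matrix(runif(12 * k) < 0.5, nrow = 12)
  for (mode in c("directional", "non_directional")) {
    for (i in 1:12) {
      strand <- if (i %% 2 == 0) "OT" else "OB"
      set.seed(1000 + i)
      rd <- convert_in_silico(ref, states[i, ], conversion_rate = 1,
                              strand = strand)
      al <- align_bisulfite(rd, ref, mode = mode)
      expect_equal(al$identity, 1)
      expect_true(al$pass)
      expect_identical(al$calls, ifelse(states[i, ], "METH", "UNMETH"))
      if (mode == "directional") expect_equal(al$form, strand)
    }
  }
})

test_that("non-directional mode recognises CTOT/CTOB complement reads", {
  ref <- make_ref(seed = 14, len = 100, n_cpg = 6)
  k <- 6L
  states <- rep(c(TRUE, FALSE), 3)
  set.seed(7)
  ot <- convert_in_silico(ref, states, conversion_rate = 1, strand = "OT")
  ctot <- bisulfite_read("ctot", reverse_complement(ot$seq))
  al <- align_bisulfite(ctot, ref, mode = "non_directional")
  expect_equal(al$identity, 1)
  expect_identical(al$calls, ifelse(states, "METH", "UNMETH"))
  expect_true(al$form %in% c("CTOT", "OB"))  # score ties break by priority
})

test_that("call_matrix assembles the lollipop matrix and applies QC", {
  ref <- make_ref(seed = 5, len = 120, n_cpg = 8)
  k <- 8L
  set.seed(3)
  reads <- lapply(1:10, function(i)
    convert_in_silico(ref, rep("METH", k), conversion_rate = 1, strand = "OT",
                      id = paste0("m", i)))
  mat <- call_matrix(reads, ref)
  expect_equal(dim(mat$calls), c(10L, 8L))
  expect_true(all(mat$calls == 1L))
  ## conservation: METH + UNMETH + MISSING per site == passing reads
  expect_true(all(colSums(mat$calls == 1L, na.rm = TRUE) +
                  colSums(mat$calls == 0L, na.rm = TRUE) +
                  colSums(is.na(mat$calls)) == nrow(mat$calls)))

  ## an unconverted (conversion-failure) read is excluded by QC
  bad <- bisulfite_read("bad", ref$seq)  # no conversion at all
  mat2 <- call_matrix(c(reads, list(bad)), ref)
  expect_equal(nrow(mat2$calls), 10L)
  expect_false(mat2$qc$pass[mat2$qc$read_id == "bad"])
  ## zero passing reads -> explicit status
  mat3 <- call_matrix(list(bad), ref)
  expect_equal(mat3$status, "no_passing_reads")
  expect_equal(nrow(mat3$calls), 0L)
})

test_that("disordered simulation is jointly consistent with its parameter", {
  ref <- make_ref(seed = 8, len = 150, n_cpg = 10)
  sim <- generate_reads(ref, epiallele_scenario("DISORDERED", p = 0.403,
                                                n_molecules = 300,
                                                conversion_rate = 1,
                                                error_rate = 0, seed = 55))
  mat <- call_matrix(sim$reads, ref, mode = "directional")
  ## pooled binomial test at alpha = 0.01
  n_meth <- sum(mat$calls == 1L)
  n_tot <- length(mat$calls)
  pv <- stats::binom.test(n_meth, n_tot, p = 0.403)$p.value
  expect_gt(pv, 0.01)
  ## and exact agreement with ground truth under perfect chemistry
  expect_identical(unname(mat$calls == 1L), unname(sim$states))
})

test_that("summarize_methylation applies the coverage rule exactly", {
  ref <- make_ref(seed = 4, len = 80, n_cpg = 5)
  mat <- structure(list(reference_id = "amp",
                        cpg_sites = cpg_positions(ref$seq),
                        calls = NULL, qc = NULL, status = "ok"),
                   class = "methylation_calls")
  ## hand-built 5-site matrix: site 3 covered 3x, others 4x
  m <- rbind(c(1L, 0L, 1L, 1L, 0L),
             c(1L, 1L, NA, 0L, 0L),
             c(0L, 0L, 1L, 1L, 1L),
             c(1L, 0L, 0L, 1L, 0L))
  mat$calls <- m
  sm <- summarize_methylation(mat, min_coverage = 4)
  expect_equal(sm$sites$coverage, c(4L, 4L, 3L, 4L, 4L))
  expect_equal(sm$sites$retained, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(sm$sites$meth_fraction[1], 3 / 4)
  expect_equal(sm$aggregate, mean(c(3, 1, 3, 1) / 4))
  expect_equal(sm$excluded_sites, mat$cpg_sites[3])
  ## monotonicity: raising min_coverage never grows the retained set
  prev <- sm$sites$retained
  for (mc in c(4, 5, 6)) {
    cur <- summarize_methylation(mat, mc)$sites$retained
    expect_true(all(cur <= prev))
    prev <- cur
  }
  sm_all <- summarize_methylation(mat, min_coverage = 100)
  expect_true(sm_all$all_excluded)
  expect_true(is.na(sm_all$aggregate))
  expect_error(summarize_methylation(mat, 0), ">= 1")
})
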