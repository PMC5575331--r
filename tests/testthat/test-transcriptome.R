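test_that("FPKM matches the hand calculation and validates inputs", {
  counts <- matrix(c(90L, 10L), ncol = 1, dimnames = list(c("a", "b"), "s1"))
  lens <- c(a = 1000L, b = 500L)
  f <- compute_fpkm(counts, lens)
  expect_equal(unname(f[, 1]), c(9e5, 2e5))
  expect_error(compute_fpkm(counts, c(a = 1000L)), "length")
  expect_error(compute_fpkm(counts, lens, totals = 0), "positive")
})

test_that("frame translation agrees with Biostrings", {
  set.seed(33)
  for (rep in 1:10) {
    s <- paste0(sample(c("A", "C", "G", "T"), 99 + rep, replace = TRUE),
                collapse = "")
    for (f in 0:2) {
      n <- (nchar(s) - f) %/% 3L
      sub <- substr(s, f + 1L, f + 3L * n)
      want <- as.character(Biostrings::translate(Biostrings::DNAString(sub)))
      expect_identical(vigsome:::translate_frame(s, f), want)
    }
  }
  expect_identical(longest_orf_3frames("ATGAAATAA"), 2L)
  expect_identical(longest_orf_3frames("TT"), 0L)
})

test_that("the coding score separates coding from stop-dense sequences", {
  coding <- paste0("ATG", strrep("GCT", 80), "TAA")       # 246 nt, 81-aa ORF
  expect_gt(coding_score(coding), 0)
  # stops planted in all three frames every 42 nt: short ORFs, low coverage
  noncoding <- strrep(paste0("TTAATTAATTAA", strrep("GCA", 10)), 8)
  expect_lt(coding_score(noncoding), 0)
  expect_error(coding_score(strrep("A", 150)), "200 nt")
})

test_that("lncRNA classification excludes same-strand gene-model overlap", {
  seqs <- c(l1 = strrep("ACGTAA", 50))
  models <- data.frame(ref = "chr1", gene_id = "g_l1", transcript_id = "l1",
                       strand = "+", start = 100L, end = 399L,
                       biotype = "lncRNA", stringsAsFactors = FALSE)
  gm_same <- data.frame(ref = "chr1", gene_id = "gc", transcript_id = "gc.1",
                        strand = "+", start = 350L, end = 600L,
                        biotype = "protein_coding", stringsAsFactors = FALSE)
  out <- classify_lncrna(seqs, models = models, gene_models = gm_same,
                         scorer = function(s) -1)
  expect_identical(out$verdict, "excluded")
  expect_identical(out$reason, "gene_model_overlap")
  # opposite strand does not exclude
  gm_opp <- gm_same
  gm_opp$strand <- "-"
  out2 <- classify_lncrna(seqs, models = models, gene_models = gm_opp,
                          scorer = function(s) -1)
  expect_identical(out2$verdict, "lncRNA")
  expect_identical(out2$orf_aa, 99L)
})

test_that("identical intron chains produce no AS events", {
  models <- data.frame(
    ref = "c1", gene_id = "g", transcript_id = rep(c("t1", "t2"), each = 2),
    strand = "+", start = c(1L, 201L, 1L, 201L), end = c(100L, 400L, 100L, 400L),
    stringsAsFactors = FALSE)
  expect_identical(nrow(extract_as_events(models)), 0L)
  expect_identical(nrow(extract_all_as_events(models)), 0L)
})
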