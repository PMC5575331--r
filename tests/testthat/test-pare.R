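test_that("degradome profiles tally 5'-end placements", {
  set.seed(21)
  tx <- c(t1 = paste0(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                      collapse = ""))
  tag <- substr(tx, 5, 24)
  tags <- c(tag, tag, "TTTTTTTTTTTTTTTTTTTT", "ACG")  # 2 hits, 1 miss, 1 short
  prof <- build_profile(tags, tx)
  expect_s3_class(prof, "degradome_profile")
  expect_identical(prof$profile$t1[5], 2L)
  expect_identical(sum(prof$profile$t1), 2L)
  expect_identical(prof$total, 2L)
})

test_that("position categories implement the five-level scheme", {
  pc <- vigsome:::position_categories
  expect_identical(pc(c(0L, 5L, 5L, 3L, 1L, 0L, 2L)),
                   c(NA, 1L, 1L, 3L, 4L, NA, 3L))
  # unique maximum with count > 1 is category 0
  expect_identical(pc(c(9L, 2L, 2L, 0L)), c(0L, 3L, 3L, NA))
  # counts above the nonzero median are category 2
  expect_identical(pc(c(9L, 4L, 2L, 2L, 2L)), c(0L, 2L, 3L, 3L, 3L))
  expect_identical(pc(c(0L, 0L)), c(NA_integer_, NA_integer_))
  prof <- structure(list(profile = list(t1 = c(0L, 9L, 2L, 2L, 0L)),
                         total = 13L), class = "degradome_profile")
  expect_identical(categorize_site(prof, "t1", 1L), 0L)
  expect_true(is.na(categorize_site(prof, "t1", 0L)))
  expect_error(categorize_site(prof, "nope", 0L), "unknown transcript")
})

test_that("window scanning equals per-window pair scoring", {
  set.seed(23)
  q <- paste0(sample(c("A", "C", "G", "U"), 21, replace = TRUE), collapse = "")
  t <- paste0(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  sc <- vigsome:::scan_scores(vigsome:::encode_rna(q),
                              vigsome:::encode_rna(t))
  expect_length(sc, 60 - 21 + 1)
  for (s in seq_along(sc)) {
    expect_identical(sc[s], score_pairing(q, substr(t, s, s + 20)))
  }
})

test_that("the batched event caller reproduces the reference shuffle p-value", {
  set.seed(29)
  mk_seq <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
  transcripts <- c(t1 = mk_seq(120), t2 = mk_seq(120))
  q <- revcomp(substr(transcripts[["t1"]], 41, 61))   # perfect 21-nt site
  tags <- c(rep(substr(transcripts[["t1"]], 52, 71), 5),   # peak at site
            rep(substr(transcripts[["t1"]], 11, 30), 2),
            rep(substr(transcripts[["t2"]], 21, 40), 3))
  prof <- build_profile(tags, transcripts)
  events <- call_cleavage_events(q, list(s1 = prof), transcripts, seed = 3)
  expect_gte(nrow(events), 1L)
  hit <- events[events$transcript == "t1" & events$cleavage_pos == 51L, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$score, 0)
  expect_identical(hit$category, 0L)
  for (i in seq_len(nrow(events))) {
    if (is.na(events$category[i])) {
      expect_true(is.na(events$p_value[i]))
      next
    }
    ref_p <- site_pvalue(events[i, ], prof, transcripts, seed = 3)
    expect_identical(events$p_value[i], ref_p)
  }
})

test_that("event filtering requires a significant library and a good category", {
  base <- data.frame(srna = "q", srna_seq = "X", start = 0L, end = 21L,
                     score = 3, stringsAsFactors = FALSE)
  ev <- rbind(
    cbind(base, transcript = "keep", cleavage_pos = 5L,
          library = c("l1", "l2"), count = c(5L, 2L),
          category = c(0L, 3L), p_value = c(0.2, 0.01)),
    cbind(base, transcript = "bad_cat", cleavage_pos = 9L,
          library = c("l1", "l2"), count = c(5L, 2L),
          category = c(2L, 3L), p_value = c(0.01, 0.01)),
    cbind(base, transcript = "bad_p", cleavage_pos = 3L,
          library = c("l1", "l2"), count = c(5L, 2L),
          category = c(0L, 0L), p_value = c(0.2, 0.6)))
  out <- filter_events(ev)
  expect_identical(unique(out$transcript), "keep")
  expect_identical(nrow(out), 2L)
})

test_that("condition comparison flags one-sided categorical improvement", {
  ev <- data.frame(
    srna = "q", srna_seq = "X", transcript = "t", start = 10L, end = 31L,
    cleavage_pos = 21L, score = 2,
    library = c("t1", "t2", "m1"), count = c(8L, 6L, 1L),
    category = c(0L, 1L, 3L), p_value = c(0.01, 0.01, 0.4),
    stringsAsFactors = FALSE)
  cond <- factor(c("mock", "mock", "treated", "treated"),
                 levels = c("mock", "treated"))
  names(cond) <- c("m1", "m2", "t1", "t2")
  expr <- matrix(c(10, 10, 5, 5), nrow = 1,
                 dimnames = list("t", c("m1", "m2", "t1", "t2")))
  out <- compare_conditions(ev, cond, expression = expr)
  expect_identical(nrow(out), 1L)
  expect_true(out$improved_in_treated)
  expect_false(out$improved_in_mock)
  expect_identical(out$cats_mock, "3,NA")
  expect_identical(out$cats_treated, "0,1")
  expect_equal(out$target_fold_change, 0.5)
  # density export lists nonzero positions
  prof <- structure(list(profile = list(t1 = c(0L, 4L, 0L, 1L)), total = 5L),
                    class = "degradome_profile")
  path <- tempfile(fileext = ".tsv")
  write_density(prof, path)
  tab <- read.delim(path)
  expect_identical(tab$position, c(2L, 4L))
  expect_identical(tab$count, c(4L, 1L))
})
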