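test_that("read preprocessing clips adapters and applies length bounds", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "ACGTACGTACGTACGTACGTA"               # 21 nt
  reads <- c(paste0(insert, adapter),              # clipped to 21
             paste0(strrep("A", 14), substr(adapter, 1, 10)),  # 14 nt: dropped
             strrep("C", 31),                      # no adapter, too long
             strrep("G", 30),                      # no adapter, kept
             paste0(strrep("T", 15), adapter, "GGGG"))  # clipped to 15
  out <- preprocess_reads(reads, adapter = adapter)
  expect_identical(out, c(insert, strrep("G", 30), strrep("T", 15)))
  expect_warning(preprocess_reads(c("ACGTNACGTACGTACGTACGT", insert)),
                 "non-nucleotide")
  expect_error(preprocess_reads(insert, adapter = "TGGAATT"), "8 nt")
})

test_that("contaminant filtering removes substring matches on both strands", {
  contam <- c(r1 = "AAACCCGGGTTTAAACCCGGGTTTAAA")
  tags <- c(sub_fwd = substr(contam, 4, 24),          # forward substring
            sub_rc = revcomp(substr(contam, 2, 22)),  # reverse-complement
            clean = "ACGTGACGTGACGTGACGTGA")
  out <- filter_contaminants(unname(tags), contam)
  expect_identical(out, unname(tags["clean"]))
  # data.frame input is filtered by row
  tab <- data.frame(sequence = unname(tags), length = nchar(tags),
                    count.l1 = c(3L, 2L, 1L), stringsAsFactors = FALSE)
  out2 <- filter_contaminants(tab, contam)
  expect_identical(out2$sequence, unname(tags["clean"]))
  expect_warning(res <- filter_contaminants(unname(tags), character(0)),
                 "empty contaminant")
  expect_identical(res, unname(tags))
})

test_that("tag collapsing counts every library correctly", {
  libs <- list(a = c("AAA", "CCC", "AAA", "GGG"),
               b = c("CCC", "CCC"))
  tab <- collapse_and_count(libs)
  tab <- tab[order(tab$sequence), ]
  expect_identical(tab$sequence, c("AAA", "CCC", "GGG"))
  expect_identical(tab$count.a, c(2L, 1L, 1L))
  expect_identical(tab$count.b, c(0L, 2L, 0L))
  expect_identical(tab$length, c(3L, 3L, 3L))
  tpm <- normalize_tpm(tab)
  expect_equal(sum(tpm$tpm.a), 1e6)
  expect_equal(sum(tpm$tpm.b), 1e6)
})

test_that("exact mapping agrees with a gregexpr oracle and caps multi-mappers", {
  set.seed(9)
  genome <- c(chrA = paste0(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                            collapse = ""))
  tag_p <- substr(genome, 101, 121)                 # plus-strand hit
  tag_m <- revcomp(substr(genome, 201, 222))        # minus-strand hit
  hot <- "ACGTACGTACGTACGTACGTA"
  genome <- c(genome,
              chrB = paste0(c(rep(hot, 7)), collapse = ""))  # 7+ hits
  aln <- map_exact(c(tag_p, tag_m, hot), genome)
  # oracle: all occurrences via gregexpr on both strands
  occ <- function(tag, s) {
    f <- gregexpr(tag, s, fixed = TRUE)[[1]]
    r <- gregexpr(revcomp(tag), s, fixed = TRUE)[[1]]
    sum(f > 0) + sum(r > 0)
  }
  n_p <- sum(vapply(genome, function(s) occ(tag_p, s), numeric(1)))
  expect_identical(sum(aln$tag == tag_p), as.integer(n_p))
  row_p <- aln[aln$tag == tag_p & aln$ref == "chrA", ][1, ]
  expect_identical(row_p$start, 100L)               # 0-based
  expect_identical(row_p$end, 121L)
  expect_identical(row_p$strand, "+")
  expect_identical(row_p$five_prime, 100L)
  row_m <- aln[aln$tag == tag_m & aln$ref == "chrA", ][1, ]
  expect_identical(row_m$strand, "-")
  expect_identical(row_m$start, 200L)
  expect_identical(row_m$five_prime, 221L)          # 5' end on minus strand
  # over-mapping tag excluded and reported
  expect_false(hot %in% aln$tag)
  expect_true(hot %in% attr(aln, "excluded"))
})
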