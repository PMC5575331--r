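test_that("revcomp matches a chartr-based oracle", {
  oracle <- function(x) {
    vapply(toupper(x), function(s) {
      paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  set.seed(1)
  seqs <- vapply(1:25, function(i)
    paste0(sample(c("A", "C", "G", "T"), sample(5:60, 1), replace = TRUE),
           collapse = ""), character(1))
  expect_identical(revcomp(seqs), oracle(seqs))
  expect_identical(revcomp("acgt"), "ACGT")
})

test_that("substream seeds are deterministic and name-sensitive", {
  expect_identical(substream_seed(42L, "reads.fasta"),
                   substream_seed(42L, "reads.fasta"))
  expect_false(substream_seed(42L, "a") == substream_seed(42L, "b"))
  expect_false(substream_seed(1L, "a") == substream_seed(2L, "a"))
  s <- substream_seed(7L, "x")
  expect_true(s >= 0 && s < 2^31)
})

test_that("FASTA and FASTQ writing round-trips", {
  seqs <- c(r1 = "ACGTACGTACGT", r2 = "TTTTGGGG", r3 = "A")
  fa <- tempfile(fileext = ".fasta")
  fq <- tempfile(fileext = ".fastq")
  write_seqs(seqs, fa, format = "fasta")
  write_seqs(seqs, fq, format = "fastq")
  expect_identical(read_seqs(fa), seqs)
  expect_identical(read_seqs(fq), seqs)
  # quality line is constant Phred 'I' of the right length
  lines <- readLines(fq)
  expect_identical(lines[4], strrep("I", nchar(seqs[1])))
})

test_that("GFF3 writing round-trips the exon-table representation", {
  models <- data.frame(
    ref = "chr1",
    gene_id = c("gA", "gA", "gA", "gB"),
    transcript_id = c("gA.1", "gA.1", "gA.2", "gB.1"),
    strand = c("+", "+", "+", "-"),
    start = c(11L, 101L, 11L, 501L),
    end = c(50L, 150L, 150L, 800L),
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "lncRNA"),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".gff3")
  write_gff3(models, path)
  got <- read_gff3(path)
  rownames(got) <- NULL
  want <- models[order(models$ref, models$transcript_id, models$start), ]
  rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("transcript sequences splice exons and honor strand", {
  genome <- c(chr1 = "AAACCCGGGTTTACGTACGTAAAA")
  models <- data.frame(
    ref = "chr1", gene_id = "g", transcript_id = c("t1", "t1", "t2"),
    strand = c("+", "+", "-"),
    start = c(4L, 13L, 7L), end = c(6L, 16L, 12L),
    stringsAsFactors = FALSE)
  out <- transcript_seqs(models, genome)
  expect_identical(out[["t1"]], "CCCACGT")
  expect_identical(out[["t2"]], revcomp(substr(genome[[1]], 7, 12)))
  expect_identical(transcript_lengths(models),
                   c(t1 = 7L, t2 = 6L))
})
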