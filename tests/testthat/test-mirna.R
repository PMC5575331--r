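# recursive memoized maximum-base-pair oracle (Watson-Crick + G:U,
# minimum loop of min_loop unpaired nucleotides)
brute_max_pairs <- function(s, min_loop = 3L) {
  b <- strsplit(chartr("T", "U", toupper(s)), "")[[1]]
  can <- function(x, y)
    paste0(x, y) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  n <- length(b)
  memo <- matrix(NA_integer_, n, n)
  f <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- f(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (can(b[k], b[j])) {
        left <- if (k > i) f(i, k - 1L) else 0L
        best <- max(best, 1L + left + f(k + 1L, j - 1L))
      }
    }
    memo[i, j] <<- best
    best
  }
  f(1L, n)
}

test_that("the built-in folder maximizes base pairs and emits valid structures", {
  expect_identical(fold_rna("GGGGAAACCCC"), "((((...))))")
  legal <- c("AU", "UA", "CG", "GC", "GU", "UG")
  set.seed(11)
  for (rep in 1:20) {
    s <- paste0(sample(c("A", "C", "G", "U"), sample(10:16, 1),
                       replace = TRUE), collapse = "")
    db <- fold_rna(s)
    # optimality against the oracle
    expect_identical(sum(strsplit(db, "")[[1]] == "("), brute_max_pairs(s))
    # structural validity: legal pairs, minimum loop of 3
    partner <- structure_pairs(db)
    b <- strsplit(s, "")[[1]]
    for (i in which(!is.na(partner))) {
      j <- partner[i]
      expect_true(paste0(b[i], b[j]) %in% legal)
      expect_gte(abs(j - i), 4L)
    }
  }
  expect_error(fold_rna("ACGUACGU"), "shorter")
  expect_error(structure_pairs("(()"), "unbalanced")
  expect_error(structure_pairs("())"), "unbalanced")
})

test_that("hairpin evaluation enforces each precursor criterion", {
  mk <- function(db, mlen = 20L) {
    list(precursor = strrep("N", nchar(db)), structure = db,
         mature = strrep("A", mlen), mature_start = 0L)
  }
  # clean duplex: mature fully paired to the star arm
  ok <- evaluate_hairpin(mk(paste0(strrep("(", 20), "....", strrep(")", 20))))
  expect_true(ok$pass)
  expect_identical(ok$reasons, character(0))
  # five unpaired mature nucleotides exceed the limit of four
  up <- evaluate_hairpin(mk(paste0(".....", strrep("(", 15), "....",
                                   strrep(")", 15))))
  expect_false(up$pass)
  expect_identical(up$reasons, "unpaired")
  # mature folding back on itself is not on one arm
  arm <- evaluate_hairpin(mk(paste0(strrep("(", 10), "....",
                                    strrep(")", 10)), mlen = 24L))
  expect_false(arm$pass)
  expect_identical(arm$reasons, "arm")
  # asymmetric bulge: 3 mature vs 6 star unpaired between duplex segments
  bulge_db <- paste0(strrep("(", 10), "...", strrep("(", 7), "....",
                     strrep(")", 7), "......", strrep(")", 10))
  bg <- evaluate_hairpin(mk(bulge_db))
  expect_false(bg$pass)
  expect_identical(bg$reasons, "bulge")
  # mature length outside 20-24
  ln <- evaluate_hairpin(mk(paste0(strrep("(", 19), "....", strrep(")", 19)),
                            mlen = 19L))
  expect_false(ln$pass)
  expect_identical(ln$reasons, "length")
})

test_that("catalog matching counts mismatches and resolves ties", {
  catalog <- c(zmir = "ACGTACGTACGTACGTACGTA",
               amir = "ACGTACGTACGTACGTACGTT",
               bmir = "TTTTTTTTTTTTTTTTTTTTT")
  # exact hit
  m0 <- match_known(c(x = "ACGTACGTACGTACGTACGTA"), catalog)
  expect_true(m0$conserved)
  expect_identical(m0$known_id, "zmir")
  expect_identical(m0$mismatches, 0L)
  # equidistant (1 mismatch to both zmir and amir): lexicographic tie-break
  m1 <- match_known(c(x = "ACGTACGTACGTACGTACGTG"), catalog)
  expect_identical(m1$known_id, "amir")
  expect_identical(m1$mismatches, 1L)
  # three mismatches: not conserved
  m3 <- match_known(c(x = "TTTTACGTACGTACGTACGTA"), catalog)
  expect_false(m3$conserved)
  expect_true(is.na(m3$known_id))
  # length differences never match; U and T are equivalent
  expect_false(match_known(c(x = "ACGTACGT"), catalog)$conserved)
  mu <- match_known(c(x = "ACGUACGUACGUACGUACGUA"), catalog)
  expect_identical(mu$known_id, "zmir")
  expect_error(match_known(c(x = "ACGT"), character(0)), "empty")
})

test_that("planted miRNA loci are discovered and annotated on a small simulation", {
  cfg <- sim_config(seed = 3, n_mirna_loci = 3L, n_phas_loci = 0L,
                    n_coding_loci = 4L, n_lncrna_loci = 2L,
                    reads_per_srna_library = 40000L)
  ref <- make_reference(cfg)
  srna <- simulate_srna_libraries(ref, cfg)
  reads <- lapply(lapply(srna, preprocess_reads), filter_contaminants,
                  contaminants = ref$contaminants)
  tab <- normalize_tpm(collapse_and_count(reads))
  aln <- map_exact(tab$sequence, ref$genome)
  disc <- discover_mirnas(aln, tab, ref$genome, catalog = ref$catalog)
  for (i in seq_len(nrow(ref$truth$mirna))) {
    mat <- ref$truth$mirna$mature[i]
    rows <- disc[disc$tag == mat, , drop = FALSE]
    expect_gte(nrow(rows), 1L)
    expect_true(all(rows$pass))
    expect_true(all(rows$known_id ==
                      names(ref$catalog)[match(mat, ref$catalog)]))
  }
})
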