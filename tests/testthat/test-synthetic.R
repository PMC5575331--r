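small_cfg <- function(seed) {
  sim_config(seed = seed, n_mirna_loci = 2L, n_phas_loci = 2L,
             n_coding_loci = 4L, n_lncrna_loci = 2L,
             reads_per_srna_library = 20000L,
             tags_per_degradome_library = 5000L)
}

test_that("simulation output is byte-identical for a fixed configuration", {
  s1 <- simulate_vigs_experiment(small_cfg(5))
  s2 <- simulate_vigs_experiment(small_cfg(5))
  expect_identical(s1$reference$genome, s2$reference$genome)
  expect_identical(s1$srna, s2$srna)
  expect_identical(s1$degradome, s2$degradome)
  expect_identical(s1$counts, s2$counts)
  s3 <- simulate_vigs_experiment(small_cfg(6))
  expect_false(identical(s1$reference$genome, s3$reference$genome))
})

test_that("configuration limits are enforced", {
  expect_error(sim_config(n_coding_loci = 3L))
  expect_error(sim_config(n_coding_loci = 1000L, max_genome = 1e5),
               "sizing error")
})

test_that("ground truth survives a write/read round-trip", {
  ref <- make_reference(small_cfg(8))
  td <- tempfile()
  dir.create(td)
  write_truth(ref$truth, td)
  rt <- read_truth(td)
  for (nm in c("mirna", "phas", "cleavage", "expression", "as_switch",
               "effects")) {
    expect_equal(rt[[nm]], ref$truth[[nm]], tolerance = 1e-10)
  }
})

test_that("planted triggers are perfect complements of their cleavage window", {
  ref <- make_reference(small_cfg(9))
  ph <- ref$truth$phas
  expect_gt(nrow(ph), 0L)
  for (i in seq_len(nrow(ph))) {
    tx <- ref$transcripts[[ph$id[i]]]
    win <- substr(tx, ph$origin[i] - 11L, ph$origin[i] + 10L)
    expect_identical(score_pairing(ph$trigger_seq[i], win), 0)
    # the recorded trigger cleavage site sits at the phase origin
    tc <- ref$truth$cleavage
    row <- tc[tc$kind == "trigger_site" & tc$transcript == ph$id[i], ]
    expect_identical(row$cleavage_pos, ph$origin[i])
  }
})

test_that("degradome simulation refuses sites too close to transcript ends", {
  cfg <- small_cfg(10)
  ref <- make_reference(cfg)
  ref$truth$cleavage$cleavage_pos[1] <-
    nchar(ref$transcripts[[ref$truth$cleavage$transcript[1]]]) - 2L
  expect_error(simulate_degradome(ref, cfg), "placement error")
})
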