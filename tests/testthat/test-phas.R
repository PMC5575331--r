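test_that("phase registers follow the two-strand duplex convention", {
  expect_identical(phase_of(c(0L, 21L, 42L, 5L), rep("+", 4)),
                   c(0L, 0L, 0L, 5L))
  # minus-strand 5' ends are shifted by the 2-nt 3' overhang
  expect_identical(phase_of(c(2L, 23L, 44L, 3L), rep("-", 4)),
                   c(0L, 0L, 0L, 1L))
})

aln_row <- function(tag, fp, len = 21L, strand = "+", ref = "tx") {
  data.frame(tag = tag, ref = ref, start = fp, end = fp + len,
             strand = strand, five_prime = fp, length = len,
             n_hits = 1L, stringsAsFactors = FALSE)
}

test_that("window positivity rules are enforced at their boundaries", {
  lens <- c(tx = 250L)
  fps_in <- c(0L, 21L, 42L, 63L)                   # register 0
  fps_out <- c(5L, 10L, 55L, 100L, 150L, 180L)     # other registers
  mk <- function(fps, widths) {
    do.call(rbind, lapply(seq_along(fps), function(i)
      aln_row(paste0("t", sprintf("%02d", i)), fps[i], widths[i])))
  }
  # 10 unique tags, all 21 nt, 4 in register 0: positive
  a10 <- mk(c(fps_in, fps_out), rep(21L, 10))
  w <- scan_windows(a10, lens)
  w0 <- w[w$start == 0L & w$register == 0L, ]
  expect_identical(nrow(w0), 1L)
  expect_identical(w0$n_unique, 10L)
  expect_identical(w0$k, 4L)
  # 9 unique tags: below the minimum, nothing positive
  a9 <- mk(c(fps_in, fps_out[1:5]), rep(21L, 9))
  expect_identical(nrow(scan_windows(a9, lens)), 0L)
  # exactly half 21-nt is not "more than half": nothing positive
  a_half <- mk(c(fps_in, fps_out), c(rep(21L, 5), rep(22L, 5)))
  expect_identical(nrow(scan_windows(a_half, lens)), 0L)
  # 6 of 10 at 21 nt passes again
  a_six <- mk(c(fps_in, fps_out), c(rep(21L, 6), rep(22L, 4)))
  expect_gt(nrow(scan_windows(a_six, lens)), 0L)
  # minus-strand read at five_prime 23 supports register 0
  a_minus <- rbind(mk(c(0L, 42L, 63L, fps_out), rep(21L, 9)),
                   aln_row("t10", 23L, strand = "-"))
  wm <- scan_windows(a_minus, lens)
  expect_identical(wm[wm$start == 0L & wm$register == 0L, ]$k, 4L)
})

test_that("positive windows merge into loci with a 5'-most phase origin", {
  lens <- c(tx = 250L)
  a <- do.call(rbind, lapply(1:10, function(i) {
    fp <- c(0L, 21L, 42L, 63L, 5L, 10L, 55L, 100L, 150L, 180L)[i]
    aln_row(paste0("t", sprintf("%02d", i)), fp)
  }))
  w <- scan_windows(a, lens)
  loci <- merge_windows(w, a)
  l0 <- loci[loci$register == 0L, ]
  expect_identical(nrow(l0), 1L)
  expect_identical(l0$origin, 0L)
  expect_identical(l0$k, 4L)
  expect_true(l0$p_value > 0 && l0$p_value <= 1)
  # detect_phas_loci is scan + merge
  expect_equal(detect_phas_loci(a, lens), merge_windows(w, a))
})

test_that("the phasing score follows its closed form and guards k", {
  expect_equal(phasing_score(5, 10, 2), 3 * log1p(10 * 10 / 3))
  expect_equal(phasing_score(3, 0, 0), 0)
  expect_error(phasing_score(2, 10, 2), "k < 3")
})

test_that("trigger assignment requires in-register cleavage near the origin", {
  loci <- data.frame(ref = c("p1", "p1", "p2"), origin = c(300L, 300L, NA),
                     stringsAsFactors = FALSE)
  events <- data.frame(
    srna = c("far", "offreg", "good"),
    transcript = "p1",
    cleavage_pos = c(342L, 320L, 321L),
    stringsAsFactors = FALSE)
  out <- assign_trigger(loci, events)
  expect_identical(out$trigger, c("good", "good", NA))
  # cleavage exactly at the origin also qualifies
  out0 <- assign_trigger(loci[1, , drop = FALSE],
                         data.frame(srna = "exact", transcript = "p1",
                                    cleavage_pos = 300L))
  expect_identical(out0$trigger, "exact")
})
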