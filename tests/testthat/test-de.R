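test_that("size factors reproduce the median-of-ratios hand calculation", {
  counts <- matrix(c(10, 30, 50,
                     20, 60, 100), ncol = 2)
  sf <- size_factors(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(prod(sf), 1, tolerance = 1e-12)
})

test_that("the exact NB p-value collapses to the conditional binomial when dispersion vanishes", {
  # with equal group sizes (1 vs 1) and alpha -> 0 the conditional
  # distribution of a | a + b is Binomial(s, 1/2); the two-sided minimum-
  # likelihood p must match binom.test
  for (ab in list(c(3L, 10L), c(0L, 5L), c(7L, 7L), c(2L, 20L))) {
    a <- ab[1]; b <- ab[2]
    p_nb <- vigsome:::nb_exact_p(a, b, 1L, 1L, alpha = 1e-10)
    p_bin <- stats::binom.test(a, a + b, 0.5)$p.value
    expect_equal(p_nb, p_bin, tolerance = 1e-5)
  }
  expect_true(is.na(vigsome:::nb_exact_p(0L, 0L, 1L, 1L, alpha = 0.1)))
})

test_that("nb_exact_test validates inputs and handles degenerate rows", {
  m <- matrix(c(5L, 6L, 7L, 50L, 60L, 70L,
                0L, 0L, 0L, 0L, 0L, 0L), nrow = 2, byrow = TRUE)
  rownames(m) <- c("x", "zero")
  cond <- factor(rep(c("mock", "treated"), each = 3),
                 levels = c("mock", "treated"))
  res <- nb_exact_test(m, cond)
  expect_true(is.na(res$pvalue[res$id == "zero"]))
  expect_identical(res$call[res$id == "zero"], "ns")
  expect_error(nb_exact_test(m, factor(c("a", "a", "a", "a", "a", "b"))),
               "replicates")
  expect_error(nb_exact_test(m, factor(rep("a", 6))), "two levels")
})
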