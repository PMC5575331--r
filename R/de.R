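# Negative-binomial differential expression shared by the sRNA, transcript,
# gene and lncRNA callers: median-of-ratios size factors, pooled
# method-of-moments dispersion, and a conditional exact-style two-sided test.

#' Median-of-ratios size factors
#'
#' DESeq-style library size factors: each library's median ratio to the
#' per-feature geometric mean, over features with no zero counts.
#'
#' @param counts integer matrix, features x libraries.
#' @return numeric vector of size factors (geometric mean 1).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts == 0) == 0
  if (!any(pos)) {
    # degenerate: fall back to total-count ratios
    sf <- colSums(counts)
    sf <- sf / exp(mean(log(sf[sf > 0])))
    return(sf)
  }
  lgm <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(cj) {
    stats::median(exp(log(cj) - lgm))
  })
  sf / exp(mean(log(sf)))
}

# pooled method-of-moments dispersion on size-factor-normalized counts.
# Per-feature alpha = (pooled within-condition variance - mean) / mean^2,
# averaged (trimmed) over features with adequate counts.
pooled_dispersion <- function(q, condition) {
  condition <- as.factor(condition)
  groups <- split(seq_len(ncol(q)), condition)
  m <- rowMeans(q)
  # pooled within-condition variance
  ssq <- 0
  df <- 0
  for (idx in groups) {
    if (length(idx) < 2) next
    sub <- q[, idx, drop = FALSE]
    ssq <- ssq + rowSums((sub - rowMeans(sub))^2)
    df <- df + (length(idx) - 1L)
  }
  v <- ssq / df
  ok <- m > 1
  if (!any(ok)) return(1e-8)
  alpha <- (v[ok] - m[ok]) / m[ok]^2
  a <- mean(alpha, trim = 0.025)
  max(a, 1e-8)
}

# conditional exact two-sided NB test for one feature.
# a, b: rounded summed normalized counts in the two groups (sizes na, nb);
# alpha: dispersion. Returns the sum of probabilities of outcomes no more
# likely than the observed split, conditional on the total.
nb_exact_p <- function(a, b, na, nb, alpha) {
  s <- a + b
  if (s == 0) return(NA_real_)
  mhat <- s / (na + nb)
  size_a <- na / alpha
  size_b <- nb / alpha
  if (s > 5e5) {
    # normal approximation for very deep features
    mu_a <- na * mhat
    va <- mu_a + mu_a^2 / size_a
    z <- (a - mu_a) / sqrt(va)
    return(min(1, 2 * stats::pnorm(-abs(z))))
  }
  k <- 0:s
  lp <- stats::dnbinom(k, mu = na * mhat, size = size_a, log = TRUE) +
    stats::dnbinom(s - k, mu = nb * mhat, size = size_b, log = TRUE)
  lp <- lp - max(lp)
  p <- exp(lp)
  pobs <- p[a + 1L]
  sum(p[p <= pobs * (1 + 1e-8)]) / sum(p)
}

#' Negative-binomial exact differential test
#'
#' The shared two-condition count test: size-factor normalization, pooled
#' method-of-moments dispersion, per-feature conditional exact test on the
#' summed normalized counts, and Benjamini-Hochberg adjustment across tested
#' features.  Features with all-zero counts are excluded from testing and
#' reported `ns` with `NA` p-values.  A feature is called `up`/`down` when
#' its adjusted p-value is below `alpha_cut` and its fold change
#' (second condition over first) is at least `fold_cut` in either direction.
#'
#' @param counts feature x library count matrix (rownames = feature ids).
#' @param condition factor-like with two levels; the first level is the
#'   baseline (mock), the second the treatment.
#' @param alpha_cut adjusted-p threshold (default 0.05).
#' @param fold_cut fold-change threshold (default 2; inclusive).
#' @return data.frame: `id`, `base_mean_mock`, `base_mean_treated`,
#'   `fold_change` (treated/mock on normalized counts), `pvalue`, `padj`,
#'   `call` in `up`/`down`/`ns`.
#' @export
nb_exact_test <- function(counts, condition, alpha_cut = 0.05, fold_cut = 2) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L)
    stop("condition must have exactly two levels")
  tab <- table(condition)
  if (any(tab < 2L)) stop("need >= 2 replicates per condition")
  sf <- size_factors(counts)
  q <- sweep(counts, 2, sf, "/")
  alpha <- pooled_dispersion(q, condition)
  ia <- which(condition == levels(condition)[1])
  ib <- which(condition == levels(condition)[2])
  mean_a <- rowMeans(q[, ia, drop = FALSE])
  mean_b <- rowMeans(q[, ib, drop = FALSE])
  fc <- ifelse(mean_a > 0, mean_b / mean_a, ifelse(mean_b > 0, Inf, NA_real_))
  testable <- rowSums(counts) > 0
  pv <- rep(NA_real_, nrow(counts))
  a_sum <- round(rowSums(q[, ia, drop = FALSE]))
  b_sum <- round(rowSums(q[, ib, drop = FALSE]))
  for (i in which(testable)) {
    pv[i] <- nb_exact_p(a_sum[i], b_sum[i], length(ia), length(ib), alpha)
  }
  padj <- rep(NA_real_, length(pv))
  padj[testable] <- stats::p.adjust(pv[testable], method = "BH")
  call <- rep("ns", length(pv))
  sig <- !is.na(padj) & padj < alpha_cut & !is.na(fc) &
    (fc >= fold_cut | fc <= 1 / fold_cut)
  call[sig & fc > 1] <- "up"
  call[sig & fc < 1] <- "down"
  data.frame(id = if (!is.null(rownames(counts))) rownames(counts) else
               as.character(seq_len(nrow(counts))),
             base_mean_mock = mean_a, base_mean_treated = mean_b,
             fold_change = fc, pvalue = pv, padj = padj, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}
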