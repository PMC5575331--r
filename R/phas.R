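# PHAS locus detection: 189-nt sliding-window phase-register analysis,
# hypergeometric phasing p-values, phasing scores, window merging,
# differential phasiRNA abundance, and trigger assignment.
#
# Register bookkeeping uses the two-strand duplex convention with a 2-nt
# 3'-overhang: within a window starting at w, a plus-strand 21-mer whose 5'
# end sits at offset o is in register r when o = r (mod 21); a minus-strand
# 21-mer is in register r when o = r + 2 (mod 21).  A 189-nt window thus
# holds 9 plus-strand and 9 minus-strand in-register 5'-end positions
# (m_phase = 18) out of 378 possible positions (189 x 2 strands).

# per-alignment "phase offset": the register its 5' end supports, as an
# absolute (window-independent) value in 0..20
phase_of <- function(five_prime, strand) {
  ifelse(strand == "+", five_prime %% 21L, (five_prime - 2L) %% 21L)
}

#' Scan references for positive phasing windows
#'
#' Slides a `window`-nt window (default 189) along each reference and, for
#' each phase register, reports windows that satisfy the positivity rules:
#' at least `min_unique` unique sRNAs in the window, more than half of them
#' 21 nt long, and at least `min_in_register` unique 21-nt sRNAs whose 5'
#' ends fall on the register's in-phase positions.
#'
#' @param alignments alignment table from [map_exact()] (exact matches,
#'   already capped at 6 hits per tag).
#' @param ref_lengths named integer vector of reference lengths.
#' @param tab optional tag table with TPM columns; when given, `P_sum` and
#'   `U_sum` (summed TPM over all libraries of in-register vs out-of-register
#'   21-nt reads) are reported, otherwise raw counts are used.
#' @param window window span in nt (default 189).
#' @param step window step in nt (default 1).
#' @param min_unique minimum unique sRNAs per window (default 10).
#' @param min_in_register minimum in-register unique 21-nt sRNAs (default 3).
#' @return data.frame of positive windows: `ref`, `start` (0-based),
#'   `register` (absolute, 0..20), `n_unique`, `n_unique_21`, `k` (occupied
#'   in-register positions), `n_occupied` (occupied 21-nt positions),
#'   `P_sum`, `U_sum`.
#' @export
scan_windows <- function(alignments, ref_lengths, tab = NULL, window = 189L,
                         step = 1L, min_unique = 10L, min_in_register = 3L) {
  empty <- data.frame(ref = character(0), start = integer(0),
                      register = integer(0), n_unique = integer(0),
                      n_unique_21 = integer(0), k = integer(0),
                      n_occupied = integer(0), P_sum = numeric(0),
                      U_sum = numeric(0), stringsAsFactors = FALSE)
  if (nrow(alignments) == 0L) return(empty)
  abundance <- abundance_lookup(alignments$tag, tab)
  out <- list()
  for (r in unique(alignments$ref)) {
    a <- alignments[alignments$ref == r, , drop = FALSE]
    L <- ref_lengths[[r]]
    if (is.null(L) || is.na(L) || L < window) next
    a <- a[order(a$five_prime), , drop = FALSE]
    w_min <- max(0L, min(a$five_prime) - window + 1L)
    w_max <- min(L - window, max(a$five_prime))
    if (w_max < w_min) next
    starts <- seq(w_min, w_max, by = step)
    lo <- findInterval(starts - 0.5, a$five_prime) + 1L
    hi <- findInterval(starts + window - 0.5, a$five_prime)
    for (s in seq_along(starts)) {
      if (hi[s] < lo[s]) next
      sub <- a[lo[s]:hi[s], , drop = FALSE]
      n_unique <- length(unique(sub$tag))
      if (n_unique < min_unique) next
      is21 <- sub$length == 21L
      n21 <- length(unique(sub$tag[is21]))
      if (n21 * 2L <= n_unique) next
      s21 <- sub[is21, , drop = FALSE]
      phs <- phase_of(s21$five_prime, s21$strand)
      for (reg in unique(phs)) {
        inreg <- phs == reg
        if (length(unique(s21$tag[inreg])) < min_in_register) next
        k <- length(unique(paste(s21$five_prime, s21$strand)[inreg]))
        n_occ <- length(unique(paste(s21$five_prime, s21$strand)))
        ab <- abundance[s21$tag]
        out[[length(out) + 1L]] <- data.frame(
          ref = r, start = starts[s], register = reg,
          n_unique = n_unique, n_unique_21 = n21, k = k,
          n_occupied = n_occ,
          P_sum = sum(ab[inreg]), U_sum = sum(ab[!inreg]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# per-tag abundance: total TPM across libraries when available, else 1 per
# distinct tag (unique-read bookkeeping)
abundance_lookup <- function(tags, tab) {
  u <- unique(tags)
  if (is.null(tab)) return(stats::setNames(rep(1, length(u)), u))
  tpm <- rowSums(tag_tpm(tab))
  stats::setNames(ifelse(u %in% tab$sequence, tpm[match(u, tab$sequence)], 0), u)
}

#' Hypergeometric phasing p-value
#'
#' Tail probability that at least `k` of `n` occupied 21-nt 5'-end
#' positions fall on the `m_phase` in-register positions among `m` possible
#' positions, under random placement:
#' `p = sum_{x=k}^{min(n, m_phase)} C(m_phase, x) C(m - m_phase, n - x) / C(m, n)`.
#' For a single 189-nt window, `m = 378` and `m_phase = 18`.
#'
#' @param k occupied in-register positions.
#' @param n occupied positions in total.
#' @param m possible positions (default 378).
#' @param m_phase in-register positions (default 18).
#' @return p-value in `[0, 1]`.
#' @export
phasing_pvalue <- function(k, n, m = 378L, m_phase = 18L) {
  if (k > n || n > m || k > m_phase)
    stop("inconsistent window occupancy (k <= n <= m, k <= m_phase required)")
  xs <- k:min(n, m_phase)
  xs <- xs[n - xs <= m - m_phase]
  if (length(xs) == 0L) return(0)
  lden <- lchoose(m, n)
  min(1, sum(exp(lchoose(m_phase, xs) + lchoose(m - m_phase, n - xs) - lden)))
}

#' Phasing score
#'
#' `score = ln( (1 + 10 * P / (1 + U))^(k - 2) )` where `P` and `U` are the
#' summed abundances of in-register and out-of-register 21-nt reads in the
#' window and `k` the number of occupied in-register positions (>= 3).
#'
#' @param k occupied in-register positions (>= 3).
#' @param P_sum summed in-register abundance.
#' @param U_sum summed out-of-register abundance.
#' @return nonnegative score.
#' @export
phasing_score <- function(k, P_sum, U_sum) {
  if (k < 3L) stop("phasing score undefined for k < 3")
  (k - 2) * log1p(10 * P_sum / (1 + U_sum))
}

#' Merge positive windows into PHAS loci
#'
#' Overlapping or adjacent positive windows on the same reference with the
#' same absolute phase register are merged; locus statistics (occupancy,
#' p-value, score, phase origin) are recomputed over the merged span with
#' `m = 2 * span` and `m_phase` equal to the number of in-register 5'-end
#' positions in the span.
#'
#' @param windows positive windows from [scan_windows()].
#' @param alignments the alignment table used for scanning.
#' @param tab optional tag table (TPM abundances, as in [scan_windows()]).
#' @param window window span used in the scan (default 189).
#' @return data.frame of loci: `ref`, `start`, `end` (0-based half-open),
#'   `register`, `n_unique`, `k`, `n_occupied`, `P_sum`, `U_sum`,
#'   `p_value`, `score`, `origin` (0-based phase origin).
#' @export
merge_windows <- function(windows, alignments, tab = NULL, window = 189L) {
  empty <- data.frame(ref = character(0), start = integer(0), end = integer(0),
                      register = integer(0), n_unique = integer(0),
                      k = integer(0), n_occupied = integer(0),
                      P_sum = numeric(0), U_sum = numeric(0),
                      p_value = numeric(0), score = numeric(0),
                      origin = integer(0), stringsAsFactors = FALSE)
  if (nrow(windows) == 0L) return(empty)
  abundance <- abundance_lookup(alignments$tag, tab)
  out <- list()
  for (key in unique(paste(windows$ref, windows$register))) {
    wsub <- windows[paste(windows$ref, windows$register) == key, , drop = FALSE]
    wsub <- wsub[order(wsub$start), , drop = FALSE]
    reg <- wsub$register[1]
    ref <- wsub$ref[1]
    # merge overlapping/adjacent [start, start + window) intervals
    cur_s <- wsub$start[1]; cur_e <- wsub$start[1] + window
    spans <- list()
    for (i in seq_len(nrow(wsub))[-1]) {
      if (wsub$start[i] <= cur_e) {
        cur_e <- max(cur_e, wsub$start[i] + window)
      } else {
        spans[[length(spans) + 1L]] <- c(cur_s, cur_e)
        cur_s <- wsub$start[i]; cur_e <- wsub$start[i] + window
      }
    }
    spans[[length(spans) + 1L]] <- c(cur_s, cur_e)
    a <- alignments[alignments$ref == ref, , drop = FALSE]
    for (sp in spans) {
      sub <- a[a$five_prime >= sp[1] & a$five_prime < sp[2], , drop = FALSE]
      s21 <- sub[sub$length == 21L, , drop = FALSE]
      phs <- phase_of(s21$five_prime, s21$strand)
      inreg <- phs == reg
      span_len <- sp[2] - sp[1]
      offs <- seq_len(span_len) - 1L + sp[1]
      m_phase <- sum(offs %% 21L == reg) + sum((offs - 2L) %% 21L == reg)
      pos_key <- paste(s21$five_prime, s21$strand)
      k <- length(unique(pos_key[inreg]))
      n_occ <- length(unique(pos_key))
      ab <- abundance[s21$tag]
      P_sum <- sum(ab[inreg]); U_sum <- sum(ab[!inreg])
      pv <- phasing_pvalue(k, n_occ, m = 2L * span_len, m_phase = m_phase)
      sc <- if (k >= 3L) phasing_score(k, P_sum, U_sum) else NA_real_
      # phase origin: 5'-most occupied in-register position, with
      # minus-strand 5' ends projected back onto the plus-strand register
      # (the 2-nt duplex overhang)
      origin <- NA_integer_
      if (any(inreg)) {
        adj <- ifelse(s21$strand == "-", s21$five_prime - 2L, s21$five_prime)
        origin <- min(adj[inreg])
      }
      out[[length(out) + 1L]] <- data.frame(
        ref = ref, start = sp[1], end = sp[2], register = reg,
        n_unique = length(unique(sub$tag)), k = k, n_occupied = n_occ,
        P_sum = P_sum, U_sum = U_sum, p_value = pv, score = sc,
        origin = origin, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$ref, res$start, res$register), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect PHAS loci from alignments
#'
#' Convenience wrapper: [scan_windows()] then [merge_windows()].
#'
#' @inheritParams scan_windows
#' @return merged locus table (see [merge_windows()]).
#' @export
detect_phas_loci <- function(alignments, ref_lengths, tab = NULL,
                             window = 189L, step = 1L, min_unique = 10L,
                             min_in_register = 3L) {
  w <- scan_windows(alignments, ref_lengths, tab = tab, window = window,
                    step = step, min_unique = min_unique,
                    min_in_register = min_in_register)
  merge_windows(w, alignments, tab = tab, window = window)
}

#' Differential phasiRNA abundance between conditions
#'
#' Per-locus abundance is the summed TPM of 21-nt in-register tags in the
#' locus, per library.  A two-sided Welch t-test on `log2(TPM + 1)` across
#' replicates is reported together with the fold change (treated/mock of
#' condition means); loci with fold change at least 2 in either direction
#' and `p < 0.05` are flagged.
#'
#' @param loci locus table from [merge_windows()].
#' @param alignments alignment table.
#' @param tab tag table with per-library TPM.
#' @param condition two-level factor over libraries (first level = mock).
#' @return locus table with `abund.<lib>` columns, `fold_change`,
#'   `p_value_de`, `flag` (`"up"`, `"down"` or `"ns"`).
#' @export
differential_phas <- function(loci, alignments, tab, condition) {
  condition <- as.factor(condition)
  if (any(table(condition) < 2L)) stop("need >= 2 replicates per condition")
  tpm <- tag_tpm(tab)
  libs <- tag_libs(tab)
  abund <- matrix(0, nrow(loci), ncol(tpm), dimnames = list(NULL, libs))
  for (i in seq_len(nrow(loci))) {
    a <- alignments[alignments$ref == loci$ref[i] &
                      alignments$five_prime >= loci$start[i] &
                      alignments$five_prime < loci$end[i] &
                      alignments$length == 21L, , drop = FALSE]
    inreg <- phase_of(a$five_prime, a$strand) == loci$register[i]
    tags <- unique(a$tag[inreg])
    if (length(tags))
      abund[i, ] <- colSums(tpm[match(tags, tab$sequence), , drop = FALSE])
  }
  ia <- condition == levels(condition)[1]
  ib <- condition == levels(condition)[2]
  fc <- pv <- rep(NA_real_, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    x <- log2(abund[i, ia] + 1); y <- log2(abund[i, ib] + 1)
    ma <- mean(abund[i, ia]); mb <- mean(abund[i, ib])
    fc[i] <- if (ma > 0) mb / ma else NA_real_
    pv[i] <- if (stats::var(x) + stats::var(y) > 0)
      stats::t.test(y, x)$p.value else 1
  }
  flag <- rep("ns", nrow(loci))
  sig <- !is.na(pv) & pv < 0.05 & !is.na(fc) & (fc >= 2 | fc <= 0.5)
  flag[sig & fc > 1] <- "up"
  flag[sig & fc < 1] <- "down"
  out <- cbind(loci, as.data.frame(abund))
  names(out)[(ncol(loci) + 1L):ncol(out)] <- paste0("abund.", libs)
  out$fold_change <- fc
  out$p_value_de <- pv
  out$flag <- flag
  out
}

#' Assign trigger sRNAs to PHAS loci
#'
#' A locus is assigned trigger `t` when a validated cleavage event of `t`
#' on the locus reference lies within 21 nt of the locus phase origin and
#' the cleavage position is in register with the locus phase (offset from
#' the origin divisible by 21).
#'
#' @param loci locus table with `origin`.
#' @param events validated cleavage events (columns `srna`, `transcript`,
#'   `cleavage_pos`), e.g. from [filter_events()].
#' @return `loci` with added `trigger` column (`NA` when unassigned).
#' @export
assign_trigger <- function(loci, events) {
  trig <- rep(NA_character_, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    if (is.na(loci$origin[i])) next
    ev <- events[events$transcript == loci$ref[i], , drop = FALSE]
    if (nrow(ev) == 0L) next
    d <- ev$cleavage_pos - loci$origin[i]
    ok <- abs(d) <= 21L & d %% 21L == 0L
    if (any(ok)) trig[i] <- ev$srna[which(ok)[1]]
  }
  loci$trigger <- trig
  loci
}
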