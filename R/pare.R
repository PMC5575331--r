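# Degradome (PARE) analysis: per-transcript 5'-end density profiles,
# sRNA-target complementarity scoring (Allen penalties), exhaustive target
# search, CleaveLand-style site categories, composition-preserving shuffle
# p-values, event filtering and cross-condition comparison.

RNA_CODE <- c(A = 1L, C = 2L, G = 3L, U = 4L, T = 4L, N = 5L)

# penalty matrix, rows = sRNA base, cols = target (mRNA sense) base.
# Watson-Crick pair 0, G:U wobble 0.5, anything else (incl. N) 1.
pair_penalty_matrix <- function() {
  m <- matrix(1, 5, 5, dimnames = list(c("A", "C", "G", "U", "N"),
                                       c("A", "C", "G", "U", "N")))
  m["A", "U"] <- 0; m["U", "A"] <- 0; m["G", "C"] <- 0; m["C", "G"] <- 0
  m["G", "U"] <- 0.5; m["U", "G"] <- 0.5
  m
}

encode_rna <- function(x) {
  v <- RNA_CODE[strsplit(toupper(x), "")[[1]]]
  v[is.na(v)] <- 5L
  unname(v)
}

#' Score sRNA-target complementarity (Allen penalties)
#'
#' Aligns the sRNA antiparallel to a gap-free target window of equal
#' length.  Per position: Watson-Crick pair 0, G:U wobble 0.5, mismatch 1;
#' penalties are doubled at sRNA positions 2-13 (1-based from the sRNA 5'
#' end).  The score is the penalty sum.
#'
#' @param srna sRNA sequence, 5'->3' (RNA or DNA alphabet).
#' @param target target window, 5'->3' in mRNA sense, same length.
#' @return numeric penalty score (>= 0).
#' @export
score_pairing <- function(srna, target) {
  q <- encode_rna(srna)
  t <- encode_rna(target)
  if (length(q) != length(t)) stop("sRNA and target window lengths differ")
  L <- length(q)
  pm <- pair_penalty_matrix()
  w <- rep(1, L); w[2:min(13L, L)] <- 2
  sum(w * pm[cbind(q, t[L:1])])
}

# vectorized score of every gap-free window of `tcodes` (encoded transcript)
# against encoded query `qcodes`; returns scores indexed by 0-based window
# start.  Window [s, s+L): sRNA position i pairs transcript position
# s + L - i (0-based).
scan_scores <- function(qcodes, tcodes) {
  L <- length(qcodes)
  n <- length(tcodes)
  if (n < L) return(numeric(0))
  pm <- pair_penalty_matrix()
  w <- rep(1, L); w[2:min(13L, L)] <- 2
  starts <- 0:(n - L)
  total <- numeric(length(starts))
  for (i in seq_len(L)) {
    tpos <- starts + L - i          # 0-based transcript positions
    total <- total + w[i] * pm[cbind(qcodes[i], tcodes[tpos + 1L])]
  }
  total
}

#' Build degradome density profiles
#'
#' Exact-matches degradome tags to transcript plus strands; every
#' occurrence's 5'-most aligned position increments that transcript's
#' profile.  Tags shorter than `min_len` are discarded first.
#'
#' @param tags character vector of degradome tag sequences (one element per
#'   read; duplicates allowed).
#' @param transcripts named character vector of transcript sequences.
#' @param min_len minimum tag length (default 15).
#' @return object of class `degradome_profile`: list with `profile` (named
#'   list of per-position count vectors, 0-based positions stored 1-based in
#'   R vectors), `total` mapped placements.
#' @export
build_profile <- function(tags, transcripts, min_len = 15L) {
  tags <- tags[nchar(tags) >= min_len]
  prof <- lapply(transcripts, function(s) integer(nchar(s)))
  total <- 0L
  if (length(tags)) {
    u <- unique(tags)
    cnt <- tabulate(match(tags, u), nbins = length(u))
    hits <- exact_hits_plus(u, transcripts)
    if (nrow(hits)) {
      for (j in seq_len(nrow(hits))) {
        r <- hits$ref[j]
        pos <- hits$start[j] + 1L
        prof[[r]][pos] <- prof[[r]][pos] + cnt[hits$tag_idx[j]]
        total <- total + cnt[hits$tag_idx[j]]
      }
    }
  }
  structure(list(profile = prof, total = total), class = "degradome_profile")
}

#' Find candidate sRNA target sites
#'
#' Exhaustive gap-free scan of every window of every transcript against
#' every query; windows scoring at most `max_score` are reported with the
#' predicted cleavage position (the transcript nucleotide pairing sRNA
#' position 10; cleavage between positions 10 and 11).
#'
#' @param srnas named character vector of 21-22-nt sRNA sequences (others
#'   are dropped with a warning).
#' @param transcripts named character vector of transcript sequences.
#' @param max_score maximum allowed penalty score (default 7).
#' @return data.frame: `srna`, `srna_seq`, `transcript`, `start`, `end`
#'   (0-based half-open window), `cleavage_pos` (0-based), `score`.
#' @export
find_targets <- function(srnas, transcripts, max_score = 7) {
  if (is.null(names(srnas))) names(srnas) <- paste0("sRNA_", seq_along(srnas))
  len_ok <- nchar(srnas) %in% 21:22
  if (any(!len_ok)) {
    warning(sum(!len_ok), " sRNA(s) outside 21-22 nt dropped")
    srnas <- srnas[len_ok]
  }
  tcodes <- lapply(transcripts, encode_rna)
  out <- list()
  for (i in seq_along(srnas)) {
    q <- encode_rna(srnas[[i]])
    L <- length(q)
    for (tr in names(transcripts)) {
      sc <- scan_scores(q, tcodes[[tr]])
      hit <- which(sc <= max_score)
      if (length(hit) == 0L) next
      st <- hit - 1L
      out[[length(out) + 1L]] <- data.frame(
        srna = names(srnas)[i], srna_seq = unname(srnas[[i]]), transcript = tr,
        start = st, end = st + L, cleavage_pos = st + L - 10L,
        score = sc[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(srna = character(0), srna_seq = character(0),
                      transcript = character(0), start = integer(0),
                      end = integer(0), cleavage_pos = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# per-position categories for a transcript count vector (internal):
# 0 unique maximum with count > 1; 1 tied maximum > 1; 2 > median of
# nonzero positions; 3 <= that median; 4 singleton; NA where count == 0
position_categories <- function(counts) {
  cat <- rep(NA_integer_, length(counts))
  nz <- counts > 0L
  if (!any(nz)) return(cat)
  mx <- max(counts)
  med <- stats::median(counts[nz])
  n_at_max <- sum(counts == mx)
  cat[nz & counts == 1L] <- 4L
  big <- nz & counts > 1L
  cat[big & counts == mx & n_at_max == 1L] <- 0L
  cat[big & counts == mx & n_at_max > 1L] <- 1L
  cat[big & counts < mx & counts > med] <- 2L
  cat[big & counts < mx & counts <= med] <- 3L
  cat
}

#' CleaveLand-style category of a cleavage site
#'
#' Category 0: the site's count exceeds 1 and is the transcript's unique
#' maximum; 1: equals a tied maximum (> 1); 2: > 1, below the maximum but
#' above the median of nonzero positions; 3: > 1 and at or below that
#' median; 4: exactly 1.  A site with no tag returns `NA` (no event in
#' that sample).
#'
#' @param profile `degradome_profile` from [build_profile()].
#' @param transcript transcript id.
#' @param position 0-based cleavage position.
#' @return integer category in 0..4, or `NA`.
#' @export
categorize_site <- function(profile, transcript, position) {
  counts <- profile$profile[[transcript]]
  if (is.null(counts)) stop("unknown transcript: ", transcript)
  position_categories(counts)[position + 1L]
}

#' Shuffle-permutation p-value for a cleavage event
#'
#' Shuffles the query sequence `n_shuffles` times (preserving length and
#' nucleotide composition) and counts shuffles that achieve a score at or
#' below the observed score at any site whose category (in this sample's
#' profile) is equal to or better than the event's.
#' `p = (1 + hits) / (1 + n_shuffles)`.  Seeded and reproducible.
#'
#' @param event list or one-row data.frame with `srna_seq`, `score`, and
#'   `category` (the event's category in this sample).
#' @param profile the sample's `degradome_profile`.
#' @param transcripts named character vector of transcript sequences.
#' @param n_shuffles number of shuffles (default 100, >= 1).
#' @param seed integer seed; the actual stream is derived from
#'   `(seed, srna_seq)` so each query has its own substream.
#' @return p-value in `(0, 1]`.
#' @export
site_pvalue <- function(event, profile, transcripts, n_shuffles = 100L,
                        seed = 1L) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  if (is.na(event$category)) return(NA_real_)
  tcodes <- lapply(transcripts, encode_rna)
  cats <- lapply(names(transcripts), function(tr)
    position_categories(profile$profile[[tr]]))
  names(cats) <- names(transcripts)
  q <- encode_rna(event$srna_seq)
  L <- length(q)
  set.seed(substream_seed(seed, paste0("shuffle:", event$srna_seq)))
  hits <- 0L
  for (s in seq_len(n_shuffles)) {
    qs <- sample(q)
    found <- FALSE
    for (tr in names(transcripts)) {
      sc <- scan_scores(qs, tcodes[[tr]])
      if (length(sc) == 0L) next
      good <- sc <= event$score
      if (!any(good)) next
      cl <- (which(good) - 1L) + L - 10L
      cc <- cats[[tr]][cl + 1L]
      if (any(!is.na(cc) & cc <= event$category)) { found <- TRUE; break }
    }
    if (found) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_shuffles)
}

#' Call cleavage events across degradome libraries
#'
#' Pipeline glue: finds candidate target sites ([find_targets()]), then for
#' each event and each degradome library records the tag count at the site,
#' its category ([categorize_site()]) and, for categorized sites, the
#' shuffle p-value ([site_pvalue()]).
#'
#' @param srnas named 21-22-nt query set.
#' @param profiles named list of `degradome_profile`, one per library.
#' @param transcripts named character vector of transcript sequences.
#' @param max_score passed to [find_targets()].
#' @param n_shuffles,seed passed to [site_pvalue()].
#' @return data.frame with one row per event x library: event columns plus
#'   `library`, `count`, `category`, `p_value`.
#' @export
call_cleavage_events <- function(srnas, profiles, transcripts, max_score = 7,
                                 n_shuffles = 100L, seed = 1L) {
  ev <- find_targets(srnas, transcripts, max_score = max_score)
  if (nrow(ev) == 0L) {
    out <- cbind(ev, data.frame(library = character(0), count = integer(0),
                                category = integer(0), p_value = numeric(0)))
    return(out)
  }
  tcodes <- lapply(transcripts, encode_rna)
  pm <- pair_penalty_matrix()
  rows <- list()
  for (lib in names(profiles)) {
    prof <- profiles[[lib]]
    cnt <- vapply(seq_len(nrow(ev)), function(i)
      prof$profile[[ev$transcript[i]]][ev$cleavage_pos[i] + 1L], integer(1))
    ct <- vapply(seq_len(nrow(ev)), function(i)
      categorize_site(prof, ev$transcript[i], ev$cleavage_pos[i]), integer(1))
    pv <- rep(NA_real_, nrow(ev))
    todo <- which(!is.na(ct))
    if (length(todo)) {
      cats_all <- lapply(names(transcripts), function(tr)
        position_categories(prof$profile[[tr]]))
      names(cats_all) <- names(transcripts)
      # candidate sites (nonzero degradome positions) and the encoded
      # target bases each sRNA position pairs there, per query width
      site_mat <- list()
      for (L in unique(nchar(ev$srna_seq[todo]))) {
        Tm <- list(); cv <- list()
        for (tr in names(transcripts)) {
          n <- length(tcodes[[tr]])
          p <- which(prof$profile[[tr]] > 0L) - 1L
          p <- p[p >= L - 10L & p <= n - 10L]
          if (!length(p)) next
          idx <- outer(p, 10L - seq_len(L), "+") + 1L
          Tm[[tr]] <- matrix(tcodes[[tr]][idx], nrow = length(p))
          cv[[tr]] <- cats_all[[tr]][p + 1L]
        }
        site_mat[[as.character(L)]] <- list(
          T = do.call(rbind, Tm), cat = unlist(cv, use.names = FALSE))
      }
      for (qs in unique(ev$srna_seq[todo])) {
        q <- encode_rna(qs)
        L <- length(q)
        w <- rep(1, L); w[2:min(13L, L)] <- 2
        set.seed(substream_seed(seed, paste0("shuffle:", qs)))
        Q <- t(vapply(seq_len(n_shuffles), function(s) sample(q),
                      integer(L)))
        sm <- site_mat[[as.character(L)]]
        if (is.null(sm$T) || nrow(sm$T) == 0L) {
          cmin <- matrix(Inf, n_shuffles, 5)
        } else {
          mins <- .shuffle_min_scores_cpp(sm$T, as.integer(sm$cat), pm, w, Q)
          cmin <- t(apply(mins, 1, cummin))
        }
        for (i in todo[ev$srna_seq[todo] == qs]) {
          hits <- sum(cmin[, ct[i] + 1L] <= ev$score[i])
          pv[i] <- (1 + hits) / (1 + n_shuffles)
        }
      }
    }
    rows[[lib]] <- cbind(ev, data.frame(library = lib, count = cnt,
                                        category = ct, p_value = pv,
                                        stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Filter cleavage events across samples
#'
#' Keeps events (grouped by sRNA, transcript and cleavage position) with a
#' p-value below 0.05 in at least one sample and a category of 0 or 1 in at
#' least one sample (not necessarily the same sample).
#'
#' @param events per-event-per-sample table from [call_cleavage_events()].
#' @return subset of `events` for validated event groups.
#' @export
filter_events <- function(events) {
  key <- paste(events$srna, events$transcript, events$cleavage_pos)
  ok_p <- tapply(events$p_value, key, function(p) any(!is.na(p) & p < 0.05))
  ok_c <- tapply(events$category, key, function(ct) any(!is.na(ct) & ct <= 1L))
  keep <- names(ok_p)[ok_p & ok_c]
  events[key %in% keep, , drop = FALSE]
}

#' Compare cleavage activity between conditions
#'
#' For each validated event group, reports the per-sample category
#' profiles, a categorical improvement flag (all samples of one condition
#' at category at most `category_threshold` while at least one sample of
#' the other condition is worse or absent), and optionally the target
#' transcript's expression fold change.
#'
#' @param events validated events from [filter_events()].
#' @param condition named two-level factor over degradome library names
#'   (first level = mock).
#' @param expression optional expression matrix (transcripts x samples,
#'   e.g. FPKM) used to report the target's treated/mock fold change.
#' @param category_threshold categorical cut for the flag (default 1).
#' @return data.frame, one row per event group, with `cats_mock`,
#'   `cats_treated` (comma-separated), `improved_in_treated`,
#'   `improved_in_mock`, `target_fold_change`.
#' @export
compare_conditions <- function(events, condition, expression = NULL,
                               category_threshold = 1L) {
  condition <- as.factor(condition)
  mock_libs <- names(condition)[condition == levels(condition)[1]]
  trt_libs <- names(condition)[condition == levels(condition)[2]]
  key <- paste(events$srna, events$transcript, events$cleavage_pos)
  out <- list()
  for (k in unique(key)) {
    e <- events[key == k, , drop = FALSE]
    cm <- e$category[match(mock_libs, e$library)]
    ct <- e$category[match(trt_libs, e$library)]
    good <- function(x) !is.na(x) & x <= category_threshold
    imp_t <- all(good(ct)) && any(!good(cm))
    imp_m <- all(good(cm)) && any(!good(ct))
    fc <- NA_real_
    if (!is.null(expression) && e$transcript[1] %in% rownames(expression)) {
      x <- expression[e$transcript[1], ]
      fc <- mean(x[trt_libs]) / mean(x[mock_libs])
    }
    out[[length(out) + 1L]] <- data.frame(
      srna = e$srna[1], transcript = e$transcript[1],
      cleavage_pos = e$cleavage_pos[1], score = e$score[1],
      cats_mock = paste(cm, collapse = ","),
      cats_treated = paste(ct, collapse = ","),
      improved_in_treated = imp_t, improved_in_mock = imp_m,
      target_fold_change = fc, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a degradome density file
#'
#' TSV with columns `transcript`, `position` (1-based) and `count` for all
#' nonzero positions.
#'
#' @param profile `degradome_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density <- function(profile, path) {
  rows <- lapply(names(profile$profile), function(tr) {
    v <- profile$profile[[tr]]
    nz <- which(v > 0L)
    if (!length(nz)) return(NULL)
    data.frame(transcript = tr, position = nz, count = v[nz],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
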