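# Transcript-level analysis: FPKM, differential expression, alternative
# splicing event extraction and Type I/II change classification, and
# lncRNA identification.

#' Compute FPKM
#'
#' `fpkm = count / (length/1000) / (total/1e6)`.
#'
#' @param counts transcript x sample count matrix.
#' @param lengths named vector of transcript lengths (nt), matched to
#'   rownames of `counts`.
#' @param totals per-sample totals of mapped fragments (default: column
#'   sums of `counts`).
#' @return FPKM matrix with the same dimensions as `counts`.
#' @export
compute_fpkm <- function(counts, lengths, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(totals <= 0)) stop("per-sample totals must be positive")
  len <- lengths[rownames(counts)]
  if (any(is.na(len) | len <= 0)) stop("missing or nonpositive transcript length")
  sweep(counts / (len / 1000), 2, totals / 1e6, "/")
}

#' Differential expression of transcripts and genes
#'
#' Applies the shared negative-binomial exact test at the transcript level
#' and, when a transcript-to-gene map is supplied, also at the gene level
#' (counts summed over isoforms).
#'
#' @param counts transcript x sample count matrix.
#' @param condition two-level factor (first level = mock).
#' @param gene_of optional named vector mapping transcript ids to gene ids.
#' @param ... passed to [nb_exact_test()].
#' @return with `gene_of`: list with `transcript` and `gene` tables;
#'   otherwise a single transcript-level table.
#' @export
differential_genes <- function(counts, condition, gene_of = NULL, ...) {
  tr <- nb_exact_test(counts, condition, ...)
  if (is.null(gene_of)) return(tr)
  g <- gene_of[rownames(counts)]
  gc <- rowsum(as.matrix(counts), group = g)
  list(transcript = tr, gene = nb_exact_test(gc, condition, ...))
}

# intron table of one isoform from its sorted exon rows (1-based closed)
introns_of <- function(ex) {
  ex <- ex[order(ex$start), , drop = FALSE]
  n <- nrow(ex)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-n] + 1L, end = ex$start[-1] - 1L)
}

#' Extract alternative-splicing events from a locus
#'
#' Pairwise comparison of isoform intron chains within one locus.  Event
#' types: `intron_retention` (an intron of one isoform is fully exonic in
#' the other), `exon_skipping` (an internal exon of one isoform is absent
#' from the other, whose single intron spans both flanking introns and the
#' exon), `alt_5prime_donor` / `alt_3prime_acceptor` (two overlapping
#' introns sharing one boundary; donor = intron 5' end in transcription
#' direction, so labels are strand-aware).  Events are deduplicated across
#' isoform pairs by type and coordinates.
#'
#' Reported coordinates (1-based closed): the retained intron, the skipped
#' exon, or the interval between the two alternative splice boundaries.
#'
#' @param models exon table of the isoforms of one locus (same `ref` and
#'   `strand`).
#' @return data.frame: `locus`, `type`, `isoform_a`, `isoform_b`, `ref`,
#'   `strand`, `start`, `end`.
#' @export
extract_as_events <- function(models) {
  empty <- data.frame(locus = character(0), type = character(0),
                      isoform_a = character(0), isoform_b = character(0),
                      ref = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  isos <- unique(models$transcript_id)
  if (length(isos) < 2L) return(empty)
  stopifnot(length(unique(models$strand)) == 1L,
            length(unique(models$ref)) == 1L)
  strand <- models$strand[1]
  locus <- if ("gene_id" %in% names(models)) models$gene_id[1] else NA_character_
  exon_list <- lapply(isos, function(tr)
    models[models$transcript_id == tr, , drop = FALSE])
  names(exon_list) <- isos
  intron_list <- lapply(exon_list, introns_of)
  has_intron <- function(intr, s, e) any(intr$start == s & intr$end == e)
  out <- list()
  emit <- function(type, a, b, s, e) {
    out[[length(out) + 1L]] <<- data.frame(
      locus = locus, type = type, isoform_a = a, isoform_b = b,
      ref = models$ref[1], strand = strand, start = s, end = e,
      stringsAsFactors = FALSE)
  }
  for (ai in seq_along(isos)) for (bi in seq_along(isos)) {
    if (ai == bi) next
    a <- isos[ai]; b <- isos[bi]
    exA <- exon_list[[a]][order(exon_list[[a]]$start), , drop = FALSE]
    exB <- exon_list[[b]][order(exon_list[[b]]$start), , drop = FALSE]
    inA <- intron_list[[a]]; inB <- intron_list[[b]]
    # intron retention: intron of A absent in B and fully inside a B exon
    for (i in seq_len(nrow(inA))) {
      s <- inA$start[i]; e <- inA$end[i]
      if (has_intron(inB, s, e)) next
      if (any(exB$start < s & exB$end > e)) emit("intron_retention", a, b, s, e)
    }
    # exon skipping: internal exon of A absent from B, flanking introns of A
    # merged into one B intron spanning intron-exon-intron
    if (nrow(exA) >= 3L) {
      for (i in 2:(nrow(exA) - 1L)) {
        es <- exA$start[i]; ee <- exA$end[i]
        if (any(exB$start == es & exB$end == ee)) next
        l <- c(exA$end[i - 1L] + 1L, es - 1L)
        r <- c(ee + 1L, exA$start[i + 1L] - 1L)
        if (has_intron(inB, l[1], r[2])) emit("exon_skipping", a, b, es, ee)
      }
    }
    # alternative donor/acceptor: overlapping introns sharing one boundary.
    # When an exon lies entirely inside the differing interval the pattern
    # is exon skipping / intron retention, not a boundary shift, so the
    # pair is not reported here.
    exon_inside <- function(ds, de) {
      any(exA$start >= ds & exA$end <= de) ||
        any(exB$start >= ds & exB$end <= de)
    }
    for (i in seq_len(nrow(inA))) for (j in seq_len(nrow(inB))) {
      s1 <- inA$start[i]; e1 <- inA$end[i]
      s2 <- inB$start[j]; e2 <- inB$end[j]
      if (s1 == s2 && e1 == e2) next
      if (s1 == s2 && e1 != e2) {
        ds <- min(e1, e2) + 1L; de <- max(e1, e2)
        if (exon_inside(ds, de)) next
        # shared genomic-left boundary: donor on '+', acceptor on '-'
        type <- if (strand == "+") "alt_3prime_acceptor" else "alt_5prime_donor"
        emit(type, a, b, ds, de)
      } else if (e1 == e2 && s1 != s2) {
        ds <- min(s1, s2); de <- max(s1, s2) - 1L
        if (exon_inside(ds, de)) next
        type <- if (strand == "+") "alt_5prime_donor" else "alt_3prime_acceptor"
        emit(type, a, b, ds, de)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("type", "start", "end")]), , drop = FALSE]
  res <- res[order(res$start, res$type), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract AS events for all multi-isoform loci
#'
#' @param models full exon table.
#' @return row-bound [extract_as_events()] results over loci with >= 2
#'   isoforms.
#' @export
extract_all_as_events <- function(models) {
  out <- lapply(unique(models$gene_id), function(g) {
    m <- models[models$gene_id == g, , drop = FALSE]
    if (length(unique(m$transcript_id)) < 2L) return(NULL)
    extract_as_events(m)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) extract_as_events(models[0, , drop = FALSE]) else res
}

#' Classify alternative-splicing changes as Type I or Type II
#'
#' For each locus with AS events: the expressed-isoform set per condition
#' contains isoforms with mean FPKM above `floor` in that condition.
#' Type II: the expressed sets differ between conditions (a splicing
#' variant present in one condition, absent in the other).  Type I: the
#' sets are identical and exactly one isoform of the locus is
#' differentially expressed.  Loci meeting neither rule are `unclassified`.
#'
#' @param events AS event table ([extract_all_as_events()]).
#' @param de_isoform isoform-level DE table ([differential_genes()],
#'   transcript component).
#' @param fpkm FPKM matrix (isoforms x samples).
#' @param condition two-level factor over samples (first level = mock).
#' @param gene_of named vector mapping isoform ids to locus ids.
#' @param floor expression floor in FPKM (default 1).
#' @return data.frame: `locus`, `class` in
#'   `c("type_I", "type_II", "unclassified")`, `expressed_mock`,
#'   `expressed_treated`, `n_de_isoforms`.
#' @export
classify_as_changes <- function(events, de_isoform, fpkm, condition, gene_of,
                                floor = 1) {
  condition <- as.factor(condition)
  ia <- condition == levels(condition)[1]
  ib <- condition == levels(condition)[2]
  out <- list()
  for (g in unique(events$locus)) {
    isos <- names(gene_of)[gene_of == g]
    isos <- isos[isos %in% rownames(fpkm)]
    em <- isos[rowMeans(fpkm[isos, ia, drop = FALSE]) > floor]
    et <- isos[rowMeans(fpkm[isos, ib, drop = FALSE]) > floor]
    nde <- sum(de_isoform$call[match(isos, de_isoform$id)] != "ns", na.rm = TRUE)
    cls <- if (!setequal(em, et)) "type_II"
    else if (nde == 1L) "type_I"
    else "unclassified"
    out[[length(out) + 1L]] <- data.frame(
      locus = g, class = cls,
      expressed_mock = paste(sort(em), collapse = ","),
      expressed_treated = paste(sort(et), collapse = ","),
      n_de_isoforms = nde, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

CODONS <- local({
  aa <- c("KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF")
  bases <- c("A", "C", "G", "T")
  tab <- character(0)
  i <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    i <- i + 1
    tab[paste0(b1, b2, b3)] <- substr(aa, i, i)
  }
  tab
})

# translate a DNA sequence in one frame (frame = 0,1,2); returns AA string
translate_frame <- function(seq, frame) {
  s <- substr(seq, frame + 1L, nchar(seq))
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  codons <- substring(s, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  paste0(CODONS[codons], collapse = "")
}

#' Longest open reading frame over the three forward frames
#'
#' Translates frames +1, +2 and +3 with the standard code and returns the
#' length (in amino acids) of the longest stop-free stretch across the
#' frames.  No start codon is required and the reverse strand is not
#' considered.
#'
#' @param sequence DNA sequence.
#' @return integer ORF length in aa (0 for sequences shorter than 3 nt).
#' @export
longest_orf_3frames <- function(sequence) {
  sequence <- toupper(chartr("U", "T", sequence))
  if (nchar(sequence) < 3L) return(0L)
  best <- 0L
  for (f in 0:2) {
    aa <- translate_frame(sequence, f)
    if (!nzchar(aa)) next
    runs <- nchar(strsplit(aa, "*", fixed = TRUE)[[1]])
    if (length(runs)) best <- max(best, runs)
  }
  as.integer(best)
}

# position (frame, codon offset) of the longest stop-free stretch; used by
# the coding-potential heuristic
longest_orf_region <- function(sequence) {
  sequence <- toupper(chartr("U", "T", sequence))
  best <- list(len = 0L, frame = 0L, aa_start = 0L)
  for (f in 0:2) {
    aa <- translate_frame(sequence, f)
    if (!nzchar(aa)) next
    parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
    off <- 0L
    for (p in parts) {
      if (nchar(p) > best$len)
        best <- list(len = nchar(p), frame = f, aa_start = off)
      off <- off + nchar(p) + 1L
    }
  }
  best
}

#' Heuristic coding-potential score
#'
#' Combines the longest-ORF coverage fraction with a codon-usage log-odds
#' of the ORF against the sequence's own mononucleotide background:
#' `score = w_cov * (coverage - cov0) + w_codon * bias`, where `coverage`
#' is `3 * orf_aa / length` and `bias` is the mean per-codon log-odds
#' (finite-sample corrected).  Calibrated so that random-composition
#' sequences score below 0 while sequences with a stop-free frame covering
#' more than ~80% of the transcript score above 0.  Negative scores
#' predict noncoding.  Pluggable: any scorer with this sign convention can
#' replace it in [classify_lncrna()].
#'
#' @param sequence DNA sequence, >= 200 nt.
#' @param cov0 coverage midpoint (default 0.6).
#' @param w_cov,w_codon weights (defaults 4 and 0.25).
#' @return numeric score; `< 0` predicts noncoding.
#' @export
coding_score <- function(sequence, cov0 = 0.6, w_cov = 4, w_codon = 0.25) {
  sequence <- toupper(chartr("U", "T", sequence))
  if (nchar(sequence) < 200L) stop("coding_score requires >= 200 nt")
  reg <- longest_orf_region(sequence)
  coverage <- 3 * reg$len / nchar(sequence)
  bias <- 0
  if (reg$len >= 10L) {
    s <- substr(sequence, reg$frame + 1L, nchar(sequence))
    orf <- substr(s, 3L * reg$aa_start + 1L, 3L * (reg$aa_start + reg$len))
    n <- nchar(orf) %/% 3L
    codons <- substring(orf, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
    base_freq <- table(factor(strsplit(sequence, "")[[1]],
                              levels = c("A", "C", "G", "T")))
    base_freq <- (base_freq + 1) / sum(base_freq + 1)
    all_codons <- names(CODONS)
    p_bg <- vapply(all_codons, function(cd) {
      prod(base_freq[strsplit(cd, "")[[1]]])
    }, numeric(1))
    obs <- table(factor(codons, levels = all_codons))
    p_obs <- (obs + 0.5) / sum(obs + 0.5)
    bias <- sum(obs / sum(obs) * log(p_obs / p_bg)) - (length(all_codons) - 1) / (2 * n)
  }
  unname(w_cov * (coverage - cov0) + w_codon * bias)
}

#' Classify transcripts as lncRNAs
#'
#' Excludes transcripts shorter than 200 nt and transcripts with any
#' same-strand exonic overlap with annotated gene models; remaining
#' transcripts are lncRNAs iff their longest 3-forward-frame ORF is below
#' 100 aa and their coding-potential score is below 0.
#'
#' @param seqs named character vector of candidate transcript sequences.
#' @param models exon table of the candidate transcripts (for overlap
#'   testing); may be `NULL` when `gene_models` is `NULL`.
#' @param gene_models exon table of annotated gene models, or `NULL`.
#' @param scorer coding-potential scorer, `function(sequence) -> numeric`
#'   with negative = noncoding (default [coding_score()]).
#' @return data.frame: `transcript`, `length`, `orf_aa`, `score`,
#'   `verdict` (`"lncRNA"`, `"coding"`, `"excluded"`), `reason`.
#' @export
classify_lncrna <- function(seqs, models = NULL, gene_models = NULL,
                            scorer = coding_score) {
  ids <- names(seqs)
  out <- list()
  overlaps_model <- function(tr) {
    if (is.null(gene_models) || is.null(models)) return(FALSE)
    ex <- models[models$transcript_id == tr, , drop = FALSE]
    if (nrow(ex) == 0L) return(FALSE)
    for (i in seq_len(nrow(ex))) {
      hit <- gene_models$ref == ex$ref[i] & gene_models$strand == ex$strand[i] &
        gene_models$start <= ex$end[i] & gene_models$end >= ex$start[i]
      if (any(hit)) return(TRUE)
    }
    FALSE
  }
  for (tr in ids) {
    len <- nchar(seqs[[tr]])
    if (len < 200L) {
      out[[tr]] <- data.frame(transcript = tr, length = len,
                              orf_aa = NA_integer_, score = NA_real_,
                              verdict = "excluded", reason = "short",
                              stringsAsFactors = FALSE)
      next
    }
    if (overlaps_model(tr)) {
      out[[tr]] <- data.frame(transcript = tr, length = len,
                              orf_aa = NA_integer_, score = NA_real_,
                              verdict = "excluded", reason = "gene_model_overlap",
                              stringsAsFactors = FALSE)
      next
    }
    orf <- longest_orf_3frames(seqs[[tr]])
    sc <- scorer(seqs[[tr]])
    verdict <- if (orf < 100L && sc < 0) "lncRNA" else "coding"
    reason <- if (verdict == "lncRNA") "" else
      paste(c(if (orf >= 100L) "orf" else NULL,
              if (sc >= 0) "coding_potential" else NULL), collapse = ",")
    out[[tr]] <- data.frame(transcript = tr, length = len, orf_aa = orf,
                            score = sc, verdict = verdict, reason = reason,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Differential lncRNA expression with all-replicate consistency
#'
#' Runs the shared negative-binomial test with the usual thresholds
#' (adjusted p < 0.05, fold >= 2), then additionally requires every
#' treated replicate's normalized count to lie strictly on the same side
#' of every mock replicate's normalized count (all pairwise consistent
#' direction).  Only then is the lncRNA called.
#'
#' @param counts lncRNA x sample count matrix.
#' @param condition two-level factor (first level = mock).
#' @param ... passed to [nb_exact_test()].
#' @return DE table with added logical `consistent` column; `call` is
#'   downgraded to `"ns"` where consistency fails.
#' @export
differential_lncrna <- function(counts, condition, ...) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  res <- nb_exact_test(counts, condition, ...)
  sf <- size_factors(counts)
  q <- sweep(counts, 2, sf, "/")
  ia <- condition == levels(condition)[1]
  ib <- condition == levels(condition)[2]
  res$consistent <- vapply(seq_len(nrow(q)), function(i) {
    min(q[i, ib]) > max(q[i, ia]) || max(q[i, ib]) < min(q[i, ia])
  }, logical(1))
  res$call[!res$consistent] <- "ns"
  res
}
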