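# miRNA discovery: candidate locus selection, RNA folding (pluggable
# engine with a built-in base-pair-maximization fallback), hairpin
# evaluation, and matching against a known-miRNA catalog.

#' Select candidate miRNA loci
#'
#' Keeps alignments of tags expressed above `min_tpm` in at least one
#' library (strict) and mapping to at most `max_loci` genomic loci.
#'
#' @param alignments alignment table from [map_exact()].
#' @param tab tag table with TPM columns.
#' @param min_tpm strict TPM threshold (default 10).
#' @param max_loci maximum allowed mapped loci per tag (default 20).
#' @return subset of `alignments` for qualifying tags.
#' @export
candidate_loci <- function(alignments, tab, min_tpm = 10, max_loci = 20L) {
  tpm <- tag_tpm(tab)
  expressed <- tab$sequence[rowSums(tpm > min_tpm) >= 1L]
  keep <- alignments$tag %in% expressed & alignments$n_hits <= max_loci
  alignments[keep, , drop = FALSE]
}

#' Fold an RNA sequence into a secondary structure
#'
#' Predicts a dot-bracket structure with a pluggable folding engine.  The
#' built-in default maximizes base pairs (Watson-Crick plus G:U) by dynamic
#' programming with a minimum hairpin loop of 3 nt and deterministic
#' tie-breaking toward 5'-most pairs.
#'
#' @param sequence RNA or DNA sequence (T is treated as U); >= 10 nt.
#' @param engine optional `function(sequence) -> dot-bracket` replacing the
#'   built-in folder (e.g. a wrapper around an external MFE program).
#' @param min_loop minimum loop length for the built-in folder.
#' @return dot-bracket string of the same length as `sequence`.
#' @export
fold_rna <- function(sequence, engine = NULL, min_loop = 3L) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 10L) stop("sequence shorter than 10 nt")
  if (!is.null(engine)) {
    db <- engine(sequence)
  } else {
    db <- .fold_nussinov_cpp(sequence, as.integer(min_loop))
  }
  stopifnot(nchar(db) == nchar(sequence))
  db
}

# dot-bracket -> 1-based partner vector (NA where unpaired)
structure_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced structure")
  partner
}

#' Build a hairpin candidate from a mapped locus
#'
#' Extracts the mapped tag plus `flank` nt on each side (clipped at
#' reference ends), orients it 5'->3' on the mapped strand, and folds it.
#'
#' @param genome named character vector of reference sequences.
#' @param ref,start,end,strand locus of the mapped tag (0-based half-open,
#'   as produced by [map_exact()]).
#' @param flank flanking length on each side (default 200).
#' @param engine folding engine passed to [fold_rna()].
#' @return list of class `hairpin_candidate` with `precursor`, `structure`,
#'   `mature`, `mature_start` (0-based within precursor), `locus`.
#' @export
hairpin_candidate <- function(genome, ref, start, end, strand, flank = 200L,
                              engine = NULL) {
  seq_len_ref <- nchar(genome[[ref]])
  lo <- max(0L, start - flank)
  hi <- min(seq_len_ref, end + flank)
  pre <- substr(genome[[ref]], lo + 1L, hi)
  mstart <- start - lo
  mature <- substr(pre, mstart + 1L, mstart + (end - start))
  if (strand == "-") {
    pre <- revcomp(pre)
    mstart <- nchar(pre) - (mstart + (end - start))
    mature <- revcomp(mature)
  }
  structure(list(precursor = pre, structure = fold_rna(pre, engine = engine),
                 mature = mature, mature_start = mstart,
                 locus = list(ref = ref, start = start, end = end,
                              strand = strand)),
            class = "hairpin_candidate")
}

#' Evaluate a hairpin candidate against plant-miRNA precursor criteria
#'
#' A candidate passes when (a) the mature sequence lies on one arm of a
#' stem-loop (it does not pair with itself and all its pairing partners lie
#' on one side), (b) at most `max_unpaired` mature nucleotides are unpaired
#' against the star arm, (c) no asymmetric bulge larger than `max_bulge` nt
#' occurs within the miRNA/miRNA* duplex, and (d) the mature length is
#' within `mature_len`.
#'
#' @param cand `hairpin_candidate` (or a list with `structure`,
#'   `mature_start` and `mature`).
#' @param max_unpaired maximum unpaired mature nucleotides (default 4).
#' @param max_bulge maximum duplex bulge asymmetry in nt (default 2).
#' @param mature_len allowed mature length range (default `c(20, 24)`).
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   failed criteria among `"arm"`, `"unpaired"`, `"bulge"`, `"length"`).
#' @export
evaluate_hairpin <- function(cand, max_unpaired = 4L, max_bulge = 2L,
                             mature_len = c(20L, 24L)) {
  ml <- nchar(cand$mature)
  if (cand$mature_start < 0L ||
      cand$mature_start + ml > nchar(cand$precursor %||% cand$structure))
    stop("mature sequence not within precursor")
  partner <- structure_pairs(cand$structure)
  mi <- cand$mature_start + 1L           # 1-based first mature position
  mj <- cand$mature_start + ml           # 1-based last mature position
  reasons <- character(0)
  if (ml < mature_len[1] || ml > mature_len[2]) reasons <- c(reasons, "length")
  partners <- partner[mi:mj]
  paired <- which(!is.na(partners))
  # (a) mature must not pair with itself and partners must be one-sided
  self_pair <- any(!is.na(partners) & partners >= mi & partners <= mj)
  one_sided <- length(paired) == 0L ||
    all(partners[paired] > mj) || all(partners[paired] < mi)
  if (self_pair || !one_sided || length(paired) == 0L)
    reasons <- c(reasons, "arm")
  # (b) unpaired mature nucleotides
  if (sum(is.na(partners)) > max_unpaired) reasons <- c(reasons, "unpaired")
  # (c) duplex bulge asymmetry between consecutive paired mature positions
  if (!self_pair && one_sided && length(paired) >= 2L) {
    for (t in seq_len(length(paired) - 1L)) {
      p1 <- paired[t]; p2 <- paired[t + 1L]
      gap_m <- p2 - p1 - 1L
      gap_s <- abs(partners[p1] - partners[p2]) - 1L
      if (abs(gap_m - gap_s) > max_bulge) {
        reasons <- c(reasons, "bulge")
        break
      }
    }
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match candidate mature miRNAs against a known catalog
#'
#' Ungapped comparison of equal-length sequences; a candidate is annotated
#' with the catalog entry giving the fewest mismatches when that number is
#' at most `max_mismatch`.  Ties resolve to the lexicographically first
#' catalog id.
#'
#' @param matures named character vector of candidate mature sequences.
#' @param catalog named character vector of known mature sequences.
#' @param max_mismatch maximum mismatches for a match (default 2).
#' @return data.frame with `candidate`, `mature`, `known_id`, `mismatches`,
#'   `conserved` (logical).
#' @export
match_known <- function(matures, catalog, max_mismatch = 2L) {
  if (length(catalog) == 0L) stop("catalog is empty")
  cat_ids <- names(catalog)
  cat_seqs <- toupper(chartr("U", "T", catalog))
  cat_split <- strsplit(cat_seqs, "")
  ids <- names(matures)
  if (is.null(ids)) ids <- paste0("cand_", seq_along(matures))
  res <- lapply(seq_along(matures), function(i) {
    s <- strsplit(toupper(chartr("U", "T", matures[i])), "")[[1]]
    mm <- vapply(cat_split, function(cs) {
      if (length(cs) != length(s)) return(NA_integer_)
      sum(cs != s)
    }, integer(1))
    ok <- which(!is.na(mm) & mm <= max_mismatch)
    if (length(ok) == 0L)
      return(data.frame(candidate = ids[i], mature = unname(matures[i]),
                        known_id = NA_character_, mismatches = NA_integer_,
                        conserved = FALSE, stringsAsFactors = FALSE))
    best <- ok[mm[ok] == min(mm[ok])]
    best <- best[order(cat_ids[best])][1]
    data.frame(candidate = ids[i], mature = unname(matures[i]),
               known_id = cat_ids[best], mismatches = mm[best],
               conserved = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Discover candidate miRNAs from mapped small RNAs
#'
#' Pipeline glue: selects candidate loci ([candidate_loci()]), builds and
#' folds a precursor for each locus ([hairpin_candidate()]), evaluates it
#' ([evaluate_hairpin()]) and annotates passing candidates against a known
#' catalog ([match_known()]).
#'
#' @param alignments genome alignments from [map_exact()].
#' @param tab tag table with TPM.
#' @param genome named character vector of reference sequences.
#' @param catalog known mature catalog (named character vector), or `NULL`.
#' @param ... passed to [candidate_loci()].
#' @param engine folding engine for [fold_rna()].
#' @return data.frame: one row per candidate locus with evaluation verdict
#'   and catalog annotation.
#' @export
discover_mirnas <- function(alignments, tab, genome, catalog = NULL, ...,
                            engine = NULL) {
  loci <- candidate_loci(alignments, tab, ...)
  if (nrow(loci) == 0L)
    return(data.frame(tag = character(0), ref = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), pass = logical(0),
                      reasons = character(0), known_id = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    cand <- hairpin_candidate(genome, l$ref, l$start, l$end, l$strand,
                              engine = engine)
    ev <- evaluate_hairpin(cand)
    data.frame(tag = l$tag, ref = l$ref, start = l$start, end = l$end,
               strand = l$strand, pass = ev$pass,
               reasons = paste(ev$reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$known_id <- NA_character_
  if (!is.null(catalog) && any(out$pass)) {
    ann <- match_known(stats::setNames(out$tag[out$pass],
                                       seq_len(sum(out$pass))), catalog)
    out$known_id[out$pass] <- ann$known_id
  }
  out
}
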