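# Small-RNA core: read preprocessing, contaminant filtering, unique-tag
# counting, TPM normalization, expression filtering, differential calling
# and exact-match mapping.

#' Preprocess small-RNA reads
#'
#' Clips the 3' adapter at the first exact match of the adapter's 8-nt
#' prefix, then drops reads shorter than `min_len` or longer than `max_len`
#' nucleotides.  Reads containing characters other than A/C/G/T are skipped
#' with a warning.
#'
#' @param reads character vector of read sequences (DNA).
#' @param adapter 3' adapter sequence (>= 8 nt) or `NULL` to skip clipping.
#' @param min_len minimum insert length kept (default 15).
#' @param max_len maximum insert length kept (default 30).
#' @return character vector of clean insert sequences.
#' @export
preprocess_reads <- function(reads, adapter = NULL, min_len = 15L, max_len = 30L) {
  reads <- toupper(reads)
  bad <- grepl("[^ACGT]", reads)
  if (any(bad)) {
    warning(sum(bad), " read(s) with non-nucleotide characters skipped")
    reads <- reads[!bad]
  }
  if (!is.null(adapter)) {
    adapter <- toupper(adapter)
    if (nchar(adapter) < 8L)
      stop("adapter must be at least 8 nt for prefix matching")
    key <- substr(adapter, 1L, 8L)
    pos <- regexpr(key, reads, fixed = TRUE)
    clip <- pos > 0L
    reads[clip] <- substr(reads[clip], 1L, pos[clip] - 1L)
  }
  len <- nchar(reads)
  reads[len >= min_len & len <= max_len]
}

#' Remove tags matching structural-RNA contaminants
#'
#' Drops tags whose sequence, or reverse complement, occurs as an exact
#' substring of any contaminant sequence (rRNA, tRNA, snoRNA, snRNA sets).
#'
#' @param tags character vector of tag sequences, or a tag table from
#'   [collapse_and_count()].
#' @param contaminants character vector of contaminant sequences.
#' @return input with contaminant tags removed.
#' @export
filter_contaminants <- function(tags, contaminants) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  if (length(contaminants) == 0L) {
    warning("empty contaminant set; no tags removed")
    return(tags)
  }
  seqs <- toupper(seqs)
  # enumerate all contaminant substrings at the tag lengths present; a tag
  # whose reverse complement occurs in a contaminant occurs forward in the
  # contaminant's reverse complement
  src <- toupper(contaminants)
  src <- c(src, revcomp(src))
  lens <- unique(nchar(seqs))
  subs <- unlist(lapply(lens, function(L) {
    unlist(lapply(src[nchar(src) >= L], function(s) {
      n <- nchar(s)
      substring(s, 1:(n - L + 1L), L:n)
    }))
  }))
  hit <- seqs %in% subs
  if (is.data.frame(tags)) tags[!hit, , drop = FALSE] else tags[!hit]
}

#' Collapse reads into a unique-tag count table
#'
#' @param libraries named list of clean read vectors (one element per
#'   library).
#' @return data.frame with `sequence`, `length`, and one `count.<lib>`
#'   column per library; total counts per column equal library read totals.
#' @export
collapse_and_count <- function(libraries) {
  stopifnot(is.list(libraries))
  if (is.null(names(libraries)))
    names(libraries) <- paste0("lib", seq_along(libraries))
  all_seqs <- sort(unique(unlist(libraries, use.names = FALSE)))
  counts <- vapply(libraries, function(reads) {
    tabulate(match(reads, all_seqs), nbins = length(all_seqs))
  }, integer(length(all_seqs)))
  if (length(all_seqs) == 0L) {
    counts <- matrix(0L, 0, length(libraries),
                     dimnames = list(NULL, names(libraries)))
  }
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(all_seqs))
  colnames(counts) <- names(libraries)
  out <- data.frame(sequence = all_seqs, length = nchar(all_seqs),
                    stringsAsFactors = FALSE)
  cm <- as.data.frame(counts)
  names(cm) <- paste0("count.", names(libraries))
  cbind(out, cm)
}

# internal accessors for tag tables
tag_counts <- function(tab) {
  as.matrix(tab[, grep("^count\\.", names(tab)), drop = FALSE])
}
tag_tpm <- function(tab) {
  m <- as.matrix(tab[, grep("^tpm\\.", names(tab)), drop = FALSE])
  if (ncol(m) == 0L) stop("TPM not computed; run normalize_tpm() first")
  m
}
tag_libs <- function(tab) sub("^count\\.", "", grep("^count\\.", names(tab), value = TRUE))

#' Normalize tag counts to transcripts per million (TPM)
#'
#' `tpm = count / library_total * 1e6`; each library's TPM column sums to
#' one million.
#'
#' @param tab tag table from [collapse_and_count()].
#' @return tag table with added `tpm.<lib>` columns.
#' @export
normalize_tpm <- function(tab) {
  counts <- tag_counts(tab)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("zero-total library: ", paste(tag_libs(tab)[totals == 0], collapse = ", "))
  tpm <- sweep(counts, 2, totals, "/") * 1e6
  tm <- as.data.frame(tpm)
  names(tm) <- paste0("tpm.", tag_libs(tab))
  cbind(tab[, !grepl("^tpm\\.", names(tab)), drop = FALSE], tm)
}

#' Keep tags expressed above a TPM floor in at least one library
#'
#' @param tab tag table with TPM columns.
#' @param min_tpm strict threshold (default 5): a tag is kept iff
#'   `tpm > min_tpm` in at least one library.
#' @return filtered tag table.
#' @export
filter_expressed <- function(tab, min_tpm = 5) {
  tpm <- tag_tpm(tab)
  tab[rowSums(tpm > min_tpm) >= 1L, , drop = FALSE]
}

#' Differential small-RNA expression
#'
#' Applies the shared negative-binomial exact test ([nb_exact_test()]) to
#' the tag count table.  Tags are called differential when the
#' Benjamini-Hochberg adjusted p-value is below 0.05 and the fold change is
#' at least 2 in either direction.
#'
#' @param tab tag table (counts required, TPM optional).
#' @param condition two-level factor of library conditions, in the tag
#'   table's library order; first level is the baseline.
#' @param ... passed to [nb_exact_test()].
#' @return data.frame of per-tag results (see [nb_exact_test()]); `id` is
#'   the tag sequence.
#' @export
differential_srna <- function(tab, condition, ...) {
  counts <- tag_counts(tab)
  rownames(counts) <- tab$sequence
  nb_exact_test(counts, condition, ...)
}

# shared exact-occurrence engine: all plus-strand occurrences of each
# pattern in each reference, grouped by pattern width for PDict matching.
exact_hits_plus <- function(patterns, references) {
  refs <- Biostrings::DNAStringSet(unlist(references))
  out <- vector("list", 0L)
  widths <- nchar(patterns)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(patterns[idx]))
    for (r in seq_along(refs)) {
      m <- Biostrings::matchPDict(pd, refs[[r]])
      starts <- Biostrings::startIndex(m)
      hit <- which(lengths(starts) > 0)
      if (length(hit) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        tag_idx = rep(idx[hit], lengths(starts[hit])),
        ref = names(refs)[r],
        start = unlist(starts[hit]) - 1L,  # to 0-based
        width = w, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(tag_idx = integer(0), ref = character(0),
                      start = integer(0), width = integer(0)))
  do.call(rbind, out)
}

#' Map tags to references by exact matching
#'
#' Reports every exact occurrence of each tag on both strands of the
#' reference sequences.  Coordinates are 0-based half-open; `five_prime` is
#' the plus-strand coordinate of the tag's 5' nucleotide (`start` on `+`,
#' `end - 1` on `-`).  Tags with more than `max_hits` total occurrences are
#' excluded and reported in the `"excluded"` attribute.
#'
#' @param tags character vector of tag sequences.
#' @param references named character vector (or `DNAStringSet`) of
#'   reference sequences.
#' @param max_hits maximum allowed occurrences per tag (default 6).
#' @return data.frame with `tag`, `ref`, `start`, `end`, `strand`,
#'   `five_prime`, `length`, `n_hits`; attribute `excluded` lists
#'   over-mapping tag sequences.
#' @export
map_exact <- function(tags, references, max_hits = 6L) {
  tags <- toupper(unique(tags))
  if (methods::is(references, "DNAStringSet"))
    references <- stats::setNames(as.character(references), names(references))
  empty <- data.frame(tag = character(0), ref = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), five_prime = integer(0),
                      length = integer(0), n_hits = integer(0),
                      stringsAsFactors = FALSE)
  if (length(tags) == 0L) { attr(empty, "excluded") <- character(0); return(empty) }
  plus <- exact_hits_plus(tags, references)
  minus <- exact_hits_plus(revcomp(tags), references)
  mk <- function(h, strand) {
    if (nrow(h) == 0L) return(empty[, 1:7])
    data.frame(tag = tags[h$tag_idx], ref = h$ref, start = h$start,
               end = h$start + h$width, strand = strand,
               five_prime = if (strand == "+") h$start else h$start + h$width - 1L,
               length = h$width, stringsAsFactors = FALSE)
  }
  aln <- rbind(mk(plus, "+"), mk(minus, "-"))
  if (nrow(aln) == 0L) { attr(empty, "excluded") <- character(0); return(empty) }
  hits <- table(aln$tag)
  aln$n_hits <- as.integer(hits[aln$tag])
  excluded <- names(hits)[hits > max_hits]
  aln <- aln[!(aln$tag %in% excluded), , drop = FALSE]
  aln <- aln[order(aln$ref, aln$start, aln$strand, aln$tag), , drop = FALSE]
  rownames(aln) <- NULL
  attr(aln, "excluded") <- excluded
  aln
}
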