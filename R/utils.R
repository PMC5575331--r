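# Shared low-level helpers: sequence manipulation, deterministic RNG
# substreams, FASTA/FASTQ/GFF3 writing and reading.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T, case preserved as
#'   uppercase on output).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

# deterministic 31-bit hash of a string; used to derive per-file RNG
# substreams from (seed, name) so every output file is reproducible on its
# own, independent of generation order.
str_hash <- function(name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  h
}

#' Derive a deterministic RNG substream seed
#'
#' Maps a master seed and a stream name to a 31-bit seed.  Used by the
#' synthetic-data generator so each output file has its own reproducible
#' substream.
#'
#' @param seed integer master seed.
#' @param name character stream name (conventionally the output file name).
#' @return integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, name) {
  as.integer(((seed %% 65521) * 30011 + str_hash(name)) %% 2147483647)
}

# vectorized random DNA strings of given (possibly varying) lengths
random_dna <- function(n, lengths) {
  if (n == 0L) return(character(0))
  if (length(lengths) == 1L) lengths <- rep(lengths, n)
  out <- character(n)
  for (len in unique(lengths)) {
    idx <- which(lengths == len)
    m <- matrix(sample(DNA_BASES, length(idx) * len, replace = TRUE), ncol = len)
    out[idx] <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  out
}

#' Write sequences as FASTA or FASTQ
#'
#' @param seqs named (or unnamed) character vector of sequences.
#' @param path output file path.
#' @param format `"fasta"` or `"fastq"` (constant Phred+33 quality `I`).
#' @return `path`, invisibly.
#' @export
write_seqs <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("read_", seq_along(seqs))
  if (format == "fasta") {
    lines <- as.vector(rbind(paste0(">", ids), unname(seqs)))
  } else {
    qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
    lines <- as.vector(rbind(paste0("@", ids), unname(seqs), "+", qual))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from FASTA or FASTQ
#'
#' @param path input file; format detected from the first character.
#' @return named character vector of sequences.
#' @export
read_seqs <- function(path) {
  first <- substr(readLines(path, n = 1L), 1, 1)
  if (identical(first, "@")) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
  }
  stats::setNames(as.character(x), names(x))
}

# ---- GFF3 (minimal dialect: gene/mRNA/exon with ID=/Parent=) ----

#' Write transcript models as GFF3
#'
#' Emits `gene`, `mRNA` and `exon` features (1-based, closed intervals) with
#' `ID=`/`Parent=` attributes from an exon table.
#'
#' @param models exon table: one row per exon with columns `ref`,
#'   `gene_id`, `transcript_id`, `strand`, `start`, `end` (1-based closed)
#'   and optionally `biotype`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  stopifnot(all(c("ref", "gene_id", "transcript_id", "strand", "start", "end") %in%
                  names(models)))
  lines <- "##gff-version 3"
  for (g in unique(models$gene_id)) {
    mg <- models[models$gene_id == g, , drop = FALSE]
    bt <- if ("biotype" %in% names(mg)) mg$biotype[1] else "protein_coding"
    lines <- c(lines, paste(mg$ref[1], "vigsome", "gene", min(mg$start), max(mg$end),
                            ".", mg$strand[1], ".",
                            paste0("ID=", g, ";biotype=", bt), sep = "\t"))
    for (tr in unique(mg$transcript_id)) {
      mt <- mg[mg$transcript_id == tr, , drop = FALSE]
      mt <- mt[order(mt$start), , drop = FALSE]
      lines <- c(lines, paste(mt$ref[1], "vigsome", "mRNA", min(mt$start), max(mt$end),
                              ".", mt$strand[1], ".",
                              paste0("ID=", tr, ";Parent=", g), sep = "\t"))
      lines <- c(lines, paste(mt$ref, "vigsome", "exon", mt$start, mt$end,
                              ".", mt$strand, ".", paste0("Parent=", tr), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript models from GFF3
#'
#' Strict parser for the gene/mRNA/exon dialect written by [write_gff3()].
#' Returns the exon table representation used throughout the package.
#'
#' @param path GFF3 file path.
#' @return data.frame with columns `ref`, `gene_id`, `transcript_id`,
#'   `strand`, `start`, `end`, `biotype`.
#' @export
read_gff3 <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  f <- strsplit(raw, "\t", fixed = TRUE)
  stopifnot(all(lengths(f) == 9L))
  m <- do.call(rbind, f)
  attr_field <- function(a, key) {
    hit <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]+"), a))
    out <- rep(NA_character_, length(a))
    ok <- lengths(regmatches(a, gregexpr(paste0("(^|;)", key, "="), a))) > 0
    out[ok] <- sub(paste0("^;?", key, "="), "", hit)
    out
  }
  type <- m[, 3]
  genes <- data.frame(id = attr_field(m[type == "gene", 9], "ID"),
                      biotype = attr_field(m[type == "gene", 9], "biotype"),
                      stringsAsFactors = FALSE)
  mrna <- data.frame(id = attr_field(m[type == "mRNA", 9], "ID"),
                     gene = attr_field(m[type == "mRNA", 9], "Parent"),
                     stringsAsFactors = FALSE)
  ex <- m[type == "exon", , drop = FALSE]
  tr <- attr_field(ex[, 9], "Parent")
  out <- data.frame(ref = ex[, 1],
                    gene_id = mrna$gene[match(tr, mrna$id)],
                    transcript_id = tr,
                    strand = ex[, 7],
                    start = as.integer(ex[, 4]),
                    end = as.integer(ex[, 5]),
                    stringsAsFactors = FALSE)
  out$biotype <- genes$biotype[match(out$gene_id, genes$id)]
  out[order(out$ref, out$transcript_id, out$start), , drop = FALSE]
}

#' Spliced transcript sequences from an exon table
#'
#' Concatenates exon sequences in genomic order and reverse-complements
#' minus-strand transcripts.
#'
#' @param models exon table (see [read_gff3()]).
#' @param genome named character vector of reference sequences.
#' @return named character vector of transcript sequences.
#' @export
transcript_seqs <- function(models, genome) {
  out <- character(0)
  for (tr in unique(models$transcript_id)) {
    mt <- models[models$transcript_id == tr, , drop = FALSE]
    mt <- mt[order(mt$start), , drop = FALSE]
    pieces <- substring(genome[[mt$ref[1]]], mt$start, mt$end)
    s <- paste0(pieces, collapse = "")
    if (mt$strand[1] == "-") s <- revcomp(s)
    out[[tr]] <- s
  }
  out
}

#' Transcript lengths from an exon table
#'
#' @param models exon table.
#' @return named integer vector of summed exon lengths.
#' @export
transcript_lengths <- function(models) {
  len <- tapply(models$end - models$start + 1L, models$transcript_id, sum)
  stats::setNames(as.integer(len), names(len))
}
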