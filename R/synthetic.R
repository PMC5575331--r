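# Synthetic-data generator: builds a small reference (genome, transcript
# models, transcript sequences), plants ground truth (miRNA hairpins, PHAS
# loci, cleavage sites, expression effects, splicing switches) and
# simulates sRNA libraries, degradome libraries and expression counts for
# a mock vs treated design with negative-binomial noise.
#
# All randomness flows from one master seed; each output stream draws from
# a substream derived from (seed, stream name), so any single output is
# reproducible in isolation and identical configs give identical bytes.

nonstop_codons <- function() names(CODONS)[CODONS != "*"]

#' Simulation configuration
#'
#' Parameters of the synthetic experiment: 3 mock vs 3 treated replicate
#' libraries by default, with planted condition effects mirroring a VIGS
#' inoculation study (a 2-fold miRNA decrease, 2-fold decreases at two
#' PHAS loci, one enhanced cleavage event with a reduced target, 2-fold
#' mRNA changes, 4-fold lncRNA changes and two splicing switches).
#'
#' @param seed master integer seed.
#' @param n_replicates_per_condition replicates per condition (default 3).
#' @param n_mirna_loci,n_phas_loci,n_coding_loci,n_lncrna_loci locus counts
#'   (defaults 5, 10, 20, 10; at least 4 coding loci are required because
#'   the first four carry the alternative-splicing structures).
#' @param reads_per_srna_library expected sRNA reads per library
#'   (default 3e5).
#' @param tags_per_degradome_library expected degradome tags per library
#'   (default 3e4).
#' @param nb_dispersion shared negative-binomial dispersion (default 0.05).
#' @param background_fraction fraction of unassignable background sRNA
#'   reads (default 0.2).
#' @param degradome_background_fraction fraction of uniform background
#'   degradome tags (default 0.3).
#' @param phas_cycles phased duplex cycles per PHAS locus (default 8).
#' @param adapter 3' adapter appended in FASTQ mode.
#' @param degradome_tag_length degradome tag length in nt (default 20).
#' @param effect_specs data.frame of planted effects (`target`, `kind`,
#'   `magnitude`); default [default_effects()].  Effects whose target does
#'   not exist under the locus counts are dropped.
#' @param max_genome maximum genome size in nt (default 2e6).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_replicates_per_condition = 3L,
                       n_mirna_loci = 5L,
                       n_phas_loci = 10L,
                       n_coding_loci = 20L,
                       n_lncrna_loci = 10L,
                       reads_per_srna_library = 300000L,
                       tags_per_degradome_library = 30000L,
                       nb_dispersion = 0.05,
                       background_fraction = 0.2,
                       degradome_background_fraction = 0.3,
                       phas_cycles = 8L,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       degradome_tag_length = 20L,
                       effect_specs = default_effects(),
                       max_genome = 2e6) {
  cfg <- list(seed = as.integer(seed),
              n_replicates_per_condition = as.integer(n_replicates_per_condition),
              n_mirna_loci = as.integer(n_mirna_loci),
              n_phas_loci = as.integer(n_phas_loci),
              n_coding_loci = as.integer(n_coding_loci),
              n_lncrna_loci = as.integer(n_lncrna_loci),
              reads_per_srna_library = as.integer(reads_per_srna_library),
              tags_per_degradome_library = as.integer(tags_per_degradome_library),
              nb_dispersion = nb_dispersion,
              background_fraction = background_fraction,
              degradome_background_fraction = degradome_background_fraction,
              phas_cycles = as.integer(phas_cycles),
              adapter = adapter,
              degradome_tag_length = as.integer(degradome_tag_length),
              effect_specs = effect_specs,
              max_genome = max_genome)
  stopifnot(cfg$n_replicates_per_condition >= 1L,
            cfg$nb_dispersion > 0,
            cfg$background_fraction >= 0, cfg$background_fraction <= 1,
            cfg$degradome_background_fraction >= 0,
            cfg$degradome_background_fraction <= 1,
            cfg$n_coding_loci >= 4L,
            cfg$phas_cycles >= 1L)
  est_len <- cfg$n_mirna_loci * 450 + cfg$n_phas_loci * 1200 +
    cfg$n_coding_loci * 1600 + cfg$n_lncrna_loci * 800 +
    300 * (cfg$n_mirna_loci + cfg$n_phas_loci + cfg$n_coding_loci +
             cfg$n_lncrna_loci + 1)
  if (est_len > cfg$max_genome)
    stop("sizing error: requested loci need ~", est_len,
         " nt, exceeding max_genome = ", cfg$max_genome)
  class(cfg) <- "sim_config"
  cfg
}

#' Default planted condition effects
#'
#' @return data.frame with columns `target`, `kind`, `magnitude`.
#' @export
default_effects <- function() {
  data.frame(
    target = c("mir_1", "phas_01", "phas_02", "mir_2:gene_06.1", "gene_06",
               "gene_10", "gene_11", "gene_03.2", "gene_01", "gene_02",
               "lnc_01", "lnc_02"),
    kind = c("srna_fold_change", "phas_fold_change", "phas_fold_change",
             "cleavage_enhancement", "mrna_fold_change", "mrna_fold_change",
             "mrna_fold_change", "mrna_fold_change", "as_switch", "as_switch",
             "lncrna_fold_change", "lncrna_fold_change"),
    magnitude = c(0.5, 0.5, 0.5, 10, 0.6, 2, 0.5, 3, 0.45, 0.45, 4, 0.25),
    stringsAsFactors = FALSE)
}

#' Sample names of the simulated design
#'
#' @param config `sim_config`.
#' @return list with `samples` (character) and `condition` (two-level
#'   factor, levels `mock`, `treated`, named by sample).
#' @export
sim_design <- function(config) {
  n <- config$n_replicates_per_condition
  samples <- c(paste0("mock_", seq_len(n)), paste0("treated_", seq_len(n)))
  condition <- factor(rep(c("mock", "treated"), each = n),
                      levels = c("mock", "treated"))
  names(condition) <- samples
  list(samples = samples, condition = condition)
}

rnb <- function(n, mu, dispersion) {
  stats::rnbinom(n, mu = mu, size = 1 / max(dispersion, 1e-8))
}

# insert `piece` into `seq` at 1-based position `at` (overwrites)
overwrite_at <- function(seq, at, piece) {
  paste0(substr(seq, 1L, at - 1L), piece,
         substr(seq, at + nchar(piece), nchar(seq)))
}

# random stop-free coding sequence of `n_aa` codons
random_cds <- function(n_aa) {
  paste0(sample(nonstop_codons(), n_aa, replace = TRUE), collapse = "")
}

# mutate a sequence until its longest 3-frame ORF is below `max_aa` amino
# acids, by planting a stop codon mid-ORF in the offending frame
break_orfs <- function(seq, max_aa = 99L) {
  repeat {
    reg <- longest_orf_region(seq)
    if (reg$len <= max_aa) return(seq)
    mid <- reg$aa_start + reg$len %/% 2L
    pos <- reg$frame + 3L * mid + 1L
    seq <- overwrite_at(seq, pos, "TAA")
  }
}

#' Build the synthetic reference and ground truth
#'
#' Lays out miRNA hairpin loci, PHAS transcripts, protein-coding loci
#' (including four multi-isoform loci carrying one alternative-splicing
#' structure each: exon skipping, intron retention, alternative donor,
#' alternative acceptor) and lncRNA loci on one chromosome, and records the
#' planted ground truth.  Each miRNA precursor is verified to fold into a
#' qualifying hairpin under the built-in folding routine; each lncRNA is
#' guaranteed a longest 3-frame ORF below 100 aa.
#'
#' @param config `sim_config`.
#' @return list of class `sim_reference`: `genome` (named character),
#'   `models` (exon table), `transcripts` (named character),
#'   `gene_models` (exon table of annotated protein-coding loci),
#'   `catalog` (known-miRNA FASTA set), `contaminants`, `truth` (list of
#'   data.frames), `config`.
#' @export
make_reference <- function(config) {
  set.seed(substream_seed(config$seed, "reference"))
  eff <- config$effect_specs
  eff_mag <- function(kind, target) {
    hit <- eff$kind == kind & eff$target == target
    if (any(hit)) eff$magnitude[which(hit)[1]] else NA_real_
  }
  chrom <- "chr1"
  pieces <- character(0)
  offset <- 0L   # 0-based running genome offset
  spacer <- function() {
    s <- random_dna(1, 300)
    pieces[[length(pieces) + 1L]] <<- s
    offset <<- offset + 300L
    invisible(NULL)
  }
  add_piece <- function(s) {
    start <- offset
    pieces[[length(pieces) + 1L]] <<- s
    offset <<- offset + nchar(s)
    start
  }

  # ---- miRNA hairpin loci ----
  mir <- list()
  for (i in seq_len(config$n_mirna_loci)) {
    strand <- if (i %% 2L == 1L) "+" else "-"
    for (try in 1:40) {
      mature <- random_dna(1, 21)
      star <- revcomp(mature)
      stem <- random_dna(1, 150)
      locus <- paste0(random_dna(1, 50), stem, mature, random_dna(1, 8),
                      star, revcomp(stem), random_dna(1, 50))
      m_off <- 200L                     # mature offset within locus (0-based)
      genomic <- if (strand == "+") locus else revcomp(locus)
      # candidate evaluation exactly as discovery will see it
      tmp_genome <- stats::setNames(genomic, chrom)
      ms <- if (strand == "+") m_off else nchar(locus) - m_off - 21L
      cand <- hairpin_candidate(tmp_genome, chrom, ms, ms + 21L, strand,
                                flank = 200L)
      if (evaluate_hairpin(cand)$pass) break
      if (try == 40) stop("failed to plant a qualifying miRNA hairpin")
    }
    spacer()
    gstart <- add_piece(genomic)
    mstart <- if (strand == "+") gstart + m_off else
      gstart + nchar(locus) - m_off - 21L
    mir[[i]] <- data.frame(
      id = sprintf("mir_%d", i), mature = mature, star = star,
      ref = chrom, mature_start = mstart, mature_end = mstart + 21L,
      strand = strand, arm = "5p",
      in_catalog = i <= 3L, weight = 15,
      fold = {
        f <- eff_mag("srna_fold_change", sprintf("mir_%d", i))
        if (is.na(f)) 1 else f
      },
      stringsAsFactors = FALSE)
  }
  mirna <- if (length(mir)) do.call(rbind, mir) else
    data.frame(id = character(0), mature = character(0), star = character(0),
               ref = character(0), mature_start = integer(0),
               mature_end = integer(0), strand = character(0),
               arm = character(0), in_catalog = logical(0),
               weight = numeric(0), fold = numeric(0),
               stringsAsFactors = FALSE)

  # ---- PHAS loci (single-exon plus-strand transcripts) ----
  models <- list()
  phas <- list()
  tr_seqs <- character(0)
  for (i in seq_len(config$n_phas_loci)) {
    id <- sprintf("phas_%02d", i)
    s <- random_dna(1, 1200)
    spacer()
    gstart <- add_piece(s)
    origin <- 300L
    f <- eff_mag("phas_fold_change", id)
    trigger <- revcomp(substr(s, origin - 11L, origin + 10L))  # 22 nt
    models[[length(models) + 1L]] <- data.frame(
      ref = chrom, gene_id = paste0("g_", id), transcript_id = id,
      strand = "+", start = gstart + 1L, end = gstart + nchar(s),
      biotype = "protein_coding", stringsAsFactors = FALSE)
    tr_seqs[[id]] <- s
    phas[[i]] <- data.frame(
      id = id, origin = origin, register = origin %% 21L,
      n_cycles = config$phas_cycles, weight = 40,
      fold = if (is.na(f)) 1 else f,
      trigger_id = paste0("trig_", id), trigger_seq = trigger,
      stringsAsFactors = FALSE)
  }
  phas <- if (length(phas)) do.call(rbind, phas) else NULL

  # ---- protein-coding loci ----
  # first four are the multi-isoform AS loci
  as_defs <- list(
    list(type = "exon_skipping", strand = "+",
         exA = rbind(c(1, 300), c(401, 580), c(681, 980)),
         exB = rbind(c(1, 300), c(681, 980))),
    list(type = "intron_retention", strand = "-",
         exA = rbind(c(1, 400), c(501, 900)),
         exB = rbind(c(1, 900))),
    list(type = "alt_5prime_donor", strand = "+",
         exA = rbind(c(1, 300), c(501, 900)),
         exB = rbind(c(1, 350), c(501, 900))),
    list(type = "alt_3prime_acceptor", strand = "-",
         exA = rbind(c(1, 300), c(501, 900)),
         exB = rbind(c(1, 350), c(501, 900))))
  expr_rows <- list()
  cleav <- list()
  as_truth <- list()
  for (i in seq_len(config$n_coding_loci)) {
    gene <- sprintf("gene_%02d", i)
    if (i <= 4L) {
      d <- as_defs[[i]]
      span <- max(d$exA[, 2], d$exB[, 2])
      lenA <- sum(d$exA[, 2] - d$exA[, 1] + 1)
      # isoform A sense sequence: 5'UTR 30, stop-free CDS, stop, 3'UTR
      n_aa <- (lenA - 120L) %/% 3L
      sA <- paste0(random_dna(1, 30), random_cds(n_aa), "TAA")
      sA <- paste0(sA, random_dna(1, lenA - nchar(sA)))
      gen_concat <- if (d$strand == "+") sA else revcomp(sA)
      # write exonic pieces of A into the genomic span, introns random
      g <- random_dna(1, span)
      at <- 1L
      for (e in seq_len(nrow(d$exA))) {
        w <- d$exA[e, 2] - d$exA[e, 1] + 1L
        g <- overwrite_at(g, d$exA[e, 1], substr(gen_concat, at, at + w - 1L))
        at <- at + w
      }
      spacer()
      gstart <- add_piece(g)
      for (iso in c("A", "B")) {
        ex <- if (iso == "A") d$exA else d$exB
        tid <- paste0(gene, ".", if (iso == "A") "1" else "2")
        models[[length(models) + 1L]] <- data.frame(
          ref = chrom, gene_id = gene, transcript_id = tid,
          strand = d$strand, start = gstart + ex[, 1], end = gstart + ex[, 2],
          biotype = "protein_coding", stringsAsFactors = FALSE)
      }
      sw <- eff_mag("as_switch", gene)
      base <- stats::runif(1, 400, 800)
      if (!is.na(sw)) {
        # Type II switch: minor isoform absent in mock, present in treated
        props_mock <- c(1, 0); props_trt <- c(1 - sw, sw)
        as_truth[[length(as_truth) + 1L]] <- data.frame(
          locus = gene, type = d$type, switched_isoform = paste0(gene, ".2"),
          stringsAsFactors = FALSE)
      } else {
        props_mock <- props_trt <- c(0.6, 0.4)
      }
      for (j in 1:2) {
        tid <- paste0(gene, ".", j)
        f <- eff_mag("mrna_fold_change", tid)
        f <- if (is.na(f)) 1 else f
        expr_rows[[length(expr_rows) + 1L]] <- data.frame(
          transcript_id = tid, gene_id = gene, biotype = "protein_coding",
          mu_mock = base * props_mock[j],
          mu_treated = base * props_trt[j] * f, stringsAsFactors = FALSE)
      }
    } else {
      strand <- if (i %% 2L == 0L) "+" else "-"
      len <- 1500L
      n_aa <- 350L
      sA <- paste0(random_dna(1, 60), random_cds(n_aa), "TAA")
      sA <- paste0(sA, random_dna(1, len - nchar(sA)))
      tid <- paste0(gene, ".1")
      # plant a miRNA complementary site in the 3' UTR of genes 5..(4+n_mir)
      k <- i - 4L
      if (k <= config$n_mirna_loci) {
        w0 <- 60L + 3L * n_aa + 3L + 80L       # 0-based window start in UTR
        site <- revcomp(mirna$mature[k])
        sA <- overwrite_at(sA, w0 + 1L, site)
        enh <- eff_mag("cleavage_enhancement",
                       paste0(mirna$id[k], ":", tid))
        base_sig <- 30
        cleav[[length(cleav) + 1L]] <- data.frame(
          srna_id = mirna$id[k], srna_seq = mirna$mature[k], transcript = tid,
          cleavage_pos = w0 + 21L - 10L,
          mu_mock = if (is.na(enh)) base_sig else 4,
          mu_treated = if (is.na(enh)) base_sig else 4 * enh,
          kind = if (is.na(enh)) "mirna_site" else "enhanced_site",
          stringsAsFactors = FALSE)
        if (!is.na(enh)) {
          # constitutive decoy peak that dominates the site in mock samples
          cleav[[length(cleav) + 1L]] <- data.frame(
            srna_id = "decoy", srna_seq = NA_character_, transcript = tid,
            cleavage_pos = w0 + 11L + 150L, mu_mock = 12, mu_treated = 10,
            kind = "decoy", stringsAsFactors = FALSE)
        }
      }
      gen <- if (strand == "+") sA else revcomp(sA)
      spacer()
      gstart <- add_piece(gen)
      models[[length(models) + 1L]] <- data.frame(
        ref = chrom, gene_id = gene, transcript_id = tid, strand = strand,
        start = gstart + 1L, end = gstart + len,
        biotype = "protein_coding", stringsAsFactors = FALSE)
      f <- eff_mag("mrna_fold_change", gene)
      f <- if (is.na(f)) 1 else f
      base <- stats::runif(1, 300, 700)
      expr_rows[[length(expr_rows) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = gene, biotype = "protein_coding",
        mu_mock = base, mu_treated = base * f, stringsAsFactors = FALSE)
    }
  }

  # trigger cleavage sites at the PHAS phase origins
  if (!is.null(phas)) {
    for (i in seq_len(nrow(phas))) {
      cleav[[length(cleav) + 1L]] <- data.frame(
        srna_id = phas$trigger_id[i], srna_seq = phas$trigger_seq[i],
        transcript = phas$id[i], cleavage_pos = phas$origin[i],
        mu_mock = 30, mu_treated = 30, kind = "trigger_site",
        stringsAsFactors = FALSE)
      f <- 1
      base <- stats::runif(1, 200, 500)
      expr_rows[[length(expr_rows) + 1L]] <- data.frame(
        transcript_id = phas$id[i], gene_id = paste0("g_", phas$id[i]),
        biotype = "protein_coding", mu_mock = base, mu_treated = base * f,
        stringsAsFactors = FALSE)
    }
  }

  # ---- lncRNA loci ----
  for (i in seq_len(config$n_lncrna_loci)) {
    id <- sprintf("lnc_%02d", i)
    strand <- if (i %% 2L == 1L) "+" else "-"
    s <- break_orfs(random_dna(1, 800))
    gen <- if (strand == "+") s else revcomp(s)
    spacer()
    gstart <- add_piece(gen)
    models[[length(models) + 1L]] <- data.frame(
      ref = chrom, gene_id = paste0("g_", id), transcript_id = id,
      strand = strand, start = gstart + 1L, end = gstart + 800L,
      biotype = "lncRNA", stringsAsFactors = FALSE)
    f <- eff_mag("lncrna_fold_change", id)
    f <- if (is.na(f)) 1 else f
    base <- stats::runif(1, 100, 250)
    expr_rows[[length(expr_rows) + 1L]] <- data.frame(
      transcript_id = id, gene_id = paste0("g_", id), biotype = "lncRNA",
      mu_mock = base, mu_treated = base * f, stringsAsFactors = FALSE)
  }
  spacer()

  genome <- stats::setNames(paste0(pieces, collapse = ""), chrom)
  models <- do.call(rbind, models)
  rownames(models) <- NULL
  transcripts <- transcript_seqs(models, genome)
  # PHAS transcript sequences sanity: single-exon plus-strand
  truth <- list(
    mirna = mirna,
    phas = if (is.null(phas)) data.frame() else phas,
    cleavage = if (length(cleav)) do.call(rbind, cleav) else data.frame(),
    expression = do.call(rbind, expr_rows),
    as_switch = if (length(as_truth)) do.call(rbind, as_truth) else
      data.frame(locus = character(0), type = character(0),
                 switched_isoform = character(0), stringsAsFactors = FALSE),
    effects = eff)
  rownames(truth$expression) <- NULL
  # known-miRNA catalog: the conserved subset plus unrelated decoys
  in_cat <- which(mirna$in_catalog)
  catalog <- stats::setNames(mirna$mature[in_cat],
                             if (length(in_cat)) paste0("syn-miR", in_cat)
                             else character(0))
  catalog <- c(catalog, stats::setNames(random_dna(5, 21),
                                        paste0("syn-miR-decoy", 1:5)))
  contaminants <- stats::setNames(random_dna(5, 500), paste0("rRNA_like_", 1:5))
  structure(list(genome = genome, models = models, transcripts = transcripts,
                 gene_models = models[models$biotype == "protein_coding", ,
                                      drop = FALSE],
                 catalog = catalog, contaminants = contaminants,
                 truth = truth, config = config),
            class = "sim_reference")
}

# planted sRNA tag universe with per-tag mock/treated expected weights
srna_tag_universe <- function(ref) {
  truth <- ref$truth
  rows <- list()
  add <- function(seq, w, fold, origin) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sequence = seq, w_mock = w, w_treated = w * fold, origin = origin,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(truth$mirna))) {
    m <- truth$mirna[i, ]
    add(m$mature, m$weight, m$fold, m$id)
    add(m$star, m$weight / 20, m$fold, paste0(m$id, "*"))
  }
  if (nrow(truth$phas)) {
    set.seed(substream_seed(ref$config$seed, "phas_offsets"))
    for (i in seq_len(nrow(truth$phas))) {
      p <- truth$phas[i, ]
      s <- ref$transcripts[[p$id]]
      n_pos <- 2L * p$n_cycles
      w_in <- p$weight * 0.9 / n_pos
      for (j in seq_len(p$n_cycles) - 1L) {
        fp_plus <- p$origin + 21L * j
        add(substr(s, fp_plus + 1L, fp_plus + 21L), w_in, p$fold, p$id)
        fp_minus <- p$origin + 21L * j + 2L     # minus-strand 5' end
        add(revcomp(substr(s, fp_minus - 20L + 1L, fp_minus + 1L)),
            w_in, p$fold, p$id)
      }
      # off-register 21-mers (imperfect processing)
      offs <- p$origin + sample(setdiff(5:150, seq(0, 189, by = 21)), 3)
      for (o in offs)
        add(substr(s, o + 1L, o + 21L), p$weight * 0.1 / 3, p$fold, p$id)
      add(p$trigger_seq, 3, 1, p$trigger_id)
    }
  }
  # contaminant-derived tags
  for (j in 1:10) {
    src <- ref$contaminants[[(j - 1L) %% length(ref$contaminants) + 1L]]
    st <- 40L * j
    add(substr(src, st, st + 20L), 2, 1, "contaminant")
  }
  tab <- do.call(rbind, rows)
  tab[!duplicated(tab$sequence), , drop = FALSE]
}

#' Simulate small-RNA libraries
#'
#' Each library receives negative-binomial counts for every planted tag
#' (mature miRNAs and stars, phased 21-nt siRNAs from both strands of each
#' PHAS locus with the minus-strand 5' ends offset by 2 nt, trigger sRNAs,
#' a small contaminant-derived component) with condition effects applied
#' multiplicatively, plus `background_fraction` random reads of 15-30 nt.
#'
#' @param ref `sim_reference` from [make_reference()].
#' @param config `sim_config` (defaults to the one inside `ref`).
#' @param outdir optional directory; when given, one
#'   `srna_<sample>.<fasta|fastq>` file is written per library.
#' @param format `"fasta"` (clean inserts) or `"fastq"` (adapter appended).
#' @return named list of read vectors, one per sample.
#' @export
simulate_srna_libraries <- function(ref, config = ref$config, outdir = NULL,
                                    format = c("fasta", "fastq")) {
  format <- match.arg(format)
  design <- sim_design(config)
  uni <- srna_tag_universe(ref)
  depth <- config$reads_per_srna_library
  bf <- config$background_fraction
  libs <- list()
  for (s in design$samples) {
    set.seed(substream_seed(config$seed, paste0("srna_", s)))
    w <- if (design$condition[[s]] == "mock") uni$w_mock else uni$w_treated
    mu <- depth * (1 - bf) * w / sum(uni$w_mock)
    counts <- rnb(length(mu), mu, config$nb_dispersion)
    n_bg <- round(depth * bf)
    bg <- random_dna(n_bg, sample(15:30, n_bg, replace = TRUE))
    reads <- c(rep(uni$sequence, counts), bg)
    if (format == "fastq") reads <- paste0(reads, config$adapter)
    libs[[s]] <- reads
    if (!is.null(outdir)) {
      ext <- if (format == "fastq") "fastq" else "fasta"
      write_seqs(stats::setNames(reads, paste0(s, "_r", seq_along(reads))),
                 file.path(outdir, paste0("srna_", s, ".", ext)),
                 format = format)
    }
  }
  libs
}

#' Simulate degradome libraries
#'
#' Tag 5' ends concentrate at the planted cleavage positions (the
#' transcript nucleotide pairing position 10 of the guide sRNA) with
#' per-condition signal strengths; the remaining tags are uniform
#' background drawn from random transcript positions.  Tags have fixed
#' length (default 20 nt).
#'
#' @inheritParams simulate_srna_libraries
#' @return named list of tag-sequence vectors, one per sample.
#' @export
simulate_degradome <- function(ref, config = ref$config, outdir = NULL) {
  design <- sim_design(config)
  tl <- config$degradome_tag_length
  sites <- ref$truth$cleavage
  tr_len <- nchar(ref$transcripts)
  if (nrow(sites)) {
    too_close <- sites$cleavage_pos > tr_len[sites$transcript] - tl
    if (any(too_close))
      stop("placement error: cleavage site within ", tl,
           " nt of transcript 3' end (",
           paste(sites$transcript[too_close], collapse = ", "), ")")
  }
  libs <- list()
  for (s in design$samples) {
    set.seed(substream_seed(config$seed, paste0("degradome_", s)))
    mu <- if (design$condition[[s]] == "mock") sites$mu_mock else sites$mu_treated
    counts <- if (nrow(sites)) rnb(nrow(sites), mu, config$nb_dispersion) else integer(0)
    planted <- rep(substr(ref$transcripts[sites$transcript],
                          sites$cleavage_pos + 1L, sites$cleavage_pos + tl),
                   counts)
    n_bg <- round(config$tags_per_degradome_library *
                    config$degradome_background_fraction)
    tr_pick <- sample(names(ref$transcripts), n_bg, replace = TRUE,
                      prob = tr_len)
    pos <- floor(stats::runif(n_bg) * (tr_len[tr_pick] - tl))
    bg <- substr(ref$transcripts[tr_pick], pos + 1L, pos + tl)
    reads <- c(planted, unname(bg))
    libs[[s]] <- reads
    if (!is.null(outdir))
      write_seqs(stats::setNames(reads, paste0(s, "_d", seq_along(reads))),
                 file.path(outdir, paste0("degradome_", s, ".fasta")))
  }
  libs
}

#' Simulate per-isoform expression counts
#'
#' Negative-binomial counts around the planted per-condition expected
#' means (fold changes and isoform-usage switches included).
#'
#' @inheritParams simulate_srna_libraries
#' @return integer matrix, transcripts x samples; written to
#'   `counts.tsv` under `outdir` when given.
#' @export
simulate_expression_counts <- function(ref, config = ref$config, outdir = NULL) {
  design <- sim_design(config)
  ex <- ref$truth$expression
  set.seed(substream_seed(config$seed, "counts.tsv"))
  m <- vapply(design$samples, function(s) {
    mu <- if (design$condition[[s]] == "mock") ex$mu_mock else ex$mu_treated
    as.integer(rnb(nrow(ex), mu, config$nb_dispersion))
  }, integer(nrow(ex)))
  rownames(m) <- ex$transcript_id
  if (!is.null(outdir)) {
    df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(outdir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  m
}

#' Write the reference bundle to disk
#'
#' Emits `genome.fasta`, `transcripts.fasta`, `models.gff3`,
#' `catalog.fasta`, `contaminants.fasta` and the ground-truth tables
#' (`truth_*.tsv`).
#'
#' @param ref `sim_reference`.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_reference <- function(ref, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_seqs(ref$genome, file.path(outdir, "genome.fasta"))
  write_seqs(ref$transcripts, file.path(outdir, "transcripts.fasta"))
  write_gff3(ref$models, file.path(outdir, "models.gff3"))
  write_seqs(ref$catalog, file.path(outdir, "catalog.fasta"))
  write_seqs(ref$contaminants, file.path(outdir, "contaminants.fasta"))
  write_truth(ref$truth, outdir)
  invisible(outdir)
}

#' Serialize / deserialize ground truth
#'
#' @param truth truth list from [make_reference()].
#' @param dir directory for the `truth_*.tsv` files.
#' @return `write_truth`: `dir` invisibly; `read_truth`: the truth list.
#' @export
write_truth <- function(truth, dir) {
  for (nm in names(truth)) {
    utils::write.table(truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  files <- list.files(dir, pattern = "^truth_.*\\.tsv$", full.names = TRUE)
  out <- lapply(files, function(f)
    utils::read.table(f, sep = "\t", header = TRUE, stringsAsFactors = FALSE))
  names(out) <- sub("^truth_(.*)\\.tsv$", "\\1", basename(files))
  out
}

#' Run the full synthetic experiment
#'
#' Builds the reference and simulates sRNA libraries, degradome libraries
#' and expression counts.
#'
#' @param config `sim_config`.
#' @param outdir optional output directory; when given all files are
#'   written there.
#' @param srna_format passed to [simulate_srna_libraries()].
#' @return list with `reference`, `srna`, `degradome`, `counts`,
#'   `condition`.
#' @export
simulate_vigs_experiment <- function(config, outdir = NULL,
                                     srna_format = "fasta") {
  ref <- make_reference(config)
  if (!is.null(outdir)) write_reference(ref, outdir)
  srna <- simulate_srna_libraries(ref, config, outdir = outdir,
                                  format = srna_format)
  deg <- simulate_degradome(ref, config, outdir = outdir)
  counts <- simulate_expression_counts(ref, config, outdir = outdir)
  list(reference = ref, srna = srna, degradome = deg, counts = counts,
       condition = sim_design(config)$condition)
}
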