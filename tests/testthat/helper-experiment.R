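# Shared, lazily built synthetic experiments so expensive simulations run
# at most once per test session.

.exp_cache <- new.env(parent = emptyenv())

# full default experiment (seed 1) with the sRNA core already run
default_experiment <- function() {
  if (is.null(.exp_cache$default)) {
    cfg <- sim_config(seed = 1)
    sim <- simulate_vigs_experiment(cfg)
    ref <- sim$reference
    reads <- lapply(sim$srna, preprocess_reads)
    reads <- lapply(reads, filter_contaminants, contaminants = ref$contaminants)
    tab <- normalize_tpm(collapse_and_count(reads))
    expr <- filter_expressed(tab, min_tpm = 5)
    .exp_cache$default <- list(cfg = cfg, sim = sim, ref = ref, tab = tab,
                               expr = expr, condition = sim$condition)
  }
  .exp_cache$default
}

# small-RNA pipeline for one seed of the PHAS-recovery experiment:
# 10 planted PHAS loci, 3+3 replicates, background fraction 0.2
run_phas_seed <- function(seed, n_phas = 10L) {
  cfg <- sim_config(seed = seed, n_mirna_loci = 0L, n_phas_loci = n_phas,
                    reads_per_srna_library = 240000L)
  ref <- make_reference(cfg)
  srna <- simulate_srna_libraries(ref)
  reads <- lapply(lapply(srna, preprocess_reads), filter_contaminants,
                  contaminants = ref$contaminants)
  tab <- normalize_tpm(collapse_and_count(reads))
  expr <- filter_expressed(tab, min_tpm = 5)
  aln <- map_exact(expr$sequence, ref$transcripts)
  loci <- detect_phas_loci(aln, transcript_lengths(ref$models), expr)
  dp <- differential_phas(loci, aln, expr, sim_design(cfg)$condition)
  list(ref = ref, loci = loci, diff = dp)
}

# degradome side of the default experiment (profiles + called events)
default_pare <- function() {
  if (is.null(.exp_cache$pare)) {
    e <- default_experiment()
    profiles <- lapply(e$sim$degradome, build_profile,
                      transcripts = e$ref$transcripts)
    queries <- e$expr$sequence[nchar(e$expr$sequence) %in% c(21, 22)]
    events <- call_cleavage_events(queries, profiles, e$ref$transcripts,
                                   seed = 1)
    .exp_cache$pare <- list(profiles = profiles, queries = queries,
                            events = events,
                            validated = filter_events(events))
  }
  .exp_cache$pare
}

# independent per-position complementarity tally used as a scoring oracle
naive_pair_score <- function(srna, target) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  q <- strsplit(chartr("T", "U", toupper(srna)), "")[[1]]
  t <- strsplit(chartr("T", "U", toupper(target)), "")[[1]]
  L <- length(q)
  tot <- 0
  for (i in seq_len(L)) {
    tb <- t[L + 1L - i]
    pen <- if (identical(unname(comp[q[i]]), tb)) 0
      else if ((q[i] == "G" && tb == "U") || (q[i] == "U" && tb == "G")) 0.5
      else 1
    tot <- tot + (if (i >= 2 && i <= 13) 2 else 1) * pen
  }
  tot
}
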