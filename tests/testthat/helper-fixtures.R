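# Shared fixtures, built once per test run.
#
# sim_fixture() runs the full default-scale simulation and phasing chain
# (simulate -> pair -> count k-mers -> diagnostic selection -> cluster ->
# density tracks -> exchange HMM) and caches the result; the heavy stages
# run a single time however many test files use them.

.fixture_env <- new.env(parent = emptyenv())

sim_fixture <- function() {
  if (!is.null(.fixture_env$sim)) return(as.list(.fixture_env))
  cfg <- sim_config(seed = 42)
  sim <- simulate_allotetraploid(cfg)
  paf <- truth_paf(sim)
  pairs <- pair_homoeologs(paf)
  kc <- kmer_config(window = 5e4)
  counts <- count_kmers(sim$genome, kc)
  diag <- select_diagnostic_kmers(counts, pairs, kc)
  assignment <- cluster_subgenomes(diag, pairs)
  tracks <- density_tracks(sim$genome, diag, window = 5e4)
  exchanges <- detect_exchanges(assignment, tracks)
  for (nm in c("cfg", "sim", "paf", "pairs", "kc", "counts", "diag",
               "assignment", "tracks", "exchanges")) {
    assign(nm, get(nm), envir = .fixture_env)
  }
  as.list(.fixture_env)
}

# A small, fast simulation without TE bursts or exchange, for gene-level
# checks.
lean_sim <- function(seed = 11, n_pairs = 4, n_genes = 250,
                     retention_a = 0.85, retention_b = 0.79) {
  cfg <- sim_config(
    n_pairs = n_pairs, chrom_len = 5e5, n_genes_per_chrom = n_genes,
    gene_len = 1000, copies_per_family_a = 0, copies_per_family_b = 0,
    retention_prob_a = retention_a, retention_prob_b = retention_b,
    exchange_spec = data.frame(pair = integer(0), from = character(0),
                               start = numeric(0), end = numeric(0)),
    seed = seed)
  simulate_allotetraploid(cfg)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
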