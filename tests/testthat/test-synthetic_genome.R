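no_burst_cfg <- function(rate = 1.3e-8, seed = 3) {
  sim_config(n_pairs = 2, chrom_len = 2e5, n_genes_per_chrom = 20,
             substitution_rate = rate,
             copies_per_family_a = 0, copies_per_family_b = 0,
             exchange_spec = data.frame(pair = integer(0),
                                        from = character(0),
                                        start = numeric(0),
                                        end = numeric(0)),
             retention_prob_a = 1, retention_prob_b = 1, seed = seed)
}

test_that("zero substitution rate leaves parents identical to the ancestor", {
  prog <- simulate_progenitors(no_burst_cfg(rate = 0))
  expect_identical(as.character(prog$parent_a), as.character(prog$ancestor))
  expect_identical(as.character(prog$parent_b), as.character(prog$ancestor))
})

test_that("equal seeds give byte-identical simulations", {
  cfg <- sim_config(n_pairs = 2, chrom_len = 1e5, n_genes_per_chrom = 10,
                    copies_per_family_a = 20, copies_per_family_b = 60,
                    exchange_spec = data.frame(pair = 1, from = "B",
                                               start = 2e4, end = 4e4),
                    seed = 99)
  s1 <- simulate_allotetraploid(cfg)
  s2 <- simulate_allotetraploid(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$elements, s2$elements)
  expect_identical(s1$truth$gene_fate, s2$truth$gene_fate)
})

test_that("5'-3' LTR divergence matches the closed-form expectation", {
  # Both terminal repeats accumulate r*T substitutions independently;
  # composing the two JC branches gives expected p-distance
  # 3/4 (1 - exp(-4/3 * 2 r T)) ~= 0.0857 at T = 3.5e6, r = 1.3e-8.
  cfg <- sim_config(n_pairs = 2, chrom_len = 1e6, n_genes_per_chrom = 10,
                    copies_per_family_a = 120, copies_per_family_b = 120,
                    burst_age = 3.5e6, burst_age_sd = 1,
                    exchange_spec = data.frame(pair = integer(0),
                                               from = character(0),
                                               start = numeric(0),
                                               end = numeric(0)),
                    seed = 5)
  sim <- simulate_allotetraploid(cfg)
  s5 <- ltr_seqs(sim$genome, sim$elements, "five")
  s3 <- ltr_seqs(sim$genome, sim$elements, "three")
  n <- length(s5)
  expect_gte(n, 200)
  p <- vapply(seq_len(n), function(i)
    align_ltr_pair(s5[[i]], s3[[i]])$p, numeric(1))
  d <- 2 * 1.3e-8 * 3.5e6
  p_expected <- 0.75 * (1 - exp(-4 / 3 * d))
  L <- nchar(s5[[1]])
  se <- sqrt(p_expected * (1 - p_expected) / (L * n))
  expect_lt(abs(mean(p) - p_expected), 3 * se + 1e-4)
})

test_that("gene retention follows the configured binomial probabilities", {
  sim <- lean_sim(seed = 21)
  fate <- sim$truth$gene_fate
  n <- length(fate)
  got_a <- mean(fate %in% c("both", "A_only"))
  got_b <- mean(fate %in% c("both", "B_only"))
  se_a <- sqrt(0.85 * 0.15 / n); se_b <- sqrt(0.79 * 0.21 / n)
  expect_lt(abs(got_a - 0.85), 3 * se_a)
  expect_lt(abs(got_b - 0.79), 3 * se_b)
  # conservation: every ancestral gene has exactly one fate
  expect_equal(sum(table(fate)), n)
  expect_true(all(fate %in% c("both", "A_only", "B_only", "lost_both")))
  # and the ortholog table agrees with the fates exactly
  orth <- sim$ortholog_table
  expect_identical(
    unname(fate[orth$ref_gene] == "both"),
    !is.na(orth$gene_a) & !is.na(orth$gene_b))
})

test_that("retention probability one keeps every gene in both subgenomes", {
  sim <- lean_sim(seed = 4, n_pairs = 2, n_genes = 40,
                  retention_a = 1, retention_b = 1)
  expect_true(all(sim$truth$gene_fate == "both"))
})

test_that("planted exchange is recorded with its exact coordinates", {
  fx <- sim_fixture()
  ex <- fx$sim$truth$exchange_segments
  expect_equal(nrow(ex), 1)
  expect_equal(ex$start, 1.0e6)
  expect_equal(ex$end, 1.2e6)
  expect_equal(fx$sim$truth$subgenome_of[[ex$scaffold]], "A")
  expect_error(
    simulate_allotetraploid(
      sim_config(n_pairs = 1, chrom_len = 1e5, n_genes_per_chrom = 5,
                 copies_per_family_a = 0, copies_per_family_b = 0,
                 exchange_spec = data.frame(pair = 1, from = "B",
                                            start = 5e4, end = 2e5),
                 seed = 1)),
    "out of bounds")
})

test_that("lost genes are replaced by background sequence, not just unannotated", {
  sim <- lean_sim(seed = 13, n_pairs = 2, n_genes = 100,
                  retention_a = 0.5, retention_b = 1)
  lost_a <- names(sim$truth$gene_fate)[sim$truth$gene_fate == "B_only"]
  expect_gt(length(lost_a), 10)
  # the A copy region should no longer match the B copy region
  g <- sim$truth$name_map
  prog_genes <- sim$progenitors$genes
  row <- prog_genes[prog_genes$gene == lost_a[1], ]
  seq_a <- substr(unclass(sim$genome)[[g[[sprintf("A%02d", row$pair)]]]],
                  row$start_a + 1, row$start_a + 1000)
  seq_b <- substr(unclass(sim$genome)[[g[[sprintf("B%02d", row$pair)]]]],
                  row$start_b + 1, row$start_b + 1000)
  mism <- mean(strsplit(seq_a, "")[[1]] != strsplit(seq_b, "")[[1]])
  expect_gt(mism, 0.5)  # background vs gene: ~75% mismatch
})

test_that("the simulated JC process is self-consistent under jc_distance", {
  # comparing ancestor and one parent recovers r*T within sampling error
  cfg <- no_burst_cfg(seed = 17)
  prog <- simulate_progenitors(cfg)
  anc <- strsplit(unclass(prog$ancestor)[[1]], "")[[1]]
  pa <- strsplit(unclass(prog$parent_a)[[1]], "")[[1]]
  p <- mean(anc != pa)
  k <- jc_distance(p)
  d_true <- 1.3e-8 * 5.8e6
  se <- sqrt(p * (1 - p) / length(anc))
  expect_lt(abs(k - d_true), 4 * se)
})
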