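test_that("retention accounting reproduces the published-style worked row", {
  # 19,523 ancestral; 16,666 in A; 15,464 in B; 12,195 in both
  expect_warning(rt <- retention_table(19523, 16666, 15464, 12195),
                 "differs from n_ancestral")
  expect_equal(rt$pct_a, 85.3660, tolerance = 1e-4)
  expect_equal(rt$pct_b, 79.2091, tolerance = 1e-4)
  expect_equal(rt$pct_both, 62.4648, tolerance = 1e-4)
  expect_equal(round(c(rt$pct_a, rt$pct_b, rt$pct_both)), c(85, 79, 62))
})

test_that("tally_retention counts presence flags and rejects bad input", {
  orth <- data.frame(ref_gene = c("g1", "g2", "g3", "g4"),
                     gene_a = c("g1_A", "g2_A", NA, NA),
                     gene_b = c("g1_B", NA, "g3_B", NA),
                     stringsAsFactors = FALSE)
  rt <- tally_retention(orth)
  expect_equal(rt$n_ancestral, 3)  # g4 has no surviving copy
  expect_equal(rt$retained_a, 2)
  expect_equal(rt$retained_b, 2)
  expect_equal(rt$retained_both, 1)
  # row order cannot matter
  rt2 <- tally_retention(orth[c(3, 1, 4, 2), ])
  expect_equal(rt2[names(rt2) != "call"], rt[names(rt) != "call"])
  expect_error(tally_retention(orth[c(1, 1), ]), "duplicate")
  expect_error(tally_retention(orth[0, ]), "empty")

  all_both <- data.frame(ref_gene = c("a", "b"), in_a = TRUE, in_b = TRUE)
  rt3 <- tally_retention(all_both)
  expect_equal(c(rt3$pct_a, rt3$pct_b, rt3$pct_both), c(100, 100, 100))
})

test_that("simulated retention percentages match the configured probabilities", {
  sim <- lean_sim(seed = 51, n_pairs = 4, n_genes = 250)
  rt <- tally_retention(sim$ortholog_table)
  n <- rt$n_ancestral
  # conditional on being ancestral (>= 1 copy), expectations shift
  # slightly; 3 binomial SEs around the unconditional values still hold
  se <- 100 * sqrt(0.85 * 0.15 / n)
  expect_lt(abs(rt$pct_a / 100 - 0.85 / (1 - 0.15 * 0.21)), 3 * se / 100 + 0.01)
  expect_gt(rt$pct_a, rt$pct_b)
})

test_that("fisher_exact_2x2 equals enumeration and the trusted reference", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)),
               34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 5, 9), 2)), 1)  # degenerate

  set.seed(501)
  for (rep in 1:200) {
    m <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(m) > 40 || sum(m) == 0) next
    got <- fisher_exact_2x2(m)
    expect_equal(got, brute_fisher_two_sided(m), tolerance = 1e-10,
                 info = paste(m, collapse = ","))
    expect_equal(got, stats::fisher.test(m)$p.value, tolerance = 1e-7)
    one <- fisher_exact_2x2(m, sided = "greater")
    expect_gte(one, 0)
    expect_lte(one, 1)
    # when the top-left cell sits at or above its null expectation, the
    # two-sided p dominates the favored one-sided tail
    if (m[1, 1] >= sum(m[1, ]) * sum(m[, 1]) / sum(m)) {
      expect_gte(got + 1e-12, one)
    }
  }
})

test_that("the retention-bias test reproduces the published p-values", {
  # orthogroup-analysis row: 15,262 / 12,716 / 12,278 / 9,620
  rt_og <- suppressWarnings(retention_table(15262, 12716, 12278, 9620))
  p_o <- fisher_exact_2x2(retention_bias_table(rt_og))
  expect_lt(abs(p_o - 1.63e-10) / 1.63e-10, 0.10)
  # collinearity-scan row is far below the double-precision print floor
  rt_m <- suppressWarnings(retention_table(19523, 16666, 15464, 12195))
  expect_lt(fisher_exact_2x2(retention_bias_table(rt_m)), 2.2e-16)
  expect_lt(fisher_exact_2x2(retention_bias_table(rt_m, "retained_lost")),
            2.2e-16)
})

test_that("retention-bias test is calibrated, and shared genes inflate it", {
  set.seed(502)
  n <- 1500
  reps <- 400
  # Fisher's own sampling model: two independent cohorts, equal retention
  rej_ind <- 0
  for (i in seq_len(reps)) {
    ra <- sum(runif(n) < 0.82); rb <- sum(runif(n) < 0.82)
    m <- matrix(c(ra, n - ra, rb, n - rb), 2, byrow = TRUE)
    if (fisher_exact_2x2(m) < 0.05) rej_ind <- rej_ind + 1
  }
  expect_lt(abs(rej_ind / reps - 0.05), 0.03)

  # the within-genome null puts the same genes in both rows; the counts
  # are negatively dependent, so the test runs slightly hot (~7%)
  rej_sh <- 0
  for (i in seq_len(reps)) {
    in_a <- runif(n) < 0.82; in_b <- runif(n) < 0.82
    anc <- in_a | in_b
    rt <- suppressWarnings(
      retention_table(sum(anc), sum(in_a), sum(in_b), sum(in_a & in_b)))
    if (fisher_exact_2x2(retention_bias_table(rt)) < 0.05) rej_sh <- rej_sh + 1
  }
  expect_gt(rej_sh / reps, 0.04)
  expect_lt(rej_sh / reps, 0.12)
})

test_that("go_enrichment computes expecteds, p-values and orderings", {
  universe <- sprintf("g%03d", 1:200)
  term_map <- data.frame(
    gene = c(universe[1:40], universe[150:189]),
    term = rep(c("T_planted", "T_flat"), each = 40),
    stringsAsFactors = FALSE)
  # foreground holds 30 of T_planted's 40 genes but only 8 of T_flat's
  fg <- c(universe[1:30], universe[41:72], universe[150:157])
  out <- go_enrichment(fg, universe, term_map)
  expect_equal(out$term[1], "T_planted")
  expect_equal(out$annotated, c(40, 40))
  expect_equal(out$significant[out$term == "T_planted"], 30)
  expect_equal(out$expected,
               40 * length(fg) / 200 * c(1, 1))
  expect_true(all(out$p >= 0 & out$p <= 1))

  # foreground == universe: every p is 1 and expected equals annotated
  out2 <- go_enrichment(universe, universe, term_map)
  expect_true(all(out2$p == 1))
  expect_equal(out2$expected, out2$annotated)

  expect_error(go_enrichment(c("nope"), universe, term_map), "subset")
})

test_that("expected counts are cross-consistent with published-style rows", {
  # the foreground fraction implied by one row predicts the others
  frac <- 455.35 / 962
  expect_lt(abs(go_expected(593, frac, 1) - 280.69), 0.5)
  expect_lt(abs(go_expected(3176, frac, 1) - 1503.31), 0.5)
})

test_that("exclude_regions removes copies inside masked regions", {
  orth <- data.frame(ref_gene = c("g1", "g2"),
                     gene_a = c("g1_A", "g2_A"),
                     gene_b = c("g1_B", NA), stringsAsFactors = FALSE)
  genes <- feature_table(c("s1", "s1", "s2"), c(100, 5000, 100),
                         c(1100, 6000, 1100), "+", "gene",
                         c("g1_A", "g2_A", "g1_B"))
  regions <- data.frame(scaffold = "s1", start = 0, end = 2000)
  got <- exclude_regions(orth, genes, regions)
  expect_true(is.na(got$gene_a[1]))   # g1_A inside the region
  expect_false(is.na(got$gene_a[2]))  # g2_A outside
  expect_false(is.na(got$gene_b[1]))  # other scaffold untouched
})
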