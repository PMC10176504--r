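test_that("global alignment statistics are exact on constructed cases", {
  s <- random_dna(300)
  a <- align_ltr_pair(s, s)
  expect_equal(a$identity, 1)
  expect_equal(a$coverage_x, 1)
  expect_equal(a$coverage_y, 1)
  expect_equal(a$p, 0)

  s2 <- s
  substr(s2, 100, 100) <- if (substr(s, 100, 100) == "A") "C" else "A"
  a2 <- align_ltr_pair(s, s2)
  expect_equal(a2$identity, 299 / 300)
  expect_equal(a2$mismatches, 1)
  expect_equal(a2$p, 1 / 300)
})

test_that("alignment score equals a textbook dynamic program", {
  set.seed(401)
  for (rep in 1:50) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    x <- random_dna(n1)
    y <- if (rep %% 3 == 0) random_dna(n2) else {
      # related pair: mutate and clip so indels appear
      z <- jc_mutate(x, 0.1)
      substr(z, 1, max(10, n1 - sample(0:10, 1)))
    }
    got <- align_ltr_pair(x, y)
    expect_equal(got$score, naive_nw_score(x, y), info = paste("rep", rep))
  }
})

test_that("banded alignment agrees with the full matrix on collinear pairs", {
  set.seed(402)
  for (rep in 1:10) {
    x <- random_dna(300)
    y <- jc_mutate(x, 0.1)
    full <- align_ltr_pair(x, y)
    banded <- align_ltr_pair(x, y, band = 50)
    expect_equal(banded$score, full$score)
    expect_equal(banded$p, full$p)
  }
})

test_that("MCL clusters disconnected cliques as components", {
  ids <- sprintf("n%02d", 1:8)
  adj <- matrix(0, 8, 8, dimnames = list(ids, ids))
  adj[1:4, 1:4] <- 0.9; adj[5:8, 5:8] <- 0.9
  cl <- mcl_cluster(adj)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:4])), 1)
  expect_equal(length(unique(cl[5:8])), 1)
  expect_false(cl[1] == cl[5])

  single <- mcl_cluster(matrix(0, 1, 1, dimnames = list("x", "x")))
  expect_equal(unname(single), 1L)
})

test_that("MCL splits a barbell graph and matches direct matrix iteration", {
  ids <- sprintf("n%d", 1:8)
  adj <- matrix(0, 8, 8, dimnames = list(ids, ids))
  adj[1:4, 1:4] <- 1; adj[5:8, 5:8] <- 1
  diag(adj) <- 0
  adj[4, 5] <- adj[5, 4] <- 0.1  # weak bridge
  # the weak bridge makes this the slowest-converging case in the suite;
  # give the iteration room to pass the 1e-6 criterion
  cl <- mcl_cluster(adj, inflation = 3, max_iter = 500)
  expect_equal(length(unique(cl)), 2)
  expect_equal(unname(cl[1:4]), rep(cl[[1]], 4))
  expect_equal(unname(cl[5:8]), rep(cl[[5]], 4))

  # independent plain-R transcript of the same iteration rules
  m <- adj
  diag(m) <- apply(m, 1, max)
  norm <- function(x) {
    cs <- colSums(x); cs[cs == 0] <- 1
    sweep(x, 2, cs, "/")
  }
  m <- norm(m)
  for (i in 1:500) {
    m_new <- norm((m %*% m)^3)
    m_new[m_new < 1e-5] <- 0
    m_new <- norm(m_new)
    if (max(abs(m_new - m)) < 1e-6) { m <- m_new; break }
    m <- m_new
  }
  # attractor rows of the limit matrix describe the same two clusters
  att <- which(diag(m) > 1e-5)
  oracle_clusters <- unique(lapply(att, function(a) sort(which(m[a, ] > 1e-5))))
  expect_equal(length(oracle_clusters), 2)
  expect_setequal(oracle_clusters[[1]],
                  sort(unname(which(cl == cl[oracle_clusters[[1]][1]]))))
})

test_that("subfamily building separates synthetic families", {
  set.seed(403)
  consA <- random_dna(300); consB <- random_dna(300)
  seqs <- c(setNames(vapply(1:6, function(i) jc_mutate(consA, 0.05), ""),
                     sprintf("a%d", 1:6)),
            setNames(vapply(1:5, function(i) jc_mutate(consB, 0.05), ""),
                     sprintf("b%d", 1:5)))
  sf <- build_subfamilies(seqs)
  expect_equal(length(sf$families), 2)
  expect_setequal(sf$families[[1]], sprintf("a%d", 1:6))
  expect_setequal(sf$families[[2]], sprintf("b%d", 1:5))

  lone <- build_subfamilies(c(only = random_dna(200)))
  expect_equal(lengths(lone$families), c(SF001 = 1L))
})

test_that("subfamily enrichment requires both occurrence and bp folds", {
  mk <- function(occ_a, occ_b, bp_a, bp_b) {
    ids <- sprintf("e%02d", seq_len(occ_a + occ_b))
    sf <- list(membership = setNames(rep("SF001", length(ids)), ids),
               families = list(SF001 = ids))
    elements <- data.frame(
      id = ids,
      scaffold = rep(c("sA", "sB"), c(occ_a, occ_b)),
      start = 0,
      end = c(rep(bp_a / occ_a, occ_a), rep(bp_b / occ_b, occ_b)),
      stringsAsFactors = FALSE)
    subfamily_enrichment(sf, elements, c(sA = "A", sB = "B"))
  }
  # occurrence fold 4.5, bp fold 3.1 -> enriched toward A
  r1 <- mk(9, 2, 9000, 2900)
  expect_true(r1$enriched)
  expect_equal(r1$direction, "A")
  # bp fold only 2.25 -> not enriched
  r2 <- mk(9, 2, 9000, 4000)
  expect_false(r2$enriched)
})

test_that("jc_distance matches the closed form and its domain", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.05), -0.75 * log(1 - 4 * 0.05 / 3))
  expect_equal(jc_distance(0.05), 0.0517, tolerance = 1e-3)
  expect_error(jc_distance(0.75), "saturation")
  expect_error(jc_distance(-0.01), "saturation")
  # monotone and always at least the uncorrected distance
  p <- seq(0.01, 0.7, by = 0.01)
  k <- jc_distance(p)
  expect_true(all(diff(k) > 0))
  expect_true(all(k >= p))
})

test_that("the k/2r clock dates constructed divergences", {
  # k = 0.156 at r = 1.3e-8 -> 6.0 million years
  expect_equal(0.156 / (2 * 1.3e-8) / 1e6, 6.0)
  s <- random_dna(400)
  ages0 <- date_family(setNames(c(s, s), c("e1", "e1b")), seqs3 = NULL,
                       mode = "within_family_pairs")
  expect_equal(ages0$t, 0)
  # doubling the rate halves every age
  set.seed(404)
  seqs5 <- setNames(vapply(1:6, function(i) jc_mutate(s, 0.04), ""),
                    sprintf("e%d", 1:6))
  a1 <- date_family(seqs5, mode = "within_family_pairs", r = 1.3e-8)
  a2 <- date_family(seqs5, mode = "within_family_pairs", r = 2.6e-8)
  expect_equal(a1$t, 2 * a2$t)
  expect_equal(a1$k, a2$k)
})

test_that("saturated pairs are dropped with a message", {
  # homopolymers leave the aligner no gap tricks: every column mismatches
  s <- strrep("A", 40)
  far <- strrep("C", 40)
  expect_message(
    ages <- date_family(setNames(c(s, s, far), c("x", "y", "z")),
                        mode = "within_family_pairs"),
    "saturated")
  expect_equal(nrow(ages), 1)  # only the identical pair survives
})
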