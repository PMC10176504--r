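# LTR retrotransposon subfamilies and insertion dating.
#
# Elements are clustered into subfamilies on a graph whose edges are
# exact pairwise global alignments of their terminal-repeat segments
# passing identity and mutual-coverage filters, using Markov clustering
# (MCL). Subfamily enrichment between subgenomes uses both occurrence and
# bp counts. Insertion ages come from the Jukes-Cantor corrected
# divergence k via t = k / (2r): two sequences identical at insertion
# diverge at rate r each.

#' LTR alignment configuration
#'
#' @param min_identity minimum alignment identity for a clustering edge
#'   (filter on exact global alignment, standing in for a similarity
#'   search cutoff).
#' @param min_mutual_coverage minimum fraction of each sequence covered by
#'   the alignment (both sequences).
#' @param match,mismatch,gap linear-gap alignment scores.
#' @return list of class `ltr_align_config`.
#' @export
ltr_align_config <- function(min_identity = 0.70, min_mutual_coverage = 0.90,
                             match = 1, mismatch = -1, gap = -2) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_mutual_coverage > 0, min_mutual_coverage <= 1)
  structure(list(min_identity = min_identity,
                 min_mutual_coverage = min_mutual_coverage,
                 match = match, mismatch = mismatch, gap = gap),
            class = "ltr_align_config")
}

#' Global alignment of two LTR segments
#'
#' Needleman-Wunsch with linear gap scoring. Identity is matches over all
#' alignment columns; coverage of each sequence is the fraction lying
#' between the first and last column where both sequences have a base
#' (terminal overhangs excluded); `p` is the proportion of differing
#' sites with gap columns excluded.
#'
#' @param seq_x,seq_y ACGT strings.
#' @param cfg an [ltr_align_config()] (scores taken from it).
#' @param band diagonal band half-width; 0 (default) runs the full
#'   dynamic-programming matrix.
#' @return list with `score, identity, coverage_x, coverage_y, p, sites,
#'   matches, mismatches, columns`.
#' @export
align_ltr_pair <- function(seq_x, seq_y, cfg = ltr_align_config(), band = 0) {
  .nw_align_cpp(seq_x, seq_y, cfg$match, cfg$mismatch, cfg$gap,
                as.integer(band))
}

#' Extract LTR segment sequences from a genome
#'
#' @param genome a [genome_set()].
#' @param elements element table with columns `id, scaffold, l5_start,
#'   l5_end, l3_start, l3_end` (0-based half-open), as produced by the
#'   simulator or parsed from an annotation.
#' @param which `"five"` or `"three"`.
#' @return named character vector of sequences.
#' @export
ltr_seqs <- function(genome, elements, which = c("five", "three")) {
  which <- match.arg(which)
  s <- if (which == "five") elements$l5_start else elements$l3_start
  e <- if (which == "five") elements$l5_end else elements$l3_end
  seqs <- substring(unclass(genome)[elements$scaffold], s + 1, e)
  setNames(seqs, elements$id)
}

#' Markov clustering (MCL) of a weighted undirected graph
#'
#' Column-stochastic matrix iteration: expansion (matrix square) and
#' inflation (elementwise power, column renormalization) with pruning of
#' entries below `prune`, until the largest entry change is below `tol`
#' or `max_iter` is reached (non-convergence returns the current
#' clustering with a warning). Self-loops are set to each node's maximum
#' incident edge weight before normalization. Clusters are read off the
#' attractor rows of the limit matrix; attractors sharing members are
#' merged.
#'
#' @param adj symmetric numeric adjacency matrix (zero diagonal or not;
#'   the diagonal is overwritten by the self-loop rule).
#' @param inflation inflation exponent.
#' @param prune entries below this are zeroed each iteration.
#' @param tol convergence threshold on the max entry change.
#' @param max_iter iteration cap.
#' @return integer vector of cluster labels (1-based), named by the
#'   matrix's row names.
#' @export
mcl_cluster <- function(adj, inflation = 3, prune = 1e-5, tol = 1e-6,
                        max_iter = 200) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  n <- nrow(adj)
  if (n == 1) return(setNames(1L, rownames(adj)))
  m <- adj
  diag(m) <- 0
  selfw <- apply(m, 1, max)
  selfw[selfw == 0] <- 1
  diag(m) <- selfw
  norm <- function(x) {
    cs <- colSums(x)
    cs[cs == 0] <- 1  # a column emptied by pruning stays empty
    sweep(x, 2, cs, "/")
  }
  m <- norm(m)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    old <- m
    m <- m %*% m
    m <- norm(m^inflation)
    m[m < prune] <- 0  # prune the normalized matrix, then re-normalize
    m <- norm(m)
    if (max(abs(m - old)) < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("MCL did not converge; returning current clustering")
  attractors <- which(diag(m) > prune)
  labels <- integer(n)
  next_lab <- 0L
  for (a in attractors) {
    members <- which(m[a, ] > prune)
    seen <- unique(labels[members][labels[members] > 0])
    if (length(seen) == 0) {
      next_lab <- next_lab + 1L
      lab <- next_lab
    } else {
      lab <- min(seen)
      for (s2 in seen) labels[labels == s2] <- lab
    }
    labels[members] <- lab
  }
  if (any(labels == 0)) {  # isolated or never-attracted nodes: singletons
    for (i in which(labels == 0)) {
      next_lab <- next_lab + 1L
      labels[i] <- next_lab
    }
  }
  labels <- as.integer(factor(labels, levels = unique(labels)))
  setNames(labels, rownames(adj))
}

#' Cluster LTR elements into subfamilies
#'
#' Builds the element graph (edges where alignment identity and mutual
#' coverage pass the thresholds of `cfg`; candidate pairs are restricted
#' to those sharing at least one 11-mer seed, mirroring seeded similarity
#' search) and partitions it with [mcl_cluster()]. Node order is
#' canonicalized to lexicographic id so results are reproducible
#' bit-for-bit. With more than `max_elements` elements a deterministic
#' systematic subsample (every m-th id) is clustered — the standard
#' exemplar-reduction step for redundant repeat libraries.
#'
#' @param seqs named character vector of LTR segment sequences (one per
#'   element, typically the 5' LTR).
#' @param cfg an [ltr_align_config()].
#' @param inflation MCL inflation.
#' @param max_elements subsample ceiling.
#' @param band diagonal band half-width for the pairwise alignments
#'   (terminal-repeat pairs worth an edge are near-collinear; 0 disables
#'   banding).
#' @return list of class `ltr_subfamilies`: `membership` (named integer
#'   vector element -> family), `families` (list of member id vectors,
#'   largest first), `edges` (data.frame).
#' @export
build_subfamilies <- function(seqs, cfg = ltr_align_config(), inflation = 3,
                              max_elements = 600, band = 50) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  seqs <- seqs[order(names(seqs))]
  if (length(seqs) > max_elements) {
    idx <- unique(round(seq(1, length(seqs), length.out = max_elements)))
    seqs <- seqs[idx]
  }
  n <- length(seqs)
  edges <- .align_edges_cpp(unname(seqs), cfg$min_identity,
                            cfg$min_mutual_coverage, cfg$match,
                            cfg$mismatch, cfg$gap, 11L, as.integer(band))
  adj <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (nrow(edges) > 0) {
    adj[cbind(edges$i, edges$j)] <- edges$identity
    adj[cbind(edges$j, edges$i)] <- edges$identity
  }
  membership <- mcl_cluster(adj, inflation = inflation)
  fam <- split(names(membership), membership)
  fam <- fam[order(-vapply(fam, length, integer(1)))]
  names(fam) <- sprintf("SF%03d", seq_along(fam))
  membership <- setNames(rep(names(fam), lengths(fam)), unlist(fam))
  structure(list(membership = membership, families = fam,
                 edges = data.frame(
                   id_x = names(seqs)[edges$i], id_y = names(seqs)[edges$j],
                   identity = edges$identity, stringsAsFactors = FALSE)),
            class = "ltr_subfamilies")
}

#' Subgenome enrichment of LTR subfamilies
#'
#' A subfamily is enriched when it is at least `min_fold` times more
#' common in one subgenome by both occurrence count and total bp, in the
#' same direction; zero denominators count as infinite fold.
#'
#' @param subfam an [build_subfamilies()] result.
#' @param elements element table with `id, scaffold, start, end`.
#' @param assignment a [cluster_subgenomes()] result (or a named vector
#'   scaffold -> "A"/"B").
#' @param min_fold enrichment threshold.
#' @return data.frame, one row per subfamily: occurrence and bp counts per
#'   subgenome, `enriched` flag and `direction` (`"A"`, `"B"` or `NA`).
#' @export
subfamily_enrichment <- function(subfam, elements, assignment, min_fold = 3) {
  asg <- if (inherits(assignment, "subgenome_assignment"))
    assignment$assignment else assignment
  ids <- names(subfam$membership)
  el <- elements[match(ids, elements$id), ]
  stopifnot(!anyNA(el$id))
  side <- asg[el$scaffold]
  stopifnot(!anyNA(side))
  bp <- el$end - el$start
  fam <- subfam$membership
  rows <- lapply(names(subfam$families), function(f) {
    sel <- fam == f
    occ_a <- sum(sel & side == "A"); occ_b <- sum(sel & side == "B")
    bp_a <- sum(bp[sel & side == "A"]); bp_b <- sum(bp[sel & side == "B"])
    pass <- function(x, y) x > 0 & x >= min_fold * y
    a_enr <- pass(occ_a, occ_b) && pass(bp_a, bp_b)
    b_enr <- pass(occ_b, occ_a) && pass(bp_b, bp_a)
    data.frame(family = f, n = sum(sel), occ_a = occ_a, occ_b = occ_b,
               bp_a = bp_a, bp_b = bp_b,
               enriched = a_enr || b_enr,
               direction = if (a_enr) "A" else if (b_enr) "B" else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Jukes-Cantor distance
#'
#' Corrects an observed proportion of differing sites for multiple hits:
#' `k = -(3/4) log(1 - 4p/3)`. The correction saturates at `p = 0.75`;
#' values at or beyond it are an error.
#'
#' @param p proportion of differing sites, in `[0, 0.75)`. Vectorized.
#' @return substitutions per site, `k >= p`.
#' @export
jc_distance <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 0.75)) {
    stop("Jukes-Cantor distance is defined for 0 <= p < 0.75 (saturation)")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Date LTR insertions with the k/2r clock
#'
#' Two dating modes. `five_vs_three_prime`: the two terminal repeats of
#' one element were identical at insertion, so their Jukes-Cantor
#' distance divided by `2r` is that element's age (one estimate per
#' element). `within_family_pairs`: all pairwise distances among the
#' family's 5' LTRs, dating the family's expansion (one estimate per
#' pair; pairs are capped by a deterministic systematic subsample for
#' large families). Gap columns are excluded from `p`; saturated pairs
#' (`p >= 0.75`) are dropped with a count reported.
#'
#' @param seqs5 named character vector of 5' LTR sequences.
#' @param seqs3 3' LTR sequences (same order), required for the
#'   five-vs-three mode.
#' @param mode dating mode.
#' @param r substitution rate per site per year.
#' @param cfg alignment scores.
#' @param max_pairs pair cap for the within-family mode.
#' @param band diagonal band half-width for the alignments (LTR pairs
#'   being dated are near-collinear; 0 disables banding).
#' @return data.frame of class `ltr_ages` with columns `id` (or
#'   `id_x, id_y`), `p`, `k`, `t` (years).
#' @export
date_family <- function(seqs5, seqs3 = NULL,
                        mode = c("within_family_pairs",
                                 "five_vs_three_prime"),
                        r = 1.3e-8, cfg = ltr_align_config(),
                        max_pairs = 2000, band = 50) {
  mode <- match.arg(mode)
  stopifnot(r > 0)
  if (mode == "five_vs_three_prime") {
    stopifnot(!is.null(seqs3), length(seqs3) == length(seqs5))
    p <- vapply(seq_along(seqs5), function(i)
      align_ltr_pair(seqs5[[i]], seqs3[[i]], cfg, band)$p, numeric(1))
    ids <- data.frame(id = names(seqs5), stringsAsFactors = FALSE)
  } else {
    n <- length(seqs5)
    if (n < 2) stop("within-family dating needs at least 2 sequences")
    prs <- t(combn(n, 2))
    if (nrow(prs) > max_pairs) {
      idx <- unique(round(seq(1, nrow(prs), length.out = max_pairs)))
      prs <- prs[idx, , drop = FALSE]
    }
    p <- vapply(seq_len(nrow(prs)), function(i)
      align_ltr_pair(seqs5[[prs[i, 1]]], seqs5[[prs[i, 2]]], cfg, band)$p,
      numeric(1))
    ids <- data.frame(id_x = names(seqs5)[prs[, 1]],
                      id_y = names(seqs5)[prs[, 2]],
                      stringsAsFactors = FALSE)
  }
  sat <- !is.na(p) & p >= 0.75
  if (any(sat)) {
    message(sum(sat), " saturated pairs (p >= 0.75) dropped")
  }
  keep <- !is.na(p) & p < 0.75
  ids <- ids[keep, , drop = FALSE]
  p <- p[keep]
  k <- jc_distance(p)
  out <- cbind(ids, data.frame(p = p, k = k, t = k / (2 * r)))
  rownames(out) <- NULL
  class(out) <- c("ltr_ages", "data.frame")
  out
}

#' Peak of an age distribution
#'
#' Kernel density mode of the `t` column of an [date_family()] result, in
#' years.
#'
#' @param ages an `ltr_ages` data.frame.
#' @param bw bandwidth passed to [stats::density()].
#' @return the age (years) at the density peak.
#' @export
age_peak <- function(ages, bw = "nrd0") {
  stopifnot(nrow(ages) >= 2)
  d <- density(ages$t, bw = bw)
  d$x[which.max(d$y)]
}
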