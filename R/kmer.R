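# Diagnostic k-mer discovery and subgenome assignment.
#
# Short k-mers whose abundance differs systematically between the members
# of each homoeologous pair are relics of progenitor-specific repeat
# activity; their per-scaffold counts drive a hierarchical clustering of
# scaffolds into the two parental subgenomes, and their windowed densities
# expose homoeologous exchange.

#' k-mer analysis configuration
#'
#' @param k k-mer length (odd, between 5 and 13; 13 by default so a k-mer
#'   is long enough to be repeat-diagnostic yet countable in a flat table).
#' @param min_total_count a k-mer must occur at least this often in the
#'   whole assembly to be considered (high-abundance filter).
#' @param min_fold minimum abundance fold-change between the members of a
#'   homoeologous pair, required of both the raw and the
#'   length-standardized counts.
#' @param canonical merge each k-mer with its reverse complement under the
#'   lexicographic minimum (default; scaffold strand is arbitrary).
#' @param window window size in bp for density tracks.
#' @return list of class `kmer_config`.
#' @export
kmer_config <- function(k = 13, min_total_count = 100, min_fold = 3,
                        canonical = TRUE, window = 1e6) {
  stopifnot(k >= 5, k <= 13, k %% 2 == 1, min_fold > 1,
            min_total_count >= 1, window > 0)
  structure(list(k = as.integer(k), min_total_count = min_total_count,
                 min_fold = min_fold, canonical = isTRUE(canonical),
                 window = window), class = "kmer_config")
}

#' Count high-abundance k-mers per scaffold
#'
#' Exact sliding counts; windows containing N (or any non-ACGT letter)
#' contribute nothing. In canonical mode a k-mer and its reverse
#' complement are merged under the lexicographic minimum. Only k-mers
#' whose genome-wide total reaches `min_total_count` are returned.
#'
#' @param genome a [genome_set()].
#' @param cfg a [kmer_config()].
#' @return list of class `kmer_counts`: `kmers` (character), `counts`
#'   (integer matrix, k-mers x scaffolds), `lengths` (scaffold lengths),
#'   `config`.
#' @export
count_kmers <- function(genome, cfg = kmer_config()) {
  stopifnot(inherits(cfg, "kmer_config"))
  lens <- scaffold_lengths(genome)
  short <- lens < cfg$k
  if (any(short)) {
    warning("scaffolds shorter than k skipped: ",
            paste(names(genome)[short], collapse = ", "))
    genome <- genome[!short]
    lens <- lens[!short]
  }
  if (length(genome) == 0) stop("no scaffold is at least k bp long")
  res <- .count_kmers_cpp(as.character(genome), cfg$k, cfg$canonical,
                          cfg$min_total_count)
  counts <- res$counts
  dimnames(counts) <- list(res$kmer, names(genome))
  structure(list(kmers = res$kmer, counts = counts, lengths = lens,
                 config = cfg), class = "kmer_counts")
}

std_per_mb <- function(counts, lengths) {
  sweep(counts, 2, as.numeric(lengths[colnames(counts)]) / 1e6, "/")
}

fold_pass <- function(num, den, min_fold) {
  # fold >= min_fold with a zero denominator counting as infinite fold;
  # 0/0 never passes.
  num > 0 & num >= min_fold * den
}

two_cluster <- function(std_mat) {
  d <- dist(t(std_mat), method = "euclidean")
  tree <- hclust(d, method = "complete")
  list(cluster = cutree(tree, k = 2), tree = tree, dist = d)
}

check_pairs_split <- function(cl, pairs) {
  bad <- pairs[cl[pairs$scaffold_x] == cl[pairs$scaffold_y], , drop = FALSE]
  if (nrow(bad) > 0) {
    stop("homoeologous pairs not separated by the 2-cluster cut: ",
         paste(paste(bad$scaffold_x, bad$scaffold_y, sep = "/"),
               collapse = ", "))
  }
}

#' Select diagnostic k-mers from homoeologous pair contrasts
#'
#' A k-mer is diagnostic for a pair when its abundance fold-change between
#' the two members reaches `min_fold` both on raw counts and on counts
#' standardized per Mb of scaffold, in the same direction. Sides are then
#' oriented across pairs by a provisional 2-cluster cut of the scaffolds,
#' each k-mer is assigned to the side it favours in the majority of pairs
#' where it is diagnostic (conflicting k-mers without a majority are
#' dropped), and the side holding more preferred k-mers is labelled A.
#'
#' @param counts a [count_kmers()] result.
#' @param pairs data.frame from [pair_homoeologs()].
#' @param cfg the [kmer_config()].
#' @return list of class `diagnostic_kmers`: `a_preferred`, `b_preferred`
#'   (character vectors), `counts` (matrix restricted to diagnostic
#'   k-mers), `lengths`, `config`.
#' @export
select_diagnostic_kmers <- function(counts, pairs, cfg = counts$config) {
  stopifnot(inherits(counts, "kmer_counts"), nrow(pairs) >= 1)
  m <- counts$counts
  s <- std_per_mb(m, counts$lengths)
  np <- nrow(pairs)

  # direction per k-mer and pair: +1 toward scaffold_x, -1 toward
  # scaffold_y, 0 not diagnostic in this pair
  dir <- matrix(0L, nrow(m), np)
  for (p in seq_len(np)) {
    x <- pairs$scaffold_x[p]; y <- pairs$scaffold_y[p]
    to_x <- fold_pass(m[, x], m[, y], cfg$min_fold) &
      fold_pass(s[, x], s[, y], cfg$min_fold)
    to_y <- fold_pass(m[, y], m[, x], cfg$min_fold) &
      fold_pass(s[, y], s[, x], cfg$min_fold)
    dir[to_x, p] <- 1L
    dir[to_y, p] <- -1L
  }
  cand <- rowSums(dir != 0L) > 0
  if (!any(cand)) stop("no diagnostic k-mers found; clustering impossible")

  cl <- two_cluster(s[cand, , drop = FALSE])$cluster
  check_pairs_split(cl, pairs)

  # votes toward cluster 1 vs cluster 2
  side_x <- cl[pairs$scaffold_x]  # cluster of each pair's x member
  v1 <- integer(nrow(m)); v2 <- integer(nrow(m))
  for (p in seq_len(np)) {
    tox <- dir[, p] == 1L; toy <- dir[, p] == -1L
    if (side_x[p] == 1) {
      v1 <- v1 + tox; v2 <- v2 + toy
    } else {
      v2 <- v2 + tox; v1 <- v1 + toy
    }
  }
  pref1 <- cand & v1 > v2
  pref2 <- cand & v2 > v1
  dropped <- cand & v1 == v2
  if (any(dropped)) {
    message(sum(dropped), " k-mers diagnostic in conflicting directions dropped")
  }
  if (!any(pref1) && !any(pref2)) {
    stop("no consistently oriented diagnostic k-mers; clustering impossible")
  }
  # A = the side with more preferred k-mers
  if (sum(pref1) >= sum(pref2)) {
    a_sel <- pref1; b_sel <- pref2
  } else {
    a_sel <- pref2; b_sel <- pref1
  }
  keep <- a_sel | b_sel
  structure(list(a_preferred = rownames(m)[a_sel],
                 b_preferred = rownames(m)[b_sel],
                 counts = m[keep, , drop = FALSE],
                 lengths = counts$lengths, config = cfg),
            class = "diagnostic_kmers")
}

#' Cluster scaffolds into subgenomes on diagnostic k-mer counts
#'
#' Agglomerative clustering (Euclidean distance on per-Mb standardized
#' diagnostic counts, complete linkage), tree cut at two clusters. The
#' cluster enriched for the larger (A-preferred) k-mer set is labelled A.
#' It is an error for any homoeologous pair to fall entirely in one
#' cluster.
#'
#' @param diag a [select_diagnostic_kmers()] result.
#' @param pairs data.frame from [pair_homoeologs()].
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list of class `subgenome_assignment`: `assignment` (named
#'   vector scaffold -> "A"/"B"), `tree` (hclust), `dist`.
#' @export
cluster_subgenomes <- function(diag, pairs, linkage = "complete") {
  stopifnot(inherits(diag, "diagnostic_kmers"), nrow(pairs) >= 2)
  if (nrow(diag$counts) == 0 || all(diag$counts == 0)) {
    stop("diagnostic count matrix is empty or all zeros")
  }
  s <- std_per_mb(diag$counts, diag$lengths)
  d <- dist(t(s), method = "euclidean")
  tree <- hclust(d, method = linkage)
  cl <- cutree(tree, k = 2)
  check_pairs_split(cl, pairs)

  # which cluster do the A-preferred k-mers point to?
  in1 <- names(cl)[cl == 1]; in2 <- names(cl)[cl == 2]
  mass <- function(set, cols) {
    if (length(set) == 0 || length(cols) == 0) return(0)
    mean(s[set, cols, drop = FALSE])
  }
  a_to_1 <- mass(diag$a_preferred, in1) > mass(diag$a_preferred, in2)
  lab <- if (a_to_1) c("A", "B") else c("B", "A")
  assignment <- setNames(lab[cl], names(cl))
  structure(list(assignment = assignment, tree = tree, dist = d),
            class = "subgenome_assignment")
}

#' Windowed density track of A- and B-preferred k-mers
#'
#' Exact occurrence counts of each diagnostic set per fixed window along
#' one scaffold; the final partial window keeps its true (shorter) span.
#'
#' @param genome a [genome_set()].
#' @param scaffold scaffold name.
#' @param diag a [select_diagnostic_kmers()] result.
#' @param window window size in bp (defaults to the config value).
#' @return data.frame `scaffold, start, end, a_count, b_count`.
#' @export
density_track <- function(genome, scaffold, diag, window = diag$config$window) {
  stopifnot(inherits(diag, "diagnostic_kmers"),
            scaffold %in% names(genome))
  seq <- unclass(genome)[[scaffold]]
  hits <- .window_hits_cpp(seq, diag$config$k, diag$config$canonical,
                           diag$a_preferred, diag$b_preferred, window)
  n <- nchar(seq)
  nwin <- nrow(hits)
  starts <- (seq_len(nwin) - 1) * window
  data.frame(scaffold = scaffold, start = starts,
             end = pmin(starts + window, n),
             a_count = hits[, 1], b_count = hits[, 2],
             stringsAsFactors = FALSE)
}

#' Density tracks for every scaffold
#' @inheritParams density_track
#' @return named list of [density_track()] data.frames.
#' @export
density_tracks <- function(genome, diag, window = diag$config$window) {
  setNames(lapply(names(genome), function(s)
    density_track(genome, s, diag, window)), names(genome))
}
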