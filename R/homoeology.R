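# Homoeologous scaffold pairing from whole-genome self-alignments, and a
# collinearity scanner (best-reciprocal anchors chained by dynamic
# programming) used to build ortholog tables against a reference diploid.

union_cov <- function(starts, ends, len) {
  if (length(starts) == 0) return(0)
  r <- IRanges::reduce(IRanges::IRanges(start = starts + 1, end = ends))
  sum(IRanges::width(r)) / len
}

#' Pair homoeologous scaffolds from a self-alignment
#'
#' For every ordered scaffold pair, coverage is the union of aligned
#' intervals on that scaffold divided by its length. Pairs where both
#' coverages exceed `min_cov` ("more than 50% matching across both
#' scaffolds") are candidates; a greedy pass by descending
#' `min(cov_x, cov_y)` enforces that each scaffold ends up in at most one
#' pair.
#'
#' @param paf PAF data.frame (see [read_paf()]) with self-hits
#'   (query == target) tolerated; they are removed.
#' @param min_cov coverage threshold, both sides must exceed it.
#' @return data.frame with `scaffold_x, scaffold_y, cov_x, cov_y`, one row
#'   per accepted pair.
#' @export
pair_homoeologs <- function(paf, min_cov = 0.5) {
  empty <- data.frame(scaffold_x = character(0), scaffold_y = character(0),
                      cov_x = numeric(0), cov_y = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(paf) || nrow(paf) == 0) {
    warning("empty PAF: no homoeologous pairs")
    return(empty)
  }
  paf <- paf[paf$query != paf$target, , drop = FALSE]
  if (nrow(paf) == 0) {
    warning("only self-hits in PAF: no homoeologous pairs")
    return(empty)
  }
  lens <- c(setNames(paf$qlen, paf$query), setNames(paf$tlen, paf$target))
  lens <- lens[!duplicated(names(lens))]

  a <- pmin(paf$query, paf$target)
  b <- pmax(paf$query, paf$target)
  key <- paste(a, b, sep = "\r")
  rows <- lapply(split(seq_len(nrow(paf)), key), function(idx) {
    sub <- paf[idx, ]
    x <- min(sub$query[1], sub$target[1]); y <- max(sub$query[1], sub$target[1])
    xs <- c(sub$qstart[sub$query == x], sub$tstart[sub$target == x])
    xe <- c(sub$qend[sub$query == x], sub$tend[sub$target == x])
    ys <- c(sub$qstart[sub$query == y], sub$tstart[sub$target == y])
    ye <- c(sub$qend[sub$query == y], sub$tend[sub$target == y])
    data.frame(scaffold_x = x, scaffold_y = y,
               cov_x = union_cov(xs, xe, lens[[x]]),
               cov_y = union_cov(ys, ye, lens[[y]]),
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, rows)
  cand <- cand[cand$cov_x > min_cov & cand$cov_y > min_cov, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(-pmin(cand$cov_x, cand$cov_y),
                     cand$scaffold_x, cand$scaffold_y), , drop = FALSE]
  used <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$scaffold_x[i] %in% used) && !(cand$scaffold_y[i] %in% used)) {
      keep[i] <- TRUE
      used <- c(used, cand$scaffold_x[i], cand$scaffold_y[i])
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

best_reciprocal <- function(hits) {
  pick <- function(df, by, other) {
    o <- order(df[[by]], -df$score, df[[other]])
    df <- df[o, ]
    df[!duplicated(df[[by]]), , drop = FALSE]
  }
  bx <- pick(hits, "gene_x", "gene_y")
  by <- pick(hits, "gene_y", "gene_x")
  kx <- paste(bx$gene_x, bx$gene_y, sep = "\r")
  ky <- paste(by$gene_x, by$gene_y, sep = "\r")
  bx[kx %in% ky, , drop = FALSE]
}

chain_dp <- function(rx, ry, max_gap) {
  # longest chain with strictly increasing rx and ry, both gaps <= max_gap
  n <- length(rx)
  o <- order(rx, ry)
  rx <- rx[o]; ry <- ry[o]
  L <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (rx[i] > rx[j] && ry[i] > ry[j] &&
          rx[i] - rx[j] <= max_gap && ry[i] - ry[j] <= max_gap &&
          L[j] + 1L > L[i]) {
        L[i] <- L[j] + 1L
        prev[i] <- j
      }
    }
  }
  if (n == 0) return(list(len = 0L, members = integer(0)))
  best <- which.max(L)
  chain <- integer(0)
  i <- best
  while (i > 0) { chain <- c(i, chain); i <- prev[i] }
  list(len = L[best], members = o[chain])
}

#' Chain best-reciprocal anchors into collinear blocks
#'
#' Hits are first reduced to best reciprocal pairs (top score per gene on
#' each axis, ties broken by lexicographic partner id). Blocks are then
#' longest monotone chains over the rank pairs, allowing rank gaps of at
#' most `max_gap` on both axes; both orientations are searched, blocks are
#' extracted greedily (longest first) and each anchor belongs to at most
#' one block. Chains shorter than `min_block` are discarded.
#'
#' @param hits data.frame with columns `gene_x, rank_x, gene_y, rank_y,
#'   score`.
#' @param max_gap maximum rank gap between consecutive anchors.
#' @param min_block minimum anchors per block.
#' @return list of blocks; each block is a list with `anchors` (data.frame
#'   `gene_x, gene_y, rank_x, rank_y`), `orientation` (`"+"`/`"-"`) and
#'   `length`.
#' @export
chain_anchors <- function(hits, max_gap = 25, min_block = 5) {
  if (is.null(hits) || nrow(hits) == 0) return(list())
  anc <- best_reciprocal(hits)
  blocks <- list()
  remaining <- anc
  while (nrow(remaining) >= min_block) {
    fwd <- chain_dp(remaining$rank_x, remaining$rank_y, max_gap)
    rev <- chain_dp(remaining$rank_x, -remaining$rank_y, max_gap)
    if (max(fwd$len, rev$len) < min_block) break
    use_fwd <- fwd$len >= rev$len
    ch <- if (use_fwd) fwd else rev
    rows <- remaining[ch$members, , drop = FALSE]
    blocks[[length(blocks) + 1]] <- list(
      anchors = data.frame(gene_x = rows$gene_x, gene_y = rows$gene_y,
                           rank_x = rows$rank_x, rank_y = rows$rank_y,
                           stringsAsFactors = FALSE),
      orientation = if (use_fwd) "+" else "-",
      length = ch$len)
    remaining <- remaining[-ch$members, , drop = FALSE]
  }
  blocks
}

#' Build the reference-to-subgenome ortholog table from collinear blocks
#'
#' Each reference (x-side) gene is mapped to at most one copy per
#' subgenome. When a reference gene is anchored more than once within one
#' subgenome, the anchor from the longer block wins (a message reports
#' genes seen in more than two blocks of one subgenome).
#'
#' @param blocks output of [chain_anchors()] computed against the
#'   reference diploid (reference genes on the x axis).
#' @param gene_subgenome named character vector mapping y-side gene ids to
#'   `"A"` or `"B"` (derived from the scaffold assignment).
#' @return data.frame `ref_gene, gene_a, gene_b` with `NA` for missing
#'   copies.
#' @export
ortholog_table <- function(blocks, gene_subgenome) {
  if (length(blocks) == 0) {
    return(data.frame(ref_gene = character(0), gene_a = character(0),
                      gene_b = character(0), stringsAsFactors = FALSE))
  }
  rows <- do.call(rbind, lapply(seq_along(blocks), function(b) {
    a <- blocks[[b]]$anchors
    data.frame(ref_gene = a$gene_x, gene_y = a$gene_y,
               block_len = blocks[[b]]$length, stringsAsFactors = FALSE)
  }))
  rows$side <- unname(gene_subgenome[rows$gene_y])
  rows <- rows[!is.na(rows$side), , drop = FALSE]
  over <- aggregate(block_len ~ ref_gene + side, rows, length)
  noisy <- over$ref_gene[over$block_len > 2]
  if (length(noisy)) {
    message(length(unique(noisy)),
            " reference genes hit in >2 blocks of one subgenome; longest kept")
  }
  rows <- rows[order(rows$ref_gene, rows$side, -rows$block_len), ]
  rows <- rows[!duplicated(rows[c("ref_gene", "side")]), , drop = FALSE]
  refs <- sort(unique(rows$ref_gene))
  a <- rows[rows$side == "A", ]; b <- rows[rows$side == "B", ]
  data.frame(ref_gene = refs,
             gene_a = a$gene_y[match(refs, a$ref_gene)],
             gene_b = b$gene_y[match(refs, b$ref_gene)],
             stringsAsFactors = FALSE)
}
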