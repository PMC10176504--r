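# Biased fractionation accounting and exact tests.
#
# Ancestral (preduplication) genes are reference-diploid genes with at
# least one surviving copy across the subgenomes. Retention per subgenome
# is the fraction of ancestral genes with a copy in that subgenome; the
# bias test asks whether single-copy survival is split evenly between the
# subgenomes. GO over-representation uses per-term one-sided Fisher tests
# against the ancestral universe.

#' Construct a retention table from counts
#'
#' Percentages are kept at full precision; rounding happens only in the
#' print method. Count inconsistencies (`retained_a + retained_b -
#' retained_both != n_ancestral`, as happens in some published
#' accountings where a small residue of genes escapes both categories)
#' give a warning, not an error.
#'
#' @param n_ancestral ancestral (preduplication) gene count.
#' @param retained_a,retained_b genes with a copy in subgenome A / B.
#' @param retained_both genes with copies in both.
#' @return list of class `retention_table` with the counts, the derived
#'   single-copy counts and `pct_a, pct_b, pct_both`.
#' @export
retention_table <- function(n_ancestral, retained_a, retained_b,
                            retained_both) {
  stopifnot(n_ancestral > 0, retained_a >= 0, retained_b >= 0,
            retained_both >= 0,
            retained_both <= min(retained_a, retained_b),
            retained_a <= n_ancestral, retained_b <= n_ancestral)
  if (retained_a + retained_b - retained_both != n_ancestral) {
    warning("retained_a + retained_b - retained_both (",
            retained_a + retained_b - retained_both,
            ") differs from n_ancestral (", n_ancestral, ")")
  }
  structure(list(n_ancestral = n_ancestral,
                 retained_a = retained_a, retained_b = retained_b,
                 retained_both = retained_both,
                 single_a = retained_a - retained_both,
                 single_b = retained_b - retained_both,
                 pct_a = 100 * retained_a / n_ancestral,
                 pct_b = 100 * retained_b / n_ancestral,
                 pct_both = 100 * retained_both / n_ancestral),
            class = "retention_table")
}

#' @export
print.retention_table <- function(x, ...) {
  cat("ancestral genes:", x$n_ancestral, "\n")
  cat(sprintf("retained in A: %d (%.0f%%)\n", x$retained_a, x$pct_a))
  cat(sprintf("retained in B: %d (%.0f%%)\n", x$retained_b, x$pct_b))
  cat(sprintf("retained in both: %d (%.0f%%)\n", x$retained_both, x$pct_both))
  invisible(x)
}

#' Tally retention from an ortholog table
#'
#' @param orth data.frame with columns `ref_gene` and either `gene_a` /
#'   `gene_b` (ids or `NA`) or logical `in_a` / `in_b`. Rows with no copy
#'   in either subgenome are not ancestral and are ignored; duplicate
#'   `ref_gene` ids are an error.
#' @return a [retention_table()].
#' @export
tally_retention <- function(orth) {
  if (is.null(orth) || nrow(orth) == 0) stop("empty ortholog table")
  if (anyDuplicated(orth$ref_gene)) stop("duplicate ref_gene ids")
  in_a <- if (!is.null(orth$in_a)) as.logical(orth$in_a) else !is.na(orth$gene_a)
  in_b <- if (!is.null(orth$in_b)) as.logical(orth$in_b) else !is.na(orth$gene_b)
  anc <- in_a | in_b
  if (!any(anc)) stop("no ancestral genes (no gene has any retained copy)")
  suppressWarnings(
    retention_table(sum(anc), sum(in_a), sum(in_b), sum(in_a & in_b)))
}

#' The 2x2 table for the retention-bias test
#'
#' Two constructions of the contingency table behind the question "is
#' gene loss split evenly between the subgenomes?":
#' `single_copy` (default) contrasts genes surviving only in A vs only in
#' B against the rest of the ancestral set — the contrast on the
#' asymmetric outcomes of fractionation; `retained_lost` contrasts
#' retained vs lost per subgenome.
#'
#' @param rt a [retention_table()].
#' @param construction which 2x2 to build.
#' @return 2x2 integer matrix (rows: subgenomes A and B).
#' @export
retention_bias_table <- function(rt, construction = c("single_copy",
                                                      "retained_lost")) {
  construction <- match.arg(construction)
  n <- rt$n_ancestral
  if (construction == "single_copy") {
    matrix(c(rt$single_a, n - rt$single_a,
             rt$single_b, n - rt$single_b), 2, 2, byrow = TRUE,
           dimnames = list(c("A", "B"), c("single", "rest")))
  } else {
    matrix(c(rt$retained_a, n - rt$retained_a,
             rt$retained_b, n - rt$retained_b), 2, 2, byrow = TRUE,
           dimnames = list(c("A", "B"), c("retained", "lost")))
  }
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with fixed margins, computed in log space
#' (log-gamma) so arbitrarily large counts are safe. The two-sided
#' p-value is the sum of point probabilities no larger than the observed
#' one (within a relative tolerance of 1e-7, the convention of the usual
#' statistical environments); `"greater"` is the one-sided
#' over-representation tail on the top-left cell.
#'
#' @param m 2x2 matrix of non-negative integer counts.
#' @param sided `"two"` or `"greater"`.
#' @return the p-value.
#' @export
fisher_exact_2x2 <- function(m, sided = c("two", "greater")) {
  sided <- match.arg(sided)
  stopifnot(all(dim(m) == c(2, 2)), all(m >= 0), all(m == round(m)))
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  m1 <- a + b; m2 <- c_ + d; n1 <- a + c_
  N <- m1 + m2
  if (m1 == 0 || m2 == 0 || n1 == 0 || n1 == N) return(1)
  lo <- max(0, n1 - m2); hi <- min(n1, m1)
  x <- lo:hi
  logp <- lchoose(m1, x) + lchoose(m2, n1 - x) - lchoose(N, n1)
  if (sided == "greater") {
    return(min(1, sum(exp(logp[x >= a]))))
  }
  obs <- logp[x == a]
  min(1, sum(exp(logp[logp <= obs + log(1 + 1e-7)])))
}

#' Expected foreground count for a GO term
#'
#' @param annotated genes in the universe carrying the term.
#' @param n_foreground,n_universe foreground and universe sizes.
#' @return the expected count `annotated * n_foreground / n_universe`.
#' @export
go_expected <- function(annotated, n_foreground, n_universe) {
  annotated * n_foreground / n_universe
}

#' GO term over-representation
#'
#' One-sided Fisher test per term on the table
#' `[[significant, annotated - significant],
#'    [|fg| - significant, |universe| - annotated - |fg| + significant]]`.
#' The expected count is `annotated * |fg| / |universe|`. No
#' multiple-testing correction is applied by default (raw Fisher
#' p-values); `adjust = TRUE` appends a Benjamini-Hochberg column.
#'
#' @param foreground foreground gene ids (must be a subset of the
#'   universe).
#' @param universe universe gene ids.
#' @param term_map data.frame with columns `gene, term`, or a named list
#'   of character term vectors per gene. Ancestor-term propagation, if
#'   wanted, must already be applied.
#' @param adjust append a BH-adjusted column.
#' @return data.frame sorted by p: `term, annotated, significant,
#'   expected, p` (and `p_adj`).
#' @export
go_enrichment <- function(foreground, universe, term_map, adjust = FALSE) {
  foreground <- unique(foreground)
  universe <- unique(universe)
  if (!all(foreground %in% universe)) {
    stop("foreground genes must be a subset of the universe")
  }
  if (is.list(term_map) && !is.data.frame(term_map)) {
    term_map <- data.frame(
      gene = rep(names(term_map), lengths(term_map)),
      term = unlist(term_map, use.names = FALSE), stringsAsFactors = FALSE)
  }
  term_map <- term_map[term_map$gene %in% universe, , drop = FALSE]
  n_fg <- length(foreground)
  n_u <- length(universe)
  terms <- unique(term_map$term)
  rows <- lapply(terms, function(tm) {
    genes <- unique(term_map$gene[term_map$term == tm])
    annotated <- length(genes)
    significant <- sum(genes %in% foreground)
    p <- fisher_exact_2x2(matrix(c(significant, annotated - significant,
                                   n_fg - significant,
                                   n_u - annotated - n_fg + significant),
                                 2, 2, byrow = TRUE), sided = "greater")
    data.frame(term = tm, annotated = annotated, significant = significant,
               expected = go_expected(annotated, n_fg, n_u), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$term), , drop = FALSE]
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Exclude genes in given regions from an ortholog table
#'
#' Re-runs of the retention accounting without genes in ambiguous
#' regions: copies of a reference gene falling inside any of the regions
#' are treated as absent.
#'
#' @param orth ortholog table (`ref_gene, gene_a, gene_b`).
#' @param genes a [feature_table()] of gene features locating the copies.
#' @param regions a [feature_table()] (or BED-like data.frame) of regions
#'   to exclude.
#' @return the filtered ortholog table.
#' @export
exclude_regions <- function(orth, genes, regions) {
  if (is.null(regions) || nrow(regions) == 0) return(orth)
  hit <- rep(FALSE, nrow(genes))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (genes$scaffold == regions$scaffold[i] &
                    genes$end > regions$start[i] &
                    genes$start < regions$end[i])
  }
  bad <- genes$id[hit]
  orth$gene_a[orth$gene_a %in% bad] <- NA
  orth$gene_b[orth$gene_b %in% bad] <- NA
  orth
}
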