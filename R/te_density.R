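# TE density in fixed windows flanking genes, and rank-based group
# comparisons. Density is TE-occupied bp (union of TE intervals) within
# the window divided by the window size, so it is bounded by 1 and
# invariant to TE fragmentation.

#' TE density in gene-flanking windows
#'
#' For each gene, the upstream window is the `window` bp before its start
#' and the downstream window the `window` bp after its end; when
#' `orientation_aware`, genes on the minus strand have the two swapped.
#' Occupancy is computed on the union of TE intervals intersected with
#' the window. Windows truncated at scaffold ends are divided by the
#' truncated length and flagged (`truncation = "renormalize"`), or their
#' density set to `NA` (`"drop"`).
#'
#' @param genes,tes [feature_table()]s on shared scaffolds.
#' @param scaffold_lengths named vector of scaffold lengths.
#' @param window flank size in bp.
#' @param orientation_aware flip up/downstream for minus-strand genes.
#' @param truncation behaviour at scaffold ends.
#' @return data.frame: `gene, scaffold, upstream_density,
#'   downstream_density, upstream_truncated, downstream_truncated`.
#'   Genes on scaffolds absent from `scaffold_lengths` are skipped with a
#'   warning.
#' @export
flank_density <- function(genes, tes, scaffold_lengths, window = 5000,
                          orientation_aware = TRUE,
                          truncation = c("renormalize", "drop")) {
  truncation <- match.arg(truncation)
  stopifnot(window > 0)
  known <- genes$scaffold %in% names(scaffold_lengths)
  if (any(!known)) {
    warning(sum(!known), " genes on unknown scaffolds skipped")
    genes <- genes[known, , drop = FALSE]
  }
  te_by_scaf <- lapply(split(tes, tes$scaffold), function(df)
    IRanges::reduce(IRanges::IRanges(start = df$start + 1, end = df$end)))

  occupancy <- function(scaf, s, e) {
    # occupied bp of [s, e) 0-based half-open
    if (e <= s) return(0)
    r <- te_by_scaf[[scaf]]
    if (is.null(r)) return(0)
    q <- IRanges::IRanges(start = s + 1, end = e)
    sum(IRanges::width(IRanges::intersect(r, q)))
  }

  n <- nrow(genes)
  up_d <- down_d <- numeric(n)
  up_tr <- down_tr <- logical(n)
  for (i in seq_len(n)) {
    len <- as.numeric(scaffold_lengths[[genes$scaffold[i]]])
    before <- c(max(genes$start[i] - window, 0), genes$start[i])
    after <- c(genes$end[i], min(genes$end[i] + window, len))
    flip <- orientation_aware && genes$strand[i] == "-"
    up <- if (flip) after else before
    down <- if (flip) before else after
    for (side in c("up", "down")) {
      w <- if (side == "up") up else down
      span <- w[2] - w[1]
      truncated <- span < window
      dens <- if (span <= 0) {
        NA_real_
      } else if (truncated && truncation == "drop") {
        NA_real_
      } else {
        occupancy(genes$scaffold[i], w[1], w[2]) / span
      }
      if (side == "up") { up_d[i] <- dens; up_tr[i] <- truncated }
      else { down_d[i] <- dens; down_tr[i] <- truncated }
    }
  }
  data.frame(gene = genes$id, scaffold = genes$scaffold,
             upstream_density = up_d, downstream_density = down_d,
             upstream_truncated = up_tr, downstream_truncated = down_tr,
             stringsAsFactors = FALSE)
}

#' Mann-Whitney U test
#'
#' Exact enumeration of rank assignments when the combined sample size is
#' at most 12 and there are no ties; otherwise the normal approximation
#' with tie-corrected variance and continuity correction. The two-sided
#' exact p is the probability of a U at least as far from its null mean
#' as observed. Identical samples give p = 1.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list with `U` (for the first sample), `p` (two-sided) and the
#'   `mode` used.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(length(x) > 0, length(y) > 0)
  nx <- length(x); ny <- length(y)
  all_v <- c(x, y)
  rk <- rank(all_v)
  U <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- any(duplicated(all_v))
  if (length(unique(all_v)) == 1) {
    return(list(U = U, p = 1, mode = "degenerate"))
  }
  if (mode == "auto") {
    mode <- if (nx + ny <= 12 && !has_ties) "exact" else "normal"
  }
  mu <- nx * ny / 2
  if (mode == "exact") {
    if (has_ties) stop("exact mode requires tie-free samples")
    combos <- combn(nx + ny, nx)
    us <- apply(combos, 2, function(idx) sum(sort(rk)[idx]) - nx * (nx + 1) / 2)
    # ranks are 1..N when tie-free; U over all C(N, nx) assignments
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
  } else {
    n <- nx + ny
    tie_tab <- table(all_v)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1, mode = "degenerate"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(U = U, p = p, mode = mode)
}

#' Compare flank TE densities between gene groups
#'
#' Per-group mean and standard error plus a Mann-Whitney U test, for one
#' flank side, in the layout of a per-subgenome (or single-copy vs
#' duplicated) density summary.
#'
#' @param records a [flank_density()] result.
#' @param groups named character vector gene id -> group label (exactly
#'   two distinct labels among the matched genes).
#' @param side `"upstream"` or `"downstream"`.
#' @return data.frame with one row per group (`group, n, mean, se`) and
#'   attributes `U` and `p`.
#' @export
compare_groups <- function(records, groups,
                           side = c("upstream", "downstream")) {
  side <- match.arg(side)
  col <- paste0(side, "_density")
  g <- groups[records$gene]
  keep <- !is.na(g) & !is.na(records[[col]])
  v <- records[[col]][keep]
  g <- g[keep]
  labs <- sort(unique(g))
  if (length(labs) < 2) stop("need two groups to compare")
  if (length(labs) > 2) stop("more than two groups: ",
                             paste(labs, collapse = ", "))
  x <- v[g == labs[1]]; y <- v[g == labs[2]]
  mw <- mann_whitney_u(x, y)
  out <- data.frame(group = labs,
                    n = c(length(x), length(y)),
                    mean = c(mean(x), mean(y)),
                    se = c(stats::sd(x) / sqrt(length(x)),
                           stats::sd(y) / sqrt(length(y))),
                    stringsAsFactors = FALSE)
  attr(out, "U") <- mw$U
  attr(out, "p") <- mw$p
  out
}
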