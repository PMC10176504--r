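# Synthetic allotetraploid genome with known truth.
#
# The model: one ancestor per homoeologous chromosome pair; two parental
# (progenitor) genomes derived from the ancestor by independent
# Jukes-Cantor substitution at density r*T per branch; subgenome-specific
# LTR retrotransposon bursts (each family a consensus, copies inserted at
# ages drawn around the burst peak, the two terminal repeats of each copy
# mutated independently at density r*age); hybridization by concatenation;
# biased gene loss with per-subgenome retention probabilities; and a
# planted homoeologous translocation. Everything downstream is measured
# against the truth recorded here.

INT2BASE <- c("A", "C", "G", "T")

int_to_dna <- function(v) intToUtf8(c(65L, 67L, 71L, 84L)[v])

dna_to_int <- function(s) {
  lut <- integer(128)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt(s)]
}

# Jukes-Cantor substitution at expected density d substitutions/site,
# applied through the exact marginal of the process: each site changes
# with probability 3/4 (1 - exp(-4d/3)), uniformly to one of the other
# three bases.
jc_mutate_int <- function(v, d) {
  if (d <= 0) return(v)
  p_change <- 0.75 * (1 - exp(-4 * d / 3))
  idx <- which(runif(length(v)) < p_change)
  if (length(idx)) {
    v[idx] <- ((v[idx] - 1L + sample.int(3L, length(idx), replace = TRUE)) %% 4L) + 1L
  }
  v
}

#' Apply Jukes-Cantor substitutions to a DNA string
#'
#' Each site is substituted with the exact marginal probability
#' `3/4 (1 - exp(-4d/3))` of a Jukes-Cantor process run for expected
#' density `d` substitutions per site; substituted sites change to one of
#' the other three bases uniformly. No indels are introduced.
#'
#' @param seq an ACGT character string.
#' @param d expected substitutions per site.
#' @return the mutated string.
#' @export
jc_mutate <- function(seq, d) {
  int_to_dna(jc_mutate_int(dna_to_int(seq), d))
}

#' Simulation configuration
#'
#' Defaults describe the desk-scale study system: 10 homoeologous pairs of
#' 2-Mb chromosomes, progenitors diverged 5.8 million years at a
#' substitution rate of 1.3e-8 per site per year, 8 LTR subfamilies
#' bursting in subgenome A against 1 in subgenome B with insertion ages
#' centred on 3.5 million years, gene retention probabilities 0.85 (A) and
#' 0.79 (B), and one planted 200-kb homoeologous translocation.
#'
#' @param n_pairs homoeologous chromosome pairs.
#' @param chrom_len chromosome length, bp.
#' @param n_genes_per_chrom gene templates per chromosome.
#' @param gene_len gene template length, bp.
#' @param divergence_time progenitor divergence, years.
#' @param substitution_rate substitutions per site per year.
#' @param burst_families_a,burst_families_b subgenome-specific LTR
#'   subfamilies per progenitor.
#' @param copies_per_family_a,copies_per_family_b element copies inserted
#'   per subfamily.
#' @param burst_age,burst_age_sd burst peak and spread, years; ages are
#'   truncated to (0, divergence_time).
#' @param ltr_len,internal_len terminal repeat and internal region length,
#'   bp.
#' @param retention_prob_a,retention_prob_b per-gene retention
#'   probabilities after hybridization.
#' @param exchange_spec data.frame with columns `pair`, `from` (`"A"` or
#'   `"B"`), `start`, `end` giving segments copied onto the homoeologous
#'   partner; `NULL` plants the default single 200-kb translocation from
#'   the B member of pair 1 at 1.0-1.2 Mb.
#' @param seed integer seed; equal seeds give byte-identical output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 10, chrom_len = 2e6,
                       n_genes_per_chrom = 100, gene_len = 1000,
                       divergence_time = 5.8e6, substitution_rate = 1.3e-8,
                       burst_families_a = 8, burst_families_b = 1,
                       copies_per_family_a = 250, copies_per_family_b = 2000,
                       burst_age = 3.5e6, burst_age_sd = 1e6,
                       ltr_len = 400, internal_len = 800,
                       retention_prob_a = 0.85, retention_prob_b = 0.79,
                       exchange_spec = NULL, seed = 1L) {
  if (is.null(exchange_spec)) {
    exchange_spec <- data.frame(pair = 1L, from = "B",
                                start = 1.0e6, end = 1.2e6)
  }
  cfg <- list(n_pairs = as.integer(n_pairs), chrom_len = as.integer(chrom_len),
              n_genes_per_chrom = as.integer(n_genes_per_chrom),
              gene_len = as.integer(gene_len),
              divergence_time = divergence_time,
              substitution_rate = substitution_rate,
              burst_families_a = as.integer(burst_families_a),
              burst_families_b = as.integer(burst_families_b),
              copies_per_family_a = as.integer(copies_per_family_a),
              copies_per_family_b = as.integer(copies_per_family_b),
              burst_age = burst_age, burst_age_sd = burst_age_sd,
              ltr_len = as.integer(ltr_len),
              internal_len = as.integer(internal_len),
              retention_prob_a = retention_prob_a,
              retention_prob_b = retention_prob_b,
              exchange_spec = exchange_spec, seed = as.integer(seed))
  stopifnot(cfg$n_pairs >= 1, cfg$chrom_len > 0, cfg$gene_len > 0,
            cfg$retention_prob_a >= 0, cfg$retention_prob_a <= 1,
            cfg$retention_prob_b >= 0, cfg$retention_prob_b <= 1,
            cfg$burst_age <= cfg$divergence_time,
            cfg$ltr_len > 0, cfg$internal_len >= 0)
  class(cfg) <- "sim_config"
  cfg
}

truncnorm_ages <- function(n, mean, sd, upper) {
  out <- numeric(0)
  guard <- 0
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x > 0 & x < upper])
    guard <- guard + 1
    if (guard > 1000) stop("cannot sample insertion ages in (0, upper)")
  }
  out[seq_len(n)]
}

# Draw insertion positions on one chromosome avoiding gene templates.
draw_positions <- function(n, chrom_len, gene_starts, gene_len) {
  if (n == 0) return(integer(0))
  gs <- sort(gene_starts)
  pos <- integer(0)
  for (try in seq_len(100)) {
    cand <- as.integer(floor(runif(n - length(pos), 1, chrom_len - 1)))
    idx <- findInterval(cand, gs)
    in_gene <- idx > 0 & cand < gs[pmax(idx, 1)] + gene_len
    in_gene[idx == 0] <- FALSE
    pos <- c(pos, cand[!in_gene])
    if (length(pos) >= n) return(pos[seq_len(n)])
  }
  stop("failed to place LTR insertions outside gene templates")
}

# Splice element sequences into a chromosome. `positions` are insertion
# points in the pre-insertion coordinate (element inserted before that
# base). Returns the new integer sequence plus the final start of each
# element and the cumulative-offset map needed to lift other coordinates.
splice_elements <- function(seq_int, positions, element_seqs) {
  o <- order(positions)
  positions <- positions[o]
  element_seqs <- element_seqs[o]
  lens <- vapply(element_seqs, length, integer(1))
  parts <- vector("list", 2 * length(positions) + 1)
  prev <- 0L
  for (i in seq_along(positions)) {
    parts[[2 * i - 1]] <- if (positions[i] > prev) seq_int[(prev + 1):positions[i]] else integer(0)
    parts[[2 * i]] <- element_seqs[[i]]
    prev <- positions[i]
  }
  parts[[2 * length(positions) + 1]] <-
    if (prev < length(seq_int)) seq_int[(prev + 1):length(seq_int)] else integer(0)
  offset_before <- c(0, cumsum(lens))[seq_along(positions)]
  list(seq = unlist(parts, use.names = FALSE),
       starts = positions + offset_before,  # 0-based final start of element
       positions = positions, lens = lens, order = o)
}

# Lift a 0-based coordinate from pre-insertion to post-insertion space.
lift_coord <- function(x, positions, lens) {
  if (length(positions) == 0) return(x)
  cum <- cumsum(lens)
  idx <- findInterval(x, positions)
  x + ifelse(idx > 0, cum[pmax(idx, 1)], 0)
}

#' Simulate the diploid progenitors of an allotetraploid
#'
#' Draws a uniform-ACGT ancestor per chromosome pair with planted gene
#' templates, derives each parent by independent Jukes-Cantor substitution
#' at density `r * T` per branch, and inserts subgenome-specific LTR
#' retrotransposon copies with recorded ages. Each element is
#' 5'LTR-internal-3'LTR; the two terminal repeats of a copy are mutated
#' independently at density `r * age`, which is exactly the divergence
#' signal the k/2r insertion clock assumes.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `sim_progenitors` with the ancestor and both
#'   parent genomes, gene coordinates in all three coordinate systems,
#'   the element table (family, age, spans of both terminal repeats) and
#'   the consensus sequences.
#' @export
simulate_progenitors <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_pairs <- cfg$n_pairs
  r <- cfg$substitution_rate
  d_branch <- r * cfg$divergence_time

  anc <- vector("list", n_pairs)
  genes <- vector("list", n_pairs)
  spacing <- cfg$chrom_len / cfg$n_genes_per_chrom
  for (i in seq_len(n_pairs)) {
    anc[[i]] <- sample.int(4L, cfg$chrom_len, replace = TRUE)
    base <- round((seq_len(cfg$n_genes_per_chrom) - 0.5) * spacing)
    jit <- round(runif(cfg$n_genes_per_chrom, -spacing / 4, spacing / 4))
    starts <- pmin(pmax(base + jit, 0), cfg$chrom_len - cfg$gene_len)
    genes[[i]] <- data.frame(
      gene = sprintf("g%02d_%03d", i, seq_len(cfg$n_genes_per_chrom)),
      pair = i, start_anc = starts, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)

  parents <- list(A = lapply(anc, jc_mutate_int, d = d_branch),
                  B = lapply(anc, jc_mutate_int, d = d_branch))

  fam_ids <- c(if (cfg$burst_families_a > 0)
                 sprintf("famA_%d", seq_len(cfg$burst_families_a)),
               if (cfg$burst_families_b > 0)
                 sprintf("famB_%d", seq_len(cfg$burst_families_b)))
  fam_side <- c(rep("A", cfg$burst_families_a), rep("B", cfg$burst_families_b))
  consensus <- lapply(fam_ids, function(f) {
    list(ltr = sample.int(4L, cfg$ltr_len, replace = TRUE),
         internal = sample.int(4L, cfg$internal_len, replace = TRUE))
  })
  names(consensus) <- fam_ids

  copies <- list()
  for (f in seq_along(fam_ids)) {
    side <- fam_side[f]
    n_cp <- if (side == "A") cfg$copies_per_family_a else cfg$copies_per_family_b
    if (n_cp == 0) next
    copies[[f]] <- data.frame(
      family = fam_ids[f], side = side,
      pair = sample.int(n_pairs, n_cp, replace = TRUE),
      age = truncnorm_ages(n_cp, cfg$burst_age, cfg$burst_age_sd,
                           cfg$divergence_time),
      stringsAsFactors = FALSE)
  }
  copies <- if (length(copies)) do.call(rbind, copies) else
    data.frame(family = character(0), side = character(0),
               pair = integer(0), age = numeric(0), stringsAsFactors = FALSE)
  copies$id <- if (nrow(copies) > 0)
    sprintf("ltr_%s_%05d", copies$side, seq_len(nrow(copies))) else character(0)

  el_len <- 2L * cfg$ltr_len + cfg$internal_len
  elements <- list()
  for (side in c("A", "B")) {
    for (i in seq_len(n_pairs)) {
      sel <- which(copies$side == side & copies$pair == i)
      if (length(sel) == 0) next
      gs <- genes$start_anc[genes$pair == i]
      pos <- draw_positions(length(sel), cfg$chrom_len, gs, cfg$gene_len)
      seqs <- vector("list", length(sel))
      for (k in seq_along(sel)) {
        cp <- copies[sel[k], ]
        cons <- consensus[[cp$family]]
        d_age <- r * cp$age
        seqs[[k]] <- c(jc_mutate_int(cons$ltr, d_age), cons$internal,
                       jc_mutate_int(cons$ltr, d_age))
      }
      sp <- splice_elements(parents[[side]][[i]], pos, seqs)
      parents[[side]][[i]] <- sp$seq
      sel_o <- sel[sp$order]
      elements[[paste(side, i)]] <- data.frame(
        id = copies$id[sel_o], family = copies$family[sel_o],
        side = side, pair = i, age = copies$age[sel_o],
        start = sp$starts, end = sp$starts + el_len,
        l5_start = sp$starts, l5_end = sp$starts + cfg$ltr_len,
        l3_start = sp$starts + cfg$ltr_len + cfg$internal_len,
        l3_end = sp$starts + el_len,
        anc_pos = sp$positions, stringsAsFactors = FALSE)
    }
  }
  elements <- if (length(elements)) do.call(rbind, elements) else
    data.frame(id = character(0), family = character(0), side = character(0),
               pair = integer(0), age = numeric(0), start = numeric(0),
               end = numeric(0), l5_start = numeric(0), l5_end = numeric(0),
               l3_start = numeric(0), l3_end = numeric(0),
               anc_pos = numeric(0), stringsAsFactors = FALSE)
  rownames(elements) <- NULL

  # Lift gene coordinates onto each parent.
  genes$start_a <- NA_real_; genes$start_b <- NA_real_
  for (i in seq_len(n_pairs)) {
    gi <- genes$pair == i
    for (side in c("A", "B")) {
      e <- elements[elements$side == side & elements$pair == i, ]
      lifted <- lift_coord(genes$start_anc[gi], e$anc_pos, e$end - e$start)
      if (side == "A") genes$start_a[gi] <- lifted else genes$start_b[gi] <- lifted
    }
  }

  to_genome <- function(lst, prefix) {
    genome_set(setNames(vapply(lst, int_to_dna, character(1)),
                        sprintf("%s%02d", prefix, seq_along(lst))))
  }
  structure(list(
    ancestor = to_genome(anc, "anc"),
    parent_a = to_genome(parents$A, "A"),
    parent_b = to_genome(parents$B, "B"),
    genes = genes, elements = elements,
    consensus = consensus, config = cfg), class = "sim_progenitors")
}

#' Merge simulated progenitors into an allotetraploid with gene loss
#'
#' Concatenates both parental chromosome sets behind neutral scaffold
#' names (a seeded permutation hides which is which), deletes each
#' ancestral gene from subgenome A with probability `1 - retention_prob_a`
#' and from B with `1 - retention_prob_b` (deletion replaces the gene
#' sequence with random background so sequence-level analyses stay
#' honest), overwrites the planted exchange segments from source onto
#' destination scaffolds, and emits gene/TE annotations, the
#' ancestor-to-copies ortholog table, and the full truth set.
#'
#' @param prog output of [simulate_progenitors()].
#' @param cfg the same [sim_config()].
#' @return a list of class `allotetraploid_sim` with components `genome`,
#'   `genes`, `tes`, `elements`, `ortholog_table`, `truth` and `config`.
#' @export
simulate_allopolyploid <- function(prog, cfg) {
  stopifnot(inherits(prog, "sim_progenitors"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n_pairs <- cfg$n_pairs

  seqs <- c(as.list(unclass(prog$parent_a)), as.list(unclass(prog$parent_b)))
  internal_names <- names(seqs)
  side_of <- rep(c("A", "B"), each = n_pairs)
  pair_of <- rep(seq_len(n_pairs), 2)

  genes <- prog$genes
  n_genes <- nrow(genes)
  ret_a <- runif(n_genes) < cfg$retention_prob_a
  ret_b <- runif(n_genes) < cfg$retention_prob_b

  blank_gene <- function(seq, start, len) {
    repl <- int_to_dna(sample.int(4L, len, replace = TRUE))
    substr(seq, start + 1, start + len) <- repl
    seq
  }
  for (g in which(!ret_a)) {
    nm <- sprintf("A%02d", genes$pair[g])
    seqs[[nm]] <- blank_gene(seqs[[nm]], genes$start_a[g], cfg$gene_len)
  }
  for (g in which(!ret_b)) {
    nm <- sprintf("B%02d", genes$pair[g])
    seqs[[nm]] <- blank_gene(seqs[[nm]], genes$start_b[g], cfg$gene_len)
  }

  # Planted homoeologous exchange: copy source segment onto the partner.
  ex <- cfg$exchange_spec
  exchange_rows <- list()
  destroyed_genes <- character(0)
  copied_elements <- list()
  dropped_elements <- character(0)
  if (!is.null(ex) && nrow(ex) > 0) {
    for (k in seq_len(nrow(ex))) {
      from <- match.arg(ex$from[k], c("A", "B"))
      to <- if (from == "A") "B" else "A"
      src <- sprintf("%s%02d", from, ex$pair[k])
      dst <- sprintf("%s%02d", to, ex$pair[k])
      s <- ex$start[k]; e <- ex$end[k]
      if (s < 0 || e <= s || e > nchar(seqs[[src]]) || e > nchar(seqs[[dst]])) {
        stop("exchange segment out of bounds: ", src, " -> ", dst,
             " [", s, ", ", e, ")")
      }
      substr(seqs[[dst]], s + 1, e) <- substr(seqs[[src]], s + 1, e)
      exchange_rows[[k]] <- data.frame(internal = dst, start = s, end = e,
                                       source = src, stringsAsFactors = FALSE)
      # Destination genes inside the segment are overwritten, hence lost.
      gsel <- genes$pair == ex$pair[k]
      gstart <- if (to == "A") genes$start_a else genes$start_b
      hit <- gsel & gstart + cfg$gene_len > s & gstart < e
      destroyed_genes <- c(destroyed_genes,
                           paste(genes$gene[hit], to, sep = "_"))
      if (to == "A") ret_a[hit] <- FALSE else ret_b[hit] <- FALSE
      # Destination elements overlapping the segment are gone; source
      # elements fully inside it now have a copy at the same coordinates.
      el <- prog$elements
      dhit <- el$side == to & el$pair == ex$pair[k] & el$end > s & el$start < e
      dropped_elements <- c(dropped_elements, el$id[dhit])
      shit <- el$side == from & el$pair == ex$pair[k] & el$start >= s & el$end <= e
      if (any(shit)) {
        cp <- el[shit, ]
        cp$id <- paste0(cp$id, "_x")
        cp$side <- to  # physically now on the partner scaffold
        copied_elements[[length(copied_elements) + 1]] <- cp
      }
    }
  }

  # Neutral scaffold ids behind a seeded permutation.
  perm <- sample.int(2L * n_pairs)
  neutral <- sprintf("scaf%02d", seq_len(2L * n_pairs))
  name_map <- setNames(neutral[order(perm)], internal_names)
  genome <- genome_set(setNames(unlist(seqs), name_map[internal_names]))
  genome <- genome[order(names(genome))]
  class(genome) <- "genome_set"

  subgenome_of <- setNames(side_of, name_map[internal_names])
  pair_idx <- setNames(pair_of, name_map[internal_names])
  homoeolog_of <- setNames(
    name_map[sprintf("%s%02d", ifelse(side_of == "A", "B", "A"), pair_of)],
    name_map[internal_names])

  fate <- ifelse(ret_a & ret_b, "both",
                 ifelse(ret_a, "A_only", ifelse(ret_b, "B_only", "lost_both")))
  gene_fate <- setNames(fate, genes$gene)

  gene_rows <- rbind(
    data.frame(scaffold = name_map[sprintf("A%02d", genes$pair[ret_a])],
               start = genes$start_a[ret_a],
               id = paste0(genes$gene[ret_a], "_A"),
               stringsAsFactors = FALSE),
    data.frame(scaffold = name_map[sprintf("B%02d", genes$pair[ret_b])],
               start = genes$start_b[ret_b],
               id = paste0(genes$gene[ret_b], "_B"),
               stringsAsFactors = FALSE))
  gene_ft <- feature_table(gene_rows$scaffold, gene_rows$start,
                           gene_rows$start + cfg$gene_len,
                           strand = "+", kind = "gene", id = gene_rows$id)

  el <- prog$elements
  el <- el[!(el$id %in% dropped_elements), ]
  if (length(copied_elements)) el <- rbind(el, do.call(rbind, copied_elements))
  el$scaffold <- name_map[sprintf("%s%02d", el$side, el$pair)]
  rownames(el) <- NULL

  te_ft <- rbind(
    feature_table(el$scaffold, el$start, el$end, "+", "LTR_element", el$id),
    feature_table(el$scaffold, el$l5_start, el$l5_end, "+", "LTR_5p",
                  sprintf("%s.5p", el$id)),
    feature_table(el$scaffold, el$l3_start, el$l3_end, "+", "LTR_3p",
                  sprintf("%s.3p", el$id)))

  orth <- data.frame(
    ref_gene = genes$gene,
    gene_a = ifelse(ret_a, paste0(genes$gene, "_A"), NA_character_),
    gene_b = ifelse(ret_b, paste0(genes$gene, "_B"), NA_character_),
    stringsAsFactors = FALSE)

  exch_ft <- if (length(exchange_rows)) {
    exr <- do.call(rbind, exchange_rows)
    feature_table(name_map[exr$internal], exr$start, exr$end, ".",
                  "exchange_segment",
                  sprintf("exchange_%d", seq_len(nrow(exr))))
  } else {
    feature_table(character(0), numeric(0), numeric(0), character(0),
                  character(0), character(0))
  }

  truth <- list(subgenome_of = subgenome_of, pair_of = pair_idx,
                homoeolog_of = homoeolog_of, gene_fate = gene_fate,
                ltr_age = setNames(el$age, el$id),
                ltr_family = setNames(el$family, el$id),
                exchange_segments = exch_ft,
                destroyed_gene_copies = destroyed_genes,
                name_map = name_map)

  structure(list(genome = genome, genes = gene_ft, tes = te_ft,
                 elements = el, ortholog_table = orth, truth = truth,
                 config = cfg), class = "allotetraploid_sim")
}

#' Simulate a complete allotetraploid genome with ground truth
#'
#' Convenience wrapper running [simulate_progenitors()] then
#' [simulate_allopolyploid()].
#'
#' @param cfg a [sim_config()].
#' @return the `allotetraploid_sim` list, with the progenitors attached as
#'   `$progenitors`.
#' @export
simulate_allotetraploid <- function(cfg = sim_config()) {
  prog <- simulate_progenitors(cfg)
  sim <- simulate_allopolyploid(prog, cfg)
  sim$progenitors <- prog
  sim
}

#' Emit the true homoeologous alignment of a simulation as PAF records
#'
#' The ancestral backbone shared by the two members of each homoeologous
#' pair maps piecewise between the parent coordinate systems (the pieces
#' are delimited by subgenome-specific insertions). One PAF record per
#' backbone piece of at least `min_len` bp is emitted, with the A member
#' as query. This is the alignment a whole-genome aligner would recover,
#' with coordinates taken from the truth instead.
#'
#' @param sim an `allotetraploid_sim`.
#' @param min_len minimum backbone piece to report, bp.
#' @param identity nominal alignment identity used to fill `nmatch`.
#' @return a PAF data.frame (see [read_paf()]).
#' @export
truth_paf <- function(sim, min_len = 1000, identity = 0.86) {
  cfg <- sim$config
  el <- sim$elements
  nm <- sim$truth$name_map
  lens <- scaffold_lengths(sim$genome)
  out <- list()
  for (i in seq_len(cfg$n_pairs)) {
    qa <- nm[sprintf("A%02d", i)]; tb <- nm[sprintf("B%02d", i)]
    ea <- el[el$scaffold == qa & !grepl("_x$", el$id), ]
    eb <- el[el$scaffold == tb & !grepl("_x$", el$id), ]
    bp <- sort(unique(c(0, ea$anc_pos, eb$anc_pos, cfg$chrom_len)))
    st <- bp[-length(bp)]; en <- bp[-1]
    keep <- en - st >= min_len
    st <- st[keep]; en <- en[keep]
    if (!length(st)) next
    qs <- lift_coord(st, ea$anc_pos, ea$end - ea$start)
    ts <- lift_coord(st, eb$anc_pos, eb$end - eb$start)
    out[[i]] <- data.frame(
      query = unname(qa), qlen = as.numeric(lens[qa]), qstart = unname(qs),
      qend = unname(qs + (en - st)),
      strand = "+", target = unname(tb), tlen = as.numeric(lens[tb]),
      tstart = unname(ts), tend = unname(ts + (en - st)),
      nmatch = round(identity * (en - st)), alen = en - st, mapq = 60,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Write simulation outputs to disk
#'
#' FASTA for the tetraploid genome, GFF3 for genes and TEs, and TSV truth
#' tables (subgenome labels, gene fates, element ages/families, exchange
#' segments).
#'
#' @param sim an `allotetraploid_sim`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_features(sim$genes, file.path(dir, "genes.gff3"), "gff3")
  write_features(sim$tes, file.path(dir, "tes.gff3"), "gff3")
  tr <- sim$truth
  write.table(data.frame(scaffold = names(tr$subgenome_of),
                         subgenome = tr$subgenome_of,
                         pair = tr$pair_of,
                         homoeolog = tr$homoeolog_of),
              file.path(dir, "truth_subgenomes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = names(tr$gene_fate), fate = tr$gene_fate),
              file.path(dir, "truth_gene_fates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(element = names(tr$ltr_age), age = tr$ltr_age,
                         family = tr$ltr_family[names(tr$ltr_age)]),
              file.path(dir, "truth_ltr.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_features(tr$exchange_segments, file.path(dir, "truth_exchange.bed"),
                 "bed")
  write.table(sim$ortholog_table, file.path(dir, "ortholog_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_paf(truth_paf(sim), file.path(dir, "homoeologs.paf"))
  invisible(dir)
}
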