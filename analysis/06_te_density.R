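#!/usr/bin/env Rscript
# TE density in 5,000-bp windows flanking genes, compared between
# subgenomes and between single-copy and duplicated genes with
# Mann-Whitney U tests (the layout of a per-group density summary table).
#
# Both subgenomes share one TE process in the simulator outside the
# subgenome-specific bursts, so the subgenome contrast is expected to be
# null here; the single-copy vs duplicated contrast is likewise null by
# construction (fates are drawn independently of TE context).

library(subkit)

sim <- readRDS("results/sim.rds")
lens <- scaffold_lengths(sim$genome)
tes <- sim$tes[sim$tes$kind == "LTR_element", ]

rec <- flank_density(sim$genes, tes, lens, window = 5000)

truth <- sim$truth
report_side <- function(groups, label) {
  for (side in c("upstream", "downstream")) {
    out <- compare_groups(rec, groups, side)
    message(sprintf(
      "%s, %s: %s %.3f +/- %.3f vs %s %.3f +/- %.3f (U = %.0f, p = %.2g)",
      label, side, out$group[1], out$mean[1], out$se[1],
      out$group[2], out$mean[2], out$se[2],
      attr(out, "U"), attr(out, "p")))
  }
}

by_subgenome <- setNames(unname(truth$subgenome_of[sim$genes$scaffold]),
                         sim$genes$id)
report_side(by_subgenome, "subgenome")

fate <- truth$gene_fate[sub("_[AB]$", "", sim$genes$id)]
by_fate <- setNames(ifelse(fate == "both", "duplicated", "single_copy"),
                    sim$genes$id)
report_side(by_fate, "gene class")

dir.create("results", showWarnings = FALSE)
write.table(rec, "results/te_flank_density.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

summ <- do.call(rbind, lapply(
  list(c("subgenome", "upstream"), c("subgenome", "downstream"),
       c("gene_class", "upstream"), c("gene_class", "downstream")),
  function(spec) {
    groups <- if (spec[1] == "subgenome") by_subgenome else by_fate
    out <- compare_groups(rec, groups, spec[2])
    data.frame(contrast = spec[1], side = spec[2], group = out$group,
               n = out$n, mean = out$mean, se = out$se,
               U = attr(out, "U"), p = attr(out, "p"))
  }))
write.table(summ, "results/te_density_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/te_density_summary.tsv")
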