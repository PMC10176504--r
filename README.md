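# subkit

Post-assembly dissection of paleo-allotetraploid genomes in R: assigning
scaffolds to their two parental subgenomes, testing for homoeologous
exchange, dating subgenome-specific LTR retrotransposon bursts, and
quantifying biased fractionation — with a synthetic allotetraploid
simulator providing complete ground truth for validation.

It is written for genome-assembly groups working on polyploid plants
(grasses especially) whose diploid progenitors are unknown or
unsequenced, so the subgenome structure must be recovered from the
assembly itself.

## What it computes

**Subgenome phasing.** Homoeologous scaffold pairs are taken from a
whole-genome self-alignment (union coverage > 50% on both scaffolds).
Diagnostic 13-mers are those at assembly abundance ≥ 100 that differ
≥ 3-fold between pair members on both raw and per-Mb-standardized
counts, in the same direction. Scaffolds are clustered on these counts
(Euclidean distance, complete linkage, cut at 2), giving the A/B
assignment; A is the side with more preferred k-mers.

**Homoeologous exchange.** Each scaffold becomes a sequence of windows
labelled by their majority diagnostic k-mer type. A two-state HMM
(starts 0.5/0.5, switch probability 0.01, emissions Viterbi-trained on
clean scaffolds) is decoded by Viterbi; maximal runs decoded against the
scaffold's assignment are exchange calls.

**LTR dynamics.** Elements are clustered into subfamilies by Markov
clustering (inflation 3) of a graph whose edges are global alignments of
their terminal repeats at ≥ 70% identity and ≥ 90% mutual coverage.
Subfamilies ≥ 3-fold more common in one subgenome by both occurrence and
bp are flagged as enriched. Insertion ages use the k/2r clock,
t = k / (2r) with the Jukes–Cantor distance k = −(3/4) ln(1 − 4p/3) and
r = 1.3 × 10⁻⁸ substitutions/site/year, either between each element's
own two terminal repeats (identical at insertion) or among a
subfamily's 5′ LTRs.

**Fractionation and TE context.** Ancestral-gene accounting per
subgenome (retained in A / in B / in both), a log-space Fisher's exact
test for retention bias, per-term GO over-representation, and TE density
in 5,000-bp gene-flanking windows compared by Mann–Whitney U tests.

**The simulator.** `simulate_allotetraploid()` generates the whole study
system — two JC-diverged progenitors, subgenome-specific LTR bursts with
known ages, biased gene loss, one planted 200-kb translocation — with a
truth set for every quantity the pipeline estimates.

## Worked example

```r
library(subkit)

sim   <- simulate_allotetraploid(sim_config(seed = 20231))
pairs <- pair_homoeologs(truth_paf(sim))
kc    <- kmer_config(window = 5e4)
diag  <- select_diagnostic_kmers(count_kmers(sim$genome, kc), pairs, kc)
asg   <- cluster_subgenomes(diag, pairs)
sum(asg$assignment == sim$truth$subgenome_of[names(asg$assignment)])
#> [1] 20

ex <- detect_exchanges(asg, density_tracks(sim$genome, diag, window = 5e4))
ex$calls[, c("scaffold", "start", "end")]
#>   scaffold start     end
#> 1   scaf08 1e+06 1200000
sim$truth$exchange_segments$start
#> [1] 1e+06
```

The 20 scaffolds split perfectly into the two true subgenomes, and the
planted 200-kb translocation on `scaf08` is called at exactly its true
coordinates. Downstream, the same run recovers 8 A-enriched and 1
B-enriched LTR subfamilies and an insertion-age peak of 3.4 MYA against
a true burst at 3.5 MYA:

```r
s5 <- ltr_seqs(sim$genome, sim$elements, "five")
s3 <- ltr_seqs(sim$genome, sim$elements, "three")
age_peak(date_family(s5, s3, mode = "five_vs_three_prime")) / 1e6
#> [1] 3.405677
```

The retention accounting reproduces published-style tables exactly; for
example, counts of 19,523 ancestral genes with 16,666 / 15,464 / 12,195
retained in A / B / both give 85% / 79% / 62%:

```r
rt <- suppressWarnings(retention_table(19523, 16666, 15464, 12195))
round(c(rt$pct_a, rt$pct_b, rt$pct_both))
#> [1] 85 79 62
fisher_exact_2x2(retention_bias_table(rt))   # retention bias, subgenome A favoured
#> [1] 1.198889e-52
```

## The analysis workflow

`analysis/` holds the numbered drivers that run the full study on the
simulated genome and write tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | builds the default allotetraploid + truth tables |
| `02_phase_subgenomes.R` | pairs, diagnostic 13-mers, clustering, density tracks |
| `03_exchange.R` | HMM training/decoding, exchange calls vs truth |
| `04_ltr_dynamics.R` | subfamilies, enrichment, insertion-age distribution |
| `05_fractionation.R` | ortholog table, retention accounting, bias test, GO |
| `06_te_density.R` | flank densities and group comparisons |

Run them in order with `Rscript analysis/01_simulate.R` etc.; each step
reads the previous step's outputs from `results/`.

## The methods vignette

`vignettes/subgenome-methods.Rmd` documents the models and their
assumptions, every tunable parameter with its default and rationale,
what the simulator does and does not emulate, and the numerical
conventions (tie-breaking, zero-denominator folds, window noise floors,
MCL numerics, test calibration).
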