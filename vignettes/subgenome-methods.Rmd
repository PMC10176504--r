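---
title: "Methods: subgenome phasing, exchange detection, and fractionation statistics"
author: "subkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgenome phasing, exchange detection, and fractionation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

An allotetraploid genome carries two complete chromosome sets inherited
from two diploid progenitor species. After a few million years of shared
residence in one nucleus, the two subgenomes still differ in their repeat
landscapes (transposable elements that were active in only one progenitor
before hybridization), in how many duplicated genes each has lost
(fractionation, often biased toward one subgenome), and occasionally in
physically exchanged chromosome segments (homoeologous exchange). When no
sequenced diploid relative exists, the progenitor assignment of each
scaffold must be recovered from the genome itself. `subkit` implements
that recovery and the downstream comparative statistics as one tested
pipeline, and ships a simulator that generates allotetraploid genomes
with complete ground truth so every stage can be validated end to end.

# The simulator: what it emulates

`simulate_allotetraploid()` builds the study system the pipeline is
designed for:

* One ancestral chromosome per homoeologous pair, uniform over ACGT, with
  non-overlapping gene templates planted at roughly regular spacing.
* Two parents derived by independent Jukes-Cantor (JC) substitution at
  density $rT$ per branch — default $r = 1.3\times10^{-8}$
  substitutions/site/year and $T = 5.8$ million years (MY), so about 7.5%
  of sites per branch. Substitutions are applied through the exact JC
  marginal (each site changes with probability
  $\tfrac34(1 - e^{-4d/3})$), which makes the process exactly invertible
  by the JC distance formula — the cross-module recovery tests depend on
  this self-consistency.
* Subgenome-specific LTR retrotransposon bursts: 8 subfamilies in
  subgenome A and 1 in B, each subfamily a random consensus
  (400 bp LTR + 800 bp internal + 400 bp LTR). Copies are inserted
  outside gene templates with ages drawn from a normal distribution
  centred at 3.5 MY (sd 1 MY), truncated to (0, 5.8 MY); each copy's two
  terminal repeats are mutated independently at density $r \cdot
  \mathrm{age}$. The two repeats of one element were identical at
  insertion, which is precisely the assumption of the $k/2r$ insertion
  clock dated later.
* Copy numbers default to 250 per A subfamily and 2,000 for the single B
  subfamily, i.e. about one insertion per 12 kb on either side and a
  ~16% subgenome-specific TE fraction — a repeat load in the range of
  LTR-rich grass genomes, and dense enough that 50-kb analysis windows
  almost always contain diagnostic sequence.
* Hybridization by concatenation behind neutral, seed-shuffled scaffold
  names; per-gene retention draws (defaults 0.85 for A, 0.79 for B, the
  biased-fractionation signal); gene loss implemented as sequence
  replacement by random background, not mere annotation removal, so
  k-mer and alignment stages cannot cheat; and one planted 200-kb
  homoeologous translocation (B member of pair 1 copied over its A
  partner at 1.0-1.2 Mb).

Desk scale is 10 pairs x 2 Mb (~46 Mb with insertions), which runs the
whole pipeline in about a minute. What the simulator does **not**
emulate: gene structure (no introns/UTRs), indels outside structured
insertions, non-LTR repeat classes, nested or fragmented elements,
recombination, selection, GC heterogeneity, and assembly artefacts.
Passing the recovery tests therefore demonstrates correctness of the
algorithms under the model's assumptions, not robustness to everything a
real assembly contains.

# Subgenome phasing by diagnostic k-mers

1. **Homoeologous pairs** (`pair_homoeologs`): from a whole-genome
   self-alignment (PAF), coverage per scaffold of a candidate pair is the
   union of aligned intervals over scaffold length; both coverages must
   exceed 0.5 ("more than 50% matching across both scaffolds"). Union
   coverage is the conservative reading of "matching"; matched bases
   (`nmatch`) would be an alternative and is noted as a sensitivity
   concern. Greedy selection by descending minimum coverage enforces
   that each scaffold joins at most one pair.
2. **Counting** (`count_kmers`): exact sliding 13-mer counts in compiled
   code, canonical (strand-merged) by default because scaffold strand is
   arbitrary; windows containing N contribute nothing. Only k-mers with
   assembly-wide abundance >= 100 are retained (the high-abundance
   filter); this threshold applies genome-wide, not per scaffold. The
   flat-table implementation caps k at 13 (4^13 entries); that is the
   intended operating point, and the in-memory design is documented as a
   ceiling rather than worked around.
3. **Diagnostic selection** (`select_diagnostic_kmers`): a k-mer is
   diagnostic for a pair when its abundance differs >= 3-fold between the
   members **both** on raw counts and on counts standardized per Mb of
   scaffold, in the same direction. Zero denominators count as infinite
   fold (a k-mer absent from one member is maximally diagnostic); 0/0
   never passes. Across pairs, each k-mer is assigned to a side by
   majority vote after a provisional 2-cluster cut orients the pairs;
   k-mers with no majority are dropped. The side holding more preferred
   k-mers is labelled A — a deterministic convention mirroring the
   empirical asymmetry of progenitor repeat activity.
4. **Clustering** (`cluster_subgenomes`): agglomerative clustering of
   scaffolds (Euclidean distance on per-Mb standardized diagnostic
   counts, complete linkage — the default of the heatmap-clustering tool
   family this analysis style uses), cut at two clusters. A pair with
   both members in one cluster is a hard error: the assignment would be
   meaningless.

# Homoeologous exchange: the windowed HMM

Each scaffold is summarized as a sequence of windows (50 kb at desk
scale; 1 Mb is the chromosome-scale default) carrying the majority
diagnostic k-mer type `a` or `b`. Ties are `missing`. Windows whose
combined hit count falls below `min_hits` (default 25) are also
`missing`: the chance-match background of the diagnostic sets is roughly
$|sets| \cdot w / 4^k$ hits per window (~10 both at desk scale and at
919 k-mers x 1 Mb), and a window with only background hits carries no
usable evidence — low-signal regions are a known source of
misassignment.

The two-state HMM has fixed starts (0.5/0.5) and fixed switch
probability 0.01; only the emissions are trained, by Viterbi training
(decode, re-estimate emission frequencies per decoded state with Laplace
+1 smoothing, iterate to a fixed point). Training uses the cleanest
scaffold of each subgenome (lowest minority-symbol fraction) — the
programmatic version of training on visually exchange-free scaffolds;
the scaffolds can also be named explicitly. Decoding is Viterbi in log
space; `missing` windows contribute an emission factor of 1, keeping the
transition chain intact; ties break toward the previous state (sticky),
which favours fewer segments, matching the prior that exchange is rare.
Maximal runs of windows decoded against the scaffold's assignment become
exchange calls at window resolution; runs consisting solely of missing
windows are not called. Posterior decoding and Baum-Welch are
deliberately out of scope — hard Viterbi training matches the analysis
this pipeline reproduces.

With trained emissions near 0.98 and switch 0.01, flipping state
requires roughly three windows of contrary evidence; the planted 200-kb
segment spans four 50-kb windows, and false positives require three
consecutive misleading windows on a clean scaffold (measured at <= 1% of
exchange-free scaffolds).

# LTR subfamilies and insertion dating

Elements are clustered on their 5' terminal-repeat sequences. Candidate
pairs must share an 11-mer seed (the seeded-search shortcut; unrelated
400-bp sequences share one with ~2% probability), then are aligned by
global Needleman-Wunsch with linear gaps (+1/-1/-2). An edge requires
identity >= 0.70 over the alignment and >= 90% mutual coverage. The
identity filter replaces a similarity-search e-value cutoff, which has
no meaning without database statistics; the 90% mutual-coverage filter
is kept verbatim. Inside the all-pairs scan the alignment runs in a
diagonal band (half-width 50), exact for the near-collinear repeat pairs
an edge can come from; the exported single-pair function defaults to the
full matrix and is tested against a textbook implementation. For very
redundant inputs a deterministic systematic subsample (every m-th id,
default ceiling 600) is clustered — the standard exemplar-reduction step
for repeat libraries.

Markov clustering (`mcl_cluster`) runs on the column-stochastic
adjacency with self-loops set to each node's maximum incident weight:
expansion (matrix square), inflation (elementwise power 3,
renormalize), then pruning of normalized entries below 1e-5, iterated to
a 1e-6 fixed point (cap 200 iterations; the order —
normalize-then-prune — matters, since inflated raw entries of a large
clique all fall below any absolute floor before normalization). Clusters
are read off attractor rows, merging attractors that share members;
node order is canonicalized to lexicographic id so results are
bit-for-bit reproducible.

A subfamily is subgenome-enriched when it is >= 3-fold more common in
one subgenome by **both** occurrence count and total bp, in the same
direction (the stricter joint reading of "using both occurrence and bp
count"); zero denominators again count as infinite fold.

Dating uses $t = k/(2r)$ with $k = -\tfrac34\ln(1 - 4p/3)$ (Jukes-Cantor
correction; gap columns are excluded from $p$, saturated pairs with $p
\ge 0.75$ are dropped and counted). Two modes are provided because
"aligning the LTRs of each family" is ambiguous: `within_family_pairs`
(all pairwise 5'-LTR distances within a subfamily, dating the expansion)
and `five_vs_three_prime` (each element's own two terminal repeats,
identical at insertion — the classical element clock, one age per
element). The within-family mode is the default literal reading; the
element clock is what the simulator-recovery checks use because it has
one unambiguous truth value per element. `age_peak()` reports the kernel
density mode of an age distribution.

# Fractionation statistics

`tally_retention` counts ancestral genes (reference-diploid genes with
at least one surviving copy) and the retained fraction per subgenome;
percentages are exact and only rounded for display. Published accounting
tables of this kind can be internally inconsistent by a small residue
(retained_A + retained_B - retained_both != n_ancestral), so the
constructor warns rather than errors.

The retention-bias test is Fisher's exact test on a 2x2 table computed
in log space (log-gamma), so arbitrarily large counts are safe; the
two-sided p-value sums point probabilities no larger than the observed
one (within 1e-7 relative), the convention of the standard statistical
environments. Two constructions of the table are provided:
`single_copy` (default) contrasts genes surviving only in A vs only in
B against the rest of the ancestral set, and `retained_lost` contrasts
retained vs lost per subgenome. The default was chosen because it is the
construction that actually reproduces the published example p-value of
this analysis family (1.58e-10 vs printed 1.63e-10 on the orthogroup-row
counts; the retained/lost table gives 8.2e-11), and because it matches
the described comparison of genes "present only in subgenome A, only in
subgenome B, or in both".

One calibration subtlety is worth stating plainly: when the null is
simulated on a single genome's own gene set, the A and B rows of either
table share genes, the per-gene indicators are negatively correlated
given ancestrality, and the test runs slightly hot (about 7% rejections
at nominal 5% for retention near 0.8). Under the sampling model Fisher
actually assumes — two independent cohorts — the implementation is
calibrated at 5%. Both facts are asserted in the test suite. At the
p-values this analysis produces (1e-10 and below), the inflation is
immaterial to any conclusion.

GO over-representation (`go_enrichment`) is a plain per-term one-sided
Fisher test of foreground vs universe with expected counts
`annotated x |fg| / |universe|`; no multiple-testing correction by
default (raw p-values are what the reference analyses report; a
Benjamini-Hochberg column is optional). The term-elimination and
weighting algorithms of dedicated GO tools are out of scope, so deeply
nested terms can differ from those tools' output. The term map is a flat
gene-to-terms table; ancestor propagation, if wanted, is the caller's
responsibility.

# TE density near genes

`flank_density` computes, for each gene, the TE-occupied fraction of the
5,000-bp windows upstream and downstream (strand-aware by default;
toggleable). Occupancy uses the union of TE intervals, the only reading
bounded by 1 and invariant to how elements are fragmented in an
annotation. Windows truncated at scaffold ends are renormalized by the
truncated length and flagged (or dropped, by option). Group comparisons
use the Mann-Whitney U test: exact by enumeration of rank assignments
when the pooled sample is <= 12 and tie-free, otherwise the normal
approximation with tie-corrected variance and continuity correction;
identical samples give p = 1.

# Numerical and convention choices, collected

* Internal coordinates are 0-based half-open everywhere; GFF3's 1-based
  closed convention is converted only at I/O boundaries.
* pg -> Mbp conversion for flow-cytometry genome sizes defaults to 978
  Mbp/pg (the standard DNA mass-length constant; it reproduces the
  2.56 pg -> 1.25 Gb worked example exactly).
* Ambiguity letters in FASTA degrade to N with a logged count rather
  than erroring; k-mer windows containing N are skipped deterministically.
* Fold filters treat x/0 as infinite for x > 0, and 0/0 as failing.
* Anchor chaining is longest monotone chains by dynamic programming with
  rank gaps <= 25 on both axes and blocks >= 5 anchors (the conventions
  of the standard collinearity scanners), both orientations searched,
  greedy longest-first extraction, each anchor in at most one block.
  Best-reciprocal filtering breaks score ties by lexicographic id.
* Viterbi ties break sticky; MCL node order is lexicographic; subsample
  grids are deterministic (no RNG outside the simulator and tests).
* All simulator randomness flows from one integer seed; equal seeds give
  byte-identical genomes.

# Problem sizes

The shipped analyses and acceptance checks run the full pipeline on the
default desk-scale system (20 scaffolds x ~2.3 Mb, ~4,000 LTR elements,
~1,900 gene copies), cluster a 600-element exemplar subsample, date all
elements, and use 100-1,000 replicates for false-positive and
calibration rates. These sizes were chosen so a complete run finishes in
about a minute on one core while leaving every statistical check with
comfortable resolution (binomial SE under 1% where 2% margins are
asserted).

# Known limitations

* The phasing stage assumes exactly two subgenomes and unambiguous
  pairing; higher ploidy or fragmented assemblies would need a
  generalized cut and pairing step.
* Exchange calls are window-resolution; no per-base breakpoint
  refinement is attempted.
* The in-memory k-mer table is sized for assemblies up to roughly 1 Gb
  at k = 13; larger genomes would need disk-backed counting.
* Alignment is linear-gap global; affine gaps and local alignment are
  not modelled (the terminal-repeat inputs this package targets are
  near-collinear and length-matched).
* The simulator's clean separability means recovery rates here are upper
  bounds on real-data performance.
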