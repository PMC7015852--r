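---
title: "Inferring and placing whole-genome duplications with wgdlens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and placing whole-genome duplications with wgdlens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An ancient whole-genome duplication (WGD, paleopolyploidy) leaves two
correlated signatures in a modern genome: an excess of paralogue pairs
whose synonymous distance (Ks) clusters around the age of the event, and
runs of duplicated genes in conserved order (collinear segments) eroded
by fractionation. `wgdlens` implements the full inference chain around
these signatures — paranome construction, redundancy-corrected Ks age
distributions, collinearity detection, orthologue-based relative dating,
and phylogenomic mapping of duplication events onto a species tree — and
ships a generative simulator so every stage can be validated against
known truth. The motivating application is the early-diverging angiosperm
order Nymphaeales (water lilies), where a WGD on the Nymphaeaceae stem
sits close to the Nymphaeaceae–Cabombaceae split, but all machinery is
lineage-agnostic.

## The node-weighted Ks distribution

The number of synonymous substitutions per synonymous site, Ks, is a
proxy for the age of a duplication because synonymous sites are close to
neutral. A gene family of *n* members contributes *n(n−1)/2* pairwise Ks
estimates but only *n−1* duplication events, so raw pair histograms
overweight large families. The correction used here:

1. split each family into subfamilies by connected components of the
   graph of pairs with Ks ≤ 5 (saturated pairs excluded);
2. build a subfamily tree (neighbor joining on the Ks matrix, midpoint
   rooted);
3. for each internal node with child clades *A* and *B*, add the
   *m = |A|·|B|* cross-clade pair estimates with weight *1/m*.

Every pair enters at exactly one node (the MRCA of its two genes), so
per-event weights sum to one and each subfamily contributes total weight
*n−1*. The weighted values feed a Gaussian KDE (512-point grid,
Silverman bandwidth on the weighted sample unless overridden); the peak
is the grid argmax and its 90% confidence interval is the percentile
interval of the mode over 200 bootstrap resamples (weights carried).

Two readings of the subfamily rule are possible (connected components
vs. complete linkage); components are used because the weighting only
needs a partition, and a `threshold` argument exposes the cutoff.
Likewise the weighting emits the raw *m* pair values at 1/*m* rather
than one node-averaged value; this follows the additive reading of the
rule and keeps the distribution's support unchanged.

## Ks estimation

Pairwise Ks uses the NG86 counting estimator: fractional synonymous site
counts per codon from the standard genetic code (changes to stop codons
count as nonsynonymous sites), differences averaged with equal weight
over all minimal mutational pathways excluding those through stop
codons, and the Jukes–Cantor correction
`Ks = −(3/4)·log(1 − (4/3)·ps)`; `ps ≥ 3/4` is flagged saturated.
A likelihood codon-model estimator would be the higher-fidelity choice
for real data; the counting estimator is deterministic, dependency-free,
and accurate where it matters here — peak location — with a plug-in
interface (`read_ks_table()`) so externally computed per-pair Ks values
can be injected at any stage. Pairs with fewer than 30 counted codon
columns are flagged low-information.

## Homology

The paranome is built from an all-against-all protein similarity graph
thresholded at an E-value-like significance of 1e-10 and clustered with
Markov clustering (expansion/inflation to convergence, inflation 2;
non-convergence falls back to connected components with a warning).
The builtin scorer uses global match/mismatch scoring (+2/−1, affine
gaps for unequal lengths) over candidate pairs sharing at least two
exact 6-mers, with Karlin–Altschul-style significance calibrated on the
empirical residue composition; it is a deliberate, deterministic
stand-in for local heuristic search, and `mode = "file"` accepts
12-column tabular hits from a real search for full-scale runs.
One-to-one orthologues are plain reciprocal best hits (score ties broken
lexicographically and counted); this drops the in/out-paralog refinement
of dedicated tools, a fidelity gap accepted because only one-to-one
pairs are consumed downstream. Low-copy nuclear (LCN) families are
selected by the single-copy predicate: exactly one copy in every focal
species and in at least `min_single_in_panel` panel species (default 5).

## Synteny

Gene positions are 0-based ranks per chromosome; blocks are chains of
homologous pairs strictly monotone on both axes (increasing or
decreasing on the second genome), with rank gaps of at most 20 on both
axes between consecutive pairs and at least 4 pairs per block. "20 genes
apart" is read as rank difference ≤ 20 symmetrically on both genomes,
the standard collinearity convention; the flag is exposed. Chains are
extracted greedily (longest first; ties by the lexicographically
smallest rank sequence) by dynamic programming, and matches are assigned
to at most one block. Tandem arrays (same-family genes at consecutive
ranks) are collapsed to their lowest-rank member before chaining so
tandem runs cannot fabricate blocks. One-to-one screening keeps blocks
greedily by descending pair count, rejecting any block whose interval
overlaps a kept block on either axis — a greedy stand-in for an exact
quota-based screen; tests report its optimality gap on small instances.
Anchor pairs are the matched pairs of surviving intra-genomic blocks,
with pairs above the Ks cap (5) or saturated removed and counted.

## Duplication mapping

Gene trees are neighbor joining on JC-corrected distances with
column-resampling bootstrap supports (200 replicates by default);
externally computed Newick trees with supports are accepted for full
fidelity. Trees are rooted on the outgroup when its genes form a clade,
else by midpoint. Each internal node maps to the species-tree MRCA of
its leaf species and is classified: duplication if its child clades'
species sets intersect; speciation if they are disjoint and both
children map strictly below the node's image; otherwise inconsistent
(a `strict` flag additionally requires children to map into the image's
immediate children). For an anchor pair whose MRCA is a duplication
node, the event is circumscribed between that node's image (lower
bound) and the image of the first speciation node on the rootward walk
(upper bound; inconsistent and duplication nodes on the walk are
skipped, since the three-way classification makes them usable as
neither bound). If the bounds are joined by one species-tree branch the
event is assigned to it; event support is the bootstrap of the branch
leading to the duplication node, tallied at thresholds 50 and 80.
Families eligible for mapping mirror the analysis filter: at least one
anchor pair, at least one outgroup gene, at most 200 genes.

## The simulator

The generative model defines the study conditions; its parameters are
artifact choices (no real dataset is emulated):

* **Species tree** — an 8-taxon Nymphaeales-like ultrametric topology
  with per-lineage branch lengths in Ks units (tip depth 1.6 per
  lineage; splits at pairwise Ks 0.3–3.0), with optional per-branch rate
  multipliers. The pairwise Ks between two species is twice their split
  depth, and the WGD age `wgd_ks` (default 0.9, between the
  Nymphaeaceae crown at 0.6 and the Nymphaeaceae–Cabombaceae split at
  1.2) is likewise a *pairwise* distance: each duplicate lineage
  accrues `wgd_ks/2`.
* **Gene families** — one lineage per family enters at the root;
  birth/death at 0.05/0.05 events per Ks unit adds background
  duplicates and losses. A lineage crossing the WGD point duplicates;
  the new copy survives with `retention_prob` (0.3). With loss rate 0
  the retained count is exactly Binomial(n_families, retention_prob),
  which the tests verify.
* **Sequences** — indel-free codon streams over six four-fold
  degenerate amino acids (V, S, P, T, A, G). The third codon position
  evolves as a Kimura two-parameter chain (kappa, default 2) at one
  synonymous substitution per site per Ks unit, so every codon carries
  exactly one NG86 synonymous site and pairwise synonymous distance is
  additive and identifiable; the amino acid switches uniformly among
  the six at the reduced rate 2·omega per codon (omega 0.15). This
  makes estimator consistency provable (the JC correction of a kappa=2
  chain is biased by under 3% for Ks ≤ 1.2) at the cost of unrealistic
  protein composition — acceptable because no stage depends on real
  amino-acid frequencies.
* **Layout** — families occupy contiguous loci on 4 chromosomes.
  WGD-descendant species carry duplicated chromosome copies (chr1/chr1b,
  ...) preserving locus order; each retained duplicate is deleted with
  `fractionation_prob` (0.2), and deleted genes are pruned from trees
  and sequences so orders, FASTA and truth stay consistent. Background
  duplicates are placed tandem (next to their parent locus) with
  probability `tandem_prob` (0.5), else at a random position.
  Allopolyploidy is emulated by lengthening the second homoeologue's
  stem by `allo_extra_ks/2`.

What passing tests on these data do *not* show: robustness to indels
and alignment error, to rate variation among sites, to missing or
misassembled regions, to tandem arrays larger than the simulator
produces, or to the biased codon usage of real genomes.

## Numerical choices and degenerate inputs

All randomness derives from one master seed through named substreams,
so every experiment is reproducible bit-for-bit. NJ branch lengths are
clamped at zero; negative least-squares branch lengths in
`fit_branch_ks()` are clamped by nonnegative least squares and
reported. Constant-value KDE inputs return a zero-width interval;
fewer than 30 values in range is an error advising a wider range.
Saturated Ks pairs are excluded from subfamily edges and distributions;
within-subfamily saturated entries are flattened to twice the threshold
only for tree building, never emitted. All-identical alignments yield a
flagged star-like gene tree. Midpoint-rooting ties go to the branch
nearest the lexicographically smallest leaf (via the deterministic
midpoint implementation used).

## Problem sizes

The bundled analysis and validation runs use 300 families of 500
codons (the peak-recovery conditions: retention 0.3, WGD at 0.9),
200-family runs for duplication placement, and 100-family replicates
for relative timing; these sizes give stable peak locations and event
counts while keeping each experiment in the tens of seconds on one
core. Full-genome inputs enter through the file interfaces (FASTA,
tabular hits, GFF3/BED-like orders, Newick).

## Known limitations

Counting-based Ks saturates above ~2 and the estimator refuses pairs at
ps ≥ 3/4; peak locations beyond Ks ≈ 2 are compressed. The greedy 1:1
screen and greedy chain extraction are not globally optimal. RBH
orthology underestimates orthologue sets after lineage-specific
duplication. NJ gene trees with JC distances underperform likelihood
trees on deep or rate-heterogeneous families; the import path for
external trees exists for that reason. Only one WGD per simulation is
modelled, and no inversions, translocations or transposable elements.
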