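---
title: "Methods: integrated molecular and morphological analysis of a grape-like radiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated molecular and morphological analysis of a grape-like radiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitnet)
```

## The scientific problem

The grape genus *Vitis* is a recently radiated group: a handful of
continental clades (an East Asian clade, the European *V. vinifera* clade,
two North American clades and the isolated Californian lineage, with
*Muscadinia* as outgroup) whose species remain largely interfertile.
Interspecific F1 hybrids — natural and man-made — sit inside or between
clades in phylogenetic trees and blur the species relationships, and
SNP arrays discovered mostly in *V. vinifera* distort branch lengths through
ascertainment bias. vitnet implements the complete analysis chain such a
study needs: per-locus diversity statistics on phased Sanger haplotypes,
haplotype phasing itself, median-joining networks, a defined hybrid-detection
procedure with cross-direction (maternal parent) inference from chloroplast
markers, distance trees with bootstrap, the ascertainment-bias subsampling
experiment, and phylogenetic-signal analysis of leaf measurements and OIV
descriptors. A synthetic-data generator reproduces the statistical structure
of such data with full ground truth, so every stage is testable without
access to the original material.

## Sequence input and site classification

Input alignments are per-locus diploid Sanger consensus sequences in FASTA:
each accession contributes one sequence in which heterozygous positions are
encoded by the six two-fold IUPAC codes (K, M, R, S, W, Y) and missing data
by `N` or `-`. Indel columns are assumed to be edited out upstream; the
loader can optionally drop any column containing `-` to reproduce that
editing on raw input. Coordinates are 0-based half-open internally
(`snp_positions`, concatenation boundaries); 1-based positions appear only
in human-readable reports.

`classify_sites()` treats heterozygote codes as missing — exactly what a
consensus-based site scan does — so its counts deliberately underestimate
polymorphism relative to the phased analysis; the difference between the two
is itself a quantity of interest (diploid site scans miss the variation that
only heterozygotes carry).

## Haplotype phasing

`phase_em()` reconstructs the two haplotypes of each accession per locus
with an expectation–maximisation algorithm on population haplotype
frequencies (the classic frequency-EM for multi-site genotypes). The
E-step distributes every individual over all haplotype pairs compatible with
its genotype, with missing genotypes summed over their completions; the
M-step re-estimates the frequency vector. We run 10 random restarts, up to
500 iterations each, log-likelihood tolerance 1e-8, and assign each
individual its maximum-posterior pair, with ties broken toward the
lexicographically smallest pair so the output is fully deterministic given
the seed (default 1). The reported `phase_confidence` is the posterior
probability of the chosen pair. As a pure implementation optimisation,
pairs whose posterior weight falls below 1e-10 after a three-iteration
burn-in are dropped from the E-step (each individual always keeps its best
pair); this leaves the fixed point unchanged at the reported tolerance.

Individuals whose ambiguity exceeds `max_het_sites` (default 16, i.e. at
most 2^15 unordered pair completions) are phased greedily site by site
against the EM haplotype pool, conditioning on the already-placed sites, and
flagged with confidence 0 — bounded compute with explicit degradation.

Two properties matter downstream. First, re-collapsing any phased pair
reproduces the input genotype exactly, and phasing never imputes missing
sites. Second, the inter-haplotype Hamming distance per accession — the
hybrid-detection statistic — is invariant to phase switches, so hybrid
detection is robust even where the phase itself is uncertain. Switch
accuracy does matter for parental-clade assignment; on neutral-coalescent
test data at the study's scale (80 diploids, locus θ ≈ 10, no
recombination) the switch-error rate, excluding statistically unphaseable
population singletons as usual, is below 5%. Frequency-based phasing cannot
orient singleton variants; no additional prior is used, and none is needed
at the clade level.

## Diversity statistics

For each locus the package reports, on the phased haplotypes: sample size,
segregating sites S, number of distinct haplotypes, Watterson's
θ_W = S/(a₁·L), nucleotide diversity π, haplotype diversity
He = n/(n−1)(1−Σp²), Tajima's D with the standard constants, and Fay & Wu's
H. Missing data are handled by pairwise deletion throughout: each haplotype
pair is compared over the sites where both are unambiguous, and the mean
pairwise count entering D is taken on the same basis. Haplotype identity for
the tallies is exact string match after excluding, per comparison, sites
missing in either haplotype (greedy grouping in input order, hence
deterministic). The sample size n entering the constants is the number of
phased haplotypes actually present at the locus.

Fay & Wu's H is computed unnormalized as θ_π − θ_H over the sites that can
be oriented with the outgroup; the ancestral state is the majority base
across outgroup haplotypes, with ties, ingroup-absent outgroup states, and
non-biallelic ingroup sites excluded. Published per-locus tables for this
kind of data print positive H values of unclear variant and sign convention;
vitnet's H is the textbook θ_π − θ_H (typically negative when
high-frequency derived alleles are in excess) and is reported as such rather
than matched to any particular table.

## Median-joining networks

`build_mj_network()` implements the median-joining construction for the
(essentially binary) post-phasing data: Hamming distances among distinct
haplotypes; a minimum-spanning network that keeps every link within ε
(default 0) of the level at which its endpoints' components first connect;
iterative insertion of per-site-majority median vectors of connected
triplets whenever they reduce the local Steiner cost; and pruning of
inferred nodes of degree ≤ 2 (observed nodes are never deleted). All ties
break lexicographically, so the network is deterministic; node-for-node
identity with any particular program's drawing is not claimed — the testable
surface is the connection cost (checked against a brute-force Steiner
minimum on small instances) and the clade-adjacency structure. Sites with
missing states are dropped (with a log) before network construction.

`nearest_clade()` formalizes how such networks are read for hybrids: a
haplotype is assigned the clade of its minimum-Hamming labeled neighbour,
with ties across clades yielding `UNKNOWN`.

## Hybrid detection

The procedure chains five steps:

1. **d̄ statistic** — the per-accession mean over loci of the inter-haplotype
   Hamming distance. An F1 between clades carries one haplotype from each
   parent at *every* locus, so d̄ ≈ twice the between-clade divergence,
   far above the within-species baseline.
2. **Outlier flags** — Tukey's boxplot fence (value > Q3 + 1.5·IQR,
   linear-interpolation quartiles) within the accession's clade group; wild
   and cultivated members of the domesticated clade are one group. Groups
   under 4 members fall back to the pooled fence. The Tukey rule is the
   standard formalization of "outliers in a boxplot".
3. **Parental clades** — each haplotype of a flagged (or known) hybrid is
   mapped per locus to its nearest labeled clade, with known hybrids and the
   accession itself excluded from the pools; the parental pair is the two
   most frequent clade labels, each required in ≥ 25% of informative loci.
   The threshold means a single homoplasic locus cannot create a hybrid
   call; a non-hybrid yields the degenerate pair (clade, clade).
4. **Array heterozygosity** — the fraction of heterozygous calls per
   accession on the SNP array, with the same outlier rule; hybrids with a
   discovery-panel parent show extreme values.
5. **Maternal clade** — chloroplast SNPs are haploid, so heterozygous calls
   are set to missing and loci kept only if biallelic across the sample; the
   multilocus strings define chlorotypes, single-linkage collapsed at ≤ 1
   mismatch. The chloroplast is maternally inherited: if exactly one
   parental clade has non-hybrid members sharing the hybrid's collapsed
   group, that clade is the female parent. If both share it the direction is
   reported `UNKNOWN`; if neither, `UNKNOWN` with the nearest clade and its
   distance — the package reports the evidence rather than reproducing a
   narrative judgement.

An outlier counts as a *confirmed* interspecific hybrid only when its two
haplotype lineages resolve to two distinct clades — the (clade, clade) pair
is the non-hybrid signature, so elevated within-clade diversity alone never
triggers exclusion. Hybrid-free reruns of the trees use the union of known
hybrids and these confirmed outliers. Within-clade hybrids are
out of reach of this design by construction (their d̄ is not elevated), and
that limitation is inherited knowingly.

## Distance trees, bootstrap, ascertainment

Sequence distances are raw p-distances over comparable sites, with
heterozygotes treated as allele draws (a heterozygote against a homozygote
sharing one allele contributes 0.5); array distances are allele-sharing
(1 − IBS). No model correction is applied — at these shallow divergences
p-distances are effectively linear, and the acceptance surface (clade
membership, hybrid placement, branch-length bias) is topology- and
branch-level. Trees are Saitou–Nei neighbour-joining (via ape), with
negative branch estimates clamped to zero and logged. Bootstrap support
(default B = 100) resamples alignment columns or SNPs, rebuilds the tree,
and reports the percentage of replicates containing each internal
bipartition; only column indices are drawn, so supports are invariant to
taxon order. Maximum-likelihood heuristic search is deliberately out of
scope: NJ serves as the tree-building surrogate for both data types.

The ascertainment experiment thins the discovery-panel class of SNPs to a
sequence of targets (defaults proportional to a 12,971 → 7,197 → 3,197 →
2,697-SNP series, i.e. 10,774 → 5,000 → 1,000 → 500 panel SNPs), rebuilds
the NJ tree per set, and summarises per-clade mean root-to-tip path lengths
on the outgroup-rooted tree as ratios to the overall ingroup mean. The
discovery-panel clade starts with a ratio well above 1 and the ratio falls
monotonically as its SNPs are thinned.

## Morphometrics and phylogenetic signal

`prepare_traits()` reduces per-leaf measurements to per-accession medians,
averages left/right paired parameters after the medians, and derives the
circularity Circ = 4π·area/perimeter² (1 for a circle). PCA is scaled to
unit variance by default — the convention of the standard multivariate
packages — with the unscaled variant behind a flag; ordinal OIV codes are
treated as numeric, as is common in ampelography.

Abouheif's test uses the proximity a_ij = 1/∏(direct descendants of the
internal nodes on the tip path); the statistic is the Moran form
C = z'Wz/z'z with row-normalized W, and the one-sided upper p-value comes
from 999 label permutations with the add-one correction (seed default 1).
On a star tree the statistic collapses to −1/(n−1) for any trait — a useful
closed-form check. The pPCA eigen-decomposes t(X)·W_sym·X/n on the centered,
scaled traits with the symmetrized, uniformly row-weighted proximity;
positive eigenvalues are global (clade-level) structures, negative are local
contrasts, and the variant choice is recorded in the output metadata.
Top-loading selection keeps traits below the 10th or above the 90th
percentile of the first-axis loadings.

The phylogeny used for signal analysis is the hybrid-free NJ tree from the
concatenated loci — the pipeline wires it in and records the provenance.

## The synthetic-data generator

`simulate_vitis()` emulates the statistical structure the analysis assumes,
not any particular dataset:

* **Radiation structure.** Five ingroup clades plus an outgroup as a star
  radiation (the rapid-radiation regime such genera show), three species per
  clade, two accessions per species, three outgroup accessions. The
  divergence budget is hierarchical — per-lineage clade 0.006,
  species 0.002 and haplotype 0.002 substitutions/site by default — so
  realized pairwise between-clade divergence matches the configured 0.02,
  within-clade species divergence 0.008, and within-species diversity 0.004.
  Sequences evolve by Poisson numbers of Jukes–Cantor-style point mutations;
  within-species variation uses a star genealogy rather than a full
  coalescent — adequate for the diversity-statistic regimes of interest and
  controllable, but it makes most within-species variants private
  (coalescent haplotype sharing is emulated only at the species level).
* **Loci.** 12 loci of 600 bp (the study scale for multi-locus Sanger
  designs), no recombination within a locus, consistent with short
  amplicons.
* **Hybrids.** F1s draw one haplotype from a fixed donor species in each
  parental clade at every locus and inherit the maternal clade's chloroplast
  haplotype; defaults plant three hybrids between clades, one of them
  pre-labeled as known.
* **SNP array.** 1,200 nuclear SNPs with panel composition 83/14.5/2.5%
  (vinifera/american/muscadinia), each SNP polymorphic only within its
  discovery panel (species- or accession-level placement), plus 2% missing
  calls. 23 chloroplast SNPs carry clade-diagnostic chlorotypes (two
  dedicated sites per clade, so clades are ≥ 4 steps apart) with a one-step
  within-clade variant each; chloroplast calls are complete.
* **Traits.** Brownian motion on the unit-depth species tree plus
  clade-level mean shifts plus i.i.d. noise; OIV codes are the same latent
  model discretised to 1–9. Per-leaf replicates (8 leaves per accession,
  including a left/right angle pair and area/perimeter) feed the
  trait-preparation tests.

What passing tests on this generator show — and what they do not: the
pipeline provably recovers between-clade F1s, their parental clades and
cross directions, and the ascertainment-bias signature under realistic
divergence ratios; it is not evidence about backcrosses, within-clade
hybrids, recombinant amplicons, or base-calling artefacts, none of which the
generator emulates.

## Numerical choices and degenerate inputs

* Quartiles for the outlier fence: linear interpolation (R type 7).
* EM: seed 1, 10 restarts, tolerance 1e-8; exact ties lexicographic.
* Tajima's D is undefined (NA, flagged) at S = 0, never reported as 0;
  a monomorphic locus gets θ_W = π = 0 and He = 0.
* Pairs with zero comparable sites are skipped with a warning in π and are
  an error in distance matrices (a tree cannot be built there).
* Zero-variance traits are dropped before scaled PCA; constant traits are
  flagged NA in the signal test.
* Networks with fewer than two distinct haplotypes are not built.
* Bootstrap supports are only attached for ≥ 4 taxa.

## Problem sizes used by the checks

The packaged checks run at desk scale, chosen so the full suite stays quick
while estimates remain stable: end-to-end hybrid recovery over 50 replicate
datasets at the default conditions above; Abouheif calibration with 1,000
null datasets × 999 permutations on a balanced 32-tip tree and power over
200 Brownian datasets; oracle equivalence for the diversity statistics on
100 fuzzed alignments; Steiner-minimum checks on ≤ 5 haplotypes × ≤ 8
sites; ascertainment monotonicity over 20 replicate datasets. The
acceptance script reruns the pipeline once and the hybrid-recovery loop
over 10 datasets.

## Known limitations

* Within-species genealogies are star-shaped in the generator; diversity
  statistics on simulated data therefore sit in a skewed (negative-D)
  regime, as real radiation data often do, but neutral-equilibrium
  calibration tests use a separate coalescent harness.
* Frequency-EM phasing cannot orient population singletons; parental-clade
  assignment is insensitive to this, but haplotype networks of very rare
  variants inherit the arbitrary (deterministic) orientation.
* The median-joining search is a heuristic; optimality is verified only at
  oracle scale.
* pPCA is implemented in one variant (symmetrized proximity, uniform row
  weights); other row-weighting conventions exist and give slightly
  different eigenvalues.
* Detection is designed for between-clade F1s; later-generation backcrosses
  and within-clade hybrids are out of scope.
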