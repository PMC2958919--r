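---
title: "Delimiting species and diagnosing introgression with dominant multilocus markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting species and diagnosing introgression with dominant multilocus markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aflpdelim)
```

## The problem

In a recent radiation, a single-locus gene tree (typically
mitochondrial) often conflicts with morphology: several species come
out para- or polyphyletic. Three processes produce that pattern —
inadequate taxonomy, incomplete lineage sorting (ILS) of ancestral
polymorphism, and introgression — and they demand different taxonomic
and evolutionary conclusions. Genome-wide dominant markers (AFLP)
carry the complementary signal: if morphology-defined species form
separate genotypic clusters in the multilocus data, taxonomy is not
the culprit, and the combination of (i) the depth of the discordant
coalescences in the gene tree, (ii) the geography of the specimens
carrying shared haplotypes and (iii) admixture scans of the nuclear
markers can separate ILS from introgression. This package implements
that workflow end to end, plus the generators needed to test it
without any external data.

## Data model

An `AFLPMatrix` is a specimens × markers table over {present, absent,
missing}. Missing is a first-class state: it is written as `?`,
stored as `NA`, and never silently collapsed to absence anywhere in
the pipeline. Marker labels encode primer combination and fragment
size (`"PC1_142"`); parseable sizes are validated against the 70–322
base scoring window within which dominant fragments are reproducible.
A specimen with no present band cannot be a real AFLP profile; such
rows are flagged on construction and rejected by `jaccardMatrix()`.

## Distances, trees, networks

**Jaccard distances.** For dominant data only band sharing is
informative — a shared absence may be two different recessive states —
so the distance between specimens is `1 − a/(a + b + c)` over the loci
scored in *both* specimens (pairwise deletion; the choice is ours to
make, as standard practice, because marker software conventions vary).
A pair with empty presence union has no defined distance and raises an
error naming the pair.

**Neighbor-joining.** Saitou–Nei agglomeration with the Q-criterion.
Two conventions are pinned down so the output is reproducible:
Q-minimum ties join the lowest-index pair, and a negative branch
length is clamped to zero with the deficit moved to its sister edge so
the joined pair's path length is preserved (the Kuhner–Felsenstein
convention). On additive input the tree and its branch lengths are
recovered exactly (tested against random generating trees and
`ape::nj`). Bootstrap support resamples marker *columns* (loci are the
exchangeable units; specimens are not), rebuilds the NJ tree, and
counts bipartitions of the point-estimate tree, reported as
percentages on the node labels.

**Neighbor-net.** The circular ordering comes from the Bryant–Moulton
two-stage agglomeration (provided by `phangorn`); split weights are
then estimated in this package by non-negative least squares over all
`n(n−1)/2` splits compatible with the ordering, dropping splits at or
below `1e-8` of the total weight (the numerical floor of the NNLS).
On circular-decomposable input the weighted splits reproduce the
distances exactly; on tree metrics the splits are the tree's
bipartitions with branch lengths as weights. The dense all-splits
design matrix grows as `O(n⁴)` entries, which is comfortable up to
roughly a hundred taxa — the scale of a single-radiation dataset.

## Gaussian clustering with a noise component

Model-based clustering needs metric coordinates, so the Jaccard
distances are first embedded by non-metric MDS; four dimensions is the
established recommendation for dominant markers and the default.
The optimizer is SMACOF majorization alternating with monotone
(isotonic) regression, with disparities normalized to fixed norm; the
internally monitored normalized stress is non-increasing by the
majorization argument (asserted in the tests), and the reported value
is Kruskal's stress-1. Defaults: 20 starts (one classical-scaling
start, the rest random Gaussian), tolerance `1e-6` on the stress
decrease, 500 iterations maximum. Ties in the dissimilarities are
handled by the primary approach (tied blocks ordered by current
configuration distance). If `dim ≥ n` the fit is degenerate by
construction and returns stress 0 with a warning.

A known property of ordinal scaling deserves a flag: when the data are
strongly discrete (tight, well-separated clusters), stress-1 admits
near-zero "collapsed" solutions in which each cluster shrinks to a
point. Our cleanly simulated recovery data reaches such solutions;
empirical matrices with within-cluster spread do not, and give stress
in the 10–15% range. The collapse does not harm cluster recovery — it
*is* the cluster structure — but the stress value should not be read
as a quality score when it is near zero.

The mixture stage fits, for every cluster count `k` in the scan range
and four covariance families (spherical-equal, spherical-varying,
diagonal-varying, full-varying — the sphere-to-ellipsoid spectrum at
tractable parameter counts in four dimensions), an EM model
initialized from model-based hierarchical clustering, and selects the
model maximizing `BIC = 2·logL − params·ln n`. The EM backend is
`mclust`, the reference implementation of exactly this procedure;
models whose covariance degenerates are skipped and logged. With
`noise = TRUE` a uniform component over the axis-aligned bounding box
is added, initialized by Byers–Raftery nearest-neighbour cleaning:
the `k`-th nearest-neighbour distances (default `k = 5`) are
transformed so that a homogeneous Poisson process makes them
Gamma-distributed, a two-component Gamma mixture is fitted by EM, and
the sparser component is flagged as noise. The pure-noise model
(`k = 0`, zero free parameters, `BIC = 2·logL`) enters the comparison
so uniform scatter is not forced into spurious clusters. The scan
upper bound defaults to `min(100, n − 1)` with no early stopping.

## Bayesian assignment for dominant phenotypes

The default likelihood treats each marker as one dominant bit per
specimen: cluster `k` carries a band frequency `p_kl ~ Beta(1, 1)`
and a band is `Bernoulli(p_kl)`. This "phenotype" coding is the
minimal faithful treatment of one-bit dominant data. Because one may
instead read a band as a dominant phenotype over two Hardy–Weinberg
allele copies (`Pr(band) = 1 − (1 − p_kl)²`), that "recessive"
interpretation is available as `model = "recessive"`, implemented by
latent allele-copy augmentation; both interpretations are runnable
because the original analyses of dominant data do not typically state
which coding was used.

Without admixture, specimens carry a single cluster label with a
uniform prior, Gibbs-updated jointly with `p`. With admixture each
specimen has ancestry `q_i ~ Dirichlet(α, …, α)` and each scored cell
a latent cluster of origin; `α` is shared and updated by a Metropolis
step (Gaussian proposal, default step 0.025, uniform prior on
(0, 10], initial 1) unless fixed. Missing cells are skipped in the
likelihood and in the ancestry counts.

The evidence estimate per run is `L(K) = mean(lnL) − var(lnL)/2`
(population variance) over the thinned post-burn-in trace. The
recorded `lnL` integrates the discrete latent assignments out of the
likelihood — `Pr(X|P)` without admixture, `Pr(X|P,Q)` with — because
the less skewed the trace, the more accurate this Gaussian-flavoured
approximation is. Its residual bias grows with the information per
cell: on tiny enumerable matrices (3×3, 3×4) the estimate sits within
about 0.4 log units of the exact brute-force marginal (tested), while
dense 4×4 patterns can push the joint-trace variant beyond a full log
unit. Treat `L(K)` as a comparison statistic across `K`, not as a
calibrated marginal likelihood.

`ΔK` follows Evanno's construction exactly: per-run absolute second
differences of `L(K)`, averaged over runs, divided by the sample
standard deviation of `L(K)` across runs; `ΔK` is undefined at the
boundary `K` values and wherever the across-run spread is zero (those
`K` are flagged and excluded from the argmax). Defaults mirror the
protocol of the study design this package serves: 10 runs of 100,000
iterations after 10,000 burn-in for the `K` scan, 5 runs for pairwise
admixture scans, thinning 10. The test suite and acceptance script
use scaled-down chains (400–8,000 sweeps on matrices up to 90 × 300),
which the recovery experiments show are ample at those sizes.

Pairwise admixture scans restrict the matrix to two species, fit
`K = 2` with admixture, keep the best of the runs by `L(K)`, anchor
clusters to species by majority assignment, and report each
individual's ancestry in its own species' cluster; a foreign ancestry
above the threshold (below) is the admixture criterion for the
discordance classifier.

## Dirichlet-process clustering

The number of clusters and the assignment are jointly given a Chinese
restaurant process prior with concentration `α`, and the Bernoulli
phenotype model is collapsed analytically (Beta-binomial
predictives), so a single Gibbs scan reseats each specimen into an
existing cluster with probability ∝ size × predictive, or a new one
with probability ∝ `α` × prior predictive. With zero markers the
sampler targets the CRP prior exactly, which the tests exploit as the
module's strongest oracle (unsigned-Stirling closed form). The chain
starts from the all-singletons partition: single-element moves merge
clusters easily but can essentially never nucleate a cluster out of a
large mixed one (the proposal must pass through a one-specimen
cluster whose predictive is hundreds of log units below), so the
fragmented start is the choice that lets the sampler find concentrated
posteriors. `α` defaults to the value solving
`E[k | α, n] = Σ α/(α+i) = 5`, making the prior explicit and
reproducible; it can be set directly, and scanning a list of prior
means is the supported sensitivity analysis because posterior cluster
counts from under-specified priors deserve scrutiny rather than trust.

The mean partition minimizes the summed partition distance (minimum
number of reassignments, computed as `n` minus a maximum-weight
bipartite matching of clusters) to the sampled partitions; the search
hill-climbs by single-element reassignment from the best sampled
partitions (10 restarts). On problems small enough to enumerate all
partitions the search is exact, which the tests verify.

## Concordance and the three criteria

`assessMonophyly()` classifies each species in a rooted gene tree as
monophyletic, paraphyletic (its intruders form a single clade) or
polyphyletic, reporting intruder tips (foreign tips inside the
species' MRCA clade) and outlier tips (conspecific tips outside the
species' largest pure clade). `coalescenceDepthProfile()` assigns
each discordance event the height of the smallest clade joining the
discordant tip to heterospecific neighbours, divided by root height;
heights are maximum root-to-tip paths, so no ultrametricity is
assumed, and the profile is scale-invariant. Flagged outgroup tips
are excluded from the root-height normalization.

`classifyDiscordance()` applies the decision table: relative depth ≥
0.5 and maximum foreign ancestry < 0.10 → incomplete lineage sorting;
shallow depth with admixture → recent divergence or introgression
(deliberately left unresolved — both a narrow hybrid zone and
peripatric origin produce this signature); the two conflicting
combinations, or a missing admixture analysis, → ambiguous. The 0.5
and 0.10 thresholds are declared conventions, configurable and
reported with the labels, because the underlying criteria are
qualitative; making them explicit is what makes the classifier
testable. The geographic criterion (mean great-circle distance among
carriers of shared haplotypes versus the species' range span) is
reported as a score, never gated on, because a concentration of
shared markers near a range boundary can equally reflect a
pre-existing cline in the ancestor.

## Composition diagnostics

The chi-square test compares each taxon's A/C/G/T counts (gaps and
ambiguity codes excluded) with the pooled composition,
`df = (taxa − 1) × 3`; it ignores phylogenetic correlation, which is
why the matched-pairs (Bowker) test of symmetry accompanies it: for
each taxon pair, over columns where both taxa are unambiguous
(pairwise deletion), `Σ (n_ij − n_ji)²/(n_ij + n_ji)` across
discordant off-diagonal state pairs, `df` equal to their number. The
per-class percentage of significant pairs uses p < 0.05 to match the
conventional summary; the threshold is settable. RY recoding pools
purines and pyrimidines at selected codon positions (gaps kept,
existing R/Y kept, anything else to N); after recoding, the symmetry
table collapses to at most one discordant pair and the chi-square df
to `taxa − 1`. Codon classes derive from the alignment's declared
`frameOffset` — the reading frame is a required user input, since a
fragment's frame cannot be inferred from the alignment itself.

## What the generators emulate — and what they do not

`simulateAFLP()` draws population band frequencies from the
Balding–Nichols construction (`Beta(p₀(1−F)/F, (1−p₀)(1−F)/F)`,
mean `p₀`, variance `F·p₀(1−p₀)`), matching the
correlated-frequencies assumption behind Bayesian assignment; default
conditions are three populations of 30 specimens, 300 markers,
`F = 0.5`, per-locus `p₀ ~ U(0.1, 0.9)` — a strongly drifted,
well-sampled radiation. Emission is haploid-band by default, with the
dominant-diploid option for the recessive reading. Outliers are
uniform-profile specimens, i.e. exactly the target of the noise
component. Not emulated: AFLP size homoplasy (co-migrating
non-homologous fragments), scoring error, or linkage — so passing
recovery tests demonstrates correctness of the inference machinery,
not robustness to those artefacts.

`simulateCoalescentTree()` runs a multispecies coalescent on a ladder
species tree (species joined in order at the given divergence times),
constant population size `N`, time units where the pairwise
coalescence rate is `1/N` (`E[T₂] = N`); an introgression event moves
each live recipient lineage to the donor with the given probability —
recent events thus produce shallow discordant coalescences, ancestral
polymorphism deep ones. `simulateCompositionAlignment()` draws
columns i.i.d. (a shared fraction identical across taxa, the rest
from per-taxon compositions); it exercises the symmetry statistics
without modelling phylogenetic correlation, and tree-based
nonstationary simulation is out of scope.

## Numerical choices and degenerate inputs

* Beta/probability draws are clamped to `[1e-12, 1 − 1e-12]` before
  logs.
* Modal-assignment ties break toward the lower cluster label; NJ
  Q-ties toward the lowest-index pair.
* The NNLS split filter is relative (`1e-8` of total weight).
* Zero-marker matrices are valid inputs to the samplers (prior-only
  runs); empty matrices, `K < 1`, `burnIn ≥ iterations`, empty traces,
  empty partition samples, `kNN ≥ n` and zero root height all raise
  immediate errors.
* Fixed seeds make every generator and sampler bit-reproducible; the
  acceptance script threads one seed through every stage.

## Limitations

Ordinal-MDS collapse on discrete data (above); evidence-estimate bias
on information-dense cells (above); the Dirichlet-process sampler
relies on the fragmented start rather than split-merge moves, so
posteriors on data with very weak structure mix slowly; the
mean-partition search is heuristic beyond enumerable sizes; the
discordance classifier encodes qualitative criteria as explicit
thresholds and should be read accordingly. Formal model-based
ILS/introgression tests (D-statistics, coalescent model choice) and
gene-tree inference itself are out of scope: trees enter as newick.
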