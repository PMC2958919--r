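# aflpdelim

Species delimitation and introgression inference from dominant
multilocus markers (AFLP), for systematists working on recent
radiations where a gene tree, morphology and genome-wide markers
disagree.

When closely related species are nonmonophyletic in a mitochondrial
gene tree, three processes can be responsible: inadequate taxonomy,
incomplete lineage sorting (ILS) of ancestral polymorphism, or
introgression. `aflpdelim` implements the multilocus workflow that
discriminates among them with dominant presence/absence markers:

* **Distances and networks.** Jaccard distances
  `d = 1 − a/(a + b + c)` (shared presences `a`, private presences
  `b`, `c`; shared absences ignored; missing cells pairwise-deleted),
  neighbor-joining with marker bootstrap, and neighbor-net split
  networks (circular ordering by the Bryant–Moulton agglomeration;
  split weights by non-negative least squares over all splits
  compatible with the ordering).
* **Three genotypic-cluster delimitation methods.**
  (1) Gaussian clustering: 4-dimensional non-metric MDS of the
  Jaccard distances followed by Gaussian mixture fitting with BIC
  selection (`2·logL − params·ln n`, maximised) over 0–100 clusters,
  optionally with a uniform noise component for outliers initialised
  by Byers–Raftery nearest-neighbour cleaning.
  (2) Bayesian assignment for dominant phenotypes with and without
  admixture (Gibbs sampler; cluster band frequencies `p_kl ~
  Beta(1,1)`; ancestries `q_i ~ Dirichlet(α)`), with the evidence
  estimate `L(K) = mean(lnL) − var(lnL)/2` and Evanno's
  `ΔK(K) = mean_r|L_r(K+1) − 2L_r(K) + L_r(K−1)| / sd_r L(K)`.
  (3) Dirichlet-process clustering (collapsed Chinese-restaurant-
  process Gibbs sampler) with the posterior over the number of
  clusters and a mean-partition summary (minimum summed partition
  distance).
* **Discordance diagnosis.** Per-species monophyly assessment in a
  gene tree, relative coalescence depths of discordant haplotypes,
  pairwise `K = 2` admixture scans, and a three-criterion
  classification: deep coalescence without admixture → ILS; shallow
  coalescence with admixture in neighbouring individuals → recent
  divergence or introgression; conflicting signals → ambiguous.
* **Alignment composition diagnostics.** Chi-square homogeneity test
  of base composition across taxa, matched-pairs (Bowker) tests of
  symmetry per codon-position class, RY recoding.
* **Synthetic data.** Balding–Nichols AFLP matrices with known
  ancestry (`p_kl ~ Beta(p₀(1−F)/F, (1−p₀)(1−F)/F)`), multispecies
  coalescent gene trees with optional introgression events, and
  alignments with taxon-specific base composition — so every stage is
  testable without downloads.

## Worked example

Simulate three drifted populations and run all three delimitation
methods:

```r
library(aflpdelim)
sim <- simulateAFLP(PopModel(K = 3, L = 300, F = 0.5, nPerPop = 30,
                             seed = 1))
sim$aflp
#> AFLPMatrix: 90 specimens x 300 markers
#>   present: 13478  absent: 13522  missing: 0
#>   metadata columns: specimen_id, species_label, locality_code, ...

d   <- jaccardMatrix(sim$aflp)
emb <- nmdsEmbed(d, dim = 4, starts = 10, seed = 1)
fit <- fitGaussianMixtureBIC(emb, kRange = 1:12, seed = 1)
fit
#> GaussianMixtureFit: k = 3 (VVV), BIC = 5828.20
#>   [2*loglik - params*ln n, maximize]

ps <- dppGibbs(sim$aflp, alpha = 1, cycles = 1200, sampleEvery = 5,
               burninSamples = 40, seed = 1)
ps
#> PartitionSample: 200 sampled partitions of 90 specimens
#>   P(k): k=3:1.000
meanPartition(ps)
#> SpecimenPartition: 90 specimens in 3 clusters
#>   sizes: 30 30 30

lnP <- structureKScan(sim$aflp, Ks = 1:5, runs = 4,
                      iterations = 400, burnIn = 150, thin = 5,
                      seed = 1)
dk <- evannoDeltaK(lnP)
round(dk$deltaK, 2)
#> [1]    NA  1.63 25.76  2.52    NA
attr(dk, "bestK")
#> [1] 3
```

All three methods recover the three generating populations: the BIC
scan selects `k = 3`, the Dirichlet-process posterior puts probability
1.000 on three clusters, and `ΔK` peaks at `K = 3`. (The near-zero
NMDS stress reported for this simulation is the known behaviour of
ordinal scaling on strongly discrete data — tight clusters collapse to
points; field data with within-cluster spread gives stress around
10–15%.) The adjusted Rand index of the mean partition against the
simulated truth is 1.

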