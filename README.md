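# mitophylo

Phylogeographic analysis of human mitochondrial DNA in R. The package
covers the statistical workflow used to characterise matrilineal gene
pools from mtDNA resequencing data: reference-relative variant handling,
haplogroup classification against motif trees, most-parsimonious haplotype
trees, rho-statistic coalescence dating, haplotype diversity and
neutrality statistics, and population structure by FST/MDS/PCA — plus
seeded synthetic-data generators so every stage is testable without any
external download.

It is aimed at population geneticists working with control-region or
complete mtDNA sequences aligned to the standard 16,569-np coordinate
frame.

## The statistics at the core

* **Rho dating.** For a clade with $n$ tips,
  $\rho = n^{-1}\sum_i l_i n_i$ over branches $i$ carrying $l_i$
  clock-qualified mutations and subtending $n_i$ tips, with Saillard error
  $\sigma = n^{-1}\sqrt{\sum_i l_i n_i^2}$. Ages are
  $\rho \times$ years-per-mutation under three fixed calibrations: 3624 y
  (complete genome), 4610 y (coding region), 7884 y (synonymous changes).
* **Ewens sampling formula.**
  $P(K \mid \theta, n) = |S_1(n,K)|\,\theta^K / \prod_{i=0}^{n-1}(\theta+i)$,
  evaluated in log space; $\hat\theta_k$ solves
  $\sum_{i=0}^{n-1}\theta/(\theta+i) = K$ and its 95% CI inverts the
  distribution's tails. Fu's $F_s = \ln(S'/(1-S'))$ with
  $S' = P(K' \ge K_{obs} \mid \theta = \Pi)$; Tajima's
  $D = (\Pi - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$.
* **Parsimony.** Binary presence/absence characters on a non-recombining
  genome; perfect-phylogeny backbone plus greedy recurrent-event
  placement, with final event assignment by exact per-site small
  parsimony, and an exhaustive optimality oracle for up to 7 samples.
* **Structure.** Hudson-style
  $F_{ST} = (\pi_B-\bar\pi_W)/\pi_B$ from mean pairwise differences,
  Kruskal stress-1 nonmetric MDS, covariance PCA of haplogroup frequency
  vectors.

Variants use the community token dialect (`16189` transition, `408A`
stated derived base, `8278.1C` insertion, `8281-8289d` deletion, `16311!`
back mutation). A synthetic reference genome with the canonical gene map
ships with the package (see the methods vignette for exactly what is and
is not faithful to the real sequence).

## Worked example

```r
library(mitophylo)

# Published haplogroup counts for two populations (149 + 98 samples)
ft <- readFrequencyTable(system.file("extdata",
        "published_haplogroup_counts.tsv", package = "mitophylo"))
cm <- read.delim(system.file("extdata", "eurasian_components.tsv",
        package = "mitophylo"), comment.char = "#")
round(componentShares(ft, cm), 1)
#>         Barghuts Altaian_Kazakhs
#> eastern     91.9            60.2
#> western      8.1            39.8

# Ewens theta from the observed number of haplotypes (n = 149, K = 97)
tk <- thetaK(149, 97)
sprintf("theta_k = %.2f (95%% CI %.2f-%.2f)", tk$theta, tk$ciLow, tk$ciHigh)
#> "theta_k = 119.43 (95% CI 82.59-174.06)"

# Date a simulated founder clade (true age 18,120 y, complete-genome clock)
sim <- simulateStarClade(n = 50, ageYears = 18120, seed = 1)
est <- rhoStatistic(sim$tree)
est
#> RhoEstimate root | rho = 5.2400 +/- 0.3237 | n = 50 | clock = complete_genome
ageEstimate(est)$kya
#> 19

# Expansion signature in a coalescent sample
ex <- simulateCoalescentSample(n = 50, theta = 5, model = "expansion", seed = 1)
c(D = tajimasD(ex$sample), Fs = fusFs(ex$sample))
#>     D        Fs
#> -1.46     -3.03

fisherExact2x2(13, 136, 1, 97)   # haplogroup G2, 13/149 vs 1/98
#> 0.010
```

The component shares say 91.9% of the first population's lineages belong
to eastern-Eurasian haplogroups versus 60.2% in the second; the dated
star clade recovers its true 18.1-kya age within one standard error; the
expansion sample shows the negative Tajima's D / Fu's Fs signature of
recent growth; and the G2 frequency difference is significant at P = 0.01.

A full pipeline run (classification, frequencies, diversity, tree, dating,
FST/MDS) is one call:

```r
runPipeline(list(profiles = "profiles.tsv", outDir = "out", seed = 1))
```

or from a shell via `inst/scripts/run_pipeline.R --config run.cfg`.

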