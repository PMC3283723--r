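---
title: "Methods: mtDNA phylogeography with mitophylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtDNA phylogeography with mitophylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitophylo)
```

# Scope and data model

`mitophylo` implements the statistical core of a human mitochondrial DNA
(mtDNA) phylogeography study: variants called against the 16,569-np
reference coordinate frame are classified into haplogroups, arranged into
most-parsimonious trees, dated with the rho statistic under calibrated
mutation clocks, and summarised per population with diversity and
neutrality statistics and FST/MDS/PCA ordination. The currency of every
module is the *mutation event*: a reference-relative transition,
transversion, insertion or deletion, written in the community's token
dialect (bare position = transition, position+base = stated derived base,
`"8278.1C"` = insertion, `"8281-8289d"` = span deletion, `"!"` = back
mutation).

## The synthetic reference

The package ships a deterministic *synthetic* reference genome
(`inst/extdata/synthetic_mtref.fasta`, regenerable with
`inst/scripts/make_synthetic_reference.R`) rather than the real reference
sequence. Coordinates, region bounds, gene order (13 protein genes with the
ATP8/ATP6 and ND4L/ND4 overlaps, ND6 on the light strand, two rRNAs, tRNA
blocks), the 9-bp COII/tRNA-Lys repeat, and a handful of pinned bases that
the packaged haplogroup fixture relies on are all faithful to the canonical
map; the remaining base identities are a seeded random draw with a
human-mtDNA-like composition. Every coordinate-dependent computation
(masking, clock counting, synonymy against this annotation, region windows)
is therefore exact and testable, while base-level identity with the real
genome is explicitly *not* claimed — analyses of real data should supply
their own reference via the `reference` arguments.

## Regions, the exclusion mask and clocks

Default analysis windows are HVS1 16024–16400, HVS2 57–372, coding
577–16023, complete 1–16569; all are overridable with explicit bounds. HVS1
sequencing in the motivating study extended below np 16024, but the
canonical HVS1 bound was chosen as the analysis default because positions
upstream are outside HVS1 proper; the window is a parameter, not a
constant.

The phylogenetic exclusion mask removes np 16519 for all event kinds, and
point indels and transversions (transitions are retained) in the
hypermutable stretches 16180–16193, 303–315, 522–524 and 960–963. The mask
is applied to phylogeny and dating inputs, not to classification motifs:
published haplogroup diagnostics (e.g. the B-defining transition at 16189)
live inside masked ranges, so masking motifs would destroy classification.

Three fixed linear clocks convert mutation counts into years: one mutation
per 3624 years (complete-genome substitutions), 4610 years (coding-region
substitutions, np 577–16023) and 7884 years (synonymous substitutions
only). Indels never qualify for any clock. Synonymy is decided under the
vertebrate mitochondrial code; at positions covered by overlapping protein
genes a change is called synonymous only if it is synonymous in *every*
overlapping frame (the conservative convention in mtDNA rate work), and
light-strand genes are evaluated on the complementary strand.

# Haplogroup classification

A haplogroup tree is a set of named nodes, each with defining mutations;
the *cumulative motif* of a node is the union of defining events on the
root-to-node path, with a `!`-flagged event cancelling its ancestral
counterpart. A profile is scored against every node as
(matches − mismatches) over the node's motif restricted to positions
observable in the profile's region; the best-scoring node wins, ties are
broken deterministically (shallower node, then lexicographic) and flagged
`ambiguous` rather than hidden. Private mutations never affect the score,
so adding them never changes the assignment — a property the suite tests.

The packaged tree (`fixtureHaplogroupTree()`) is deliberately minimal: it
encodes only partial motifs published in the text it models (subclades such
as B4j, B4b1a3a, B4c1a2, N9a3a, M10a1a2a, M11b2, M13a1b, R11b1), plus a
macrohaplogroup scaffold, and is marked illustrative. It is sufficient for
fixtures and synthetic mixtures, not a nomenclature reference.

# Most-parsimonious trees

Each distinct variant token is treated as a binary presence/absence
character with the ancestral state given by the root profile — appropriate
for a non-recombining genome where incompatibility between characters
implies homoplasy. `buildMpTree()`:

1. orders sites by derived-carrier count (ties: position, then token);
2. builds a perfect-phylogeny backbone from the sites whose carrier sets
   are pairwise nested or disjoint (the laminar family of clusters);
3. greedily decomposes each incompatible site over existing clades, which
   is what placing it as recurrent events means;
4. finally re-assigns *all* sites on the fixed topology by exact binary
   small parsimony (dynamic programming with the root state fixed,
   deterministic tie-break toward the parent state).

Step 4 guarantees the published contract: the reported score is attained by
the returned tree, equals `parsimonyScore()` recomputed on it, never beats
the global optimum, and equals the optimum whenever a perfect phylogeny
exists. `exhaustiveMp()` certifies optimality for up to 7 samples by
enumerating all rooted binary topologies ((2n−3)!! of them) and scoring
each with the same exact per-site dynamic program; multifurcations in the
heuristic's output are never resolved artificially. The manual curation of
published trees implies judgement calls about where recurrent mutations
sit; the greedy rule here is one defensible, deterministic formalisation,
not a claimed replica of any curator.

Trees round-trip through an annotated newick dialect in which branch
lengths are event counts and branch mutation tokens ride in `[...]`
comments. Standard newick readers drop comments, which is why the dialect
has its own small reader.

# Rho dating

For a clade with $n$ tips, $\rho = n^{-1}\sum_i l_i n_i$ over branches $i$
($l_i$ clock-qualified events, $n_i$ tips subtended) — the mean number of
mutations from the clade root to its tips — and the Saillard error is
$\sigma = n^{-1}\sqrt{\sum_i l_i n_i^2}$. Ages are the linear conversion
$\rho \times$ years-per-mutation, with the reported range
$(\rho \mp \sigma)$ converted the same way; published "error ranges" of
this kind are not explicit about their coverage, so the package computes
and labels a one-standard-error range. $\rho$ depends only on root-to-tip
distances (so it is topology-invariant given those distances) while
$\sigma$ grows when deep branches are shared; both facts are tested. No
time-dependent rate correction is applied — the three fixed calibrations
are the model.

# Diversity and neutrality statistics

Computed on a binary site-by-individual incidence matrix. By default,
substitutions only — indels are excluded from S, Pi, D and Fs, matching the
exclusion philosophy of the phylogenetic mask and the default behaviour of
the standard analysis software; `includeIndels = TRUE` treats indel tokens
as extra binary sites.

* Haplotype diversity $H = n(1-\sum p_j^2)/(n-1)$ with Nei's sampling
  standard error; $K$ distinct haplotypes; $S$ segregating sites; $\Pi$
  mean pairwise differences with the no-recombination (total) variance
  standard error.
* Ewens $\hat\theta_k$ solves $\sum_{i=0}^{n-1}\theta/(\theta+i)=K$
  (uniroot, tolerance $10^{-6}$); its 95% CI inverts the Ewens
  distribution of $K$: the bounds are the $\theta$ values at which the
  upper/lower tail probability of the observed $K$ equals 0.025. The exact
  inversion algorithm used to produce published CI bounds of this kind is
  not documented; the package's bounds are exact for the stated criterion
  but may differ from other software by a few percent.
* The Ewens probabilities use unsigned Stirling numbers of the first kind
  computed by the two-term recursion entirely in log space (log-sum-exp),
  since $n \approx 150$ overflows fixed precision; the distribution
  normalises to 1 within $10^{-10}$ up to $n = 200$.
* Tajima's $D$ uses the 1989 constants; undefined at $S=0$.
* Fu's $F_s = \ln(S'/(1-S'))$ with
  $S' = P(K' \ge K_{obs} \mid \theta = \Pi)$ summed in log space. This is
  the exact evaluation of the definition; implementations that truncate
  the tail or work in fixed precision can report substantially less
  extreme values for large $n$, so cross-package numerical agreement on
  $F_s$ should not be expected even when $n$, $K$ and $\Pi$ agree.
* Fisher's exact two-tailed test delegates to the standard hypergeometric
  enumeration (`stats::fisher.test`), with an independent enumeration
  oracle in the tests.

Missing data: profiles carry no per-site missingness (ambiguity codes are
dropped at variant calling), so pairwise-deletion versus complete-deletion
distinctions do not arise in the packaged path; callers aligning real
sequences should be aware calls at ambiguous bases are simply absent.

# FST and ordination

Pairwise FST is the Hudson-style
$(\pi_B - \bar\pi_W)/\pi_B$ from mean pairwise haplotype differences (plain
number-of-differences distance, no substitution-model correction). This is
deliberately the simplest estimator that can be verified by hand; it is an
approximation to AMOVA-style estimators and can return small negative
values, which are reported raw and floored at zero only for ordination
input. Nonmetric MDS minimises Kruskal stress-1 via vegan's monotone
regression majorization, started from the classical-scaling configuration
plus 8 seeded random restarts (local minima are real even for small
matrices); the best configuration is kept. PCA is the eigen-decomposition
of the covariance of the column-centred (unscaled) frequency matrix, as is
conventional for haplogroup frequency vectors.

# Synthetic data: what it emulates and what it does not

The generators define the conditions under which the pipeline is tested:

* `simulateStarClade()` — a founder clade of age $T$: each lineage carries
  Poisson($T$/rate) transitions at distinct positions (infinite sites
  across the clade, masked points excluded). With the complete-genome
  clock and $T = 18{,}120$ y the per-lineage expectation is 5 mutations;
  over 200 seeds with $n = 50$ the mean $\hat\rho \times 3624$ recovers
  $T$ within 5% and the one-sigma range covers the truth in roughly the
  nominal fraction (the acceptance bound of 60% allows for the Poisson
  skew of small counts).
* `simulateCoalescentSample()` — Kingman genealogy with mutation rate
  $\theta/2$ per lineage per $2N$ generations. The sudden-expansion model
  (relative size 1 after the change, 1/factor before it; defaults: onset
  0.05 and factor 100, a strong post-glacial-style expansion) compresses
  ancient coalescences into a star-like burst and yields the classic
  signature the study reports from real data: strongly negative Tajima's
  $D$ and Fu's $F_s$. Neutral constant-size samples at $n = 50$,
  $\theta = 5$ centre $D$ near zero (the small negative bias of $D$'s
  skewed null is expected and is inside the $\pm 0.15$ calibration band).
* `simulateAdmixedPopulation()` — haplogroup mixtures: each individual
  inherits a node's cumulative motif plus Poisson(1) private mutations at
  motif-free positions, with truth labels retained.

What passing these tests shows: the estimators are unbiased and correctly
calibrated *under their own model assumptions* (infinite sites, no rate
heterogeneity beyond the optional hotspot weights, no selection, no
recombination, complete motifs present in profiles). What they do not
show: robustness to real mtDNA mutational spectra, hypervariable-site
homoplasy beyond what the mask removes, partial or erroneous motifs, or
sequencing error. Problem sizes in the shipped suite (e.g. 200 dating
seeds, 1000 neutral and 500 expansion replicates, exhaustive-search
instances up to $n = 7$) were chosen as the smallest sizes at which the
stochastic bounds are statistically meaningful.

# Numerical and design choices

* All tie-breaks are deterministic and documented (site ordering, cluster
  attachment, parsimony traceback toward the parent state, assignment
  tie-breaks by depth then name); reruns with one seed are byte-identical,
  which the pipeline test enforces.
* Degenerate inputs return documented sentinels rather than guesses:
  $D$ and $F_s$ are `NA` without polymorphism, $\hat\theta_k$ is 0 at
  $K=1$ and `Inf` at $K=n$, the all-zero distance matrix ordinates to the
  null configuration with a warning, and FST of identical samples is 0.
* `runPipeline()` is a thin, deterministic orchestrator: every stage is a
  call into the functions above, outputs are TSV with a run log carrying
  the package version and seed, and any stage failure aborts with a
  stage-tagged error. A counts-only mode reproduces frequency and
  component-share tables directly from a published count matrix.

# Known limitations

The haplogroup fixture is partial by construction; classification quality
on real data is bounded by motif completeness of the tree supplied. The
parsimony heuristic is exact only on homoplasy-free data — on saturated
instances it can exceed the optimum (never undercut it). FST here is not
the AMOVA estimator, and the $\theta_k$ CI algorithm is the package's own
exact inversion. The synthetic reference supports every computation except
base-identity claims about real positions.
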