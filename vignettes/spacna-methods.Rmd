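---
title: "Allele-specific copy number and clone phylogeography from spatial transcriptomics: models and methods"
author: "spacna authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spacna methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

spacna infers allele-specific copy number aberrations (CNAs), spatially
coherent cancer clones, per-spot tumor proportions and a clone
phylogeography from spot-level spatial transcriptomics (SRT) data. Its
inputs are a gene x spot transcript count matrix $X^0$, SNP x spot allele
count matrices $Y^0$ (UMIs supporting population-phased haplotype 1) and
$D^0$ (total UMIs at the SNP), spot coordinates $S$ and gene/SNP
annotation. This vignette describes the statistical models behind each
stage, the parameters that matter, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Quality filters

Spots are removed when their transcript UMI total or SNP-covering UMI
total falls below 50 (both thresholds default to 50). Genes are removed
when (1) expressed — count above zero — in fewer than 0.5% of spots,
(2) flagged by a pluggable high-expression outlier detector (the default
is a neighbourhood-density score on log total counts with a configurable
contamination fraction; any function from per-gene totals to a logical
vector can be substituted), or (3) carrying an immunoglobulin or HLA flag,
since those loci vary strongly without CNAs. SNPs are kept only when they
fall inside a retained gene's closed interval [start, end] on the same
chromosome and inside no HLA-flagged gene. The 0.5% expression fraction is
evaluated after spot filtering (a convention, noted here because either
order is defensible). The three gene rules are independent predicates, so
the retained set is their intersection and the rules commute.

## Pseudobulk phasing

Population-based phasing is accurate for nearby SNPs but accumulates
switch errors over distance. Because every cell in one tissue carries the
same two haplotypes, pooling allele counts across spots into a pseudobulk
sample $(y^0_g, d^0_g)$ concentrates the signal needed to repair those
errors. The phasing model is a hidden Markov model over SNPs whose hidden
state couples a phase label $h_g \in \{1, 2\}$ with a B-allele-frequency
(BAF) cluster $z_g \in \{1..K\}$:

$$y^0_g \mid h_g = 1, z_g = i \sim \mathrm{BetaBinom}(d^0_g,\ \tau p_i,\ \tau(1-p_i)),$$

with the two shape parameters swapped when $h_g = 2$, so the two phases of
a cluster are mirror images. Transitions factorise into a cluster
self-transition probability $t$ and a phase self-transition probability
$q$. Parameters are estimated by Baum-Welch; the per-cluster BAFs and the
concentration $\tau$ lack closed-form M-steps and are updated by 1-D
numerical maximisation of the expected log-likelihood (a generalised EM
step, so the observed likelihood still increases monotonically — asserted
in the tests at relative tolerance 1e-8). The MAP phase/cluster path is
decoded by Viterbi with ties broken toward the lower-indexed state.

Defaults: $K = 5$ clusters with initial BAFs spread over (0.05, 0.5],
$\tau = 30$, $t = 1 - 10^{-4}$, $q = 1 - 10^{-3}$. Chromosomes are
independent chains: the Markov chain restarts from the uniform start
distribution at every chromosome boundary, and consequently the overall
haplotype orientation is only identified per chromosome (and only where
allelic imbalance exists at all — on fully balanced data the phase
posterior is 0.5 everywhere). All accuracy statements about phasing are
therefore made within allelically imbalanced blocks, up to one global flip
per chromosome.

## Binning and aggregation

Variable-length bins are grown greedily left to right within each
chromosome until the pooled total allele count reaches a minimum (default
300 UMIs); the remainder at a chromosome end forms a final, possibly
deficient, bin. Phased allele counts are then aggregated per bin and spot,

$$D_{j,s} = \sum_{g \in J} D^0_{g,s}, \qquad
  Y_{j,s} = \sum_{g \in J} \left(\mathbb{1}[h_g = 1]\, Y^0_{g,s}
          + \mathbb{1}[h_g = 2]\, (D^0_{g,s} - Y^0_{g,s})\right),$$

and the inferred haplotype 1 is called the B haplotype. Transcript counts
are aggregated by assigning each gene to the bin whose genomic span
contains its transcription start; bin spans form a covering partition of
the chromosome with boundaries midway between adjacent bins' SNPs, so
every gene maps to exactly one bin. Aggregation conserves the total
allele count per spot.

## Baseline and allele-specific-expression mask

Normal (diploid) spots are identified either from supplied tumor
proportions (below 0.5) or by k-means on per-bin phased BAF profiles
(default 5 clusters; uncovered bins imputed at 0.5; the cluster whose
centre deviates least from 0.5 is called normal). Pooled normal transcript
counts give the baseline per-bin expression proportions $\lambda$. Bins
showing allelic imbalance even in normal spots (imprinting, eQTLs) are
CNA-irrelevant and masked: a two-sided exact binomial test of the pooled
normal BAF against 0.5 per bin, Benjamini-Hochberg corrected at level
0.05. This exact test is this package's concrete choice for the masking
rule; it is the minimal test with controlled error for the purpose.

## Joint clone and state inference

The genome of every clone $m$ is described by a path $Z_{\cdot,m}$ over
$K$ copy-number states. Each state $k$ carries a latent read-depth ratio
(RDR) $\mu_k$ — relative total copy number against the diploid baseline —
and a latent BAF $p_k$. The state space is paired by haplotype
orientation: every imbalanced state exists with BAF $p$ and $1 - p$,
sharing one RDR, so the same event on opposite haplotypes in different
clones (a mirrored CNA) maps to mirrored states. The balanced state is
pinned at $(\mu, p) = (1, 0.5)$, anchoring the otherwise scale-free RDR.
Default $K = 7$: one balanced state plus three mirror pairs.

Emissions for spot $s$ at bin $j$ under state $k$ are

* transcripts: negative binomial with mean
  $T_s\, \lambda_j\, \tilde\mu_k(\theta_s) / c_m$ and dispersion $\phi$
  (variance $\mu + \phi \mu^2$), where $T_s$ is the spot total and $c_m$
  a free per-clone scale absorbing the genome-wide expected depth of the
  clone's profile;
* alleles: beta-binomial with mean $\tilde p_k(\theta_s)$ and
  concentration $\tau_{bb}$.

When a tumor proportion $\theta_s$ is available the state parameters are
mixed with the normal state before evaluation:
$\tilde\mu = \theta\mu + (1-\theta)$ and
$\tilde p = (\theta p \mu + 0.5(1-\theta)) / (\theta\mu + 1-\theta)$.
These forms reduce to pure-normal emissions at $\theta = 0$, act unmixed
at $\theta = 1$, and agree with the purity relation below in the LOH
limit ($p = 0$), which is why they were chosen among the possibilities
left open by the model sketch.

Inference is block coordinate ascent on one objective: the sum over spots
of the emission log-likelihood under the spot's clone profile, plus the
state-path transition term, plus a Potts coherence term
$\beta \sum_{(s,s')} w_{ss'} \mathbb{1}[\ell_s = \ell_{s'}]$ over a
spatial neighbour graph. Given labels, the genome axis runs hard
(Viterbi) EM: state paths are re-decoded per clone and chromosome, and
$\mu, p, c, \phi, \tau_{bb}$ and the self-transition probability are
updated by exact conditional maximisation given the decoded paths. Given
states, the space axis runs iterated conditional modes (ICM) sweeps in
spot order with ties to the lowest clone index. Every sub-step ascends
the shared objective, so the reported trace is non-decreasing by
construction — hard EM was chosen over marginal Baum-Welch here precisely
to make the joint ascent exact rather than approximate. ICM is a local
method: it is guaranteed to reach a labelling no single-spot change can
improve, not the global optimum, which is why the fit starts from a
spatially contiguous seeded partition (deterministic region growing from
seeded random spots) rather than a uniform random one.

The neighbour graph is the union of per-slice k-nearest-neighbour graphs
(default k = 6, the hexagonal Visium geometry; weight 1), optional
inter-slice edges from a slice alignment matrix (weight = alignment
mass), and optional expression-space kNN edges with a configurable
weight. The coherence weight defaults to $\beta = 2$ per unit edge
weight; too strong a prior can overrule the data, so it is exposed.

The number of clones is selected by over-specifying the initial count
(default 5) and merging: repeatedly, the pair of clones whose
state-implied (RDR, BAF) profiles differ on the smallest fraction of bins
is merged and the state model refit, while that fraction is below a
threshold. The default threshold is 0.02: duplicate clones fitted on
strong pseudobulks have essentially identical Viterbi profiles (observed
distance ~0), whereas two genuinely distinct clones can differ on only a
few percent of bins when their CNAs are sparse — a single 4-bin event in
a 100-bin genome is 4%. A larger threshold risks cascading genuinely
distinct clones into one; users with very fine subclonal structure should
lower it further. States whose parameters differ by less than 0.02 in
both RDR and BAF are treated as the same state in this comparison, since
mirror pairs that collapse onto BAF 0.5 are duplicated balanced states,
and isolated single-bin differences are ignored as Viterbi decoding
flicker — a real event spans several bins (the phylogeny marker filter
itself requires three), so a one-bin disagreement between two otherwise
identical profiles is decoding noise, not evidence of a distinct clone.

The genome-axis update runs hard (Viterbi) EM rather than marginal
Baum-Welch: re-decoding the MAP path and conditionally maximising the
parameters given it ascend exactly the same joint objective that the ICM
label update ascends, which makes the monotonicity of the outer trace a
theorem rather than an approximation. The phasing HMM, which stands
alone, uses classical (soft) Baum-Welch.

## Tumor proportion from LOH

In a region where the tumor lost one haplotype entirely, a spot mixing a
fraction $\theta$ of tumor (LOH state RDR $\mu$) with normal cells shows

$$f = \frac{0.5\,(1-\theta)}{\theta\mu + (1-\theta)},
\qquad\text{inverted as}\qquad
\theta = \frac{0.5 - f}{0.5 + \mu f - f}.$$

LOH regions are found by running the state HMM on the all-spot pseudobulk
with allele emissions only and a single clone, then flagging states whose
BAF deviates from 0.5 by at least 0.2 (the default detection threshold).
Counts are oriented so the lost haplotype is the numerator, pooled over
all LOH bins per spot, and the relation inverted; estimates are clipped
to [0, 1] because sampling noise can push the raw value outside. The
BAF-only run does not estimate depth, so $\mu = 1$ is used unless per-bin
RDR estimates are supplied, in which case a support-weighted mean over
the LOH bins is taken. Spots with fewer than 10 pooled LOH UMIs (default)
get no direct estimate; with a spatial graph available their value is
imputed as the mean over neighbours. The estimator's error grows as LOH
support shrinks; at 200 LOH UMIs per spot its mean absolute error over a
$\theta \times \mu$ grid is about 0.04 (computed by the acceptance
script).

## Integer copy numbers and event classes

Each state's latent $(\mu_k, p_k)$ is matched to an integer haplotype
pair: for a candidate ploidy scale $\gamma$ (copies per unit RDR), state
$k$ maps to the $(a, b)$ with $0 \le a, b \le 6$, $a + b \ge 1$
minimising $((a+b)/\gamma - \mu_k)^2 + (b/(a+b) - p_k)^2$, and the
$\gamma \in \{1.5, 2, 2.5, 3, 3.5, 4\}$ with the smallest
occupancy-weighted total error is selected. This quadratic matching is
exact on its own inverse images: latent values generated from any integer
pair with $a + b \le 6$ are recovered exactly. The pair $(0, 0)$ is
excluded — expression near zero cannot reliably separate homozygous
deletion from dropout — and copies are capped at 6 per haplotype because
high amplifications compress the observable RDR differences. Segments
(maximal runs of constant $(a, b)$ across all clones) are labelled
neutral, del, amp, CNLOH (one haplotype lost, total unchanged) or LOH,
and flagged mirrored when two clones are imbalanced in opposite
orientations.

## Phylogeography

Complete loss of a haplotype is irreversible: a lineage cannot regain
what it lost. Maximal runs of bins with $a = 0$ or $b = 0$ and a constant
carrier set, spanning at least 3 bins and supported by at least 100
SNP-covering UMIs in every carrier clone (defaults), become binary
phylogenetic markers; losses of opposite haplotypes over the same region
are distinct characters. The clone tree minimises total marker gains
under star homoplasy — a marker may arise independently on several
branches but is never lost — found by exhaustive search over all rooted
binary topologies for up to 7 clones (the (2n-3)!! enumeration; a greedy
agglomerative heuristic with a flag above that). Each marker is assigned
to the stems of its maximal carrier subtrees. A leaf whose pendant edge
gains no marker, and which is the only such child of its parent, is
promoted to that parent: a clone with no unique events is the ancestor of
its siblings. A diploid, marker-free root sits above the clone MRCA.

Leaves are projected to the centroid of their member spots (3D when
slice z-offsets are given). Ancestral locations maximise a Gaussian
diffusion likelihood in which a child's location is normal around its
parent's with variance proportional to the markers gained on the edge;
the maximiser solves a small positive-definite linear system per
coordinate, equivalent to each free node being the precision-weighted
(1/w) average of its tree neighbours. Zero-gain edges take weight 0.5 so
variances stay positive; the root is estimated jointly with the other
internal nodes.

## Somatic SNV filter

Given a candidate variant table with per-spot variant/total counts and
per-spot tumor proportions, spots with proportion below 0.5 are normal
and a variant is somatic when it is (1) not a known germline SNP, (2)
genic, (3) free of germline evidence — zero variant reads in all normal
spots and at least 15 total normal reads (less leaves germline status
undecidable), and (4) supported in tumor spots by at least 5 pooled
variant reads at pooled VAF above 0.3. Tumor VAF is computed on pooled
counts over the tumor spots (the natural pseudobulk reading). The rules
are pure predicates: the survivor set is their intersection, order-free,
and monotone in the thresholds.

## Synthetic data

The generator emulates a Visium-like experiment end to end: a hexagonal
spot lattice (100-unit pitch standing in for the 55 um spot spacing, one
or more slices), tumor clone territories as Voronoi cells of seeded
spots (contiguous in 3D across slices) plus a normal-tissue territory of
20% of spots by default — real tumor sections carry substantial normal
tissue, and the normal-identification step is meaningless without it.
Clone profiles are generated by dropping LOH markers along a random
rooted tree under irreversibility; each marker spans 8 of a chromosome's
20 bins, the chromosome-arm scale that dominates real tumor genomes, and
each clone receives one private marker so the planted clone structure is
identifiable (a clone with no events of its own would be
indistinguishable from normal tissue by construction). An optional
mirrored segment places the same gain on opposite haplotypes in clones 1
and 2. Per-gene and per-SNP baseline weights come from a gamma
(Dirichlet) draw; transcripts are negative binomial with means following
the admixture-mixed relative copy number; allele counts are
beta-binomial around the mixed BAF; and a first-order Markov switch
process corrupts the population phasing in blocks. Defaults are 500
spots, 100 bins on 5 chromosomes, 3 clones, ~3,000 transcript UMIs and
~250 SNP-covering UMIs per spot (the scale of published Visium tumor
sections), NB dispersion 0.1, BB concentration 30, switch rate 0.02 and
full purity within tumor territories. Everything is deterministic given the seed.

What the generator does not emulate: gene-level biological covariance
(co-expression programs), cell-type mixtures beyond a single
tumor/normal axis, spatially varying capture efficiency, histology, or
segmentation noise in real annotations. Passing recovery tests on these
simulations therefore demonstrates correctness of the inference under
the package's own generative assumptions — a necessary condition — but
not performance on real tissue, where emission misspecification and
unmodelled expression variation dominate.

## Problem sizes and determinism

The test suite and the acceptance script run on deliberately modest
problem sizes — hundreds of spots, tens to hundreds of bins, 20 seeded
replicates for the monotonicity checks — chosen so that the full
analysis re-runs from scratch in minutes on one core while still
exercising every code path at the scale where the planted structure is
identifiable. All stochastic steps (simulation, k-means and partition
initialisation) take explicit seeds; re-running any pipeline with the
same configuration and seed reproduces identical labels bit for bit.

## Known limitations

* Haplotype orientation is identified only per chromosome and only in
  the presence of allelic imbalance; all A/B outputs are relative to the
  inferred B haplotype, not to parental origin.
* ICM and block coordinate ascent find local optima; different seeds can
  yield different (locally optimal) clone partitions on weakly separated
  data.
* The clone-merge threshold trades duplicate removal against sensitivity
  to clones distinguished by few, small events.
* Integer copy numbers above 6 per haplotype are not represented, and
  homozygous deletions are mapped to the nearest representable state.
* The tumor-proportion estimator needs LOH regions; a genome without
  detectable LOH yields no purity estimates.
* With an admixed normal profile pinned into the label update, the
  ascent guarantee holds for the tumor-spot terms only; in the default
  pure-clone mode it is exact.
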