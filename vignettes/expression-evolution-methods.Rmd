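---
title: "Methods: reconstructing ancestral expression programs and ranking evolved increases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing ancestral expression programs and ranking evolved increases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
the models, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical decisions that a maintainer would otherwise have to reverse
engineer from the code.

## The problem

Several related species are profiled by RNA-seq through a shared
developmental series (six stages, S0–S5, of perithecium development in
the motivating system). For genes conserved as single-copy orthologs
(SCOGs, one gene per species), we want to identify the ones whose
expression program has *increased* in a specific lineage since the
species diverged, and to quantify how diverged each cluster's expression
profile is overall.

Absolute expression (RPKM) is not comparable between species: library
composition, annotation quality and gene models differ. Stage-to-stage
log2 fold changes within a species are comparable, additive, and a natural
continuous character for evolutionary modelling; they are what the package
evolves, reconstructs and contrasts.

## Active-gene filter (zRPKM)

RNA-seq is noisy at the low end, and a fold change between two
near-zero measurements is dominated by that noise. Per stage (matching
per-sample semantics of the standard zFPKM approach), the filter fits a
Gaussian kernel density to log2 of the strictly positive RPKM values,
takes the density mode as `mu`, and estimates the scale from the right
flank only — `sigma = (U - mu) * sqrt(pi/2)` with `U` the mean of log2
values above the mode — treating that flank as half of a Gaussian of
actively transcribed genes, undisturbed by the low-expression noise mass
on the left. A gene's activity score is its z-value averaged over stages,
and `mean z >= -3` (inclusive) calls it active. Clusters containing *any*
inactive member are excluded, because one unusable species invalidates
the cross-species contrast.

Numerical choices:

* Bandwidth is Silverman's rule of thumb on the log2-positive values; the
  density is evaluated on a 512-point grid spanning the data range plus
  three bandwidths on each side; a tied maximum resolves to the smallest
  grid value. These are the conventional defaults of `stats::density()`
  and make the fit deterministic.
* Zeros are excluded from the density fit (log2(0) is undefined) but are
  mapped to a `-Inf` sentinel in the z-table, so an all-zero gene has
  mean z of `-Inf` and can never be called active, under any threshold.
* At least 50 positive values are required per stage; below that a KDE
  mode is not trustworthy and the fit errors rather than guessing.
* Two published phrasings of the activity rule coexist: "averaged z at or
  above −3" and "below −3 throughout the stages". The averaged rule is
  the default (`rule = "mean"`); `rule = "any_stage"` implements the
  other reading (active if any single stage reaches the threshold). We do
  not assert which was intended; the default follows the more precise
  methods-style phrasing.

## Expression point estimates

When replicate count libraries are available for a stage, they are pooled
under `count[g, r] ~ Poisson(a_g * b_r)` with the replicate effects
summing to the number of replicates. The ML solution is closed form (row
and column sums; the iterative-proportional-fitting fixed point), and the
per-gene `a_g` is the pooled point estimate. This deliberately replaces a
full Bayesian expression model: everything downstream consumes a single
point value per gene and stage, so the posterior machinery would add cost
without changing the pipeline's inputs. Overdispersion is likewise not
modelled here — with three or fewer replicates a dispersion estimate is
mostly prior anyway.

Fold changes are `delta[t] = log2((x[t+1] + eps)/(x[t] + eps))` with
pseudocount `eps = 1` RPKM by default. After the activity filter, genes
are expressed somewhere, so `eps` only guards rare stage-level zeros; 1
RPKM is small against typical expressed levels but keeps a 0 → 5 RPKM
transition from registering as an infinite fold change. It does shrink
fold changes of genes expressed near 1 RPKM — a known, accepted bias
toward conservatism for barely-expressed genes.

## Ancestral reconstruction under Brownian motion

Each character (one cluster × one transition; five characters per
cluster) evolves independently by Brownian motion on the rooted species
tree: the change along a branch is Normal(0, sigma^2 × branch length).
No correlation between transitions or between clusters is modelled — the
contrast statistic is defined per transition, and modelling a 5×5
covariance per cluster would need many more species than are available.

* The root (MRCA) estimate is the generalized-least-squares estimator
  `(1'V^-1 1)^-1 1'V^-1 x`, `V[i,j]` = shared root-to-MRCA path length.
  It is computed by Felsenstein pruning in linear time; a dense-matrix
  GLS implementation exists in the test suite as an independent oracle.
  The estimate is a convex combination of tip values (always inside the
  tip range) and invariant to rescaling all branch lengths.
* Internal-node states minimize the sum over edges of squared change per
  unit length with tips fixed — the ML/posterior-mean states — computed
  by a two-pass Gaussian message-passing sweep; the test oracle solves
  the equivalent graph-Laplacian linear system directly.
* The Brownian rate uses the ML (1/n) normalization, assembled from the
  pruning contrasts. It affects only reported variances, never the point
  estimates.
* Branch lengths must be positive; zero-length branches are floored to
  `epsilon = 1e-8` at parse time (with a warning) because a zero branch
  makes the precision-weighted averages singular.
* Unnamed internal nodes receive deterministic names `N1..Nk` in
  post-order at parse time, so any ancestor — not only the root — can be
  addressed by name or as `"MRCA:leafA,leafB"`. This is how a contrast
  against, say, the common ancestor of the two sister species is
  requested.

The species tree is a required input: the motivating study's tree is
published as a topology without branch lengths, so the package never
assumes particular lengths, and the generator documents the ones it uses.

## Fold-change differential and ranking

For a focal species, `fcd[t] = deltaX[t] - deltaY[t]` (extant minus
reconstructed ancestral fold change) and the gene's score is
`fcd_max = max_t fcd[t]`. Ranking is by `fcd_max` descending, ties broken
lexically by cluster id — a documented, stable tie rule so that reruns
and row permutations give byte-identical output. The per-transition
argmax takes the first index on ties.

FCD is computed and ranked on the log2 scale, with `2^fcd_max` reported
alongside as the linear-scale column: published priority tables print
linear-looking magnitudes while the defining formula is a difference, and
ranking is invariant to this monotone choice, so both are exposed.
`scale = "linear_difference"` gives the literal linear-scale difference
`2^deltaX - 2^deltaY` for readers who want the formula applied to linear
fold changes. We make no claim about which scale reproduces any
particular published magnitude.

## Expression divergence and cluster classes

Per cluster, each species' six-stage profile is normalized to sum to one
(a point on the stage simplex; scale-invariant, hence cross-species
comparable), and divergence is the mean Euclidean distance over all
species pairs — bounded by `sqrt(2)`, the simplex diameter. Distances
restricted to pairs involving one focal species are also emitted
(`mean_euclid_<species>`), because published per-species panels can be
read either way; both the pooled and the per-species tests are available
and the package takes no position on which was used.

A cluster is "functional" when at least `min_functional = 2` members
carry a predicted protein domain at the stringent E-value cutoff, else
"hypothetical". The source material states the rule once as "at least
two genes" and once as "more than two species"; the default follows the
former, and the knob is exposed rather than silently resolving the
discrepancy.

The two classes are compared by a Mann-Whitney U test: U from midranks;
an exact two-sided p from the null U distribution when
`choose(n + m, n) <= 1e5` and there are no ties, otherwise the normal
approximation with tie and continuity corrections. Two-sided because the
direction is the question, not an assumption.

## Phylostratigraphy

Gene ages come from a user-supplied ortholog presence/absence matrix over
reference taxa grouped into an ordered stratum hierarchy (oldest first,
youngest = the focal lineage alone). A gene is assigned the *oldest*
stratum containing at least one taxon with a homolog — presence in an old
taxon wins even when intermediate strata show no hit, which makes the
assignment monotone under added presences. Genes with no hits outside the
focal species fall in the orphan stratum, or `"others"` when the
hierarchy defines none. Running the similarity searches that produce the
matrix is out of scope; curated databases do that better.

## The synthetic-data generator

`emit_dataset()` draws: a shared stage-0 log2 RPKM per cluster from
Normal(4, 2²); per-transition root fold changes from Normal(0, 1); BM
evolution of those characters along the tree at rate sigma² = 1 (log2²
per unit branch length), ×4 for the hypothetical class (10% of
clusters); a +4 log2 activation shift at the S3→S4 transition on the
focal terminal branch for 25 planted clusters; 2% silent clusters with
RPKM ~ Uniform(0, 0.05) in every species; gene lengths ~
LogNormal(log 1500, 0.25) bp; Poisson counts at library size 10⁷ mapped
back to observed RPKM. The default tree is ultrametric with depth 1 and
the clade structure of the motivating five-species system (the two
*Fusarium*-like tips sister, their ancestor named and addressable; the
*Neurospora*/*Chaetomium* pair sister to the *Magnaporthe*-like tip).
These values were chosen once as a realistic desk-scale emulation —
baseline and spread matching the usual log2-RPKM densities, a
hypothetical-class share matching the ~10% seen in curated SCOG sets, a
planted shift large enough to be a genuine activation but small enough
that count noise and reconstruction shrinkage matter — and are not
tuned per analysis.

What it does *not* emulate: overdispersed counts (a negative-binomial
knob exists in principle but Poisson is the default because the pipeline
consumes point estimates), mapping/annotation artifacts, correlated
evolution between transitions, non-ultrametric trees (the estimators do
not assume ultrametricity; the generator just produces it), and
cluster-size variation (every synthetic cluster has exactly one member
per species). Passing tests on this generator therefore demonstrates the
estimators' correctness and calibration under the assumed model, not
robustness to everything real data can do.

## Problem sizes and runtime

The shipped tests and the acceptance script use: 2000 clusters × 5
species × 6 stages for pipeline-level checks (seconds); 1000 replicate
characters for estimator calibration; 100 random trees of up to 12 taxa
for oracle-equivalence sweeps; 10⁵ random profile pairs for divergence
bounds; full enumeration up to `n = m = 8` for the rank-sum oracle. These
sizes make every check deterministic under a fixed seed and fast enough
to run on a laptop, while being large enough that the statistical
assertions (bias within 3 standard errors, variance within 10% of the
GLS prediction, ≥ 20/25 planted recoveries) are meaningful.

## Known limitations

* A single Brownian rate per character: no Ornstein–Uhlenbeck pull, no
  rate shifts. Lineage-specific activation enters only through the data,
  not the model — which is exactly what the FCD statistic is designed to
  detect, but means the reconstruction shrinks real shifts toward the
  ancestral mean (the planted-shift recovery quantifies the cost).
* The pseudocount biases fold changes of weakly expressed genes toward
  zero; lowering it increases sensitivity and noise together.
* Clusters missing a member in any species are rejected, not imputed.
* The Mann-Whitney exact path requires tie-free data; midrank + normal
  approximation handles ties, as in standard implementations.
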