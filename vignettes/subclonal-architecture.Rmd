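---
title: "Models and methods: subclonal architecture from deep sequencing"
author: "clonehistory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: subclonal architecture from deep sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonehistory)
```

This vignette explains the statistical models behind each stage of the
package, the tunable parameters and their defaults, what the bundled
synthetic-tumor generator does and does not emulate, and the numerical
choices made where the methods literature leaves the design open.

## The observation model

A bulk tumor sample of purity $\rho$ mixes tumor and normal cells. A somatic
substitution carried at multiplicity $m$ (copies per carrying cell) by a
fraction $\pi$ of tumor cells, at a locus of tumor copy number $\eta_T$ and
normal copy number $\eta_N$, is reported by a read with probability
$m\rho\pi / (\rho\eta_T + (1-\rho)\eta_N)$. Writing
$\zeta = \rho / (\rho\eta_T + (1-\rho)\eta_N)$ for the fully clonal
single-copy expectation, the variant read count is
$y \sim \mathrm{Bin}(N, \zeta\pi)$ (for $m = 1$), and inverting the mean
gives the cancer cell fraction
$f = \min\!\big(1, \tfrac{r}{R}\tfrac{\rho\eta_T + (1-\rho)\eta_N}{\rho}\big)$
computed by `cellFraction()`. Purity and ploidy are taken as given (e.g.
ASCAT estimates); they enter every stage through `SampleMeta`.

Mutations on segments that are themselves subclonal mixtures use the
cell-fraction-weighted mean total copy number for $\zeta$
(`segmentTotalCN()`); the locus-level mixture is not deconvolved per
mutation, a deliberate simplification that biases $f$ by at most the
difference between the two state totals times the minority fraction.

## Dirichlet-process clustering

`fitDirichlet()` models the mutation cell fractions as draws from a
Dirichlet process, $\pi_i \sim DP(\alpha P_0)$ with $P_0 = U(0,1)$ and
$\alpha \sim \Gamma(0.01, 0.01)$, truncated at $H = 30$ components through
the stick-breaking construction
$\kappa_h = V_h \prod_{l<h}(1 - V_l)$, $V_h \sim \mathrm{Beta}(1, \alpha)$,
with $V_H = 1$ so the weights sum to one at every iteration (a tested
invariant). The posterior is explored by Gibbs sampling with:

- categorical allocation of mutations to components (Gumbel-max sampling of
  the log posteriors);
- conjugate Beta updates for the sticks and a conjugate Gamma update for
  $\alpha$;
- a reflected random-walk Metropolis update for each occupied component
  location $\pi_h$ — the binomial likelihood with per-mutation $\zeta_i$ is
  not conjugate in $\pi$, so no Gibbs draw exists; the step size is adapted
  toward a 44% acceptance rate during burn-in only, preserving detailed
  balance afterwards. Empty components are refreshed from the uniform base
  measure, which is their exact conditional posterior.

Defaults are 20,000 iterations with 13,000 burn-in; the bundled tests and
the acceptance script use 5,000/2,000 at a few hundred mutations, where the
chain converges within the first few hundred iterations (convergence is
monitored by a split-chain potential scale reduction on the total
log-likelihood, threshold 1.1; exceeding it records a warning in the fit
object rather than failing silently).

**Sensitivity correction.** Deep subclones are undercalled by the variant
caller. Given a detection-sensitivity curve $S(\theta)$, reported weights
are $\omega_h = \kappa_h S(\pi_h) / \sum_i \kappa_i S(\pi_i)$, and
per-cluster mutation counts are observed allocations divided by
$S(\pi_h)$. In `classifyMutations()` the correction factor is capped at
$1/0.05$ (`sensFloor`): below 5% sensitivity a handful of observed
mutations would otherwise be amplified into unstable thousands, so counts
in very deep subclonality bands are conservative lower bounds.

**Posterior density and cluster summaries.** The marginal density of
subclonal fractions is the $\kappa$-weighted Gaussian-kernel density of the
monitored $(\pi_h, \kappa_h)$ draws. The kernel bandwidth follows
Silverman's rule on the weight-pooled draws (floored at 0.004 so perfectly
concentrated posteriors still render); each draw's density is renormalised
to integrate to one over $(0, 1]$. Clusters are summarised at the modes of
the posterior median density; each monitored draw's components are
aggregated to their nearest mode, yielding medians and 95% posterior
intervals for weights and corrected mutation counts. Modes carrying less
than 1% of corrected weight are dropped from the summary.

## Detection sensitivity

`spikeInSensitivity()` emulates the spike-in protocol: at each subclonality
level $\theta$ it simulates wild-type pileups (Poisson depths, base-call
errors at a flat rate, default 0.002/read), introduces variant reads by the
per-read uniform-draw scheme at expected fraction $\zeta\theta$ (error reads
already showing the variant are flipped away when drawn), applies a caller
predicate, and records the detected fraction. The default predicate — at
least 4 variant reads and VAF at least 0.05 — stands in for a production
somatic caller and is pluggable; published per-sample sensitivities depend
on the caller's full filter stack and are not reproducible from a predicate,
so only qualitative behaviour (near-certain detection of clonal variants at
high depth, steep loss below ~50% of tumor cells at 30–40x) is asserted.

`fitLogistic()` fits $S(\theta) = A/(1+\exp((\chi - \log\theta)/\sigma))$
by nonlinear least squares (Levenberg–Marquardt), started at $A$ = max
response, $\chi$ = log of the level nearest half-max, $\sigma = 0.5$.
`defaultSensitivityCurve()` (A = 0.9, $\chi$ = −0.9, $\sigma$ = 0.2) gives
roughly 90%/60%/5% detection at 100%/50%/25% of tumor cells, the regime
typical of 30–40x genomes, and is the default thinning curve in the
simulator.

## Timing chromosomal gains

On a gained segment, pre-gain mutations sit on every copy of the duplicated
allele (ploidy 2), post-gain mutations on one (ploidy 1).
`assignMultiplicity()` first sets aside subclonal mutations (VAF below 75%
of the clonal single-copy expectation $\zeta$), then assigns the
maximum-likelihood multiplicity under $\mathrm{Bin}(R, m\zeta)$. The gain
date in molecular time is

- trisomy 2+1: $t = n_2 / (n_2 + (n_1 - n_2)/3)$ — the pre-gain per-copy
  count is approximated by $n_2$, so $(n_1 - n_2)/3$ is the post-gain
  per-copy count across three copies (floored at zero);
- UPD 2+0 and tetraploid 2+2: $t = n_2 / (n_2 + n_1/2)$.

These three cases cover whole-arm/whole-chromosome gains; more general
copy-number histories are out of scope. Uncertainty comes from resampling
the per-mutation ploidy labels with replacement (10,000 resamples by
default, percentile 95% interval). `heterogeneityTest()` asks whether
several gains could be simultaneous (one endoreduplication) by a chi-square
independence test on the per-segment $(n_2, n_1)$ table — the literature
reports only p-values for this comparison, so the statistic is this
package's choice. Note the known, accepted misclassification: mutations on
the non-amplified parental copy of a 2+1 region are counted "late", which
dilutes, never fabricates, early/late spectrum differences.

`compareSpectra()` compares early (ploidy > 1) against late (ploidy 1)
substitution-class counts, restricted to gained regions, by a chi-square
test of independence over the six pyrimidine-strand classes.

## Subclonal allele-specific copy number

Imputation phases heterozygous SNPs into parent-specific haplotype blocks
(~hundreds of kb); within a block the haplotype-1 read fraction is binomial
around one of two bands, and blocks switch bands at recombination hotspots.
The pipeline in `callSubclonalCN()`:

1. **Re-phasing** (`rephaseBlocks`): a block is flipped onto the lower band
   when its pooled read fraction is significantly above 0.5 (z > 1.96).
   Flipping on the sign of the deviation alone would fold balanced regions
   below 0.5 by the magnitude of the block-level noise and bias the
   clonality test toward spurious subclonality; leaving non-significant
   blocks untouched keeps balanced regions unbiased at the cost of a slight
   attenuation toward 0.5 in weakly imbalanced regions.
2. **Segmentation** (`pcfSegment` via `phaseSwitchSegment`): exact
   least-squares piecewise-constant fitting by dynamic programming on the
   block-level mean fractions, with penalty $3\log n$ per breakpoint on the
   noise-standardised signal (a difference-based MAD estimates the noise).
   The $\log n$ factor keeps the breakpoint penalty parameter O(1) across
   signal lengths; the penalty parameter itself is 3.
3. **Clonality test** (`testClonality`): the real-valued inversion
   $n_A = (\rho - 1 + (1-h_f)\psi 2^{l_R})/\rho$ (and symmetrically $n_B$)
   defines four floor/ceiling candidate integer states; the segment is
   clonal if its fraction is within 0.01 (`minDev`) of a candidate's
   theoretical $h_f = (1-\rho+\rho n_B)/(2(1-\rho)+\rho(n_A+n_B))$ or not
   rejected by a two-sided one-sample t test at $\alpha = 0.05$ over the
   per-SNP fractions. With thousands of SNPs the t test rejects arbitrarily
   small deviations, so `minDev` is the effective guard — that is its
   purpose.
4. **Two-state mixture** (`estimateTau`): assuming the aberration changed
   exactly one allele by one copy, only two of the four state combinations
   are feasible (mixing totals $\lfloor n\rfloor{+}\lfloor n\rfloor$ with
   +1, or +1 with +2); the logR-derived total selects between them, and the
   mixing fraction follows in closed form. `state1` is reported as the
   lower-total state. The 95% CI resamples per-SNP fractions (1,000
   resamples by default). Values outside [0, 1] by numeric noise are
   clipped with a warning; infeasibility of both combinations is an error.
5. **Balanced losses**: a segment with balanced haplotype fraction but logR
   clearly below the diploid baseline (margin 0.05 by default) is flagged
   "balanced subclonal loss suspected" — equal loss of both parental copies
   is invisible to allele fractions and can only be suspected from
   coverage.

`fineTunePurity()` refines a coarse purity estimate on a clonal reference
segment by grid search over ±0.02 at 10⁻⁴ resolution, minimising the
haplotype-fraction residual.

## Phasing

`phaseMutationToSNP()` uses the SNP allele linked to a mutation by spanning
read pairs: a two-sided binomial test compares the linked allele's tumor
read fraction to the baseline (0.5 on a near-diploid chromosome);
significantly below places the mutation on the subclonally deleted parental
copy, above on the retained copy, and non-significant calls defer to the
block-level haplotype when available. No multiple-testing correction is
applied — calls are reported per mutation with their p-values so users can
audit.

`classifyPair()` applies the read-pair existence rules for nearby subclonal
mutation pairs literally: collinearity needs at least one pair reporting
both variants and one reporting the earlier variant alone, with none
reporting the reverse; mutual exclusivity needs each variant seen without
the other and none together, and is only issued where the tumor copy number
is 1 (at higher copy number the variants could share a subclone on
different parental copies). `minSupport` (default 1, the literal "at least
one") hardens the rules against sequencing errors.

## Phylogeny

If two lineages occupy fractions of tumor cells summing to more than 100%,
some cell carries both — they are collinear on the tree, the larger
ancestral (`pigeonholeConstraints`). `buildTree()` nests items greedily in
descending fraction order, honouring pigeonhole and phasing constraints
exactly, and applies the same argument recursively inside each lineage
(the threshold is the parent's fraction, not 1). Two situations are
reported rather than resolved: an item forced nowhere that could nest in
more than one branch keeps its place under the most-recent common ancestor
with an `ambiguous` flag; and a sibling set that is jointly infeasible
without any pairwise ordering (a multi-way pigeonhole) is nested under the
largest admissible branch, also flagged. An exclusive pair whose fractions
sum over 1 is a contradiction and errors, naming the pair. Children may
exceed their parent's fraction by at most $\varepsilon = 0.02$ — posterior
cell-fraction estimates are noisy, and exact sums only occur in print.

## The synthetic-tumor generator

`simulateTumor()` emulates: clone trees with fixed cell fractions
(children's fractions bounded by the parent's), per-clone mutation counts,
binomial read sampling at the observation model above with Poisson depths
scaled by local relative copy number, mutation multiplicity on gained
segments assigned by a uniform draw against the configured gain time (so
configured timings are recoverable), subclonal two-state segments,
haplotype blocks with random parental orientation and binomial SNP read
counts around the mixture haplotype fraction, read-pair co-occurrence
records for mutation pairs within the insert size (700 bp default), a flat
per-read error rate, detection thinning by a sensitivity curve, and
time-varying substitution spectra (early vs late class probabilities). The
truth object records every latent value.

It does **not** emulate: read-level sequence (FASTQ), alignment and mapping
artefacts, GC-dependent coverage waves, overdispersed depths, correlated
errors, kataegis-style clustered mutations, or rearrangements. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated observation model, not robustness to real-data artefacts; logR
is generated noise-free, so segmentation difficulty comes entirely from the
allele-fraction noise.

Depth choices in the bundled tests: the four-component recovery runs at 150x
(the regime where sensitivity correction matters), and the 40-subclone
flat-profile property at 500x with 500 mutations — deep, validation-grade
read depths at which 2.5%-spaced subclones remain individually
unresolvable but no merged component dominates; at 150x that simulation
collapses to a handful of blurred clusters and the flatness property is not
meaningful. The chromosome-13-style copy-number recovery uses 5,000 SNPs at
188x, matching a deeply sequenced genome.

## Known limitations

- Single-sample only; no multi-region or longitudinal joint modelling.
- The DP sampler labels are not identifiable; summaries are density-mode
  based, so two true clusters closer than the posterior resolution merge.
- The timing formulas cover 2+1, 2+0 and 2+2 gains only, and inherit the
  "non-amplified copy counted late" simplification.
- τ estimation assumes a single aberration event (exactly one copy of one
  allele changed); regions with two independent subclonal aberrations
  violate the model.
- The CLI is a thin dispatcher; anything beyond the provided subcommands is
  intended to be driven from R.
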