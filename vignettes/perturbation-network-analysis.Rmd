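---
title: "Detecting subtle microbiome perturbations through interaction networks"
author: "perturbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting subtle microbiome perturbations through interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`perturbnet` analyzes paired time-series abundance tables — a control
series (condition `C`) and a perturbed series (condition `B`) of the same
community sampled on the same dates — and asks whether a perturbation
that barely moves diversity indices nevertheless reorganizes the
community's *interaction structure*. The canonical use case is a
lab-scale anaerobic digester bioaugmented with a single pregrown strain:
the added family stays rare, Shannon/inverse-Simpson/Chao1 hardly move,
yet gas production changes. The analysis therefore works at three levels:
per-taxon abundance features, pairwise co-occurrence, and inferred
interaction networks with their centralities and motifs.

The dynamical model underlying network inference is the discrete-time
generalized Lotka–Volterra (gLV) map

$$x_i(k+1) = x_i(k)\,\exp\!\Big(\Delta t\,\big(b_i + \sum_j a_{ij}
x_j(k)\big) + \varepsilon_{ik}\Big),$$

where $b_i$ is an intrinsic growth rate (per unit time), $a_{ij}$ the
effect of taxon $j$ on taxon $i$ (per abundance unit per unit time), and
$\varepsilon$ optional log-scale process noise. Its gradient-matching
inverse — regressing $y_i(k) = \ln(x_i(k+1)/x_i(k))/\Delta t$ on an
intercept and all abundances — is linear, so on noiseless data with a
well-conditioned design the fit recovers $(b, A)$ exactly; the test suite
asserts this to $10^{-6}$. The synthetic generator uses *exactly* this
forward model, which turns noiseless recovery into an identity check
rather than a statistical one.

## Stages and the parameters that matter

### Abundance features

* Averaged abundance level $\bar{x}_i$ = sum of relative abundances over
  the samples where the taxon is detected, divided by the number of those
  samples. An all-zero profile is defined to have $\bar{x}_i = 0$ rather
  than erroring, so condition-specific taxa survive the pipeline.
* Level thresholds (relative %, defaults 1 and 0.1): high `H` strictly
  above 1%, rare `R` strictly below 0.1%, low `L` the inclusive band
  in between. `core` = detected in every sample; `nR` = rare and
  not core.
* Differential status: two-sided paired Student's t-test on date-aligned
  C/B values at `alpha = 0.05`, no multiple-testing correction (the
  protocol applies none); `Diff_UP`/`Diff_DN` by the sign of the mean
  difference. Identically zero differences give p = 1 (tie broken to
  `NDiff_DN`); a constant nonzero difference is treated as a perfectly
  consistent shift (p = 0).
* Depth normalization: each sample is rescaled to the minimum total depth
  (`counts * min(depth)/depth`), the expected-value analogue of rarefying
  to even depth, and a taxon is discarded only when its adjusted count is
  below 1 in *every* sample — the least destructive reading of the
  discard rule. The alternative of dividing all samples by one scalar
  depth would, at realistic depths (~19,000 reads), push almost every
  taxon below 1 and empty the table, so it is not offered.

### Co-occurrence clusters

Three steps: (1) average-linkage hierarchical clustering of taxa on
$1 - r$ of their concatenated C+B profiles, cut at `cut_height`
(default $1 - r_{crit}(n_{samples}, \alpha)$, the distance at which a
correlation stops being significant — the procedure itself does not
prescribe a cut); (2) within each cluster, links with a significant
within-condition correlation are kept only if at least one endpoint is an
*anchor*, i.e. has significant self-correlation $r_{C_iB_i}$ between its
C and B trajectories; members with no retained link are dropped;
(3) links are tagged `before`/`after` by which condition's correlation is
significant. Correlation significance everywhere is the two-sided
t-transform with $n-2$ degrees of freedom.

Trajectory shapes: the three named patterns (ascent, descent, convex
rise-then-fall) come with no formal definition, so the package pins one:
a quadratic least-squares fit against the date index is "convex" when the
quadratic coefficient is negative, the vertex lies strictly inside the
date range and the quadratic term improves the fit (F-test p < 0.05);
otherwise the linear slope's sign decides ascent vs descent. The rule is
invariant under positive affine rescaling.

The association between categorical taxon features uses Fisher's exact
test — hypergeometric for 2×2, Monte Carlo (seeded, default $10^5$
replicates) for larger tables, where no exact small-sample test is
canonical.

### Ensemble network inference

Defaults follow the protocol: `n_networks = 1000` fits, each on
`member_frac = 0.9` of the taxa, sampled without replacement. Each fit is
the ridge gradient-matching regression (`ridge = 1e-3`; at ~113 taxa and
~6 transitions the design is wildly underdetermined and an unpenalized
fit would be meaningless). Transitions with a zero endpoint are skipped
for that taxon, since the log growth is undefined; a half-minimum
pseudo-abundance alternative was considered and rejected as it
manufactures growth rates for absent taxa.

Per ordered pair $j \to i$, a run contributes a signed outcome when both
taxa are in the run and $|a_{ij}|$ exceeds a numerical floor
(`1e-10`, so numerically zero coefficients are not counted as signs).
Coherence is the modal-sign fraction among signed outcomes of runs
containing both taxa (runs missing a taxon cannot speak to its edges and
are excluded from the denominator); strength is the median $|a_{ij}|$
over modal-sign runs. A reliable edge needs coherence ≥ `coherence`
(default 0.9) *and* a one-sided exact binomial test of the modal count
against 0.5 at `alpha` — the weakest defensible reading of the protocol's
unspecified "proportional test". Reliability is monotone in the
threshold, and the whole ensemble is deterministic given a seed.

### Centralities and the topological niche

On each top-$S$ sub-network (grid default 500/1000/1500/2000 plus all
interactions): indegree normalized by $n-1$, directed shortest-path
betweenness normalized by $(n-1)(n-2)$ — with $n$ the sub-network's own
node count so values are comparable across levels — and eigenvector
centrality for reporting only (no downstream rule consumes it). Taxa
absent from a sub-network mediate nothing there and score 0.

The niche statistic sums the B−C centrality difference over the grid and
normalizes. Read literally (per-taxon maximum over levels in the
denominator) the score can leave the stated [−1, 1] range, so the default
normalizes by the maximum absolute per-taxon sum across taxa, which
forces the range and pins the largest scorer to ±1; the literal variant
remains available via `normalization = "per_taxon_max"`. Classification:
both scores > 0.1 → niche after the perturbation; both < −0.1 → niche in
the control; both inside the band → none; opposite signs outside the
band → ambiguous. The four published rules do not cover mixed cases (one
score inside the band, one outside); these default conservatively to
`none`.

### Motif analysis

Motif types are canonical adjacency-bitmask identifiers: edge $i \to j$
of an $n$-node digraph sets bit $2^{n^2-(n(i-1)+j)}$, and the canonical
id is the minimum over all $n!$ relabelings (brute-force minimization —
6 or 24 permutations — guaranteeing bit-exact ids). Exhaustive
enumeration of all masks yields exactly 13 connected 3-node and 199
connected 4-node classes; the familiar 3-node dictionary falls out as
divergence 6, chain 12, convergence 36, feed-forward 38, dyad-plus-
in-edge 74, reciprocal hub 78, feedback cycle 98.

The census counts *induced* occurrences: every weakly connected node
subset contributes exactly once, under its induced type (tools differ
subtly on this; the convention is pinned because it makes counts
well-defined and subset-partitioning). Enumeration uses the exact ESU
strategy in C++, which keeps 4-node censuses of 2000-edge networks on
~113 nodes tractable.

The null model is degree-preserving edge switching that additionally
preserves the count of reciprocal dyads: single arcs are switched
pairwise (rejecting switches that would duplicate an edge or create a
reciprocal pair) and reciprocal dyads are rewired as units; default 100
attempted switches per edge. Significance: z ≥ 2 and a real count ≥ 4
(the published defaults of the classical tools), over `n_random = 100`
null networks by default; a type is *representative* when significant at
three or more of the four strength levels. When the null ensemble has
zero spread, z is 0 if the real count equals the null mean and is
otherwise flagged infinite and never significant — an infinite z from a
degenerate null is evidence of a frozen graph, not of enrichment.

`correlated_feedback_fraction()` reports the share of a 4-node type's
instances embedding an induced feedback cycle (type 98) whose members are
correlated taxa; the default requires all three cycle nodes correlated,
with an `"any"` mode because the phrase "with correlated microbes" is
ambiguous.

### PCA report

Centered, unscaled PCA of the combined samples × taxa relative
abundances (no transform is prescribed; a log-ratio option was considered
and left out to keep the default faithful — relative abundances are what
every other stage consumes). Loadings are joined with feature annotations
and a cluster-epoch code (cluster label + `b`/`a`/`ba`).

## What the synthetic generator emulates — and what it does not

`generate_dataset()` produces paired count tables shaped like the
motivating study: 113 taxa, 7 paired dates per condition, per-sample
depth drawn Normal(19392, 982) (truncated at one read) and distributed
multinomially, so column sums are exact depths. On top of a stationary
gLV community (lognormal equilibrium, sdlog 1.2; interactions Bernoulli
density 0.1 with 70% negative signs, half-normal magnitudes; rows scaled
by $1/x^*_i$ so the Jacobian at equilibrium is independent of abundance
unevenness; growth rates balance the equilibrium) it plants:

* 25 correlated-trajectory taxa in three groups (8 ascent, 8 descent,
  9 convex), the same template applied congruently in C and B with
  Gaussian noise (default SD 0.05 of the taxon scale) so self-correlation
  is high by construction;
* 33 differential taxa (16 up, 17 down): the B trajectory is the C
  trajectory shifted multiplicatively by $1 \pm$ (effect × within-date
  noise SD), defaults effect 3 and noise 0.1, drawn from the more
  abundant half of the community so the planted shift is not drowned in
  count noise;
* one invader taxon absent from C and constant at 0.4% relative abundance
  in B — emulating an added strain that persists but stays rare;
* 10 interaction rows rewired in the B model (growth rates rebalanced so
  the equilibrium is preserved), giving the network stages a true
  structural difference to find.

Everything is a deterministic function of the master seed, and the truth
record (including both interaction matrices and all planted labels)
serializes losslessly to JSON.

What the generator does *not* emulate: taxonomic misassignment, chimeras,
16S copy-number bias, compositional artefacts beyond the closure to 100%,
overdispersed (non-multinomial) count noise, and non-stationary dynamics
such as regime shifts. Passing tests therefore demonstrate that the
implementation recovers the structures it defines, under realistic
depths and community shape — not that the statistical procedure would
recover them from arbitrary real sequencing data.

## Numerical choices and degenerate inputs

* Zero-variance profiles: correlations are undefined, flagged
  non-significant, and excluded from clustering.
* Constant trajectories: zero log growth gives exactly zero gLV
  coefficients; a taxon with no usable transition gets a zero row and a
  flag.
* Simulation overflow is truncated at a cap with a warning, and the
  forward-simulation fit score (1 − mean Bray–Curtis dissimilarity)
  reports 0 for diverging models.
* Ties in top-k strength selection break by (source, target) order, so
  sub-networks are reproducible.
* All stage seeds derive from the master seed via `sample.int`, keeping
  every derived seed below $2^{31}$.

## Problem sizes used by the test suite

The suite validates the motif census against a brute-force all-subsets
oracle on 100 seeded digraphs (6–10 nodes), betweenness against an
exhaustive shortest-path oracle on 100 digraphs (≤ 6 nodes), and runs the
full synthetic pipeline at study shape (113 taxa, 7 + 7 samples) with a
200-network ensemble, 20 null networks per motif record and the motif
stage scaled to 3-node types (4-node censuses are exercised on the
smaller end-to-end run and against oracles) — sizes chosen
so the whole suite completes in a few minutes while still exercising
every stage at realistic dimensions; the ensemble and null sizes are
plain scale knobs, and production runs use the 1000/100 defaults.

## Known limitations

* With ~6 usable transitions and >100 taxa the per-fit regression is
  heavily ridge-regularized; inferred edge *strengths* are shrunken and
  only sign/rank information should be interpreted. Sign coherence across
  the ensemble is the designed defense, and the acceptance checks verify
  sign recovery, not magnitude recovery, under noise.
* Average-linkage clusters depend on the tree cut; the default ties the
  cut to the correlation-significance radius but other cuts are
  legitimate (`cut_height`).
* The niche statistic compares two *point-estimate* networks; it carries
  no uncertainty of its own.
* Motif significance inherits the usual caveats of switching nulls:
  z-scores are comparable within a null family, not across families with
  different preserved statistics.
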