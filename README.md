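# perturbnet

Network-based detection of subtle perturbations in time-series microbiome
data.

## The problem

Adding a single pregrown strain to an established microbial community (a
bioaugmentation) often changes community *function* — e.g. the methane
yield of an anaerobic digester — while leaving headline diversity indices
flat. `perturbnet` implements the network-level analysis that makes such
subtle perturbations visible from paired time-series 16S family-level
abundance tables (a control series C and a perturbed series B sampled on
the same dates):

1. **Abundance features.** Each taxon's averaged abundance level over its
   detected samples, x̄ᵢ = Σₖ xᵢₖ / #{xᵢₖ > 0}, classifies it as high
   (x̄ᵢ > 1%), low (0.1–1%, inclusive) or rare (< 0.1%); core taxa are
   nonzero in every sample, and paired Student's t-tests on date-aligned
   samples call differential taxa (Diff_UP / Diff_DN at α = 0.05).
2. **Co-occurrence clusters.** Pearson correlations between a taxon's C
   and B trajectories (r_CiBi) and between taxa within a condition
   (r_CiCj, r_BiBj) feed an average-linkage clustering on the 1 − r
   distance; retained cluster links need a significant within-condition
   correlation anchored by a taxon with significant r_CiBi, and are
   tagged before/after the perturbation. Trajectories are classified as
   ascent, descent or convex (rise-then-fall).
3. **Interaction networks.** An ensemble of generalized Lotka–Volterra
   fits — per-capita log growth ln(xᵢ(k+1)/xᵢ(k))/Δt regressed on all
   abundances by ridge least squares, 1000 fits each on a random 90% of
   taxa — yields directed signed edges aᵢⱼ (j → i). Edges with ≥ 90%
   sign coherence that pass an exact binomial proportion test are
   "reliable".
4. **Topological niche.** For each taxon, Nicheᵢ = Σ_S (Centralityᵢ, S^B −
   Centralityᵢ,S^C) over the strength grid (top-500 … all interactions),
   normalized to [−1, 1]; indegree and betweenness scores outside a
   ±0.1 band classify taxa into perturbed-niche, control-niche,
   non-influential or ambiguous.
5. **Motifs.** Connected 3-/4-node induced subgraphs are censused
   exactly (ESU enumeration in C++), typed by canonical adjacency-bitmask
   identifiers (convergence = 36, cascade dyad = 74, reciprocal hub = 78,
   feedback cycle = 98, …), and scored against a degree- and
   reciprocity-preserving edge-switch null (significant: z ≥ 2, count ≥ 4;
   representative: significant at ≥ 3 of 4 strength levels).

A fully seeded synthetic community generator (known interaction matrix,
planted correlated/differential/invader taxa, multinomial read sampling
at 19,392 ± 982 reads) makes every stage testable end to end.

## Worked example

```r
library(perturbnet)

cfg <- pipeline_config(
  ensemble = list(n_networks = 200, member_frac = 0.9, ridge = 1e-3),
  n_random = 20)
res <- run_pipeline(cfg, seed = 11)
#> [   0.0s] generating synthetic dataset (113 taxa, 7 dates/condition)
#> [   0.0s] normalized: 113 taxa retained
#> [   0.1s] annotated taxa: 41 differential of 113
#> [   1.3s] co-occurrence: 8 clusters over 66 taxa
#> [   3.5s] network C: 10858 reliable of 12656 observed interactions
#> [   5.8s] network B: 11296 reliable of 12656 observed interactions
#> [   6.0s] niche: 21 taxa outside the non-influential band
#> [ 126.5s] motifs C: 94 significant records, 14 representative types
#> [ 258.5s] motifs B: 137 significant records, 23 representative types
#> [ 258.5s] PCA: PC1+PC2 explain 93.56% of variance

table(res$niche$niche_class)
#>  bioaug_niche control_niche          none
#>            11            10            92
```

Reading the output: 41 of 113 taxa shift abundance between conditions
(the generator planted 33); 21 taxa occupy a topological niche — they
gained (11) or lost (10) network centrality after the perturbation; and
each condition has its own set of representative 3-/4-node motif types.
`res$annotations`, `res$clusters`, `res$networks`, `res$niche` and
`res$motifs` hold the per-stage tables; `out_dir =` writes them as TSV.

Individual stages are exported (`annotate_taxa()`,
`build_cooccurrence_clusters()`, `ensemble_infer()` /
`reliability_filter()`, `centrality_profiles()` / `niche_scores()`,
`motif_census()` / `motif_significance()`, `generate_dataset()`) and can
be used on your own `read_abundance_table()` inputs.

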