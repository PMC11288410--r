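# lithnet

Time-binned similarity networks of artefact assemblages.

`lithnet` is for archaeologists and cultural-evolution researchers who
want to read social connectivity out of material culture: if two
site/level contexts share many of the same artefact types, they were
plausibly exchanging information. The package implements the full
inference chain for geometric microliths — the trapeze / triangle /
segment projectile inserts common to Late Mesolithic and Early
Neolithic toolkits — and for any other artefact class describable by
closed categorical traits.

## What it computes

1. **Paradigmatic typology.** Each artefact is encoded as the
   cross-product of five traits (shape, symmetry, edge form, retouch
   mode, retouch direction; 540 possible cells). Types seen only once
   in the whole record are filtered out: a type that never recurs says
   nothing about contact.
2. **Calibration and binning.** Radiocarbon dates (errors ≤ 100 yr,
   no aggregate samples) are calibrated on a 1-year grid — posterior at
   calendar year *t* ∝ N(y; μ(t), σ² + τ(t)²) — and a context joins
   every 200-year bin that captures ≥ 35% of a date's two-sigma
   probability mass.
3. **Similarity.** Per bin, presence/absence of types gives a Jaccard
   matrix J(a,b) = |A∩B| / |A∪B|, rescaled across bins by
   `n_types(bin) / max(n_types)` so that type-poor windows cannot fake
   high similarity.
4. **Networks.** Per-bin undirected weighted graphs with density,
   global clustering (3·triangles / connected triples), within-component
   average path length, betweenness and eigenvector centrality,
   Leiden/CPM communities (γ = 0.02, 1000 iterations, 100 restarts),
   and the node turnover ratio between consecutive bins,
   NTR = (created − destroyed) / |N_t|.
5. **Small-world test.** Each network against 1000 Erdős–Rényi graphs
   matched exactly on nodes and density (G(n,m)), summarised by
   Watts–Strogatz σ = (C/C̄ᵣ)/(L/L̄ᵣ) and a clause-by-clause verdict.
6. **Bootstrap.** Multinomial re-draws of every context's type counts
   at fixed sample size, propagated through the whole network
   construction, with degree confidence bands and rank-stability
   scores.

A synthetic-data generator with planted regional communities
(`generate_synthetic()`) makes every stage testable offline, and
`recovery_experiment()` scores how well the pipeline recovers the
planted structure (adjusted Rand index per bin).

## Worked example

```r
library(lithnet)

cfg <- synth_config(n_sites = 8, n_regions = 2, concentration = 0.95,
                    seed = 7)
sim <- generate_synthetic(cfg, dir = "inputs")
res <- run_pipeline(sim$paths$assemblage, sim$paths$dates,
                    sim$paths$curve, "outputs", config = run_config(seed = 7))

res$metrics[, c("bin", "n_nodes", "n_edges", "density", "clustering",
                "apl", "n_communities")]
#>         bin n_nodes n_edges density clustering apl n_communities
#> 1 8200-8001       2       1     1.0      0.000 1.0             1
#> 2 7600-7401       3       3     1.0      1.000 1.0             1
#> 3 7400-7201       5       9     0.9      0.875 1.1             1
#> 4 7200-7001       4       6     1.0      1.000 1.0             1
#> 5 7000-6801       4       6     1.0      1.000 1.0             1

res$ntr
#>        from        to created destroyed n_nodes   ntr
#> 1 8200-8001 7600-7401       3         2       3  0.33
#> 2 7600-7401 7400-7201       2         0       5  0.40
#> 3 7400-7201 7200-7001       3         4       4 -0.25
#> 4 7200-7001 7000-6801       2         2       4  0.00
```

Reading it: only bins with at least two dated, type-bearing contexts
become networks (the empty bins are logged and skipped). The dense,
near-complete graphs are what a single well-mixed synthetic region
produces; `ntr` then tracks membership churn — e.g. the
7400–7201 → 7200–7001 transition loses four contexts and gains three,
giving (3 − 4)/4 = −0.25. With the networks complete, the matched
random graphs are identical to the observed ones and σ = 1 exactly, the
correct null result.

The package also ships the published per-site/level summary of the
Western Mediterranean microlith record (`study_site_levels()`,
totals 976 / 924 pieces) and its per-bin diversity table
(`study_bin_summary()`); e.g.

```r
study_type_spearman()
#> rho = -0.118, p = 0.763   # type diversity is not a sample-size artefact
```

The full documentation of models, conventions and design decisions is
in the vignette, `vignettes/similarity-networks.Rmd`.

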