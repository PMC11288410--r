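---
title: "Inferring time-binned similarity networks from artefact assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring time-binned similarity networks from artefact assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lithnet)
```

## The problem

When communities exchange information, the material culture they produce
tends to converge: two sites that share many of the same artefact types
are more plausibly connected than two that share few. `lithnet` turns
that premise into a reproducible inference pipeline for geometric
microliths — small trapezoidal, triangular or segment-shaped stone
projectile inserts that were manufactured by both Late Mesolithic
foragers and Early Neolithic farmers — but nothing in the machinery is
specific to that artefact class: any assemblage describable by a small
set of closed categorical traits will do.

The pipeline proceeds in five stages, each usable on its own:

1. **Typology.** Each artefact is encoded as a composite *paradigmatic
   type*: the unordered cross-product of five trait dimensions (shape,
   symmetry, edge form, retouch mode, retouch direction) with no
   hierarchy among traits. The vocabulary is closed (3 x 2 x 6 x 3 x 5 =
   540 possible cells) and encoding is a bijection, so classifications
   are exactly reversible. Types observed only once in the whole record
   carry no information about contact and are filtered out with their
   records (`filter_shared_types()`).
2. **Chronology.** Radiocarbon dates are calibrated against a
   standard-format curve and each dated context is assigned to 200-year
   calendar bins wherever at least 35% of a date's two-sigma probability
   mass falls (`assign_time_bins()`).
3. **Similarity.** Per bin, a contexts-by-types contingency table is
   binarised to presence/absence and turned into a Jaccard similarity
   matrix, then rescaled across bins by relative type diversity
   (`jaccard_matrix()`, `normalise_similarity()`).
4. **Networks.** Each bin's matrix becomes an undirected weighted graph
   whose structural metrics (density, transitivity, average path
   length), community structure (Leiden under the Constant Potts Model)
   and node turnover across bins are computed (`network_metrics()`,
   `ntr()`), together with a matched random-graph small-world test
   (`small_world_test()`).
5. **Uncertainty.** A bootstrap re-draws each context's type counts at
   fixed sample size and propagates them through the whole similarity /
   network construction (`bootstrap_bin()`).

## Models and conventions

### Calibration and binning

Calibration is the standard intercept-free probabilistic scheme: for a
measurement $y \pm \sigma$ and a curve with mean $\mu(t)$ and error
$\tau(t)$ (linearly interpolated to a 1-calendar-year grid), the
posterior at calendar year $t$ is proportional to
$\exp\!\left(-\tfrac{(y-\mu(t))^2}{2(\sigma^2+\tau(t)^2)}\right)$,
normalised to sum to 1 over the grid. The "two sigma" set is the
highest-posterior-density set accumulated in descending probability to
at least 0.954 mass — not a central interval, so multi-modal posteriors
on wiggly curves are handled naturally (a central-interval variant would
differ only there).

Dates with errors above 100 years and dates on aggregated samples are
discarded before calibration; the error rule is strictly "greater than",
so a 100-year date survives. Sample-selection judgements that require
stratigraphic knowledge (preferring short-lived materials, vetting the
association between artefact and dated unit) are curatorial metadata,
not computation, and are deliberately out of scope.

Three choices in the binning rule were genuinely open and are therefore
configurable, with the defaults chosen as the most literal reading of
the 35%-of-two-sigma-mass rule:

* **Mass base.** The fraction is computed on the two-sigma-restricted
  posterior *renormalised to 1* (`mass_base = "two_sigma"`); the raw
  full-posterior fraction is available (`"full"`). Renormalisation is
  the default because "probability mass calibrated at two sigma" reads
  most naturally as a statement about the two-sigma distribution.
* **Multiple dates per context.** A bin qualifies when *any* single
  date gives it at least the threshold (`combine = "any"`); an AND-mode
  exists. The OR reading is what lets a context whose two dates sit in
  different windows legitimately span three consecutive bins, the
  behaviour documented for real multi-date contexts.
* **Bin edges.** `"8600-8401"` denotes the closed calendar-year set
  {8600, ..., 8401} cal BP; bins tile the range with no shared years.

Assignment is monotone in the threshold (raising it never adds a bin),
and with a threshold at or below 0.5 a date whose two-sigma mass lies
inside the binned range always lands somewhere.

For published tables that report only a context's occupation *time
frame* rather than per-date posteriors, `frames_to_bins()` maps frames
onto bins by an overlap-of-at-least-100-years rule (half a bin). The
half-bin cutoff both forgives frames whose printed endpoints are a year
off the grid (e.g. `7400-7200`) and refuses memberships supported by a
single overlapping year.

### Similarity and the diversity normalisation

Binarisation before Jaccard is intentional: raw frequencies confound
similarity with site function, preservation and excavation intensity, so
only presence carries signal (a frequency-weighted coefficient such as
Brainerd-Robinson is deliberately not offered). Pairs with an empty type
union score 0 by convention — unreachable after the shared-type filter,
but guarded.

Across bins, the number of types in play varies strongly, and type-poor
bins reach high Jaccard values more easily. The cross-bin correction
multiplies each bin's matrix by `n_types(bin) / max(n_types)`, leaving
the most diverse bin untouched and shrinking the others linearly. The
literature that motivates normalising to the most diverse window states
the intent but not the algebra; the linear-in-relative-diversity scaling
used here is this package's reconstruction, it is strictly monotone (so
within-bin pair orderings are preserved), the applied factor is emitted
in all outputs, and `normalise = FALSE` switches it off for sensitivity
analysis.

### Network metrics

Structural metrics are computed on the **unweighted topology** —
density $2m/n(n-1)$, global clustering by the triangle method
(3 x triangles / connected triples), average path length over reachable
pairs only (so fragmented graphs average within components), raw-count
betweenness and max-1-scaled eigenvector centrality — while **community
detection uses the edge weights**. This split mirrors the defaults of
the desktop network tools practitioners use, and it is what makes a
complete similarity network report clustering 1 and APL exactly 1
regardless of its weights. `weighted = TRUE` variants exist.

Leiden is run with the Constant Potts Model objective
$Q=\sum_c\left[w_{in}(c) - \gamma\binom{n_c}{2}\right]$ at resolution
$\gamma = 0.02$, 1000 iterations and 100 restarts by default; restarts
are seeded and the best partition by CPM quality is kept. The reported
`quality_norm` divides the objective by the total edge weight, which
maps the *returned* partition into [0, 1] (the singleton partition
scores 0, a penalty-free all-capturing partition 1); it is a
convention, labelled as such, not a probability. On graphs of up to
five or six nodes the implementation is checked against exhaustive
enumeration of all set partitions.

The node turnover ratio between consecutive bins is
$\mathrm{NTR}_t = (|N_t \setminus N_{t-1}| - |N_{t-1} \setminus N_t|)
/ |N_t|$: positive when nodes are being created, negative when
destroyed, 0 for balanced or identical transitions, and antisymmetric
under swapping the creation and destruction counts.

### Small-world testing

Each observed network is compared against 1000 Erdős–Rényi graphs
matched on node count and density. "Same density" is implemented as the
fixed-edge-count model $G(n,m)$ with $m = \mathrm{round}(d\,n(n-1)/2)$,
so the match is exact in every replicate ($G(n,p)$ is available); a
complete observed graph therefore has an ensemble of identical complete
graphs and $\sigma = 1$ exactly. The Watts–Strogatz coefficient is
$\sigma = (C/\bar C_{rand}) / (L/\bar L_{rand})$, NaN whenever the
observed clustering or either path-length term is undefined (clustering
0, null clustering 0, or an edgeless graph). Null replicates that come
out edgeless have no APL and are excluded from the null mean with a
reported count.

Because the literature argues small-worldness verbally, the verdict rule
is an explicit codification with each clause reported separately:
`small_world` needs observed clustering above the null upper quartile,
observed APL at or below the null mean, and $\sigma > 1$; `candidate`
relaxes only the APL clause (random graphs have short paths *per se*, so
failing to undercut them is not disqualifying).

### Bootstrap

Each replicate redraws every context's type counts from a multinomial
with the observed proportions at the observed $n$ — sample sizes are
conserved exactly — and rebuilds the binary matrix, Jaccard and network.
Record-level resampling with replacement would be equivalent and is not
separately implemented. The per-context statistic summarised is the
weighted degree (row sum of similarities to the other contexts), with
2.5%–97.5% bands and a rank-stability score (share of replicates in
which the context's degree rank moves by at most one position); the
exact plotted statistic in the motivating workflow is under-specified,
so the report names its statistic explicitly.

## The synthetic generator

`generate_synthetic()` emulates the empirical record's shape: ~12 sites
with 1–3 levels each, per-context counts of 1–200 pieces, dates with
20–100-year errors spanning 8600–6801 cal BP, and planted regional
structure — each region's type profile puts a configurable
`concentration` of its mass on region-exclusive types drawn from the
540-cell paradigm (1 = disjoint supports, 0 = a single shared profile).
Trait tuples, not abstract type ids, are generated, so the typology
encoder is exercised end to end. Dates are measured on an identity toy
curve (calendar age = radiocarbon age) by default, keeping tests
self-contained; any real curve file can be substituted.

What passing tests on synthetic data do **not** show: the generator has
no taphonomic loss, no spatial autocorrelation beyond the planted
regions, no correlation between context age and type profile drift, and
its date errors are honest Gaussians. Recovery results on it bound the
pipeline's correctness, not the interpretability of any real record.

`recovery_experiment()` runs the full pipeline on a generated dataset
and scores the Leiden partition against the planted regions with the
adjusted Rand index per bin (the degenerate all-singleton case, where
the ARI formula is 0/0, is scored 1 exactly when the co-membership
relations agree). With disjoint regional supports recovery is exact;
mixing the profiles degrades it monotonically.

## Numerical choices and degenerate inputs

* Calibration grid: 1 calendar year; curve interpolation linear; curves
  are re-sorted ascending and must be strictly monotone in cal BP.
* A date outside the curve's radiocarbon range is an error, not a
  truncated posterior.
* Jaccard with an empty union is 0; the matrix diagonal is 1.
* Edgeless graphs: APL and sigma are undefined (error / NaN), never 0.
* Transitivity with no connected triples is 0.
* Bins with fewer than two populated contexts are skipped with a
  message; the pipeline continues.
* Every stochastic routine takes an explicit integer seed, and equal
  seeds reproduce ensembles, bootstrap reports and output files
  byte-for-byte.

## Worked example

```{r example, eval = FALSE}
cfg <- synth_config(n_sites = 8, n_regions = 2, concentration = 0.95,
                    seed = 7)
sim <- generate_synthetic(cfg, dir = "inputs")
res <- run_pipeline(sim$paths$assemblage, sim$paths$dates,
                    sim$paths$curve, "outputs")
res$metrics      # per-bin density, clustering, APL, communities
res$ntr          # node turnover between consecutive bins
res$smallworld$table
```

The test suite runs the same stages at reduced problem sizes (50–200
null and bootstrap replicates, 10-iteration/10-restart Leiden on graphs
of at most a dozen nodes, a 10,000-replicate ensemble only for the
null-clustering convergence check); these sizes are the package's own
choices for its examples and checks, while the analysis defaults in
`run_config()` remain the full 1000/1000/100 settings.

## Known limitations

* The diversity normalisation is a reconstruction (see above); its
  factor is linear in relative type diversity by design, not by
  derivation.
* The turnover statistic depends only on node sets, not on edge
  structure; a bin whose membership is unchanged but whose ties are
  rewired scores 0.
* Frame-based bin membership (`frames_to_bins()`) is a coarsening of
  per-date assignment: contexts whose published membership depended on
  calibration detail finer than their printed frame can land
  differently.
* No Bayesian phase modelling, reservoir corrections, outlier handling
  or summed-probability demography; calibration here serves binning
  only.
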