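# nichedomains

Data-driven climate regionalization from species distributions.

Classical climate classifications (Köppen and its descendants) delimit
regions from climate variables alone. `nichedomains` derives **climatic
niche domains** — and the **climate regions** that are their geographic
footprints — from the organisms themselves: the realized climatic niches of
many species, projected into a binned two-dimensional climate space and
clustered as a weighted bipartite network.

## The method in brief

1. **Climate space.** Two co-registered rasters (an energy surrogate such
   as potential evapotranspiration and a water surrogate such as annual
   precipitation) are block-averaged to a coarse analysis grid and each
   axis is cut into `d` quantile intervals over all land cells, giving a
   grid of climatic bins. Each species' occupied cells become a niche
   profile `w[i,j]` — the proportion of species `j`'s occurrences in bin
   `i` (rows sum to 1).
2. **Network and domains.** Bins and species form the two node sets of a
   weighted bipartite network with links `w[i,j] > 0`. Niche domains are
   modules minimizing the **map equation** `L(M) = q H(Q) + Σ_m p_m H(P_m)`
   (description length, in bits, of a random walk under partition `M`),
   found by a multi-restart greedy search with optional hierarchical
   refinement.
3. **Robustness.** Within-cell fine-pixel climates are resampled with
   replacement (bootstrap), the network rebuilt and re-clustered; a
   domain's support is the fraction of bootstrap partitions containing a
   module with Jaccard similarity > 0.5 to it.
4. **Geography.** Bin specificity `S_i = Σ_{j∈D} w[i,j] / Σ_j w[i,j]`
   (Eq. 1) maps transition zones; its projection `S_P` is compared with
   the actual specificity `S_A` computed from the species present in each
   cell (Eq. 2); the **geographical signal**
   `G = (1/N) Σ_q |S_A(q) − S_P(q)|` (Eq. 3) quantifies the mismatch
   between a domain's climate and its species' geography.
   Regionalizations are compared with adjusted mutual information (exact
   hypergeometric chance correction).

A synthetic-world generator plants climate archetypes with controllable
niche overlap and geographic restriction, providing recoverable ground
truth for every step.

## Worked example

```r
library(nichedomains)

cfg <- run_config(
  world      = world_config(fine_shape = c(120L, 120L), seed = 7L),
  archetypes = default_archetypes(breadth = 0.06, n_species = 60L),
  d = 12L, n_runs = 50L, n_runs_boot = 30L, B = 20L, seed = 7L
)
res <- run_pipeline(cfg)
#> simulate: 240 species on 295 coarse land cells
#> filter: 240 species kept (removed 0)
#> bin: 12 x 12 effective divisions, 125 occupied bins
#> network: 88 bins, 240 species, W = 240
#> domains: 4 finest domains, L = 5.59563 bits
#> bootstrap: support quantiles 1 1 1 1 1
#> signal: G = 0 over 195 cells

res$support
#>   domain n_bins n_species support
#> 1      1     36        60       1
#> 2      2      9        60       1
#> 3      3     30        60       1
#> 4      4     13        60       1
```

Four archetypes were planted; four domains come back, each containing
exactly its 60 planted species (adjusted mutual information 1.0 against
the planted labels), every domain has full bootstrap support, and the
geographical signal is ~0 because no geographic restriction was applied.
`res` also carries the region map (`res$regions`), the specificity rasters
(`res$S_P`, `res$S_A`), and a per-domain summary (`domain_summary()`).

The numbered scripts under `analysis/` run the full set of experiments —
world simulation, division selection, domain detection with bootstrap
support, the niche-overlap sweep, and the geographic-restriction signal
experiment — writing their tables under `results/`.

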