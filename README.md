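# trophoscape

Tools for analysing the **trophic structure of large-mammal communities**:
which feeding guilds exist, how guild assemblages cluster into recurring
community trophic structures across a global grid, how those structures track
climatic thresholds, and how human pressures push communities out of their
climatically expected structure into simplified ones.  The package is aimed
at macroecologists working with gridded species assemblages and
diet-composition data, and ships a synthetic-data generator that emulates the
statistical structure of such data so the entire pipeline is testable without
any external data products.

## The core statistic

Both guilds (species clustered in diet space) and structures (cells clustered
in guild-count space) are found with fuzzy c-means.  The number of
*well-defined* clusters is chosen with the average membership degree (AMD)
validity statistic,

```
AMD = (1/n) * sum_j MD_j  -  1/c
```

where `MD_j` is sample *j*'s membership to its nearest fuzzy cluster, `n` the
number of samples and `c` the number of clusters.  Randomly distributed data
give memberships near `1/c` and AMD near 0; crisp clusters push AMD towards
`1 - 1/c`.  Scanning `c` with hundreds of seeded restarts and keeping the
best AMD per `c` finds both the number of clusters and their degree of
definition.  Climatic thresholds are then recovered with globally optimised
(evolutionary) classification trees penalised per leaf, observed and
climate-predicted structure maps are compared with Cohen's kappa, and
observed-vs-predicted disagreements are typed and related to land-use and
population indicators via Student's t tests and impact trees.

## Worked example

Plant six Gaussian clusters in an 11-dimensional space and ask the AMD scan
how many well-defined clusters the data contain:

```r
library(trophoscape)
bench <- generate_cluster_benchmark(n = 2000, d = 11, k = 6, sd = 1, seed = 42)
scan  <- amd_scan(bench$samples, c_min = 2, c_max = 9, replicates = 20, seed = 1)
scan
#> AMD scan over c = 2..9 (20 replicates each)
#> selected c = 6 (best AMD 0.6246)
scan$curve
#>   c   best_amd replicates
#> 1 2 0.04556438         20
#> 2 3 0.27598392         20
#> 3 4 0.41907360         20
#> 4 5 0.53007902         20
#> 5 6 0.62457868         20
#> 6 7 0.56523597         20
#> 7 8 0.50557050         20
#> 8 9 0.47858027         20
```

The curve peaks exactly at the planted `c = 6`, and the peak height (0.62,
against the crisp-limit bound `1 - 1/6 = 0.83`) measures how well defined the
clusters are: rerunning with `sd = 1.7` still peaks at 6 but lower (~0.40),
and uniform-random samples stay near 0 at every `c`.

The full synthetic pipeline — world simulation, guild inference, structure
detection, random-forest interpolation, climate tree, transition typing,
energy networks — runs in one call:

```r
res <- run_pipeline(pipeline_config(seed = 1))
res
#> pipeline run (seed 1): 3000 cells, 330 species
#> structures detected: 6; climate-tree misclassification 0.033; kappa 0.674
```

`res$classification` holds per-cell structure labels with membership degrees
and provenance (clustered vs interpolated), `res$climate_tree` the fitted
threshold model (inspect with `extract_thresholds()`), `res$transitions` the
observed-vs-predicted disagreement typing, and `res$networks` one bipartite
resource-to-guild energy-flow network per structure.

See the vignette (`vignettes/trophic-structures.Rmd`) for the model details,
the synthetic world's design, and the package's numerical conventions.

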