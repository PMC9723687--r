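# rarescape

Null-model inference of the ecological processes that assemble rare and
common microbial biospheres.

Most microbial communities consist of a few abundant taxa and a long tail of
rare ones, and a central question in microbial ecology is which *assembly
processes* — variable selection, homogeneous selection, dispersal
limitation, homogenizing dispersal, or undominated drift — structure each
fraction. `rarescape` is for microbial ecologists with a rarefied ASV
feature table, sample metadata, and a rooted phylogeny (the standard output
of an amplicon pipeline) who want to quantify those processes per community
component, as is routinely done for soil successional and other
spatiotemporal designs.

## The method

For every pair of communities $(k, m)$ the package computes the
abundance-weighted between-community mean nearest taxon distance

$$\beta\mathrm{MNTD} = \tfrac12\Big[\textstyle\sum_i f_{ik}\min_j
\Delta_{i_k j_m} + \sum_i f_{im}\min_j \Delta_{i_m j_k}\Big]$$

and standardizes it against a tip-shuffling null (999 permutations) into
$\beta\mathrm{NTI}$. Pairs with $\beta\mathrm{NTI} > +2$ are classified as
variable selection, $< -2$ as homogeneous selection. Remaining pairs go to
the abundance-based Raup–Crick statistic on Bray–Curtis dissimilarity,
$RC_{bray} \in [-1, 1]$, built from 999 null assemblies that preserve each
sample's richness and read total: $RC_{bray} > +0.95$ means dispersal
limitation, $< -0.95$ homogenizing dispersal, in between undominated. The
fractions of pairs per process, per biosphere component (rare / common /
whole, split at fixed or sample-specific h-index-style rarity cutoffs) and
per grouping (temporal: same stage; spatial: same time, different stage)
form the assembly report. A Sloan neutral-model fit (occurrence frequency
vs. mean abundance, migration parameter $m$) provides a phylogeny-free
cross-check, and every ASV is typed as permanently/conditionally/
transiently rare or permanently common.

A synthetic-data generator produces datasets under known assembly regimes
(Gaussian niche filtering on a phylogenetically conserved trait, neutral
drift chains, disjoint dispersal pools) so the whole pipeline is validated
by parameter recovery — no external data needed.

## Worked example

Simulate a community assembled under one shared strong habitat filter
(homogeneous selection is the known truth), run the pipeline, and read the
report:

```r
library(rarescape)

ds <- simulate_dataset(scenario_config("homogeneous_selection",
                                       n_taxa = 200, design = c(2, 2, 3),
                                       depth = 2000, seed = 1))
run <- run_full_analysis(ds$table, ds$metadata, ds$tree,
                         cutoff = 0.001,          # 0.1% rarity cutoff
                         n_null_bnti = 199, n_null_rc = 199,
                         full_tree_null = TRUE,   # tree = known regional pool
                         seed = 101)
run
#> assembly_run
#>   cutoff component     grouping variable_selection homogeneous_selection
#> 3  0.001    common          all                  0                 98.48
#> 5  0.001     whole          all                  0                 87.88
#> 6  0.001     whole within_stage                  0                 83.33
#>   dispersal_limitation homogenizing_dispersal undominated n_pairs
#> 3                    0                      0        1.52      66
#> 5                    0                      0       12.12      66
#> 6                    0                      0       16.67      30
```

87.9% of all whole-community pairs are classified as homogeneous selection
— the generating regime is recovered. The rarity typing for the same run:

```r
table(run$types$type)
#>          permanently_rare          transiently_rare conditionally_rare_common
#>                         3                         4                        38
#>        permanently_common
#>                         0
```

And the Sloan neutral model, fitted to the whole community, confirms that
this dataset is far from neutral (a negative R² means the neutral curve
fits worse than a flat line — expected, since selection generated it):

```r
fit_sloan(ds$table)
#> sloan_fit: m = 0.001834 (N*m = 3.7), R^2 = -1.926 over 45 ASVs
```

On neutral-drift data the same call recovers the generating migration
parameter within ±20% (see `simulate_sloan_dataset()`).

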