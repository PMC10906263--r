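# paleoregions

Bioregion-based species richness and geographic range analysis for fossil
occurrence data, built for the question of how crown mammals replaced the
stem-mammal lineages (tritylodontids, docodonts, morganucodontids,
haramiyidans of disputed affinity) through the Mesozoic — but applicable to
any two-group comparison over Paleobiology-Database-style occurrence
tables.

The fossil record samples space and time unevenly, so raw richness counts
and raw range sizes mostly measure collecting effort. `paleoregions`
controls for this in three ways:

* **Bioregions.** Within each time bin, collections are grouped by paired
  hierarchical clustering — on great-circle distance (average linkage, cut
  at a node height of 100 km) and on modified Forbes taxonomic distance
  (`1 − F'`, with `F' = a(n+√n) / (a(n+√n) + 1.5bc)`; cut at 0.5) — and a
  bioregion is a set of collections sharing a cluster in *both* analyses:
  a geographically continuous area with a distinct assemblage.
* **Coverage-quorum richness (SQS).** Per bioregion and group, taxon
  richness is estimated at a fixed sample coverage (Good–Turing
  `Ĉ = 1 − (f₁/n)·(n−1)f₁/((n−1)f₁+2f₂)`; quorum 0.9) by hypergeometric
  rarefaction and Chao1-type extrapolation, so comparisons are made at
  equal completeness rather than equal effort.
* **MST range fractions.** A group's geographic range per bin is the
  minimum-spanning-tree length over the collections where it occurs,
  divided by the MST length over all collections — the fraction of the
  sampled world it occupies.

Because the crown/stem placement of Haramiyida is unsettled, every analysis
can be run under three scenarios (`haramiyida_crown`, `haramiyida_stem`,
`haramiyida_polyphyletic`). A synthetic-world generator with known
bioregions, abundance structure and planted range restrictions provides
ground truth for every stage.

## Worked example

Generate a two-bin world with four bioregions per bin where stem species
are confined to two of the four regions, then run the full analysis:

```r
library(paleoregions)

spec  <- world_spec(n_bins = 2, K = 4, stem_region_whitelist = c(1, 2),
                    seed = 7)
world <- generate_world(spec)
cfg   <- run_config(occurrences = world[c("occurrences", "collections")],
                    bins = world$bins, scenario_name = "haramiyida_crown")
res   <- run_pipeline(cfg)
res
#> paleoregions result: 2 bin(s), 8 bioregion(s), 823 of 823 occurrences used

res$bin_means
#>    bin group n_bioregions mean_richness
#> 1 bin1 crown            4      2.731957
#> 3 bin1  stem            2      1.871809
#> 2 bin2 crown            4      3.400716
#> 4 bin2  stem            2      1.452998

subset(res$ranges, select = -absent)
#>    bin group n_collections    mst_km total_mst_km  fraction
#> 1 bin1 crown            40 25714.237     25714.24 1.0000000
#> 2 bin1  stem            20 16008.409     25714.24 0.6225504
#> 3 bin2 crown            40 16073.864     16073.86 1.0000000
#> 4 bin2  stem            19  6278.689     16073.86 0.3906148
```

Reading the output: crown mammals occur in all four bioregions of each bin
and span the whole sampled range (fraction 1); stem mammals yield quorum
estimates only in their two whitelisted regions, with lower mean richness
at coverage 0.9, and occupy 62% / 39% of the sampled range — the planted
restriction, recovered. `res$richness` holds the per-bioregion points
behind the means, `res$proportions` the crown share of taxa in bioregions
containing both groups, and `res$log` accounts for every input occurrence
(`used` or `excluded` with a reason).

Real data enter through `read_occurrences()` (PBDB flat CSV dialect,
configurable column map), `read_bins()` or the bundled `mesozoic_stages()`
stage table, and the same `run_config()`.

## Command line

```sh
Rscript -e 'paleoregions::cli_main()' generate --seed 7 --k 4 \
    --stem-whitelist 1,2 --out world/
Rscript -e 'paleoregions::cli_main()' run --occurrences world/occurrences.csv \
    --bins world/bins.csv --scenario crown --out results/
```

`run` writes tidy CSVs (`bioregions`, `richness`, `bin_means`,
`proportions`, `ranges`, `log`) from which the usual richness-through-time,
crown-proportion and range-fraction figures can be drawn.

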