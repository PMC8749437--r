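# cladeflow

Population-genomic dissection of a bacterial species that has split into two
habitat-associated lineages — for example a *Streptomyces* species with
free-living (FL) and insect-associated (IA) isolates. Starting from a
core-genome alignment, a pan-genome gene matrix, sample metadata and growth
phenotypes, `cladeflow` quantifies how strongly the two lineages are
differentiated, how much DNA still flows between them, and whether geography
or habitat better explains the genetic structure.

It is aimed at microbial population genomicists who already have the
upstream products (ortholog clustering, core alignment, ClonalFrameML runs)
and want the downstream statistics to be reproducible, testable R code
rather than one-off scripts.

## What it computes

* **Clade-specific variation.** SNP extraction from the core alignment;
  clade-specific SNPs (disjoint allele sets between clades, the dimorphic
  subset being fixed differences); sliding-window SNP density with
  fold-over-mean peak calling; clade-specific genes (universal in one clade,
  absent from the other) from the presence/absence matrix.
* **Differentiation.** Sliding-window Hudson-type
  F<sub>ST</sub> = 1 − π<sub>within</sub>/π<sub>between</sub>, where
  π<sub>within</sub> is the unweighted mean of the two within-clade mean
  pairwise difference rates and π<sub>between</sub> the between-clade rate,
  with per-pair, per-site exclusion of gaps/N (default 5-kb windows, 2.5-kb
  step).
* **Recombination.** r/m = (R/θ) × δ × ν from ClonalFrameML parameters
  (rate ratio × mean import length × import divergence); donor-origin
  classification of recombination tracts by p-distance of each imported
  fragment to every leaf and internal node, with an ambiguity band and an
  external-origin distance cap; per-clade origin summaries.
* **Pan-genome structure.** Core / accessory / strain-specific /
  single-copy-core partition; Jaccard distances d on accessory gene
  repertoires; neighbor-joining and average-linkage trees.
* **Geography vs ecology.** Haversine geographic distances, 0/1 habitat
  contrasts, phylogenetic distances (patristic or p-distance); Mantel and
  partial Mantel permutation tests of isolation-by-distance against
  isolation-by-environment.
* **Phenotype.** Growth rate as the maximum-slope well-fitting window of an
  absorbance time series (ABS450 h⁻¹) and Mann-Whitney U comparisons
  between lineages.
* **Ground-truth simulation.** A two-clade forward simulator
  (`simulate_dataset()`) with planted fixed differences, recombination
  tracts with known donor classes, habitat-specific genes, clade-confounded
  geography and a planted growth effect, so every stage is testable without
  any external genomes.

## Worked example

```r
library(cladeflow)

cfg <- sim_config(n_clade_a = 6, n_clade_b = 8, core_length = 50000, seed = 42)
sim <- simulate_dataset(cfg)

snps <- extract_snps(sim$alignment)
cs   <- clade_specific_snps(snps, sim$truth$clade_assignment)
fst  <- window_fst(sim$alignment, sim$truth$clade_assignment)
track_summary(fst)
#>   stat   mean     sd n_windows n_defined window  step
#> 1 fst   0.710 0.0469        20        20   5000  2500
```

The 14 simulated genomes carry 4,598 SNPs of which 990 are clade-specific
(926 fixed differences), and the genome-wide window F<sub>ST</sub> is
0.710 ± 0.047 (mean ± SD) — strong but incomplete differentiation, as
expected for recently diverged sister lineages with ongoing recombination.

```r
geo <- geo_distance_matrix(sim$metadata)
hab <- habitat_matrix(sim$metadata)
phy <- phylo_distance_matrix(aln = sim$alignment)
ord <- rownames(geo)
partial_mantel_test(phy[ord, ord], hab[ord, ord], geo, n_perm = 9999, seed = 1)
#> r = 0.9790, p = 0.0004      # habitat explains divergence...
partial_mantel_test(phy[ord, ord], geo, hab[ord, ord], n_perm = 9999, seed = 1)
#> r = 0.0174, p = 0.3168      # ...geography, controlling habitat, does not
```

Habitat type predicts phylogenetic distance when geographic distance is
controlled for; geography has no residual effect — the
isolation-by-environment signature, recovered here even though habitat and
geography are deliberately confounded in the simulated sampling design.

```r
origins <- assign_origins(sim$truth$recomb_events, sim$alignment,
                          source_panel(sim), sim$truth$clade_assignment)
summarize_origins(origins, sim$truth$clade_assignment)
#>   clade origin_call            n total percent
#> 1 FL    external              97   380    25.5
#> 2 FL    internal-ambiguous    69   380    18.2
#> 3 FL    other-clade           37   380     9.7
#> 4 FL    within-clade         177   380    46.6
#> ...
```

With literature-scale import lengths (δ ≈ 88 bp) a substantial fraction of
tracts is intrinsically ambiguous — short fragments carry too few
informative sites to pin a donor clade — which mirrors what origin
classification reports on real data.

```r
rates <- growth_rates(sim$growth)
compare_growth(rates, sim$truth$clade_assignment)
#>   condition    U_a  U_b p_value ...
#> 1 control       17   31 0.414
#> 2 iron_limited   0   48 0.000666
```

The planted IA growth advantage under iron limitation is detected
(Mann-Whitney U, exact two-sided p), while the control condition shows none.

`run_pipeline(out_dir, cfg)` chains all stages and writes every artifact
(FASTA, TSV tracks and tables, Newick, JSON summaries) plus a manifest with
the seed and input checksums.

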