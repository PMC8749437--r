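---
title: "Methods: quantifying differentiation and gene flow between two bacterial lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying differentiation and gene flow between two bacterial lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladeflow)
```

`cladeflow` analyses a bacterial species that has diverged into two
habitat-associated lineages. This vignette is the package's account of the
models and procedures it implements, the parameters that matter, and the
design choices made where more than one defensible option existed.

## The setting

A set of conspecific genomes (average nucleotide identity well above the
~95–96% species cutoff) splits into two clades that coincide with habitat
type — say, free-living (FL) versus insect-associated (IA) — and, as is
common in practice, also with geography. The analytical questions are:

1. How differentiated are the clades along the core genome (F~ST~,
   clade-specific SNPs and genes)?
2. How much homologous recombination occurs, and where do imported
   fragments come from (within the recipient's clade, the other clade, or
   outside the species)?
3. Does habitat or geography better predict genetic distance, given that
   the two are confounded in the sampling design?
4. Do the lineages differ phenotypically (growth rates across conditions)?

## Differentiation statistics

**SNP extraction.** An alignment column is polymorphic if at least two
distinct bases among `A C G T` occur in it; gaps and `N` never create or
suppress polymorphism on their own. A SNP is *clade-specific* when the two
clades' allele sets (missing data excluded) are disjoint, and a
clade-specific SNP with exactly two alleles overall is a *fixed
difference* (the "dimorphic" subset). Sites at which one clade has only
missing data are skipped and reported: specificity is undefined there.

**Windows.** All coordinates are 0-based half-open. Sliding windows of
`window` bp (default 5000) advance by `step` bp (default 2500); the final
partial window is emitted only if at least `step` long, so every emitted
window supports at least half a window of data. A genome shorter than one
window yields a single truncated window with a warning. SNP counts place a
SNP in every window containing it, so overlapping windows intentionally
count each SNP about `window/step` times; the per-window mean reported
alongside uses the same convention. Peak calling selects windows at or
above `fold` (default 4) times the genome-wide mean and merges selected
windows that overlap or abut, because overlapping windows would otherwise
report one locus twice.

**F~ST~.** The per-window statistic is the Hudson-type
$F_{ST} = 1 - \pi_w/\pi_b$, with $\pi_w$ the unweighted mean of the two
within-clade mean pairwise difference rates and $\pi_b$ the between-clade
mean pairwise rate. Each pair's rate uses only sites valid in both
sequences; a pair with no valid site drops out of its window mean. Windows
with $\pi_b = 0$ are undefined and excluded from the genome-wide mean and
SD. The estimator was chosen for transparency — it can be checked against
a brute-force enumeration of all sample pairs, which the test suite does to
$10^{-12}$ — and is deliberately not clamped: values below 0 (within-clade
diversity exceeding between-clade divergence) are informative, and
$F_{ST} = 1$ occurs exactly when clades are internally invariant but
different. A clade represented by one sample contributes within-clade
diversity 0 by convention, with a message.

## Recombination

**r/m arithmetic.** The relative impact of recombination versus mutation on
the per-site substitution rate is the product $(R/\theta)\,\delta\,\nu$ of
the ClonalFrameML-style parameters: recombination-to-mutation rate ratio,
mean import length (bp) and per-site divergence of imported DNA. The
package multiplies; the point of `rm_table()` is a tested, reusable record
of that column of arithmetic, plus readers for ClonalFrameML's
`importation_status` and EM output files.

**Origin assignment.** For each recombination tract the recipient's
imported fragment is compared by p-distance (pairwise deletion) to every
panel sequence — all leaves and internal nodes, the recipient excluded.
With $m$ the minimum distance over the whole panel:

* if $m > \tau$ the fragment is *external*: no sampled lineage, ancestral
  or extant, is close enough to be its source;
* otherwise classification uses the clade-labelled sources only. With
  $m_c$ their minimum, every labelled source within $(1+\varepsilon)m_c$
  votes; a single clade yields *within-clade* or *other-clade* relative to
  the recipient, and both clades yield *internal-ambiguous*. Nodes labelled
  `ancestral` support the external test but cast no clade vote; this keeps
  the rule monotone — shrinking $\varepsilon$ can only turn ambiguous calls
  into specific ones, never the reverse, because the band always contains
  its own argmin.

Defaults are $\varepsilon = 0.1$ (relative band) and $\tau = 0.045$
(1.5 times the default clade split depth, comfortably above within-species
distances and far below the ~0.09+ p-distance of external material).
Tracts with fewer than 10 pairwise-valid sites get no call.

A point worth stating plainly: with literature-scale mean import lengths
(δ on the order of 88 bp) the three origin classes are *intrinsically*
blurred — an 88-bp fragment carries roughly $88 \times$ (clade split) ≈ 2–3
informative sites, so a large ambiguous fraction is a property of the data,
not a defect of the rule. The package's origin-recovery validation
therefore runs in an identifiable regime (kb-scale tracts, ~200 events),
where per-class recall against simulator truth exceeds 90%; at δ ≈ 88 the
same machinery reproduces the realistic mix of specific and ambiguous
calls.

## Pan-genome structure

Core genes are present in every genome, accessory genes in some but not
all, strain-specific genes in exactly one, and single-copy core genes have
exactly one copy everywhere; a gene absent from all genomes is not a
pan-genome member and is dropped with a warning. Jaccard distances
$d = 1 - |G_i \cap G_j| / |G_i \cup G_j|$ are computed on accessory
(dispensable) repertoires by default — the informative fraction — with a
flag for whole-pan-genome distances; a pair of empty repertoires gets
$d = 0$ with a warning rather than an error. Neighbor joining is delegated
to `ape::nj` (standard Q-criterion agglomeration; negative branch lengths
are not adjusted) and validated in the tests against closed-form three-taxon
solutions and additive matrices. For a presence/absence clustering in the
style of pan-genome overview figures, average-linkage hierarchical
clustering on Jaccard distances is provided; the linkage is an explicit
approximation, since such figures rarely state one.

## Geography versus ecology

Geographic distances are haversine great circles on a sphere of radius
6,378,137 m (the common geospatial default). Samples without coordinates
are excluded listwise before matrix construction, never pairwise, and the
exclusion is logged. Habitat contrasts are 0 within type and 1 between
types; more than two habitat types is an error unless a multi-class flag is
set, because the design is binary. Phylogenetic distances come either from
a tree (patristic) or from the alignment (p-distance, pairwise deletion).

**Mantel machinery.** The Mantel statistic is the Pearson correlation of
upper-triangle vectors; the null jointly permutes rows and columns of the
first matrix, and the one-sided (greater) p-value is
$(1 + \#\{r_{perm} \ge r_{obs}\})/(n_{perm}+1)$. An exhaustive mode
enumerates all $n!$ relabellings for exact small-sample p-values. The
partial Mantel statistic is the first-order partial correlation
$r_{ab\cdot c}$; its null permutes matrix `a` only and recomputes the full
partial statistic each time. This permute-raw-matrix scheme is the
simplest defensible choice and is stated here deliberately, since
implementations differ and the choice matters. One-sided-greater is the
default because the scientific question is directional (does habitat
*increase* genetic distance?); a negative-association result then shows up
as p near 1, and a two-sided flag exists.

Partial Mantel tests are known to be anticonservative when the predictor
and the control matrix are nearly collinear: with only two sampling
regions perfectly aligned with habitat, cor(geography, habitat) approaches
1, the partial statistic's denominator collapses, and the geography test
rejects far above its nominal level even when geography has no effect. The
simulator therefore mirrors a design that breaks the collinearity the way
real multi-region sampling does: the free-living clade is drawn from two
far-apart sampling regions (default centroids in Central America for the
IA clade and East Asia plus the southern Indian Ocean for FL), so
within-habitat geographic distances span the same order of magnitude as
between-habitat ones. Under that design the package's recovery experiment
(100 simulations, study-sized 8 + 29 sampling) finds the habitat partial
test significant and the geography partial test non-significant in ≥95% of
replicates, and the plain Mantel test holds its 5% level on independent
null matrices.

## Growth phenotypes

The growth rate of an absorbance time series is the slope of its linear
range, operationalised as: fit OLS to every contiguous window of at least
`k_min` points (default 5, i.e. 2 h at 30-min sampling) and take the
maximum slope among windows with $R^2 \ge$ `r2_min` (default 0.95). If no
window fits well enough the maximum-slope minimal window is returned with a
`low_fit` flag rather than an error, so plate-scale screens do not stop on
one noisy well. A perfectly flat window counts as a perfect fit with slope
0. The estimate is invariant to adding a constant to all readings and
scales inversely with time units.

Group comparisons use the Mann-Whitney U test with midrank ties: exact by
full enumeration when the combined sample size is ≤16 with no ties (the
suite verifies exactness against enumeration for every tie-free split up
to n = 10), otherwise the normal approximation with tie and continuity
corrections. Replicates are aggregated to strain means by default — the
strain, not the well, is the biological unit — with a flag to rank
replicate slopes directly.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` is a forward simulator on the simplest genealogy that
produces the two-clade signal: a species root, two clade ancestors
(split mutations half on each branch, expected per-site divergence
`split_depth`), and a star topology within each clade (terminal branches
with per-site mutation probability `theta`). Mutations are finite-sites,
resampling uniformly among the three alternative bases; homoplasy is
allowed and simply happens. Recombination imports geometric-length tracts
(mean `tract_mean`, truncated at the genome) at uniform positions,
`Poisson(rho_rel × theta × core_length)` events per genome, so
`rho_rel` plays the role of R/θ and the realized import-to-mutation
substitution ratio has closed-form expectation
`rho_rel × tract_mean × donor_div` — which the tests verify by Monte
Carlo. Donors are the recipient's clade ancestor (within), the other clade
ancestor (other), or an independent external lineage drawn per event at
3 × `split_depth` from the root (external donors must be more distant than
either clade, and independent draws prevent two external imports from
mimicking a shared within-species source). Each donor fragment is further
mutated at `donor_div`. Tracts are placed without overlap within a
recipient so donor truth and substitution accounting stay exact.

Default parameters describe a 37-genome, two-habitat species:
8 + 29 samples, `split_depth = 0.03` (between-clade ANI ≈ 97%),
`theta = 0.002`, `rho_rel = 0.5`, `tract_mean = 88` bp,
`donor_mix = (0.6, 0.1, 0.3)` over within/other/external, and
`donor_div = 0.005`. `donor_div` is the divergence of an import from its
class reference, not the aggregate import divergence a ClonalFrameML-style
ν estimates: under the default mix the emergent divergence of imported DNA
from its recipient is ≈ 0.6×0.005 + 0.1×0.035 + 0.3×0.094 ≈ 0.035, i.e.
the package-level ν of such a dataset sits near the mid-0.03s, as reported
for real two-lineage species. The default core length is 200 kb — a
working scale that keeps a full simulate-analyse cycle in seconds; the
validation experiments in the test suite use 10–200 kb genomes, 100-seed
replication for the Mantel recovery, 10 seeds elsewhere, all chosen as the
smallest sizes at which the statistics under test are stable.

Habitat-specific genes are planted as universal-in-one-clade/absent-in-the-
other blocks (defaults 98 and 150 genes, with 560 shared core genes, a 2%
chance of a second copy of a core gene in one genome to exercise the
single-copy definition, and ~740 random accessory genes); `gene_noise`
flips planted cells for robustness experiments and is 0 by default so
recovery is exact. Geography places the IA clade around (10°N, 84°W) and
alternates FL samples between (35°N, 105°E) and (30°S, 70°E) with 500-km
Gaussian jitter — the clade-confounded, two-region design discussed above.
Growth curves are piecewise lag/linear/plateau with Gaussian noise
(σ = 0.005 ABS450) and a planted +0.03 ABS450 h⁻¹ effect for the IA clade
under the `iron_limited` condition only.

What the simulator does *not* model, and what passing tests therefore do
not show: no within-clade coalescent structure (the star topology makes
within-clade pairs exchangeable — real lineage structure would add
covariance the F~ST~ and Mantel machinery would still handle, but recovery
rates would differ), no selection, no insertions/deletions (gap handling is
exercised by injected missing data instead), no ancestral recombination
shared by clade subsets, and growth effects on a single condition only.
Conclusions about real data should lean on the correctness guarantees (the
oracle-checked statistics) rather than on the recovery percentages, which
are properties of the simulated conditions.

## Degenerate inputs and numerical conventions

* Alignments are uppercased on read; `U` maps to `T` and anything outside
  `A C G T N -` maps to `N` with a counted warning; ragged or
  duplicate-id FASTA is an error naming the offender.
* A donor mixture that does not sum to 1 is rejected, never silently
  renormalised.
* Windows with no surviving comparison, pairs with no valid site, and
  all-missing clade sites are reported as undefined/skipped, never imputed.
* The Mantel p-value can never be 0 by construction; zero-variance
  matrices are rejected before permutation.
* Neighbor joining breaks ties as `ape::nj` does; determinism of the whole
  pipeline rests on the single seed recorded in every manifest.
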