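# resistome

Gene-centric profiling of arsenic resistance and metabolism genes in soil
genomes and metagenomes.

Arsenic is among the most widespread toxic elements in soil, and microbial
communities shape its fate: efflux pumps and cytoplasmic reductases
detoxify it, while arsenite oxidases and respiratory arsenate reductases
couple its redox chemistry to energy metabolism. `resistome` implements a
complete, tested analysis pipeline for nine marker genes of these processes
— *acr3*, *arsB* (arsenite efflux), *arsC* (grx), *arsC* (trx) (cytoplasmic
arsenate reduction), *arsD*, *arsM* (methylation), and *aioA*, *arrA*,
*arxA* (arsenic energy metabolism) — for microbial ecologists working with
complete-genome collections and gene-targeted metagenome assemblies.

## What it computes

Starting from homology-search hit tables (bit score *S*, percent alignment
*A* against the gene HMM), the quality cascade retains a hit iff

    S > 100  and  A > 90%        (all genes)
    S > 1000                      (additionally for aioA, arrA, arxA)

with strict inequalities, keeps only the top-scoring hit per ORF, and
tallies retained hits into a genome × gene × location (chromosome/plasmid)
genotype matrix. Downstream, the package provides:

- **Phylogenetic signal** of binary gene-presence traits via Blomberg's
  *K*: with phylogenetic GLS mean *â* and tip covariance *V*,
  *K* = (MSE₀/MSE)ₒᵦₛ / (MSE₀/MSE)ₑₓₚ, tested by permuting tip values and
  comparing phylogenetically corrected MSEs, with Benjamini–Hochberg FDR
  over the trait family.
- **Abundance estimation** two ways: cultivation-weighted expectation
  Â(s, g) = Σₖ wₛₖ cₖ𝑔 under 16S-inferred organism weights, and
  cultivation-independent normalization of coverage-adjusted gene counts to
  per-site *rplB* (single-copy marker) totals.
- **Biogeography**: greedy centroid clustering of assembled protein
  variants at 90% amino-acid identity, abundance–occupancy tables, and
  endemic (< 3 sites) versus cosmopolitan classification; Mann–Whitney U
  comparisons and a Mantel test of haversine geographic distance against
  Bray–Curtis gene-content dissimilarity.
- **Synthetic study conditions**: seeded generators for genomes, hit
  tables, trees, traits, sites, variant FASTAs and organism weights, each
  with a machine-readable truth ledger, so every stage is testable without
  external downloads.

## Worked example

```r
library(resistome)

g  <- generate_genomes(n_genomes = 200, seed = 42)   # planted genotypes
pr <- process_hits(g$hits, g$genomes)                # screen + dedup + taxonomy
pr$report
#> Hit screening report
#>   input rows:          423
#>   rejected (score <= 100):     34
#>   rejected (alignment <= 90): 28
#>   rejected (aioA/arrA/arxA score <= 1000): 9
#>   retained:            352

gm <- build_genotype_matrix(pr$hits, g$genomes)
gm
#> Genotype matrix: 200 genomes x 9 genes
#>   copies: 338 chromosomal, 14 plasmid-borne
#>   genomes with >= 1 gene: 167 (83.5%); none: 33 (16.5%)
```

The screening report partitions every input row into retained and per-rule
rejected counts; the genotype matrix print shows the chromosome/plasmid
split and the fraction of genomes testing positive for no gene. A
phylogenetic-signal test on a clade-clustered trait:

```r
tree <- ape::rcoal(64)
tr   <- simulate_traits_on_tree(tree, "clustered", prevalence = 0.25, seed = 1)
signal_test(tr, tree, seed = 1, name = "acr3|chromosome")
#> Phylogenetic signal tests (1 trait(s), 999 permutations)
#>            trait n_positive     K     p p_adjusted low_power
#>  acr3|chromosome         16 4.714 0.001         NA     FALSE
```

*K* ≫ 1 and p = 0.001 (the permutation floor at 999 permutations): close
relatives share the trait far more than chance. Endemism of assembled
variants across sites:

```r
s   <- generate_sites(8, seed = 42)
cl  <- greedy_cluster(dereplicate(s$variants), 90)
res <- classify_occupancy(cl)
res$endemic_count / nrow(res$clusters)
#> endemic clusters: 112 of 113 (99.1%)
```

Most variant clusters occur at fewer than three sites — the planted
biogeographic structure the classifier recovers exactly.

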