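---
title: "Methods: gene-centric arsenic resistome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-centric arsenic resistome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistome)
```

## Scope and model

`resistome` profiles nine marker genes of microbial arsenic detoxification
and metabolism across two kinds of input: replicon-resolved complete
genomes (a cultivation-dependent view) and gene-targeted assemblies from
soil metagenomes (a cultivation-independent view). The package's unit of
evidence is a *hit*: one match of a gene's HMM against an ORF, carrying a
bit score and the percent of the HMM model length covered by the
alignment. Everything downstream — genotypes, phylogenetic signal,
abundances, biogeography — is derived from retained hits or from assembled
protein variants with coverage-adjusted abundances.

The pipeline assumes hits were produced upstream by an hmmsearch-style
scan with a sequence e-value cutoff around 1e-10; that cutoff is a
producer-side contract, not re-applied here.

## The quality-filter cascade

`screen_hits()` retains a hit iff score > 100 bits AND percent alignment
> 90, and additionally score > 1000 bits for *aioA*, *arrA* and *arxA*.
All four comparisons are strict. The elevated threshold exists because
these genes belong to large oxidoreductase families whose non-arsenic
homologs produce mid-score hits against complete genomes; a manual
inspection step motivating it is not automatable, so the elevated floor is
the rule this package applies. The stringent 90% model coverage is
appropriate because the searches target complete genomes, where truncated
genes are not expected.

Rows failing several rules are attributed to the first failing rule in
score → alignment → elevated order, so the report's rejection counts
partition the input exactly (`retained + Σ rejected = input`).

`dedup_orfs()` keeps the top-scoring hit per (genome, ORF). Score ties are
broken by the canonical gene ordering `arsenic_genes()` — a deterministic,
row-order-invariant rule chosen because the data give no other basis; the
tie can only occur between different gene models with identical bit
scores, which the synthetic generator never produces but real data could.

## Genotype matrices and summaries

`build_genotype_matrix()` tallies deduplicated hits into genome × gene
copy counts split by replicon type. Genomes with no retained hit remain as
all-zero rows: the fraction of genomes testing positive for *no* gene is a
headline quantity (`none_fraction()`), and dropping those rows would bias
it. A genome "tests positive" for a gene when it has at least one retained
copy on either replicon; `plasmid_fraction()` by contrast is a
*copy-level* proportion (plasmid copies over all copies of that gene),
because mobile copies, not carrier genomes, are the quantity of interest
for horizontal transfer.

`phylum_gene_proportions()` reports carrier-based proportions (each
carrier genome counted once per gene); a hit-based variant would weight
multi-copy genomes more heavily and is deliberately not the default.

## Blomberg's K and the permutation test

For a tip trait x on a tree with tip covariance V (shared branch length;
`phylo_vcv()`), with phylogenetic GLS mean
â = (1ᵀV⁻¹1)⁻¹ 1ᵀV⁻¹x:

- MSE₀ = Σᵢ(xᵢ − â)² / (n − 1) — the phylogenetically naive error;
- MSE = (x − â)ᵀV⁻¹(x − â) / (n − 1) — the phylogenetically corrected
  error;
- K = (MSE₀/MSE) / [(tr V − n / Σᵢⱼ(V⁻¹)ᵢⱼ) / (n − 1)].

K ≈ 1 under Brownian evolution, ≈ 0 for phylogenetically random traits; on
a star phylogeny the expected ratio collapses and K = 1 exactly for any
non-constant trait — the package's analytic check. Binary presence/absence
traits are analyzed with this continuous-trait statistic directly,
mirroring how the test is applied to genotypes in practice; this is a
fidelity choice, not a methodological endorsement (threshold models or the
D-statistic are out of scope).

`signal_test()` permutes tip-to-value assignments (999 by default, with
the add-one estimator p = (1 + #{MSEₚₑᵣₘ ≤ MSEₒᵦₛ}) / (n + 1), so p > 0
always), orienting the null so that *smaller* corrected MSE than permuted
data means signal. `fdr_adjust()` applies Benjamini–Hochberg — the default
meaning of "FDR-adjusted" absent further qualification — over all testable
traits of one run; constant traits are flagged untestable and excluded
from the family. Traits with fewer than 5 positive or 5 negative tips are
reported but flagged `low_power`.

Numerical choices: V is inverted directly; if numerically singular, a
ridge of 1e-8 × mean diagonal is added (and message()d). Permutations are
drawn under a private RNG stream seeded by the `seed` argument, so results
are reproducible without touching the session RNG.

**Known attenuation under dichotomization.** The calibration band "mean
K ≈ 1" holds for continuous Brownian traits (the test suite verifies
K against an independent direct-formula implementation and the picante
reference). Thresholding a Brownian trait at the prevalence quantile —
the generator's `brownian_threshold` mode — discards the trait's
magnitude information and attenuates K to roughly half its continuous
calibration on standard 64-tip tree shapes; the acceptance script reports
this measured mean alongside the other quantities. Threshold traits still
carry clearly *more* signal than random traits (an ordering the unit
suite asserts), but users should not expect K ≈ 1 from binarized
Brownian controls.

## Abundance estimators

`cultivation_weighted_abundance()` computes Â(s, g) = Σₖ wₛₖ cₖ𝑔 with
per-sample weights summing to 1 (±1e-6) and cₖ𝑔 the genome's total copy
number (a presence-based variant sits behind `use_presence = TRUE`;
copy-based is the default because the estimate is an abundance, not a
prevalence). The estimator is linear in the weights, so averaging sample
estimates within a soil order is identical to estimating under
order-averaged weights — the two conceivable orderings of "mean normalized
abundance per soil order" coincide and only one table is emitted.

`rplb_normalize()` divides each site's coverage-adjusted gene count by the
site's total count of *rplB*, a universal single-copy ribosomal protein
gene, giving an approximate per-genome frequency invariant to sequencing
depth. A gene that was not assembled at a site is recorded as explicitly
*not detected* (`detected = FALSE`, `normalized = NA`), never as zero:
failure to assemble does not demonstrate absence, and cross-site summaries
default to the conservative convention of using detecting sites only.
The one deliberate exception is `gene_content_distance()`, where
dissimilarities require complete vectors and undetected genes enter as 0;
this asymmetry is intentional and documented here.

`community_structure()` flags the six most abundant phyla per site and
warns when they cover less than 75% of the community, the convention used
when summarizing *rplB*-based community composition.

## Variant clustering and endemism

`pairwise_identity()` computes a global Needleman–Wunsch alignment with
guide scores match +1, mismatch 0, gap open −5, gap extend −1 (a gap of
length L costs 5 + L), then identity = 100 × matches / alignment columns,
excluding terminal-gap columns from the denominator — ragged assembly ends
are tolerated, internal indels are penalized. The alignment engine is
Biostrings; the test suite checks optimal scores against an independently
coded Gotoh dynamic program.

`greedy_cluster()` is deterministic UCLUST-style centroid clustering
within each gene: sequences in decreasing total-abundance order (ties:
longer first, then lexicographic id) join the first centroid at ≥ the
threshold (default 90%) or found a new one. Any threshold-consistent
method recovers the planted partition on the synthetic fixtures because
their identity bands are disjoint by construction (below).
`classify_occupancy()` labels a cluster endemic iff it is present (summed
coverage-adjusted abundance > 0 — no minimum-abundance floor) at fewer
than three distinct sites. The endemic proportion is reported over
clusters; a dereplicated-sequence denominator would differ and is
recoverable from the members table.

## Comparative statistics

`mann_whitney()` uses U = #{xᵢ > yⱼ} + ½#{xᵢ = yⱼ}; the two-sided p-value
comes from the exact null distribution when both n ≤ 10 with no ties
(where it equals full enumeration, as the test suite verifies), otherwise
from the normal approximation with tie and continuity corrections.

`mantel()` correlates upper triangles (Pearson) and permutes one matrix's
labels, one-sided for positive association — the conventional orientation
for distance-decay hypotheses. When n! does not exceed the requested
permutation count the test enumerates *all* relabelings and the p-value is
exact; otherwise it samples with the add-one estimator. Geographic
distances are haversine with Earth radius 6371 km; gene-content
dissimilarity defaults to Bray–Curtis on rplB-normalized abundances
(Jaccard and Euclidean are available), the field default for
compositional data when no metric is otherwise specified.

## The synthetic study conditions

The generators define the conditions under which the pipeline is tested;
their defaults were chosen once, on the following grounds, and are not
tuned to test outcomes.

- `generate_genomes()`: 25 phyla; one chromosome and 0–3 plasmids per
  genome; an expected 14.3% of genomes carry no profiled gene; per-gene
  unconditional prevalences (`default_genotype_prevalence()`) echo the
  qualitative ranking seen in complete soil genomes (*arsC* (grx) most
  common at 0.45, efflux pumps intermediate, energy-metabolism genes rare
  at 0.01–0.04). True hits draw scores uniformly on 150–2500 (1100–2500
  for the elevated genes) and alignment on 92–100; decoys (rate 0.3 per
  genome) draw score 20–99, alignment 10–89, or score 110–999 for
  elevated genes. No generated score falls in [100, 110) or [1000, 1100):
  the score bands are disjoint from the thresholds, so planted-genotype
  recovery is an exact test, not a statistical one. An `adversarial` mode
  instead emits hits exactly at score 100, score 1000 and alignment 90 to
  pin the strict inequalities.
- `generate_sites()`: protein variants of length 150 (transporter-like
  genes) or 120 (the small reductases) are mutated from per-gene random
  ancestors; cluster ancestors are redrawn until all between-cluster
  differences are ≥ 0.25 per residue while members stay within 0.02 of
  their ancestor, so within-cluster identity is ≥ 96% and between-cluster
  identity ≤ 79% — disjoint bands with margin around the 90% threshold.
  Shared-pool clusters (0.7% by default) are emitted with identical
  residue strings at 3 or more sites; local clusters occur at exactly one
  site. Per-site *rplB* totals are uniform on 50–500; coordinates come
  from five continental bounding boxes so geographic distances are
  non-degenerate for Mantel testing.
- `generate_organism_weights()`: flat-Dirichlet weights per sample
  (gamma draws normalized to 1 within 1e-9), soil orders cycled across
  samples.
- Every generator writes/returns a truth ledger (planted genotype table,
  cluster membership and occupancy, realized endemic proportion, totals);
  recovery tests compare against ledgers, never against re-derived
  quantities. Identical arguments and seed give byte-identical outputs;
  all draws happen under a private RNG stream.

What the generators do **not** emulate: sequencing error and read-level
noise, assembly chimeras, realistic amino-acid substitution processes,
correlated gene co-occurrence (operons), phylogenetically structured
genotypes (planted genotypes are independent across genomes, so genuine
genotype–phylogeny signal is absent by design and signal tests on
synthetic genotypes are null controls), and taxon-abundance skew. Passing
tests therefore demonstrate correctness of the computations under planted
truth, not robustness to real-data noise.

## Problem sizes

The shipped checks use 922 genomes for genotype recovery, a 64-tip tree
with 200 Brownian-threshold replicates and 500 permutation-test replicates
(999 permutations each) for signal calibration, 8–16 sites for clustering
and endemism, and 200 replicates for Mantel test size — sizes at which
every property is informative while a full run stays comfortably
interactive.

## Limitations

- The K test treats binary traits as continuous (see the attenuation note
  above); no threshold-model alternative is provided.
- The Mantel metric, permutation count and sidedness for real historical
  analyses vary across studies; the defaults here are documented choices,
  and a published Mantel r is not reproducible from this package without
  the original site profiles.
- Identity is defined relative to one optimal alignment; co-optimal
  alignments with different identity values are possible for unusual
  sequences, in which case the engine's tie-breaking decides.
- The screening cascade does not model the manual inspection of low-score
  hits that motivated the elevated thresholds; it applies the resulting
  rule only.
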