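---
title: "Circular-shift enrichment of miRNA target genes in GWAS top signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular-shift enrichment of miRNA target genes in GWAS top signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirshift)
```

## The question the pipeline answers

Suppose a family-based GWAS has produced, for every SNP on a genotyping
array, a posterior probability of association that moved up or down from a
shared prior. Suppose, separately, that a set of miRNAs is biologically
implicated in the phenotype (here: miRNAs depleted when the microprocessor
component DGCR8 is haploinsufficient, as in the 22q11.2 deletion syndrome),
and a CLIP-seq compendium lists the genes those miRNAs bind. The question is
whether the genes lying near the strongest association signals are enriched
for targets of those miRNAs — evidence that the association signals act
through the miRNA regulatory layer.

`mirshift` implements that test end to end:

1. **Evidence screen** (`classify_evidence()`, `summarize_association()`):
   each SNP is *for* association if its posterior exceeds the prior,
   *against* if below, *uninformative* if equal (within a tolerance,
   default 1e-12). Percentages are quoted over informative SNPs.
2. **Selection** (`select_top_fraction()`): the top `fraction` (default
   0.005) of the *for* SNPs, ranked by posterior, become a boolean mask
   over the genome-ordered SNP array. The count is
   `floor(fraction * n_for)` — with 14,705 positive SNPs the default
   fraction selects exactly 73. Ties break by genome order.
3. **Tiered SNP-to-gene mapping** (`map_snps()`): for each selected SNP,
   search half-width windows of 25 kb, 250 kb, 500 kb, 1 Mb and stop at the
   first tier that captures at least one gene; return *all* genes at that
   tier. Gene-dense regions therefore contribute tight candidate sets while
   gene-poor regions can still nominate distant genes, mirroring how
   long-range cis-regulation concentrates in gene deserts.
4. **Target set** (`map_orthologs()`, `build_target_set()`): source-species
   miRNAs are mapped (many-to-many) to their orthologs; a gene is a target
   when it interacts — with support from at least `min_support = 2` CLIP-seq
   experiments per miRNA–gene pair — with at least `min_mirnas = 2` distinct
   miRNAs of interest.
5. **Circular-shift permutation test** (`run_permutation_test()`): the
   statistic is the fraction of mapped candidate genes that are targets.
   The null rotates the selection mask along the SNP array (chromosomes laid
   end-to-end in layout order) by an offset drawn uniformly from
   `{1, ..., N-1}`, re-maps the rotated selection through the same tiered
   algorithm, and recomputes the statistic.

## Why a rotation null

Array probes are not uniform along the genome, and top signals cluster
within linkage-disequilibrium blocks. A null that re-sampled SNPs
independently would destroy both structures and overstate significance.
Rotating the *pattern* of selected SNPs preserves its internal clustering
exactly and preserves the array's gene-density landscape, randomizing only
where the pattern falls. Offsets 0 and N are identity rotations and are
excluded, so the null never contains the observed configuration by
construction. (A rotation by N-k for small k can still land near the
original; that residual dependence is inherent to the scheme and vanishes
as N grows.)

The empirical p-value uses the add-one estimator with ties counted as at
least as extreme,

$$p = \frac{1 + \#\{b : \hat{f}_b \ge \hat{f}_{\mathrm{obs}}\}}{B + 1},$$

which can never report zero and is valid (conservative) for any number of
replicates.

## Coordinate and dialect decisions

* All internal coordinates are 0-based half-open (BED convention); readers
  accept 1-based inclusive tables via `one_based = TRUE`.
* "Within *w*" means point-to-interval distance at most *w*, **boundary
  inclusive**, measured to the nearest edge of the gene body (not the TSS).
  The choice is a documented convention, not an inference about how any
  particular study measured it.
* Windows clip at chromosome ends; the search never crosses a chromosome
  boundary.
* Chromosome order comes from the layout file, never from sorting names.
* Strand is stored and ignored: mapping distance is strand-agnostic.
* Duplicate interaction rows aggregate by **max** support: support counts
  experiments, so max is conservative and idempotent.
* Whether a CLIP-seq compendium's "two or more experiments" threshold
  applies per miRNA–gene pair or across miRNAs is ambiguous in such
  queries; we implement per-pair support and expose both `min_support` and
  `min_mirnas` so either reading is expressible.
* Ranking for selection defaults to the posterior (under a shared prior,
  posterior order is evidence order); `rank_by = "ratio"` ranks by
  posterior/prior for per-SNP priors. Which an upstream evidence engine
  used internally is not asserted.

The fast mapper indexes gene intervals per chromosome with
`IRanges::findOverlaps`; a deliberately naive exhaustive-scan twin,
`map_snp_bruteforce()`, shares no code with it and guards its correctness
on randomized instances in the test suite.

## The synthetic-study generator

Real inputs of this kind (250K-array genotypes, posterior tables, CLIP-seq
compendia) are not shippable, so `generate_study()` fabricates a complete,
internally consistent study. Defaults emulate the shape of the motivating
design: 221,996 SNPs over 22 numerically ordered chromosomes of tapering
length; ~20,000 genes placed by an inhomogeneous point process with
gene-rich and gene-poor blocks (so every mapping tier is exercised);
~14% of genes entering the interaction table, each with a zero-truncated
geometric number of distinct interacting miRNAs (success parameter 0.35,
chosen so the histogram over k = 1, 2, 3, ... decays like published
CLIP-seq interaction tables, with roughly a third of genes at k = 1);
interaction support at least 2 with probability 0.7; a shared prior of
0.04%; ~4% uninformative SNPs; and 7% of informative SNPs positive.
Posterior magnitudes are arbitrary ranks — only their order matters to
selection — because computing calibrated evidence values is out of scope.

Enrichment is planted **positionally**: `n_risk_genes` risk genes are drawn
(from the target set, or uniformly under the null regime) and every SNP
within 25 kb of one has its posterior odds multiplied by `boost`. The
planted signal must therefore survive the actual tiered mapping to be
detected, which makes the power tests exercise the full causal path the
enrichment hypothesis posits, not a label permutation.

A single root seed is split into fixed per-generator streams
(`(seed * 7919 + stream * 104729) mod 2147483647`), so each table can be
regenerated independently and bit-identically; `generate_study()` writes a
manifest sufficient to reproduce every file checksum.

What the generator does **not** emulate: linkage disequilibrium between
SNPs (selected top SNPs are exchangeable points, not LD clusters), the true
inter-probe spacing distribution of a real array (uniform by default, with
a crude clustered mode), isoform structure, and any correlation between
gene length and target status. Tests passing on synthetic studies
demonstrate the machinery's correctness and calibration under these
idealized conditions, not performance on real data.

## Scaled study sizes in the test suite

The statistical suites run on a scaled study: 4 chromosomes totalling
1e8 bp, 20,000 SNPs, and 6,000 genes of log-normal length
(meanlog = log 8000, sdlog = 0.8). The gene density is deliberately higher
than a human-genome pro-rata share: with the realistic positive-SNP rate
(7%) and selection fraction (0.005), a scaled study selects only ~6 SNPs,
and the granularity of the target-fraction statistic is set by how many
genes those SNPs map to. At pro-rata density each replicate would carry
only ~7 genes, and tie-heavy discrete fractions make the add-one estimator
visibly conservative; at the chosen density each replicate maps ~30 genes,
comparable in resolution to the motivating study's ~73, and the p-value is
calibrated. The calibration suite runs 200 independent null studies at 500
replicates each and checks that the fraction with p ≤ 0.05 lies inside the
exact binomial 95% interval around 0.05; the power suite checks that the
median p over 20 seeds is non-increasing over the planted-boost grid
{1, 10, 50}.

## A worked example

```{r example, eval = FALSE}
library(mirshift)

res <- run_study(
  config = list(
    simulate = TRUE,
    sim = list(n_chrom = 4, chrom_length = 2.5e7, n_genes = 6000,
               gene_length_law = c(log(8000), 0.8), n_snps = 20000,
               boost = 50, n_risk_genes = 20, risk_gene_source = "target"),
    n_sims = 2000),
  seed = 1, out_dir = tempfile("mirshift"))
res$result
```

On this planted-enrichment study the observed target fraction is around
19% against a null mean near 7%, with an empirical p of roughly 0.02 —
qualitatively the same picture as a real enriched study. Under
`risk_gene_source = "any", boost = 1` the same pipeline returns p-values
uniform on (0, 1].

## Numerical and degenerate-input behaviour

* `target_fraction()` on an empty mapped set returns fraction 0 with an
  `empty` flag rather than failing; the permutation test treats empty
  replicates the same way.
* `select_top_fraction()` refuses to select zero SNPs (`floor` of a small
  fraction) or to run with no positive SNPs, with actionable messages.
* Probabilities are validated at the boundary: priors strictly inside
  (0, 1), posteriors in [0, 1]; interaction support must be ≥ 1; tier
  half-widths strictly increasing.
* All generators restore the caller's RNG state (`withr::with_seed`), and
  `run_permutation_test()` is bit-identical for identical inputs and seed.

## Limitations

The mapper is purely positional: no LD-aware expansion, no eQTL or
regulatory-element integration, no TSS-anchored distances. The test
statistic ignores how *many* selected SNPs nominate the same gene. The
rotation null preserves clustering but assumes the array order is fixed and
known. These are properties of the reproduced scheme, not accidents of the
implementation.
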