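# mirshift

Circular-shift enrichment testing of miRNA target genes among the top
signals of a family-based GWAS.

## What it does, and for whom

When a GWAS is too small to yield genome-wide-significant hits, its top
signals can still be interrogated collectively: are the genes near the
strongest signals enriched for a biologically motivated gene set? This
package implements that analysis for miRNA target sets — built from
CLIP-seq interaction tables via ortholog-mapped miRNAs of interest — as
used to probe the miRNA-mediated risk hypothesis in 22q11.2 deletion
syndrome schizophrenia. It is aimed at statistical geneticists who have
per-SNP evidence tables (prior and posterior probabilities of association)
and want a positional, density-adaptive candidate-gene enrichment test with
a clustering-preserving permutation null.

The pipeline:

1. **Evidence screen** — a SNP gives evidence *for* association when its
   posterior exceeds the prior, *against* when below, and is
   *uninformative* when equal.
2. **Selection** — the top `fraction` (default 0.005) of positive SNPs,
   ranked by posterior, marked on the genome-ordered SNP array as a boolean
   mask; the count is `floor(fraction × n_for)`.
3. **Tiered SNP→gene mapping** — expanding half-width windows
   25 kb → 250 kb → 500 kb → 1 Mb that stop at the first non-empty tier,
   returning every gene in that window: tight candidate sets in gene-dense
   regions, long reach in gene deserts.
4. **Target set** — genes interacting (support ≥ 2 CLIP-seq experiments per
   pair) with ≥ 2 distinct miRNAs of interest.
5. **Circular-shift null** — the statistic is the fraction of mapped genes
   in the target set,

   *f* = |mapped ∩ targets| / |mapped|.

   The selection mask is rotated along the concatenated genome by a random
   offset in {1, …, N−1} and re-mapped through the same algorithm, B times
   (default 10,000); the empirical p-value is the add-one estimator
   p = (1 + #{f_b ≥ f_obs}) / (B + 1).

A synthetic-study generator (`generate_study()`) fabricates complete input
sets — genome, annotation, SNP array, interaction, ortholog and association
tables — under a null regime or with enrichment planted positionally near
miRNA-target genes, so the entire pipeline runs and is testable with no
external downloads.

## Worked example

```r
library(mirshift)

res <- run_study(
  config = list(
    simulate = TRUE,
    sim = list(n_chrom = 4, chrom_length = 2.5e7, n_genes = 6000,
               gene_length_law = c(log(8000), 0.8), n_snps = 20000,
               boost = 50, n_risk_genes = 20, risk_gene_source = "target"),
    n_sims = 2000),
  seed = 1, out_dir = "mirshift-out")
#> read 20000 SNPs, 6000 genes, 2625 interactions
#> evidence: 20000 total, 792 uninformative, 1538 for (8%), 17670 against (92%)
#> selected top 7 positive SNP(s) (fraction 0.005)
#> target set: 435 gene(s) from 65 miRNA(s)
#> observed: 7/36 target genes (19.4%); empirical p = 0.01349

res$result
#> Circular-shift enrichment test (7 selected SNPs, 2000 replicates)
#>   observed: 7 / 36 target genes (19.4%)
#>   null: mean gene count 35.9 (s.d. 13.5); mean target fraction 7.3%
#>   empirical p = 0.01349  (add-one estimator, ties counted as >=)
```

The selected SNPs sit near planted risk genes drawn from the miRNA target
set, so the observed target fraction (19.4%) clearly exceeds the rotation
null's mean (7.3%) and the test detects the enrichment (p ≈ 0.013). (The
boost also nudges the evidence mix: some SNPs near risk genes cross the
prior, so the positive share prints as 8% rather than the configured 7%.)
With
`risk_gene_source = "any", boost = 1` the same pipeline is calibrated:
p-values are uniform on (0, 1].

`run_study()` writes `enrichment.json` (all result fields plus seed and
config hash), `replicates.tsv` (per-replicate offset, gene count, hits,
fraction) and `selection.tsv`. A thin command-line wrapper with
`simulate | map | summarize | enrich | run-all` subcommands is installed at
`inst/cli/mirshift.R`.

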