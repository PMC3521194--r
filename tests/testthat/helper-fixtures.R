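# In-code fixtures shared across the suite.

tiny_layout <- function() genome_layout(c("chr1", "chr2"), c(2e6, 1e6))

tiny_genes <- function(layout = tiny_layout()) {
  gene_table(data.frame(
    gene_id = c("A", "B", "C"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100000, 600000, 50000),
    end = c(110000, 610000, 60000),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE), layout)
}

# regular SNP grid in genome order
tiny_array <- function(n = 20, layout = tiny_layout()) {
  per <- split(seq_len(n) - 1L,
               rep(seq_len(nrow(layout)), length.out = n))
  df <- do.call(rbind, lapply(seq_along(per), function(i) {
    k <- length(per[[i]])
    data.frame(snp_id = sprintf("s%d_%d", i, seq_len(k)),
               chrom = layout$chrom[i],
               pos = round(seq(1e4, layout$length[i] - 1e4, length.out = k)),
               stringsAsFactors = FALSE)
  }))
  snp_array(df, layout)
}

# association table with exact class counts; posteriors are distinct so the
# selection ranking is unambiguous
make_assoc <- function(array, n_for, n_against, n_uninformative,
                       prior = 4e-4) {
  n <- nrow(array)
  stopifnot(n_for + n_against + n_uninformative == n)
  posterior <- c(prior * (2 + seq_len(n_for) / n_for),        # > prior
                 prior * (seq_len(n_against) / (2 * n_against + 1)), # < prior
                 rep(prior, n_uninformative))
  association_table(data.frame(snp_id = array$snp_id, prior = prior,
                               posterior = posterior,
                               stringsAsFactors = FALSE))
}

# random (layout, genes, snp) instance for the mapper-equivalence property
random_mapping_instance <- function() {
  len <- sample(c(3e6, 5e6), 1)
  layout <- genome_layout(c("chr1", "chr2"), c(len, len / 2))
  n_genes <- sample(0:8, 1)
  genes <- if (n_genes == 0L) {
    data.frame(gene_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), strand = character(0))
  } else {
    chrom <- sample(layout$chrom, n_genes, replace = TRUE)
    start <- floor(runif(n_genes) * (.subset2(layout, "length")[
      match(chrom, layout$chrom)] - 2e4))
    data.frame(gene_id = paste0("g", seq_len(n_genes)), chrom = chrom,
               start = start, end = start + sample(200:15000, n_genes,
                                                   replace = TRUE),
               strand = "+", stringsAsFactors = FALSE)
  }
  genes <- gene_table(genes, layout)
  chrom <- sample(layout$chrom, 1)
  snp <- list(snp_id = "s", chrom = chrom,
              pos = sample.int(layout$length[match(chrom, layout$chrom)], 1) - 1)
  tiers <- if (runif(1) < 0.5) tier_config() else c(1e3, 1e4, 1e5, 5e5)
  list(layout = layout, genes = genes, snp = snp, tiers = tiers)
}

# scaled synthetic study used by the calibration and power suites: a 1e8 bp
# genome carrying a gene annotation dense enough that each permutation
# replicate maps a few tens of genes, preserving the granularity of the
# target-fraction statistic under scale-down
scaled_study_cfg <- function(seed, ...) {
  do.call(sim_config, utils::modifyList(
    list(seed = seed, n_chrom = 4, chrom_length = 2.5e7, n_genes = 6000,
         gene_length_law = c(meanlog = log(8000), sdlog = 0.8),
         n_snps = 20000),
    list(...)))
}

# run one scaled study end-to-end in memory and return the enrichment result
run_scaled_study <- function(seed, n_sims, perm_seed = seed + 1000L, ...) {
  cfg <- scaled_study_cfg(seed, ...)
  gn <- generate_genome(cfg)
  it <- generate_interactions(cfg, gn$genes)
  array <- generate_snp_array(cfg, gn$layout)
  targets <- build_target_set(
    it$interactions, map_orthologs(it$source_mirnas, it$orthologs)$mapped)
  assoc <- generate_association(cfg, gn$layout, gn$genes, array, targets)
  mask <- select_top_fraction(assoc, array)
  run_permutation_test(array, mask, gn$genes, targets = targets,
                       n_sims = n_sims, seed = perm_seed, layout = gn$layout)
}

# interaction table whose per-gene distinct-miRNA histogram matches a given
# (k, n_genes) table; support fixed at 2 experiments
interactions_from_histogram <- function(ks, n_genes, n_mirnas = max(ks)) {
  k_per_gene <- rep(ks, n_genes)
  gene_id <- sprintf("T%05d", seq_along(k_per_gene))
  data.frame(
    mirna_id = sprintf("miR-%02d", unlist(lapply(k_per_gene, seq_len))),
    gene_id = rep(gene_id, k_per_gene),
    support = 2,
    stringsAsFactors = FALSE)
}
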