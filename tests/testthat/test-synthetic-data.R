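small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chrom = 3, chrom_length = 4e6, n_genes = 300,
         gene_length_law = c(meanlog = log(5000), sdlog = 0.7),
         n_snps = 3000, n_mirnas = 12),
    list(...))
  do.call(sim_config, args)
}

test_that("generators are pure functions of the config", {
  cfg <- small_cfg(seed = 17)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  expect_identical(generate_interactions(cfg, g1$genes),
                   generate_interactions(cfg, g1$genes))
  a1 <- generate_snp_array(cfg, g1$layout)
  expect_identical(a1, generate_snp_array(cfg, g1$layout))
  expect_false(identical(g1$genes,
                         generate_genome(small_cfg(seed = 18))$genes))
})

test_that("generated tables pass validation and survive a disk round trip", {
  d <- withr::local_tempdir()
  st <- generate_study(small_cfg(seed = 5), d)
  layout <- read_layout(st$paths$layout)
  expect_equal(layout, st$layout)
  expect_equal(read_genes(st$paths$genes, layout), st$genes)
  expect_equal(read_snp_array(st$paths$snps, layout), st$array,
               ignore_attr = "layout")
  expect_equal(read_association(st$paths$association), st$assoc)
  expect_equal(read_interactions(st$paths$interactions), st$interactions)
  expect_equal(read_orthologs(st$paths$orthologs), st$orthologs)

  # regeneration with the same config reproduces every file bit-identically
  d2 <- withr::local_tempdir()
  st2 <- generate_study(small_cfg(seed = 5), d2)
  f <- setdiff(names(st$paths), "manifest")
  expect_identical(unname(tools::md5sum(unlist(st$paths[f]))),
                   unname(tools::md5sum(unlist(st2$paths[f]))))
})

test_that("gene placement follows the density blocks", {
  # intensity 10 on the first 20% vs 0.5 elsewhere: expected share of genes
  # in the first block is 2 / 2.4 = 83%
  share <- vapply(1:20, function(s) {
    cfg <- small_cfg(seed = s,
                     density_blocks = data.frame(intensity = c(10, 0.5),
                                                 fraction = c(0.2, 0.8)))
    gn <- generate_genome(cfg)
    cum <- c(0, cumsum(as.numeric(gn$layout$length)))
    pos0 <- cum[match(gn$genes$chrom, gn$layout$chrom)] + gn$genes$start
    mean(pos0 < 0.2 * sum(as.numeric(gn$layout$length)))
  }, 0)
  expect_gt(mean(share), 0.6)
  expect_lt(abs(mean(share) - 10 * 0.2 / (10 * 0.2 + 0.5 * 0.8)), 0.05)

  expect_equal(nrow(generate_genome(small_cfg(n_genes = 0))$genes), 0L)
  expect_error(generate_genome(small_cfg(
    n_genes = 300, gene_length_law = c(meanlog = log(1e6), sdlog = 1))),
    "infeasible packing")
})

test_that("per-gene miRNA counts decay like a zero-truncated geometric", {
  # degenerate law: every target gene interacts with exactly one miRNA
  cfg1 <- small_cfg(mirna_count_law = 1)
  gn <- generate_genome(cfg1)
  it1 <- generate_interactions(cfg1, gn$genes)
  h <- interaction_count_histogram(it1$interactions,
                                   sprintf("hsa-mir-%03d", 1:12),
                                   min_support = 1)
  expect_equal(h$n_mirnas, 1L)
  expect_length(build_target_set(it1$interactions,
                                 sprintf("hsa-mir-%03d", 1:12),
                                 min_support = 1)$gene_ids, 0)

  # p >= 0.5: aggregated histogram over 20 seeds is non-increasing in k
  counts <- integer(6)
  for (s in 1:20) {
    cfg <- small_cfg(seed = s, mirna_count_law = 0.5)
    it <- generate_interactions(cfg, gn$genes)
    h <- interaction_count_histogram(it$interactions,
                                     sprintf("hsa-mir-%03d", 1:12),
                                     min_support = 1)
    for (k in seq_len(6)) {
      counts[k] <- counts[k] + sum(h$n_genes[h$n_mirnas == k])
    }
  }
  expect_true(all(diff(counts) <= 0))
})

test_that("association tables hit the configured evidence mix", {
  cfg <- small_cfg(seed = 2, n_snps = 10000)
  gn <- generate_genome(cfg)
  array <- generate_snp_array(cfg, gn$layout)
  assoc <- generate_association(cfg, gn$layout, gn$genes, array)
  s <- summarize_association(assoc)
  n_inf <- s$n_total - s$n_uninformative
  # binomial tolerance (4 sd) around the configured rates
  expect_lt(abs(s$n_uninformative / s$n_total - cfg$frac_uninformative),
            4 * sqrt(cfg$frac_uninformative / s$n_total))
  expect_lt(abs(s$n_for / n_inf - cfg$frac_positive),
            4 * sqrt(cfg$frac_positive / n_inf))
})

test_that("boost = 1 makes the null and target regimes identical", {
  cfg_any <- small_cfg(seed = 9, boost = 1, risk_gene_source = "any")
  cfg_tgt <- small_cfg(seed = 9, boost = 1, risk_gene_source = "target")
  gn <- generate_genome(cfg_any)
  it <- generate_interactions(cfg_any, gn$genes)
  array <- generate_snp_array(cfg_any, gn$layout)
  targets <- build_target_set(
    it$interactions, map_orthologs(it$source_mirnas, it$orthologs)$mapped,
    min_support = 1, min_mirnas = 1)
  expect_identical(
    generate_association(cfg_any, gn$layout, gn$genes, array, targets),
    generate_association(cfg_tgt, gn$layout, gn$genes, array, targets))

  expect_error(generate_association(small_cfg(risk_gene_source = "target"),
                                    gn$layout, gn$genes, array,
                                    targets = NULL),
               "non-empty target set")

  # no positive SNPs -> downstream selection refuses
  cfg0 <- small_cfg(seed = 9, frac_positive = 0)
  a0 <- generate_association(cfg0, gn$layout, gn$genes, array)
  expect_error(select_top_fraction(a0, array), "nothing to select")
})

test_that("planted enrichment raises the observed target fraction", {
  frac <- function(s, source, boost) {
    cfg <- small_cfg(seed = s, n_snps = 6000, boost = boost,
                     risk_gene_source = source, n_risk_genes = 15)
    gn <- generate_genome(cfg)
    it <- generate_interactions(cfg, gn$genes)
    array <- generate_snp_array(cfg, gn$layout)
    targets <- build_target_set(
      it$interactions, map_orthologs(it$source_mirnas, it$orthologs)$mapped)
    assoc <- generate_association(cfg, gn$layout, gn$genes, array, targets)
    mask <- select_top_fraction(assoc, array, fraction = 0.05)
    m <- map_snps(as.data.frame(array)[mask, ], gn$genes, layout = gn$layout)
    target_fraction(m$union_genes, targets)$fraction
  }
  seeds <- 1:20
  planted <- vapply(seeds, frac, 0, source = "target", boost = 50)
  null <- vapply(seeds, frac, 0, source = "any", boost = 1)
  expect_gt(mean(planted), mean(null))  # paired over the same seeds
})
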