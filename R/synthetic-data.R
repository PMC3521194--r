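# Synthetic study generator: genome + annotation, SNP array, CLIP-seq-style
# interaction table, miRNA ortholog table, and association evidence, under a
# null regime or with enrichment planted positionally near risk genes.
#
# Every generator is a pure function of its config: a single root seed is
# split into fixed per-generator streams, so any table can be regenerated
# independently and bit-identically.

.child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647)
}

#' Configuration for a synthetic study
#'
#' Defaults emulate the shape of a 250K-array family GWAS screened against a
#' CLIP-seq interaction compendium: 221,996 SNPs over 22 numerically ordered
#' chromosomes, ~20,000 genes with gene-rich and gene-poor regions, ~14% of
#' genes appearing in the interaction table with a geometrically decaying
#' number of distinct interacting miRNAs, a prior probability of association
#' of 0.04%, ~4% uninformative SNPs, and 7% of informative SNPs showing
#' evidence for association.
#'
#' @param seed integer root seed.
#' @param n_chrom number of chromosomes; lengths taper linearly from 1.6x to
#'   0.4x `chrom_length` so early chromosomes are longest.
#' @param chrom_length mean chromosome length in bp.
#' @param n_genes number of genes.
#' @param gene_length_law `c(meanlog, sdlog)` of the log-normal gene length
#'   distribution in bp.
#' @param density_blocks data frame with columns `intensity` (relative gene
#'   placement intensity) and `fraction` (of the concatenated genome;
#'   fractions must sum to 1). Default creates gene-rich and gene-poor
#'   regions so every mapping tier is exercised.
#' @param n_snps number of SNPs.
#' @param snp_placement `"uniform"` (default) or `"clustered"`; real
#'   genotyping arrays have locally clustered probes, and the clustered mode
#'   is a crude stand-in for that.
#' @param n_mirnas number of (target-species) miRNAs of interest.
#' @param mirna_count_law success parameter of the zero-truncated geometric
#'   law for the number of distinct miRNAs interacting with a target gene.
#' @param support_law probability that an interaction has CLIP-seq support
#'   >= 2 experiments.
#' @param frac_target_genes fraction of genes that appear in the interaction
#'   table at all.
#' @param prior shared prior probability of association.
#' @param frac_uninformative expected fraction of SNPs whose posterior equals
#'   the prior.
#' @param frac_positive expected fraction of informative SNPs with posterior
#'   above the prior.
#' @param boost multiplicative inflation (>= 1) of the posterior odds of SNPs
#'   within `risk_window` of a risk gene; 1 disables planting.
#' @param n_risk_genes number of risk genes drawn.
#' @param risk_gene_source `"any"` (risk genes uniform over all genes: the
#'   null) or `"target"` (risk genes drawn from the miRNA target set:
#'   planted enrichment).
#' @param risk_window half-width in bp defining "near a risk gene".
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 22,
                       chrom_length = 1.25e8,
                       n_genes = 20000,
                       gene_length_law = c(meanlog = log(20000), sdlog = 1),
                       density_blocks = data.frame(
                         intensity = c(4, 1, 0.25),
                         fraction = c(0.2, 0.5, 0.3)),
                       n_snps = 221996,
                       snp_placement = c("uniform", "clustered"),
                       n_mirnas = 65,
                       mirna_count_law = 0.35,
                       support_law = 0.7,
                       frac_target_genes = 0.143,
                       prior = 4e-4,
                       frac_uninformative = 0.0414,
                       frac_positive = 0.07,
                       boost = 1,
                       n_risk_genes = 20,
                       risk_gene_source = c("any", "target"),
                       risk_window = 25000) {
  cfg <- list(seed = seed, n_chrom = n_chrom, chrom_length = chrom_length,
              n_genes = n_genes, gene_length_law = gene_length_law,
              density_blocks = density_blocks, n_snps = n_snps,
              snp_placement = match.arg(snp_placement), n_mirnas = n_mirnas,
              mirna_count_law = mirna_count_law, support_law = support_law,
              frac_target_genes = frac_target_genes, prior = prior,
              frac_uninformative = frac_uninformative,
              frac_positive = frac_positive, boost = boost,
              n_risk_genes = n_risk_genes,
              risk_gene_source = match.arg(risk_gene_source),
              risk_window = risk_window)
  probs <- c(cfg$support_law, cfg$frac_target_genes, cfg$prior,
             cfg$frac_uninformative, cfg$frac_positive, cfg$mirna_count_law)
  if (any(probs < 0 | probs > 1)) stop("probability parameters must lie in [0, 1]")
  if (cfg$boost < 1) stop("boost must be >= 1")
  if (abs(sum(cfg$density_blocks$fraction) - 1) > 1e-8) {
    stop("density_blocks fractions must sum to 1")
  }
  structure(cfg, class = "sim_config")
}

# chromosome offsets in the concatenated genome
.genome_offsets <- function(layout) {
  c(0, cumsum(as.numeric(layout$length)))
}

.pos0_to_chrom <- function(pos0, layout) {
  cum <- .genome_offsets(layout)
  i <- findInterval(pos0, cum, rightmost.closed = FALSE, left.open = FALSE)
  data.frame(chrom = layout$chrom[i], pos = pos0 - cum[i],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic genome layout and gene annotation
#'
#' Genes are placed by an inhomogeneous point process: the concatenated
#' genome is partitioned into blocks with relative intensities from
#' `cfg$density_blocks`, a block is chosen with probability proportional to
#' intensity x fraction, and the gene start is uniform within it. Lengths
#' are log-normal, clipped at the chromosome end; overlaps are permitted.
#'
#' @param cfg a [sim_config()].
#' @return List with `layout` (a [genome_layout()]) and `genes` (a validated
#'   annotation).
#' @export
generate_genome <- function(cfg) {
  taper <- if (cfg$n_chrom == 1L) 1 else seq(1.6, 0.4, length.out = cfg$n_chrom)
  layout <- genome_layout(paste0("chr", seq_len(cfg$n_chrom)),
                          round(cfg$chrom_length * taper))
  if (cfg$n_genes == 0L) {
    genes <- gene_table(data.frame(gene_id = character(0), chrom = character(0),
                                   start = numeric(0), end = numeric(0),
                                   strand = character(0)), layout)
    return(list(layout = layout, genes = genes))
  }
  G <- sum(as.numeric(layout$length))
  mean_len <- exp(cfg$gene_length_law[[1]] + cfg$gene_length_law[[2]]^2 / 2)
  if (cfg$n_genes * mean_len > G) {
    stop("infeasible packing: expected total gene span exceeds the genome")
  }
  withr::with_seed(.child_seed(cfg$seed, 1L), {
    blocks <- cfg$density_blocks
    bnd <- c(0, cumsum(blocks$fraction)) * G
    b <- sample.int(nrow(blocks), cfg$n_genes, replace = TRUE,
                    prob = blocks$intensity * blocks$fraction)
    pos0 <- floor(bnd[b] + stats::runif(cfg$n_genes) * (bnd[b + 1L] - bnd[b]))
    len <- pmax(200, round(stats::rlnorm(cfg$n_genes,
                                         cfg$gene_length_law[[1]],
                                         cfg$gene_length_law[[2]])))
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  })
  cp <- .pos0_to_chrom(pos0, layout)
  chrom_len <- .chrom_length(layout, cp$chrom)
  start <- pmin(cp$pos, chrom_len - 200)
  end <- pmin(start + len, chrom_len)
  ord <- order(match(cp$chrom, layout$chrom), start)
  genes <- data.frame(gene_id = sprintf("G%05d", seq_len(cfg$n_genes)),
                      chrom = cp$chrom[ord], start = start[ord],
                      end = end[ord], strand = strand[ord],
                      stringsAsFactors = FALSE)
  list(layout = layout, genes = gene_table(genes, layout))
}

#' Generate a CLIP-seq-style interaction table and ortholog map
#'
#' A random subset of genes (`frac_target_genes`) enters the interaction
#' table; each such gene interacts with `k` distinct miRNAs, `k` drawn
#' zero-truncated geometric with success parameter `mirna_count_law`, so the
#' gene count decays monotonically in `k` as in real CLIP-seq compendia.
#' Per-interaction support is 1 with probability `1 - support_law` and
#' geometric above 2 otherwise. Source-species miRNA names map 1:1 onto the
#' miRNAs used.
#'
#' @param cfg a [sim_config()].
#' @param genes gene annotation.
#' @return List with `interactions`, `orthologs`, `source_mirnas`.
#' @export
generate_interactions <- function(cfg, genes) {
  stopifnot(cfg$n_mirnas >= 2)
  mirnas <- sprintf("hsa-mir-%03d", seq_len(cfg$n_mirnas))
  sources <- sprintf("mmu-mir-%03d", seq_len(cfg$n_mirnas))
  orthologs <- data.frame(source_mirna = sources, target_mirna = mirnas,
                          stringsAsFactors = FALSE)
  n_target <- round(cfg$frac_target_genes * nrow(genes))
  if (n_target == 0L) {
    return(list(interactions = data.frame(mirna_id = character(0),
                                          gene_id = character(0),
                                          support = numeric(0)),
                orthologs = orthologs, source_mirnas = sources))
  }
  withr::with_seed(.child_seed(cfg$seed, 2L), {
    target_genes <- sample(genes$gene_id, n_target)
    k <- pmin(stats::rgeom(n_target, cfg$mirna_count_law) + 1L, cfg$n_mirnas)
    picks <- lapply(k, function(ki) sample.int(cfg$n_mirnas, ki))
    total <- sum(k)
    support <- ifelse(stats::runif(total) < cfg$support_law,
                      2L + stats::rgeom(total, 0.5), 1L)
  })
  interactions <- data.frame(
    mirna_id = mirnas[unlist(picks, use.names = FALSE)],
    gene_id = rep(target_genes, k),
    support = support, stringsAsFactors = FALSE)
  list(interactions = interactions, orthologs = orthologs,
       source_mirnas = sources)
}

#' Generate a genome-ordered synthetic SNP array
#'
#' Uniform placement samples distinct positions over the concatenated genome
#' (no duplicate (chrom, pos) by construction). Clustered placement groups
#' SNPs around random cluster centers with normal scatter, a crude stand-in
#' for the local probe clustering of real genotyping arrays.
#'
#' @param cfg a [sim_config()].
#' @param layout a [genome_layout()].
#' @return A [snp_array()]; ids are assigned in genome order.
#' @export
generate_snp_array <- function(cfg, layout) {
  G <- sum(as.numeric(layout$length))
  stopifnot(cfg$n_snps >= 1, cfg$n_snps <= G)
  pos0 <- withr::with_seed(.child_seed(cfg$seed, 3L), {
    if (cfg$snp_placement == "uniform") {
      sample.int(G, cfg$n_snps) - 1
    } else {
      n_clust <- max(1L, round(cfg$n_snps / 50))
      centers <- floor(stats::runif(n_clust) * G)
      p <- centers[sample.int(n_clust, cfg$n_snps, replace = TRUE)] +
        round(stats::rnorm(cfg$n_snps, 0, 3e4))
      p <- unique(pmin(pmax(p, 0), G - 1))
      while (length(p) < cfg$n_snps) {
        p <- unique(c(p, floor(stats::runif(cfg$n_snps - length(p)) * G)))
      }
      p[seq_len(cfg$n_snps)]
    }
  })
  cp <- .pos0_to_chrom(sort(pos0), layout)
  snp_array(data.frame(snp_id = sprintf("snp%07d", seq_len(cfg$n_snps)),
                       chrom = cp$chrom, pos = cp$pos,
                       stringsAsFactors = FALSE), layout)
}

#' Generate per-SNP association evidence, optionally with planted enrichment
#'
#' Each SNP is uninformative (posterior = prior) with probability
#' `frac_uninformative`; otherwise it shows evidence for association
#' (posterior above the prior) with probability `frac_positive` and evidence
#' against (posterior below the prior) otherwise. Posterior magnitudes are
#' arbitrary ranks, not calibrated evidence values: only their order matters
#' to top-fraction selection.
#'
#' Enrichment is planted positionally: `n_risk_genes` risk genes are drawn
#' (from the target set when `risk_gene_source = "target"`, uniformly over
#' all genes under the `"any"` null), and every SNP within `risk_window` of
#' a risk gene has its posterior odds multiplied by `boost` (capped below
#' 1). With `boost = 1` the two regimes are distributionally identical. The
#' planted signal therefore has to survive the actual tiered mapping to be
#' detected, exercising the full causal path from regulatory SNP to nearby
#' target gene.
#'
#' @param cfg a [sim_config()].
#' @param layout,genes,array the synthetic genome and SNP array.
#' @param targets a `target_set`; required when `risk_gene_source` is
#'   `"target"`.
#' @return A validated association table (see [association_table()]).
#' @export
generate_association <- function(cfg, layout, genes, array, targets = NULL) {
  n <- nrow(array)
  risk_pool <- if (cfg$risk_gene_source == "target") {
    if (is.null(targets) || length(targets$gene_ids) == 0L) {
      stop("risk_gene_source = 'target' requires a non-empty target set")
    }
    targets$gene_ids
  } else {
    genes$gene_id
  }
  withr::with_seed(.child_seed(cfg$seed, 4L), {
    u <- stats::runif(n)
    post_for <- cfg$prior * exp(stats::runif(n, log(1.5), log(50)))
    post_against <- cfg$prior * stats::runif(n, 0, 0.99)
    risk_genes <- sample(risk_pool, min(cfg$n_risk_genes, length(risk_pool)))
  })
  cut_unin <- cfg$frac_uninformative
  cut_for <- cut_unin + (1 - cut_unin) * cfg$frac_positive
  posterior <- ifelse(u < cut_unin, cfg$prior,
                      ifelse(u < cut_for, post_for, post_against))
  if (cfg$boost > 1 && length(risk_genes)) {
    g <- genes[genes$gene_id %in% risk_genes, , drop = FALSE]
    near <- !is.na(.map_snps_rows(array, gene_index(g, layout),
                                  cfg$risk_window)$tier_bp)
    odds <- posterior / (1 - posterior) * cfg$boost
    posterior <- ifelse(near, pmin(odds / (1 + odds), 0.999), posterior)
  }
  association_table(data.frame(snp_id = array$snp_id, prior = cfg$prior,
                               posterior = posterior,
                               stringsAsFactors = FALSE))
}

#' Generate a complete synthetic study on disk
#'
#' Composes the genome, interaction, SNP-array and association generators,
#' writes every pipeline input table plus a `manifest.json` holding the full
#' config; re-running with the same config reproduces every file
#' bit-identically.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`layout`, `genes`,
#'   `array`, `interactions`, `orthologs`, `source_mirnas`, `assoc`,
#'   `targets`) and `paths` to the written files.
#' @export
generate_study <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gn <- generate_genome(cfg)
  it <- generate_interactions(cfg, gn$genes)
  array <- generate_snp_array(cfg, gn$layout)
  mapped <- map_orthologs(it$source_mirnas, it$orthologs)$mapped
  targets <- if (nrow(it$interactions) > 0L && length(mapped)) {
    build_target_set(it$interactions, mapped)
  } else {
    structure(list(gene_ids = character(0), min_support = 2, min_mirnas = 2,
                   mirnas_used = mapped), class = "target_set")
  }
  assoc <- generate_association(cfg, gn$layout, gn$genes, array, targets)
  paths <- list(layout = file.path(dir, "layout.tsv"),
                genes = file.path(dir, "genes.tsv"),
                snps = file.path(dir, "snps.tsv"),
                association = file.path(dir, "association.tsv"),
                interactions = file.path(dir, "interactions.tsv"),
                orthologs = file.path(dir, "orthologs.tsv"),
                source_mirnas = file.path(dir, "source_mirnas.txt"),
                manifest = file.path(dir, "manifest.json"))
  write_layout(gn$layout, paths$layout)
  write_genes(gn$genes, paths$genes)
  write_snp_array(array, paths$snps)
  write_association(assoc, paths$association)
  write_interactions(it$interactions, paths$interactions)
  write_orthologs(it$orthologs, paths$orthologs)
  writeLines(it$source_mirnas, paths$source_mirnas)
  files <- unlist(paths[names(paths) != "manifest"])
  manifest <- list(config = unclass(cfg),
                   md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(layout = gn$layout, genes = gn$genes, array = array,
                 interactions = it$interactions, orthologs = it$orthologs,
                 source_mirnas = it$source_mirnas, assoc = assoc,
                 targets = targets, paths = paths))
}
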