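# Density-adaptive tiered SNP-to-gene assignment.
#
# For each SNP the search tries successively wider half-width windows
# (default 25 kb, 250 kb, 500 kb, 1 Mb) and stops at the first tier that
# captures at least one gene; ALL genes at that tier are returned. "Within w"
# means point-to-interval distance <= w, boundary inclusive, measured to the
# nearest edge of the gene body. Windows never cross chromosome boundaries.
#
# The fast path indexes gene intervals with IRanges; map_snp_bruteforce() is
# a deliberately naive exhaustive-scan twin kept as the correctness oracle.

#' Build an interval index over a gene annotation
#'
#' Precomputes per-chromosome IRanges so repeated tiered queries (one per SNP
#' per permutation replicate) are sub-linear in the number of genes. Gene
#' intervals are stored closed on the last covered base, so an overlap with
#' the window `[pos - w, pos + w]` is exactly "edge distance <= w".
#'
#' @param genes validated gene annotation (see [gene_table()]).
#' @param layout a [genome_layout()].
#' @return A `gene_index` object.
#' @export
gene_index <- function(genes, layout) {
  rows <- split(seq_len(nrow(genes)),
                factor(genes$chrom, levels = layout$chrom))
  per_chrom <- lapply(rows, function(i) {
    list(ranges = IRanges::IRanges(start = as.integer(genes$start[i] + 1),
                                   end = as.integer(genes$end[i])),
         rows = i)
  })
  structure(list(per_chrom = per_chrom, gene_id = genes$gene_id,
                 genes = genes, layout = layout),
            class = "gene_index")
}

.as_gene_index <- function(genes, layout) {
  if (inherits(genes, "gene_index")) genes else gene_index(genes, layout)
}

# Tiered mapping for a batch of SNPs; returns integer row indices into the
# index's gene table plus the winning tier. This is the workhorse the
# permutation test calls once for the whole array.
.map_snps_rows <- function(snps, gi, tiers) {
  unknown <- setdiff(unique(snps$chrom), gi$layout$chrom)
  if (length(unknown)) {
    stop("SNP chromosome(s) absent from layout: ",
         paste(unknown, collapse = ", "))
  }
  n <- nrow(snps)
  rows <- rep(list(integer(0)), n)
  tier_bp <- rep(NA_real_, n)
  active <- rep(TRUE, n)
  for (w in tiers) {
    if (!any(active)) break
    ai <- which(active)
    for (ch in unique(snps$chrom[ai])) {
      entry <- gi$per_chrom[[ch]]
      if (is.null(entry) || length(entry$rows) == 0L) next
      ci <- ai[snps$chrom[ai] == ch]
      p1 <- as.numeric(snps$pos[ci]) + 1
      q <- IRanges::IRanges(start = as.integer(pmax(p1 - w, -.Machine$integer.max / 2)),
                            end = as.integer(p1 + w))
      ov <- IRanges::findOverlaps(q, entry$ranges)
      qh <- S4Vectors::queryHits(ov)
      if (length(qh) == 0L) next
      hits <- split(entry$rows[S4Vectors::subjectHits(ov)], qh)
      at <- ci[as.integer(names(hits))]
      rows[at] <- unname(hits)
      tier_bp[at] <- w
      active[at] <- FALSE
    }
  }
  list(rows = rows, tier_bp = tier_bp)
}

#' Map one SNP to candidate genes by the tiered window search
#'
#' @param snp a one-row data frame (or list) with `snp_id`, `chrom`, `pos`
#'   (0-based point position).
#' @param genes gene annotation data frame or a prebuilt [gene_index()].
#' @param tiers strictly increasing half-widths in bp; see [tier_config()].
#' @param layout the [genome_layout()]; required unless `genes` is already a
#'   `gene_index`.
#' @return Sorted character vector of gene ids captured at the smallest
#'   non-empty tier; empty when no gene lies within the widest tier.
#' @examples
#' layout <- genome_layout("chr1", 2e6)
#' genes <- gene_table(data.frame(gene_id = "A", chrom = "chr1",
#'                                start = 100000, end = 110000, strand = "+"),
#'                     layout)
#' map_snp(list(snp_id = "rs1", chrom = "chr1", pos = 120000), genes,
#'         layout = layout)
#' @export
map_snp <- function(snp, genes, tiers = tier_config(), layout = NULL) {
  gi <- .as_gene_index(genes, layout)
  snp_df <- data.frame(snp_id = as.character(snp$snp_id),
                       chrom = as.character(snp$chrom),
                       pos = as.numeric(snp$pos), stringsAsFactors = FALSE)
  res <- .map_snps_rows(snp_df, gi, tier_config(tiers))
  sort(gi$gene_id[res$rows[[1L]]])
}

#' Map a set of SNPs and take the union of their candidate genes
#'
#' @param snps data frame of SNPs (`snp_id`, `chrom`, `pos`), e.g. the
#'   selected rows of a [snp_array()].
#' @inheritParams map_snp
#' @return List with `union_genes` (sorted deduplicated union over SNPs),
#'   `per_snp` (named list of per-SNP gene-id sets) and `tier_bp` (named
#'   vector of the winning tier per SNP, `NA` when no tier captured a gene).
#' @export
map_snps <- function(snps, genes, tiers = tier_config(), layout = NULL) {
  gi <- .as_gene_index(genes, layout)
  res <- .map_snps_rows(snps, gi, tier_config(tiers))
  per_snp <- lapply(res$rows, function(r) sort(gi$gene_id[r]))
  names(per_snp) <- snps$snp_id
  list(union_genes = sort(gi$gene_id[unique(unlist(res$rows, use.names = FALSE))]),
       per_snp = per_snp,
       tier_bp = setNames(res$tier_bp, snps$snp_id))
}

#' Brute-force twin of the tiered mapper (test oracle)
#'
#' Identical contract to [map_snp()], implemented by an exhaustive distance
#' scan over every gene on the SNP's chromosome. It exists solely so the
#' indexed implementation can be checked against it on randomized instances;
#' it shares no code with the fast path.
#'
#' @inheritParams map_snp
#' @param genes gene annotation data frame (not an index).
#' @export
map_snp_bruteforce <- function(snp, genes, tiers = tier_config(), layout) {
  if (!(snp$chrom %in% layout$chrom)) {
    stop("SNP chromosome absent from layout: ", snp$chrom)
  }
  tiers <- tier_config(tiers)
  g <- genes[genes$chrom == snp$chrom, , drop = FALSE]
  if (nrow(g) == 0L) return(character(0))
  pos <- as.numeric(snp$pos)
  inside <- pos >= g$start & pos < g$end
  d <- ifelse(inside, 0, pmin(abs(pos - (g$end - 1)), abs(g$start - pos)))
  for (w in tiers) {
    hit <- d <= w
    if (any(hit)) return(sort(g$gene_id[hit]))
  }
  character(0)
}

#' Per-pair SNP-to-gene mapping table
#'
#' Long-format report of [map_snps()]: one row per (SNP, captured gene) with
#' the winning tier and the edge distance in bp.
#'
#' @inheritParams map_snps
#' @return Data frame with columns `snp_id`, `gene_id`, `tier_bp`,
#'   `distance_bp`.
#' @export
snp_gene_map_table <- function(snps, genes, tiers = tier_config(),
                               layout = NULL) {
  gi <- .as_gene_index(genes, layout)
  res <- .map_snps_rows(snps, gi, tier_config(tiers))
  n_per <- lengths(res$rows)
  i <- rep(seq_len(nrow(snps)), n_per)
  rows <- unlist(res$rows, use.names = FALSE)
  if (length(rows) == 0L) {
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      tier_bp = numeric(0), distance_bp = numeric(0)))
  }
  pos <- as.numeric(snps$pos[i])
  start <- gi$genes$start[rows]
  end <- gi$genes$end[rows]
  inside <- pos >= start & pos < end
  d <- ifelse(inside, 0, pmin(abs(pos - (end - 1)), abs(start - pos)))
  out <- data.frame(snp_id = snps$snp_id[i], gene_id = gi$gene_id[rows],
                    tier_bp = res$tier_bp[i], distance_bp = d,
                    stringsAsFactors = FALSE)
  out[order(match(out$snp_id, snps$snp_id), out$distance_bp), , drop = FALSE]
}
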