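# miRNA-of-interest list via ortholog mapping, and the CLIP-seq-supported
# target gene set that the enrichment statistic is computed against.

#' Map source-species miRNAs to target-species orthologs
#'
#' The mapping is many-to-many: every target ortholog of any listed source
#' miRNA enters the miRNAs-of-interest set. Sources with no pair are returned
#' rather than raised, so the caller can log ortholog coverage.
#'
#' @param source_mirnas character vector (or set) of source miRNA ids.
#' @param pairs ortholog pair table (see [read_orthologs()]).
#' @return List with `mapped` (sorted unique target ids) and `unmapped`
#'   (sorted source ids with no ortholog).
#' @examples
#' pairs <- data.frame(source_mirna = "mmu-miR-134",
#'                     target_mirna = "hsa-miR-134")
#' map_orthologs("mmu-miR-134", pairs)
#' @export
map_orthologs <- function(source_mirnas, pairs) {
  source_mirnas <- unique(as.character(source_mirnas))
  hit <- pairs$source_mirna %in% source_mirnas
  list(mapped = sort(unique(pairs$target_mirna[hit])),
       unmapped = sort(setdiff(source_mirnas, pairs$source_mirna)))
}

#' Build the miRNA target gene set
#'
#' A gene belongs to the target set when it interacts, with CLIP-seq support
#' of at least `min_support` experiments per miRNA-gene pair, with at least
#' `min_mirnas` distinct miRNAs from the miRNAs-of-interest set. Both
#' thresholds default to 2: interactions are required to be replicated in two
#' or more CLIP-seq experiments, and a target gene must be hit by two or more
#' of the miRNAs of interest.
#'
#' @param interactions interaction table (see [read_interactions()]).
#' @param mirnas character vector of miRNAs of interest; must be non-empty.
#' @param min_support minimum CLIP-seq experiments per interaction (>= 1).
#' @param min_mirnas minimum distinct qualifying miRNAs per gene (>= 1).
#' @return A `target_set`: list with `gene_ids`, `min_support`, `min_mirnas`,
#'   `mirnas_used`.
#' @export
build_target_set <- function(interactions, mirnas, min_support = 2,
                             min_mirnas = 2) {
  mirnas <- unique(as.character(mirnas))
  if (length(mirnas) == 0L) {
    stop("empty miRNA set: a target set over no miRNAs is meaningless")
  }
  stopifnot(min_support >= 1, min_mirnas >= 1)
  counts <- .qualifying_mirna_counts(interactions, mirnas, min_support)
  structure(list(gene_ids = sort(names(counts)[counts >= min_mirnas]),
                 min_support = min_support, min_mirnas = min_mirnas,
                 mirnas_used = sort(mirnas)),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf(
    "miRNA target set: %d gene(s); support >= %d experiment(s), >= %d of %d miRNA(s)\n",
    length(x$gene_ids), x$min_support, x$min_mirnas, length(x$mirnas_used)))
  invisible(x)
}

# distinct qualifying miRNAs per gene, over genes with >= 1 qualifying
# interaction
.qualifying_mirna_counts <- function(interactions, mirnas, min_support) {
  qual <- interactions[interactions$support >= min_support &
                         interactions$mirna_id %in% mirnas, , drop = FALSE]
  if (nrow(qual) == 0L) return(integer(0))
  pairs <- unique(qual[, c("mirna_id", "gene_id")])
  c(table(pairs$gene_id))
}

#' Histogram of distinct interacting miRNAs per gene
#'
#' For every gene with at least one qualifying interaction (support >=
#' `min_support`, miRNA among `mirnas`), counts how many distinct miRNAs of
#' interest it interacts with, and tabulates genes by that count. The counts
#' sum to the number of genes with any qualifying interaction.
#'
#' @inheritParams build_target_set
#' @return Data frame with columns `n_mirnas` (k) and `n_genes`, sorted by k.
#' @export
interaction_count_histogram <- function(interactions, mirnas,
                                        min_support = 2) {
  mirnas <- unique(as.character(mirnas))
  if (length(mirnas) == 0L) stop("empty miRNA set")
  counts <- .qualifying_mirna_counts(interactions, mirnas, min_support)
  if (length(counts) == 0L) {
    return(data.frame(n_mirnas = integer(0), n_genes = integer(0)))
  }
  tab <- table(counts)
  data.frame(n_mirnas = as.integer(names(tab)), n_genes = as.integer(tab))
}
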