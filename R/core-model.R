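#' @importFrom utils write.table
#' @importFrom stats rbinom rgeom rlnorm runif sd setNames
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# TSV plumbing
#
# All tables are tab-separated UTF-8 with '#' comment lines. Parse errors must
# name the offending line, so rows are split by hand rather than via
# read.delim (which cannot report line numbers).
# ---------------------------------------------------------------------------

.read_tsv <- function(path, columns, header = TRUE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(columns)), columns))
    attr(out, "lineno") <- integer(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (header) {
    hdr <- fields[[1L]]
    missing <- setdiff(columns, hdr)
    if (length(missing)) {
      stop(sprintf("%s: missing required column(s): %s", path,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    body <- fields[-1L]
    body_lineno <- lineno[-1L]
  } else {
    hdr <- columns
    body <- fields
    body_lineno <- lineno
  }
  nf <- lengths(body)
  bad <- which(nf < length(hdr))
  if (length(bad)) {
    stop(sprintf("%s: line %d: expected %d tab-separated fields, found %d",
                 path, body_lineno[bad[1L]], length(hdr), nf[bad[1L]]),
         call. = FALSE)
  }
  cols <- lapply(seq_along(hdr), function(j) vapply(body, `[[`, "", j))
  out <- as.data.frame(setNames(cols, hdr), check.names = FALSE)[, columns, drop = FALSE]
  attr(out, "lineno") <- body_lineno
  out
}

.parse_num <- function(x, lineno, path, what, integer = FALSE) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("%s: line %d: cannot parse %s value '%s'",
                 path, lineno[bad[1L]], what, x[bad[1L]]), call. = FALSE)
  }
  if (integer) {
    frac <- which(v != trunc(v))
    if (length(frac)) {
      stop(sprintf("%s: line %d: %s must be an integer, got '%s'",
                   path, lineno[frac[1L]], what, x[frac[1L]]), call. = FALSE)
    }
  }
  v
}

.write_tsv <- function(df, path) {
  # integer-valued numeric columns are printed without decoration so that a
  # write/read round trip is bit-identical
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && all(df[[j]] == trunc(df[[j]]))) {
      df[[j]] <- format(df[[j]], scientific = FALSE, trim = TRUE)
    }
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

# ---------------------------------------------------------------------------
# GenomeLayout
# ---------------------------------------------------------------------------

#' Genome layout: ordered chromosomes and their lengths
#'
#' The row order of the layout is the genome-wide concatenation order used to
#' sort the SNP array and to lay chromosomes end-to-end for the circular-shift
#' null. It is taken from the file, never from lexicographic sorting, so
#' "numerical order" is explicit and user-controlled.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length numeric vector of strictly positive lengths in base pairs.
#' @return A `genome_layout`: a data frame with columns `chrom` and `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != length(length)) stop("chrom and length differ in length")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("all chromosome lengths must be strictly positive")
  }
  structure(data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' Read a genome layout table
#'
#' @param path TSV with header columns `chrom`, `length`; `#` lines ignored.
#' @return A [genome_layout()].
#' @export
read_layout <- function(path) {
  df <- .read_tsv(path, c("chrom", "length"))
  len <- .parse_num(df$length, attr(df, "lineno"), path, "length", integer = TRUE)
  genome_layout(df$chrom, len)
}

#' @rdname read_layout
#' @param layout a `genome_layout`.
#' @export
write_layout <- function(layout, path) {
  .write_tsv(as.data.frame(layout), path)
}

.chrom_length <- function(layout, chrom) {
  layout$length[match(chrom, layout$chrom)]
}

# ---------------------------------------------------------------------------
# Gene annotation
# ---------------------------------------------------------------------------

#' Validate a gene annotation against a genome layout
#'
#' Internal coordinates are 0-based half-open (BED convention): a gene covers
#' `[start, end)`. Strand is stored but ignored by every computation in the
#' package; mapping distance is strand-agnostic. The annotation is expected to
#' be pre-collapsed to one row per gene identifier (transcript isoforms merged
#' upstream).
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param layout a [genome_layout()]. Rows on chromosomes absent from the
#'   layout are dropped with a message.
#' @return The validated (possibly filtered) data frame.
#' @export
gene_table <- function(genes, layout) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  stopifnot(all(need %in% names(genes)))
  genes <- as.data.frame(genes)[, need]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  genes$strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, "unknown")
  off <- !(genes$chrom %in% layout$chrom)
  if (any(off)) {
    message(sprintf("dropping %d gene(s) on chromosome(s) absent from layout: %s",
                    sum(off), paste(unique(genes$chrom[off]), collapse = ", ")))
    genes <- genes[!off, , drop = FALSE]
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         genes$gene_id[anyDuplicated(genes$gene_id)])
  }
  bad <- genes$start < 0 | genes$start >= genes$end
  if (any(bad)) {
    stop(sprintf("gene %s: invalid interval [%s, %s): need 0 <= start < end",
                 genes$gene_id[which(bad)[1L]],
                 genes$start[which(bad)[1L]], genes$end[which(bad)[1L]]))
  }
  too_long <- genes$end > .chrom_length(layout, genes$chrom)
  if (any(too_long)) {
    stop(sprintf("gene %s: end %s exceeds length of %s",
                 genes$gene_id[which(too_long)[1L]],
                 genes$end[which(too_long)[1L]],
                 genes$chrom[which(too_long)[1L]]))
  }
  rownames(genes) <- NULL
  genes
}

#' Read a gene annotation (BED6 or headered TSV)
#'
#' Accepts either BED (first six columns honoured: chrom, start, end, name,
#' score, strand; no header) or a headered TSV with columns `gene_id`,
#' `chrom`, `start`, `end`, `strand`. The dialect is auto-detected from the
#' header line. Coordinates are 0-based half-open on disk unless
#' `one_based = TRUE`, which shifts 1-based inclusive coordinates on read.
#'
#' @inheritParams gene_table
#' @param path file path.
#' @param one_based logical; declare the input as 1-based inclusive.
#' @return A validated gene annotation data frame (see [gene_table()]).
#' @export
read_genes <- function(path, layout, one_based = FALSE) {
  first <- ""
  for (l in readLines(path, n = 50L, encoding = "UTF-8", warn = FALSE)) {
    if (!grepl("^[[:space:]]*#", l) && nzchar(trimws(l))) { first <- l; break }
  }
  is_tsv <- all(c("gene_id", "chrom") %in% strsplit(first, "\t", fixed = TRUE)[[1L]])
  if (is_tsv) {
    df <- .read_tsv(path, c("gene_id", "chrom", "start", "end", "strand"))
  } else {
    raw <- .read_tsv(path, c("chrom", "start", "end", "gene_id"), header = FALSE)
    # BED column 6, if present, carries strand; column 5 (score) is ignored
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    body <- lines[!grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))]
    strand <- vapply(strsplit(body, "\t", fixed = TRUE), function(f) {
      if (length(f) >= 6L) f[[6L]] else "unknown"
    }, "")
    df <- data.frame(gene_id = raw$gene_id, chrom = raw$chrom,
                     start = raw$start, end = raw$end, strand = strand,
                     stringsAsFactors = FALSE)
    attr(df, "lineno") <- attr(raw, "lineno")
  }
  ln <- attr(df, "lineno")
  start <- .parse_num(df$start, ln, path, "start", integer = TRUE)
  end <- .parse_num(df$end, ln, path, "end", integer = TRUE)
  if (one_based) start <- start - 1
  gene_table(data.frame(gene_id = df$gene_id, chrom = df$chrom,
                        start = start, end = end, strand = df$strand,
                        stringsAsFactors = FALSE), layout)
}

#' @rdname read_genes
#' @param genes a validated gene annotation.
#' @export
write_genes <- function(genes, path) {
  .write_tsv(genes[, c("gene_id", "chrom", "start", "end", "strand")], path)
}

# ---------------------------------------------------------------------------
# SNP array
# ---------------------------------------------------------------------------

#' Genome-ordered SNP array
#'
#' Sorts SNPs by (layout chromosome order, position). The row index of a SNP
#' in the result is its genome-wide rank: the coordinate that the
#' circular-shift null rotates. Positions are 0-based points.
#'
#' @param snps data frame with columns `snp_id`, `chrom`, `pos`.
#' @param layout a [genome_layout()].
#' @return A `snp_array`: a data frame sorted into genome order, with the
#'   layout attached as attribute `layout`.
#' @export
snp_array <- function(snps, layout) {
  need <- c("snp_id", "chrom", "pos")
  stopifnot(all(need %in% names(snps)))
  snps <- as.data.frame(snps)[, need]
  snps$snp_id <- as.character(snps$snp_id)
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.numeric(snps$pos)
  unknown <- setdiff(unique(snps$chrom), layout$chrom)
  if (length(unknown)) {
    stop("SNPs on chromosome(s) absent from layout: ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp_id")
  if (any(snps$pos < 0 | snps$pos >= .chrom_length(layout, snps$chrom))) {
    stop("SNP position outside [0, chromosome length)")
  }
  key <- paste(snps$chrom, snps$pos)
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, pos) pair: ", key[anyDuplicated(key)])
  }
  ord <- order(match(snps$chrom, layout$chrom), snps$pos)
  snps <- snps[ord, , drop = FALSE]
  rownames(snps) <- NULL
  structure(snps, layout = layout, class = c("snp_array", "data.frame"))
}

#' Read a SNP array table
#'
#' @param path TSV with header columns `snp_id`, `chrom`, `pos`.
#' @inheritParams snp_array
#' @param one_based logical; shift 1-based positions to 0-based on read.
#' @return A [snp_array()].
#' @export
read_snp_array <- function(path, layout, one_based = FALSE) {
  df <- .read_tsv(path, c("snp_id", "chrom", "pos"))
  pos <- .parse_num(df$pos, attr(df, "lineno"), path, "pos", integer = TRUE)
  if (one_based) pos <- pos - 1
  snp_array(data.frame(snp_id = df$snp_id, chrom = df$chrom, pos = pos,
                       stringsAsFactors = FALSE), layout)
}

#' @rdname read_snp_array
#' @param array a [snp_array()].
#' @export
write_snp_array <- function(array, path) {
  .write_tsv(as.data.frame(array)[, c("snp_id", "chrom", "pos")], path)
}

# ---------------------------------------------------------------------------
# Association evidence
# ---------------------------------------------------------------------------

#' Per-SNP association evidence (prior and posterior probabilities)
#'
#' The evidence measure is a posterior probability of association that moves
#' up (evidence for) or down (evidence against) from a prior; a posterior
#' equal to the prior is uninformative. The table is consumed pre-computed
#' (e.g. KELVIN-style output) or simulated; this package never computes the
#' posteriors themselves.
#'
#' @param assoc data frame with columns `snp_id`, `prior`, `posterior`.
#' @return A validated data frame.
#' @export
association_table <- function(assoc) {
  need <- c("snp_id", "prior", "posterior")
  stopifnot(all(need %in% names(assoc)))
  assoc <- as.data.frame(assoc)[, need]
  assoc$snp_id <- as.character(assoc$snp_id)
  assoc$prior <- as.numeric(assoc$prior)
  assoc$posterior <- as.numeric(assoc$posterior)
  if (anyDuplicated(assoc$snp_id)) stop("duplicate snp_id in association table")
  if (any(assoc$prior <= 0 | assoc$prior >= 1)) {
    stop("prior probabilities must lie strictly inside (0, 1)")
  }
  if (any(assoc$posterior < 0 | assoc$posterior > 1)) {
    stop("posterior probabilities must lie in [0, 1]")
  }
  rownames(assoc) <- NULL
  assoc
}

#' Read / write an association evidence table
#'
#' @param path TSV with header columns `snp_id`, `prior`, `posterior`.
#' @return [read_association()] returns a validated data frame.
#' @export
read_association <- function(path) {
  df <- .read_tsv(path, c("snp_id", "prior", "posterior"))
  ln <- attr(df, "lineno")
  association_table(data.frame(
    snp_id = df$snp_id,
    prior = .parse_num(df$prior, ln, path, "prior"),
    posterior = .parse_num(df$posterior, ln, path, "posterior"),
    stringsAsFactors = FALSE))
}

#' @rdname read_association
#' @param assoc a validated association table.
#' @export
write_association <- function(assoc, path) {
  .write_tsv(assoc, path)
}

# ---------------------------------------------------------------------------
# miRNA-gene interactions and miRNA orthologs
# ---------------------------------------------------------------------------

#' Read a miRNA-gene interaction table
#'
#' Each row records that a CLIP-seq compendium supports an interaction between
#' a miRNA and a gene, with `support` counting the number of CLIP-seq
#' experiments. Duplicate (mirna_id, gene_id) rows are aggregated by taking
#' the maximum support (support counts experiments, so max is conservative
#' and idempotent); the number of collapsed duplicates is reported.
#'
#' @param path TSV with header columns `mirna_id`, `gene_id`, `support`.
#' @return Data frame with one row per (mirna_id, gene_id) pair.
#' @export
read_interactions <- function(path) {
  df <- .read_tsv(path, c("mirna_id", "gene_id", "support"))
  sup <- .parse_num(df$support, attr(df, "lineno"), path, "support",
                    integer = TRUE)
  if (any(sup < 1)) {
    stop(sprintf("%s: line %d: support must be >= 1", path,
                 attr(df, "lineno")[which(sup < 1)[1L]]))
  }
  out <- data.frame(mirna_id = df$mirna_id, gene_id = df$gene_id,
                    support = sup, stringsAsFactors = FALSE)
  key <- paste(out$mirna_id, out$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    n_dup <- nrow(out) - length(unique(key))
    agg <- tapply(out$support, key, max)
    keep <- !duplicated(key)
    out <- out[keep, , drop = FALSE]
    out$support <- as.numeric(agg[paste(out$mirna_id, out$gene_id, sep = "\r")])
    message(sprintf("aggregated %d duplicate interaction row(s) by max support",
                    n_dup))
  }
  rownames(out) <- NULL
  out
}

#' @rdname read_interactions
#' @param interactions an interaction table.
#' @export
write_interactions <- function(interactions, path) {
  .write_tsv(interactions[, c("mirna_id", "gene_id", "support")], path)
}

#' Read a miRNA ortholog table
#'
#' Many-to-many pairs mapping miRNA identifiers in a source species (e.g.
#' mouse) to a target species (e.g. human). Duplicate pairs are collapsed.
#'
#' @param path TSV with header columns `source_mirna`, `target_mirna`.
#' @return Data frame of unique pairs.
#' @export
read_orthologs <- function(path) {
  df <- .read_tsv(path, c("source_mirna", "target_mirna"))
  out <- data.frame(source_mirna = df$source_mirna,
                    target_mirna = df$target_mirna, stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' @rdname read_orthologs
#' @param orthologs an ortholog pair table.
#' @export
write_orthologs <- function(orthologs, path) {
  .write_tsv(orthologs[, c("source_mirna", "target_mirna")], path)
}

#' Tiered search half-widths for SNP-to-gene mapping
#'
#' Strictly increasing half-widths in base pairs. The default reproduces the
#' four-tier scheme 25 kb, 250 kb, 500 kb, 1 Mb: the search stops at the first
#' tier that captures at least one gene, so candidate capture adapts to local
#' gene density.
#'
#' @param half_widths numeric vector, strictly increasing, in bp.
#' @return The validated numeric vector.
#' @export
tier_config <- function(half_widths = c(25000, 250000, 500000, 1000000)) {
  half_widths <- as.numeric(half_widths)
  if (length(half_widths) == 0L) stop("at least one tier is required")
  if (any(half_widths <= 0) || any(diff(half_widths) <= 0)) {
    stop("tier half-widths must be positive and strictly increasing")
  }
  half_widths
}
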