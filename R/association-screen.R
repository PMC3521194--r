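# Evidence-direction classification and top-fraction selection.
#
# A posterior probability of association above the prior is evidence for
# association; below, evidence against; equal (within tolerance) means the
# data were uninformative for that SNP.

#' Classify SNP evidence direction
#'
#' @param prior,posterior numeric vectors of probabilities in \[0, 1\]
#'   (recycled).
#' @param tol numeric tolerance for "posterior equals prior".
#' @return Character vector in `c("for", "against", "uninformative")`.
#' @examples
#' classify_evidence(0.0004, c(0.017, 0.0004, 0.0001))
#' @export
classify_evidence <- function(prior, posterior, tol = 1e-12) {
  if (any(prior < 0 | prior > 1 | posterior < 0 | posterior > 1)) {
    stop("prior and posterior must lie in [0, 1]")
  }
  ifelse(abs(posterior - prior) <= tol, "uninformative",
         ifelse(posterior > prior + tol, "for", "against"))
}

#' Summarize evidence direction over an association table
#'
#' Percentages are computed over informative SNPs only (total minus
#' uninformative) and are reported both at full precision and rounded to the
#' nearest integer, mirroring how such screens are usually quoted. With no
#' informative SNP the percentage fields are `NA`.
#'
#' @param assoc validated association table (see [association_table()]).
#' @param tol tolerance passed to [classify_evidence()].
#' @return List with `n_total`, `n_uninformative`, `n_for`, `n_against`,
#'   `pct_for`, `pct_against` (full precision), and `pct_for_rounded`,
#'   `pct_against_rounded`.
#' @export
summarize_association <- function(assoc, tol = 1e-12) {
  cls <- classify_evidence(assoc$prior, assoc$posterior, tol)
  n_total <- length(cls)
  n_unin <- sum(cls == "uninformative")
  n_for <- sum(cls == "for")
  n_against <- sum(cls == "against")
  n_inf <- n_total - n_unin
  pct_for <- if (n_inf > 0) 100 * n_for / n_inf else NA_real_
  pct_against <- if (n_inf > 0) 100 * n_against / n_inf else NA_real_
  list(n_total = n_total, n_uninformative = n_unin, n_for = n_for,
       n_against = n_against, pct_for = pct_for, pct_against = pct_against,
       pct_for_rounded = if (is.na(pct_for)) NA_real_ else round(pct_for),
       pct_against_rounded = if (is.na(pct_against)) NA_real_ else round(pct_against))
}

#' Select the top fraction of positive SNPs as a genome-ordered mask
#'
#' Takes the `floor(fraction * n_for)` SNPs with the strongest evidence for
#' association among SNPs classified "for", and marks them in a boolean mask
#' aligned to the genome-ordered SNP array — the selection pattern that the
#' circular-shift null later rotates. Ranking is by posterior descending
#' (with a shared prior, posterior order is evidence order); with per-SNP
#' priors, `rank_by = "ratio"` ranks by posterior/prior instead. Ties are
#' broken by genome order (earlier index wins) for determinism.
#'
#' @param assoc association table covering every SNP in `array`.
#' @param array a [snp_array()].
#' @param fraction fraction of positive SNPs to select, in (0, 1].
#' @param rank_by `"posterior"` (default) or `"ratio"` (posterior/prior).
#' @param tol tolerance passed to [classify_evidence()].
#' @return Logical mask of length `nrow(array)` with attribute `selection`,
#'   a data frame (snp_id, index, rank, posterior) of the selected SNPs in
#'   rank order.
#' @export
select_top_fraction <- function(assoc, array, fraction = 0.005,
                                rank_by = c("posterior", "ratio"),
                                tol = 1e-12) {
  rank_by <- match.arg(rank_by)
  stopifnot(fraction > 0, fraction <= 1)
  m <- match(array$snp_id, assoc$snp_id)
  if (anyNA(m)) {
    stop("association table is missing ", sum(is.na(m)), " SNP(s) of the array")
  }
  prior <- assoc$prior[m]
  posterior <- assoc$posterior[m]
  cls <- classify_evidence(prior, posterior, tol)
  n_for <- sum(cls == "for")
  if (n_for == 0L) stop("no SNP shows evidence for association; nothing to select")
  k <- floor(fraction * n_for)
  if (k < 1L) {
    stop(sprintf(
      "fraction %g of %d positive SNPs selects none; raise the fraction",
      fraction, n_for))
  }
  idx_for <- which(cls == "for")
  key <- switch(rank_by, posterior = posterior[idx_for],
                ratio = posterior[idx_for] / prior[idx_for])
  picked <- idx_for[order(-key, idx_for)][seq_len(k)]
  mask <- rep(FALSE, nrow(array))
  mask[picked] <- TRUE
  attr(mask, "selection") <- data.frame(
    snp_id = array$snp_id[picked], index = picked, rank = seq_len(k),
    posterior = posterior[picked], stringsAsFactors = FALSE)
  mask
}
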