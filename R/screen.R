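#' Call positive cells at an RPKM threshold
#'
#' A cell is positive for a gene when its expression is strictly greater
#' than `threshold_rpkm`; a value of exactly the threshold is negative.
#' Zeros never become positive for any non-negative threshold, so sparsity
#' is preserved.
#'
#' @param expr RPKM matrix from [compute_rpkm()].
#' @param threshold_rpkm positivity threshold, >= 0 (default 1.0).
#' @return sparse binary cells x genes matrix with attribute
#'   `threshold_rpkm`.
#' @export
call_positive <- function(expr, threshold_rpkm = 1.0) {
  if (!is.numeric(threshold_rpkm) || length(threshold_rpkm) != 1L ||
      is.na(threshold_rpkm) || threshold_rpkm < 0)
    hs_stop("threshold_rpkm must be a single non-negative number",
            "hepscreen_config_error")
  calls <- methods::as(methods::as(expr > threshold_rpkm, "dMatrix"),
                       "CsparseMatrix")
  dimnames(calls) <- dimnames(expr)
  attr(calls, "threshold_rpkm") <- threshold_rpkm
  calls
}

#' Per-gene, per-group positive-cell rates
#'
#' The positive-cell rate of a gene in a group is the number of cells
#' positive for the gene divided by the total number of cells in the group.
#' Denominators are the per-group cell counts of the matrix passed in —
#' i.e. post-QC, post-gate when called from the pipeline.
#'
#' @param calls binary matrix from [call_positive()].
#' @param group_of_cell named character vector (or factor) mapping every
#'   cell id in `calls` to its group label; each group must be non-empty.
#' @return data.frame with one row per (gene, group): `gene_id`, `group`,
#'   `n_positive`, `n_cells`, `rate`.
#' @export
positive_rates <- function(calls, group_of_cell) {
  cells <- rownames(calls)
  grp <- as.character(group_of_cell)[match(cells, names(group_of_cell))]
  if (anyNA(grp))
    hs_stop(paste0("cells without a group assignment: ",
                   paste(head(cells[is.na(grp)], 10L), collapse = ", ")),
            "hepscreen_input_error")
  groups <- sort(unique(grp))
  out <- lapply(groups, function(g) {
    sel <- grp == g
    n <- sum(sel)
    if (n == 0L)
      hs_stop(sprintf("group '%s' has no cells", g), "hepscreen_input_error")
    npos <- Matrix::colSums(calls[sel, , drop = FALSE])
    data.frame(gene_id = colnames(calls), group = g,
               n_positive = as.integer(npos), n_cells = n,
               rate = as.numeric(npos) / n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rank genes by old-minus-young positive-cell-rate difference
#'
#' The screening statistic: `delta = rate_old - rate_young`, sorted
#' descending, so rank 1 is the gene whose detection rate rises most with
#' age. A gene measured in only one group gets rate 0 in the other (absence
#' of detection is informative for an increase screen). Ties are broken by
#' ascending gene id, making the ranking fully deterministic.
#'
#' @param rates data.frame from [positive_rates()] with groups `"young"` and
#'   `"old"`.
#' @return data.frame `gene_id`, `rate_young`, `rate_old`, `delta`, `rank`,
#'   sorted by rank.
#' @export
rank_by_rate_difference <- function(rates) {
  for (g in c("young", "old")) {
    if (!any(rates$group == g))
      hs_stop(sprintf("group '%s' missing from rate table", g),
              "hepscreen_input_error")
  }
  genes <- sort(unique(rates$gene_id))
  y <- rates[rates$group == "young", ]
  o <- rates[rates$group == "old", ]
  rate_young <- y$rate[match(genes, y$gene_id)]
  rate_old <- o$rate[match(genes, o$gene_id)]
  rate_young[is.na(rate_young)] <- 0
  rate_old[is.na(rate_old)] <- 0
  delta <- rate_old - rate_young
  ord <- order(-delta, genes)
  data.frame(gene_id = genes[ord], rate_young = rate_young[ord],
             rate_old = rate_old[ord], delta = delta[ord],
             rank = seq_along(genes), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Select top-ranked candidate genes, optionally ortholog-filtered
#'
#' For a cross-species follow-up only genes with a known ortholog are
#' useful, so genes without an `ortholog_symbol` in the annotation are
#' dropped *before* truncating to the top `top_k` (rank order preserved).
#'
#' @param ranking data.frame from [rank_by_rate_difference()].
#' @param annotation annotation supplying `symbol` and `ortholog_symbol`.
#' @param top_k number of candidates to keep (default 43).
#' @param require_ortholog drop genes lacking an ortholog before truncation
#'   (default TRUE).
#' @return head of the ranking (at most `top_k` rows) with `symbol` and
#'   `ortholog_symbol` columns joined on.
#' @export
select_candidates <- function(ranking, annotation, top_k = 43L,
                              require_ortholog = TRUE) {
  if (!is.numeric(top_k) || length(top_k) != 1L || top_k < 1)
    hs_stop("top_k must be a count >= 1", "hepscreen_config_error")
  idx <- match(ranking$gene_id, annotation$gene_id)
  out <- ranking
  out$symbol <- annotation$symbol[idx]
  out$ortholog_symbol <- annotation$ortholog_symbol[idx]
  if (require_ortholog)
    out <- out[!is.na(out$ortholog_symbol), , drop = FALSE]
  out <- head(out, as.integer(top_k))
  row.names(out) <- NULL
  out
}
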