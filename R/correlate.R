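#' Within-group pairwise gene-gene correlations
#'
#' Correlates the expression vectors of each unordered gene pair across the
#' cells of one group. A gene with zero variance across those cells —
#' typically a gene with no expression at all, like a senescence marker in
#' young tissue — has no defined correlation with anything, including
#' itself; such entries are returned as `NA` and serialized as `"-"` by
#' [write_correlation_tsv()].
#'
#' @param expr RPKM matrix (cells x genes).
#' @param genes gene ids to correlate (must be columns of `expr`).
#' @param group_cells cell ids of the group (>= 3 required).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return symmetric numeric matrix (genes x genes) with unit diagonal where
#'   defined and `NA` where undefined; attributes `n_cells` and `method`.
#' @export
pairwise_correlation <- function(expr, genes, group_cells,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  unknown <- setdiff(genes, colnames(expr))
  if (length(unknown))
    hs_stop(paste0("genes not in expression matrix: ",
                   paste(head(unknown, 10L), collapse = ", ")),
            "hepscreen_input_error")
  missing_cells <- setdiff(group_cells, rownames(expr))
  if (length(missing_cells))
    hs_stop(paste0("cells not in expression matrix: ",
                   paste(head(missing_cells, 10L), collapse = ", ")),
            "hepscreen_input_error")
  if (length(group_cells) < 3L)
    hs_stop("at least 3 cells are required to estimate correlations",
            "hepscreen_input_error")

  x <- as.matrix(expr[group_cells, genes, drop = FALSE])
  constant <- apply(x, 2L, function(v) max(v) == min(v))
  cc <- suppressWarnings(cor(x, method = method))
  cc[constant, ] <- NA_real_
  cc[, constant] <- NA_real_
  diag(cc)[!constant] <- 1
  dimnames(cc) <- list(genes, genes)
  attr(cc, "n_cells") <- length(group_cells)
  attr(cc, "method") <- method
  cc
}

#' Correlate candidate genes against a senescence gene set
#'
#' Computes the within-group correlation of each query gene against each
#' gene-set member that is present in the expression data (resolved through
#' the annotation's symbols), flagging pairs at or above `high_r` as highly
#' correlated. Set members that were not measured are reported, not
#' silently dropped.
#'
#' @param expr RPKM matrix (cells x genes).
#' @param query_genes gene ids of the candidates.
#' @param gene_set a list from [read_gene_set()] (fields `name`, `symbols`),
#'   or a character vector of symbols.
#' @param group_cells cell ids of the group (>= 3).
#' @param annotation annotation mapping symbols to gene ids.
#' @param high_r cutoff for the "high correlation" flag (default 0.6).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame `query_gene`, `set_symbol`, `set_gene_id`,
#'   `coefficient` (NA when undefined), `high`; attribute `not_measured`
#'   lists set symbols absent from `expr`.
#' @export
geneset_correlation <- function(expr, query_genes, gene_set, group_cells,
                                annotation, high_r = 0.6,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.character(gene_set)) gene_set <- list(name = "gene_set",
                                               symbols = gene_set)
  symbols <- unique(gene_set$symbols)
  if (length(symbols) == 0L)
    hs_stop("gene set is empty", "hepscreen_input_error")
  set_ids <- annotation$gene_id[match(symbols, annotation$symbol)]
  measured <- !is.na(set_ids) & set_ids %in% colnames(expr)
  not_measured <- symbols[!measured]
  set_symbols <- symbols[measured]
  set_ids <- set_ids[measured]

  if (length(set_ids) == 0L) {
    out <- data.frame(query_gene = character(), set_symbol = character(),
                      set_gene_id = character(), coefficient = numeric(),
                      high = logical(), stringsAsFactors = FALSE)
    attr(out, "not_measured") <- not_measured
    return(out)
  }

  cc <- pairwise_correlation(expr, unique(c(query_genes, set_ids)),
                             group_cells, method = method)
  out <- expand.grid(query_gene = query_genes, set_gene_id = set_ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$set_symbol <- set_symbols[match(out$set_gene_id, set_ids)]
  out$coefficient <- cc[cbind(out$query_gene, out$set_gene_id)]
  out$high <- !is.na(out$coefficient) & out$coefficient >= high_r
  out <- out[, c("query_gene", "set_symbol", "set_gene_id",
                 "coefficient", "high")]
  attr(out, "not_measured") <- not_measured
  out
}
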