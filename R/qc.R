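#' Cell quality-control filter
#'
#' Removes cells detecting fewer than `min_genes` genes (count > 0) and
#' cells whose mitochondrial reads exceed `max_mito` of total raw counts.
#' Both rules are strict inequalities, so boundary cells — exactly
#' `min_genes` genes detected, or a mitochondrial fraction of exactly
#' `max_mito` — are retained. The gene universe is unchanged; only cells are
#' dropped.
#'
#' @param counts sparse cells x genes integer matrix with dimnames.
#' @param annotation gene annotation with `gene_id` and `is_mitochondrial`;
#'   must cover every gene in `counts`.
#' @param min_genes minimum detected-gene count to keep a cell (default 200).
#' @param max_mito maximum mitochondrial fraction of total counts to keep a
#'   cell (default 0.20).
#' @return list with `counts` (kept cells) and `report`, a data.frame over
#'   every input cell: `cell_id`, `genes_detected`, `mito_fraction`,
#'   `passed`, `reason` (none | low_genes | high_mito | both).
#' @export
qc_filter <- function(counts, annotation, min_genes = 200L, max_mito = 0.20) {
  check_count_matrix(counts)
  missing <- setdiff(colnames(counts), annotation$gene_id)
  if (length(missing)) {
    shown <- head(missing, 10L)
    hs_stop(paste0("genes absent from annotation: ",
                   paste(shown, collapse = ", "),
                   if (length(missing) > 10L) sprintf(" (and %d more)",
                                                      length(missing) - 10L)),
            "hepscreen_input_error")
  }
  mito_ids <- annotation$gene_id[annotation$is_mitochondrial]
  is_mito <- colnames(counts) %in% mito_ids

  genes_detected <- Matrix::rowSums(counts > 0)
  total <- Matrix::rowSums(counts)
  mito_counts <- if (any(is_mito)) {
    Matrix::rowSums(counts[, is_mito, drop = FALSE])
  } else {
    rep(0, nrow(counts))
  }
  mito_fraction <- ifelse(total > 0, mito_counts / total, 0)

  low <- genes_detected < min_genes
  high <- mito_fraction > max_mito
  passed <- !low & !high
  reason <- rep("none", nrow(counts))
  reason[low] <- "low_genes"
  reason[high] <- "high_mito"
  reason[low & high] <- "both"

  report <- data.frame(cell_id = rownames(counts),
                       genes_detected = as.integer(genes_detected),
                       mito_fraction = as.numeric(mito_fraction),
                       passed = passed, reason = reason,
                       stringsAsFactors = FALSE)
  list(counts = counts[passed, , drop = FALSE], report = report)
}

check_count_matrix <- function(counts) {
  if (!methods::is(counts, "Matrix") && !is.matrix(counts))
    hs_stop("counts must be a (sparse) matrix", "hepscreen_input_error")
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    hs_stop("count matrix is empty", "hepscreen_input_error")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    hs_stop("count matrix must carry cell and gene dimnames",
            "hepscreen_input_error")
  invisible(counts)
}

#' Per-cell RPKM expression matrix
#'
#' `rpkm(c, g) = count(c, g) * 1e9 / (total_counts(c) * length_bp(g))` —
#' reads per kilobase of transcript per million reads, computed within each
#' cell from that cell's total counts. The sparsity pattern is preserved:
#' a zero count is exactly zero RPKM.
#'
#' @param counts sparse cells x genes matrix (post-QC; every cell must have
#'   total count > 0).
#' @param annotation annotation supplying `length_bp` for every gene.
#' @return sparse cells x genes numeric matrix of RPKM values.
#' @export
compute_rpkm <- function(counts, annotation) {
  check_count_matrix(counts)
  idx <- match(colnames(counts), annotation$gene_id)
  if (anyNA(idx))
    hs_stop(paste0("genes absent from annotation: ",
                   paste(head(colnames(counts)[is.na(idx)], 10L),
                         collapse = ", ")),
            "hepscreen_input_error")
  len <- annotation$length_bp[idx]
  if (any(len <= 0))
    hs_stop("annotation has non-positive transcript lengths",
            "hepscreen_input_error")
  total <- Matrix::rowSums(counts)
  if (any(total == 0))
    hs_stop(paste0("cells with zero total counts: ",
                   paste(head(rownames(counts)[total == 0], 10L),
                         collapse = ", ")),
            "hepscreen_input_error")
  rpkm <- Diagonal(x = 1e9 / total) %*% counts %*% Diagonal(x = 1 / len)
  dimnames(rpkm) <- dimnames(counts)
  methods::as(methods::as(rpkm, "generalMatrix"), "CsparseMatrix")
}

#' Gate cells on a hepatocyte marker gene
#'
#' Restricts the analysis to hepatocytes by keeping cells whose expression
#' of the gate gene (albumin by default) exceeds `threshold_rpkm`, reusing
#' the screen's strict positive-cell rule: a cell at exactly the threshold
#' is not retained. Cell order is preserved.
#'
#' @param expr RPKM matrix from [compute_rpkm()].
#' @param annotation annotation used to resolve `gate_symbol` to one gene id.
#' @param gate_symbol gene symbol of the gate gene (default `"Alb"`).
#' @param threshold_rpkm positivity threshold (default 1.0).
#' @return character vector of retained cell ids.
#' @export
gate_positive_cells <- function(expr, annotation, gate_symbol = "Alb",
                                threshold_rpkm = 1.0) {
  hits <- annotation$gene_id[!is.na(annotation$symbol) &
                               annotation$symbol == gate_symbol]
  hits <- intersect(hits, colnames(expr))
  if (length(hits) == 0L)
    hs_stop(sprintf("gate symbol '%s' not found among measured genes",
                    gate_symbol), "hepscreen_input_error")
  if (length(hits) > 1L)
    hs_stop(sprintf("gate symbol '%s' is ambiguous (%d gene ids)",
                    gate_symbol, length(hits)), "hepscreen_input_error")
  rownames(expr)[expr[, hits] > threshold_rpkm]
}
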