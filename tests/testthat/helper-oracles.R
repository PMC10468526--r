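# Independent dense brute-force reference implementations, written as plain
# per-cell / per-gene loops so they share no code path with the package.

oracle_qc_keep <- function(dense, is_mito, min_genes, max_mito) {
  keep <- logical(nrow(dense))
  for (i in seq_len(nrow(dense))) {
    det <- 0L; tot <- 0; mito <- 0
    for (j in seq_len(ncol(dense))) {
      v <- dense[i, j]
      if (v > 0) det <- det + 1L
      tot <- tot + v
      if (is_mito[j]) mito <- mito + v
    }
    frac <- if (tot > 0) mito / tot else 0
    keep[i] <- det >= min_genes && frac <= max_mito
  }
  keep
}

oracle_rpkm <- function(dense, length_bp) {
  out <- matrix(0, nrow(dense), ncol(dense), dimnames = dimnames(dense))
  for (i in seq_len(nrow(dense))) {
    tot <- sum(dense[i, ])
    for (j in seq_len(ncol(dense)))
      out[i, j] <- dense[i, j] * 1e9 / (tot * length_bp[j])
  }
  out
}

oracle_calls <- function(dense_rpkm, threshold) {
  out <- matrix(0L, nrow(dense_rpkm), ncol(dense_rpkm),
                dimnames = dimnames(dense_rpkm))
  for (i in seq_len(nrow(dense_rpkm)))
    for (j in seq_len(ncol(dense_rpkm)))
      if (dense_rpkm[i, j] > threshold) out[i, j] <- 1L
  out
}

oracle_rates <- function(dense_calls, groups) {
  rows <- list()
  for (g in sort(unique(groups))) {
    sel <- which(groups == g)
    for (j in seq_len(ncol(dense_calls))) {
      npos <- 0L
      for (i in sel) if (dense_calls[i, j] > 0) npos <- npos + 1L
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = colnames(dense_calls)[j], group = g,
                   n_positive = npos, n_cells = length(sel),
                   rate = npos / length(sel), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

oracle_ranking <- function(rates) {
  genes <- sort(unique(rates$gene_id))
  ry <- ro <- setNames(numeric(length(genes)), genes)
  for (k in seq_len(nrow(rates))) {
    if (rates$group[k] == "young") ry[rates$gene_id[k]] <- rates$rate[k]
    if (rates$group[k] == "old") ro[rates$gene_id[k]] <- rates$rate[k]
  }
  delta <- ro - ry
  ord <- order(-delta, genes)
  data.frame(gene_id = genes[ord], delta = as.numeric(delta[ord]),
             rank = seq_along(genes), stringsAsFactors = FALSE)
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2); vy <- sum((y - my)^2)
  if (vx == 0 || vy == 0) return(NA_real_)
  sum((x - mx) * (y - my)) / sqrt(vx * vy)
}

# Random small fixture: sparse-ish count matrix + matching annotation and
# group labels; every cell has a nonzero total.
make_fixture <- function(seed, n_cells = 30L, n_genes = 60L, n_mito = 6L) {
  set.seed(seed)
  lambda <- rexp(n_genes, rate = 1 / 3)
  dense <- matrix(rpois(n_cells * n_genes, rep(lambda, each = n_cells)),
                  n_cells, n_genes)
  dense[, 1] <- dense[, 1] + 1L  # no zero-total cells
  cell_ids <- sprintf("fx_cell_%03d", seq_len(n_cells))
  gene_ids <- sprintf("fx_gene_%03d", seq_len(n_genes))
  dimnames(dense) <- list(cell_ids, gene_ids)
  is_mito <- c(rep(FALSE, n_genes - n_mito), rep(TRUE, n_mito))
  ann <- data.frame(
    gene_id = gene_ids,
    symbol = paste0("S", gene_ids),
    length_bp = sample(300:10000, n_genes, replace = TRUE),
    is_mitochondrial = is_mito,
    ortholog_symbol = ifelse(runif(n_genes) < 0.2, NA_character_,
                             toupper(paste0("S", gene_ids))),
    stringsAsFactors = FALSE)
  groups <- sample(c("young", "old"), n_cells, replace = TRUE)
  groups[1:2] <- c("young", "old")  # both groups always present
  list(dense = dense,
       counts = methods::as(Matrix::Matrix(dense, sparse = TRUE),
                            "CsparseMatrix"),
       annotation = ann,
       groups = setNames(groups, cell_ids))
}

# Compact simulation config for unit tests. QC thresholds must be lowered to
# match the reduced gene universe, and the mito-abundance boost (calibrated
# for the 2000-gene default) is switched off so mito genes do not dominate a
# tiny universe.
small_sim <- function(seed, ...) {
  sim_config(n_cells_young = 60L, n_cells_old = 120L, n_genes = 150L,
             n_mito_genes = 5L, mito_abundance_factor = 1, seed = seed, ...)
}
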