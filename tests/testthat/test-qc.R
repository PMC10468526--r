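# Boundary fixture: 250 genes so the default min_genes = 200 is reachable.
# Cells are built to sit exactly on, just below and just above each QC rule.
boundary_fixture <- function() {
  n_genes <- 250L
  gene_ids <- sprintf("bg_%03d", seq_len(n_genes))
  is_mito <- c(rep(FALSE, 240L), rep(TRUE, 10L))
  ann <- data.frame(gene_id = gene_ids, symbol = gene_ids,
                    length_bp = 1000L, is_mitochondrial = is_mito,
                    ortholog_symbol = toupper(gene_ids),
                    stringsAsFactors = FALSE)
  mk_cell <- function(n_detected, mito_count = 0L, first_gene = 1L) {
    v <- integer(n_genes)
    v[seq_len(n_detected)] <- 1L
    v[1L] <- first_gene
    v[241L] <- mito_count
    v
  }
  cells <- rbind(
    at_200 = mk_cell(200L),
    at_199 = mk_cell(199L),
    # 200 non-mito counts + 50 mito = total 250, fraction exactly 0.20
    mito_20 = mk_cell(200L, mito_count = 50L),
    # 237 non-mito counts + 63 mito = total 300, fraction exactly 0.21
    mito_21 = mk_cell(200L, mito_count = 63L, first_gene = 38L))
  colnames(cells) <- gene_ids
  counts <- methods::as(Matrix::Matrix(cells, sparse = TRUE), "CsparseMatrix")
  list(counts = counts, annotation = ann)
}

test_that("QC boundaries follow the strict less-than / more-than rules", {
  fx <- boundary_fixture()
  res <- qc_filter(fx$counts, fx$annotation)
  rep <- res$report
  expect_equal(rep$genes_detected[rep$cell_id == "at_200"], 200L)
  expect_true(rep$passed[rep$cell_id == "at_200"])
  expect_false(rep$passed[rep$cell_id == "at_199"])
  expect_equal(rep$reason[rep$cell_id == "at_199"], "low_genes")
  expect_equal(rep$mito_fraction[rep$cell_id == "mito_20"], 0.20)
  expect_true(rep$passed[rep$cell_id == "mito_20"])
  expect_false(rep$passed[rep$cell_id == "mito_21"])
  expect_equal(rep$reason[rep$cell_id == "mito_21"], "high_mito")
  expect_setequal(rownames(res$counts), c("at_200", "mito_20"))
  # gene universe unchanged
  expect_identical(colnames(res$counts), colnames(fx$counts))
})

test_that("QC matches the dense per-cell oracle and is idempotent", {
  for (s in 1:5) {
    fx <- make_fixture(s, n_cells = 50L)
    res <- qc_filter(fx$counts, fx$annotation, min_genes = 20L,
                     max_mito = 0.15)
    keep <- oracle_qc_keep(fx$dense, fx$annotation$is_mitochondrial,
                           min_genes = 20L, max_mito = 0.15)
    expect_identical(rownames(res$counts), rownames(fx$dense)[keep])
    expect_identical(res$report$passed, keep)

    again <- qc_filter(res$counts, fx$annotation, min_genes = 20L,
                       max_mito = 0.15)
    expect_identical(dim(again$counts), dim(res$counts))
    expect_true(all(again$report$passed))
  }
})

test_that("QC rejects unannotated genes and empty matrices", {
  fx <- make_fixture(1)
  expect_error(qc_filter(fx$counts, fx$annotation[-(1:3), ]), "fx_gene_001",
               class = "hepscreen_input_error")
  expect_error(qc_filter(fx$counts[0, ], fx$annotation), "empty",
               class = "hepscreen_input_error")
})

test_that("RPKM follows count * 1e9 / (total * length)", {
  ann <- data.frame(gene_id = c("g1", "g2"), symbol = c("g1", "g2"),
                    length_bp = c(500L, 2000L), is_mitochondrial = FALSE,
                    ortholog_symbol = NA_character_, stringsAsFactors = FALSE)
  counts <- Matrix::Matrix(matrix(c(3, 7), 1, dimnames = list("c1", ann$gene_id)),
                           sparse = TRUE)
  expect_equal(as.numeric(compute_rpkm(counts, ann)), c(600000, 350000))

  one <- data.frame(gene_id = "g", symbol = "g", length_bp = 1000L,
                    is_mitochondrial = FALSE, ortholog_symbol = NA,
                    stringsAsFactors = FALSE)
  m <- Matrix::Matrix(matrix(10, 1, dimnames = list("c1", "g")), sparse = TRUE)
  expect_equal(as.numeric(compute_rpkm(m, one)), 1e6)
})

test_that("RPKM matches the dense oracle, preserves zeros, and is scale-invariant", {
  fx <- make_fixture(21)
  rpkm <- compute_rpkm(fx$counts, fx$annotation)
  expected <- oracle_rpkm(fx$dense, fx$annotation$length_bp)
  expect_equal(as.matrix(rpkm), expected, tolerance = 1e-12)
  expect_identical(as.matrix(rpkm) == 0, fx$dense == 0)

  doubled <- fx$counts * 3
  expect_equal(as.matrix(compute_rpkm(doubled, fx$annotation)),
               as.matrix(rpkm), tolerance = 1e-12)
})

test_that("per-cell RPKM-length products conserve 1e9", {
  fx <- make_fixture(8, n_cells = 40L)
  rpkm <- compute_rpkm(fx$counts, fx$annotation)
  totals <- as.matrix(rpkm) %*% fx$annotation$length_bp
  expect_equal(as.numeric(totals), rep(1e9, nrow(rpkm)), tolerance = 1e-6)
})

test_that("RPKM refuses cells with zero totals, naming them", {
  fx <- make_fixture(3, n_cells = 10L)
  dense <- fx$dense
  dense["fx_cell_004", ] <- 0L
  counts <- methods::as(Matrix::Matrix(dense, sparse = TRUE), "CsparseMatrix")
  expect_error(compute_rpkm(counts, fx$annotation), "fx_cell_004",
               class = "hepscreen_input_error")
})

test_that("albumin gating keeps strictly supra-threshold cells in order", {
  ann <- data.frame(gene_id = c("g1", "g2"), symbol = c("Alb", "Other"),
                    length_bp = c(1000L, 1000L), is_mitochondrial = FALSE,
                    ortholog_symbol = NA_character_, stringsAsFactors = FALSE)
  # cell r1 has Alb RPKM exactly 1: count 2, total 3906250, length 512
  ann$length_bp[1] <- 512L
  dense <- rbind(r1 = c(2, 3906248), r2 = c(4, 3906246), r3 = c(0, 100))
  colnames(dense) <- ann$gene_id
  counts <- Matrix::Matrix(dense, sparse = TRUE)
  rpkm <- compute_rpkm(counts, ann)
  expect_identical(rpkm["r1", "g1"], 1)  # exact threshold value
  expect_identical(gate_positive_cells(rpkm, ann), "r2")

  # all cells positive -> identity subset, order preserved
  high <- Matrix::Matrix(rbind(r1 = c(100, 1), r2 = c(50, 1), r3 = c(70, 1)),
                         sparse = TRUE)
  colnames(high) <- ann$gene_id
  rpkm2 <- compute_rpkm(high, ann)
  expect_identical(gate_positive_cells(rpkm2, ann), c("r1", "r2", "r3"))

  expect_error(gate_positive_cells(rpkm, ann, gate_symbol = "Missing"),
               "Missing", class = "hepscreen_input_error")
  amb <- rbind(ann, ann[1, ]); amb$gene_id[3] <- "g3"
  m3 <- cbind(high, g3 = c(1, 1, 1))
  expect_error(gate_positive_cells(compute_rpkm(m3, amb), amb),
               "ambiguous", class = "hepscreen_input_error")
})

test_that("gating equals a brute-force scan on random fixtures", {
  for (s in 6:8) {
    fx <- make_fixture(s)
    ann <- fx$annotation
    ann$symbol[5] <- "Alb"
    rpkm <- compute_rpkm(fx$counts, ann)
    dense_rpkm <- oracle_rpkm(fx$dense, ann$length_bp)
    expected <- rownames(fx$dense)[dense_rpkm[, 5] > 1]
    expect_identical(gate_positive_cells(rpkm, ann), expected)
  }
})
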