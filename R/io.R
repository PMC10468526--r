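#' Read a CellRanger-style Matrix Market count-matrix triple
#'
#' Reads `matrix.mtx` (genes x cells on disk, the CellRanger convention),
#' `genes.tsv` (gene_id, symbol; no header) and `barcodes.tsv` (one cell id
#' per line), returning a cells x genes sparse matrix. Comment lines
#' (`%...`) in the MTX header are ignored per the format.
#'
#' @param dir directory holding the triple, or explicit paths via
#'   `matrix_file`, `genes_file`, `barcodes_file`.
#' @param matrix_file,genes_file,barcodes_file individual file paths
#'   (default: the conventional names inside `dir`).
#' @return sparse integer cells x genes dgCMatrix with dimnames.
#' @export
read_count_matrix <- function(dir = NULL,
                              matrix_file = file.path(dir, "matrix.mtx"),
                              genes_file = file.path(dir, "genes.tsv"),
                              barcodes_file = file.path(dir, "barcodes.tsv")) {
  for (f in c(matrix_file, genes_file, barcodes_file)) {
    if (!file.exists(f))
      hs_stop(sprintf("input file not found: %s", f), "hepscreen_input_error")
  }
  m <- tryCatch(Matrix::readMM(matrix_file), error = function(e)
    hs_stop(sprintf("malformed Matrix Market file %s: %s", matrix_file,
                    conditionMessage(e)), "hepscreen_format_error"))
  genes <- read.delim(genes_file, header = FALSE, stringsAsFactors = FALSE)
  barcodes <- readLines(barcodes_file)
  if (nrow(genes) != nrow(m))
    hs_stop(sprintf("%s: %d genes but matrix has %d rows", genes_file,
                    nrow(genes), nrow(m)), "hepscreen_format_error")
  if (length(barcodes) != ncol(m))
    hs_stop(sprintf("%s: %d barcodes but matrix has %d columns",
                    barcodes_file, length(barcodes), ncol(m)),
            "hepscreen_format_error")
  m <- methods::as(methods::as(Matrix::t(m), "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(barcodes, genes[[1]])
  m
}

#' Write a count matrix as a CellRanger-style MTX triple
#'
#' Transposes the internal cells x genes matrix to the on-disk genes x cells
#' orientation and writes `matrix.mtx`, `genes.tsv` (gene_id, symbol) and
#' `barcodes.tsv`. Files are written atomically (temp file + rename).
#'
#' @param counts sparse cells x genes matrix with dimnames.
#' @param dir output directory (created if needed).
#' @param annotation optional annotation supplying gene symbols for
#'   `genes.tsv`; ids are repeated as symbols when absent.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(counts, dir, annotation = NULL) {
  check_count_matrix(counts)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  symbols <- colnames(counts)
  if (!is.null(annotation)) {
    idx <- match(colnames(counts), annotation$gene_id)
    symbols <- ifelse(is.na(idx), colnames(counts), annotation$symbol[idx])
  }
  with_atomic_file(file.path(dir, "matrix.mtx"), function(tmp)
    Matrix::writeMM(Matrix::t(counts), tmp))
  write_tsv_atomic(data.frame(colnames(counts), symbols),
                   file.path(dir, "genes.tsv"), col.names = FALSE)
  with_atomic_file(file.path(dir, "barcodes.tsv"), function(tmp)
    writeLines(rownames(counts), tmp))
  invisible(dir)
}

with_atomic_file <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_tsv_atomic <- function(df, path, col.names = TRUE) {
  with_atomic_file(path, function(tmp)
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = col.names, na = "NA"))
}

#' Read / write a gene annotation table
#'
#' Tab-separated with header columns `gene_id`, `symbol`, `length_bp`,
#' `is_mitochondrial`, `ortholog_symbol` (empty or NA for genes without an
#' ortholog).
#'
#' @param path file path.
#' @return data.frame annotation.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path))
    hs_stop(sprintf("annotation file not found: %s", path),
            "hepscreen_input_error")
  ann <- read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  needed <- c("gene_id", "symbol", "length_bp", "is_mitochondrial")
  miss <- setdiff(needed, names(ann))
  if (length(miss))
    hs_stop(paste0(path, ": missing annotation columns: ",
                   paste(miss, collapse = ", ")), "hepscreen_format_error")
  if (!"ortholog_symbol" %in% names(ann)) ann$ortholog_symbol <- NA_character_
  if (any(duplicated(ann$gene_id)))
    hs_stop(paste0(path, ": duplicated gene ids"), "hepscreen_format_error")
  if (any(ann$length_bp <= 0))
    hs_stop(paste0(path, ": non-positive transcript lengths"),
            "hepscreen_format_error")
  ann$is_mitochondrial <- as.logical(ann$is_mitochondrial)
  ann
}

#' @rdname read_annotation
#' @param annotation annotation data.frame to write.
#' @export
write_annotation <- function(annotation, path) {
  write_tsv_atomic(annotation, path)
  invisible(path)
}

#' Read a gene-set file
#'
#' Plain text, one gene symbol per line; an optional first line
#' `# name=<set name>` names the set, and other `#` lines are comments.
#'
#' @param path file path.
#' @return list with `name` and `symbols`.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path))
    hs_stop(sprintf("gene-set file not found: %s", path),
            "hepscreen_input_error")
  lines <- trimws(readLines(path))
  name <- basename(path)
  m <- grepl("^#\\s*name=", lines)
  if (any(m)) name <- sub("^#\\s*name=", "", lines[which(m)[1]])
  symbols <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(symbols) == 0L)
    hs_stop(sprintf("gene set %s is empty", path), "hepscreen_input_error")
  list(name = name, symbols = unique(symbols))
}

#' Write a correlation matrix as TSV with "-" for undefined entries
#'
#' Undefined coefficients (zero-variance genes, e.g. a marker with no
#' expression in the young group) are rendered as a hyphen.
#'
#' @param cc matrix from [pairwise_correlation()].
#' @param path output path.
#' @param digits significant digits for coefficients (default 6).
#' @return `path`, invisibly.
#' @export
write_correlation_tsv <- function(cc, path, digits = 6) {
  out <- matrix("-", nrow(cc), ncol(cc), dimnames = dimnames(cc))
  def <- !is.na(cc)
  out[def] <- signif(cc[def], digits)
  df <- data.frame(gene = rownames(cc), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_atomic(df, path)
  invisible(path)
}

#' Read / write simulation truth labels
#'
#' TSV with columns `cell_id`, `group`, `senescent`.
#'
#' @param path file path.
#' @return data.frame truth table.
#' @export
read_sim_truth <- function(path) {
  if (!file.exists(path))
    hs_stop(sprintf("truth file not found: %s", path), "hepscreen_input_error")
  tr <- read.delim(path, stringsAsFactors = FALSE)
  tr$senescent <- as.logical(tr$senescent)
  tr
}

#' @rdname read_sim_truth
#' @param truth truth data.frame to write.
#' @export
write_sim_truth <- function(truth, path) {
  write_tsv_atomic(truth, path)
  invisible(path)
}
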