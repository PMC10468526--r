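#' Configuration for a full screening run
#'
#' A run is either self-contained (an embedded [sim_config()] generates the
#' counts) or file-driven (a CellRanger-style MTX triple plus annotation and
#' group-label files). Exactly one of `sim` and `input_dir` must be given.
#'
#' @param sim a [sim_config()] for a self-contained simulated run.
#' @param input_dir directory with `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @param annotation_file annotation TSV path (file-driven runs).
#' @param groups_file TSV with header columns `cell_id`, `group`
#'   (file-driven runs); groups must be labelled `young` and `old`.
#' @param gate_symbol hepatocyte gate gene symbol (default `"Alb"`).
#' @param threshold_rpkm positive-cell threshold (default 1.0).
#' @param min_genes,max_mito QC thresholds (defaults 200 and 0.20).
#' @param top_k,require_ortholog candidate selection parameters
#'   (defaults 43 and TRUE).
#' @param correlation_genes gene ids to correlate within each group;
#'   `NULL` defaults to the planted markers for simulated runs and to the
#'   top 5 candidates otherwise.
#' @param gene_set_file optional gene-set file for [geneset_correlation()].
#' @param high_r "high correlation" cutoff (default 0.6).
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @param outdir output directory for the run's tables and report.
#' @param seed optional integer; overrides `sim$seed` for simulated runs.
#'   Analysis stages are deterministic and use no randomness.
#' @return a validated `run_config` list.
#' @export
run_config <- function(sim = NULL, input_dir = NULL, annotation_file = NULL,
                       groups_file = NULL, gate_symbol = "Alb",
                       threshold_rpkm = 1.0, min_genes = 200L,
                       max_mito = 0.20, top_k = 43L, require_ortholog = TRUE,
                       correlation_genes = NULL, gene_set_file = NULL,
                       high_r = 0.6, cor_method = "pearson",
                       outdir, seed = NULL) {
  if (is.null(sim) == is.null(input_dir))
    hs_stop("exactly one of sim / input_dir must be supplied",
            "hepscreen_config_error")
  if (!is.null(sim)) {
    if (!inherits(sim, "sim_config"))
      hs_stop("sim must be a sim_config object", "hepscreen_config_error")
    if (!is.null(seed)) sim$seed <- as.integer(seed)
  } else {
    if (is.null(annotation_file) || is.null(groups_file))
      hs_stop("file-driven runs need annotation_file and groups_file",
              "hepscreen_config_error")
  }
  if (threshold_rpkm < 0 || min_genes < 0 || max_mito < 0 || max_mito > 1 ||
      top_k < 1)
    hs_stop("numeric run parameters out of range", "hepscreen_config_error")
  if (missing(outdir))
    hs_stop("outdir is required", "hepscreen_config_error")
  structure(list(sim = sim, input_dir = input_dir,
                 annotation_file = annotation_file, groups_file = groups_file,
                 gate_symbol = gate_symbol, threshold_rpkm = threshold_rpkm,
                 min_genes = as.integer(min_genes), max_mito = max_mito,
                 top_k = as.integer(top_k), require_ortholog = require_ortholog,
                 correlation_genes = correlation_genes,
                 gene_set_file = gene_set_file, high_r = high_r,
                 cor_method = cor_method, outdir = outdir,
                 seed = if (is.null(seed)) sim$seed else as.integer(seed)),
            class = "run_config")
}

#' Run the full screening workflow
#'
#' Executes simulate/load, QC filtering, per-cell RPKM, albumin gating,
#' positive-cell calling, per-group rate computation, old-minus-young
#' ranking, ortholog-filtered candidate selection, and within-group
#' correlations, writing every table under `config$outdir` and returning a
#' run report. All inputs are loaded (and all input errors raised) before
#' any file is written, and each file is written atomically, so a failed
#' run leaves no partial outputs.
#'
#' Output files: `qc_report.tsv`, `positive_rates.tsv`, `ranking.tsv`,
#' `candidates.tsv`, `correlation_young.tsv`, `correlation_old.tsv`,
#' optionally `geneset_correlation_<group>.tsv`, `report.json`, `run.log`,
#' `config.yaml`, and for simulated runs the generated input under `input/`
#' plus `sim_truth.tsv`.
#'
#' @param config a [run_config()].
#' @return the run report (list), invisibly contains all stage counts,
#'   the candidate table and correlation summaries.
#' @export
run_screen <- function(config) {
  if (!inherits(config, "run_config"))
    hs_stop("config must be a run_config object", "hepscreen_config_error")

  simulated <- !is.null(config$sim)
  if (simulated) {
    annotation <- generate_annotation(config$sim)
    sim <- simulate_counts(config$sim, annotation)
    counts <- sim$counts
    truth <- sim$truth
    groups <- setNames(truth$group, truth$cell_id)
  } else {
    counts <- read_count_matrix(config$input_dir)
    annotation <- read_annotation(config$annotation_file)
    gdf <- read.delim(config$groups_file, stringsAsFactors = FALSE)
    if (!all(c("cell_id", "group") %in% names(gdf)))
      hs_stop(paste0(config$groups_file,
                     ": needs columns cell_id and group"),
              "hepscreen_format_error")
    groups <- setNames(gdf$group, gdf$cell_id)
    truth <- NULL
  }
  gene_set <- if (!is.null(config$gene_set_file))
    read_gene_set(config$gene_set_file) else NULL

  # ---- analysis stages (deterministic) ----
  qc <- qc_filter(counts, annotation, config$min_genes, config$max_mito)
  expr <- compute_rpkm(qc$counts, annotation)
  gated <- gate_positive_cells(expr, annotation, config$gate_symbol,
                               config$threshold_rpkm)
  expr_g <- expr[gated, , drop = FALSE]
  calls <- call_positive(expr_g, config$threshold_rpkm)
  rates <- positive_rates(calls, groups[gated])
  ranking <- rank_by_rate_difference(rates)
  candidates <- select_candidates(ranking, annotation, config$top_k,
                                  config$require_ortholog)

  cor_genes <- config$correlation_genes
  if (is.null(cor_genes)) {
    cor_genes <- if (simulated) attr(truth, "marker_gene_ids")
                 else head(candidates$gene_id, 5L)
  }
  grp_gated <- groups[gated]
  cor_by_group <- lapply(c(young = "young", old = "old"), function(g)
    pairwise_correlation(expr_g, cor_genes, gated[grp_gated == g],
                         method = config$cor_method))
  gs_by_group <- if (!is.null(gene_set)) {
    lapply(c(young = "young", old = "old"), function(g)
      geneset_correlation(expr_g, cor_genes, gene_set,
                          gated[grp_gated == g], annotation,
                          high_r = config$high_r,
                          method = config$cor_method))
  } else NULL

  # ---- stage accounting ----
  count_by_group <- function(cells) {
    g <- groups[cells]
    c(young = sum(g == "young", na.rm = TRUE),
      old = sum(g == "old", na.rm = TRUE))
  }
  stages <- list(input = count_by_group(rownames(counts)),
                 post_qc = count_by_group(rownames(qc$counts)),
                 post_gate = count_by_group(gated))
  stopifnot(all(stages$post_gate <= stages$post_qc),
            all(stages$post_qc <= stages$input))

  report <- list(
    package_version = as.character(packageVersion("hepscreen")),
    seed = config$seed,
    simulated = simulated,
    n_genes = ncol(counts),
    cells = lapply(stages, as.list),
    n_candidates = nrow(candidates),
    candidates = candidates,
    correlation_genes = cor_genes,
    correlation_method = config$cor_method,
    correlation = lapply(cor_by_group, function(m) {
      m[is.na(m)] <- NA  # keep NAs explicit in JSON (null)
      as.data.frame(as.table(m), stringsAsFactors = FALSE) |>
        setNames(c("gene_a", "gene_b", "coefficient"))
    }),
    config = config_echo(config)
  )

  # ---- outputs ----
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (simulated) {
    write_count_matrix(counts, file.path(outdir, "input"), annotation)
    write_annotation(annotation, file.path(outdir, "input", "annotation.tsv"))
    write_sim_truth(truth, file.path(outdir, "sim_truth.tsv"))
  }
  write_tsv_atomic(qc$report, file.path(outdir, "qc_report.tsv"))
  write_tsv_atomic(rates, file.path(outdir, "positive_rates.tsv"))
  write_tsv_atomic(ranking, file.path(outdir, "ranking.tsv"))
  write_tsv_atomic(candidates, file.path(outdir, "candidates.tsv"))
  for (g in names(cor_by_group))
    write_correlation_tsv(cor_by_group[[g]],
                          file.path(outdir, sprintf("correlation_%s.tsv", g)))
  if (!is.null(gs_by_group)) {
    for (g in names(gs_by_group))
      write_tsv_atomic(gs_by_group[[g]],
                       file.path(outdir,
                                 sprintf("geneset_correlation_%s.tsv", g)))
  }
  with_atomic_file(file.path(outdir, "report.json"), function(tmp)
    jsonlite::write_json(report, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, na = "null"))
  with_atomic_file(file.path(outdir, "config.yaml"), function(tmp)
    yaml::write_yaml(config_echo(config), tmp))
  with_atomic_file(file.path(outdir, "run.log"), function(tmp)
    writeLines(run_log_lines(stages, nrow(candidates)), tmp))

  if (!is.null(gs_by_group)) report$geneset_correlation <- gs_by_group
  report$correlation_matrices <- cor_by_group
  invisible(report)
}

config_echo <- function(config) {
  echo <- unclass(config)
  if (!is.null(echo$sim)) echo$sim <- unclass(echo$sim)
  echo[!vapply(echo, is.null, logical(1))]
}

run_log_lines <- function(stages, n_candidates) {
  c(sprintf("input cells: young=%d old=%d", stages$input["young"],
            stages$input["old"]),
    sprintf("post-QC cells: young=%d old=%d", stages$post_qc["young"],
            stages$post_qc["old"]),
    sprintf("post-gate cells: young=%d old=%d", stages$post_gate["young"],
            stages$post_gate["old"]),
    sprintf("candidates selected: %d", n_candidates))
}
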