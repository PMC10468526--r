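#' Simulation configuration for a two-age-group hepatocyte count matrix
#'
#' Builds and validates the parameter set for the synthetic-data generator.
#' The generator emulates the structure of a plate-based hepatocyte scRNA-seq
#' experiment: two age groups of cells, lognormal library sizes, lognormal
#' per-gene relative abundances, negative-binomial counts, a block of
#' mitochondrial genes, a ubiquitously expressed albumin-like gate gene, and
#' a planted senescent subpopulation (rare in young animals, common in old)
#' that co-expresses a configurable set of marker genes.
#'
#' Defaults reproduce the scale of the screen this package implements:
#' 255 young and 1251 old cells, 2000 genes, 3 planted markers with an
#' 8-fold expression increase in senescent cells, senescent fractions
#' 0.02 (young) and 0.35 (old).
#'
#' @param n_cells_young,n_cells_old number of cells per age group.
#' @param n_genes number of genes in the simulated universe.
#' @param n_mito_genes number of genes flagged mitochondrial (`< n_genes`).
#' @param marker_gene_ids gene ids (within the simulated universe) whose
#'   relative abundance is multiplied by `marker_fold` in senescent cells.
#'   `NULL` picks the first `n_markers` non-mito genes after the gate gene.
#' @param n_markers number of planted markers when `marker_gene_ids` is NULL.
#' @param marker_symbols optional symbols to assign to the marker genes in
#'   the generated annotation (recycled error if wrong length).
#' @param senescent_fraction_young,senescent_fraction_old per-cell Bernoulli
#'   probability of senescent membership, by group; both in \[0, 1\]. The
#'   young fraction is deliberately *not* constrained to be below the old
#'   one: that ordering is the hypothesis the screen recovers, not an input.
#' @param marker_fold multiplicative effect (> 1 for a planted signal, 1 for
#'   a null simulation) on marker-gene relative abundance in senescent cells.
#' @param marker_base_quantile quantile of the baseline abundance
#'   distribution at which marker genes' baseline abundance is pinned.
#'   Informative senescence markers are lowly expressed in young tissue, so
#'   markers are planted in the low-expression regime rather than drawn at
#'   random (default 0.2).
#' @param baseline_mean_log_mu,baseline_mean_log_sigma lognormal parameters
#'   of per-gene relative abundance (log scale).
#' @param libsize_log_mu,libsize_log_sigma lognormal parameters of per-cell
#'   total read count (log scale). Defaults give a median of ~20,000 reads.
#' @param nb_dispersion negative-binomial dispersion phi > 0;
#'   `var = mu + phi * mu^2`.
#' @param gate_gene_id gene id of the albumin-like gate gene, forced to a
#'   high relative abundance (99th percentile of baseline) in every cell.
#'   `NULL` picks the first gene.
#' @param gate_symbol symbol assigned to the gate gene in the annotation.
#' @param ortholog_none_fraction fraction of non-gate, non-marker genes left
#'   without an ortholog symbol, to exercise the ortholog filter.
#' @param mito_abundance_factor fixed multiplier on mitochondrial genes'
#'   baseline abundance, giving cells a realistic mitochondrial read
#'   fraction.
#' @param seed integer seed; every stochastic draw in the generator flows
#'   from it.
#'
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_cells_young = 255L,
                       n_cells_old = 1251L,
                       n_genes = 2000L,
                       n_mito_genes = 13L,
                       marker_gene_ids = NULL,
                       n_markers = 3L,
                       marker_symbols = NULL,
                       senescent_fraction_young = 0.02,
                       senescent_fraction_old = 0.35,
                       marker_fold = 8,
                       marker_base_quantile = 0.2,
                       baseline_mean_log_mu = 0,
                       baseline_mean_log_sigma = 2,
                       libsize_log_mu = log(2e4),
                       libsize_log_sigma = 0.4,
                       nb_dispersion = 0.5,
                       gate_gene_id = NULL,
                       gate_symbol = "Alb",
                       ortholog_none_fraction = 0.1,
                       mito_abundance_factor = 10,
                       seed = 1L) {
  cfg <- list(
    n_cells_young = as.integer(n_cells_young),
    n_cells_old = as.integer(n_cells_old),
    n_genes = as.integer(n_genes),
    n_mito_genes = as.integer(n_mito_genes),
    marker_gene_ids = marker_gene_ids,
    marker_symbols = marker_symbols,
    senescent_fraction_young = senescent_fraction_young,
    senescent_fraction_old = senescent_fraction_old,
    marker_fold = marker_fold,
    marker_base_quantile = marker_base_quantile,
    baseline_mean_log_mu = baseline_mean_log_mu,
    baseline_mean_log_sigma = baseline_mean_log_sigma,
    libsize_log_mu = libsize_log_mu,
    libsize_log_sigma = libsize_log_sigma,
    nb_dispersion = nb_dispersion,
    gate_gene_id = gate_gene_id,
    gate_symbol = gate_symbol,
    ortholog_none_fraction = ortholog_none_fraction,
    mito_abundance_factor = mito_abundance_factor,
    seed = as.integer(seed)
  )

  if (is.na(cfg$n_genes) || cfg$n_genes < 2L)
    hs_stop("invalid config: n_genes must be a count >= 2",
            "hepscreen_config_error")
  if (is.na(cfg$n_mito_genes) || cfg$n_mito_genes < 0L ||
      cfg$n_mito_genes >= cfg$n_genes)
    hs_stop("invalid config: n_mito_genes must be in [0, n_genes)",
            "hepscreen_config_error")
  gene_ids <- sim_gene_ids(cfg$n_genes)
  # mito genes occupy the tail of the universe; gate and markers the head
  if (is.null(cfg$gate_gene_id)) cfg$gate_gene_id <- gene_ids[1L]
  if (is.null(cfg$marker_gene_ids)) {
    n_markers <- as.integer(n_markers)
    if (n_markers < 1L || n_markers > cfg$n_genes - cfg$n_mito_genes - 1L)
      hs_stop("invalid config: n_markers out of range", "hepscreen_config_error")
    start <- match(cfg$gate_gene_id, gene_ids)
    pool <- setdiff(gene_ids[seq_len(cfg$n_genes - cfg$n_mito_genes)],
                    cfg$gate_gene_id)
    cfg$marker_gene_ids <- pool[seq_len(n_markers)]
  }

  validate_sim_config(cfg, gene_ids)
  structure(cfg, class = "sim_config")
}

sim_gene_ids <- function(n_genes) {
  sprintf("gene_%04d", seq_len(n_genes))
}

validate_sim_config <- function(cfg, gene_ids = sim_gene_ids(cfg$n_genes)) {
  chk_count <- function(x, field, min = 1L) {
    if (length(x) != 1L || is.na(x) || x < min)
      hs_stop(sprintf("invalid config: %s must be a count >= %d", field, min),
              "hepscreen_config_error")
  }
  chk_count(cfg$n_cells_young, "n_cells_young")
  chk_count(cfg$n_cells_old, "n_cells_old")
  chk_count(cfg$n_genes, "n_genes", min = 2L)
  chk_count(cfg$n_mito_genes, "n_mito_genes", min = 0L)
  if (cfg$n_mito_genes >= cfg$n_genes)
    hs_stop("invalid config: n_mito_genes must be < n_genes",
            "hepscreen_config_error")
  for (field in c("senescent_fraction_young", "senescent_fraction_old",
                  "ortholog_none_fraction", "marker_base_quantile")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      hs_stop(sprintf("invalid config: %s must be in [0, 1]", field),
              "hepscreen_config_error")
  }
  if (!is.numeric(cfg$marker_fold) || cfg$marker_fold <= 0)
    hs_stop("invalid config: marker_fold must be > 0", "hepscreen_config_error")
  if (!is.numeric(cfg$nb_dispersion) || cfg$nb_dispersion <= 0)
    hs_stop("invalid config: nb_dispersion must be > 0", "hepscreen_config_error")
  bad <- setdiff(cfg$marker_gene_ids, gene_ids)
  if (length(bad))
    hs_stop(paste0("invalid config: marker_gene_ids outside gene universe: ",
                   paste(bad, collapse = ", ")), "hepscreen_config_error")
  if (!cfg$gate_gene_id %in% gene_ids)
    hs_stop("invalid config: gate_gene_id outside gene universe",
            "hepscreen_config_error")
  if (cfg$gate_gene_id %in% cfg$marker_gene_ids)
    hs_stop("invalid config: gate_gene_id must not be a marker gene",
            "hepscreen_config_error")
  if (!is.null(cfg$marker_symbols) &&
      length(cfg$marker_symbols) != length(cfg$marker_gene_ids))
    hs_stop("invalid config: marker_symbols length must match marker_gene_ids",
            "hepscreen_config_error")
  invisible(cfg)
}

#' Generate a gene annotation table for a simulation
#'
#' One row per simulated gene: id, symbol, transcript length (uniform in
#' 300-10000 bp), mitochondrial flag, and a mouse-ortholog symbol for all but
#' a configured fraction of genes. The gate gene and planted marker genes
#' always receive ortholog symbols: a marker without an ortholog could never
#' survive the ortholog filter, which would break the planted ground truth.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `gene_id`, `symbol`, `length_bp`,
#'   `is_mitochondrial`, `ortholog_symbol` (NA when absent).
#' @export
generate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  gene_ids <- sim_gene_ids(n)
  is_mito <- rep(FALSE, n)
  if (config$n_mito_genes > 0L)
    is_mito[seq.int(n - config$n_mito_genes + 1L, n)] <- TRUE

  symbol <- sprintf("Sym%04d", seq_len(n))
  symbol[is_mito] <- sprintf("mt-Sym%04d", which(is_mito))
  gate_idx <- match(config$gate_gene_id, gene_ids)
  symbol[gate_idx] <- config$gate_symbol
  marker_idx <- match(config$marker_gene_ids, gene_ids)
  if (!is.null(config$marker_symbols)) {
    symbol[marker_idx] <- config$marker_symbols
  }

  length_bp <- as.integer(round(runif(n, 300, 10000)))
  ortholog <- toupper(symbol)
  # markers and gate are exempt from ortholog dropout
  protected <- seq_len(n) %in% c(gate_idx, marker_idx)
  drop <- runif(n) < config$ortholog_none_fraction & !protected
  ortholog[drop] <- NA_character_

  data.frame(gene_id = gene_ids, symbol = symbol, length_bp = length_bp,
             is_mitochondrial = is_mito, ortholog_symbol = ortholog,
             stringsAsFactors = FALSE)
}

#' Simulate counts for two age groups with a planted senescent subpopulation
#'
#' Per-gene relative abundances are lognormal draws normalized to sum 1, with
#' three deterministic overrides: the gate gene is pinned at the 99th
#' percentile of baseline abundance (near-universal albumin positivity),
#' marker genes are pinned at `marker_base_quantile` (the low-expression
#' regime where a fold change crosses the detection threshold), and
#' mitochondrial genes are scaled by `mito_abundance_factor`. Each cell draws
#' a lognormal library-size scale and a Bernoulli senescent flag (probability
#' set by its group); senescent cells multiply marker abundances by
#' `marker_fold` and renormalize, so senescence does not confound library
#' size. Counts are negative binomial with mean `scale * abundance` and
#' variance `mu + phi * mu^2`.
#'
#' A single stream is seeded once per call; gene-level draws precede
#' cell-level draws, so results are independent of any chunking.
#'
#' @param config a [sim_config()].
#' @param annotation annotation from [generate_annotation()] (consistency
#'   checked).
#' @return list with `counts` (sparse cells x genes integer dgCMatrix with
#'   cell/gene dimnames) and `truth` (data.frame `cell_id`, `group`,
#'   `senescent`) carrying attributes `marker_gene_ids` and `marker_fold`.
#' @export
simulate_counts <- function(config, annotation) {
  validate_sim_config(config)
  if (!identical(annotation$gene_id, sim_gene_ids(config$n_genes)))
    hs_stop("annotation is inconsistent with config gene universe",
            "hepscreen_config_error")
  missing_markers <- setdiff(config$marker_gene_ids, annotation$gene_id)
  if (length(missing_markers))
    hs_stop(paste0("marker gene ids not in annotation: ",
                   paste(missing_markers, collapse = ", ")),
            "hepscreen_config_error")

  set.seed(config$seed)
  n_genes <- config$n_genes
  n_young <- config$n_cells_young
  n_old <- config$n_cells_old
  n_cells <- n_young + n_old
  gene_ids <- annotation$gene_id

  # gene-level draws first
  abund <- rlnorm(n_genes, config$baseline_mean_log_mu,
                  config$baseline_mean_log_sigma)
  abund[annotation$is_mitochondrial] <-
    abund[annotation$is_mitochondrial] * config$mito_abundance_factor
  abund[match(config$gate_gene_id, gene_ids)] <- quantile(abund, 0.99)
  marker_idx <- match(config$marker_gene_ids, gene_ids)
  abund[marker_idx] <- quantile(abund, config$marker_base_quantile)

  p_base <- abund / sum(abund)
  abund_sen <- abund
  abund_sen[marker_idx] <- abund_sen[marker_idx] * config$marker_fold
  p_sen <- abund_sen / sum(abund_sen)

  # cell-level draws: flags, then library sizes, then counts
  group <- rep(c("young", "old"), c(n_young, n_old))
  sen_prob <- ifelse(group == "young", config$senescent_fraction_young,
                     config$senescent_fraction_old)
  senescent <- rbinom(n_cells, 1L, sen_prob) == 1L
  libsize <- rlnorm(n_cells, config$libsize_log_mu, config$libsize_log_sigma)

  mu <- outer(libsize, p_base)
  if (any(senescent))
    mu[senescent, ] <- outer(libsize[senescent], p_sen)
  counts <- rnbinom(length(mu), mu = as.vector(mu),
                    size = 1 / config$nb_dispersion)
  counts <- matrix(counts, nrow = n_cells, ncol = n_genes)

  cell_ids <- sprintf("cell_%s_%04d", group, c(seq_len(n_young), seq_len(n_old)))
  dimnames(counts) <- list(cell_ids, gene_ids)
  counts <- methods::as(methods::as(Matrix(counts, sparse = TRUE), "generalMatrix"),
                        "CsparseMatrix")

  truth <- data.frame(cell_id = cell_ids, group = group,
                      senescent = senescent, stringsAsFactors = FALSE)
  attr(truth, "marker_gene_ids") <- config$marker_gene_ids
  attr(truth, "marker_fold") <- config$marker_fold
  list(counts = counts, truth = truth)
}
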