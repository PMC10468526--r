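test_that("positive calls use a strict threshold and match the dense oracle", {
  m <- Matrix::Matrix(matrix(c(0, 1, 1.0001, 5), 2, 2,
                             dimnames = list(c("c1", "c2"), c("g1", "g2"))),
                      sparse = TRUE)
  calls <- call_positive(m)
  expect_equal(as.matrix(calls),
               matrix(c(0, 0, 1, 1), 2, 2,
                      dimnames = dimnames(m)))
  expect_error(call_positive(m, threshold_rpkm = -1), "non-negative",
               class = "hepscreen_config_error")

  for (s in 1:5) {
    fx <- make_fixture(s)
    rpkm <- compute_rpkm(fx$counts, fx$annotation)
    calls <- call_positive(rpkm, 1.0)
    expected <- oracle_calls(oracle_rpkm(fx$dense, fx$annotation$length_bp), 1.0)
    expect_equal(as.matrix(calls), expected + 0)
  }
})

test_that("positive rates are exact per-group ratios and match the double loop", {
  calls <- Matrix::Matrix(matrix(c(1, 1, 1, 0, 0, 0, 0, 0), 4, 2,
                                 dimnames = list(paste0("c", 1:4),
                                                 c("gA", "gB"))),
                          sparse = TRUE)
  grp <- setNames(rep("old", 4), paste0("c", 1:4))
  rates <- positive_rates(calls, grp)
  expect_equal(rates$rate[rates$gene_id == "gA"], 0.75)
  expect_equal(rates$rate[rates$gene_id == "gB"], 0)

  fx <- make_fixture(13, n_cells = 200L, n_genes = 40L)
  rpkm <- compute_rpkm(fx$counts, fx$annotation)
  calls <- call_positive(rpkm)
  got <- positive_rates(calls, fx$groups)
  want <- oracle_rates(oracle_calls(oracle_rpkm(fx$dense,
                                                fx$annotation$length_bp), 1),
                       fx$groups[rownames(fx$dense)])
  got <- got[order(got$group, got$gene_id), ]
  want <- want[order(want$group, want$gene_id), ]
  expect_equal(got$n_positive, want$n_positive)
  expect_equal(got$rate, want$rate)

  expect_error(positive_rates(calls, fx$groups[-1]), "without a group",
               class = "hepscreen_input_error")
})

test_that("ranking orders by old-minus-young delta with lexicographic ties", {
  rates <- data.frame(
    gene_id = rep(c("gB", "gA", "gC", "gD"), each = 2),
    group = rep(c("young", "old"), 4),
    n_positive = c(2, 10, 1, 5, 4, 6, 2, 4),
    n_cells = rep(c(10, 20), 4),
    rate = c(0.2, 0.5, 0.1, 0.25, 0.4, 0.3, 0.2, 0.2))
  rk <- rank_by_rate_difference(rates)
  expect_equal(rk$gene_id, c("gB", "gA", "gD", "gC"))
  expect_equal(rk$delta, c(0.3, 0.15, 0.0, -0.1))
  expect_equal(rk$rank, 1:4)

  # equal deltas: smaller gene_id first
  tie <- data.frame(gene_id = rep(c("gZ", "gY"), each = 2),
                    group = rep(c("young", "old"), 2),
                    n_positive = 0, n_cells = 10,
                    rate = c(0.1, 0.3, 0.2, 0.4))
  expect_equal(rank_by_rate_difference(tie)$gene_id, c("gY", "gZ"))

  # a gene measured in one group only gets rate 0 in the other
  lop <- rbind(rates, data.frame(gene_id = "gE", group = "old",
                                 n_positive = 9, n_cells = 20, rate = 0.45))
  rkl <- rank_by_rate_difference(lop)
  expect_equal(rkl$rate_young[rkl$gene_id == "gE"], 0)
  expect_equal(rkl$delta[rkl$gene_id == "gE"], 0.45)

  expect_error(rank_by_rate_difference(rates[rates$group == "old", ]),
               "young", class = "hepscreen_input_error")
})

test_that("ranking of many random genes equals the sort oracle", {
  set.seed(99)
  genes <- sprintf("rg%03d", sample(500))
  rates <- rbind(
    data.frame(gene_id = genes, group = "young", n_positive = 0,
               n_cells = 100, rate = round(runif(500), 2)),
    data.frame(gene_id = genes, group = "old", n_positive = 0,
               n_cells = 100, rate = round(runif(500), 2)))
  rk <- rank_by_rate_difference(rates)
  want <- oracle_ranking(rates)
  expect_equal(rk$gene_id, want$gene_id)
  expect_equal(rk$delta, want$delta)
})

test_that("candidate selection filters orthologless genes before truncation", {
  ann <- data.frame(gene_id = sprintf("g%02d", 1:10),
                    symbol = sprintf("S%02d", 1:10),
                    length_bp = 1000L, is_mitochondrial = FALSE,
                    ortholog_symbol = c(NA, sprintf("O%02d", 2:10)),
                    stringsAsFactors = FALSE)
  ranking <- data.frame(gene_id = sprintf("g%02d", 1:10),
                        rate_young = 0, rate_old = seq(1, 0.1, by = -0.1),
                        delta = seq(1, 0.1, by = -0.1), rank = 1:10)
  cand <- select_candidates(ranking, ann, top_k = 5)
  # rank-1 gene g01 has no ortholog: dropped, ranks 2..6 returned
  expect_equal(cand$gene_id, sprintf("g%02d", 2:6))
  expect_equal(cand$rank, 2:6)

  plain <- select_candidates(ranking, ann, top_k = 5, require_ortholog = FALSE)
  expect_equal(plain$gene_id, sprintf("g%02d", 1:5))

  shortlist <- select_candidates(ranking, ann, top_k = 50)
  expect_equal(nrow(shortlist), 9L)
  expect_error(select_candidates(ranking, ann, top_k = 0), "top_k",
               class = "hepscreen_config_error")
})

test_that("raising the RPKM threshold never increases any positive rate", {
  cfg <- small_sim(17)
  ann <- generate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  rpkm <- compute_rpkm(sim$counts, ann)
  grp <- setNames(sim$truth$group, sim$truth$cell_id)
  prev <- NULL
  for (thr in c(0.5, 1, 2, 8)) {
    rates <- positive_rates(call_positive(rpkm, thr), grp)
    rates <- rates[order(rates$group, rates$gene_id), ]
    if (!is.null(prev)) expect_true(all(rates$rate <= prev$rate + 1e-12))
    prev <- rates
  }
})

test_that("per-group positive counts are conserved between calls and rates", {
  fx <- make_fixture(31, n_cells = 80L)
  rpkm <- compute_rpkm(fx$counts, fx$annotation)
  calls <- call_positive(rpkm)
  rates <- positive_rates(calls, fx$groups)
  for (g in c("young", "old")) {
    in_group <- names(fx$groups)[fx$groups == g]
    expect_equal(sum(rates$n_positive[rates$group == g]),
                 sum(calls[in_group, ]))
    expect_equal(sum(rates$rate[rates$group == g] *
                       rates$n_cells[rates$group == g]),
                 sum(calls[in_group, ]))
  }
})

test_that("label permutation collapses the rate-difference signal for all genes", {
  cfg <- sim_config(n_cells_young = 500L, n_cells_old = 500L, n_genes = 300L,
                    n_mito_genes = 5L, senescent_fraction_young = 0,
                    senescent_fraction_old = 0.4, marker_fold = 8, seed = 23)
  ann <- generate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  rpkm <- compute_rpkm(sim$counts, ann)
  calls <- call_positive(rpkm)
  grp <- setNames(sim$truth$group, sim$truth$cell_id)
  observed <- rank_by_rate_difference(positive_rates(calls, grp))
  marker_delta <- min(observed$delta[observed$gene_id %in%
                                       cfg$marker_gene_ids])

  set.seed(41)
  for (i in 1:3) {
    perm <- setNames(sample(grp), names(grp))
    null_rk <- rank_by_rate_difference(positive_rates(calls, perm))
    expect_lt(max(abs(null_rk$delta)), marker_delta)
    expect_lt(max(abs(null_rk$delta)), 0.2)
  }
})
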