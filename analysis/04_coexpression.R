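#!/usr/bin/env Rscript
# Co-expression analysis: correlate the three focal markers with each other
# within each age group (undefined coefficients are rendered "-"), and
# correlate them against a senescence-associated gene panel in the old
# group, where the senescent subpopulation should make panel members
# co-vary with the markers.

suppressPackageStartupMessages(library(hepscreen))

data_dir <- "results/data"
out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_count_matrix(data_dir)
ann <- read_annotation(file.path(data_dir, "annotation.tsv"))
truth <- read_sim_truth(file.path(data_dir, "sim_truth.tsv"))
gated <- readLines(file.path(data_dir, "gated_cells.txt"))
grp <- setNames(truth$group, truth$cell_id)

qc <- qc_filter(counts, ann)
expr <- compute_rpkm(qc$counts, ann)[gated, , drop = FALSE]

focal <- ann$gene_id[match(c("Glipr1", "Clec12a", "Phlda3"), ann$symbol)]
for (g in c("young", "old")) {
  cc <- pairwise_correlation(expr, focal, gated[grp[gated] == g])
  dimnames(cc) <- rep(list(ann$symbol[match(focal, ann$gene_id)]), 2)
  write_correlation_tsv(cc, file.path(out, sprintf("correlation_%s.tsv", g)))
  message(g, "-group marker correlations:")
  message(paste(capture.output(print(round(cc[, ], 3))), collapse = "\n"))
}

panel <- read_gene_set(system.file("extdata", "senescence_panel.txt",
                                   package = "hepscreen"))
gs <- geneset_correlation(expr, focal, panel, gated[grp[gated] == "old"],
                          ann, high_r = 0.6)
gs$query_symbol <- ann$symbol[match(gs$query_gene, ann$gene_id)]
write.table(gs, file.path(out, "geneset_correlation_old.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("panel '", panel$name, "': ", length(panel$symbols), " genes, ",
        length(attr(gs, "not_measured")), " not measured (",
        paste(attr(gs, "not_measured"), collapse = ", "), ")")
message("high (r >= 0.6) marker-vs-panel pairs in old group: ",
        sum(gs$high), "/", nrow(gs))
message("mean marker-vs-panel r in old group: ",
        round(mean(gs$coefficient, na.rm = TRUE), 3))
message("tables under ", out)
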