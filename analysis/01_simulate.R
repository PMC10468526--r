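#!/usr/bin/env Rscript
# Generate the synthetic study: 255 young and 1251 old hepatocytes over
# 2000 genes, with a senescent subpopulation (2% of young cells, 35% of old)
# that co-expresses eight planted genes at 8-fold: three focal markers
# (named Glipr1, Clec12a, Phlda3 after the liver age-associated genes this
# screen is designed to find) and five senescence-panel members that the
# co-expression analysis in 04 interrogates.

suppressPackageStartupMessages(library(hepscreen))

seed <- 20230830L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  n_markers = 8L,
  marker_symbols = c("Glipr1", "Clec12a", "Phlda3",
                     "Ang", "C3", "Ctsb", "Igfbp1", "Cebpb"),
  seed = seed)

ann <- generate_annotation(cfg)
sim <- simulate_counts(cfg, ann)

write_count_matrix(sim$counts, out, ann)
write_annotation(ann, file.path(out, "annotation.tsv"))
write_sim_truth(sim$truth, file.path(out, "sim_truth.tsv"))
yaml::write_yaml(unclass(cfg), file.path(out, "sim_config.yaml"))

sen <- table(sim$truth$group, sim$truth$senescent)
message("simulated ", nrow(sim$counts), " cells x ", ncol(sim$counts),
        " genes (seed ", seed, ")")
message("senescent cells: young ", sen["young", "TRUE"], "/",
        sum(sen["young", ]), ", old ", sen["old", "TRUE"], "/",
        sum(sen["old", ]))
message("planted markers: ",
        paste(ann$symbol[match(cfg$marker_gene_ids, ann$gene_id)],
              collapse = ", "))
message("wrote count matrix triple, annotation and truth under ", out)
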