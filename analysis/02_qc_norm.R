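#!/usr/bin/env Rscript
# Quality control and normalization: drop cells detecting fewer than 200
# genes or exceeding 20% mitochondrial reads, compute per-cell RPKM, and
# gate on albumin (> 1 RPKM) to keep hepatocytes only.

suppressPackageStartupMessages(library(hepscreen))

data_dir <- "results/data"
out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_count_matrix(data_dir)
ann <- read_annotation(file.path(data_dir, "annotation.tsv"))
truth <- read_sim_truth(file.path(data_dir, "sim_truth.tsv"))
grp <- setNames(truth$group, truth$cell_id)

qc <- qc_filter(counts, ann, min_genes = 200L, max_mito = 0.20)
write.table(qc$report, file.path(out, "qc_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

expr <- compute_rpkm(qc$counts, ann)
gated <- gate_positive_cells(expr, ann, gate_symbol = "Alb",
                             threshold_rpkm = 1.0)
writeLines(gated, file.path(data_dir, "gated_cells.txt"))

stage <- function(cells) table(factor(grp[cells], c("young", "old")))
message("input cells:     young ", stage(rownames(counts))["young"],
        ", old ", stage(rownames(counts))["old"])
message("after QC:        young ", stage(rownames(qc$counts))["young"],
        ", old ", stage(rownames(qc$counts))["old"],
        "  (removed: ", paste(names(table(qc$report$reason[!qc$report$passed])),
                              table(qc$report$reason[!qc$report$passed]),
                              collapse = ", "), ")")
message("after Alb gate:  young ", stage(gated)["young"],
        ", old ", stage(gated)["old"])
message("QC report in ", file.path(out, "qc_report.tsv"),
        "; gated cell ids in ", file.path(data_dir, "gated_cells.txt"))
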