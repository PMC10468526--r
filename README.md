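# hepscreen

Screening hepatocyte single-cell RNA-seq for **age-associated genes** —
marker genes whose detection rate in liver cells rises with age and which
may identify senescent cells in aged tissue.

Senescent cells are thought to be almost absent from young tissue and to
accumulate with aging, but markers to find them in most organs are
unknown. If a gene is expressed preferentially in such cells, the
fraction of hepatocytes detectably expressing it should increase with
age. `hepscreen` turns that prediction into a screening pipeline for
young-vs-old single-cell count matrices:

1. **QC** — drop cells detecting fewer than 200 genes or with more than
   20% mitochondrial reads (strict inequalities: boundary cells are
   kept);
2. **Normalization** — per-cell RPKM,
   `RPKM(c,g) = count(c,g) × 10⁹ / (total(c) × length_bp(g))`;
3. **Gating** — keep hepatocytes, i.e. cells with albumin above 1 RPKM;
4. **Screen** — call a cell *positive* for a gene when RPKM > 1; compute
   the per-group positive-cell rate `p(g,a) = n_positive / n_cells`;
   rank genes by `Δ(g) = p(g,old) − p(g,young)` descending (ties broken
   by gene id); keep the top 43 candidates that have a mouse ortholog;
5. **Co-expression** — within-group Pearson correlation of candidates
   with each other and with a senescence gene set, with explicit
   undefined values (`"-"`) for genes with no expression in a group.

Because real screening data cannot ship with a package, `hepscreen`
includes a first-class simulator: negative-binomial counts over lognormal
library sizes and gene abundances, a mitochondrial block, an albumin-like
gate gene, and a planted senescent subpopulation (rare in young animals,
common in old) that co-expresses a configurable marker module. The
planted truth labels make the whole screen testable end to end.

## Worked example

A self-contained run at the scale the screen is designed for — 255 young
and 1251 old hepatocytes, 2000 genes, three markers planted at 8-fold in
a senescent subpopulation (2% of young cells, 35% of old):

```r
library(hepscreen)

cfg <- run_config(
  sim = sim_config(marker_symbols = c("Glipr1", "Clec12a", "Phlda3"),
                   seed = 42),
  outdir = "screen_run")
rep <- run_screen(cfg)

rep$cells
#> $input:     young 255, old 1251
#> $post_qc:   young 255, old 1251
#> $post_gate: young 255, old 1250

head(rep$candidates[, c("symbol", "rate_young", "rate_old", "delta", "rank")], 3)
#>    symbol rate_young rate_old     delta rank
#> 1  Glipr1  0.1803922   0.3920 0.2116078    1
#> 2 Clec12a  0.1843137   0.3776 0.1932863    2
#> 3  Phlda3  0.2627451   0.3888 0.1260549    3
```

All three planted markers head the
candidate list: their detection rate roughly doubles from young to old
because the senescent subpopulation pushes them over the 1-RPKM
threshold. `screen_run/` holds the QC report, the per-gene rate table,
the full ranking, the candidate list, per-group correlation matrices
(undefined coefficients rendered `-`), a JSON run report and the exact
configuration; the same config and seed reproduce every file byte for
byte.

The numbered scripts under `analysis/` run the same workflow as a
narrated sequence on a fixed simulated study, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R      # 255 + 1251 cells, 8 planted genes
Rscript analysis/02_qc_norm.R      # QC + RPKM + albumin gate
Rscript analysis/03_screen.R       # rates, ranking, top-43 candidates
Rscript analysis/04_coexpression.R # within-group marker / gene-set correlation
Rscript analysis/05_recovery.R     # recovery rate vs a fold-1 null
```

`03_screen.R` reports all 8 planted genes recovered at ranks 1–8 of 2000
(e.g. `C3: rate_young 0.204, rate_old 0.412, delta 0.209, rank 1`);
`05_recovery.R` tabulates a planted-marker recovery rate of 0.95 over 20
simulations against a null (fold 1) rate of 0.05 with chance expectation
0.024.

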