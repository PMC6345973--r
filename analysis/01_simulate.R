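#!/usr/bin/env Rscript
# Stage 1: generate every input the downstream analyses consume, with known
# ground truth, and write them as the standard on-disk formats (STAR-style
# SJ.out.tab junction tables, counts TSV + design CSV, GMT gene sets,
# survival CSV + expression TSV, combination-response CSV).

suppressPackageStartupMessages(library(xbp1flux))

seed <- 1L
data_dir <- "results/data"
dir.create(file.path(data_dir, "sj"), showWarnings = FALSE, recursive = TRUE)

# Study-scale defaults: 10,000 genes, 3 vs 3 per contrast, ~5e6 spliced reads
# per sample, 10x focal-junction depletion, 300-patient cohort with HR 3.
# Two gene sets receive true negative fold-change shifts so the enrichment
# stage has planted signal among 50 hallmark-scale sets.
cfg <- sim_config(seed = seed,
                  set_shift_map = c(UPR_LIKE = -0.8, SECRETION_LIKE = -0.5))

message("Simulating junction tables ...")
jx <- simulate_junctions(cfg)
for (nm in names(jx$tables))
  write_sj_tab(jx$tables[[nm]], file.path(data_dir, "sj", paste0(nm, ".SJ.out.tab")))
utils::write.csv(data.frame(sample = names(jx$design), group = unname(jx$design)),
                 file.path(data_dir, "sj_design.csv"), row.names = FALSE, quote = FALSE)

message("Simulating count matrices for both contrasts ...")
sim <- simulate_counts(cfg)
write_counts(sim$contrast1, file.path(data_dir, "counts_sixbp1.tsv"),
             file.path(data_dir, "design_sixbp1.csv"))
write_counts(sim$contrast2, file.path(data_dir, "counts_mkc.tsv"),
             file.path(data_dir, "design_mkc.csv"))
write_gmt(sim$gene_sets, file.path(data_dir, "gene_sets.gmt"))
write_results(sim$truth, file.path(data_dir, "truth_genes.tsv"))

message("Simulating the survival cohort ...")
sv <- simulate_survival(cfg)
write_survival(sv$cohort, file.path(data_dir, "cohort.csv"))
expr_df <- data.frame(gene = rownames(sv$cohort$expression),
                      sv$cohort$expression, check.names = FALSE)
utils::write.table(expr_df, file.path(data_dir, "cohort_expression.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message("Simulating combination responses ...")
combos <- simulate_combos(cfg)
utils::write.csv(combos[, c("label", "fa", "fb", "fc")],
                 file.path(data_dir, "combos.csv"), row.names = FALSE, quote = FALSE)

message(sprintf(
  "Done: %d junction tables, 2 x %d-gene count matrices, %d gene sets, %d patients, %d combos.",
  length(jx$tables), nrow(sim$contrast1$counts), length(sim$gene_sets),
  length(sv$cohort$sample_ids), nrow(combos)))
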