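#!/usr/bin/env Rscript
# Stage 4: how concordant are the two perturbations, and which gene sets
# shift? Quadrant counts of paired log2 fold changes, the exact binomial
# overlap test on the top-100 lists (universe = genes tested in both
# contrasts), and per-set enrichment by both the KS distribution-shift test
# and the Fisher's-exact variant on significantly down-regulated genes.

suppressPackageStartupMessages(library(xbp1flux))

de_dir <- "results/de"
out_dir <- "results/concordance"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

de_a <- read_results(file.path(de_dir, "de_sixbp1.tsv"))
de_b <- read_results(file.path(de_dir, "de_mkc.tsv"))
gene_sets <- read_gmt("results/data/gene_sets.gmt")

lfc_a <- setNames(de_a$log2_fold_change, de_a$gene)
lfc_b <- setNames(de_b$log2_fold_change, de_b$gene)

quad <- quadrant_concordance(lfc_a, lfc_b)
write_results(as.data.frame(quad), file.path(out_dir, "quadrants.tsv"))
message(sprintf(
  "Quadrants (down/down, down/up, up/down, up/up): %d, %d, %d, %d; r in down/down = %.3f.",
  quad$down_down, quad$down_up, quad$up_down, quad$up_up, quad$pearson_r_down_down))

universe <- length(intersect(de_a$gene, de_b$gene))
overlaps <- do.call(rbind, lapply(c("down", "up"), function(dir) {
  ta <- readLines(file.path(de_dir, sprintf("top100_%s_sixbp1.txt", dir)))
  tb <- readLines(file.path(de_dir, sprintf("top100_%s_mkc.txt", dir)))
  ov <- topn_overlap_test(ta, tb, universe)
  message(sprintf("Top-100 %s-regulated overlap: %d genes (universe %d), binomial p = %.3g.",
                  dir, ov$k, universe, ov$p_value))
  data.frame(direction = dir, k = ov$k, n = ov$n, universe = ov$universe,
             p_value = ov$p_value)
}))
write_results(overlaps, file.path(out_dir, "overlap.tsv"))

for (nm in c("sixbp1", "mkc")) {
  de <- if (nm == "sixbp1") de_a else de_b
  lfc <- setNames(de$log2_fold_change, de$gene)
  ks <- suppressWarnings(ks_set_enrichment(lfc, gene_sets))
  write_results(ks, file.path(out_dir, sprintf("enrichment_ks_%s.tsv", nm)))
  message(sprintf("%s: top KS-enriched set %s (D = %.2f, p = %.2g, direction %d).",
                  nm, ks$set[1], ks$ks_D[1], ks$p_value[1], ks$direction[1]))
  sel <- select_significant(de, direction = "down")
  if (length(sel) > 0) {
    fe <- fisher_set_enrichment(sel, gene_sets, de$gene, min_set_size = 15)
    write_results(fe, file.path(out_dir, sprintf("enrichment_fisher_%s.tsv", nm)))
  }
}
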