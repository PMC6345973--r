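#!/usr/bin/env Rscript
# Stage 3: simplified NB differential expression for both contrasts.
# Genes must exceed 5 counts in at least one sample of each group; depth is
# normalized by median-of-ratios size factors; per-gene NB Wald tests with
# BH adjustment; top-100 down/up lists saved for the concordance stage.

suppressPackageStartupMessages(library(xbp1flux))

data_dir <- "results/data"
out_dir <- "results/de"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

contrasts <- list(
  sixbp1 = list(counts = "counts_sixbp1.tsv", design = "design_sixbp1.csv",
                reference = "siCtrl"),
  mkc = list(counts = "counts_mkc.tsv", design = "design_mkc.csv",
             reference = "vehicle"))

for (nm in names(contrasts)) {
  cc <- contrasts[[nm]]
  m <- read_counts(file.path(data_dir, cc$counts), file.path(data_dir, cc$design))
  f <- filter_genes(m)
  sf <- size_factors(f)
  res <- nb_wald_de(f, sf, reference_group = cc$reference)
  write_results(res, file.path(out_dir, paste0("de_", nm, ".tsv")))
  for (dir in c("down", "up"))
    writeLines(top_n(res, 100, dir), file.path(out_dir, sprintf("top100_%s_%s.txt", dir, nm)))
  message(sprintf(
    "%s: %d/%d genes pass the filter; %d down / %d up at adjusted p < 0.05; size factors %s.",
    nm, nrow(f$counts), nrow(m$counts),
    length(select_significant(res, direction = "down")),
    length(select_significant(res, direction = "up")),
    paste(sprintf("%.3f", sf), collapse = ", ")))
}
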