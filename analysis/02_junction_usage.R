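#!/usr/bin/env Rscript
# Stage 2: quantify the spliced-isoform abundance of the focal XBP1s junction
# (unique spliced reads per million total spliced reads) in every sample and
# test for differential usage between treated and control with the NB GLM
# (depth covariate: log10 total spliced reads).

suppressPackageStartupMessages(library(xbp1flux))

data_dir <- "results/data"
out_dir <- "results/junction"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

files <- list.files(file.path(data_dir, "sj"), full.names = TRUE)
tables <- lapply(files, function(f) read_sj_tab(f, sub("\\.SJ\\.out\\.tab$", "", basename(f))))
design_df <- utils::read.csv(file.path(data_dir, "sj_design.csv"))
design <- setNames(design_df$group, design_df$sample)

usage <- focal_usage_table(tables, xbp1s_junction())
write_results(usage, file.path(out_dir, "usage.tsv"))
message("Per-sample XBP1s junction usage (reads per million spliced reads):")
print(usage, row.names = FALSE)

fit <- differential_junction_usage(usage, design, reference_group = "control")
write_results(data.frame(group_coefficient = fit$group_coefficient,
                         standard_error = fit$standard_error,
                         wald_statistic = fit$wald_statistic,
                         p_value = fit$p_value,
                         dispersion = fit$dispersion,
                         library_covariate_coefficient = fit$library_covariate_coefficient),
              file.path(out_dir, "nbglm.tsv"))
message(sprintf(
  "Treated vs control: log fold change %.3f (fold %.2fx, SE %.3f), Wald p = %.3g.",
  fit$group_coefficient, exp(fit$group_coefficient), fit$standard_error, fit$p_value))
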