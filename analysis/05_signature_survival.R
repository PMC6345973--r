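#!/usr/bin/env Rscript
# Stage 5: signature activity and prognosis. Quantile-normalize the cohort
# expression, score each sample with the five-gene signature (mean per-gene
# z-score), correlate it with a second signature score, compare a target
# gene's expression across the score-stratified halves, and stratify
# disease-free survival at the median score (Kaplan-Meier + log-rank).

suppressPackageStartupMessages(library(xbp1flux))

data_dir <- "results/data"
out_dir <- "results/survival"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cohort <- read_survival(file.path(data_dir, "cohort.csv"),
                        file.path(data_dir, "cohort_expression.tsv"))
cohort$expression <- quantile_normalize(cohort$expression)

score <- signature_score(cohort$expression, xbp1_five_gene_signature())
write_results(data.frame(sample = names(score), score = unname(score)),
              file.path(out_dir, "signature_scores.tsv"))

# a second, partially overlapping score behaves like a correlated pathway
other <- signature_score(cohort$expression,
                         c("ANLN", "RRM2", rownames(cohort$expression)[6:9]))
cc <- score_correlation(score, other)
message(sprintf("Score-score correlation: r = %.3f (p = %.2g, n = %d).",
                cc$r, cc$p_value, cc$n))

tt <- stratified_expression_test(cohort$expression, score, "UBAC2")
write_results(tt, file.path(out_dir, "stratified_t.tsv"))
message(sprintf("UBAC2 across score halves: t = %.2f, p = %.2g.",
                tt$t_statistic, tt$p_value))

strat <- prognostic_stratification(cohort)
km_df <- do.call(rbind, lapply(c("high", "low"), function(g) {
  km <- strat[[paste0("km_", g)]]
  data.frame(group = g, time = km$time, n_risk = km$n_risk,
             n_event = km$n_event, survival = km$survival)
}))
write_results(km_df, file.path(out_dir, "km_curves.tsv"))
write_results(data.frame(chi_square = strat$logrank$chi_square,
                         p_value = strat$logrank$p_value),
              file.path(out_dir, "logrank.tsv"))
message(sprintf(
  "Median-split survival: %d high vs %d low; log-rank chi-square = %.1f, p = %.3g.",
  sum(strat$group == "high"), sum(strat$group == "low"),
  strat$logrank$chi_square, strat$logrank$p_value))
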