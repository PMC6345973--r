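# End-to-end orchestration: simulate (or load) inputs, run every stage in the
# analysis order (junction usage -> differential expression -> concordance and
# overlap -> set enrichment -> signature survival -> synergy), and write one
# TSV per stage plus a machine-parsable log and a config snapshot.

#' Pipeline configuration
#'
#' Validates thresholds and mode switches at construction; the universe for
#' the overlap/Fisher tests must be stated explicitly, either as an integer or
#' as `"filtered_intersection"` (genes passing the DE filter in both
#' contrasts) — it is never defaulted silently.
#'
#' @param seed integer seed driving every random component.
#' @param universe `"filtered_intersection"` or a positive integer; required
#'   while the overlap stage is enabled.
#' @param top_n top-list length for the overlap test.
#' @param min_set_size minimum tested members per gene set.
#' @param alpha adjusted-p cutoff for the Fisher selection rule.
#' @param enrichment_method `"ks"`, `"fisher"` or `"both"`.
#' @param synergy_mode `"literal"` (the Fa*(1-Fb) rule) or `"bliss"`.
#' @param filter_per_group filter interpretation (see [filter_genes()]).
#' @param run_overlap enable the top-list overlap stage.
#' @param sim arguments forwarded to [sim_config()] (seed is injected).
#' @return Validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, universe = NULL,
                            top_n = 100, min_set_size = 15, alpha = 0.05,
                            enrichment_method = c("both", "ks", "fisher"),
                            synergy_mode = c("literal", "bliss"),
                            filter_per_group = TRUE,
                            run_overlap = TRUE,
                            sim = list()) {
  enrichment_method <- match.arg(enrichment_method)
  synergy_mode <- match.arg(synergy_mode)
  if (top_n < 1 || min_set_size < 1) .stopf("top_n and min_set_size must be >= 1")
  if (alpha <= 0 || alpha >= 1) .stopf("alpha must be in (0, 1)")
  if (run_overlap) {
    ok <- identical(universe, "filtered_intersection") ||
      (is.numeric(universe) && length(universe) == 1 && universe > top_n)
    if (!ok)
      .stopf(paste("universe must be set explicitly ('filtered_intersection'",
                   "or an integer > top_n) while the overlap stage is enabled"))
  }
  structure(list(seed = as.integer(seed), universe = universe, top_n = top_n,
                 min_set_size = min_set_size, alpha = alpha,
                 enrichment_method = enrichment_method,
                 synergy_mode = synergy_mode,
                 filter_per_group = filter_per_group,
                 run_overlap = run_overlap, sim = sim),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return Validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.log_line <- function(con, stage, ...) {
  kv <- list(...)
  msg <- paste(sprintf("%s=%s", names(kv), vapply(kv, format, character(1))),
               collapse = " ")
  writeLines(sprintf("%s stage=%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     stage, msg), con)
}

#' Run the full synthetic pipeline
#'
#' Generates every input from the config's seed, runs all stages in order,
#' and writes the result tables, a run log and a YAML config snapshot into
#' `out_dir`. Outputs are deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with every stage's in-memory result and the
#'   output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  .log_line(log_con, "config", seed = config$seed,
            universe = paste(config$universe, collapse = ""),
            top_n = config$top_n, enrichment = config$enrichment_method,
            synergy_mode = config$synergy_mode)

  cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))

  # Stage 1: junction usage and differential usage of the focal junction.
  jx <- simulate_junctions(cfg)
  usage <- focal_usage_table(jx$tables)
  glm_res <- differential_junction_usage(usage, jx$design, reference_group = "control")
  usage_path <- file.path(out_dir, "junction_usage.tsv")
  write_results(usage, usage_path)
  glm_df <- data.frame(group_coefficient = glm_res$group_coefficient,
                       standard_error = glm_res$standard_error,
                       wald_statistic = glm_res$wald_statistic,
                       p_value = glm_res$p_value,
                       dispersion = glm_res$dispersion,
                       library_covariate_coefficient = glm_res$library_covariate_coefficient)
  write_results(glm_df, file.path(out_dir, "junction_glm.tsv"))
  .log_line(log_con, "junction", n_samples = nrow(usage),
            coefficient = glm_res$group_coefficient, p = glm_res$p_value)

  # Stage 2: differential expression, both contrasts.
  sim <- simulate_counts(cfg)
  de <- lapply(list(contrast1 = list(m = sim$contrast1, ref = "siCtrl"),
                    contrast2 = list(m = sim$contrast2, ref = "vehicle")),
               function(x) {
                 f <- filter_genes(x$m, per_group = config$filter_per_group)
                 nb_wald_de(f, reference_group = x$ref)
               })
  write_results(de$contrast1, file.path(out_dir, "de_contrast1.tsv"))
  write_results(de$contrast2, file.path(out_dir, "de_contrast2.tsv"))
  .log_line(log_con, "diffexpr", n_tested_1 = nrow(de$contrast1),
            n_tested_2 = nrow(de$contrast2))

  # Stage 3: concordance and top-list overlap.
  lfc1 <- setNames(de$contrast1$log2_fold_change, de$contrast1$gene)
  lfc2 <- setNames(de$contrast2$log2_fold_change, de$contrast2$gene)
  quad <- quadrant_concordance(lfc1, lfc2)
  conc <- data.frame(down_down = quad$down_down, down_up = quad$down_up,
                     up_down = quad$up_down, up_up = quad$up_up,
                     pearson_r_down_down = quad$pearson_r_down_down)
  overlap_rows <- NULL
  if (config$run_overlap) {
    shared <- intersect(de$contrast1$gene, de$contrast2$gene)
    universe <- if (identical(config$universe, "filtered_intersection"))
      length(shared) else config$universe
    overlap_rows <- do.call(rbind, lapply(c("down", "up"), function(dir) {
      ta <- top_n(de$contrast1, config$top_n, dir)
      tb <- top_n(de$contrast2, config$top_n, dir)
      ov <- topn_overlap_test(ta, tb, universe)
      data.frame(direction = dir, k = ov$k, n = ov$n, universe = ov$universe,
                 p_value = ov$p_value, stringsAsFactors = FALSE)
    }))
    write_results(overlap_rows, file.path(out_dir, "overlap.tsv"))
    .log_line(log_con, "overlap", universe = universe,
              k_down = overlap_rows$k[1], p_down = overlap_rows$p_value[1])
  }
  write_results(conc, file.path(out_dir, "concordance.tsv"))

  # Stage 4: gene-set enrichment on each contrast's fold changes.
  enr_ks <- enr_fisher <- NULL
  if (config$enrichment_method %in% c("ks", "both")) {
    enr_ks <- do.call(rbind, lapply(names(de), function(nm) {
      lfc <- setNames(de[[nm]]$log2_fold_change, de[[nm]]$gene)
      r <- suppressWarnings(ks_set_enrichment(lfc, sim$gene_sets, config$min_set_size))
      cbind(contrast = nm, r)
    }))
    write_results(enr_ks, file.path(out_dir, "enrichment_ks.tsv"))
  }
  if (config$enrichment_method %in% c("fisher", "both")) {
    enr_fisher <- do.call(rbind, lapply(names(de), function(nm) {
      sel <- select_significant(de[[nm]], alpha = config$alpha, direction = "down")
      if (length(sel) == 0) return(NULL)
      r <- fisher_set_enrichment(sel, sim$gene_sets, de[[nm]]$gene,
                                 min_set_size = config$min_set_size)
      cbind(contrast = nm, r)
    }))
    if (!is.null(enr_fisher))
      write_results(enr_fisher, file.path(out_dir, "enrichment_fisher.tsv"))
  }
  .log_line(log_con, "enrichment", method = config$enrichment_method)

  # Stage 5: signature scoring and survival stratification.
  sv <- simulate_survival(cfg)
  strat <- prognostic_stratification(sv$cohort)
  km_df <- do.call(rbind, lapply(c("high", "low"), function(g) {
    km <- strat[[paste0("km_", g)]]
    data.frame(group = g, time = km$time, n_risk = km$n_risk,
               n_event = km$n_event, survival = km$survival,
               stringsAsFactors = FALSE)
  }))
  write_results(km_df, file.path(out_dir, "km_curves.tsv"))
  write_results(data.frame(chi_square = strat$logrank$chi_square,
                           p_value = strat$logrank$p_value),
                file.path(out_dir, "logrank.tsv"))
  .log_line(log_con, "survival", n = length(sv$cohort$sample_ids),
            logrank_p = strat$logrank$p_value)

  # Stage 6: synergy classification.
  combos <- simulate_combos(cfg)
  syn <- cbind(label = combos$label,
               is_synergistic(combos$fa, combos$fb, combos$fc, config$synergy_mode))
  write_results(syn, file.path(out_dir, "synergy.tsv"))
  .log_line(log_con, "synergy", mode = config$synergy_mode,
            n_synergistic = sum(syn$synergistic))

  invisible(list(usage = usage, junction_glm = glm_res, de = de,
                 concordance = quad, overlap = overlap_rows,
                 enrichment_ks = enr_ks, enrichment_fisher = enr_fisher,
                 survival = strat, synergy = syn, out_dir = out_dir))
}
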