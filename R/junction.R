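# Spliced-isoform quantification from splice-junction tables. The focal
# junction defaults to the XBP1s-defining intron excised by IRE1-alpha
# (chr22:28,796,122-28,796,147, hg38): reads spanning it identify the spliced
# XBP1 isoform uniquely.

#' The XBP1s-defining splice junction (hg38)
#'
#' 26-nt intron on chr22 removed by IRE1-alpha during unconventional XBP1
#' splicing; spliced reads spanning it measure XBP1s abundance.
#'
#' @return A `focal_junction` list.
#' @export
xbp1s_junction <- function() focal_junction("chr22", 28796122L, 28796147L, "+")

#' Define a focal splice junction
#'
#' @param chrom chromosome name.
#' @param intron_start,intron_end 1-based inclusive intron bounds.
#' @param strand "+", "-" or "unknown".
#' @return A `focal_junction` list.
#' @export
focal_junction <- function(chrom, intron_start, intron_end, strand = "unknown") {
  if (intron_start < 1 || intron_end < intron_start)
    .stopf("need 1 <= intron_start <= intron_end")
  if (!strand %in% c("+", "-", "unknown"))
    .stopf("strand must be '+', '-' or 'unknown'")
  structure(list(chrom = as.character(chrom),
                 intron_start = as.integer(intron_start),
                 intron_end = as.integer(intron_end),
                 strand = strand),
            class = "focal_junction")
}

#' Parse a focal junction from "chrom:start-end[:strand]" notation
#' @param spec string such as `"chr22:28796122-28796147:+"`.
#' @return A [focal_junction()].
#' @export
parse_focal_junction <- function(spec) {
  m <- regmatches(spec, regexec("^([^:]+):([0-9]+)-([0-9]+)(?::([+-]))?$", spec))[[1]]
  if (length(m) == 0) .stopf("cannot parse focal junction '%s'", spec)
  strand <- if (nzchar(m[5])) m[5] else "unknown"
  focal_junction(m[2], as.integer(m[3]), as.integer(m[4]), strand)
}

#' Total unique spliced reads in a junction table
#'
#' The library-depth denominator of the spliced-isoform ratio: the sum of
#' unique-mapping spliced reads over all junctions.
#'
#' @param table a [junction_table()].
#' @return Non-negative integer (0 for an empty table).
#' @export
total_spliced_reads <- function(table) {
  stopifnot(inherits(table, "junction_table"))
  sum(table$unique_reads)
}

#' Focal-junction usage per million total spliced reads
#'
#' The relative abundance of the spliced isoform: unique spliced reads
#' supporting the focal junction divided by total unique spliced reads, times
#' 1e6. A focal junction absent from the table contributes 0 reads. A table
#' whose strand code is 0 (unknown) matches any query strand, and a query
#' strand of "unknown" matches any table strand.
#'
#' @param table a [junction_table()].
#' @param focal a [focal_junction()].
#' @return list with `sample_id`, `focal_reads`, `total_spliced_reads`,
#'   `ratio_per_million`.
#' @export
focal_usage <- function(table, focal = xbp1s_junction()) {
  stopifnot(inherits(table, "junction_table"), inherits(focal, "focal_junction"))
  total <- total_spliced_reads(table)
  hit <- table$chrom == focal$chrom &
    table$intron_start == focal$intron_start &
    table$intron_end == focal$intron_end
  if (focal$strand != "unknown") {
    code <- .strand_codes[[focal$strand]]
    hit <- hit & (table$strand == code | table$strand == 0L)
  }
  focal_reads <- sum(table$unique_reads[hit])
  if (total == 0) {
    if (any(hit) || focal_reads > 0)
      .stopf("undefined ratio: total spliced reads is zero")
    ratio <- 0
  } else {
    ratio <- focal_reads / total * 1e6
  }
  list(sample_id = attr(table, "sample_id"),
       focal_reads = focal_reads,
       total_spliced_reads = total,
       ratio_per_million = ratio)
}

#' Tabulate focal usage over a set of junction tables
#' @param tables list of [junction_table()]s.
#' @param focal a [focal_junction()].
#' @return data.frame with one row per sample.
#' @export
focal_usage_table <- function(tables, focal = xbp1s_junction()) {
  rows <- lapply(tables, focal_usage, focal = focal)
  data.frame(sample = vapply(rows, `[[`, character(1), "sample_id"),
             focal_reads = vapply(rows, `[[`, numeric(1), "focal_reads"),
             total_spliced_reads = vapply(rows, `[[`, numeric(1), "total_spliced_reads"),
             ratio_per_million = vapply(rows, `[[`, numeric(1), "ratio_per_million"),
             stringsAsFactors = FALSE)
}

#' Differential focal-junction usage between two groups (NB GLM)
#'
#' Fits a negative binomial GLM with log link to the per-sample focal read
#' counts with an intercept, a treatment indicator, and a library-depth
#' covariate (log10 of total spliced reads by default; set
#' `depth_scale = "raw"` for the untransformed total). Dispersion is profiled
#' by maximum likelihood with a method-of-moments fallback. The group effect
#' is tested two-sided by Wald on the normal reference.
#'
#' @param usage data.frame from [focal_usage_table()] (columns `sample`,
#'   `focal_reads`, `total_spliced_reads`).
#' @param design named character vector sample -> group label (exactly two
#'   groups, each with >= 2 samples).
#' @param reference_group group taken as baseline; the coefficient is the log
#'   fold change of the other (treatment) group relative to it.
#' @param depth_scale `"log10"` (default) or `"raw"` scale for the depth
#'   covariate.
#' @return list with `group_coefficient` (natural-log scale), `standard_error`,
#'   `wald_statistic`, `p_value`, `dispersion`,
#'   `library_covariate_coefficient`, `treatment_group`, `reference_group`.
#' @export
differential_junction_usage <- function(usage, design, reference_group,
                                        depth_scale = c("log10", "raw")) {
  depth_scale <- match.arg(depth_scale)
  absent <- setdiff(usage$sample, names(design))
  if (length(absent) > 0)
    .stopf("sample(s) missing from design: %s", paste(absent, collapse = ", "))
  groups <- design[usage$sample]
  lv <- unique(groups)
  if (length(lv) != 2) .stopf("need exactly two groups, got %d", length(lv))
  if (!reference_group %in% lv)
    .stopf("reference group '%s' not among groups %s", reference_group,
           paste(lv, collapse = ", "))
  treatment <- setdiff(lv, reference_group)
  if (min(table(groups)) < 2) .stopf("need >= 2 samples per group")
  y <- usage$focal_reads
  if (any(y != round(y))) .stopf("focal counts must be integers")
  if (all(y == 0)) .stopf("degenerate fit: focal counts are zero in both groups")
  depth <- if (depth_scale == "log10") log10(usage$total_spliced_reads)
           else usage$total_spliced_reads
  X <- cbind(intercept = 1, group = as.numeric(groups == treatment), depth = depth)
  # A constant depth covariate is collinear with the intercept; drop it.
  depth_used <- stats::sd(depth) > 0
  if (!depth_used) X <- X[, c("intercept", "group"), drop = FALSE]
  fit <- fit_nb_glm(y, X)
  est <- fit$coefficients[["group"]]
  se <- fit$se[["group"]]
  if (!is.finite(se) || se <= 0) .stopf("degenerate fit: non-positive standard error")
  list(group_coefficient = est,
       standard_error = se,
       wald_statistic = est / se,
       p_value = .wald_p(est, se),
       dispersion = fit$dispersion,
       library_covariate_coefficient = if (depth_used) fit$coefficients[["depth"]] else NA_real_,
       treatment_group = treatment,
       reference_group = reference_group)
}
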