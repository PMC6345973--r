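# Signature-activity scoring across cohorts and survival stratification.
# Scores are per-sample means of per-gene z-scores; cohorts are quantile
# normalized before cross-cohort comparison; the prognostic split is at the
# cohort median score with Kaplan-Meier curves and a log-rank test (via the
# survival package).

#' The five-gene XBP1 prognostic signature
#'
#' Five IRE1-alpha/XBP1s-regulated genes used as a disease-free-survival
#' signature in prostate cancer cohorts.
#'
#' @return Character vector of gene symbols.
#' @export
xbp1_five_gene_signature <- function() {
  c("ANLN", "CSNK1G3", "RRM2", "SLC35A2", "UBAC2")
}

#' Quantile normalization of an expression matrix
#'
#' Forces every column (sample) to the same distribution: the reference is the
#' across-column mean of the sorted values at each rank; each value is
#' replaced by the reference value at its within-column rank. Ties within a
#' column receive the mean of the reference values their ranks span.
#'
#' @param expr genes x samples numeric matrix with no missing values.
#' @return Matrix of the same shape; a single-column matrix is returned
#'   unchanged with a warning.
#' @export
quantile_normalize <- function(expr) {
  expr <- as.matrix(expr)
  if (any(!is.finite(expr))) .stopf("expression matrix must have no missing values")
  if (ncol(expr) < 2) {
    warning("single-column matrix: quantile normalization is a no-op", call. = FALSE)
    return(expr)
  }
  ref <- rowMeans(apply(expr, 2, sort))
  cref <- c(0, cumsum(ref))
  out <- apply(expr, 2, function(x) {
    lo <- rank(x, ties.method = "min")
    hi <- rank(x, ties.method = "max")
    (cref[hi + 1] - cref[lo]) / (hi - lo + 1)
  })
  dimnames(out) <- dimnames(expr)
  out
}

#' Signature activity score (mean per-gene z-score)
#'
#' Each signature gene's expression is centered and scaled across the
#' cohort's samples; a sample's score is the mean of those z-scores over the
#' signature genes present. Zero-variance genes are dropped with a warning;
#' signature genes absent from the matrix are reported in a warning.
#' `method = "rank"` uses within-gene ranks scaled to [0, 1] and centered,
#' instead of z-scores.
#'
#' @param expr genes x samples matrix with gene rownames.
#' @param signature character vector of signature genes.
#' @param method `"zscore"` (default) or `"rank"`.
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(expr, signature, method = c("zscore", "rank")) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  signature <- unique(as.character(signature))
  present <- intersect(signature, rownames(expr))
  if (length(present) == 0) .stopf("no signature gene present in the expression matrix")
  absent <- setdiff(signature, present)
  if (length(absent) > 0)
    warning(sprintf("%d signature gene(s) absent from expression: %s",
                    length(absent), paste(absent, collapse = ", ")), call. = FALSE)
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance signature gene(s)", sum(sds == 0)),
            call. = FALSE)
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) == 0) .stopf("all present signature genes have zero variance")
  }
  z <- if (method == "zscore") {
    t(scale(t(sub)))
  } else {
    t(apply(sub, 1, function(x) (rank(x) - 0.5) / length(x) - 0.5))
  }
  colMeans(z)
}

#' Pearson correlation between two signature scores
#'
#' @param score_a,score_b named per-sample score vectors; only shared samples
#'   (>= 3 required) enter the test.
#' @return list with `r`, `p_value`, `n`.
#' @export
score_correlation <- function(score_a, score_b) {
  if (is.null(names(score_a)) || is.null(names(score_b)))
    .stopf("scores must be named by sample")
  shared <- intersect(names(score_a), names(score_b))
  if (length(shared) < 3) .stopf("need >= 3 shared samples, got %d", length(shared))
  a <- score_a[shared]; b <- score_b[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    .stopf("correlation undefined: constant score vector")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(shared))
}

#' Split samples at the median of a score (ties to the low group)
#' @param score named numeric vector.
#' @return Named factor with levels `low`, `high`.
#' @export
median_split <- function(score) {
  med <- stats::median(score)
  factor(ifelse(score > med, "high", "low"), levels = c("low", "high"))
}

#' Per-gene expression comparison between score-stratified groups
#'
#' Samples are split at the median of `stratifying_score` (ties to the low
#' group); each queried gene is compared between the high and low groups by a
#' two-sided Welch t-test. A gene with zero variance in both groups is
#' degenerate and reported with `p_value = 1` and `degenerate = TRUE`.
#'
#' @param expr genes x samples matrix.
#' @param stratifying_score named per-sample score (e.g. AR activity).
#' @param genes genes to test.
#' @return data.frame with `gene`, `mean_low`, `mean_high`, `t_statistic`,
#'   `p_value`, `degenerate`.
#' @export
stratified_expression_test <- function(expr, stratifying_score, genes) {
  expr <- as.matrix(expr)
  if (is.null(names(stratifying_score))) .stopf("stratifying score must be named")
  samples <- intersect(colnames(expr), names(stratifying_score))
  grp <- median_split(stratifying_score[samples])
  if (min(table(grp)) < 2) .stopf("median split leaves a group with < 2 samples")
  absent <- setdiff(genes, rownames(expr))
  if (length(absent) > 0)
    .stopf("gene(s) absent from expression: %s", paste(absent, collapse = ", "))
  rows <- lapply(genes, function(g) {
    lo <- expr[g, samples[grp == "low"]]
    hi <- expr[g, samples[grp == "high"]]
    if (stats::sd(lo) == 0 && stats::sd(hi) == 0) {
      return(data.frame(gene = g, mean_low = mean(lo), mean_high = mean(hi),
                        t_statistic = 0, p_value = 1, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(hi, lo)
    data.frame(gene = g, mean_low = mean(lo), mean_high = mean(hi),
               t_statistic = unname(tt$statistic), p_value = tt$p.value,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' At tied times, events are processed before censorings (the standard
#' product-limit convention).
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 event, 0 censored).
#' @return list of class `km_curve` with `time` (ascending distinct observed
#'   times), `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) .stopf("empty survival input")
  if (any(times < 0)) .stopf("times must be non-negative")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, survival = fit$surv),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: %d time points, final survival %.3f\n",
              length(x$time), x$survival[length(x$survival)]))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square over the pooled event times.
#'
#' @param times_a,events_a group A follow-up and event indicators.
#' @param times_b,events_b group B follow-up and event indicators.
#' @return list with `chi_square`, `p_value`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0) .stopf("both groups must be non-empty")
  if (sum(events_a) + sum(events_b) == 0)
    .stopf("no events in either group: log-rank undefined")
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  group <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chi_square = unname(sd_$chisq),
       p_value = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Prognostic stratification of a cohort by a gene signature
#'
#' Scores every sample with [signature_score()], splits the cohort at the
#' median score (ties to low), and compares the two Kaplan-Meier curves with a
#' log-rank test.
#'
#' @param cohort a [survival_cohort()] carrying an expression matrix.
#' @param signature character vector of signature genes (default the
#'   five-gene XBP1 signature).
#' @return list with `score`, `group`, `km_high`, `km_low`, `logrank`.
#' @export
prognostic_stratification <- function(cohort, signature = xbp1_five_gene_signature()) {
  stopifnot(inherits(cohort, "survival_cohort"))
  if (is.null(cohort$expression)) .stopf("cohort carries no expression matrix")
  score <- signature_score(cohort$expression, signature)
  grp <- median_split(score)
  hi <- grp == "high"
  list(score = score, group = grp,
       km_high = km_estimate(cohort$time[hi], cohort$event[hi]),
       km_low = km_estimate(cohort$time[!hi], cohort$event[!hi]),
       logrank = logrank_test(cohort$time[hi], cohort$event[hi],
                              cohort$time[!hi], cohort$event[!hi]))
}
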