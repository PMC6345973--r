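# Simplified negative-binomial differential expression: median-of-ratios depth
# normalization, per-gene NB Wald tests with ML dispersion (no shrinkage, no
# outlier or independent filtering), BH adjustment. Deliberately lighter than
# DESeq2: the aim is the distributional behaviour of the test, not numerical
# identity with DESeq2 output.

#' Filter genes by the minimum-count rule
#'
#' Keeps a gene only if, in each of the two groups, at least one sample has a
#' count strictly greater than `threshold` (default 5). Set
#' `per_group = FALSE` for the looser reading in which a single qualifying
#' sample anywhere suffices.
#'
#' @param m a [count_matrix()] with exactly two groups.
#' @param threshold strict lower bound on the qualifying count.
#' @param per_group require a qualifying sample in each group (default) or
#'   anywhere.
#' @return Filtered [count_matrix()].
#' @export
filter_genes <- function(m, threshold = 5, per_group = TRUE) {
  stopifnot(inherits(m, "count_matrix"))
  lv <- unique(m$design)
  if (length(lv) != 2) .stopf("unsupported design: need exactly 2 groups, got %d", length(lv))
  if (per_group) {
    keep <- Reduce(`&`, lapply(lv, function(g) {
      cols <- names(m$design)[m$design == g]
      apply(m$counts[, cols, drop = FALSE] > threshold, 1, any)
    }))
  } else {
    keep <- apply(m$counts > threshold, 1, any)
  }
  count_matrix(m$counts[keep, , drop = FALSE], m$design)
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors: each gene with all-positive counts
#' contributes its count divided by its geometric mean across samples; a
#' sample's factor is the median of those ratios, then the factors are rescaled
#' to unit geometric mean.
#'
#' @param m a [count_matrix()].
#' @return Named numeric vector of positive factors (geometric mean 1).
#' @export
size_factors <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  cm <- m$counts
  pos <- rowSums(cm == 0) == 0
  if (!any(pos))
    .stopf(paste("no gene has all-positive counts; cannot form the reference",
                 "(consider a pseudo-reference fallback on a deeper matrix)"))
  logg <- rowMeans(log(cm[pos, , drop = FALSE]))
  sf <- apply(cm[pos, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - logg))
  })
  sf <- sf / exp(mean(log(sf)))
  sf
}

# One gene's NB Wald contrast: y ~ intercept + group, offset log(sf).
.de_one_gene <- function(y, group_ind, log_sf) {
  X <- cbind(intercept = 1, group = group_ind)
  fit <- tryCatch(fit_nb_glm(y, X, offset = log_sf), error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$se[["group"]]) || fit$se[["group"]] <= 0)
    return(c(coef = NA_real_, se = NA_real_, p = NA_real_, disp = NA_real_))
  c(coef = fit$coefficients[["group"]], se = fit$se[["group"]],
    p = .wald_p(fit$coefficients[["group"]], fit$se[["group"]]),
    disp = fit$dispersion)
}

#' Per-gene negative binomial Wald differential expression
#'
#' For each gene, fits `log E[count] = intercept + beta * treatment +
#' log(size factor)` with per-gene ML dispersion and tests `beta` two-sided by
#' Wald. `log2_fold_change = beta / ln 2` (treatment relative to reference).
#' P-values are BH-adjusted over the genes that converged; non-converging
#' genes carry `NA` p-values and are excluded from the BH family.
#'
#' @param m a filtered [count_matrix()] with two groups.
#' @param sf size factors from [size_factors()] (computed from `m` when
#'   omitted).
#' @param reference_group baseline group label.
#' @return data.frame with columns `gene`, `base_mean` (mean normalized
#'   count), `log2_fold_change`, `p_value`, `adj_p_value`, `rank` (ascending
#'   p, NAs last), `dispersion`, `converged`.
#' @export
nb_wald_de <- function(m, sf = NULL, reference_group) {
  stopifnot(inherits(m, "count_matrix"))
  lv <- unique(m$design)
  if (length(lv) != 2) .stopf("need exactly 2 groups")
  if (!reference_group %in% lv) .stopf("reference group '%s' not in design", reference_group)
  treatment <- setdiff(lv, reference_group)
  if (is.null(sf)) sf <- size_factors(m)
  sf <- sf[colnames(m$counts)]
  group_ind <- as.numeric(m$design == treatment)
  log_sf <- log(sf)
  norm_counts <- sweep(m$counts, 2, sf, `/`)
  res <- t(apply(m$counts, 1, .de_one_gene, group_ind = group_ind, log_sf = log_sf))
  p <- res[, "p"]
  padj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  padj[ok] <- stats::p.adjust(p[ok], method = "BH")
  out <- data.frame(gene = rownames(m$counts),
                    base_mean = rowMeans(norm_counts),
                    log2_fold_change = res[, "coef"] / log(2),
                    p_value = p,
                    adj_p_value = padj,
                    dispersion = res[, "disp"],
                    converged = ok,
                    stringsAsFactors = FALSE)
  out$rank <- rank(out$p_value, ties.method = "first", na.last = "keep")
  n_ok <- sum(ok)
  if (any(!ok))
    out$rank[!ok] <- n_ok + seq_len(sum(!ok))
  rownames(out) <- NULL
  out
}

#' Top-n genes by p-value in one direction
#'
#' Selects genes whose fold change has the requested sign, sorted by ascending
#' p-value; ties broken by larger absolute log2 fold change, then gene id.
#'
#' @param res data.frame from [nb_wald_de()].
#' @param n list length.
#' @param direction `"down"` (log2FC < 0) or `"up"` (log2FC > 0).
#' @return Character vector of gene ids (shorter than `n`, with a warning, if
#'   fewer genes qualify).
#' @export
top_n <- function(res, n, direction = c("down", "up")) {
  direction <- match.arg(direction)
  ok <- !is.na(res$p_value) &
    if (direction == "down") res$log2_fold_change < 0 else res$log2_fold_change > 0
  sub <- res[ok, , drop = FALSE]
  ord <- order(sub$p_value, -abs(sub$log2_fold_change), sub$gene)
  sub <- sub[ord, , drop = FALSE]
  if (nrow(sub) < n) {
    warning(sprintf("only %d %s-regulated genes available (asked for %d)",
                    nrow(sub), direction, n), call. = FALSE)
    return(sub$gene)
  }
  sub$gene[seq_len(n)]
}
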