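# Concordance between two perturbations and gene-set enrichment of fold-change
# shifts. Two enrichment procedures are provided deliberately: a two-sample
# Kolmogorov-Smirnov test on the log2 fold-change distribution (set members vs
# all other tested genes) and a Fisher's-exact variant on a selected gene list.

#' Quadrant concordance of two paired log2 fold-change series
#'
#' Counts genes falling in each sign quadrant of the (lfc_a, lfc_b) plane and
#' reports the Pearson correlation within the (down, down) quadrant. Genes
#' with a zero fold change in either series are excluded.
#'
#' @param lfc_a,lfc_b named numeric vectors of per-gene log2 fold changes;
#'   only the shared gene names are used.
#' @return list with `down_down`, `down_up`, `up_down`, `up_up` counts,
#'   `n_paired` (their sum) and `pearson_r_down_down` (NA with fewer than 3
#'   genes in that quadrant).
#' @export
quadrant_concordance <- function(lfc_a, lfc_b) {
  if (is.null(names(lfc_a)) || is.null(names(lfc_b)))
    .stopf("fold-change vectors must be named by gene")
  shared <- intersect(names(lfc_a), names(lfc_b))
  a <- lfc_a[shared]; b <- lfc_b[shared]
  keep <- is.finite(a) & is.finite(b) & a != 0 & b != 0
  a <- a[keep]; b <- b[keep]
  dd <- a < 0 & b < 0
  out <- list(down_down = sum(dd),
              down_up = sum(a < 0 & b > 0),
              up_down = sum(a > 0 & b < 0),
              up_up = sum(a > 0 & b > 0),
              n_paired = length(a))
  out$pearson_r_down_down <- if (sum(dd) >= 3) stats::cor(a[dd], b[dd]) else NA_real_
  out
}

#' Exact binomial test for the overlap of two top-n gene lists
#'
#' Under the null that list B is a uniform draw of n genes from the tested
#' universe, the overlap with a fixed list A of the same length is
#' Binomial(n, p) with success probability p = n / universe. The reported
#' p-value is the exact upper tail P(X >= k), computed by log-space summation
#' of the binomial probability mass so that extreme tails (far below 1e-16)
#' are exact.
#'
#' @param list_a,list_b character gene lists of equal length with no internal
#'   duplicates.
#' @param universe number of genes included in the differential expression
#'   analysis (must exceed the list length). There is no default: the universe
#'   must be stated explicitly.
#' @return list with `k` (observed overlap), `n`, `universe`, `p_success`,
#'   `p_value`.
#' @export
topn_overlap_test <- function(list_a, list_b, universe) {
  if (anyDuplicated(list_a) || anyDuplicated(list_b))
    .stopf("gene lists must not contain duplicates")
  n <- length(list_a)
  if (length(list_b) != n) .stopf("lists must have equal length")
  if (universe <= n) .stopf("universe (%d) must exceed list length (%d)", universe, n)
  k <- length(intersect(list_a, list_b))
  p <- n / universe
  list(k = k, n = n, universe = universe, p_success = p,
       p_value = binom_upper_tail(k, n, p))
}

#' Exact upper-tail binomial probability P(X >= k) by log-space summation
#'
#' @param k threshold count.
#' @param n number of trials.
#' @param p success probability in (0, 1).
#' @return P(X >= k), exact to double precision even deep in the tail.
#' @export
binom_upper_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  logs <- stats::dbinom(k:n, n, p, log = TRUE)
  mx <- max(logs)
  min(exp(mx + log(sum(exp(logs - mx)))), 1)
}

#' Kolmogorov-Smirnov gene-set enrichment of fold-change shifts
#'
#' For each set, compares the distribution of log2 fold changes of the set's
#' tested members against all other tested genes with a two-sided two-sample
#' KS test (asymptotic p-value). The direction is the sign of the difference
#' between the in-set and out-of-set median fold change, reported separately
#' so activated/repressed calls remain possible.
#'
#' @param lfc named numeric vector of per-tested-gene log2 fold changes.
#' @param collection a [gene_set_collection()].
#' @param min_set_size sets with fewer tested members are skipped with a
#'   warning (default 15, hallmark scale).
#' @return data.frame with `set`, `n_in_set`, `ks_D`, `p_value`,
#'   `neg_log10_p`, `direction`, sorted ascending by p-value.
#' @export
ks_set_enrichment <- function(lfc, collection, min_set_size = 15) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.null(names(lfc))) .stopf("lfc must be named by gene")
  lfc <- lfc[is.finite(lfc)]
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], names(lfc))
    if (length(members) < min_set_size) {
      warning(sprintf("set '%s' skipped: %d tested members < min_set_size %d",
                      nm, length(members), min_set_size), call. = FALSE)
      return(NULL)
    }
    inside <- lfc[members]
    outside <- lfc[setdiff(names(lfc), members)]
    if (length(outside) == 0) .stopf("set '%s' covers every tested gene", nm)
    kt <- suppressWarnings(stats::ks.test(inside, outside, exact = FALSE))
    p <- max(min(kt$p.value, 1), .Machine$double.xmin)
    data.frame(set = nm, n_in_set = length(members),
               ks_D = unname(kt$statistic), p_value = p,
               neg_log10_p = -log10(p),
               direction = sign(stats::median(inside) - stats::median(outside)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) .stopf("no set passed min_set_size")
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fisher's-exact gene-set enrichment of a selected gene list
#'
#' Tests each set for over-representation among `selected` genes relative to
#' the universe with a one-sided (enrichment) Fisher's exact test on the
#' 2x2 membership-by-selection table.
#'
#' @param selected character vector of selected genes (subset of
#'   `universe_genes`).
#' @param collection a [gene_set_collection()].
#' @param universe_genes all tested genes.
#' @param min_set_size sets with fewer universe members are skipped.
#' @return data.frame with `set`, `n_in_set`, `k_selected_in_set`,
#'   `odds_ratio`, `p_value`, `neg_log10_p`, sorted ascending by p.
#' @export
fisher_set_enrichment <- function(selected, collection, universe_genes,
                                  min_set_size = 1) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (anyDuplicated(selected)) .stopf("selected list must not contain duplicates")
  if (!all(selected %in% universe_genes))
    .stopf("selected genes must be a subset of the universe")
  universe_genes <- unique(universe_genes)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe_genes)
    if (length(members) < min_set_size) return(NULL)
    k <- length(intersect(selected, members))
    tab <- matrix(c(k,
                    length(members) - k,
                    length(selected) - k,
                    length(universe_genes) - length(members) - length(selected) + k),
                  nrow = 2)
    ft <- stats::fisher.test(tab, alternative = "greater")
    p <- max(min(ft$p.value, 1), .Machine$double.xmin)
    data.frame(set = nm, n_in_set = length(members), k_selected_in_set = k,
               odds_ratio = unname(ft$estimate), p_value = p,
               neg_log10_p = -log10(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) .stopf("no set intersects the universe at min_set_size")
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select genes for the Fisher enrichment variant
#'
#' Default selection rule: BH-adjusted p below `alpha` with the requested
#' fold-change sign.
#'
#' @param res data.frame from [nb_wald_de()].
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param direction `"down"`, `"up"` or `"both"`.
#' @return Character vector of gene ids.
#' @export
select_significant <- function(res, alpha = 0.05, direction = c("down", "up", "both")) {
  direction <- match.arg(direction)
  ok <- !is.na(res$adj_p_value) & res$adj_p_value < alpha
  if (direction == "down") ok <- ok & res$log2_fold_change < 0
  if (direction == "up") ok <- ok & res$log2_fold_change > 0
  res$gene[ok]
}
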