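.cm <- function(counts, groups = c("A", "A", "B", "B")) {
  m <- matrix(counts, nrow = length(counts) / length(groups), byrow = TRUE)
  dimnames(m) <- list(sprintf("g%d", seq_len(nrow(m))),
                      sprintf("s%d", seq_len(ncol(m))))
  count_matrix(m, setNames(groups, colnames(m)))
}

test_that("gene filter requires a count strictly above 5 in each group", {
  m <- .cm(c(6, 0, 0, 7,    # qualifying sample in each group -> kept
             5, 5, 5, 5,    # boundary: 5 is not 'more than five' -> dropped
             100, 100, 0, 0 # one group never qualifies -> dropped
             ))
  f <- filter_genes(m)
  expect_identical(rownames(f$counts), "g1")

  # looser reading: any single qualifying sample keeps the gene
  f2 <- filter_genes(m, per_group = FALSE)
  expect_identical(rownames(f2$counts), c("g1", "g3"))

  des3 <- setNames(c("A", "B", "C", "A"), colnames(m$counts))
  expect_error(filter_genes(count_matrix(m$counts, des3)), "2 groups")
})

test_that("filtering is idempotent and returns a subset", {
  m <- make_count_matrix(n_genes = 100, mu = 8, seed = 3)
  f1 <- filter_genes(m)
  f2 <- filter_genes(f1)
  expect_true(all(rownames(f1$counts) %in% rownames(m$counts)))
  expect_identical(f1$counts, f2$counts)
})

test_that("size factors follow the median-of-ratios closed forms", {
  # identical columns -> unit factors
  m <- .cm(c(10, 10, 20, 20, 7, 7), groups = c("A", "B"))
  expect_equal(unname(size_factors(m)), c(1, 1))

  # doubled column -> factors (1/sqrt(2), sqrt(2))
  m2 <- .cm(c(10, 20, 50, 100, 7, 14), groups = c("A", "B"))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))

  # global scaling leaves factors unchanged
  m10 <- count_matrix(m2$counts * 10L, m2$design)
  expect_equal(size_factors(m10), size_factors(m2))

  # no all-positive gene -> error pointing at the pseudo-reference fallback
  m0 <- .cm(c(0, 5, 5, 0), groups = c("A", "B"))
  expect_error(size_factors(m0), "all-positive")
})

test_that("scaling one column scales its factor proportionally", {
  m <- make_count_matrix(n_genes = 200, mu = 50, seed = 8)
  sf <- size_factors(m)
  counts2 <- m$counts
  counts2[, 2] <- counts2[, 2] * 3L
  sf2 <- size_factors(count_matrix(counts2, m$design))
  # relative to any other sample, the scaled column's factor triples
  expect_equal(unname((sf2[2] / sf2[1]) / (sf[2] / sf[1])), 3, tolerance = 1e-10)
})

test_that("size factors agree with DESeq2 estimateSizeFactors", {
  m <- make_count_matrix(n_genes = 300, mu = 80, seed = 12)
  dds <- suppressMessages(DESeq2::estimateSizeFactors(
    DESeq2::DESeqDataSetFromMatrix(m$counts,
                                   data.frame(cond = factor(m$design)), ~cond)))
  ref <- DESeq2::sizeFactors(dds)
  sf <- size_factors(m)
  # DESeq2 does not renormalize to unit geometric mean; compare shapes
  expect_equal(unname(sf / sf[1]), unname(ref / ref[1]), tolerance = 1e-10)
})

test_that("a gene constant across all samples has exactly zero log2 fold change", {
  m <- .cm(c(10, 10, 10, 10,
             6, 9, 12, 20))
  sf <- setNames(rep(1, 4), colnames(m$counts))
  res <- nb_wald_de(m, sf, reference_group = "A")
  expect_lt(abs(res$log2_fold_change[res$gene == "g1"]), 1e-8)
})

test_that("size factors act as offsets: exact group-ratio form and stability under rescaling", {
  # with unit size factors the fitted log2FC is exactly the log ratio of group
  # means, whatever the dispersion (group means are fitted exactly)
  m <- make_count_matrix(n_genes = 20, mu = 60, seed = 7)
  sf1 <- setNames(rep(1, 6), colnames(m$counts))
  res <- nb_wald_de(m, sf1, reference_group = "A")
  mA <- rowMeans(m$counts[, 1:3]); mB <- rowMeans(m$counts[, 4:6])
  expect_equal(res$log2_fold_change, unname(log2(mB / mA)), tolerance = 1e-7)

  # doubling one sample's counts together with its size factor perturbs the
  # estimate only through the NB weighting, far below biological effect sizes
  sf <- size_factors(m)
  res1 <- nb_wald_de(m, sf, reference_group = "A")
  counts2 <- m$counts
  counts2[, 1] <- counts2[, 1] * 2L
  sf2 <- sf
  sf2[1] <- sf2[1] * 2
  res2 <- nb_wald_de(count_matrix(counts2, m$design), sf2, reference_group = "A")
  expect_lt(max(abs(res2$log2_fold_change - res1$log2_fold_change)), 0.05)
})

test_that("a simulated 2x up-regulation is recovered on average", {
  set.seed(31)
  reps <- 40
  lfc <- replicate(reps, {
    y <- c(rnbinom(5, mu = 100, size = 10), rnbinom(5, mu = 200, size = 10))
    m <- count_matrix(matrix(y, nrow = 1, dimnames = list("g1", sprintf("s%d", 1:10))),
                      setNames(rep(c("A", "B"), each = 5), sprintf("s%d", 1:10)))
    nb_wald_de(m, setNames(rep(1, 10), sprintf("s%d", 1:10)), "A")$log2_fold_change
  })
  expect_equal(mean(lfc), 1, tolerance = 0.15)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  set.seed(19)
  for (i in 1:20) {
    p <- runif(sample(5:50, 1))
    expect_equal(p.adjust(p, "BH"), bh_brute_force(p), tolerance = 1e-12)
  }
  # and the DE output uses it over converged genes, keeping adj >= raw
  m <- make_count_matrix(n_genes = 60, mu = 50, seed = 2)
  res <- nb_wald_de(filter_genes(m), reference_group = "A")
  ok <- !is.na(res$p_value)
  expect_true(all(res$adj_p_value[ok] >= res$p_value[ok]))
  expect_equal(res$adj_p_value[ok], bh_brute_force(res$p_value[ok]), tolerance = 1e-12)
  expect_setequal(res$rank, seq_len(nrow(res)))
})

test_that("top_n applies direction, p-ordering and tie rules", {
  res <- data.frame(gene = sprintf("g%d", 1:5),
                    p_value = c(.01, .02, .03, .04, .05),
                    log2_fold_change = c(-1, -1, 1, -1, 1),
                    stringsAsFactors = FALSE)
  expect_equal(top_n(res, 2, "down"), c("g1", "g2"))
  expect_warning(out <- top_n(res, 100, "down"), "only 3")
  expect_equal(out, c("g1", "g2", "g4"))

  ties <- data.frame(gene = c("b", "a"), p_value = c(.5, .5),
                     log2_fold_change = c(-1, -2), stringsAsFactors = FALSE)
  expect_equal(top_n(ties, 1, "down"), "a")  # larger |lfc| wins the tie
  ties2 <- data.frame(gene = c("b", "a"), p_value = c(.5, .5),
                      log2_fold_change = c(-2, -2), stringsAsFactors = FALSE)
  expect_equal(top_n(ties2, 1, "down"), "a") # then lexicographic
})
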