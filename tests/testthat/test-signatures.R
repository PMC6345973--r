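test_that("quantile normalization forces identical column distributions", {
  set.seed(3)
  x <- matrix(rnorm(200), ncol = 4,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:4)))
  qn <- quantile_normalize(x)
  sorted <- apply(qn, 2, sort)
  for (j in 2:4) expect_identical(sorted[, j], sorted[, 1])
  # within-column order preserved
  for (j in 1:4) expect_identical(order(qn[, j]), order(x[, j]))
  # idempotent
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-12)
  # identical columns are a fixed point
  y <- matrix(rep(sort(rnorm(20)), 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(quantile_normalize(y), y)
})

test_that("quantile normalization hand example and tie rule", {
  # columns (1,3) and (2,4): rank means are (1+2)/2 and (3+4)/2
  m <- matrix(c(1, 3, 2, 4), ncol = 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), matrix(c(1.5, 3.5, 1.5, 3.5), ncol = 2))

  # a tied pair spans reference ranks 1..2 and receives their mean
  mt <- matrix(c(5, 5, 9, 1, 2, 3), ncol = 2)
  colnames(mt) <- c("s1", "s2"); rownames(mt) <- sprintf("g%d", 1:3)
  ref <- rowMeans(apply(mt, 2, sort))
  qt <- quantile_normalize(mt)
  expect_equal(unname(qt[1:2, 1]), rep(mean(ref[1:2]), 2))
  expect_equal(unname(qt[3, 1]), unname(ref[3]))

  expect_warning(quantile_normalize(mt[, 1, drop = FALSE]), "single-column")
})

test_that("quantile normalization agrees with limma on a continuous matrix", {
  set.seed(8)
  x <- matrix(rnorm(300), ncol = 5)
  dimnames(x) <- list(sprintf("g%02d", 1:60), sprintf("s%d", 1:5))
  expect_equal(unname(quantile_normalize(x)),
               unname(limma::normalizeQuantiles(x)), tolerance = 1e-10)
})

test_that("signature score is the mean per-gene z-score with the documented symmetries", {
  set.seed(13)
  expr <- matrix(rnorm(80), nrow = 8,
                 dimnames = list(sprintf("G%d", 1:8), sprintf("s%02d", 1:10)))
  sig <- c("G1", "G3", "G5")
  sc <- signature_score(expr, sig)
  # single-gene signature collapses to that gene's z-score
  z1 <- (expr["G1", ] - mean(expr["G1", ])) / sd(expr["G1", ])
  expect_equal(signature_score(expr, "G1"), z1)
  # scores are centered across samples
  expect_lt(abs(mean(sc)), 1e-10)
  # gene order within the signature is irrelevant
  expect_equal(signature_score(expr, rev(sig)), sc)
  # adding a constant to one gene's row changes nothing
  expr2 <- expr; expr2["G3", ] <- expr2["G3", ] + 100
  expect_equal(signature_score(expr2, sig), sc)
})

test_that("signature scoring flags absent and constant genes", {
  expr <- matrix(rnorm(40), nrow = 4,
                 dimnames = list(c("A", "B", "C", "Z"), sprintf("s%d", 1:10)))
  expect_warning(signature_score(expr, c("A", "MISSING")), "absent")
  exprc <- expr; exprc["B", ] <- 7
  expect_warning(sc <- signature_score(exprc, c("A", "B")), "zero-variance")
  expect_equal(sc, signature_score(exprc, "A"))
  expect_error(signature_score(expr, c("NOPE1", "NOPE2")), "no signature gene")
})

test_that("score correlation recovers exact and simulated relationships", {
  s <- setNames(rnorm(50, sd = 2), sprintf("p%02d", 1:50))
  expect_equal(score_correlation(s, 2 * s + 1)$r, 1)
  expect_equal(score_correlation(s, -s)$r, -1)
  expect_error(score_correlation(s[1:2], s[1:2]), ">= 3")
  expect_error(score_correlation(s, setNames(rep(1, 50), names(s))), "constant")

  set.seed(41)
  rs <- replicate(100, {
    z <- matrix(rnorm(400), ncol = 2) %*% chol(matrix(c(1, .6, .6, 1), 2))
    a <- setNames(z[, 1], sprintf("p%03d", 1:200))
    b <- setNames(z[, 2], sprintf("p%03d", 1:200))
    score_correlation(a, b)$r
  })
  expect_equal(mean(rs), 0.6, tolerance = 0.03)
})

test_that("median split sends ties to the low group and stratified t-tests behave", {
  sc <- setNames(c(1, 2, 2, 3, 4, 2), sprintf("s%d", 1:6))
  grp <- median_split(sc)
  expect_equal(sum(grp == "high"), 2)   # only 3 and 4 exceed the median 2
  expect_equal(unname(grp[c("s2", "s3", "s6")]), factor(rep("low", 3), levels = c("low", "high")))

  set.seed(6)
  n <- 100
  expr <- matrix(rnorm(2 * n), nrow = 2,
                 dimnames = list(c("self", "flat"), sprintf("s%03d", 1:n)))
  expr["flat", ] <- 5
  score <- setNames(expr["self", ], colnames(expr))
  res <- stratified_expression_test(expr, score, c("self", "flat"))
  self_row <- res[res$gene == "self", ]
  expect_gt(self_row$mean_high, self_row$mean_low)
  expect_lt(self_row$p_value, 1e-10)
  flat_row <- res[res$gene == "flat", ]
  expect_true(flat_row$degenerate)
  expect_equal(flat_row$p_value, 1)

  expect_error(stratified_expression_test(expr, score[1:3], "self"), "< 2 samples")
  expect_error(stratified_expression_test(expr, score, "missing_gene"), "absent")
})

test_that("Kaplan-Meier estimate matches the textbook product-limit values", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  flat <- km_estimate(c(4, 5, 6), c(0, 0, 0))
  expect_true(all(flat$survival == 1))

  # tie of an event and a censoring at t=2: the event is processed first
  km5 <- km_estimate(c(1, 2, 2, 3, 4), c(1, 1, 0, 1, 0))
  expect_equal(km5$time, c(1, 2, 3, 4))
  expect_equal(km5$survival, c(0.8, 0.6, 0.3, 0.3))
  expect_equal(km5$n_risk, c(5, 4, 2, 1))

  # monotone non-increasing, starts at or below 1
  set.seed(9)
  kmr <- km_estimate(rexp(40), rbinom(40, 1, 0.7))
  expect_true(all(diff(kmr$survival) <= 1e-12))
  expect_true(all(kmr$survival >= 0 & kmr$survival <= 1))

  expect_error(km_estimate(numeric(), numeric()), "empty")
})

test_that("without censoring the KM curve equals the empirical survival function", {
  set.seed(14)
  t <- sample(1:30, 12, replace = TRUE)
  km <- km_estimate(t, rep(1, 12))
  for (i in seq_along(km$time))
    expect_equal(km$survival[i], mean(t > km$time[i]))
})

test_that("log-rank matches the hand-enumerated hypergeometric oracle", {
  # 6-sample fixture with a tie across groups
  ta <- c(1, 3, 5); ea <- c(1, 1, 0)
  tb <- c(2, 3, 6); eb <- c(1, 1, 1)
  res <- logrank_test(ta, ea, tb, eb)
  oracle <- logrank_oracle(c(ta, tb), c(ea, eb), rep(c(1, 0), each = 3))
  expect_equal(res$chi_square, oracle, tolerance = 1e-10)

  # identical groups -> zero statistic, p = 1
  same <- logrank_test(ta, ea, ta, ea)
  expect_equal(same$chi_square, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  # label swap leaves the statistic unchanged
  sw <- logrank_test(tb, eb, ta, ea)
  expect_equal(sw$chi_square, res$chi_square, tolerance = 1e-12)

  expect_error(logrank_test(numeric(), numeric(), tb, eb), "non-empty")
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "no events")
})

test_that("prognostic stratification wires score, split, KM and log-rank together", {
  cfg <- sim_config(seed = 23, n_patients = 200)
  sv <- simulate_survival(cfg)
  out <- prognostic_stratification(sv$cohort)
  expect_equal(sum(out$group == "high") + sum(out$group == "low"), 200)
  expect_true(all(out$km_high$survival >= 0 & out$km_high$survival <= 1))
  expect_lt(out$logrank$p_value, 0.01)  # HR 3 at n=200 is easily detected
  # the high-score arm fares worse at the end of follow-up
  expect_lt(min(out$km_high$survival), min(out$km_low$survival) + 0.5)

  # the five-gene signature list is accepted verbatim as the default
  expect_equal(xbp1_five_gene_signature(),
               c("ANLN", "CSNK1G3", "RRM2", "SLC35A2", "UBAC2"))
})
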