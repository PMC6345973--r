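test_that("total spliced reads is the sum of unique reads over all junctions", {
  jt <- junction_table(make_junction_df(focal_reads = 250, background_reads = 750))
  expect_equal(total_spliced_reads(jt), 1000)
  empty <- junction_table(make_junction_df()[0, ])
  expect_equal(total_spliced_reads(empty), 0)
  jt10 <- junction_table(make_junction_df(focal_reads = 100,
                                          background_reads = rep(100, 9)))
  expect_equal(total_spliced_reads(jt10), 1000)
})

test_that("focal usage implements reads per million total spliced reads", {
  df <- make_junction_df(focal_reads = 250, background_reads = 5e6 - 250)
  u <- focal_usage(junction_table(df), xbp1s_junction())
  expect_equal(u$focal_reads, 250)
  expect_equal(u$ratio_per_million, 50)

  # focal junction absent -> zero reads, zero ratio
  no_focal <- junction_table(df[df$chrom != "chr22", ])
  u0 <- focal_usage(no_focal, xbp1s_junction())
  expect_equal(u0$focal_reads, 0)
  expect_equal(u0$ratio_per_million, 0)

  # focal is the only junction -> ratio hits the 1e6 boundary
  only <- junction_table(make_junction_df(focal_reads = 250,
                                          background_reads = integer()))
  expect_equal(focal_usage(only, xbp1s_junction())$ratio_per_million, 1e6)

  # focal present but the table has zero total reads -> undefined ratio
  zero <- make_junction_df(focal_reads = 0, background_reads = integer())
  expect_error(focal_usage(junction_table(zero), xbp1s_junction()), "undefined ratio")
})

test_that("unknown strand in the table matches any query strand", {
  df <- make_junction_df()
  df$strand[3] <- 0L
  u <- focal_usage(junction_table(df), xbp1s_junction())
  expect_equal(u$focal_reads, 250)
  minus <- focal_junction("chr22", 28796122, 28796147, "-")
  expect_equal(focal_usage(junction_table(df), minus)$focal_reads, 250)
})

test_that("ratio per million is invariant under uniform integer scaling of counts", {
  df <- make_junction_df(focal_reads = 250, background_reads = c(750, 1000))
  r1 <- focal_usage(junction_table(df), xbp1s_junction())$ratio_per_million
  for (k in c(2L, 7L, 100L)) {
    dfk <- df
    dfk$unique_reads <- dfk$unique_reads * k
    rk <- focal_usage(junction_table(dfk), xbp1s_junction())$ratio_per_million
    expect_equal(rk, r1)
  }
})

test_that("focal junction string grammar parses chrom:start-end[:strand]", {
  fj <- parse_focal_junction("chr22:28796122-28796147:+")
  expect_equal(fj$chrom, "chr22")
  expect_equal(fj$intron_start, 28796122L)
  expect_equal(fj$strand, "+")
  expect_equal(parse_focal_junction("chrX:10-20")$strand, "unknown")
  expect_error(parse_focal_junction("chr1:20"), "cannot parse")
})

.usage_fixture <- function(y, totals) {
  data.frame(sample = sprintf("s%d", seq_along(y)), focal_reads = y,
             total_spliced_reads = totals,
             ratio_per_million = y / totals * 1e6, stringsAsFactors = FALSE)
}
.design_fixture <- function(n_per_group) {
  setNames(rep(c("ctrl", "trt"), each = n_per_group),
           sprintf("s%d", seq_len(2 * n_per_group)))
}

test_that("identical focal counts and totals give a null group effect", {
  u <- .usage_fixture(rep(100, 6), rep(10000, 6))
  r <- differential_junction_usage(u, .design_fixture(3), "ctrl")
  expect_lt(abs(r$group_coefficient), 1e-8)
  expect_gt(r$p_value, 0.99)
})

test_that("swapping reference and treatment negates the coefficient and keeps p", {
  set.seed(11)
  y <- c(rnbinom(3, mu = 400, size = 20), rnbinom(3, mu = 60, size = 20))
  totals <- round(5e6 * exp(rnorm(6, 0, 0.1)))
  u <- .usage_fixture(y, totals)
  des <- .design_fixture(3)
  a <- differential_junction_usage(u, des, "ctrl")
  b <- differential_junction_usage(u, des, "trt")
  expect_equal(b$group_coefficient, -a$group_coefficient, tolerance = 1e-6)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-6)
})

test_that("a strong simulated depletion is detected with the right sign and size", {
  set.seed(21)
  y <- c(rnbinom(3, mu = 500, size = 20), rnbinom(3, mu = 50, size = 20))
  u <- .usage_fixture(y, round(5e6 * exp(rnorm(6, 0, 0.05))))
  r <- differential_junction_usage(u, .design_fixture(3), "ctrl")
  expect_lt(r$p_value, 1e-6)
  expect_lt(r$group_coefficient, -1.3)
  expect_gt(r$group_coefficient, -3.3)
})

test_that("degenerate inputs are rejected", {
  u <- .usage_fixture(rep(0, 6), rep(1000, 6))
  expect_error(differential_junction_usage(u, .design_fixture(3), "ctrl"),
               "degenerate")
  u2 <- .usage_fixture(c(10, 20, 30, 40), c(1000, 1000, 1000, 1000))
  des3 <- setNames(c("a", "b", "c", "a"), sprintf("s%d", 1:4))
  expect_error(differential_junction_usage(u2, des3, "a"), "two groups")
})

test_that("NB fit reduces to the Poisson GLM as dispersion vanishes", {
  set.seed(5)
  y <- rpois(8, lambda = rep(c(30, 90), each = 4))
  dep <- log10(round(1e6 * exp(rnorm(8, 0, 0.1))))
  X <- cbind(intercept = 1, group = rep(c(0, 1), each = 4), depth = dep)
  f <- fit_nb_glm(y, X, dispersion = 1e-8)
  g <- glm(y ~ X[, 2] + X[, 3], family = poisson)
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-4)
})

test_that("unadjusted profile ML matches glm.nb coefficients and dispersion", {
  set.seed(4)
  y <- rnbinom(20, mu = rep(c(50, 150), each = 10), size = 10)
  g <- rep(0:1, each = 10)
  f <- fit_nb_glm(y, cbind(1, g), cr_adjust = FALSE)
  m <- MASS::glm.nb(y ~ g)
  expect_equal(unname(f$coefficients), unname(coef(m)), tolerance = 1e-6)
  expect_equal(f$dispersion, 1 / m$theta, tolerance = 1e-4)
})
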