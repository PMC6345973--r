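# In-code fixtures shared across test files.

# A small junction data.frame with the XBP1s junction planted among
# background junctions.
make_junction_df <- function(focal_reads = 250, background_reads = c(750, 1000)) {
  nb <- length(background_reads)
  data.frame(
    chrom = c(rep("chr1", nb), "chr22"),
    intron_start = c(seq(1000, by = 10000, length.out = nb), 28796122L),
    intron_end = c(seq(1500, by = 10000, length.out = nb), 28796147L),
    strand = c(rep(1L, nb), 1L),
    motif = 1L, annotated = 1L,
    unique_reads = c(background_reads, focal_reads),
    multi_reads = 0L, max_overhang = 50L,
    stringsAsFactors = FALSE)
}

# Two-group count matrix from explicit per-group means (NB draws).
make_count_matrix <- function(n_genes = 50, n_per_group = 3, mu = 100, phi = 0.05,
                              groups = c("A", "B"), seed = 1) {
  set.seed(seed)
  counts <- matrix(rnbinom(n_genes * 2 * n_per_group, mu = mu, size = 1 / phi),
                   nrow = n_genes,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   sprintf("s%d", seq_len(2 * n_per_group))))
  count_matrix(counts, setNames(rep(groups, each = n_per_group),
                                colnames(counts)))
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition.
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Log-rank oracle by explicit hypergeometric moments at each event time.
logrank_oracle <- function(time, event, group) {
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
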