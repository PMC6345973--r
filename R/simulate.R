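# Seeded generators for every input the pipeline consumes, with ground truth
# recorded alongside. One root seed expands to per-component child seeds by a
# fixed derivation (child k uses seed + 77003 * k, modulo 2^31 - 1), so each
# component can be regenerated independently of the others.

.child_seed <- function(seed, k) as.integer((as.numeric(seed) + 77003 * k) %% 2147483647)

#' Simulation configuration
#'
#' Defaults emulate a desk-scale shadow of a triplicate bulk RNA-seq
#' experiment with two perturbations of the same pathway: 10,000 genes, 3 vs 3
#' samples per contrast, NB dispersion 0.05, ~5e6 total spliced reads per
#' sample, a focal junction at ~100 reads per million depleted 10-fold by
#' treatment, a 300-patient survival cohort with hazard ratio 3 across the
#' signature-score median, and 30 drug-combination rows.
#'
#' @param seed integer root seed; fully determines every generated object.
#' @param n_genes number of genes in each simulated count matrix.
#' @param samples_per_group replicates per group in each contrast.
#' @param nb_dispersion NB dispersion phi (Var = mu + phi mu^2), > 0.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   gene means.
#' @param de_fraction fraction of genes that are truly differential.
#' @param lfc_sd standard deviation of non-shared true log2 fold changes
#'   (mean 0).
#' @param shared_down_fraction fraction of DE genes down-regulated in both
#'   contrasts (their log2FC is drawn negative and shared).
#' @param set_shift_map named numeric vector: gene-set name -> additional mean
#'   log2FC shift applied to that set's members in both contrasts.
#' @param set_size members per constructed gene set.
#' @param n_null_sets unshifted gene sets added to the collection (the
#'   default collection totals 50 sets, hallmark scale).
#' @param depth_sd log-normal sd of per-sample depth factors.
#' @param n_background_junctions background junctions per sample.
#' @param junction_depth expected total unique spliced reads per sample.
#' @param focal_baseline_per_million focal-junction abundance in control
#'   samples, per million spliced reads.
#' @param focal_depletion fold depletion of the focal junction under
#'   treatment (1 = null).
#' @param n_patients survival-cohort size.
#' @param baseline_hazard exponential baseline hazard (1/study-time units).
#' @param log_hazard_ratio log hazard ratio per unit of the latent signature
#'   score.
#' @param censoring_rate target fraction censored, in [0, 1).
#' @param survival_noise_sd expression noise sd around the latent score.
#' @param n_survival_background non-signature genes in the cohort expression.
#' @param combo_fa,combo_fb central single-agent fractional responses.
#' @param combo_jitter half-width of the uniform jitter around them.
#' @param combo_interaction additive interaction placed on the combination
#'   response (> 0 synergistic truth).
#' @param combo_noise_sd Gaussian noise sd on the combination response.
#' @param n_combos combination rows generated.
#' @param combo_mode null model for the combination ("literal" or "bliss").
#' @return Validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 10000, samples_per_group = 3,
                       nb_dispersion = 0.05,
                       baseline_meanlog = 3, baseline_sdlog = 1.5,
                       de_fraction = 0.1, lfc_sd = 1,
                       shared_down_fraction = 0.3,
                       set_shift_map = NULL, set_size = 200, n_null_sets = 50,
                       depth_sd = 0.1,
                       n_background_junctions = 5000,
                       junction_depth = 5e6,
                       focal_baseline_per_million = 100,
                       focal_depletion = 10,
                       n_patients = 300, baseline_hazard = 0.1,
                       log_hazard_ratio = log(3), censoring_rate = 0.3,
                       survival_noise_sd = 1, n_survival_background = 100,
                       combo_fa = 0.5, combo_fb = 0.5, combo_jitter = 0.1,
                       combo_interaction = 0.1, combo_noise_sd = 0.05,
                       n_combos = 30, combo_mode = "literal") {
  cfg <- as.list(environment())
  for (r in c("de_fraction", "shared_down_fraction", "censoring_rate"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1) .stopf("%s must be in [0, 1]", r)
  if (censoring_rate >= 1) .stopf("censoring_rate must be < 1")
  if (nb_dispersion <= 0) .stopf("nb_dispersion must be > 0")
  if (focal_depletion < 1) .stopf("focal_depletion must be >= 1")
  if (round(de_fraction * n_genes) < 1 && de_fraction > 0)
    warning("de_fraction * n_genes < 1: zero DE genes generated", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# Shared helper: one contrast's count matrix from baseline means and true
# per-gene log2 fold changes, with per-sample depth factors.
.sim_contrast <- function(mu, lfc2, groups, phi, depth_sd) {
  n <- length(groups)
  depth <- exp(stats::rnorm(n, 0, depth_sd))
  counts <- vapply(seq_len(n), function(j) {
    m <- mu * if (groups[j] == groups[1]) 1 else 2^lfc2   # first group = reference
    stats::rnbinom(length(mu), mu = m * depth[j], size = 1 / phi)
  }, numeric(length(mu)))
  list(counts = counts, depth = depth)
}

#' Simulate paired two-contrast count matrices with known truth
#'
#' Generates NB count matrices for two contrasts over one gene universe
#' (knockdown vs control; inhibitor vs vehicle). A configured fraction of
#' genes is truly differential; a configured fraction of those is
#' down-regulated in both contrasts with a shared negative log2FC; members of
#' sets named in `set_shift_map` receive an additional mean log2FC shift in
#' both contrasts. A gene-set collection containing the shifted sets plus
#' unshifted null sets is returned with the truth table.
#'
#' @param cfg a [sim_config()].
#' @return list with `contrast1`, `contrast2` ([count_matrix()]s), `truth`
#'   (per-gene generating parameters), `gene_sets`
#'   ([gene_set_collection()]).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.child_seed(cfg$seed, 1L))
  ng <- cfg$n_genes
  genes <- sprintf("G%05d", seq_len(ng))
  mu <- stats::rlnorm(ng, cfg$baseline_meanlog, cfg$baseline_sdlog)
  n_de <- round(cfg$de_fraction * ng)
  de_idx <- if (n_de > 0) sample.int(ng, n_de) else integer()
  n_shared <- round(cfg$shared_down_fraction * n_de)
  shared_idx <- de_idx[seq_len(n_shared)]
  other_idx <- setdiff(de_idx, shared_idx)

  lfc1 <- lfc2 <- rep(0, ng)
  shared_lfc <- -abs(stats::rnorm(n_shared, 1, 0.5))
  lfc1[shared_idx] <- shared_lfc
  lfc2[shared_idx] <- shared_lfc
  lfc1[other_idx] <- stats::rnorm(length(other_idx), 0, cfg$lfc_sd)
  lfc2[other_idx] <- stats::rnorm(length(other_idx), 0, cfg$lfc_sd)

  # Gene sets: shifted sets get disjoint members and an extra mean lfc shift
  # in both contrasts; null sets are random draws.
  sets <- list()
  avail <- seq_len(ng)
  for (nm in names(cfg$set_shift_map)) {
    members <- sample(avail, min(cfg$set_size, length(avail)))
    avail <- setdiff(avail, members)
    shift <- stats::rnorm(length(members), cfg$set_shift_map[[nm]], 0.25)
    lfc1[members] <- lfc1[members] + shift
    lfc2[members] <- lfc2[members] + shift
    sets[[nm]] <- genes[members]
  }
  n_null <- max(cfg$n_null_sets - length(sets), 0)
  for (i in seq_len(n_null))
    sets[[sprintf("NULL_SET_%02d", i)]] <- genes[sample.int(ng, cfg$set_size)]
  collection <- gene_set_collection(sets)

  spg <- cfg$samples_per_group
  g1 <- rep(c("siCtrl", "siXBP1"), each = spg)
  g2 <- rep(c("vehicle", "MKC8866"), each = spg)
  c1 <- .sim_contrast(mu, lfc1, g1, cfg$nb_dispersion, cfg$depth_sd)
  c2 <- .sim_contrast(mu, lfc2, g2, cfg$nb_dispersion, cfg$depth_sd)
  s1 <- sprintf("si_%s_%d", g1, rep(seq_len(spg), 2))
  s2 <- sprintf("mkc_%s_%d", g2, rep(seq_len(spg), 2))
  dimnames(c1$counts) <- list(genes, s1)
  dimnames(c2$counts) <- list(genes, s2)

  truth <- data.frame(gene = genes, baseline_mean = mu,
                      lfc_contrast1 = lfc1, lfc_contrast2 = lfc2,
                      is_de = seq_len(ng) %in% de_idx,
                      shared_down = seq_len(ng) %in% shared_idx,
                      stringsAsFactors = FALSE)
  list(contrast1 = count_matrix(c1$counts, setNames(g1, s1)),
       contrast2 = count_matrix(c2$counts, setNames(g2, s2)),
       truth = truth, gene_sets = collection,
       depth_factors = list(contrast1 = setNames(c1$depth, s1),
                            contrast2 = setNames(c2$depth, s2)))
}

#' Simulate per-sample splice-junction tables with a depleted focal junction
#'
#' Background junctions receive log-normal relative abundances (shared across
#' samples) and Poisson counts at the configured depth; the focal junction
#' (the XBP1s key by default) receives NB counts at the configured
#' per-million baseline, depleted `focal_depletion`-fold in treated samples.
#'
#' @param cfg a [sim_config()].
#' @param focal a [focal_junction()] to plant (default [xbp1s_junction()]).
#' @return list with `tables` (named list of [junction_table()]s), `design`
#'   (sample -> group), `truth`.
#' @export
simulate_junctions <- function(cfg, focal = xbp1s_junction()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.child_seed(cfg$seed, 2L))
  nb <- cfg$n_background_junctions
  w <- stats::rlnorm(nb, 0, 1.5)
  w <- w / sum(w)
  starts <- sort(sample.int(2e8, nb))
  widths <- sample(60:5000, nb, replace = TRUE)
  spg <- cfg$samples_per_group
  groups <- rep(c("control", "treated"), each = spg)
  samples <- sprintf("%s_%d", groups, rep(seq_len(spg), 2))
  focal_mu0 <- cfg$focal_baseline_per_million * cfg$junction_depth / 1e6
  strand_code <- if (focal$strand == "unknown") 0L else .strand_codes[[focal$strand]]

  tables <- lapply(seq_along(samples), function(j) {
    depth <- cfg$junction_depth * exp(stats::rnorm(1, 0, cfg$depth_sd))
    bg <- stats::rpois(nb, w * depth)
    fm <- focal_mu0 * if (groups[j] == "treated") 1 / cfg$focal_depletion else 1
    fr <- stats::rnbinom(1, mu = fm, size = 1 / cfg$nb_dispersion)
    if (fm < 1)
      warning("depth too low for integer focal counts; focal mean < 1", call. = FALSE)
    df <- data.frame(
      chrom = c(rep("chr1", nb), focal$chrom),
      intron_start = c(starts, focal$intron_start),
      intron_end = c(starts + widths, focal$intron_end),
      strand = c(rep(1L, nb), strand_code),
      motif = c(rep(1L, nb), 1L),
      annotated = c(rep(1L, nb), 1L),
      unique_reads = c(bg, fr),
      multi_reads = 0L,
      max_overhang = 50L,
      stringsAsFactors = FALSE)
    junction_table(df, sample_id = samples[j])
  })
  names(tables) <- samples
  list(tables = tables,
       design = setNames(groups, samples),
       truth = list(focal = focal, depletion = cfg$focal_depletion,
                    focal_mean_control = focal_mu0,
                    expected_coefficient = -log(cfg$focal_depletion)))
}

#' Simulate a survival cohort driven by a latent signature score
#'
#' Each patient carries a standard-normal latent score; signature genes'
#' expression equals the score plus Gaussian noise, background genes are pure
#' noise. Event times are exponential with log hazard `log_hazard_ratio *
#' score`; censoring is independent exponential calibrated to the configured
#' censoring fraction.
#'
#' @param cfg a [sim_config()].
#' @param signature signature gene names planted in the expression matrix
#'   (default the five-gene XBP1 signature).
#' @return list with `cohort` ([survival_cohort()]) and `truth` (latent
#'   scores and generating parameters).
#' @export
simulate_survival <- function(cfg, signature = xbp1_five_gene_signature()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.child_seed(cfg$seed, 3L))
  n <- cfg$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  z <- stats::rnorm(n)
  sig_expr <- t(vapply(signature, function(g) z + stats::rnorm(n, 0, cfg$survival_noise_sd),
                       numeric(n)))
  bg <- matrix(stats::rnorm(cfg$n_survival_background * n), ncol = n,
               dimnames = list(sprintf("BG%04d", seq_len(cfg$n_survival_background)), ids))
  expr <- rbind(sig_expr, bg)
  rownames(expr) <- c(signature, rownames(bg))
  colnames(expr) <- ids
  rate <- cfg$baseline_hazard * exp(cfg$log_hazard_ratio * z)
  t_event <- stats::rexp(n, rate)
  r <- cfg$censoring_rate
  if (r > 0) {
    cens_rate <- cfg$baseline_hazard * r / (1 - r)
    t_cens <- stats::rexp(n, cens_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  list(cohort = survival_cohort(ids, time, event, expr),
       truth = list(score = setNames(z, ids),
                    log_hazard_ratio = cfg$log_hazard_ratio,
                    censoring_rate = r))
}

#' Simulate drug-combination fractional responses
#'
#' Single-agent responses are jittered uniformly around their central values;
#' the combination response is the configured null-model threshold plus the
#' interaction plus Gaussian noise, clipped to [0, 1]. The truth label is the
#' sign of the interaction.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with `label`, `fa`, `fb`, `fc`,
#'   `true_synergistic`.
#' @export
simulate_combos <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.child_seed(cfg$seed, 4L))
  n <- cfg$n_combos
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  fa <- clip01(cfg$combo_fa + stats::runif(n, -cfg$combo_jitter, cfg$combo_jitter))
  fb <- clip01(cfg$combo_fb + stats::runif(n, -cfg$combo_jitter, cfg$combo_jitter))
  thr <- expected_combination(fa, fb, cfg$combo_mode)
  fc <- clip01(thr + cfg$combo_interaction + stats::rnorm(n, 0, cfg$combo_noise_sd))
  data.frame(label = sprintf("combo_%03d", seq_len(n)),
             fa = fa, fb = fb, fc = fc,
             true_synergistic = cfg$combo_interaction > 0,
             stringsAsFactors = FALSE)
}
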