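#' Validation studies
#'
#' Simulation studies that exercise the package end-to-end on synthetic
#' data with known ground truth: null calibration and power of the
#' matched-resampling slope test, swap-vs-rejection sampler equivalence,
#' recovery of the configured sign-stratified couplings, sign-inference
#' accuracy, and the power and null behaviour of the expression-divergence
#' test. These back both the test suite and the reproduction script.
#'
#' @name validation-studies
NULL

# independent-rank universe used by the calibration study
independent_rank_universe <- function(n_genes) {
  ids <- sprintf("g%05d", seq_len(n_genes))
  list(x = setNames(rank_transform(rnorm(n_genes)), ids),
       y = setNames(rank_transform(rnorm(n_genes)), ids))
}

#' Null calibration of the slope-test p-value
#'
#' Draws, per replicate, a universe of independent x/y ranks and a tested
#' subset from the matched null itself (one matched sample anchored at a
#' uniform random subset's mean ranks), then computes the slope-test
#' p-value against `n_samples` matched nulls with a pre-specified
#' direction. Under this null the p-value should be uniform, so the
#' fraction below 0.05 should sit near 0.05.
#'
#' @param n_replicates number of replicates.
#' @param n_genes universe size.
#' @param subset_size tested subset size.
#' @param n_samples null samples per replicate.
#' @param tolerance matched-sampler RMSD tolerance.
#' @param seed master seed.
#' @return numeric vector of p-values, length `n_replicates`.
#' @export
slope_calibration_study <- function(n_replicates = 500, n_genes = 2000,
                                    subset_size = 150, n_samples = 500,
                                    tolerance = 0.01, seed = 1) {
  vapply(seq_len(n_replicates), function(r) {
    set.seed(stage_seed(seed, paste0("calib", r)))
    u <- independent_rank_universe(n_genes)
    anchor <- sample(names(u$x), subset_size)
    tested <- sample_matched_subsets(u$x, u$y, anchor, 1, tolerance,
                                     method = "swap")[[1]]
    slope_pvalue(u$x, u$y, tested, n_samples = n_samples,
                 tolerance = tolerance, method = "swap",
                 direction = "flatter")$p_value
  }, numeric(1))
}

#' Power of the slope test against a flattened TF trend
#'
#' Generates, per run, a gene universe whose generic genes follow the
#' configured genome rank-slope of Ka/Ks on expression while the TF subset
#' is generated with `tf_trend_multiplier = 0` (no trend) and shifted
#' expression, then tests the TF subset slope (direction "flatter"). The
#' returned p-values should reject at 0.05 in the large majority of runs.
#'
#' @param n_runs number of simulated datasets.
#' @param n_genes,n_tfs universe and subset sizes.
#' @param genome_slope rank-space slope for generic genes.
#' @param tf_trend_multiplier trend multiplier for the TF subset.
#' @param n_samples null samples per test.
#' @param seed master seed.
#' @return numeric vector of p-values, length `n_runs`.
#' @export
slope_power_study <- function(n_runs = 100, n_genes = 2000, n_tfs = 150,
                              genome_slope = -0.5, tf_trend_multiplier = 0,
                              n_samples = 500, seed = 1) {
  cfg <- generator_config(n_genes = n_genes, n_tfs = n_tfs,
                          genome_slope_expression = genome_slope,
                          tf_trend_multiplier = tf_trend_multiplier)
  vapply(seq_len(n_runs), function(r) {
    set.seed(stage_seed(seed, paste0("power", r)))
    gg <- generate_genes(cfg)
    genes <- add_property_ranks(gg$genes,
                                properties = c("ka_ks", "expression"))
    xr <- setNames(genes$rank_expression, genes$gene_id)
    yr <- setNames(genes$rank_ka_ks, genes$gene_id)
    slope_pvalue(xr, yr, genes$gene_id[genes$is_tf],
                 n_samples = n_samples, method = "swap",
                 direction = "flatter")$p_value
  }, numeric(1))
}

#' Swap-sampler vs rejection-sampler null-slope equivalence
#'
#' On a small universe where rejection sampling is tractable, draws
#' matched null slopes with both samplers for a mildly off-centre subset
#' and compares the two distributions with a two-sample Kolmogorov-Smirnov
#' test. Distributional agreement (large KS p) validates the swap sampler
#' against the exact rejection oracle.
#'
#' @param n_genes universe size.
#' @param subset_size subset size.
#' @param n_each null slopes per sampler.
#' @param tolerance RMSD tolerance.
#' @param seed master seed.
#' @return list: `ks_p`, `slopes_swap`, `slopes_rejection`.
#' @export
sampler_equivalence_study <- function(n_genes = 300, subset_size = 30,
                                      n_each = 200, tolerance = 0.01,
                                      seed = 1) {
  set.seed(stage_seed(seed, "sampler_eq"))
  u <- independent_rank_universe(n_genes)
  # mildly off-centre subset: prefer upper x ranks
  subset <- sample(names(u$x), subset_size, prob = 0.5 + u$x)
  sl <- function(sets) vapply(sets, function(s) subset_slope(u$x, u$y, s),
                              numeric(1))
  set.seed(stage_seed(seed, "sampler_eq_swap"))
  s_swap <- sl(sample_matched_subsets(u$x, u$y, subset, n_each, tolerance,
                                      method = "swap"))
  set.seed(stage_seed(seed, "sampler_eq_rej"))
  s_rej <- sl(sample_matched_subsets(u$x, u$y, subset, n_each, tolerance,
                                     method = "rejection",
                                     max_attempts = 5e6))
  ks <- suppressWarnings(ks.test(s_swap, s_rej))
  list(ks_p = ks$p.value, slopes_swap = s_swap, slopes_rejection = s_rej)
}

#' Recovery of the sign-stratified TF-target couplings
#'
#' Generates full synthetic datasets (default: activated coupling 0.3,
#' repressed 0), runs the analysis path — network construction, sign
#' inference from knockout X scores, sign-stratified correlations — and
#' records the recovered activated and repressed correlations per seed.
#'
#' @param n_seeds number of generated datasets.
#' @param cfg a `generator_config`.
#' @param seed master seed.
#' @return data.frame: `seed, rho_activated, rho_repressed, n_tfs_activated,
#'   n_tfs_repressed`.
#' @export
coupling_recovery_study <- function(n_seeds = 50,
                                    cfg = generator_config(),
                                    seed = 1) {
  rows <- lapply(seq_len(n_seeds), function(r) {
    ds <- generate_dataset(cfg, seed = stage_seed(seed, paste0("cr", r)))
    genes <- prepare_gene_table(ds$genes)
    net <- build_regulatory_network(ds$edge_records, genes$gene_id)
    net <- assign_edge_signs(net, ds$knockout)
    strat <- sign_stratified_correlations(net, genes)
    pick <- function(sg, col) {
      v <- strat[[col]][strat$sign == sg &
                          strat$property == "median_target_ka_ks"]
      if (length(v) == 1) v else NA_real_
    }
    data.frame(seed = r,
               rho_activated = pick("A", "rho"),
               rho_repressed = pick("R", "rho"),
               n_tfs_activated = pick("A", "n_tfs"),
               n_tfs_repressed = pick("R", "n_tfs"))
  })
  do.call(rbind, rows)
}

#' Noiseless sign-inference recovery check
#'
#' With X-score noise 0 and |mu| > threshold, sign inference must recover
#' every generated edge sign; with mu below the threshold every edge must
#' stay unsigned.
#'
#' @param seed master seed.
#' @param mu X-score magnitude for true edges.
#' @param threshold sign-inference |X| threshold.
#' @return list: `accuracy` (fraction of signable edges recovered),
#'   `n_signed`, `n_edges`, `all_unsigned`.
#' @export
sign_recovery_check <- function(seed = 1, mu = 2, threshold = 1) {
  cfg <- generator_config(xscore_mu = mu, xscore_noise_sd = 0,
                          xscore_background_sd = 0)
  ds <- generate_dataset(cfg, seed = seed)
  net <- build_regulatory_network(ds$edge_records, ds$genes$gene_id)
  net <- assign_edge_signs(net, ds$knockout, threshold = threshold)
  truth_ed <- ds$truth$edges
  truth_ed <- truth_ed[!duplicated(paste(truth_ed$tf, truth_ed$target,
                                         sep = "\r")), , drop = FALSE]
  key <- function(d, a, b) paste(d[[a]], d[[b]], sep = "\r")
  true_sign <- setNames(truth_ed$true_sign, key(truth_ed, "tf", "target"))
  covered <- net$tf %in% colnames(ds$knockout)
  signed <- net$sign != "U" & covered
  acc <- if (any(signed))
    mean(net$sign[signed] == true_sign[key(net, "tf", "target")[signed]])
  else NA_real_
  list(accuracy = acc, n_signed = sum(signed),
       n_covered_edges = sum(covered),
       all_unsigned = all(net$sign == "U"))
}

#' Null and power behaviour of the divergence t-test
#'
#' Generates synthetic datasets with the divergence-rate coupling either
#' off (null: rejection rate should sit at the nominal level) or on
#' (power: targets of the fastest TFs get an inflated divergence scale),
#' runs RPM normalization, fold-change computation and the unpaired t-test
#' on the confirmed-edge network, and reports the p-value per seed.
#'
#' @param n_seeds number of generated datasets.
#' @param coupling `divergence_rate_coupling` passed to the generator.
#' @param seed master seed.
#' @return numeric vector of p-values.
#' @export
divergence_power_study <- function(n_seeds = 100, coupling = 1, seed = 1) {
  cfg <- generator_config(divergence_rate_coupling = coupling)
  vapply(seq_len(n_seeds), function(r) {
    ds <- generate_dataset(cfg, seed = stage_seed(seed, paste0("dv", r,
                                                               coupling)))
    genes <- prepare_gene_table(ds$genes)
    net_ce <- confirmed_edges(
      build_regulatory_network(ds$edge_records, genes$gene_id), 2)
    cnt <- ds$counts
    rpm_a <- rpm_normalize(setNames(cnt$count_a, cnt$gene_id_a))
    rpm_b <- rpm_normalize(setNames(cnt$count_b, cnt$gene_id_b))
    div <- log2_fold_changes(rpm_a, rpm_b)
    rates <- setNames(genes$assigned_ka_ks, genes$gene_id)
    divergence_ttest(div, net_ce,
                     rates[genes$gene_id[genes$is_tf]])$p
  }, numeric(1))
}
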