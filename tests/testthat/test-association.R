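test_that("spearman correlation matches closed forms and oracles", {
  expect_equal(spearman_cor(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  # d^2 formula by hand: sum d^2 = 4 gives 1 - 24/120 = 0.8
  expect_equal(spearman_cor(1:5, c(2, 1, 4, 3, 5))$rho, 0.8)
  expect_error(spearman_cor(1:2, 2:3), "fewer than 3")
  expect_error(spearman_cor(rep(1, 5), 1:5), "zero variance")

  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    x <- sample(seq_len(100), n)      # untied
    y <- sample(seq_len(100), n)
    expect_equal(spearman_cor(x, y)$rho, spearman_d2(x, y))
    # tied data: Pearson of midranks
    xt <- sample(1:4, n, replace = TRUE)
    yt <- sample(1:4, n, replace = TRUE)
    if (sd(xt) > 0 && sd(yt) > 0)
      expect_equal(spearman_cor(xt, yt)$rho,
                   cor(rank(xt), rank(yt)), tolerance = 1e-12)
  }
})

test_that("correlation panel covers both protein sets with one correlate list", {
  ds <- generate_dataset(generator_config(n_genes = 600, n_tfs = 50,
                                          out_degree_min = 5,
                                          out_degree_max = 40),
                         seed = 2)
  net <- build_regulatory_network(ds$edge_records, ds$genes$gene_id)
  genes <- prepare_gene_table(ds$genes, ppi = ds$ppi, net = net)
  panel <- tf_target_correlation_panel(genes, net, ds$ppi)
  expect_true(all(c("tf", "all") %in% panel$protein_set))
  labs <- split(panel$x_label, panel$protein_set)
  expect_setequal(labs$tf, labs$all)
  expect_true(all(abs(panel$rho) <= 1))
  expect_true(all(panel$n >= 3))
  # TF rates must track median target rates under the default coupling
  mt <- panel[panel$protein_set == "tf" &
                panel$x_label == "median_target_ka_ks", ]
  expect_gt(mt$rho, 0)
})

test_that("sign strata respect the same-sign target threshold", {
  genes <- tiny_gene_table(ka = seq(0.05, 0.5, length.out = 10),
                           ids = c(paste0("tf", 1:2), paste0("g", 1:8)),
                           is_tf = c(TRUE, TRUE, rep(FALSE, 8)))
  genes <- prepare_gene_table(genes)
  # tf1 has 5 activated targets, tf2 only 4: only tf1 can enter a stratum,
  # and with fewer than 3 stratum TFs no correlation row is emitted
  net <- net_of(c(rep("tf1", 5), rep("tf2", 4)),
                c(paste0("g", 1:5), paste0("g", 1:4)),
                sign = rep("A", 9))
  strat <- sign_stratified_correlations(net, genes, 5)
  expect_equal(nrow(strat), 0)

  all_unsigned <- net_of("tf1", "g1")
  expect_equal(nrow(sign_stratified_correlations(all_unsigned, genes)), 0)
})

test_that("activator-only coupling shows up only in the activated stratum", {
  res <- coupling_recovery_study(n_seeds = 8,
                                 cfg = generator_config(ko_coverage = 0.86),
                                 seed = 303)
  expect_gt(mean(res$rho_activated), 0.1)
  expect_lt(abs(mean(res$rho_repressed)), 0.12)
  expect_gt(mean(res$rho_activated) - mean(res$rho_repressed), 0.15)
})

test_that("degree-weighted sampling draws proportional to in-degree", {
  set.seed(5)
  ids <- c("a", "b", "c")
  draws <- replicate(6000, degree_weighted_sample(ids, 1, c(1, 2, 3)))
  counts <- table(factor(draws, levels = ids))
  gof <- chisq.test(counts, p = c(1, 2, 3) / 6)
  expect_gt(gof$p.value, 0.01)
})

test_that("co-regulation spread uses median pairwise differences", {
  genes <- tiny_gene_table(ka = c(0.3, 0.1, 0.2, 0.4, 0.15, 0.25),
                           ids = c("tf1", paste0("g", 1:5)),
                           is_tf = c(TRUE, rep(FALSE, 5)))
  genes <- prepare_gene_table(genes)
  net <- net_of(rep("tf1", 3), c("g1", "g2", "g3"))
  vals <- setNames(c(0.1, 0.2, 0.4), c("g1", "g2", "g3"))
  set.seed(1)
  res <- coregulation_spread_test(net, genes, vals, n_null = 20)
  # pairwise differences {0.1, 0.2, 0.3} have median 0.2
  expect_equal(res$table$observed, 0.2)
  expect_equal(res$table$n_targets, 3L)

  # constant values: observed and expected collapse to zero, p ~ 1
  const <- setNames(rep(0.5, 5), paste0("g", 1:5))
  res0 <- coregulation_spread_test(net, genes, const, n_null = 20)
  expect_equal(res0$table$observed, 0)
  expect_equal(res0$table$expected, 0)
  expect_equal(res0$p, 1)
})

test_that("spread test result is invariant to target row order", {
  ds <- generate_dataset(generator_config(n_genes = 300, n_tfs = 20,
                                          out_degree_min = 4,
                                          out_degree_max = 20),
                         seed = 6)
  genes <- prepare_gene_table(ds$genes)
  net <- build_regulatory_network(ds$edge_records, ds$genes$gene_id)
  vals <- setNames(genes$assigned_ka_ks, genes$gene_id)
  set.seed(77)
  r1 <- coregulation_spread_test(net, genes, vals, n_null = 10)
  shuffled <- ds$edge_records[rev(seq_len(nrow(ds$edge_records))), ]
  net2 <- build_regulatory_network(shuffled, ds$genes$gene_id)
  set.seed(77)
  r2 <- coregulation_spread_test(net2, genes, vals, n_null = 10)
  expect_equal(r1$table, r2$table)
  expect_equal(r1$p, r2$p)
})

test_that("fast/slow TF target split applies the precedence rule", {
  net <- net_of(c("t1", "t1", "t2", "t2", "t3"),
                c("a", "b", "b", "c", "d"))
  rates <- c(t1 = 0.9, t2 = 0.2, t3 = 0.1)
  sp <- fast_tf_split(net, rates, fast_fraction = 0.25)
  expect_equal(sp$fast_tfs, "t1")
  expect_setequal(sp$fast_targets, c("a", "b"))
  expect_setequal(sp$other_targets, c("c", "d"))   # b went to fast
  spx <- fast_tf_split(net, rates, fast_fraction = 0.25, exclusive = TRUE)
  expect_setequal(spx$fast_targets, "a")

  # deterministic tie-break by gene id at the quantile boundary
  tied <- c(t1 = 0.5, t2 = 0.5, t3 = 0.1)
  sp2 <- fast_tf_split(net, tied, fast_fraction = 0.25)
  expect_equal(sp2$fast_tfs, "t1")
})

test_that("enrichment follows Fisher's exact oracle and the size filter", {
  fast <- paste0("f", 1:20)
  other <- paste0("o", 1:80)
  ann <- data.frame(
    gene_id = c(fast[1:8], other[1:10], fast, other[1:45]),
    term_id = c(rep("big", 18), rep("huge", 65)),
    stringsAsFactors = FALSE)
  rows <- target_set_enrichment(fast, other, ann, min_term_size = 10)
  # term "big": 8/20 vs 10/80 -> fold 3.2, p from full enumeration
  big <- rows[rows$term_id == "big", ]
  expect_equal(big$fold, (8 / 20) / (10 / 80))
  expect_equal(big$p, fisher_enum_p(8, 12, 10, 70), tolerance = 1e-12)

  # identical fractions: fold 1, p >= 0.5
  ann_eq <- data.frame(gene_id = c(fast[1:5], other[1:20]),
                       term_id = "t", stringsAsFactors = FALSE)
  eq <- target_set_enrichment(fast, other, ann_eq, min_term_size = 10)
  expect_equal(eq$fold, 1)
  expect_gte(eq$p, 0.5)

  # a term below the size threshold among the union never appears
  small <- target_set_enrichment(fast, other, ann, min_term_size = 19)
  expect_false("big" %in% small$term_id)
  expect_error(target_set_enrichment(character(0), other, ann), "non-empty")
  expect_error(target_set_enrichment(fast, c(other, fast[1]), ann),
               "disjoint")
})

test_that("binned median profiles split into equal-count bins", {
  set.seed(12)
  x <- rnorm(100); y <- rnorm(100)
  prof <- binned_median_profile(x, y, n_bins = 4)
  expect_equal(prof$n, rep(25L, 4))
  expect_true(!is.unsorted(prof$x_lo))

  # constant response: all medians equal with zero bootstrap SE
  flat <- binned_median_profile(x, rep(2, 100), n_bins = 5)
  expect_equal(flat$median_y, rep(2, 5))
  expect_equal(flat$se, rep(0, 5))
  expect_error(binned_median_profile(1:3, 1:3, n_bins = 4), "fewer points")
})
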