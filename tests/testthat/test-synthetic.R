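small_cfg <- function(...) {
  generator_config(n_genes = 400, n_tfs = 30, out_degree_min = 5,
                   out_degree_max = 30, ...)
}

test_that("generation is fully deterministic under a fixed seed", {
  d1 <- generate_dataset(small_cfg(), seed = 13)
  d2 <- generate_dataset(small_cfg(), seed = 13)
  expect_identical(d1$genes, d2$genes)
  expect_identical(d1$edge_records, d2$edge_records)
  expect_identical(d1$knockout, d2$knockout)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$annotations, d2$annotations)
  d3 <- generate_dataset(small_cfg(), seed = 14)
  expect_false(identical(d1$genes$ka_ks, d3$genes$ka_ks))
})

test_that("written dataset files are byte-identical across runs", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  generate_dataset(small_cfg(), seed = 4, outdir = out1)
  generate_dataset(small_cfg(), seed = 4, outdir = out2)
  files <- list.files(out1)
  expect_true(length(files) >= 7)
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     label = f)
})

test_that("configured null couplings produce uncorrelated properties", {
  cfg <- generator_config(n_genes = 2000, n_tfs = 100,
                          genome_slope_expression = 0,
                          genome_slope_ppi = 0,
                          tf_expression_shift = 0)
  set.seed(stage_seed(50, "genes"))
  gg <- generate_genes(cfg)
  g <- gg$genes
  expect_lt(abs(cor(g$ka_ks, g$expression, method = "spearman")), 0.1)
  expect_lt(abs(cor(g$ka_ks, g$ppi_degree, method = "spearman")), 0.1)
  expect_lt(abs(cor(g$expression, g$ppi_degree, method = "spearman")), 0.1)
})

test_that("the configured genome rank slope is recovered from the draw", {
  slopes <- vapply(1:10, function(r) {
    set.seed(stage_seed(60, paste0("rec", r)))
    gg <- generate_genes(generator_config())
    g <- add_property_ranks(gg$genes, c("ka_ks", "expression"))
    subset_slope(setNames(g$rank_expression, g$gene_id),
                 setNames(g$rank_ka_ks, g$gene_id),
                 g$gene_id[!g$is_tf])
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-0.5)), 0.1)
  expect_true(all(abs(slopes - (-0.5)) < 0.15))
})

test_that("sign split and support boundaries behave as configured", {
  all_act <- generate_dataset(small_cfg(sign_split = 1), seed = 9)
  expect_true(all(all_act$truth$edges$true_sign == "A"))

  no_redetect <- generate_dataset(small_cfg(redetect_prob = 0), seed = 9)
  net <- build_regulatory_network(no_redetect$edge_records,
                                  no_redetect$genes$gene_id)
  expect_equal(nrow(confirmed_edges(net, 2)), 0)
})

test_that("noiseless X scores invert the sign rule exactly", {
  sr <- sign_recovery_check(seed = 21)
  expect_equal(sr$accuracy, 1)
  expect_equal(sr$n_signed, sr$n_covered_edges)
  # sub-threshold magnitude leaves every edge unsigned
  sub <- sign_recovery_check(seed = 21, mu = 0.5)
  expect_true(sub$all_unsigned)
})

test_that("generated knockout coverage and edge support look as configured", {
  ds <- generate_dataset(small_cfg(ko_coverage = 0.5, n_experiments = 3,
                                   redetect_prob = 0.4), seed = 30)
  expect_equal(ncol(ds$knockout), 15)          # half of 30 TFs covered
  expect_true(all(ds$truth$edges$support >= 1 &
                    ds$truth$edges$support <= 3))
  # support >= 2 fraction near 1 - (1 - 0.4)^2 = 0.64
  expect_lt(abs(mean(ds$truth$edges$support >= 2) - 0.64), 0.1)
})

test_that("ground truth is emitted separately and never consumed by analysis", {
  ds <- generate_dataset(small_cfg(), seed = 2)
  expect_true(!is.null(ds$truth$edges$true_sign))
  analysis_fns <- c("build_regulatory_network", "confirmed_edges",
                    "tf_target_profiles", "assign_edge_signs",
                    "split_by_sign", "slope_pvalue", "subset_slope",
                    "sign_stratified_correlations",
                    "coregulation_spread_test", "target_set_enrichment",
                    "tf_target_correlation_panel", "divergence_ttest",
                    "rpm_normalize", "log2_fold_changes")
  for (fn in analysis_fns)
    expect_false("truth" %in% names(formals(get(fn, asNamespace("tfnetevo")))),
                 label = fn)
  # the data frames handed to analysis carry no truth columns
  expect_false(any(grepl("true|truth", names(ds$genes))))
  expect_false(any(grepl("true|truth", names(ds$edge_records))))
})

test_that("annotation generation biases niche terms toward fast-TF targets", {
  ds <- generate_dataset(generator_config(niche_term_bias = 4), seed = 19)
  genes <- prepare_gene_table(ds$genes)
  net <- build_regulatory_network(ds$edge_records, genes$gene_id)
  rates <- setNames(genes$assigned_ka_ks, genes$gene_id)
  sp <- fast_tf_split(net, rates[genes$gene_id[genes$is_tf]])
  enr <- target_set_enrichment(sp$fast_targets, sp$other_targets,
                               ds$annotations, min_term_size = 50)
  niche <- names(ds$truth$annotation$term_class)[
    ds$truth$annotation$term_class == "niche"]
  hits <- enr[enr$significant & enr$fold > 1.3, "term_id"]
  expect_gt(length(intersect(hits, niche)), 0)
})

test_that("infeasible coupling configurations fail with a clear message", {
  expect_error(generator_config(activated_coupling = 0.95,
                                idiosyncratic_share = 0.9),
               "infeasible")
})
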