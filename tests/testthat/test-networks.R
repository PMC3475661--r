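test_that("edge records collapse into supported unique edges", {
  rec <- edge_records_of(tf = c("t1", "t1", "t1", "t1"),
                         target = c("a", "a", "a", "b"),
                         experiment = c("E1", "E2", "E3", "E1"))
  net <- build_regulatory_network(rec)
  expect_equal(nrow(net), 2)
  expect_equal(net$support[net$target == "a"], 3L)
  expect_equal(unname(out_degree(net)["t1"]), 2L)

  empty <- build_regulatory_network(rec[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(length(out_degree(empty)), 0)

  # records outside the gene universe are dropped with a warning
  expect_warning(
    dropped <- build_regulatory_network(rec, gene_universe = c("t1", "a")),
    "dropped")
  expect_equal(nrow(dropped), 1)
  expect_equal(attr(dropped, "dropped_records"), 1L)
})

test_that("degree identities hold on generated networks", {
  ds <- generate_dataset(generator_config(n_genes = 300, n_tfs = 25,
                                          out_degree_min = 3,
                                          out_degree_max = 25),
                         seed = 3)
  net <- build_regulatory_network(ds$edge_records, ds$genes$gene_id)
  expect_equal(sum(out_degree(net)), nrow(net))
  expect_equal(sum(in_degree(net)), nrow(net))
})

test_that("confirmed-edge filtering keeps well-supported edges and is monotone", {
  rec <- edge_records_of(tf = rep("t1", 6),
                         target = c("a", "a", "b", "b", "b", "c"),
                         experiment = c("E1", "E2", "E1", "E2", "E3", "E1"))
  net <- build_regulatory_network(rec)
  expect_equal(sort(confirmed_edges(net, 2)$target), c("a", "b"))
  expect_equal(confirmed_edges(net, 1), net)      # identity at min 1
  expect_equal(nrow(confirmed_edges(net, 4)), 0)  # nothing that supported
  for (k in 1:4)                                  # raising k never adds edges
    expect_true(nrow(confirmed_edges(net, k + 1)) <=
                  nrow(confirmed_edges(net, k)))
})

test_that("TF target profiles aggregate assigned rates and fractions", {
  genes <- tiny_gene_table(ka = c(NA, 0.1, 0.5, NA, 0.2),
                           ids = c("tf1", "a", "b", "c", "d"),
                           is_tf = c(TRUE, rep(FALSE, 4)))
  genes <- add_property_ranks(assign_missing_ortholog_rate(genes))
  net <- net_of(rep("tf1", 3), c("a", "b", "c"))
  prof <- tf_target_profiles(net, genes, min_targets = 3)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$n_targets, 3L)
  # assigned rates {0.1, 0.5, 0.55}: median 0.5; one of three missing
  expect_equal(prof$median_target_ka_ks, 0.5)
  expect_equal(prof$fraction_targets_missing, 1 / 3)

  # below min_targets no profile is emitted
  net2 <- net_of(rep("tf1", 2), c("a", "b"))
  expect_equal(nrow(tf_target_profiles(net2, genes, min_targets = 3)), 0)
  expect_equal(nrow(tf_target_profiles(net2, genes, min_targets = 2)), 1)
  # ...and the missing fraction is absent below 3 targets
  expect_true(is.na(tf_target_profiles(net2, genes,
                                       min_targets = 2)$fraction_targets_missing))

  # all targets missing an ortholog
  net3 <- net_of(rep("tf1", 3), c("c", "c", "c"))  # collapses to 1 target
  net4 <- net_of(rep("tf1", 4), c("a", "c", "c", "c"))
  expect_equal(nrow(tf_target_profiles(net3, genes, 3)), 0)
  genes_all_miss <- tiny_gene_table(ka = c(0.2, NA, NA, NA),
                                    ids = c("tf1", "x", "y", "z"),
                                    is_tf = c(TRUE, FALSE, FALSE, FALSE))
  genes_all_miss <- add_property_ranks(
    assign_missing_ortholog_rate(genes_all_miss))
  p <- tf_target_profiles(net_of(rep("tf1", 3), c("x", "y", "z")),
                          genes_all_miss, 3)
  expect_equal(p$fraction_targets_missing, 1.0)
})

test_that("profiles on a sub-network equal profiles computed from scratch", {
  ds <- generate_dataset(generator_config(n_genes = 300, n_tfs = 25,
                                          out_degree_min = 4,
                                          out_degree_max = 25),
                         seed = 5)
  genes <- prepare_gene_table(ds$genes)
  net <- build_regulatory_network(ds$edge_records, ds$genes$gene_id)
  ce <- confirmed_edges(net, 2)
  prof_sub <- tf_target_profiles(ce, genes, 2)
  rebuilt <- build_regulatory_network(
    ds$edge_records[paste(ds$edge_records$tf_id, ds$edge_records$target_id) %in%
                      paste(ce$tf, ce$target), ], ds$genes$gene_id)
  expect_equal(tf_target_profiles(rebuilt, genes, 2)[names(prof_sub)],
               prof_sub)

  # fraction fields agree with a brute-force recount over the edge list
  ka <- setNames(genes$assigned_ka_ks, genes$gene_id)
  orth <- setNames(genes$ortholog_par, genes$gene_id)
  prof <- tf_target_profiles(net, genes, 3)
  for (i in seq_len(min(5, nrow(prof)))) {
    tg <- unique(net$target[net$tf == prof$tf_id[i]])
    expect_equal(prof$median_target_ka_ks[i], median(ka[tg]))
    expect_equal(prof$fraction_targets_missing[i], mean(!orth[tg]))
  }
})

test_that("partner annotation enrichment matches the 2x2 chi-square oracle", {
  # symmetric design: both endpoint classes see 50% of partners in the term
  ppi <- data.frame(gene_a = paste0("s", 1:20),
                    gene_b = paste0("o", 1:20), stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = c(paste0("s", 1:10), paste0("o", 1:10)),
                    term_id = "kinase", stringsAsFactors = FALSE)
  res <- suppressWarnings(partner_annotation_enrichment(
    ppi, paste0("s", 1:20), ann, "kinase"))
  expect_equal(res$fold, 1)
  expect_gt(res$p, 0.99)

  # enriched design: check counts, fold, and p against hand computation
  ann2 <- data.frame(gene_id = c(paste0("s", 1:4), paste0("o", 1:16)),
                     term_id = "kinase", stringsAsFactors = FALSE)
  res2 <- suppressWarnings(partner_annotation_enrichment(
    ppi, paste0("s", 1:20), ann2, "kinase"))
  tab <- res2$table
  # incidence enumeration oracle
  g <- c(ppi$gene_a, ppi$gene_b)
  partner <- c(ppi$gene_b, ppi$gene_a)
  in_sub <- g %in% paste0("s", 1:20)
  in_term <- partner %in% ann2$gene_id
  expect_equal(unname(tab[1, 1]), sum(in_sub & in_term))
  expect_equal(unname(tab[2, 1]), sum(!in_sub & in_term))
  expect_equal(res2$fold, (tab[1, 1] / sum(tab[1, ])) /
                 (tab[2, 1] / sum(tab[2, ])), ignore_attr = TRUE)
  n_tot <- sum(tab)
  chi2 <- n_tot * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rowSums(tab)) / prod(colSums(tab)) * 1
  expect_equal(unname(res2$statistic), unname(chi2))
  expect_equal(res2$p, pchisq(chi2, df = 1, lower.tail = FALSE),
               ignore_attr = TRUE)

  expect_error(partner_annotation_enrichment(ppi, character(0), ann,
                                             "kinase"), "empty")
  expect_error(partner_annotation_enrichment(ppi, "s1", ann, "absent"),
               "no genes")
})
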