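test_that("gene table TSV round trip is lossless and validated", {
  genes <- tiny_gene_table(ka = c(0.1, 0.5, NA))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(genes, path)
  back <- read_gene_table(path)
  expect_equal(as.data.frame(back), as.data.frame(genes))
  expect_true(is.na(back$ka_ks[3]))
  expect_false(back$ortholog_par[3])

  dup <- genes
  dup$gene_id <- c("g1", "g1", "g3")
  write.table(dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gene_table(path), "duplicate gene_id")
  expect_error(read_gene_table(tempfile()), "not found")
  expect_error(validate_gene_table(
    data.frame(gene_id = "a", ka_ks = -1)), "negative")
})

test_that("missing-ortholog genes get one rate above the fastest ortholog", {
  genes <- tiny_gene_table(ka = c(0.1, 0.5, NA))
  out <- assign_missing_ortholog_rate(genes)
  expect_equal(out$assigned_ka_ks, c(0.1, 0.5, 0.55))

  # no missing genes: assignment is the identity on rates
  full <- tiny_gene_table(ka = c(0.1, 0.5, 0.3))
  expect_equal(assign_missing_ortholog_rate(full)$assigned_ka_ks,
               full$ka_ks)

  # several missing genes share the identical assigned value
  two <- tiny_gene_table(ka = c(0.2, NA, NA))
  a <- assign_missing_ortholog_rate(two)$assigned_ka_ks
  expect_equal(a[2], a[3])
  expect_gt(a[2], 0.2)

  none <- tiny_gene_table(ka = c(NA, NA))
  expect_error(assign_missing_ortholog_rate(none), "no ortholog-bearing")
})

test_that("rank transform produces normalized midranks in (0, 1]", {
  expect_equal(rank_transform(c(a = 0.1, b = 0.2, c = 0.3)),
               c(a = 1/3, b = 2/3, c = 1))
  expect_equal(rank_transform(c(a = 0.5, b = 0.5)),
               c(a = 0.75, b = 0.75))
  expect_error(rank_transform(numeric(0)), "empty")

  set.seed(7)
  for (i in 1:20) {
    v <- sample(rnorm(40), 60, replace = TRUE)   # forces ties
    r <- rank_transform(v)
    expect_true(all(r > 0 & r <= 1))
    # mean of normalized ranks is (N+1)/2N; midrank sum is N(N+1)/2 exactly
    expect_equal(mean(r), (length(v) + 1) / (2 * length(v)))
    expect_equal(sum(r * length(v)), length(v) * (length(v) + 1) / 2)
    # invariant under strictly increasing transforms
    expect_equal(r, rank_transform(exp(3 * v)))
    # monotone: sorting by value sorts the ranks; ties get equal ranks
    expect_true(!is.unsorted(r[order(v)]))
    expect_equal(tapply(r, v, function(z) diff(range(z))) == 0,
                 tapply(r, v, function(z) TRUE))
  }
})

test_that("assigned missing-ortholog genes rank above all others", {
  genes <- tiny_gene_table(ka = c(0.3, 0.1, NA, NA, 0.25))
  genes <- add_property_ranks(assign_missing_ortholog_rate(genes))
  r <- genes$rank_ka_ks
  expect_true(all(r[c(3, 4)] > max(r[c(1, 2, 5)])))
  expect_equal(r[3], r[4])   # identical top midrank
})

test_that("rank-based statistics are insensitive to the assigned-rate multiplier", {
  ds <- generate_dataset(generator_config(n_genes = 400, n_tfs = 30,
                                          out_degree_min = 5,
                                          out_degree_max = 30),
                         seed = 11)
  g1 <- add_property_ranks(assign_missing_ortholog_rate(ds$genes,
                                                        multiplier = 1.1))
  g2 <- add_property_ranks(assign_missing_ortholog_rate(ds$genes,
                                                        multiplier = 2.0))
  expect_equal(g1$rank_ka_ks, g2$rank_ka_ks)
  net <- build_regulatory_network(edge_records_of(
    ds$edge_records$tf_id, ds$edge_records$target_id,
    ds$edge_records$experiment_id), ds$genes$gene_id)
  s1 <- sign_stratified_correlations(assign_edge_signs(net, ds$knockout), g1)
  s2 <- sign_stratified_correlations(assign_edge_signs(net, ds$knockout), g2)
  expect_equal(s1$rho, s2$rho)
})
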