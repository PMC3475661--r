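test_that("subset slope is the least-squares slope on genome-wide ranks", {
  x <- c(a = 0.25, b = 0.5, c = 0.75, d = 0.1, e = 0.9)
  # identity line
  expect_equal(subset_slope(x, x, c("a", "b", "c")), 1)
  # closed-form three-point case
  y <- c(a = 0.75, b = 0.25, c = 0.5, d = 0.2, e = 0.4)
  expect_equal(subset_slope(x, y, c("a", "b", "c")), -0.5)
  # flat response for tied y midranks
  y2 <- c(a = 0.4, b = 0.4, c = 0.4, d = 1, e = 0.2)
  expect_equal(subset_slope(x, y2, c("a", "b", "c")), 0)

  expect_error(subset_slope(x, y, c("a", "b")), "at least 3")
  x0 <- c(a = 0.5, b = 0.5, c = 0.5, d = 1)
  expect_error(subset_slope(x0, y, c("a", "b", "c")), "zero variance")

  # slope depends only on the subset members' genome-wide ranks
  expect_equal(subset_slope(x, y, c("a", "b", "c")),
               subset_slope(x[1:3], y[1:3], c("a", "b", "c")))
})

test_that("matched samples always satisfy the RMSD tolerance", {
  set.seed(42)
  u <- random_rank_universe(200)
  subset <- sample(names(u$x), 25)
  tx <- mean(u$x[subset]); ty <- mean(u$y[subset])
  for (method in c("swap", "rejection")) {
    sets <- sample_matched_subsets(u$x, u$y, subset, 40, tolerance = 0.02,
                                   method = method)
    expect_length(sets, 40)
    rmsd <- vapply(sets, function(s)
      sqrt(((mean(u$x[s]) - tx)^2 + (mean(u$y[s]) - ty)^2) / 2),
      numeric(1))
    expect_true(all(rmsd <= 0.02))
    expect_true(all(lengths(sets) == 25))
  }
})

test_that("a vacuous tolerance accepts every rejection draw", {
  set.seed(1)
  u <- random_rank_universe(50)
  subset <- sample(names(u$x), 10)
  sets <- sample_matched_subsets(u$x, u$y, subset, 30, tolerance = 1,
                                 method = "rejection")
  expect_equal(attr(sets, "sampler_stats")$acceptance_rate, 1)
})

test_that("slope test is deterministic under a fixed seed", {
  set.seed(9)
  u <- random_rank_universe(300)
  subset <- sample(names(u$x), 40)
  run <- function() {
    set.seed(123)
    slope_pvalue(u$x, u$y, subset, n_samples = 100, method = "swap")
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$null_slopes, r2$null_slopes)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$direction, r2$direction)
})

test_that("an empirical p of zero is reported as the 1/n bound", {
  # universe with a strong positive trend; the subset is fabricated flat,
  # far outside anything matched resampling can produce
  n <- 120
  ids <- sprintf("g%03d", 1:n)
  x <- setNames(rank_transform(seq_len(n)), ids)
  y <- x
  sub_ids <- ids[seq(10, 88, by = 6)]
  y[sub_ids] <- rev(y[sub_ids])       # slope -1 inside, +1 outside
  set.seed(4)
  res <- slope_pvalue(x, y, sub_ids, n_samples = 50, tolerance = 0.05,
                      method = "swap", direction = "flatter")
  expect_true(res$p_is_bound)
  expect_equal(res$p_value, 1 / 50)
})

test_that("direction labels follow the sign of the null trend", {
  set.seed(21)
  n <- 500
  ids <- sprintf("g%03d", 1:n)
  x <- setNames(rank_transform(rnorm(n)), ids)
  noise <- rnorm(n)
  y_neg <- setNames(rank_transform(-2 * x + noise), ids)
  sub <- sample(ids, 60)
  # negative trend: a subset slope above the null median reads "flatter"
  res <- slope_pvalue(x, y_neg, sub, n_samples = 100, direction = "auto")
  expect_true(res$direction %in% c("flatter", "steeper"))
  obs_above <- res$observed_slope > res$sampler_stats$null_median
  expect_equal(res$direction == "flatter", obs_above)
})

test_that("swap and rejection samplers draw the same null-slope law", {
  eq <- sampler_equivalence_study(n_genes = 250, subset_size = 25,
                                  n_each = 120, seed = 8)
  expect_gt(eq$ks_p, 0.01)
})
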