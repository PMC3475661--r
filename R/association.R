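#' Spearman rank correlation with pairwise-complete handling
#'
#' Thin wrapper around the standard Spearman test: rho on midranks, p from
#' the large-sample approximation. Pairs with either value missing are
#' dropped; fewer than 3 complete pairs or zero variance is an error
#' (callers that tabulate many correlates should catch it and emit the row
#' as absent rather than zero).
#'
#' @param x,y numeric vectors of equal length.
#' @param x_label,y_label labels carried into the result.
#' @return one-row data.frame: `x_label, y_label, rho, abs_rho, p, n`.
#' @export
spearman_cor <- function(x, y, x_label = "x", y_label = "y") {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("fewer than 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  data.frame(x_label = x_label, y_label = y_label,
             rho = unname(ct$estimate), abs_rho = abs(unname(ct$estimate)),
             p = ct$p.value, n = length(x), stringsAsFactors = FALSE)
}

# spearman_cor that returns NULL (row absent) on degenerate input
spearman_row <- function(x, y, x_label, y_label, extra = NULL) {
  row <- tryCatch(spearman_cor(x, y, x_label, y_label),
                  error = function(e) NULL)
  if (!is.null(row) && !is.null(extra)) row <- cbind(extra, row)
  row
}

#' Correlation panel of Ka/Ks against genomic and network properties
#'
#' For the TF set and for all proteins, Spearman correlations of Ka/Ks
#' (assigned values, missing-ortholog genes at their top rate) against:
#' expression, CAI, PPI degree, regulatory in-degree, median interactor
#' Ka/Ks (over PPI partners), median regulator Ka/Ks (over incoming TFs),
#' and — defined through the regulatory network — median target Ka/Ks and
#' the fraction of targets missing an ortholog. Target-based correlates are
#' only defined for profiled TFs, so in the all-protein panel those rows are
#' computed over the same TFs; the correlate list is structurally identical
#' for the two sets. Correlates with fewer than 3 complete pairs are
#' omitted, not reported as zero.
#'
#' @param genes a prepared `gene_table`.
#' @param net a `reg_network`.
#' @param ppi PPI edge data.frame.
#' @param min_targets minimum targets for a TF profile.
#' @param comparison species tag for ortholog flags.
#' @return tidy data.frame: `protein_set, x_label, y_label, rho, abs_rho,
#'   p, n`.
#' @export
tf_target_correlation_panel <- function(genes, net, ppi, min_targets = 3,
                                        comparison = "par") {
  ka <- setNames(genes$assigned_ka_ks, genes$gene_id)
  med_nb <- function(nb_split) {
    out <- setNames(rep(NA_real_, nrow(genes)), genes$gene_id)
    v <- vapply(nb_split, function(nb) median(ka[nb], na.rm = TRUE),
                numeric(1))
    out[names(v)] <- v
    out
  }
  e <- ppi[ppi$gene_a != ppi$gene_b, , drop = FALSE]
  interactor_ka <- med_nb(split(c(e$gene_b, e$gene_a), c(e$gene_a, e$gene_b)))
  regulator_ka <- med_nb(split(net$tf, net$target))

  profiles <- tf_target_profiles(net, genes, min_targets, comparison)
  prof_ka <- ka[profiles$tf_id]

  per_gene <- list(
    expression = genes$expression,
    cai = genes$cai,
    ppi_degree = genes$ppi_degree,
    in_degree = genes$in_degree,
    median_interactor_ka_ks = unname(interactor_ka[genes$gene_id]),
    median_regulator_ka_ks = unname(regulator_ka[genes$gene_id]))
  per_gene <- per_gene[!vapply(per_gene, is.null, logical(1))]

  sets <- list(tf = genes$is_tf, all = rep(TRUE, nrow(genes)))
  rows <- list()
  for (set_name in names(sets)) {
    sel <- sets[[set_name]]
    for (lab in names(per_gene)) {
      rows[[length(rows) + 1L]] <- spearman_row(
        per_gene[[lab]][sel], genes$assigned_ka_ks[sel], lab, "ka_ks",
        extra = data.frame(protein_set = set_name,
                           stringsAsFactors = FALSE))
    }
    # target-derived correlates exist only for profiled TFs
    for (lab in c("median_target_ka_ks", "fraction_targets_missing")) {
      rows[[length(rows) + 1L]] <- spearman_row(
        profiles[[lab]], prof_ka, lab, "ka_ks",
        extra = data.frame(protein_set = set_name,
                           stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sign-stratified TF-target co-evolution correlations
#'
#' Splits each TF's regulon by inferred regulatory sign and asks, across
#' TFs, whether TF Ka/Ks follows (i) the median Ka/Ks of activated targets,
#' (ii) the median Ka/Ks of repressed targets, and (iii, iv) the fraction of
#' activated / repressed targets missing an ortholog. A TF enters a sign
#' stratum only with at least `min_same_sign_targets` distinct targets of
#' that sign, guarding against edge-sign uncertainty.
#'
#' @param net a signed `reg_network` (see [assign_edge_signs()]).
#' @param genes a prepared `gene_table`.
#' @param min_same_sign_targets stratum membership threshold (default 5).
#' @param comparison species tag for the ortholog flag.
#' @return data.frame: `sign, property, rho, p, n_tfs` (one row per
#'   stratum x property with enough TFs; empty for an all-unsigned
#'   network).
#' @export
sign_stratified_correlations <- function(net, genes,
                                         min_same_sign_targets = 5,
                                         comparison = "par") {
  ka <- setNames(genes$assigned_ka_ks, genes$gene_id)
  has_orth <- setNames(genes[[paste0("ortholog_", comparison)]],
                       genes$gene_id)
  rows <- list()
  for (sg in c("A", "R")) {
    sub <- net[net$sign == sg, , drop = FALSE]
    if (nrow(sub) == 0) next
    targets_by_tf <- lapply(split(sub$target, sub$tf), unique)
    targets_by_tf <- lapply(targets_by_tf, intersect, x = genes$gene_id)
    keep <- vapply(targets_by_tf, length, integer(1)) >=
      min_same_sign_targets
    targets_by_tf <- targets_by_tf[keep]
    if (length(targets_by_tf) < 3) next
    tf_ka <- ka[names(targets_by_tf)]
    med_ka <- vapply(targets_by_tf, function(tg) median(ka[tg]), numeric(1))
    frac_missing <- vapply(targets_by_tf,
                           function(tg) mean(!has_orth[tg]), numeric(1))
    for (prop in c("median_target_ka_ks", "fraction_targets_missing")) {
      v <- if (prop == "median_target_ka_ks") med_ka else frac_missing
      r <- spearman_row(tf_ka, v, "tf_ka_ks", prop)
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sign = sg, property = prop, rho = r$rho, p = r$p, n_tfs = r$n,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(sign = character(), property = character(),
                      rho = numeric(), p = numeric(), n_tfs = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Degree-proportional weighted sampling without replacement
#'
#' Draws a gene set of the requested size where each gene is selected with
#' probability proportional to its regulatory in-degree, without
#' replacement (successive draws with weight renormalization). This is the
#' null model for co-regulated gene sets: random "target" sets mimic the
#' propensity of highly regulated genes to appear in regulons.
#'
#' @param ids candidate gene ids.
#' @param size number of genes to draw.
#' @param weights positive sampling weights (e.g. in-degrees), same length
#'   as `ids`.
#' @return character vector of sampled ids.
#' @export
degree_weighted_sample <- function(ids, size, weights) {
  stopifnot(length(ids) == length(weights), size <= length(ids),
            all(weights > 0))
  if (length(ids) == 1) return(rep(ids, size))
  sample(ids, size, replace = FALSE, prob = weights)
}

#' Spread of a property among co-regulated genes
#'
#' For each TF with at least `min_targets` targets possessing an ortholog
#' (and a value for the property), the observed spread is the median of
#' |value_i - value_j| over all unordered target pairs. The expected spread
#' is the mean of the same statistic over `n_null` equally sized random
#' gene sets drawn with probability proportional to regulatory in-degree
#' (see [degree_weighted_sample()]). The per-TF observed and expected
#' spreads are then compared with the Wilcoxon rank-sum test; the default
#' alternative `"less"` asks whether co-regulated genes are closer in the
#' property than expected.
#'
#' @param net a `reg_network`.
#' @param genes a prepared `gene_table`.
#' @param values named numeric vector of the gene property (e.g. assigned
#'   Ka/Ks or log read counts).
#' @param min_targets minimum qualifying targets per TF (default 3).
#' @param n_null number of null sets per TF (default 100).
#' @param comparison species tag for the ortholog flag.
#' @param alternative `wilcox.test` alternative (default `"less"`).
#' @return list of class `spread_test`: per-TF table (`tf_id, n_targets,
#'   observed, expected`), `p`, `n_null`, `alternative`.
#' @export
coregulation_spread_test <- function(net, genes, values, min_targets = 3,
                                     n_null = 100, comparison = "par",
                                     alternative = c("less", "two.sided",
                                                     "greater")) {
  alternative <- match.arg(alternative)
  has_orth <- setNames(genes[[paste0("ortholog_", comparison)]],
                       genes$gene_id)
  indeg <- in_degree(net, genes$gene_id)
  eligible <- genes$gene_id[has_orth[genes$gene_id] &
                              genes$gene_id %in% names(values)]
  eligible <- eligible[!is.na(values[eligible])]
  pool <- eligible[indeg[eligible] >= 1]
  if (length(pool) < min_targets)
    stop("no eligible gene pool for the spread test")
  pool_w <- as.numeric(indeg[pool])

  med_spread <- function(v) median(as.numeric(dist(v)))
  targets_by_tf <- lapply(split(net$target, net$tf),
                          function(t) intersect(unique(t), eligible))
  keep <- vapply(targets_by_tf, length, integer(1)) >= min_targets
  targets_by_tf <- targets_by_tf[keep]
  if (length(targets_by_tf) == 0) stop("no qualifying TFs for spread test")

  rows <- lapply(names(targets_by_tf), function(tf) {
    tg <- targets_by_tf[[tf]]
    obs <- med_spread(values[tg])
    nulls <- vapply(seq_len(n_null), function(b) {
      s <- degree_weighted_sample(pool, length(tg), pool_w)
      med_spread(values[s])
    }, numeric(1))
    data.frame(tf_id = tf, n_targets = length(tg), observed = obs,
               expected = mean(nulls), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  p <- if (all(tab$observed == tab$expected)) 1 else
    suppressWarnings(wilcox.test(tab$observed, tab$expected,
                                 alternative = alternative)$p.value)
  structure(list(table = tab, p = p, n_null = n_null,
                 alternative = alternative),
            class = "spread_test")
}

#' @export
print.spread_test <- function(x, ...) {
  cat("Co-regulation spread test over", nrow(x$table), "TFs\n")
  cat(sprintf("  median observed %.4f vs expected %.4f;  rank-sum p = %.4g (%s)\n",
              median(x$table$observed), median(x$table$expected), x$p,
              x$alternative))
  invisible(x)
}

#' Split TFs and their targets into fastest-evolving and other groups
#'
#' Ranks TFs (those with at least one target) by evolutionary rate, takes
#' the top `fast_fraction` as "fast" (ties at the quantile boundary broken
#' by gene id for determinism), and partitions their distinct targets.
#' Genes targeted by both fast and other TFs are assigned to the fast set
#' (precedence rule); `exclusive = TRUE` drops such shared genes from both
#' sets instead.
#'
#' @param net a `reg_network`.
#' @param tf_rates named numeric vector of TF evolutionary rates (assigned
#'   Ka/Ks).
#' @param fast_fraction fraction of fastest TFs (default 0.25).
#' @param exclusive drop shared targets instead of fast-set precedence.
#' @return list: `fast_tfs, other_tfs, fast_targets, other_targets`.
#' @export
fast_tf_split <- function(net, tf_rates, fast_fraction = 0.25,
                          exclusive = FALSE) {
  tfs <- intersect(names(tf_rates), unique(net$tf))
  tfs <- tfs[!is.na(tf_rates[tfs])]
  if (length(tfs) < 2) stop("need at least 2 TFs with rates and targets")
  ord <- tfs[order(-tf_rates[tfs], tfs)]
  n_fast <- max(1L, ceiling(fast_fraction * length(ord)))
  fast_tfs <- ord[seq_len(n_fast)]
  other_tfs <- ord[-seq_len(n_fast)]
  fast_targets <- unique(net$target[net$tf %in% fast_tfs])
  other_targets <- unique(net$target[net$tf %in% other_tfs])
  if (exclusive) {
    shared <- intersect(fast_targets, other_targets)
    fast_targets <- setdiff(fast_targets, shared)
    other_targets <- setdiff(other_targets, shared)
  } else {
    other_targets <- setdiff(other_targets, fast_targets)
  }
  list(fast_tfs = fast_tfs, other_tfs = other_tfs,
       fast_targets = fast_targets, other_targets = other_targets)
}

#' Category enrichment in targets of fast-evolving TFs
#'
#' For each annotation category with at least `min_term_size` members among
#' the union of the two target sets, a one-sided Fisher's exact test for
#' enrichment of the category in `fast_targets` relative to
#' `other_targets`. Fold enrichment is the ratio of within-set category
#' fractions. All tested rows are emitted; those with raw p < 0.05 are
#' flagged (no multiple-testing correction is applied).
#'
#' @param fast_targets,other_targets disjoint gene sets (resolve overlaps
#'   with [fast_tf_split()] before calling).
#' @param ann annotation map data.frame (`gene_id, term_id`).
#' @param min_term_size minimum category size among the union (default 50).
#' @return data.frame: `term_id, n_genes, n_fast, fold, p, significant`,
#'   sorted by p.
#' @export
target_set_enrichment <- function(fast_targets, other_targets, ann,
                                  min_term_size = 50) {
  if (length(fast_targets) == 0 || length(other_targets) == 0)
    stop("both target sets must be non-empty")
  if (length(intersect(fast_targets, other_targets)) > 0)
    stop("target sets must be disjoint")
  universe <- c(fast_targets, other_targets)
  ann <- ann[ann$gene_id %in% universe, , drop = FALSE]
  term_sizes <- table(ann$term_id)
  terms <- names(term_sizes)[term_sizes >= min_term_size]
  if (length(terms) == 0)
    return(data.frame(term_id = character(), n_genes = integer(),
                      n_fast = integer(), fold = numeric(), p = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  nf <- length(fast_targets); no <- length(other_targets)
  rows <- lapply(terms, function(term) {
    tg <- unique(ann$gene_id[ann$term_id == term])
    a <- length(intersect(fast_targets, tg))
    c_ <- length(intersect(other_targets, tg))
    tab <- matrix(c(a, nf - a, c_, no - c_), nrow = 2, byrow = TRUE)
    p <- fisher.test(tab, alternative = "greater")$p.value
    fold <- (a / nf) / (c_ / no)
    data.frame(term_id = term, n_genes = length(tg), n_fast = a,
               fold = fold, p = p, significant = p < 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binned median profile with bootstrap standard errors
#'
#' Histogram-style summary used for plotting: points are split into
#' `n_bins` equal-count bins along x (by x order), and each bin reports the
#' median of y — robust to outliers and to the value assigned to
#' missing-ortholog genes — with a standard error estimated from `n_boot`
#' bootstrap resamples of the bin, plus the member count.
#'
#' @param x,y paired numeric vectors.
#' @param n_bins number of equal-count bins (>= 2).
#' @param n_boot bootstrap resamples for the SE of the median (default 100).
#' @return data.frame: `bin, x_lo, x_hi, median_y, se, n`.
#' @export
binned_median_profile <- function(x, y, n_bins = 5, n_boot = 100) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (length(x) < n_bins) stop("fewer points than bins")
  ord <- order(x)
  bin_of <- ceiling(seq_along(ord) * n_bins / length(ord))
  rows <- lapply(seq_len(n_bins), function(b) {
    ids <- ord[bin_of == b]
    yb <- y[ids]
    boots <- vapply(seq_len(n_boot), function(i)
      median(yb[sample.int(length(yb), replace = TRUE)]), numeric(1))
    data.frame(bin = b, x_lo = min(x[ids]), x_hi = max(x[ids]),
               median_y = median(yb), se = sd(boots), n = length(yb))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
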