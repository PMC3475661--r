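#' Read regulatory edge records
#'
#' Edge-record TSV dialect: columns `tf_id, target_id, experiment_id, source`
#' with `source` in `{chip, curated}`. One row per (edge, experiment)
#' observation; independent experiments reporting the same edge are collapsed
#' by [build_regulatory_network()] into a support count.
#'
#' @param path TSV path.
#' @return data.frame of raw edge records.
#' @export
read_edge_records <- function(path) {
  if (!file.exists(path)) stop("edge record file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("tf_id", "target_id", "experiment_id", "source")
  if (!all(need %in% names(df)))
    stop("edge records must have columns: ", paste(need, collapse = ", "))
  df
}

#' Build a directed regulatory network from edge records
#'
#' Collapses duplicate (tf, target) records into single edges whose `support`
#' is the number of distinct experiment identifiers reporting them. Records
#' naming genes outside the supplied gene universe are dropped with a
#' warning; the dropped count is kept in the `dropped_records` attribute.
#' Edge signs start out `"U"` (unsigned) until [assign_edge_signs()] runs.
#'
#' @param records data.frame with `tf_id, target_id, experiment_id, source`.
#' @param gene_universe optional character vector of valid gene ids.
#' @return a `reg_network`: data.frame with columns
#'   `tf, target, source, support, sign`.
#' @export
build_regulatory_network <- function(records, gene_universe = NULL) {
  stopifnot(is.data.frame(records))
  n_dropped <- 0L
  if (!is.null(gene_universe) && nrow(records) > 0) {
    keep <- records$tf_id %in% gene_universe &
      records$target_id %in% gene_universe
    n_dropped <- sum(!keep)
    if (n_dropped > 0) {
      warning(n_dropped, " edge record(s) referenced genes outside the ",
              "universe and were dropped")
      records <- records[keep, , drop = FALSE]
    }
  }
  if (nrow(records) == 0) {
    edges <- data.frame(tf = character(), target = character(),
                        source = character(), support = integer(),
                        sign = character(), stringsAsFactors = FALSE)
  } else {
    key <- paste(records$tf_id, records$target_id, records$source,
                 sep = "\r")
    support <- vapply(split(records$experiment_id, key),
                      function(e) length(unique(e)), integer(1))
    parts <- strsplit(names(support), "\r", fixed = TRUE)
    edges <- data.frame(
      tf = vapply(parts, `[`, "", 1L),
      target = vapply(parts, `[`, "", 2L),
      source = vapply(parts, `[`, "", 3L),
      support = as.integer(support),
      sign = "U",
      stringsAsFactors = FALSE)
    edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(edges, class = c("reg_network", "data.frame"),
            dropped_records = n_dropped)
}

#' @export
print.reg_network <- function(x, ...) {
  cat("Regulatory network: ", nrow(x), " edges, ",
      length(unique(x$tf)), " TFs, ", length(unique(x$target)),
      " targets\n", sep = "")
  signs <- table(factor(x$sign, levels = c("A", "R", "U")))
  cat("  signs: ", signs[["A"]], " activating, ", signs[["R"]],
      " repressive, ", signs[["U"]], " unsigned\n", sep = "")
  invisible(x)
}

#' Distinct-target out-degree per TF
#'
#' @param net a `reg_network`.
#' @param ids optional gene ids to report (zero-filled).
#' @return named integer vector of distinct-target counts.
#' @export
out_degree <- function(net, ids = NULL) {
  d <- vapply(split(net$target, net$tf), function(t) length(unique(t)),
              integer(1))
  if (is.null(ids)) return(d)
  setNames(ifelse(ids %in% names(d), d[ids], 0L), ids)
}

#' Distinct-regulator in-degree per gene
#'
#' @inheritParams out_degree
#' @return named integer vector of distinct-regulator counts.
#' @export
in_degree <- function(net, ids = NULL) {
  d <- vapply(split(net$tf, net$target), function(t) length(unique(t)),
              integer(1))
  if (is.null(ids)) return(d)
  setNames(ifelse(ids %in% names(d), d[ids], 0L), ids)
}

#' Restrict a network to confirmed edges
#'
#' Confirmed edges (CE) are those supported by `min_support` or more
#' independent experiments — a guard against false-positive interactions
#' from single high-throughput screens.
#'
#' @param net a `reg_network` built from ChIP-source records.
#' @param min_support minimum number of independent experiments (default 2).
#' @return the filtered `reg_network`.
#' @export
confirmed_edges <- function(net, min_support = 2) {
  out <- net[net$support >= min_support, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(net),
            dropped_records = attr(net, "dropped_records"))
}

#' Per-TF aggregate profiles over target genes
#'
#' For every TF with at least `min_targets` distinct targets, summarizes the
#' evolutionary properties of its regulon: median target Ka/Ks (over assigned
#' values, so missing-ortholog targets enter at their top-assigned rate),
#' the fraction of targets missing an ortholog in the comparison species,
#' the fractions of targets in the genome-wide top 20% of conservation
#' (Ka/Ks rank <= 0.2), PPI degree and expression (rank >= 0.8), the median
#' target expression, and the TF's own regulatory in-degree. The
#' missing-ortholog fraction is only reported for TFs with >= 3 targets
#' regardless of `min_targets`, because ortholog loss affects only a small
#' fraction of genes and the estimate is too coarse below that.
#'
#' @param net a `reg_network`.
#' @param genes a prepared `gene_table` (see [prepare_gene_table()]): must
#'   carry `assigned_ka_ks` and, for the top-20% fractions, the
#'   corresponding rank columns.
#' @param min_targets minimum distinct targets for a profile (3 for the full
#'   ChIP network; 2 is customary for the sparser confirmed-edge network).
#' @param comparison species tag for the ortholog flag.
#' @return data.frame of class `tf_profiles`, one row per qualifying TF.
#' @export
tf_target_profiles <- function(net, genes, min_targets = 3,
                               comparison = "par") {
  if (!"assigned_ka_ks" %in% names(genes))
    stop("genes must carry assigned_ka_ks; run prepare_gene_table() first")
  flag_col <- paste0("ortholog_", comparison)
  ka <- setNames(genes$assigned_ka_ks, genes$gene_id)
  expr <- if ("expression" %in% names(genes))
    setNames(genes$expression, genes$gene_id) else NULL
  has_orth <- setNames(genes[[flag_col]], genes$gene_id)
  rk_ka <- if ("rank_ka_ks" %in% names(genes))
    setNames(genes$rank_ka_ks, genes$gene_id) else NULL
  rk_ppi <- if ("rank_ppi_degree" %in% names(genes))
    setNames(genes$rank_ppi_degree, genes$gene_id) else NULL
  rk_expr <- if ("rank_expression" %in% names(genes))
    setNames(genes$rank_expression, genes$gene_id) else NULL
  indeg <- in_degree(net, genes$gene_id)

  targets_by_tf <- lapply(split(net$target, net$tf), unique)
  targets_by_tf <- lapply(targets_by_tf, intersect, x = genes$gene_id)
  keep <- vapply(targets_by_tf, length, integer(1)) >= min_targets
  targets_by_tf <- targets_by_tf[keep]
  if (length(targets_by_tf) == 0) {
    out <- data.frame(tf_id = character(), n_targets = integer(),
                      median_target_ka_ks = numeric(),
                      fraction_targets_missing = numeric(),
                      fraction_targets_top20_conserved = numeric(),
                      fraction_targets_top20_interactive = numeric(),
                      fraction_targets_top20_expressed = numeric(),
                      median_target_expression = numeric(),
                      in_degree = integer(), stringsAsFactors = FALSE)
    class(out) <- c("tf_profiles", "data.frame")
    return(out)
  }

  frac20 <- function(r, tg, top) {
    if (is.null(r)) return(NA_real_)
    v <- r[tg]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    if (top) mean(v >= 0.8) else mean(v <= 0.2)
  }
  rows <- lapply(names(targets_by_tf), function(tf) {
    tg <- targets_by_tf[[tf]]
    data.frame(
      tf_id = tf,
      n_targets = length(tg),
      median_target_ka_ks = median(ka[tg], na.rm = TRUE),
      fraction_targets_missing =
        if (length(tg) >= 3) mean(!has_orth[tg]) else NA_real_,
      fraction_targets_top20_conserved = frac20(rk_ka, tg, top = FALSE),
      fraction_targets_top20_interactive = frac20(rk_ppi, tg, top = TRUE),
      fraction_targets_top20_expressed = frac20(rk_expr, tg, top = TRUE),
      median_target_expression =
        if (is.null(expr)) NA_real_ else median(expr[tg], na.rm = TRUE),
      in_degree = unname(indeg[tf]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tf_profiles", "data.frame")
  out
}

#' Read an undirected PPI edge table
#'
#' Columns: `gene_a, gene_b, n_reports`.
#'
#' @param path TSV path.
#' @return data.frame of PPI edges.
#' @export
read_ppi_table <- function(path) {
  if (!file.exists(path)) stop("PPI file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(df)))
    stop("PPI table must have columns gene_a, gene_b")
  df
}

#' PPI degree (distinct interaction partners) per gene
#'
#' Self-interactions are not counted as partners.
#'
#' @param ppi PPI edge data.frame.
#' @param ids optional gene ids to report (zero-filled).
#' @return named integer vector.
#' @export
ppi_degrees <- function(ppi, ids = NULL) {
  e <- ppi[ppi$gene_a != ppi$gene_b, , drop = FALSE]
  ends <- c(e$gene_a, e$gene_b)
  partners <- c(e$gene_b, e$gene_a)
  d <- vapply(split(partners, ends), function(p) length(unique(p)),
              integer(1))
  if (is.null(ids)) return(d)
  setNames(ifelse(ids %in% names(d), d[ids], 0L), ids)
}

#' Read a flat gene-to-category annotation map
#'
#' Columns: `gene_id, term_id`, one membership per row. Categories are flat
#' sets (no ontology-graph propagation).
#'
#' @param path TSV path.
#' @return data.frame with `gene_id, term_id`.
#' @export
read_annotation_map <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(df)))
    stop("annotation map must have columns gene_id, term_id")
  df
}

#' Annotation enrichment among PPI partners of a gene subset
#'
#' Asks whether interaction partners of genes in `subset` are enriched for a
#' functional category relative to partners of other genes — e.g. whether a
#' greater fraction of TF interactions involve kinases. Each undirected PPI
#' edge contributes two directed incidences (gene, partner); incidences are
#' cross-classified by (gene in subset) x (partner annotated with `term`)
#' and tested with a 1-df chi-square test without continuity correction.
#' A warning is issued when any expected cell count falls below 5.
#'
#' @param ppi PPI edge data.frame.
#' @param subset character vector of gene ids (e.g. the TF set).
#' @param ann annotation map data.frame.
#' @param term category identifier to test.
#' @return list with `fold` (subset partner fraction over non-subset
#'   partner fraction), `p`, `statistic` and the 2x2 `table`.
#' @export
partner_annotation_enrichment <- function(ppi, subset, ann, term) {
  if (length(subset) == 0) stop("empty gene subset")
  term_genes <- unique(ann$gene_id[ann$term_id == term])
  if (length(term_genes) == 0)
    stop("term ", term, " annotates no genes")
  e <- ppi[ppi$gene_a != ppi$gene_b, , drop = FALSE]
  g <- c(e$gene_a, e$gene_b)
  partner <- c(e$gene_b, e$gene_a)
  in_sub <- g %in% subset
  in_term <- partner %in% term_genes
  if (!any(in_term))
    stop("term ", term, " annotates no PPI partners; fold undefined")
  tab <- matrix(c(sum(in_sub & in_term), sum(in_sub & !in_term),
                  sum(!in_sub & in_term), sum(!in_sub & !in_term)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("subset", "other"),
                                c("in_term", "not_in_term")))
  if (sum(in_sub) == 0) stop("subset has no PPI incidences")
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts < 5))
    warning("expected cell count below 5; chi-square approximation is poor")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  fold <- (tab[1, 1] / sum(tab[1, ])) / (tab[2, 1] / sum(tab[2, ]))
  list(fold = unname(fold), p = ct$p.value,
       statistic = unname(ct$statistic), table = tab)
}
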