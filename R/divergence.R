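#' Reads-per-million normalization with an expression floor
#'
#' Divides each gene's read count by the number of millions of reads in the
#' sample, then fixes the lowest possible expression at `floor` RPM so that
#' fold changes involving unexpressed genes stay finite. Before flooring,
#' the per-sample RPM values sum to exactly 10^6.
#'
#' @param counts nonnegative numeric vector of read counts (named by gene).
#' @param floor minimum RPM (default 1).
#' @return numeric vector of floored RPM values.
#' @export
rpm_normalize <- function(counts, floor = 1) {
  if (any(counts < 0)) stop("negative read counts")
  total <- sum(counts)
  if (total <= 0) stop("all-zero sample: cannot normalize")
  pmax(counts * 1e6 / total, floor)
}

#' Between-species log2 expression fold changes
#'
#' Builds the per-ortholog-pair divergence table: log2 fold change of
#' floored RPM values between the two species (logging brings the fold
#' change distribution closer to normal) and its absolute value. Genes
#' without an ortholog pair are excluded; genes floored in both species get
#' a fold change of 0.
#'
#' @param rpm_a,rpm_b named RPM vectors (already floored) for the two
#'   species.
#' @param orthologs named character vector mapping species-a gene ids to
#'   species-b gene ids; by default genes are matched by shared names.
#' @return data.frame of class `divergence_table`: `gene_a, gene_b, rpm_a,
#'   rpm_b, log2_fc, abs_log2_fc`.
#' @export
log2_fold_changes <- function(rpm_a, rpm_b, orthologs = NULL) {
  if (is.null(orthologs)) {
    common <- intersect(names(rpm_a), names(rpm_b))
    orthologs <- setNames(common, common)
  }
  a_ids <- names(orthologs)
  b_ids <- unname(orthologs)
  keep <- a_ids %in% names(rpm_a) & b_ids %in% names(rpm_b)
  a_ids <- a_ids[keep]; b_ids <- b_ids[keep]
  if (anyDuplicated(a_ids) || anyDuplicated(b_ids))
    stop("ortholog map must be one-to-one on included pairs")
  lfc <- log2(rpm_a[a_ids] / rpm_b[b_ids])
  out <- data.frame(gene_a = a_ids, gene_b = b_ids,
                    rpm_a = unname(rpm_a[a_ids]),
                    rpm_b = unname(rpm_b[b_ids]),
                    log2_fc = unname(lfc), abs_log2_fc = abs(unname(lfc)),
                    stringsAsFactors = FALSE)
  class(out) <- c("divergence_table", "data.frame")
  out
}

#' Read a two-species ortholog count table
#'
#' Columns: `gene_id_a, count_a, gene_id_b, count_b`, one ortholog pair per
#' row.
#'
#' @param path TSV path.
#' @return data.frame of paired counts.
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id_a", "count_a", "gene_id_b", "count_b")
  if (!all(need %in% names(df)))
    stop("counts table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Do targets of fast-evolving TFs diverge more in expression?
#'
#' Unpaired t-test (Welch by default) comparing absolute log2 expression
#' fold changes between targets of the fastest-evolving TFs (top
#' `fast_fraction` by rate) and targets of the remaining TFs. Target group
#' membership follows [fast_tf_split()] (fast-set precedence for shared
#' targets). The test statistic is invariant to swapping the species order
#' since it uses absolute fold changes.
#'
#' @param div a `divergence_table` (see [log2_fold_changes()]); `gene_a`
#'   ids must match the regulatory network's gene ids.
#' @param net a `reg_network` (typically the confirmed-edge network).
#' @param tf_rates named numeric vector of TF evolutionary rates.
#' @param fast_fraction fraction of fastest TFs (default 0.25).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return list: `t, p, mean_fast, mean_other, n_fast, n_other, fast_tfs`.
#' @export
divergence_ttest <- function(div, net, tf_rates, fast_fraction = 0.25,
                             var_equal = FALSE) {
  split_ <- fast_tf_split(net, tf_rates, fast_fraction)
  fast_vals <- div$abs_log2_fc[div$gene_a %in% split_$fast_targets]
  other_vals <- div$abs_log2_fc[div$gene_a %in% split_$other_targets]
  if (length(fast_vals) < 2 || length(other_vals) < 2)
    stop("each target group needs at least 2 genes with fold changes")
  if (sd(c(fast_vals, other_vals)) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- t.test(fast_vals, other_vals, var.equal = var_equal)
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_fast = mean(fast_vals), mean_other = mean(other_vals),
       n_fast = length(fast_vals), n_other = length(other_vals),
       fast_tfs = split_$fast_tfs)
}
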