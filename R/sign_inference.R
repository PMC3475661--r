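#' Read a TF-knockout X-score matrix
#'
#' X scores are confidence-weighted log expression ratios of knockout versus
#' wild type: rows are target genes, columns are knocked-out TFs, empty
#' cells are missing. The matrix layout guarantees at most one X per
#' (TF, gene) pair.
#'
#' @param path TSV path; first column `gene_id`, remaining columns named by
#'   knocked-out TF.
#' @return numeric matrix, rownames = genes, colnames = TFs.
#' @export
read_knockout_matrix <- function(path) {
  if (!file.exists(path)) stop("knockout matrix file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("", "NA"), check.names = FALSE)
  if (names(df)[1] != "gene_id")
    stop("knockout matrix must have gene_id as its first column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' Write a knockout X-score matrix to TSV
#'
#' @param ko numeric matrix (genes x TFs).
#' @param path output path.
#' @export
write_knockout_matrix <- function(ko, path) {
  df <- data.frame(gene_id = rownames(ko), ko, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Infer regulatory edge signs from TF-knockout expression
#'
#' For edges whose (TF, target) pair has an X score of absolute value
#' strictly greater than `threshold`, the regulatory mode is inferred from
#' the direction of the target's expression change when its TF is removed.
#' Under the default `"ko_over_wt"` orientation (X = log ratio of knockout
#' over wild type), a drop in target expression (X < -threshold) means the
#' TF was activating it; a rise (X > +threshold) means repression. Edges
#' with |X| <= threshold or no X available remain unsigned and are retained.
#' The orientation flag accommodates source datasets logged the other way.
#'
#' Assignment is idempotent, independent of edge order, and monotone in the
#' threshold: raising it only converts signed edges to unsigned.
#'
#' @param net a `reg_network`.
#' @param ko knockout X-score matrix (genes x TFs).
#' @param threshold absolute X score that must be exceeded (strict, default 1).
#' @param orientation `"ko_over_wt"` (default) or `"wt_over_ko"`.
#' @return the network with `sign` in `{A, R, U}` filled in.
#' @export
assign_edge_signs <- function(net, ko, threshold = 1,
                              orientation = c("ko_over_wt", "wt_over_ko")) {
  orientation <- match.arg(orientation)
  x <- rep(NA_real_, nrow(net))
  has <- net$tf %in% colnames(ko) & net$target %in% rownames(ko)
  if (any(has))
    x[has] <- ko[cbind(match(net$target[has], rownames(ko)),
                       match(net$tf[has], colnames(ko)))]
  if (orientation == "wt_over_ko") x <- -x
  sign <- rep("U", nrow(net))
  sign[!is.na(x) & x < -threshold] <- "A"
  sign[!is.na(x) & x > threshold] <- "R"
  net$sign <- sign
  net
}

#' Split a signed network into activating and repressive subnetworks
#'
#' Partitions the signed edges; unsigned edges belong to neither output, so
#' `|activating| + |repressive| + |unsigned| = |edges|`.
#'
#' @param net a `reg_network` with signs assigned.
#' @return list with `activating` and `repressive` networks.
#' @export
split_by_sign <- function(net) {
  strip <- function(e) {
    rownames(e) <- NULL
    structure(e, class = class(net),
              dropped_records = attr(net, "dropped_records"))
  }
  list(activating = strip(net[net$sign == "A", , drop = FALSE]),
       repressive = strip(net[net$sign == "R", , drop = FALSE]))
}
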