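#' Read a per-gene property table
#'
#' The gene table is the shared substrate of all analyses: one row per
#' protein-coding gene with its evolutionary rate (Ka/Ks against the closest
#' comparison species), mRNA expression level, codon adaptation index (CAI),
#' a TF flag and ortholog-presence flags per comparison species. Ka/Ks is
#' absent (empty field or `NA`) for genes with no ortholog in the primary
#' comparison species; see [assign_missing_ortholog_rate()].
#'
#' Expected tab-separated columns: `gene_id, ka_ks, expression, cai, is_tf,
#' ortholog_par, ortholog_mik` (booleans encoded 0/1, missing `ka_ks` empty).
#'
#' @param path path to a TSV file.
#' @return a validated `data.frame` of class `gene_table`.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("gene table file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  for (col in c("is_tf", "ortholog_par", "ortholog_mik"))
    if (col %in% names(df)) df[[col]] <- as.logical(as.integer(df[[col]]))
  validate_gene_table(df)
}

#' Write a gene table to TSV
#'
#' Inverse of [read_gene_table()]: booleans are written as 0/1 and missing
#' `ka_ks` as an empty field, so a write-then-read round trip reproduces the
#' table.
#'
#' @param genes a `gene_table` data.frame.
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes
  for (col in c("is_tf", "ortholog_par", "ortholog_mik"))
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

validate_gene_table <- function(df) {
  if (!"gene_id" %in% names(df)) stop("gene table must have a gene_id column")
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in gene table: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  for (col in c("ka_ks", "expression", "cai")) {
    if (!col %in% names(df)) next
    if (is.logical(df[[col]]) && all(is.na(df[[col]])))
      df[[col]] <- as.numeric(df[[col]])   # all-missing column
    if (!is.numeric(df[[col]]))
      stop("column ", col, " could not be parsed as numeric")
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop("negative values in column ", col)
  }
  if ("cai" %in% names(df) && any(df$cai > 1, na.rm = TRUE))
    stop("cai values must lie in [0, 1]")
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Assign a Ka/Ks value to genes lacking an ortholog
#'
#' Genes with no ortholog in the comparison species carry no measurable
#' substitution rate but represent the extreme of sequence divergence (lost
#' in the comparison species or lineage-specifically gained). They are all
#' assigned one common value strictly above the fastest-evolving
#' ortholog-bearing gene, so that downstream rank transforms place them in a
#' tied block at the top of the Ka/Ks ranking. Median- and rank-based
#' statistics are insensitive to the exact value; the multiplier is exposed
#' for sensitivity checks.
#'
#' @param genes a `gene_table`.
#' @param comparison species tag, `"par"` or `"mik"`; selects the
#'   `ortholog_<comparison>` flag column.
#' @param multiplier assigned value is `max(ka_ks) * multiplier` over
#'   ortholog-bearing genes; must be > 1.
#' @return the gene table with an `assigned_ka_ks` column; ortholog-bearing
#'   genes keep their measured value unchanged.
#' @export
assign_missing_ortholog_rate <- function(genes, comparison = "par",
                                         multiplier = 1.1) {
  stopifnot(multiplier > 1)
  flag_col <- paste0("ortholog_", comparison)
  if (!flag_col %in% names(genes))
    stop("gene table lacks column ", flag_col)
  known <- !is.na(genes$ka_ks) & genes[[flag_col]]
  if (!any(known))
    stop("no ortholog-bearing genes with a Ka/Ks value; cannot assign")
  top <- max(genes$ka_ks[known]) * multiplier
  genes$assigned_ka_ks <- ifelse(known, genes$ka_ks, top)
  genes
}

#' Normalized midrank transform
#'
#' Transforms values into genome-wide normalized ranks: ascending midranks
#' (average ranks for ties) divided by the number of non-missing values, so
#' outputs lie in (0, 1] and tied inputs receive equal output. Downstream
#' slope tests use these ranks unmodified for any subset, rather than
#' re-ranking within the subset, so subset slopes remain comparable to the
#' genome-wide slope.
#'
#' Missing values stay missing and do not consume ranks.
#'
#' @param values a (optionally named) numeric vector.
#' @return numeric vector of the same shape with ranks in (0, 1].
#' @export
rank_transform <- function(values) {
  if (length(values) == 0) stop("rank_transform: empty input")
  ok <- !is.na(values)
  out <- rep(NA_real_, length(values))
  out[ok] <- rank(values[ok], ties.method = "average") / sum(ok)
  names(out) <- names(values)
  out
}

#' Add normalized-rank columns for gene properties
#'
#' For each property column present in the table, appends
#' `rank_<property>` computed by [rank_transform()] over the genes carrying
#' that property (genes missing a property get `NA` and are excluded
#' pairwise downstream, never imputed). By convention `rank_ka_ks` ranks
#' `assigned_ka_ks` when present (i.e. after the missing-ortholog
#' assignment) and raw `ka_ks` otherwise.
#'
#' @param genes a `gene_table`.
#' @param properties character vector of property columns to rank.
#' @return the gene table with rank columns appended.
#' @export
add_property_ranks <- function(genes,
                               properties = c("ka_ks", "expression", "cai",
                                              "ppi_degree", "in_degree")) {
  for (prop in properties) {
    src <- if (prop == "ka_ks" && "assigned_ka_ks" %in% names(genes))
      "assigned_ka_ks" else prop
    if (!src %in% names(genes)) next
    genes[[paste0("rank_", prop)]] <- rank_transform(genes[[src]])
  }
  genes
}

#' Prepare a gene table for network analyses
#'
#' Convenience wrapper: applies the missing-ortholog Ka/Ks assignment,
#' attaches PPI degree and regulatory in-degree columns when networks are
#' supplied, and computes all normalized rank columns.
#'
#' @param genes a `gene_table`.
#' @param ppi optional PPI edge data.frame (see [read_ppi_table()]).
#' @param net optional regulatory network (see [build_regulatory_network()]).
#' @param comparison species tag for the ortholog flag.
#' @param multiplier missing-ortholog assignment multiplier.
#' @return gene table with `assigned_ka_ks`, degree and rank columns.
#' @export
prepare_gene_table <- function(genes, ppi = NULL, net = NULL,
                               comparison = "par", multiplier = 1.1) {
  genes <- assign_missing_ortholog_rate(genes, comparison, multiplier)
  if (!is.null(ppi))
    genes$ppi_degree <- ppi_degrees(ppi, genes$gene_id)
  if (!is.null(net))
    genes$in_degree <- in_degree(net, genes$gene_id)
  add_property_ranks(genes)
}
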