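# Small in-code fixtures shared across test files.

# minimal gene table with controllable Ka/Ks and ortholog flags
tiny_gene_table <- function(ka = c(0.1, 0.5, NA),
                            ids = paste0("g", seq_along(ka)),
                            is_tf = rep(FALSE, length(ka)),
                            expression = seq_along(ka) * 10,
                            ortholog = !is.na(ka)) {
  validate_gene_table(data.frame(
    gene_id = ids, ka_ks = as.numeric(ka), expression = expression,
    cai = seq(0.2, 0.8, length.out = length(ka)),
    is_tf = is_tf, ortholog_par = ortholog, ortholog_mik = ortholog,
    stringsAsFactors = FALSE))
}

# edge records: one row per (edge, experiment)
edge_records_of <- function(tf, target, experiment = "E1",
                            source = "chip") {
  data.frame(tf_id = tf, target_id = target, experiment_id = experiment,
             source = source, stringsAsFactors = FALSE)
}

# a reg_network built directly from tf/target (one experiment each)
net_of <- function(tf, target, sign = NULL) {
  net <- build_regulatory_network(edge_records_of(tf, target))
  if (!is.null(sign)) {
    key <- paste(tf, target, sep = "\r")
    net$sign <- sign[match(paste(net$tf, net$target, sep = "\r"), key)]
  }
  net
}

# a small universe of named normalized ranks with no x-y association
random_rank_universe <- function(n, prefix = "g") {
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  list(x = setNames(rank_transform(rnorm(n)), ids),
       y = setNames(rank_transform(rnorm(n)), ids))
}

# brute-force one-sided (enrichment) Fisher p by hypergeometric enumeration
fisher_enum_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  xs <- max(0, k - n):min(k, m)
  probs <- exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k))
  sum(probs[xs >= a])
}

# Spearman via the classic d^2 formula (untied data only)
spearman_d2 <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
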