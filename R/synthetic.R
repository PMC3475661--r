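#' Configuration for the synthetic data generator
#'
#' Defines the statistical structure of a synthetic yeast-like dataset:
#' correlated gene properties (expression, CAI, Ka/Ks, PPI degree), a TF
#' subset with its own trend parameters and lower expression, a TF-to-target
#' regulatory network in which activated targets' Ka/Ks is coupled to their
#' TF's Ka/Ks while repressed targets' is not, ortholog-loss probabilities
#' increasing with regulator rate, knockout X scores consistent with edge
#' signs, and two-species read counts whose divergence grows with regulator
#' rate. Couplings are realized through a rank-targeted Gaussian copula
#' (latent correlated normals mapped through marginal quantile functions),
#' so configured Spearman-scale couplings are achieved without distorting
#' the marginals. Every parameter lives here and nowhere else; the
#' generated ground truth is emitted alongside the data and never consumed
#' by analysis stages.
#'
#' Slope parameters are rank-space slopes (equivalently Spearman
#' correlations at the genome scale). `activated_coupling` and
#' `repressed_coupling` are calibrated so that the TF-level statistic the
#' analysis estimates — the Spearman correlation between TF Ka/Ks and the
#' *median* Ka/Ks of same-sign targets — recovers the configured value; a
#' per-TF shared module component plus an idiosyncratic share
#' (`idiosyncratic_share`) makes that calibration independent of regulon
#' size to first order.
#'
#' @param n_genes number of protein-coding genes (default 2000, a
#'   desk-scale genome; raise towards 6000 for a full-genome emulation).
#' @param n_tfs number of transcription factors (default 174).
#' @param expression_meanlog,expression_sdlog log-normal mRNA abundance
#'   parameters (arbitrary RPM-like units).
#' @param ka_meanlog,ka_sdlog log-normal Ka/Ks marginal parameters.
#' @param genome_slope_expression rank-space slope of Ka/Ks on expression
#'   for generic genes (default -0.5).
#' @param genome_slope_ppi rank-space slope of Ka/Ks on PPI degree
#'   (default -0.3).
#' @param tf_trend_multiplier scales the genome slopes for the TF subset
#'   (default 0.3: TF trends much flatter).
#' @param tf_expression_shift latent-normal shift of TF expression
#'   (default -0.8: TFs are lowly expressed).
#' @param cai_expression_cor latent correlation of CAI with expression.
#' @param ppi_degree_min,ppi_degree_alpha,ppi_degree_max discrete Pareto
#'   marginal for PPI degree.
#' @param out_degree_min,out_degree_max,out_degree_alpha truncated discrete
#'   power law for TF out-degree. The default range 30-200 reflects
#'   ChIP-derived regulons (thousands of signable edges over ~10^2 TFs).
#' @param tf_target_weight sampling weight multiplier for TF genes as
#'   regulatory targets.
#' @param tf_on_tf_fast_bias extra TF-target weight proportional to the
#'   regulator's Ka/Ks rank (fast TFs preferentially regulate other TFs).
#' @param activated_coupling TF-level Spearman coupling between TF Ka/Ks
#'   and median activated-target Ka/Ks (default 0.3).
#' @param repressed_coupling same for repressed targets (default 0).
#' @param idiosyncratic_share share of target Ka/Ks module variance that is
#'   target-specific rather than shared within the regulon (default 0.3).
#' @param sign_split fraction of regulatory edges that are activating
#'   (default 0.65).
#' @param missing_fraction_base baseline probability that a gene lacks an
#'   ortholog in the comparison species (default 0.1).
#' @param missing_vs_tf_rate_coupling linear modulation of the missing
#'   probability by the primary activating regulator's Ka/Ks rank.
#' @param xscore_mu,xscore_noise_sd knockout X-score location (sign times
#'   mu) and noise for true edges.
#' @param xscore_background_sd X-score noise for non-edges.
#' @param ko_coverage fraction of TFs with knockout data (default 0.78,
#'   i.e. ~135 of 174).
#' @param n_experiments,redetect_prob per-edge experiment support: support
#'   is 1 plus Binomial(`n_experiments` - 1, `redetect_prob`) re-detections.
#' @param count_depth expected reads per expression unit for the
#'   two-species count tables.
#' @param divergence_scale baseline SD of the between-species log2
#'   expression shift.
#' @param divergence_rate_coupling growth of that SD with the regulator
#'   Ka/Ks rank (1 = doubled scale for targets of the fastest TFs).
#' @param n_terms,term_size_min,term_size_max annotation categories and
#'   their size range.
#' @param niche_term_bias odds multiplier with which niche terms prefer
#'   targets of fast TFs (and core terms prefer other targets).
#' @param fast_fraction fraction of TFs counted as fast evolving.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 2000,
                             n_tfs = 174,
                             expression_meanlog = 3,
                             expression_sdlog = 1.5,
                             ka_meanlog = log(0.12),
                             ka_sdlog = 0.6,
                             genome_slope_expression = -0.5,
                             genome_slope_ppi = -0.3,
                             tf_trend_multiplier = 0.3,
                             tf_expression_shift = -0.8,
                             cai_expression_cor = 0.9,
                             ppi_degree_min = 1,
                             ppi_degree_alpha = 2.2,
                             ppi_degree_max = 300,
                             out_degree_min = 30,
                             out_degree_max = 200,
                             out_degree_alpha = 2,
                             tf_target_weight = 1.5,
                             tf_on_tf_fast_bias = 1,
                             activated_coupling = 0.3,
                             repressed_coupling = 0,
                             idiosyncratic_share = 0.3,
                             sign_split = 0.65,
                             missing_fraction_base = 0.1,
                             missing_vs_tf_rate_coupling = 1,
                             xscore_mu = 2,
                             xscore_noise_sd = 0.5,
                             xscore_background_sd = 0.3,
                             ko_coverage = 0.78,
                             n_experiments = 3,
                             redetect_prob = 0.4,
                             count_depth = 50,
                             divergence_scale = 0.5,
                             divergence_rate_coupling = 1,
                             n_terms = 30,
                             term_size_min = 30,
                             term_size_max = 120,
                             niche_term_bias = 3,
                             fast_fraction = 0.25) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_tfs < cfg$n_genes,
            cfg$sign_split >= 0, cfg$sign_split <= 1,
            cfg$missing_fraction_base >= 0, cfg$missing_fraction_base <= 1,
            cfg$ko_coverage >= 0, cfg$ko_coverage <= 1,
            cfg$idiosyncratic_share > 0, cfg$idiosyncratic_share < 1,
            cfg$redetect_prob >= 0, cfg$redetect_prob <= 1,
            cfg$fast_fraction > 0, cfg$fast_fraction < 1,
            cfg$out_degree_min >= 1,
            cfg$out_degree_max < cfg$n_genes,
            cfg$out_degree_min <= cfg$out_degree_max,
            abs(cfg$genome_slope_expression) < 1,
            abs(cfg$genome_slope_ppi) < 1)
  # fail early on infeasible coupling/share combinations
  coupling_loadings(cfg$activated_coupling, cfg, cfg$sign_split)
  coupling_loadings(cfg$repressed_coupling, cfg, 1 - cfg$sign_split)
  structure(cfg, class = "generator_config")
}

# Spearman rho -> latent Gaussian correlation (bivariate normal identity)
latent_cor <- function(rho_s) 2 * sin(pi * rho_s / 6)

# expected out-degree under the truncated discrete power law
expected_out_degree <- function(cfg) {
  k <- cfg$out_degree_min:cfg$out_degree_max
  w <- k^(-cfg$out_degree_alpha)
  sum(k * w) / sum(w)
}

# Loadings for the target Ka/Ks module structure. A target's Ka/Ks latent is
#   z = r_e * z_expr + s * (a * z_tf + c * w_tf + b * eps),  s^2 = 1 - r_e^2,
# with w_tf shared across targets whose primary regulator is that TF and
# a^2 + c^2 + b^2 = 1, b^2 = idiosyncratic_share. Each target couples to one
# (uniformly chosen) primary regulator, so in a dense network only a fraction
# phi = E[1/(1 + other same-sign regulators)] of a TF's stratum targets are
# coupled to it; `a` is chosen so the TF-level Spearman between z_tf and the
# median same-sign-target latent equals the configured coupling despite that
# dilution:
#   corr = phi * s * a / sqrt(V),
#   V = phi^2 s^2 (a^2 + c^2)
#       + g * (phi (r_e^2 + s^2 b^2) + (1 - phi)) / kbar,
# with g = pi/2 (median efficiency), kbar the expected same-sign regulon
# size, and phi = (1 - exp(-lambda))/lambda for the Poisson same-sign
# in-degree lambda.
coupling_loadings <- function(coupling, cfg, sign_prob) {
  r_e <- latent_cor(cfg$genome_slope_expression)
  s2 <- 1 - r_e^2
  beta <- cfg$idiosyncratic_share
  g <- pi / 2
  ek <- expected_out_degree(cfg)
  kbar <- max(3, ek * max(sign_prob, 0.05))
  lambda <- max(cfg$n_tfs * ek * max(sign_prob, 0.05) / cfg$n_genes, 1e-6)
  phi <- (1 - exp(-lambda)) / lambda
  V <- phi^2 * s2 * (1 - beta) +
    g * (phi * (r_e^2 + s2 * beta) + (1 - phi)) / kbar
  r_lat <- coupling / (6 / pi * asin(0.5))   # Spearman -> latent scale
  # empirical calibration constant: absorbs attenuations the closed form
  # ignores — tied rank blocks created by the missing-ortholog assignment,
  # clustering of non-coupled regulon members around their own primary
  # regulators, and finite-regulon median efficiency — fixed once by
  # matching the analysis-level recovery on repeated generator draws
  kappa <- 0.86
  a <- r_lat * sqrt(V) / (phi * sqrt(s2) * kappa)
  if (a^2 > 1 - beta)
    stop("coupling ", coupling, " infeasible with idiosyncratic_share ",
         beta, ": reduce the coupling or the share")
  list(a = a, c = sqrt(1 - beta - a^2), b = sqrt(beta))
}

# discrete Pareto degree from a latent normal
degree_from_latent <- function(z, dmin, alpha, dmax) {
  u <- pnorm(z)
  d <- floor(dmin * (1 - u)^(-1 / (alpha - 1)))
  pmin(pmax(d, dmin), dmax)
}

#' Generate a gene property table with configured trends
#'
#' Draws expression (log-normal, TFs shifted lower), CAI (noisy monotone
#' transform of expression), Ka/Ks (coupled to expression at the configured
#' rank-space genome slope, with TF rows using `slope * tf_trend_multiplier`)
#' and PPI degree (heavy-tailed, negatively rank-coupled to Ka/Ks), via a
#' Gaussian copula. Ortholog flags start all-present; ortholog loss is
#' applied by [generate_regulatory_network()], whose regulator rates it
#' depends on. Uses the current RNG state; seed via `set.seed()` or
#' [generate_dataset()].
#'
#' @param cfg a `generator_config`.
#' @return list of class `synthetic_genes`: `genes` (a `gene_table`) and
#'   `truth` (latent variables and the config; never an analysis input).
#' @export
generate_genes <- function(cfg) {
  n <- cfg$n_genes
  ids <- sprintf("g%05d", seq_len(n))
  is_tf <- seq_len(n) <= cfg$n_tfs

  z_e0 <- rnorm(n)                               # centred expression latent
  z_e <- z_e0 + ifelse(is_tf, cfg$tf_expression_shift, 0)
  slope <- ifelse(is_tf,
                  cfg$genome_slope_expression * cfg$tf_trend_multiplier,
                  cfg$genome_slope_expression)
  re <- latent_cor(slope)
  z_ka <- re * z_e0 + sqrt(1 - re^2) * rnorm(n)

  expression <- qlnorm(pnorm(z_e), cfg$expression_meanlog,
                       cfg$expression_sdlog)
  rc <- cfg$cai_expression_cor
  cai <- pnorm(rc * z_e0 + sqrt(1 - rc^2) * rnorm(n))
  ka <- qlnorm(pnorm(z_ka), cfg$ka_meanlog, cfg$ka_sdlog)

  rp <- latent_cor(ifelse(is_tf, cfg$genome_slope_ppi * cfg$tf_trend_multiplier,
                          cfg$genome_slope_ppi))
  z_d <- rp * z_ka + sqrt(1 - rp^2) * rnorm(n)
  ppi_degree <- degree_from_latent(z_d, cfg$ppi_degree_min,
                                   cfg$ppi_degree_alpha, cfg$ppi_degree_max)

  genes <- data.frame(gene_id = ids, ka_ks = ka, expression = expression,
                      cai = cai, is_tf = is_tf,
                      ortholog_par = TRUE, ortholog_mik = TRUE,
                      ppi_degree = as.integer(ppi_degree),
                      stringsAsFactors = FALSE)
  genes <- validate_gene_table(genes)
  structure(list(genes = genes,
                 truth = list(latent = list(z_e0 = z_e0, z_ka = z_ka),
                              true_ka_ks = ka, config = cfg)),
            class = "synthetic_genes")
}

#' Generate the regulatory network and couple target rates to TF rates
#'
#' Per TF, an out-degree is drawn from the truncated power law and targets
#' are sampled (TF genes up-weighted, increasingly so for fast regulators,
#' which creates the TF-on-TF hierarchy). Each edge gets a true sign with
#' probability `sign_split` of being activating. Non-TF targets then have
#' their Ka/Ks (and dependent PPI-degree latent) re-drawn around their
#' primary regulator's rate latent: activated targets at
#' `activated_coupling`, repressed-only targets at `repressed_coupling`,
#' both with a shared per-regulon module component so co-regulated genes
#' are more similar than random gene sets. Ortholog loss is then applied
#' with probability increasing in the primary activating regulator's rate
#' rank, and per-edge experiment support is drawn.
#'
#' @param cfg a `generator_config`.
#' @param gg output of [generate_genes()].
#' @return list of class `synthetic_network`: `records` (edge records with
#'   experiment ids, chip source), `genes` (updated gene table: re-drawn
#'   rates, ortholog flags, `ka_ks` blanked for missing-ortholog genes) and
#'   `truth` (per-edge true signs, per-gene primary regulator, realized
#'   couplings).
#' @export
generate_regulatory_network <- function(cfg, gg) {
  genes <- gg$genes
  n <- nrow(genes)
  ids <- genes$gene_id
  tf_ids <- ids[genes$is_tf]
  z_e0 <- gg$truth$latent$z_e0
  z_ka <- gg$truth$latent$z_ka
  ka <- gg$truth$true_ka_ks
  rk <- rank(ka) / n                      # true genome-wide Ka/Ks rank
  names(rk) <- ids

  kvals <- cfg$out_degree_min:cfg$out_degree_max
  kw <- kvals^(-cfg$out_degree_alpha)
  out_deg <- sample(kvals, length(tf_ids), replace = TRUE, prob = kw)
  if (max(out_deg) >= n - 1)
    stop("out-degree demand exceeds the gene pool")

  # TF genes are up-weighted as targets, the more so for fast target TFs
  # (fast TFs accumulate regulators: the positive in-degree trend) and for
  # fast regulators (fast TFs preferentially regulate other TFs)
  base_w <- rep(1, n)
  tf_pos <- which(genes$is_tf)
  base_w[tf_pos] <- cfg$tf_target_weight *
    (1 + cfg$tf_on_tf_fast_bias * rk[ids[tf_pos]])
  edge_tf <- character(0); edge_target <- character(0)
  for (i in seq_along(tf_ids)) {
    w <- base_w
    w[tf_pos] <- w[tf_pos] * (1 + cfg$tf_on_tf_fast_bias * rk[tf_ids[i]])
    w[match(tf_ids[i], ids)] <- 0     # no self-regulation
    tg <- sample(ids, out_deg[i], prob = w)
    edge_tf <- c(edge_tf, rep(tf_ids[i], out_deg[i]))
    edge_target <- c(edge_target, tg)
  }
  n_edges <- length(edge_tf)
  sign <- ifelse(runif(n_edges) < cfg$sign_split, "A", "R")

  # primary regulator: uniformly chosen among activating regulators, else
  # among repressive ones (shuffled edge order keeps the choice unbiased)
  prim_reg <- setNames(rep(NA_character_, n), ids)
  prim_sign <- setNames(rep(NA_character_, n), ids)
  shuffle <- sample.int(n_edges)
  ord_act <- shuffle[sign[shuffle] == "A"]
  ord_act <- ord_act[!duplicated(edge_target[ord_act])]
  prim_reg[edge_target[ord_act]] <- edge_tf[ord_act]
  prim_sign[edge_target[ord_act]] <- "A"
  ord_rep <- shuffle[sign[shuffle] == "R"]
  ord_rep <- ord_rep[!duplicated(edge_target[ord_rep])]
  rep_only <- is.na(prim_reg[edge_target[ord_rep]])
  prim_reg[edge_target[ord_rep][rep_only]] <- edge_tf[ord_rep][rep_only]
  prim_sign[edge_target[ord_rep][rep_only]] <- "R"

  # re-draw Ka/Ks of regulated non-TF genes around their primary regulator
  w_act <- setNames(rnorm(length(tf_ids)), tf_ids)
  w_rep <- setNames(rnorm(length(tf_ids)), tf_ids)
  la <- coupling_loadings(cfg$activated_coupling, cfg, cfg$sign_split)
  lr <- coupling_loadings(cfg$repressed_coupling, cfg, 1 - cfg$sign_split)
  r_e <- latent_cor(cfg$genome_slope_expression)
  s <- sqrt(1 - r_e^2)
  redraw <- which(!genes$is_tf & !is.na(prim_sign[ids]))
  if (length(redraw) > 0) {
    f <- prim_reg[ids[redraw]]
    sgn <- prim_sign[ids[redraw]]
    act <- sgn == "A"
    a <- ifelse(act, la$a, lr$a)
    cc <- ifelse(act, la$c, lr$c)
    b <- ifelse(act, la$b, lr$b)
    wmod <- ifelse(act, w_act[f], w_rep[f])
    eta <- a * z_ka[match(f, ids)] + cc * wmod + b * rnorm(length(redraw))
    z_new <- r_e * z_e0[redraw] + s * eta
    z_ka[redraw] <- z_new
    ka[redraw] <- qlnorm(pnorm(z_new), cfg$ka_meanlog, cfg$ka_sdlog)
    rp <- latent_cor(cfg$genome_slope_ppi)
    z_d_new <- rp * z_new + sqrt(1 - rp^2) * rnorm(length(redraw))
    genes$ppi_degree[redraw] <- as.integer(
      degree_from_latent(z_d_new, cfg$ppi_degree_min, cfg$ppi_degree_alpha,
                         cfg$ppi_degree_max))
  }
  genes$ka_ks <- ka
  rk <- setNames(rank(ka) / n, ids)          # ranks after re-draw

  # ortholog loss, modulated by the primary *activating* regulator's rate
  p_miss <- rep(cfg$missing_fraction_base, n)
  act_reg <- which(!is.na(prim_sign[ids]) & prim_sign[ids] == "A" &
                     !genes$is_tf)
  if (length(act_reg) > 0) {
    mod <- 1 + cfg$missing_vs_tf_rate_coupling *
      (2 * rk[prim_reg[ids[act_reg]]] - 1)
    p_miss[act_reg] <- pmin(0.95, pmax(0, cfg$missing_fraction_base * mod))
  }
  missing_par <- runif(n) < p_miss
  missing_mik <- missing_par | (runif(n) < 0.03)
  genes$ortholog_par <- !missing_par
  genes$ortholog_mik <- !missing_mik
  genes$ka_ks[missing_par] <- NA_real_

  support <- 1L + rbinom(n_edges, cfg$n_experiments - 1L,
                         cfg$redetect_prob)
  records <- data.frame(
    tf_id = rep(edge_tf, support),
    target_id = rep(edge_target, support),
    experiment_id = paste0("E", sequence(support)),
    source = "chip", stringsAsFactors = FALSE)

  truth <- gg$truth
  truth$latent$z_ka <- z_ka
  truth$true_ka_ks <- ka
  truth$edges <- data.frame(tf = edge_tf, target = edge_target,
                            true_sign = sign, support = support,
                            stringsAsFactors = FALSE)
  truth$primary_regulator <- prim_reg
  truth$primary_sign <- prim_sign
  truth$realized <- realized_couplings(genes, truth, cfg)
  structure(list(records = records, genes = genes, truth = truth),
            class = "synthetic_network")
}

# true rates with the missing-ortholog convention applied: genes lost in
# the comparison species sit above the fastest ortholog-bearing gene
assigned_true_rates <- function(net, genes) {
  ka <- net$truth$true_ka_ks
  ifelse(genes$ortholog_par, ka, max(ka[genes$ortholog_par]) * 1.1)
}

# empirical couplings in the generated draw (uses true rates, truth only)
realized_couplings <- function(genes, truth, cfg) {
  ka <- setNames(truth$true_ka_ks, genes$gene_id)
  ed <- truth$edges
  out <- list(genome_expression_spearman = suppressWarnings(
    cor(genes$expression, truth$true_ka_ks, method = "spearman")))
  for (sg in c("A", "R")) {
    sub <- ed[ed$true_sign == sg, , drop = FALSE]
    tl <- lapply(split(sub$target, sub$tf), unique)
    tl <- tl[vapply(tl, length, integer(1)) >= 5]
    nm <- if (sg == "A") "activated_tf_level_spearman" else
      "repressed_tf_level_spearman"
    out[[nm]] <- if (length(tl) >= 3) suppressWarnings(
      cor(ka[names(tl)],
          vapply(tl, function(tg) median(ka[tg]), numeric(1)),
          method = "spearman")) else NA_real_
  }
  out
}

#' Generate an undirected PPI edge list from the degree sequence
#'
#' Stub-pairing (configuration-model) realization of the gene table's PPI
#' degrees: stubs are shuffled and paired, self-loops and duplicate pairs
#' dropped, so realized degrees approximate the drawn heavy-tailed,
#' rate-coupled sequence.
#'
#' @param cfg a `generator_config`.
#' @param genes gene table carrying `ppi_degree`.
#' @return data.frame: `gene_a, gene_b, n_reports`.
#' @export
generate_ppi_network <- function(cfg, genes) {
  stubs <- rep(genes$gene_id, genes$ppi_degree)
  stubs <- stubs[sample.int(length(stubs))]
  if (length(stubs) %% 2 == 1) stubs <- stubs[-length(stubs)]
  a <- stubs[seq(1, length(stubs), by = 2)]
  b <- stubs[seq(2, length(stubs), by = 2)]
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[dup == FALSE]; hi <- hi[dup == FALSE]
  data.frame(gene_a = lo, gene_b = hi,
             n_reports = 1L + rbinom(length(lo), 2L, 0.3),
             stringsAsFactors = FALSE)
}

#' Generate a knockout X-score matrix consistent with true edge signs
#'
#' Covered TFs receive a full column of X scores: near-zero background
#' noise for non-targets, and for true edges a score centred at `-mu`
#' (activating: the target drops when its activator is knocked out) or
#' `+mu` (repressive), with Gaussian noise. The orientation is
#' log(knockout / wild type), matching [assign_edge_signs()]'s default.
#'
#' @param cfg a `generator_config`.
#' @param net a `synthetic_network` (provides true signs).
#' @param genes the gene table.
#' @return numeric matrix (genes x covered TFs).
#' @export
generate_knockout_xscores <- function(cfg, net, genes) {
  tf_ids <- genes$gene_id[genes$is_tf]
  covered <- tf_ids[seq_len(round(cfg$ko_coverage * length(tf_ids)))]
  m <- matrix(rnorm(nrow(genes) * length(covered), 0,
                    cfg$xscore_background_sd),
              nrow = nrow(genes), ncol = length(covered),
              dimnames = list(genes$gene_id, covered))
  ed <- net$truth$edges
  ed <- ed[ed$tf %in% covered, , drop = FALSE]
  ed <- ed[!duplicated(paste(ed$tf, ed$target, sep = "\r")), , drop = FALSE]
  mu <- ifelse(ed$true_sign == "A", -cfg$xscore_mu, cfg$xscore_mu)
  m[cbind(match(ed$target, genes$gene_id), match(ed$tf, covered))] <-
    mu + rnorm(nrow(ed), 0, cfg$xscore_noise_sd)
  m
}

#' Generate two-species read counts with rate-coupled divergence
#'
#' Species-A counts are Poisson around each gene's expression; species-B
#' counts are Poisson around expression times `2^delta`, where the log2
#' shift `delta` is Gaussian with standard deviation
#' `divergence_scale * (1 + divergence_rate_coupling)` for targets of the
#' fastest-evolving TFs (top `fast_fraction` by rate, regulators missing an
#' ortholog counting as maximally diverged) and `divergence_scale` for all
#' other genes — i.e. at coupling 1 the divergence scale of fast-TF targets
#' doubles. Genes missing an ortholog are omitted from the pairing.
#'
#' @param cfg a `generator_config`.
#' @param net a `synthetic_network`.
#' @param genes the gene table (post network generation).
#' @return list: `counts` (data.frame `gene_id_a, count_a, gene_id_b,
#'   count_b`) and `truth` (per-gene delta and regulator-rate rank).
#' @export
generate_two_species_counts <- function(cfg, net, genes) {
  n <- nrow(genes)
  ids <- genes$gene_id
  ed <- net$truth$edges
  simple_net <- structure(data.frame(tf = ed$tf, target = ed$target,
                                     stringsAsFactors = FALSE),
                          class = c("reg_network", "data.frame"))
  rates <- setNames(assigned_true_rates(net, genes), ids)
  sp <- fast_tf_split(simple_net, rates[ids[genes$is_tf]],
                      cfg$fast_fraction)
  fast_regulated <- ids %in% sp$fast_targets
  sdv <- cfg$divergence_scale *
    (1 + cfg$divergence_rate_coupling * fast_regulated)
  delta <- rnorm(n, 0, sdv)
  lambda <- genes$expression * cfg$count_depth
  count_a <- rpois(n, lambda)
  count_b <- rpois(n, lambda * 2^delta)
  keep <- genes$ortholog_par
  counts <- data.frame(gene_id_a = ids[keep], count_a = count_a[keep],
                       gene_id_b = ids[keep], count_b = count_b[keep],
                       stringsAsFactors = FALSE)
  list(counts = counts,
       truth = list(delta = setNames(delta, ids),
                    fast_regulated = setNames(fast_regulated, ids)))
}

#' Generate flat annotation categories with niche/core structure
#'
#' Half the categories are "niche" terms whose members are preferentially
#' drawn from targets of fast-evolving TFs (odds `niche_term_bias`); the
#' other half are "core" terms preferring targets of the remaining TFs.
#'
#' @param cfg a `generator_config`.
#' @param net a `synthetic_network`.
#' @param genes the gene table.
#' @return list: `annotations` (data.frame `gene_id, term_id`) and `truth`
#'   (term classes and sizes).
#' @export
generate_annotations <- function(cfg, net, genes) {
  ed <- net$truth$edges
  simple_net <- structure(data.frame(tf = ed$tf, target = ed$target,
                                     stringsAsFactors = FALSE),
                          class = c("reg_network", "data.frame"))
  rates <- setNames(assigned_true_rates(net, genes), genes$gene_id)
  sp <- fast_tf_split(simple_net, rates[genes$gene_id[genes$is_tf]],
                      cfg$fast_fraction)
  ids <- genes$gene_id
  w_niche <- 1 + (cfg$niche_term_bias - 1) * (ids %in% sp$fast_targets)
  w_core <- 1 + (cfg$niche_term_bias - 1) * (ids %in% sp$other_targets)
  rows <- list()
  classes <- character(cfg$n_terms)
  sizes <- sample(cfg$term_size_min:cfg$term_size_max, cfg$n_terms,
                  replace = TRUE)
  for (t in seq_len(cfg$n_terms)) {
    niche <- t %% 2 == 1
    classes[t] <- if (niche) "niche" else "core"
    members <- sample(ids, sizes[t], prob = if (niche) w_niche else w_core)
    rows[[t]] <- data.frame(gene_id = members,
                            term_id = sprintf("T%03d", t),
                            stringsAsFactors = FALSE)
  }
  list(annotations = do.call(rbind, rows),
       truth = list(term_class = setNames(classes,
                                          sprintf("T%03d", seq_len(cfg$n_terms))),
                    term_size = setNames(sizes,
                                         sprintf("T%03d", seq_len(cfg$n_terms)))))
}

#' Generate a complete synthetic dataset
#'
#' Orchestrates all generator stages under per-stage sub-seeds derived from
#' the master seed (so adding a stage never perturbs the others'
#' randomness) and optionally writes the dataset as plain-text files:
#' `genes.tsv, edges.tsv, ppi.tsv, knockout.tsv, counts.tsv,
#' annotations.tsv, truth.json`. Output is byte-identical for a fixed
#' (config, seed).
#'
#' @param cfg a `generator_config`.
#' @param seed master seed (integer).
#' @param outdir optional output directory.
#' @return list of class `synthetic_dataset` with elements `genes`,
#'   `edge_records`, `ppi`, `knockout`, `counts`, `annotations`, `truth`,
#'   `config`, `seed`.
#' @export
generate_dataset <- function(cfg = generator_config(), seed = 1,
                             outdir = NULL) {
  set.seed(stage_seed(seed, "genes"))
  gg <- generate_genes(cfg)
  set.seed(stage_seed(seed, "network"))
  net <- generate_regulatory_network(cfg, gg)
  set.seed(stage_seed(seed, "ppi"))
  ppi <- generate_ppi_network(cfg, net$genes)
  set.seed(stage_seed(seed, "knockout"))
  ko <- generate_knockout_xscores(cfg, net, net$genes)
  set.seed(stage_seed(seed, "counts"))
  cnt <- generate_two_species_counts(cfg, net, net$genes)
  set.seed(stage_seed(seed, "annotations"))
  ann <- generate_annotations(cfg, net, net$genes)

  truth <- net$truth
  truth$divergence <- cnt$truth
  truth$annotation <- ann$truth
  ds <- structure(list(genes = net$genes, edge_records = net$records,
                       ppi = ppi, knockout = ko, counts = cnt$counts,
                       annotations = ann$annotations, truth = truth,
                       config = cfg, seed = seed),
                  class = "synthetic_dataset")
  if (!is.null(outdir)) write_dataset(ds, outdir)
  ds
}

#' Write a synthetic dataset to plain-text files
#'
#' @param ds a `synthetic_dataset`.
#' @param outdir output directory (created if needed).
#' @return the output directory, invisibly.
#' @export
write_dataset <- function(ds, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
  write_gene_table(ds$genes, file.path(outdir, "genes.tsv"))
  tsv(ds$edge_records, "edges.tsv")
  tsv(ds$ppi, "ppi.tsv")
  write_knockout_matrix(ds$knockout, file.path(outdir, "knockout.tsv"))
  tsv(ds$counts, "counts.tsv")
  tsv(ds$annotations, "annotations.tsv")
  truth_out <- ds$truth
  truth_out$latent <- NULL            # keep the truth file compact
  truth_out$config <- unclass(ds$truth$config)
  jsonlite::write_json(truth_out, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(outdir)
}

#' Derive a deterministic per-stage sub-seed
#'
#' Hashes the master seed together with the stage name so that every stage
#' draws from an independent, reproducible stream and adding a stage never
#' perturbs the others.
#'
#' @param master master seed (integer).
#' @param stage stage name (string).
#' @return an integer seed in [0, 2^31).
#' @export
stage_seed <- function(master, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(master) * 48271 + h * 8191) %% 2147483647)
}
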