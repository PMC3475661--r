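#' Configuration for the full analysis pipeline
#'
#' Either `generator` settings plus a `seed` (synthetic mode) or an
#' `inputs` list of file paths (`genes`, `edges`, `ppi`, `knockout`,
#' `counts`, `annotations`). Stages whose inputs are absent are skipped
#' with a logged reason rather than failing.
#'
#' @param seed master seed; per-stage seeds are derived with
#'   [stage_seed()].
#' @param generator a `generator_config` or a list of overrides for one.
#' @param inputs optional named list of input file paths.
#' @param n_samples matched null-sample count per slope test.
#' @param tolerance RMSD tolerance for the matched sampler.
#' @param min_targets,min_targets_confirmed TF profile thresholds for the
#'   full and confirmed-edge networks.
#' @param min_same_sign_targets sign-stratum membership threshold.
#' @param min_term_size enrichment term-size threshold.
#' @param fast_fraction fraction of fastest-evolving TFs.
#' @param xscore_threshold knockout |X| threshold for sign inference.
#' @param comparison ortholog comparison species tag.
#' @param n_null_spread null sets per TF in the spread test.
#' @param write_figures write binned-median profile PNGs.
#' @param verbose print one structured line per stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, generator = generator_config(),
                            inputs = NULL,
                            n_samples = 10000, tolerance = 0.01,
                            min_targets = 3, min_targets_confirmed = 2,
                            min_same_sign_targets = 5,
                            min_term_size = 50, fast_fraction = 0.25,
                            xscore_threshold = 1, comparison = "par",
                            n_null_spread = 100,
                            write_figures = FALSE, verbose = TRUE) {
  if (!inherits(generator, "generator_config"))
    generator <- do.call(generator_config, as.list(generator))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `generator` key holds [generator_config()] overrides.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

load_pipeline_inputs <- function(inputs) {
  get <- function(name, reader) {
    if (is.null(inputs[[name]])) NULL else reader(inputs[[name]])
  }
  list(genes = get("genes", read_gene_table),
       edge_records = get("edges", read_edge_records),
       ppi = get("ppi", read_ppi_table),
       knockout = get("knockout", read_knockout_matrix),
       counts = get("counts", read_counts_table),
       annotations = get("annotations", read_annotation_map))
}

#' Run the full TF evolutionary-rate analysis
#'
#' Orchestrates every stage applicable to the available inputs: data
#' generation or loading; missing-ortholog assignment and genome-wide rank
#' transforms; regulatory-network construction and the confirmed-edge
#' subnetwork; rank-space slope tests of TF Ka/Ks against PPI degree,
#' regulatory in-degree, expression, CAI and median interactor Ka/Ks, with
#' CAI-substituted controls and a confirmed-edge variant; edge-sign
#' inference from knockout X scores and sign-stratified TF-target
#' co-evolution correlations; the TF/all-protein correlation panel; the
#' co-regulation spread test (Ka/Ks and log expression); the two-species
#' expression-divergence t-test; and target-set annotation enrichment.
#'
#' @param config a `pipeline_config`.
#' @param outdir optional output directory for the JSON report, result
#'   TSVs and (optionally) profile figures.
#' @return an `analysis_report` list; see the `skipped` element for stages
#'   that could not run and why.
#' @export
run_full_analysis <- function(config = pipeline_config(), outdir = NULL) {
  t_start <- Sys.time()
  log_line <- function(stage, ...) {
    if (config$verbose)
      message(sprintf("[%s] %s", stage, paste0(...)))
  }
  skipped <- list()
  report <- list(meta = list(seed = config$seed,
                             n_samples = config$n_samples,
                             tolerance = config$tolerance,
                             comparison = config$comparison))

  # ---- stage: data -------------------------------------------------------
  if (is.null(config$inputs)) {
    ds <- generate_dataset(config$generator, seed = config$seed)
    inputs <- ds[c("genes", "edge_records", "ppi", "counts",
                   "annotations")]
    inputs$knockout <- ds$knockout
    report$meta$data_source <- "synthetic"
    log_line("data", "generated synthetic dataset, ",
             nrow(inputs$genes), " genes, ",
             nrow(inputs$edge_records), " edge records")
  } else {
    inputs <- load_pipeline_inputs(config$inputs)
    report$meta$data_source <- "files"
    log_line("data", "loaded inputs from files")
  }
  genes <- inputs$genes
  if (is.null(genes) || is.null(inputs$edge_records))
    stop("pipeline requires at least a gene table and edge records")

  # ---- stage: networks and ranks ----------------------------------------
  net <- build_regulatory_network(inputs$edge_records, genes$gene_id)
  net_ce <- confirmed_edges(net, 2)
  genes <- prepare_gene_table(genes, ppi = inputs$ppi, net = net,
                              comparison = config$comparison)
  tf_ids <- genes$gene_id[genes$is_tf]
  ka_rates <- setNames(genes$assigned_ka_ks, genes$gene_id)
  log_line("networks", nrow(net), " edges (", nrow(net_ce),
           " confirmed); ranks computed")
  report$network = list(
    dialect = "chip", n_edges = nrow(net), n_confirmed = nrow(net_ce),
    n_tfs = length(unique(net$tf)))

  # ---- stage: slope tests -----------------------------------------------
  rk <- function(col) setNames(genes[[col]], genes$gene_id)
  interactor_ka <- rep(NA_real_, nrow(genes))
  if (!is.null(inputs$ppi)) {
    e <- inputs$ppi[inputs$ppi$gene_a != inputs$ppi$gene_b, , drop = FALSE]
    med <- vapply(split(c(e$gene_b, e$gene_a), c(e$gene_a, e$gene_b)),
                  function(nb) median(ka_rates[nb], na.rm = TRUE),
                  numeric(1))
    interactor_ka[match(names(med), genes$gene_id)] <- med
  }
  rank_interactor <- rank_transform(interactor_ka)
  names(rank_interactor) <- genes$gene_id
  in_degree_ce <- in_degree(net_ce, genes$gene_id)
  rank_in_degree_ce <- rank_transform(in_degree_ce)

  slope_specs <- list(
    list(id = "ka_vs_ppi_degree", x = "rank_ppi_degree", y = "rank_ka_ks",
         dialect = "chip"),
    list(id = "ka_vs_in_degree", x = "rank_in_degree", y = "rank_ka_ks",
         dialect = "chip"),
    list(id = "ka_vs_expression", x = "rank_expression", y = "rank_ka_ks",
         dialect = "chip"),
    list(id = "ka_vs_cai", x = "rank_cai", y = "rank_ka_ks",
         dialect = "chip"),
    list(id = "ka_vs_interactor_ka", x = "rank_interactor_ka",
         y = "rank_ka_ks", dialect = "chip"),
    # CAI-substituted controls for the degree trends
    list(id = "cai_vs_ppi_degree", x = "rank_ppi_degree", y = "rank_cai",
         dialect = "chip"),
    list(id = "cai_vs_in_degree", x = "rank_in_degree", y = "rank_cai",
         dialect = "chip"),
    # confirmed-edge variant
    list(id = "ka_vs_in_degree_ce", x = "rank_in_degree_ce",
         y = "rank_ka_ks", dialect = "confirmed"))
  rank_of <- function(name) {
    if (name == "rank_interactor_ka") return(rank_interactor)
    if (name == "rank_in_degree_ce") return(rank_in_degree_ce)
    if (name %in% names(genes)) return(rk(name))
    NULL
  }
  report$slope_tests <- list()
  for (spec in slope_specs) {
    xr <- rank_of(spec$x); yr <- rank_of(spec$y)
    if (is.null(xr) || is.null(yr) || all(is.na(xr)) || all(is.na(yr))) {
      skipped[[spec$id]] <- paste0("missing ranks for ", spec$x)
      next
    }
    sub <- intersect(tf_ids,
                     intersect(names(xr)[!is.na(xr)], names(yr)[!is.na(yr)]))
    set.seed(stage_seed(config$seed, paste0("slope_", spec$id)))
    st <- slope_pvalue(xr, yr, sub, n_samples = config$n_samples,
                      tolerance = config$tolerance, method = "swap")
    report$slope_tests[[spec$id]] <- list(
      dialect = spec$dialect, x = spec$x, y = spec$y,
      observed_slope = st$observed_slope, p_value = st$p_value,
      p_is_bound = st$p_is_bound, direction = st$direction,
      null_median = st$sampler_stats$null_median,
      n_samples = st$n_samples, tolerance = st$tolerance,
      subset_size = st$sampler_stats$subset_size)
    log_line("slope", spec$id, sprintf(": slope %.3f, p %s %.4g",
             st$observed_slope, if (st$p_is_bound) "<=" else "=",
             st$p_value))
  }

  # ---- stage: correlation panel -----------------------------------------
  if (!is.null(inputs$ppi)) {
    panel <- tf_target_correlation_panel(genes, net, inputs$ppi,
                                         config$min_targets,
                                         config$comparison)
    report$correlation_panel <- panel
    log_line("panel", nrow(panel), " correlations")
  } else skipped$correlation_panel <- "no PPI network"

  # ---- stage: sign inference + stratified correlations ------------------
  if (!is.null(inputs$knockout)) {
    net_signed <- assign_edge_signs(net, inputs$knockout,
                                    config$xscore_threshold)
    halves <- split_by_sign(net_signed)
    report$sign_inference <- list(
      threshold = config$xscore_threshold,
      n_signed = sum(net_signed$sign != "U"),
      n_activating = nrow(halves$activating),
      n_repressive = nrow(halves$repressive))
    strat <- sign_stratified_correlations(net_signed, genes,
                                          config$min_same_sign_targets,
                                          config$comparison)
    strat$dialect <- if (nrow(strat)) "chip" else character(0)
    report$sign_stratified <- strat
    log_line("signs", report$sign_inference$n_activating, " activating, ",
             report$sign_inference$n_repressive, " repressive edges")
  } else {
    skipped$sign_stratified <- "skipped: no knockout data"
  }

  # ---- stage: co-regulation spread --------------------------------------
  set.seed(stage_seed(config$seed, "spread"))
  spread_res <- list()
  for (what in c("ka_ks", "log_expression")) {
    vals <- if (what == "ka_ks") ka_rates else
      setNames(log(genes$expression), genes$gene_id)
    res <- tryCatch(
      coregulation_spread_test(net_ce, genes, vals,
                               min_targets = config$min_targets,
                               n_null = config$n_null_spread,
                               comparison = config$comparison),
      error = function(e) conditionMessage(e))
    if (is.character(res)) skipped[[paste0("spread_", what)]] <- res
    else {
      spread_res[[what]] <- list(dialect = "confirmed", p = res$p,
                                 n_tfs = nrow(res$table),
                                 n_null = res$n_null,
                                 alternative = res$alternative,
                                 table = res$table)
      log_line("spread", what, sprintf(": p = %.4g over %d TFs",
               res$p, nrow(res$table)))
    }
  }
  report$spread <- spread_res

  # ---- stage: expression divergence -------------------------------------
  if (!is.null(inputs$counts)) {
    cnt <- inputs$counts
    rpm_a <- rpm_normalize(setNames(cnt$count_a, cnt$gene_id_a))
    rpm_b <- rpm_normalize(setNames(cnt$count_b, cnt$gene_id_b))
    div <- log2_fold_changes(rpm_a, rpm_b,
                             setNames(cnt$gene_id_b, cnt$gene_id_a))
    tt <- tryCatch(
      divergence_ttest(div, net_ce, ka_rates[tf_ids],
                       config$fast_fraction),
      error = function(e) conditionMessage(e))
    if (is.character(tt)) skipped$divergence <- tt
    else {
      report$divergence <- list(dialect = "confirmed", t = tt$t, p = tt$p,
                                mean_fast = tt$mean_fast,
                                mean_other = tt$mean_other,
                                n_fast = tt$n_fast, n_other = tt$n_other)
      log_line("divergence", sprintf("t = %.2f, p = %.4g", tt$t, tt$p))
    }
  } else skipped$divergence <- "no two-species counts"

  # ---- stage: enrichment ------------------------------------------------
  if (!is.null(inputs$annotations)) {
    sp <- fast_tf_split(net, ka_rates[tf_ids], config$fast_fraction)
    enr <- target_set_enrichment(sp$fast_targets, sp$other_targets,
                                 inputs$annotations, config$min_term_size)
    report$enrichment <- enr
    log_line("enrichment", nrow(enr), " terms tested, ",
             sum(enr$significant), " at p < 0.05")
  } else skipped$enrichment <- "no annotations"

  report$skipped <- skipped
  report$meta$elapsed_s <-
    as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  class(report) <- "analysis_report"

  if (!is.null(outdir)) write_report(report, genes, net, config, outdir)
  report
}

# Serialize the report (JSON + TSVs + optional figures) under outdir.
write_report <- function(report, genes, net, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  json_report <- report
  json_report$meta$elapsed_s <- NULL       # keep reruns byte-identical
  jsonlite::write_json(json_report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  tsv <- function(df, name)
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
  if (!is.null(report$correlation_panel))
    tsv(report$correlation_panel, "correlation_panel.tsv")
  if (!is.null(report$sign_stratified))
    tsv(report$sign_stratified, "sign_stratified.tsv")
  if (!is.null(report$enrichment))
    tsv(report$enrichment, "enrichment.tsv")
  for (what in names(report$spread))
    tsv(report$spread[[what]]$table, paste0("spread_", what, ".tsv"))
  profiles <- tf_target_profiles(net, genes, config$min_targets,
                                 config$comparison)
  tsv(profiles, "tf_profiles.tsv")
  if (isTRUE(config$write_figures)) {
    ka <- setNames(genes$assigned_ka_ks, genes$gene_id)
    prof_profile <- binned_median_profile(ka[profiles$tf_id],
                                          profiles$median_target_ka_ks,
                                          n_bins = 5)
    tsv(prof_profile, "profile_tf_vs_target_ka.tsv")
    grDevices::png(file.path(outdir, "profile_tf_vs_target_ka.png"),
                   width = 700, height = 500)
    plot_binned_profile(prof_profile, xlab = "TF Ka/Ks (binned)",
                        ylab = "median target Ka/Ks")
    grDevices::dev.off()
  }
  invisible(outdir)
}

#' Plot a binned-median profile as a bar chart with error bars
#'
#' Bars are bin medians, whiskers the bootstrap standard error of the
#' median, and the number above each bar the bin member count.
#'
#' @param profile output of [binned_median_profile()].
#' @param xlab,ylab axis labels.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_binned_profile <- function(profile, xlab = "", ylab = "", ...) {
  ymax <- max(profile$median_y + profile$se) * 1.15
  mid <- graphics::barplot(profile$median_y,
                           names.arg = sprintf("%.2f-%.2f", profile$x_lo,
                                               profile$x_hi),
                           ylim = c(0, ymax), xlab = xlab, ylab = ylab,
                           ...)
  graphics::arrows(mid, profile$median_y - profile$se, mid,
                   profile$median_y + profile$se, angle = 90, code = 3,
                   length = 0.05)
  graphics::text(mid, profile$median_y + profile$se, labels = profile$n,
                 pos = 3, cex = 0.8)
  invisible(mid)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("TF evolutionary-rate analysis report\n")
  cat("  slope tests: ", length(x$slope_tests), "\n", sep = "")
  for (id in names(x$slope_tests)) {
    st <- x$slope_tests[[id]]
    cat(sprintf("    %-22s slope %+0.3f  p %s %.4g (%s)\n", id,
                st$observed_slope, if (st$p_is_bound) "<=" else "=",
                st$p_value, st$dialect))
  }
  if (!is.null(x$sign_inference))
    cat("  signed edges: ", x$sign_inference$n_activating, " activating / ",
        x$sign_inference$n_repressive, " repressive\n", sep = "")
  if (!is.null(x$divergence))
    cat(sprintf("  divergence t-test: t = %.2f, p = %.4g\n",
                x$divergence$t, x$divergence$p))
  if (length(x$skipped))
    cat("  skipped: ", paste(names(x$skipped), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}
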