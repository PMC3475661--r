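# tfnetevo

Network-level determinants of transcription factor (TF) evolutionary rate.

Genome-wide, protein evolutionary rate — Ka/Ks, the ratio of
non-synonymous to synonymous substitution rates against a close relative —
is dominated by expression level, codon adaptation (CAI) and
protein–protein interaction (PPI) degree. TFs break these rules: their
function is expressed through the genes they regulate, so their selective
constraint should track their transcriptional module. `tfnetevo` provides
the statistics to test this on gene-scale data, for computational
biologists studying regulatory network evolution:

* **Rank-space subset-slope test.** All genes are ranked genome-wide on
  each property; the least-squares slope of, say, Ka/Ks rank on expression
  rank over the TF subset (ranks kept genome-wide, never re-ranked within
  the subset) is compared against the slopes of random gene sets whose
  mean ranks of both variables match the TF set's within 1%
  root-mean-square deviation,

  RMSD(S) = sqrt( ((mean_x(S) − mean_x(TF))² + (mean_y(S) − mean_y(TF))²) / 2 ) ≤ 0.01.

  The empirical p-value is the fraction of (by default) 10,000 matched
  null slopes at least as extreme as the observed slope; a zero count is
  reported as p ≤ 1/n. A C++ swap sampler makes the matched null
  tractable even for off-centre subsets (TFs are lowly expressed), with
  uniform rejection sampling retained as the exact small-instance oracle.
* **TF→target aggregation**: regulatory networks from edge records with
  experiment support, confirmed-edge (support ≥ 2) filtering, per-TF
  regulon profiles (median target Ka/Ks, fraction of targets missing an
  ortholog, top-20% target fractions).
* **Edge-sign inference** from TF-knockout X scores (|X| > 1, sign from
  the direction of the target's expression change), and sign-stratified
  co-evolution correlations (TFs with ≥ 5 same-sign targets).
* **Co-regulation spread test**: are co-regulated genes closer in rate and
  expression than random gene sets drawn proportional to regulatory
  in-degree (without replacement)? Wilcoxon rank-sum over per-TF
  observed vs expected median pairwise differences.
* **Two-species expression divergence**: reads-per-million normalization
  (floored at 1 RPM), absolute log2 fold changes, and a Welch t-test of
  targets of the fastest 25% of TFs against targets of the rest.
* **Synthetic-data generator**: a Gaussian-copula emulation of the whole
  input universe — correlated gene properties, a TF subset with flattened
  trends and low expression, activator-coupled target rates, ortholog
  loss coupled to regulator rate, sign-consistent knockout scores,
  rate-coupled two-species counts, niche/core annotations — with ground
  truth recorded for parameter-recovery validation and never consumed by
  the analysis.

See the methods vignette (`vignettes/tfnetevo-methods.Rmd`) for the model
details, parameter defaults and their rationale, and known limitations.

## Worked example

Generate a synthetic genome + network, test whether the TF trend relating
Ka/Ks to expression is flatter than chance, and stratify TF–target
co-evolution by regulatory sign:

```r
library(tfnetevo)

ds    <- generate_dataset(generator_config(), seed = 42)
net   <- build_regulatory_network(ds$edge_records, ds$genes$gene_id)
genes <- prepare_gene_table(ds$genes, ppi = ds$ppi, net = net)
tfs   <- genes$gene_id[genes$is_tf]

set.seed(42)
slope_pvalue(setNames(genes$rank_expression, genes$gene_id),
             setNames(genes$rank_ka_ks, genes$gene_id),
             tfs, n_samples = 10000, direction = "flatter")
#> Rank-space subset-slope test (swap sampler)
#>   observed slope: -0.2799  (null median -0.4305)
#>   p = 0.0196  (flatter, 10000 matched samples, RMSD tol 0.01)

net <- assign_edge_signs(net, ds$knockout)
net
#> Regulatory network: 11088 edges, 174 TFs, 1988 targets
#>   signs: 5487 activating, 2958 repressive, 2643 unsigned

sign_stratified_correlations(net, genes)
#>   sign                 property    rho        p n_tfs
#> 1    A      median_target_ka_ks 0.2898 0.000622   136
#> 2    A fraction_targets_missing 0.2583 0.002395   136
#> 3    R      median_target_ka_ks 0.0913 0.290466   136
#> 4    R fraction_targets_missing 0.1148 0.183075   136
```

The observed TF slope (−0.28) is markedly flatter than the matched null
trend (−0.43): the TF set's evolutionary rate responds less to expression
than equally sized, equally expressed, equally fast random gene sets —
p = 0.0196 against 10,000 matched samples. The stratified table shows the
generator's built-in asymmetry recovered by the analysis: TF Ka/Ks follows
the median rate and the ortholog-loss fraction of *activated* targets
(rho ≈ 0.26–0.29 over 136 TFs with knockout coverage) but not of repressed
targets.

The full pipeline — slope tests with CAI controls and confirmed-edge
variants, correlation panel, sign stratification, spread tests, divergence
t-test, enrichment — runs as one call and writes a JSON report plus TSVs:

```r
report <- run_full_analysis(pipeline_config(seed = 1), outdir = "results")
```

A thin command-line front end with `generate`, `slope-test` and `run-all`
subcommands is installed at `inst/cli/tfnetevo.R`.

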