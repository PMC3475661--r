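---
title: "Methods: rank-space slope tests and TF-target co-evolution"
author: "tfnetevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-space slope tests and TF-target co-evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfnetevo)
```

## The scientific question

Protein evolutionary rate — the ratio Ka/Ks of non-synonymous to synonymous
substitution rates between a species and a close relative — is strongly
shaped by genome-wide correlates: highly expressed, highly connected
proteins evolve slowly. Transcription factors (TFs) are an exception. Their
role is defined through the genes they regulate, so the selective
constraint on a TF should track the constraint on its transcriptional
module rather than, say, its own expression level. This package implements
the statistical machinery for asking that question on a genome scale:

* Is the slope relating TF Ka/Ks to a correlate (expression, CAI, PPI
  degree, regulatory in-degree, interactor rate) *different* from what
  random gene sets with the same average properties would show?
* Does TF Ka/Ks follow the median Ka/Ks of its targets, and the fraction
  of targets that are missing in the comparison species?
* Is that co-evolution specific to *activating* regulation?
* Are co-regulated genes more similar in rate and expression than random
  gene sets drawn with in-degree-proportional probability?
* Do targets of fast-evolving TFs show larger between-species expression
  changes?

Real inputs are gene-level TSV tables (rates, expression, CAI, ortholog
flags), directed regulatory edge lists with experiment identifiers,
undirected PPI edge lists, TF-knockout X-score matrices, and two-species
read-count tables. Because the original data sources are external
databases, the package ships a synthetic-data generator that emulates the
statistical structure of those inputs with recorded ground truth; all
statistical validation runs against it.

## Rank normalization and the missing-ortholog convention

Every analysed property is transformed to genome-wide normalized midranks:
ascending average ranks divided by the number of genes carrying the
property, giving values in (0, 1]. Midranks keep rank sums exact under
ties and make Spearman correlations consistent. Crucially, subset slopes
are computed *on these genome-wide ranks*, never by re-ranking within the
subset: re-ranking would normalize every slope into a correlation
coefficient and destroy comparability between the subset and the genome.

Genes lacking an ortholog in the comparison species have no measurable
Ka/Ks but are the extreme of divergence (lost or lineage-specifically
gained). They all receive one value strictly above the fastest
ortholog-bearing gene — by default `max * 1.1` — and therefore occupy a
tied block at the top of the rate ranking. Median- and rank-based
statistics do not depend on the multiplier (the package tests assert the
rank columns and downstream correlations are identical under `1.1` versus
`2.0`); the multiplier is exposed for sensitivity checks anyway. Genes
missing some *other* property (e.g. no expression measurement) are
excluded pairwise from analyses needing it, never imputed. Each property's
ranks are computed once over all genes carrying that property, not
recomputed after restricting to complete cases; with pairwise exclusion
this keeps every analysis on the same genome-wide scale.

## The subset-slope test

For a subset $S$ (the TFs) and ranked variables $x, y$, the observed
statistic is the least-squares slope of $y$ on $x$ over $S$. Its null
distribution comes from random gene sets of size $|S|$ *matched to the
subset's mean ranks in both variables*: a candidate set $T$ qualifies when

$$\mathrm{RMSD}(T) = \sqrt{\tfrac12\left[(\bar x_T - \bar x_S)^2 +
(\bar y_T - \bar y_S)^2\right]} \le \tau,$$

with $\tau = 0.01$ (1% of the rank range) by default. Matching on both
means is essential: TFs are lowly expressed, and an unmatched random set
would differ systematically in average rank, biasing its slope. The
empirical p-value is the fraction of `n_samples` (default 10,000) null
slopes at least as extreme as the observed slope. A count of zero is
reported as the bound `p <= 1/n_samples` with `p_is_bound = TRUE`; an
empirical p of exactly zero is never reported.

**Samplers.** Rejection sampling from uniform subsets is exactly the
target distribution (uniform over qualifying sets) but becomes intractable
when the subset is off-centre. The default *swap sampler* starts from a
uniform subset, greedily swaps members against outsiders until the
tolerance is met, then performs `10 * |S|` accepted tolerance-preserving
random swaps before emitting the set. The randomizing phase is a symmetric
proposal chain on the qualifying set, so it approaches the same uniform
law; this equivalence is not assumed — the test suite compares 200 null
slopes from each sampler with a two-sample Kolmogorov-Smirnov test on a
300-gene instance where rejection is tractable. The hot loop is C++ with
all randomness drawn from R's RNG, so results are reproducible under
`set.seed()`.

**Direction.** "Flatter" means *closer to zero than the null trend*: for a
negative genome-wide trend the flatter tail is the upper tail of the null
slope distribution. `slope_pvalue()` accepts `direction = "flatter"`,
`"steeper"`, `"two_sided"`, or `"auto"` (the default), which reports the
one-sided p in whichever direction the observed slope deviates from the
null median — the convention that matches single-p-value reporting of a
named finding. Because `"auto"` selects the tail after seeing the data,
its null exceedance rate is twice nominal; calibration studies therefore
pre-specify a direction, and any confirmatory use should too. Null
samples are drawn from the full universe including the subset (an
`exclude_subset` flag is available); at yeast-genome proportions the
overlap effect is negligible.

**Calibration and power.** With the tested subset itself drawn from the
matched null (500 replicates, universe 2000, subset 150, 500 null samples,
fixed direction), the fraction of p < 0.05 must land in [0.03, 0.07]. With
generic genes generated at a rank-slope of −0.5 against expression and the
TF subset generated with no trend and shifted expression, the test rejects
at 0.05 in well over 80% of 100 runs. Both studies run inside the test
suite and the reproduction script at exactly these sizes.

## Regulatory networks and TF profiles

Edge records (one row per edge-experiment observation) collapse into
unique directed edges whose support is the number of distinct experiments.
*Confirmed edges* are those with support ≥ 2, a guard against
false-positive interactions. Degrees always count distinct neighbours.
Per-TF profiles summarize regulons: median target Ka/Ks over *assigned*
rates (so missing-ortholog targets enter at their top value), the fraction
of targets missing an ortholog, and the fractions of targets in the
genome-wide top 20% of conservation (rate rank ≤ 0.2), PPI degree and
expression (rank ≥ 0.8) — thresholds always on genome-wide ranks, not
within-regulon ranks. Profiles require ≥ 3 targets (≥ 2 is customary on
the sparser confirmed-edge network), and the missing-ortholog fraction
additionally requires ≥ 3 targets because ortholog loss affects only
~10% of genes. Sources (ChIP-derived versus literature-curated) are kept
separate; no statistic mixes dialects.

## Edge signs from knockout expression

An X score is a confidence-weighted log expression ratio of knockout
versus wild type. For edges whose |X| strictly exceeds 1, the sign of the
expression change identifies the regulatory mode: under the
`ko_over_wt` orientation, X < −1 means the target dropped when its
regulator was removed (activation), X > +1 means repression. The
orientation is a flag because source datasets differ in which way the
ratio is logged. Assignment is idempotent, order-independent, and monotone
in the threshold. Sign-stratified correlations then ask, over TFs with at
least 5 distinct same-sign targets, whether TF Ka/Ks follows the median
rate and missing-ortholog fraction of activated versus repressed targets.

## Co-regulation spread and enrichment

For each TF with ≥ 3 ortholog-bearing targets carrying the property, the
observed spread is the median absolute pairwise difference over its
targets. The null draws 100 equally sized gene sets *with probability
proportional to regulatory in-degree, without replacement* (successive
draws with weight renormalization — base R's weighted `sample()`), so null
sets mimic the propensity of highly regulated genes to appear in regulons.
The per-TF observed and expected spreads are compared with the Wilcoxon
rank-sum test, one-sided ("less") by default since the scientific question
is whether co-regulated genes are *closer* than expected; the alternative
is configurable (a signed-rank variant of the question would pair the
per-TF values, but the rank-sum form is the one implemented as primary).

Target-set enrichment compares targets of the 25% fastest-evolving TFs
(ties at the quartile boundary broken by gene id; genes targeted by both
groups count as fast-TF targets, with an exclusive-assignment option)
against targets of the remaining TFs, term by term, with a one-sided
Fisher's exact test over categories with ≥ 50 members among the union.
Raw p-values are reported and flagged at 0.05 with no multiple-testing
correction, matching standard reporting for this design; annotations are
flat sets with no ontology-graph propagation.

Binned-median profiles (the plotting summary) use equal-count bins on the
x order, report the bin median — robust to outliers and to the
missing-ortholog value — and estimate the SE of the median from 100
bootstrap resamples.

## Expression divergence between species

Counts are normalized to reads-per-million with the lowest expression
fixed at 1 RPM, which controls for sequencing depth and keeps fold changes
finite; before flooring, RPM sums to exactly $10^6$ per sample. Genes with
zero counts in both species are retained (both floored, fold change 0).
Per ortholog pair the statistic is the absolute log2 fold change, and an
unpaired t-test (Welch by default; pooled-variance available) compares
targets of the fastest 25% of TFs with targets of the rest on the
confirmed-edge network. Replicates are assumed pooled into one count
column per species.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every statistical property of the package is validated.
Marginals and couplings are produced by a rank-targeted Gaussian copula —
latent standard normals with structured correlations, mapped through the
marginal quantile functions — so configured Spearman-scale couplings are
achieved without distorting marginals.

Defaults and why:

* **2000 genes, 174 TFs.** 174 is the size of the curated yeast TF set
  the analyses are built around; 2000 genes is a desk-scale genome that
  keeps test runtimes in seconds while preserving all rank-statistics
  behaviour (a full-genome run just changes `n_genes`).
* **Expression** log-normal (meanlog 3, sdlog 1.5, arbitrary RPM-like
  units); **CAI** a noisy monotone transform of expression (latent
  correlation 0.9); **Ka/Ks** log-normal around 0.12.
* **Genome trends.** Rank slope of Ka/Ks on expression −0.5 — abundance
  as the dominant genome-wide determinant — and −0.3 on PPI degree. TF
  rows use `slope x tf_trend_multiplier` (default 0.3: the flattened TF
  trends the slope test is designed to detect) and a latent expression
  shift of −0.8 (TFs are lowly expressed, which is what makes naive
  rejection sampling intractable and the matched null necessary).
* **Out-degrees** follow a truncated discrete power law with exponent 2 on
  [30, 200]. The lower bound reflects ChIP-compendium regulons — several
  thousand signable edges over ~10^2 TFs implies ≥ 30 targets per TF on
  average — and is what lets ~150 TFs accumulate the 5 same-sign targets
  the stratified analysis requires.
* **Edge signs** are activating with probability 0.65, matching the
  roughly 2:1 activating:repressive split of signable regulation.
* **TF-target rate coupling.** Each regulated gene couples to one
  uniformly chosen primary regulator (activating if any). Its rate latent
  is `r_e z_expr + s (a z_TF + c w_TF + b eps)` with a per-regulon shared
  component `w_TF` and idiosyncratic share `b^2 = 0.3`. The loading `a`
  is solved in closed form so that the *TF-level* statistic the analysis
  estimates — Spearman between TF Ka/Ks and median same-sign-target
  Ka/Ks — equals the configured coupling (default 0.3 activated, 0
  repressed), accounting for regulon-size effects and for the dilution
  caused by targets whose primary regulator is another TF. A fixed
  empirical constant (0.86) absorbs the residual attenuations the closed
  form ignores (tied rank blocks from the missing-ortholog assignment,
  clustering of non-coupled regulon members, finite-regulon median
  efficiency); it was fixed once by matching the analysis-level recovery
  over repeated generator draws. The per-edge target-TF correlation is
  consequently lower than the configured TF-level value.
* **Ortholog loss** with baseline probability 0.1, modulated linearly by
  the primary activating regulator's rate rank (coupling 1), so fast-TF
  regulons are enriched for species-specific genes.
* **Knockout X scores**: N(−mu, sd) for activating and N(+mu, sd) for
  repressive edges (mu 2, sd 0.5), near-zero background for non-edges,
  for the 78% of TFs with knockout coverage (~135 of 174). Noiseless
  scores invert the sign rule exactly; at sd 1 the miscall rate per
  signable edge is the Gaussian tail beyond the opposite threshold,
  well under 10%.
* **Edge support**: 1 + Binomial(2, 0.4) re-detections, putting ~64% of
  edges in the confirmed network.
* **Two-species counts**: Poisson around expression x depth 50 (about
  10^3 reads for a median gene, typical of yeast RNA-seq after pooling).
  Shallower depth would let Poisson noise on lowly expressed genes leak
  expression composition into |log2FC| and mis-calibrate the null
  t-test. The log2 divergence shift has SD `scale (1 + coupling)` for
  targets of the fastest 25% of TFs — at coupling 1, a doubled
  divergence scale, the condition the power analysis assumes — and
  `scale` (0.5) otherwise; a regulator missing its ortholog counts as
  maximally diverged. A continuous modulation by regulator-rate rank was
  considered but in a realistically dense network the maximum regulator
  rank of non-fast targets crowds toward the fast boundary, compressing
  the group contrast far below the intended doubling.
* **Annotations**: 30 flat terms of 30-120 genes; odd-numbered ("niche")
  terms prefer fast-TF targets with odds 3, even-numbered ("core") terms
  prefer other targets.

Ground truth (true signs, latents, realized couplings, term classes) is
emitted alongside the data and is never an input to any analysis function;
a test asserts that no analysis entry point even has a `truth` argument.
Per-stage sub-seeds are derived by hashing the master seed with the stage
name, so adding a stage never perturbs another stage's randomness and a
fixed (config, seed) yields byte-identical output files.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: a literature-curated edge dialect distinct from
the ChIP dialect; assortativity of evolutionary rate across PPI edges
(median-interactor-rate correlations are near null here); the weak
negative in-degree trend of generic genes; ontology graph structure;
replicate-level count structure; and any sequence-level realism (rates
and CAI are drawn, not computed from sequences — rate estimation, CAI
computation and orthology calling are out of scope throughout).

## Study sizes, numerical choices, limitations

The test suite and the reproduction script run: calibration at 500 (script:
300) replicates x 500 null samples; power at 100 runs; sampler equivalence
at 200 + 200 slopes on 300 genes; coupling recovery over 50 (script: 30)
generated datasets with knockout coverage raised to 0.86 so ~150 TFs enter
each sign stratum; divergence null and power over 100 (script: 60) datasets
each; and a full double pipeline run for byte-level determinism. These
sizes are the package's study design and complete in a few minutes on one
CPU.

With ~150 TFs per stratum the Spearman estimate has a standard error near
0.08, so single-dataset stratified correlations should be read with that
uncertainty in mind; the recovery band used in validation ([0.15, 0.45]
around a configured 0.3) spans roughly ±1.8 standard errors and per-dataset
excursions outside it are expected a few percent of the time. Degenerate
inputs are errors, not silent results: subsets below 3 genes, zero
within-subset variance, empty gene pools, all-zero count samples, terms
annotating no partners. Ties are handled by midranks everywhere; the
p-value bound convention (`p <= 1/n_samples`) is used wherever a resampling
count is zero. The swap sampler inherits one approximation — finite
randomizing chains — whose practical adequacy is exactly what the
KS-equivalence test measures.
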