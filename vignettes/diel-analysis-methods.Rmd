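---
title: "Methods for diurnal multi-omics analysis with dielmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods for diurnal multi-omics analysis with dielmetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielmetrics)
```

This vignette documents the statistical methods implemented in
`dielmetrics`, the choices made where a method admits more than one
reasonable reading, and the scope and limits of the synthetic-data
generators used for validation.

# Study design and vocabulary

The package targets diurnal studies crossing a host-genotype axis
(wild-type, `WT`, vs. liver clock knockout, `LKO`) with a microbial axis
(conventionally raised, `SPF`, vs. germ-free, `GF`). Samples are collected
at a small number of zeitgeber times (ZT, hours after lights-on in a 12:12
light/dark cycle), typically 6 timepoints × 3 replicates for liver RNA and
4 timepoints × 8 replicates over 2 days for cecal 16S profiles.
`diurnal_design()` encodes such designs.

# Rhythm detection

## Empirical JTK (`ejtk_scan`)

Each feature's series is compared against a family of period-24 cosine
reference waveforms built by `build_reference_waveforms()`: peak phases on a
2-hour grid (12 waveforms by default) and, optionally, asymmetric variants
obtained by piecewise-linear time warping of the cosine's rise/fall. The
test statistic is the maximum Kendall tau-b between the observed series and
any reference waveform. Kendall correlation makes detection invariant to
monotone transformations of the data, so the same calls result from raw,
log, or variance-stabilised inputs.

Significance uses a *pooled* permutation null: values of each non-constant
feature are permuted and rescanned, and all permuted maxima are pooled into
one null sample (default `n_null = 10000`). The empirical p is
`(1 + #{null >= tau}) / (1 + n_null)`, which can never be smaller than
`1/(n_null + 1)`. To resolve smaller tails, a gamma distribution is fitted
by maximum likelihood to the transformed null statistics `s = (1 + tau)/2`.

Two numerical choices matter here:

* **Shift-profiled gamma.** A plain two-parameter gamma misfits the pooled
  max-statistic null near its left edge, which distorts the far tail. We
  therefore profile a location shift over a grid in `[0, min(s))` and keep
  the maximum-likelihood triple (shape, scale, shift); shift 0 is always in
  the grid, so the two-parameter fit is recovered when it is adequate.
  With this fit, gamma tail probabilities track the empirical tail within
  0.02 wherever the empirical tail is resolvable.
* **GammaBH.** Features are called oscillating when the Benjamini–Hochberg
  adjusted gamma p (`q_bh`) is below 0.05.

The scan's phase estimate is the grid phase of the best-matching waveform,
so its resolution equals the phase step (2 h by default). Phase is circular:
an estimate of 23 h for a truth of 0.5 h is a 1.5-h error, and any
comparison of phase orderings must account for the 0/24 wrap.

## Cosinor regression (`harmonic_regression`)

The parametric alternative fits
`y = mesor + a cos(2*pi*t/24) + b sin(2*pi*t/24)` by least squares and tests
the joint hypothesis `a = b = 0` with the exact F(2, n−3) statistic.
Amplitude is `sqrt(a^2 + b^2)` and acrophase `atan2(b, a)` converted to
hours. On noiseless cosine input the fit is exact to machine precision; on
Gaussian null input the rejection rate at p < 0.05 is 0.05 by construction,
which the test suite verifies empirically.

# Driver partitioning

`overlap_counts()` reduces per-group oscillation calls to exact Venn
regions. `classify_drivers()` applies table-driven rules over the 2×2
factorial, in precedence order:

1. *system-driven* — rhythmic in all four groups;
2. *liver-clock-driven* — rhythmic in both WT groups and neither LKO group;
3. *liver-clock-independent* — rhythmic in both LKO groups;
4. *microbe-driven* — rhythmic in both SPF groups and neither GF group;
5. *microbe-independent* — rhythmic in both GF groups.

The rules are not mutually exclusive (a system-driven feature also satisfies
both independence rules), so the primary `category` is the first match in
precedence order while `all_categories` retains every match;
`exclusive = TRUE` keeps only the first. Features matching no rule are
`"none"`. For heatmap display, `median_normalize_and_order()` divides each
row by its median (rows with a zero median are flagged and placed last) and
orders rows by estimated peak phase.

# Microbiome composition

Sample filtering removes samples whose total count falls below
`mean − 1.5 SD` of the per-sample totals; feature filtering removes ASVs
present in fewer than 10 samples. Rarefaction subsamples every remaining
sample to a common depth — by default the same `mean − 1.5 SD` statistic,
floored — using `vegan::rrarefy`, i.e. sampling without replacement, so
column sums are exactly the target depth and per-feature counts follow the
multivariate hypergeometric distribution. `collapse_taxonomy()` sums counts
at any rank of a QIIME-style 7-rank lineage, binning unnamed clades as
`unclassified-<parent>`.

## Multinomial differentials

Timepoint effects on composition are estimated by multinomial regression of
counts on ZT indicator covariates (reference-frame log-fold changes). The
optimiser is deliberately simple and transparent: full-batch gradient
descent on the negative log-likelihood plus an L2 penalty (1e-4), default
40,000 epochs at learning rate 1e-4, with a step-halving safeguard (a step
that increases the loss is retried at half the rate; the rate recovers by
5% per successful step, capped at its initial value). Multinomial
coefficients are identifiable only up to a per-covariate constant, so the
returned differentials are CLR-centred: they sum to zero across features for
each non-reference ZT, and are invariant to per-sample count scaling. On a
two-feature toy whose true composition shifts from 50:50 to 2:1 the
recovered differentials are ±ln(2)/2 to within 5×10⁻⁵.

Downstream, `loess_profile()` (degree-1, direct surface) smooths per-feature
log-ratios over ZT, `sinusoid_fit()` summarises them as a 24-h sinusoid, and
`compare_fit_quality()` contrasts paired R² between groups.

# Coexpression networks

Replicates are never averaged before correlating. Each permutation draws
one replicate per timepoint (a "flattened" series of length 6), computes
Spearman's r for every feature pair and a p-value from the t approximation
`t = r sqrt((n−2)/(1−r^2))`, and both matrices are averaged over
permutations (500 by default). Two implementation choices are load-bearing:

* **The t-approximation p is required, not optional.** At n = 6 the exact
  permutation p of Spearman's rho cannot reach 0.001 (the best possible
  two-sided exact p is 1/360), so the edge rule p < 0.001 AND r > 0.95 is
  only satisfiable with the continuous approximation.
* **Balanced replicate sampling.** Rather than sampling replicates
  independently per permutation, each replicate is used an equal number of
  times per timepoint (shuffled). This is a variance-reduction device with
  uniform marginals; whenever the requested number of permutations is at
  least the number of distinct combinations (3⁶ = 729 for 3 replicates × 6
  timepoints), the package enumerates all combinations exhaustively and the
  average is exact. On 20-feature fixtures the 500-permutation average is
  within 0.02 element-wise of the exhaustive oracle.

Before correlation, transcripts with fewer than 50 counts in every sample,
or more than two zero-count samples in any timepoint, are removed.
`build_edge_table()` applies the p/r thresholds to the upper triangle (no
self pairs), and `network_summary()` computes node/edge counts, degree and
betweenness via igraph, plus per-annotation-category counts with either a
both-endpoint or either-endpoint edge rule. Note the strict thresholds are
calibrated for transcriptome-scale inputs; small toy matrices typically
yield zero edges because the *averaged* p rarely falls below 0.001 even for
strongly coherent pairs.

# Indirect calorimetry

Energy expenditure uses the Weir equation
`EE [kcal/h] = 3.941 VO2 + 1.106 VCO2` and RER = VCO2/VO2. Photoperiods are
segmented from the lux channel by thresholding with debouncing (runs shorter
than 5 samples merge into the preceding period), labelled `light_d1`,
`dark_d1`, and so on.

Outliers are masked per channel (VO2, VCO2, EE, RER) *within each
photoperiod* using the Rousseeuw–Croux Sn scale estimator,
`Sn = 1.1926 lowmed_i highmed_j |x_i − x_j|`, implemented with the exact
high/low median position conventions and verified against a brute-force
double loop. Values outside `median ± 3 Sn` are masked. Sn, unlike the MAD,
does not collapse for skewed data, and the per-photoperiod application stops
the light/dark alternation itself from being read as dispersion.

Per-period summaries (`period_aggregate`) give beam-break sums, food/water
ranges and EC50s of the masked EE/RER/VO2 distributions. The EC50 is the
midpoint of a 4- or 5-parameter logistic fitted to the percent relative
cumulative frequency (PRCF) curve of the sorted values
(`minpack.lm::nlsLM`, with percentile interpolation as a fallback); on
symmetric samples it agrees with the median to well under 1%. Basal
metabolic rate is the minimum mean EE over short contiguous windows
(default 6 min, i.e. two 3-min samples) within ZT7–10. Group comparisons of
calorimetry endpoints adjust for body weight by ANCOVA
(`value ~ body_weight + group`).

# Shared statistics

`bh_adjust()` wraps `p.adjust(method = "BH")`; `baseline_auc()` computes the
net trapezoidal area under a baseline-subtracted tolerance curve (negative
excursions count negatively); `group_compare()` provides Welch's t and
Welch ANOVA with Dunnett-style many-to-one comparisons using the
single-step multivariate-t adjustment (`mvtnorm`), with the shared-reference
covariance structure.

# Synthetic data: scope and limits

The generators exist to provide ground truth for validation and worked
examples, not to imitate any particular dataset.

* **Transcripts** (`simulate_transcript_counts`): negative-binomial counts
  with log-mean `baseline + amplitude·cos(2π(ZT − phase)/24)`; phases on
  the 2-h grid, baselines N(4, 1), dispersion 0.05 by default. Oscillation
  can be restricted to chosen groups to plant driver categories.
* **ASV tables** (`simulate_asv_table`): multinomial draws over softmax
  log-abundances with uniform sequencing depths, plus a 7-rank taxonomy.
* **Calorimetry** (`simulate_calorimetry_trace`): 3-min cadence, 12:12 lux,
  dark-phase peaks in VO2/RER, Gaussian sensor noise. Planted sensor
  spikes are scaled to a multiple (default 10×) of the *within-photoperiod
  Sn scale of the clean channel* — the same scale the masking rule
  estimates — so "planted spike" and "true outlier under the rule" coincide
  and recovery rates are meaningful.
* **Tolerance curves** (`simulate_tolerance_curves`): group mean profiles
  plus iid Gaussian noise, with noiseless AUC truth recorded.

Limitations: problem sizes in the bundled pipeline config (hundreds of
features, thousands of permutations) are chosen so the whole validation
suite runs in minutes on one CPU; real studies operate at 10⁴–10⁵ features
and the headline counts of any particular study are functions of its data,
not reproducible from synthetic inputs. The generators use idealised noise
(NB/multinomial/Gaussian), a single fixed period of 24 h, and no
batch or cage effects. Reproducibility is strict: every generator and every
stochastic analysis step takes an explicit seed, and the pipeline derives
recorded sub-seeds from one global seed.
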