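# dielmetrics

Statistical tooling for diurnal (24-hour) multi-omics studies of host–microbe
metabolism: nonparametric rhythm detection in transcript counts, factorial
partitioning of oscillators into driver categories, compositional analysis of
16S ASV tables, permutation-resampled coexpression networks, and indirect
calorimetry summaries — plus a synthetic-data generator that plants known
rhythms so every estimator can be checked against ground truth.

## Scientific background

The liver clock and the gut microbiome jointly shape daily cycles in glucose
and lipid metabolism. Studies of this interaction typically cross a genotype
axis (wild-type vs. liver-specific clock knockout) with a microbial axis
(conventional "SPF" vs. germ-free), sample liver RNA and cecal 16S profiles
around the clock at a handful of zeitgeber times (ZT; hours after lights-on),
and record indirect-calorimetry traces. The analysis questions are always the
same:

1. **Which features oscillate?** Transcript or taxon abundance is tested for
   24-h rhythmicity. `dielmetrics` implements an empirical JTK approach
   (`ejtk_scan`): each series is compared, via Kendall's tau, against a grid
   of phase-shifted (and optionally asymmetric) period-24 reference
   waveforms; significance comes from a pooled permutation null, smoothed by
   a gamma fit to the null statistics so that small tail p-values are
   resolvable ("GammaBH" = BH-adjusted gamma p). A parametric alternative,
   cosinor `harmonic_regression`, is included for per-profile fits.
2. **What drives each oscillation?** With calls from all four groups of the
   2×2 design, `classify_drivers` applies the factorial logic: rhythmic in
   all four = system-driven; rhythmic only with an intact liver clock =
   liver-clock-driven; rhythmic in both knockouts = liver-clock-independent;
   and the analogous microbe-driven / microbe-independent splits.
   `overlap_counts` gives the Venn regions; `median_normalize_and_order`
   prepares phase-ordered heatmap matrices.
3. **How does the microbial community cycle?** ASV tables are depth-filtered
   (samples below mean − 1.5 SD of total counts), prevalence-filtered
   (features in < 10 samples), rarefied, and collapsed by taxonomy.
   Timepoint effects on composition are estimated as multinomial-regression
   differentials (reference-frame log-fold changes, CLR-centred), with
   LOESS profiles and sinusoid fits downstream.
4. **Which transcripts cycle together?** Replicates are not averaged:
   `averaged_correlation_matrices` draws one replicate per timepoint per
   permutation (500 by default, or exhaustively when feasible), computes
   Spearman correlation and its t-approximation p per draw, and averages
   both matrices; edges require averaged p < 0.001 and r > 0.95.
5. **What does the animal's energy budget do?** `weir_ee` (Weir equation),
   `compute_rer`, robust Sn-based outlier masking per photoperiod
   (`annotate_trace`), per-period sums/ranges and PRCF-EC50 summaries
   (`period_aggregate`, `prcf_ec50`), basal metabolic rate in the ZT7–10
   rest window (`basal_metabolic_rate`), and body-weight-adjusted group
   comparison (`ancova_compare`).

Shared statistics (Benjamini–Hochberg adjustment, baseline-normalised AUC for
tolerance tests, Welch/Dunnett comparisons) live in `bh_adjust`,
`baseline_auc` and `group_compare`. `run_pipeline` orchestrates everything
from one declarative config and writes checksummed artifacts.

## Worked example

Simulate a liver time course (6 ZTs × 3 replicates, 30% of 200 features
oscillating with log-amplitude 1.5), scan for rhythms, and inspect a fit:

```r
library(dielmetrics)

design <- diurnal_design(groups = "liver", n_replicates = 3L, seed = 42)
truth  <- oscillator_truth(200, groups = "liver", frac_oscillating = 0.3,
                           amplitude = 1.5, dispersion = 0.05, seed = 43)
ex <- simulate_transcript_counts(design, truth, seed = 44)

w   <- build_reference_waveforms(design$samples$zt_mod)
res <- ejtk_scan(log1p(ex$counts), w, n_null = 5000, seed = 45)
sum(res$oscillating)
#> [1] 60            # all 60 planted oscillators recovered
head(res[res$oscillating, c("feature", "tau_best", "phase_best_h", "q_bh")], 3)
#>    feature tau_best phase_best_h    q_bh
#> 1 feat0001    0.856           22 0.00138
#> 2 feat0002    0.749           14 0.00198
#> 3 feat0003    0.772            6 0.00154

fit <- harmonic_regression(log1p(ex$counts["feat0001", ]), design$samples$zt_mod)
round(c(mesor = fit$mesor, amplitude = fit$amplitude,
        acrophase = fit$acrophase_h), 2)
#>     mesor amplitude acrophase
#>      5.30      1.40     22.13   # planted phase was 22
```

Calorimetry, with 10 sensor spikes planted relative to the within-photoperiod
robust scale:

```r
tr  <- simulate_calorimetry_trace(n_days = 2, n_spikes = 10, seed = 46)
tr  <- annotate_trace(tr)                    # EE, RER, photoperiods, outliers
agg <- period_aggregate(tr)
agg[, c("period", "ec50_rer", "ec50_ee", "n_retained")]
#>     period ec50_rer ec50_ee n_retained
#> 1 light_d1   0.7914   12.50        238
#> 2  dark_d1   0.9146   16.88        235
#> 3 light_d2   0.7891   12.44        237
#> 4  dark_d2   0.9169   16.84        240

basal_metabolic_rate(tr$data$ee, tr$data$zt_h)
#> [1] 7.459                                  # kcal/h, min 6-min window in ZT7-10
sum(tr$outlier[tr$truth$spike_idx, "vo2"])
#> [1] 10                                     # all planted spikes masked
```

The light-phase RER EC50 near 0.79 (lipid oxidation at rest) versus ~0.92 in
the dark (carbohydrate oxidation while feeding) reproduces the expected
nocturnal-rodent pattern the generator plants.

End-to-end, `run_pipeline(default_config(seed = 1))` simulates the full 2×2
factorial, runs every analysis arm, and writes TSV/JSON artifacts with md5
checksums plus a `report.json` of seeds, filter logs and stage summaries.

## Reproduction

`scripts/acceptance.R` recomputes the headline quantities of every analysis
arm from freshly simulated data and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`; repeated runs with the same seed are
byte-identical. The report includes rhythm detection/false-call rates and
phase error, gamma-vs-empirical tail agreement, driver-classification
recovery, composition filter/rarefaction results, the multinomial
differential recovery error, the permutation-vs-exhaustive network gap, spike
masking rates, per-photoperiod RER EC50s and BMR. The testthat suite
(`tests/testthat/test-acceptance.R`) contains the corresponding
property-based checks; the full suite runs in well under 15 minutes on one
CPU.

## Vignette

`vignettes/diel-analysis-methods.Rmd` documents the methods in detail: the
reference-waveform construction, the pooled permutation null and its
shift-profiled gamma tail, driver-rule precedence, the multinomial
differential optimiser, the replicate-resampled network (and why the
t-approximation p is required at n = 6), robust Sn masking, PRCF-EC50
fitting, and the design of the synthetic generators, including their
limitations.
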