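#' Describe a factorial diurnal sampling design
#'
#' Encodes the sampling layout of a 2x2 factorial (genotype x microbial
#' status) diurnal study: which groups exist, which zeitgeber times are
#' sampled within a 24 h cycle, how many animals per group/timepoint, and how
#' many consecutive cycles are covered (1 for terminal liver collection,
#' 2 for repeat stool collection).
#'
#' @param groups Character vector of group labels.
#' @param timepoints_h Strictly increasing ZTs within one cycle, in hours.
#' @param n_replicates Animals per group per timepoint (>= 1).
#' @param n_cycles Number of consecutive 24 h cycles sampled.
#' @param seed Integer seed recorded with the design.
#' @return A `diurnal_design` object with a `samples` data frame holding one
#'   row per sample (`sample`, `group`, `zt`, `zt_mod`, `cycle`, `replicate`).
#' @examples
#' d <- diurnal_design() # the default liver design: 4 groups, 6 ZTs, n = 3
#' nrow(d$samples)
#' @export
diurnal_design <- function(groups = c("SPF-WT", "SPF-LKO", "GF-WT", "GF-LKO"),
                           timepoints_h = seq(2, 22, by = 4),
                           n_replicates = 3L, n_cycles = 1L, seed = 1L) {
  stopifnot(length(groups) >= 1L, !anyDuplicated(groups),
            all(diff(timepoints_h) > 0), n_replicates >= 1L, n_cycles >= 1L)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      zt_base = timepoints_h,
                      cycle = seq_len(n_cycles),
                      group = groups,
                      stringsAsFactors = FALSE)
  grid$zt <- grid$zt_base + (grid$cycle - 1L) * 24
  grid$zt_mod <- grid$zt %% 24
  grid$sample <- sprintf("%s_ZT%02d_c%d_r%d", grid$group, grid$zt_base,
                         grid$cycle, grid$replicate)
  structure(list(
    groups = groups, timepoints_h = timepoints_h,
    n_replicates = as.integer(n_replicates), n_cycles = as.integer(n_cycles),
    seed = as.integer(seed),
    samples = grid[, c("sample", "group", "zt", "zt_mod", "cycle",
                       "replicate")]
  ), class = "diurnal_design")
}

#' Ground-truth table of planted oscillators
#'
#' Builds the truth table consumed by the count simulators: each feature has
#' a baseline log-abundance, an oscillation amplitude (log scale), a peak
#' phase, a negative-binomial dispersion, and the set of groups in which it
#' oscillates (empty set = flat everywhere).
#'
#' @param n_features Number of features.
#' @param groups Group labels of the design.
#' @param frac_oscillating Fraction of features that oscillate.
#' @param oscillates_in Groups in which planted oscillators cycle; default all.
#' @param amplitude Log-scale amplitude of planted oscillators.
#' @param phase_h Peak phases; recycled/sampled over \[0, 24). `NULL` draws
#'   phases uniformly on the 2 h grid.
#' @param baseline Mean log-abundance (recycled; default draws N(4, 1)).
#' @param dispersion Negative-binomial dispersion (1/size), > 0.
#' @param seed Integer seed for the random assignments.
#' @return A data frame of class `oscillator_truth` with columns `feature`,
#'   `oscillates`, `oscillates_in` (comma-separated groups), `amplitude`,
#'   `phase_h`, `baseline`, `dispersion`.
#' @export
oscillator_truth <- function(n_features, groups = c("SPF-WT", "SPF-LKO",
                                                    "GF-WT", "GF-LKO"),
                             frac_oscillating = 0.2,
                             oscillates_in = groups,
                             amplitude = 1.5, phase_h = NULL,
                             baseline = NULL, dispersion = 0.05,
                             seed = 1L) {
  stopifnot(n_features >= 1L, frac_oscillating >= 0, frac_oscillating <= 1,
            all(oscillates_in %in% groups), all(dispersion > 0),
            all(amplitude >= 0))
  old <- withr_seed(seed); on.exit(restore_seed(old), add = TRUE)
  n_osc <- round(n_features * frac_oscillating)
  osc <- c(rep(TRUE, n_osc), rep(FALSE, n_features - n_osc))
  if (is.null(phase_h)) phase_h <- sample(seq(0, 22, by = 2), n_features,
                                          replace = TRUE)
  if (is.null(baseline)) baseline <- stats::rnorm(n_features, 4, 1)
  out <- data.frame(
    feature = sprintf("feat%04d", seq_len(n_features)),
    oscillates = osc,
    oscillates_in = ifelse(osc, paste(oscillates_in, collapse = ","), ""),
    amplitude = ifelse(osc, rep_len(amplitude, n_features), 0),
    phase_h = rep_len(phase_h, n_features) %% 24,
    baseline = rep_len(baseline, n_features),
    dispersion = rep_len(dispersion, n_features)
  )
  class(out) <- c("oscillator_truth", "data.frame")
  out
}

truth_log_mean <- function(truth, group, zt) {
  # log-mean abundance for every (feature, sample) pair
  osc_groups <- strsplit(truth$oscillates_in, ",", fixed = TRUE)
  vapply(seq_along(zt), function(j) {
    on <- vapply(osc_groups, function(g) group[j] %in% g, logical(1))
    truth$baseline +
      ifelse(on, truth$amplitude * cos(2 * pi * (zt[j] - truth$phase_h) / 24),
             0)
  }, numeric(nrow(truth)))
}

#' Simulate negative-binomial transcript counts with planted rhythms
#'
#' Counts are drawn per feature and sample from a negative binomial with
#' log-mean `baseline + amplitude * cos(2 pi (ZT - phase) / 24)` in groups
#' where the feature oscillates, and `baseline` elsewhere; `dispersion` is
#' the NB overdispersion (variance = mu + dispersion * mu^2).
#'
#' @param design A [diurnal_design()].
#' @param truth An [oscillator_truth()] table.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return A list of class `diel_experiment`: integer `counts` (features x
#'   samples), `samples` metadata data frame, and the `truth` table.
#' @export
simulate_transcript_counts <- function(design, truth, seed = design$seed) {
  stopifnot(inherits(design, "diurnal_design"), nrow(truth) >= 1L)
  if (anyDuplicated(truth$feature)) stop("duplicate feature ids in truth")
  if (any(truth$dispersion <= 0)) stop("dispersion must be positive")
  meta <- design$samples
  mu <- exp(truth_log_mean(truth, meta$group, meta$zt_mod))
  old <- withr_seed(seed); on.exit(restore_seed(old), add = TRUE)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = rep(1 / truth$dispersion,
                                             ncol(mu))),
                   nrow = nrow(truth),
                   dimnames = list(truth$feature, meta$sample))
  structure(list(counts = counts, samples = meta, truth = truth),
            class = "diel_experiment")
}

default_taxonomy <- function(features, seed = 1L) {
  # synthetic 7-rank lineages over a small set of gut-typical taxa
  pool <- data.frame(
    order = c("Clostridiales", "Clostridiales", "Clostridiales",
              "Bacteroidales", "Bacteroidales", "Lactobacillales",
              "Erysipelotrichales"),
    family = c("Lachnospiraceae", "Ruminococcaceae", "Oscillospiraceae",
               "Muribaculaceae", "Bacteroidaceae", "Lactobacillaceae",
               "Erysipelotrichaceae"),
    class = c("Clostridia", "Clostridia", "Clostridia", "Bacteroidia",
              "Bacteroidia", "Bacilli", "Erysipelotrichia")
  )
  old <- withr_seed(seed); on.exit(restore_seed(old), add = TRUE)
  idx <- sample(nrow(pool), length(features), replace = TRUE)
  data.frame(
    feature = features,
    lineage = sprintf(
      "d__Bacteria; p__%s; c__%s; o__%s; f__%s; g__g%03d; s__s%03d",
      ifelse(pool$class[idx] %in% c("Clostridia", "Bacilli",
                                    "Erysipelotrichia"),
             "Firmicutes", "Bacteroidota"),
      pool$class[idx], pool$order[idx], pool$family[idx],
      seq_along(features), seq_along(features))
  )
}

#' Simulate a multinomial ASV count table with planted rhythms
#'
#' Per sample, relative abundances are the softmax of per-feature
#' log-abundances (oscillating as in [simulate_transcript_counts()]) and
#' counts are drawn multinomially at a uniformly drawn sequencing depth, so
#' column sums equal the drawn depths exactly. A synthetic 7-rank taxonomy
#' lineage is attached to every feature.
#'
#' @param design A [diurnal_design()] (stool default: 2 cycles).
#' @param truth An [oscillator_truth()] table with >= 2 features.
#' @param depth_range Integer pair: uniform range of per-sample read depths.
#' @param taxonomy Optional data frame (`feature`, `lineage`); synthetic
#'   lineages are generated when omitted.
#' @param seed Integer seed.
#' @return An `asv_table` object: integer `counts`, `samples` metadata,
#'   `taxonomy`, an empty `filter_log`, the `truth` table and drawn `depths`.
#' @export
simulate_asv_table <- function(design, truth,
                               depth_range = c(15000L, 40000L),
                               taxonomy = NULL, seed = design$seed) {
  stopifnot(inherits(design, "diurnal_design"),
            length(depth_range) == 2L, all(depth_range > 0))
  if (nrow(truth) < 2L) stop("need at least 2 features for compositions")
  if (anyDuplicated(truth$feature)) stop("duplicate feature ids in truth")
  meta <- design$samples
  eta <- truth_log_mean(truth, meta$group, meta$zt_mod)
  old <- withr_seed(seed); on.exit(restore_seed(old), add = TRUE)
  depths <- sample(seq(depth_range[1L], depth_range[2L]), nrow(meta),
                   replace = TRUE)
  counts <- vapply(seq_len(nrow(meta)), function(j) {
    p <- exp(eta[, j] - max(eta[, j]))
    as.integer(stats::rmultinom(1L, depths[j], p / sum(p)))
  }, integer(nrow(truth)))
  dimnames(counts) <- list(truth$feature, meta$sample)
  if (is.null(taxonomy)) taxonomy <- default_taxonomy(truth$feature, seed)
  new_asv_table(counts, meta, taxonomy, truth = truth, depths = depths)
}

new_asv_table <- function(counts, samples, taxonomy, filter_log = list(),
                          truth = NULL, depths = NULL) {
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(list(counts = counts, samples = samples, taxonomy = taxonomy,
                 filter_log = filter_log, truth = truth, depths = depths),
            class = "asv_table")
}

#' Simulate a multichannel indirect-calorimetry trace
#'
#' Generates VO2, VCO2, lux, beam breaks and cumulative food/water at a
#' 3-minute cadence over `n_days` 12:12 light/dark days (lights on at ZT0).
#' VO2 and the respiratory exchange ratio follow smooth diurnal profiles
#' (higher in the dark/active phase) plus Gaussian noise; activity and
#' intake accrue mostly in the dark. Optional spike outliers of known
#' location are injected into VO2 and recorded in the returned truth.
#'
#' @param n_days Number of 24 h days (>= 1).
#' @param vo2_mean,vo2_diel Mean VO2 (L/h) and peak diurnal deviation.
#' @param rer_light,rer_dark Mean RER in light and dark phases.
#' @param noise_sd Gaussian noise SD on VO2 (L/h) and, scaled, on VCO2.
#' @param n_spikes Number of spike outliers injected into VO2.
#' @param spike_size Spike magnitude in units of `noise_sd`.
#' @param animal Animal identifier.
#' @param body_weight_g Body weight in grams (carried as metadata).
#' @param seed Integer seed.
#' @return A `calorimetry_trace` object: `data` (data frame with `time_min`,
#'   `zt_h`, `lux`, `vo2`, `vco2`, `beam_breaks`, `food_g`, `water_g`),
#'   `cadence_min`, `animal`, `body_weight_g` and `truth` (spike indices and
#'   noiseless channel values).
#' @export
simulate_calorimetry_trace <- function(n_days = 4L, vo2_mean = 3.0,
                                       vo2_diel = 0.6, rer_light = 0.75,
                                       rer_dark = 0.95, noise_sd = 0.1,
                                       n_spikes = 0L, spike_size = 10,
                                       animal = "mouse1",
                                       body_weight_g = 28, seed = 1L) {
  stopifnot(n_days >= 1L, vo2_mean > 0, noise_sd >= 0)
  per_day <- 24L * 20L                      # 3-min cadence
  n <- n_days * per_day
  time_min <- (seq_len(n) - 1L) * 3
  zt <- (time_min / 60) %% 24
  light <- zt < 12
  lux <- ifelse(light, 300, 0)
  old <- withr_seed(seed); on.exit(restore_seed(old), add = TRUE)
  # activity (and hence VO2, RER) peaks in the dark phase around ZT18
  vo2_clean <- vo2_mean + vo2_diel * cos(2 * pi * (zt - 18) / 24)
  rer_clean <- (rer_light + rer_dark) / 2 +
    (rer_dark - rer_light) / 2 * cos(2 * pi * (zt - 18) / 24)
  vo2 <- vo2_clean + stats::rnorm(n, 0, noise_sd)
  vco2 <- vo2_clean * rer_clean + stats::rnorm(n, 0, noise_sd * 0.8)
  spike_idx <- integer(0)
  if (n_spikes > 0L) {
    # spikes are planted as true outliers: their magnitude is spike_size
    # times the within-photoperiod robust (Sn) scale of the clean channel,
    # the same scale the median +/- k*Sn masking rule estimates
    spike_idx <- sort(sample(n, n_spikes))
    per <- paste0(ifelse(light, "L", "D"), cumsum(c(1, diff(light) != 0)))
    per_scale <- vapply(unique(per), function(p)
      sn_scale(vo2[per == p]), numeric(1))
    vo2[spike_idx] <- vo2[spike_idx] +
      sample(c(-1, 1), n_spikes, replace = TRUE) * spike_size *
      per_scale[per[spike_idx]]
  }
  beam <- stats::rpois(n, lambda = ifelse(light, 2, 10))
  food <- cumsum(stats::rexp(n, rate = 1) * ifelse(light, 0.0004, 0.002))
  water <- cumsum(stats::rexp(n, rate = 1) * ifelse(light, 0.0006, 0.003))
  structure(list(
    data = data.frame(time_min = time_min, zt_h = zt, lux = lux,
                      vo2 = pmax(vo2, 0), vco2 = pmax(vco2, 0),
                      beam_breaks = beam, food_g = food, water_g = water),
    cadence_min = 3, animal = animal, body_weight_g = body_weight_g,
    truth = list(spike_idx = spike_idx, vo2_clean = vo2_clean,
                 rer_clean = rer_clean)
  ), class = "calorimetry_trace")
}

#' Simulate per-animal tolerance-test curves
#'
#' Each animal's (time, glucose) curve is the group mean profile plus iid
#' Gaussian noise; the baseline-normalised AUC of each noiseless profile is
#' recorded as truth.
#'
#' @param group_means Named list: group label -> numeric mean glucose profile
#'   evaluated at `times`.
#' @param times Sampling times in minutes, starting at 0 (baseline).
#' @param noise_sd Gaussian noise SD (mg/dL).
#' @param n_per_group Animals per group.
#' @param seed Integer seed.
#' @return A list: `curves` (long data frame `animal`, `group`, `time`,
#'   `glucose`) and `truth_auc` (named vector of noiseless AUCs).
#' @export
simulate_tolerance_curves <- function(group_means,
                                      times = c(0, 15, 30, 60, 90, 120),
                                      noise_sd = 10, n_per_group = 10L,
                                      seed = 1L) {
  stopifnot(is.list(group_means), length(group_means) >= 1L,
            times[1L] == 0, all(diff(times) > 0))
  if (!all(lengths(group_means) == length(times)))
    stop("each group profile must match the times vector")
  old <- withr_seed(seed); on.exit(restore_seed(old), add = TRUE)
  rows <- lapply(names(group_means), function(g) {
    do.call(rbind, lapply(seq_len(n_per_group), function(a) {
      data.frame(animal = sprintf("%s_a%02d", g, a), group = g, time = times,
                 glucose = group_means[[g]] +
                   stats::rnorm(length(times), 0, noise_sd))
    }))
  })
  truth <- vapply(group_means, function(p) baseline_auc(p, times), numeric(1))
  list(curves = do.call(rbind, rows), truth_auc = truth)
}
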