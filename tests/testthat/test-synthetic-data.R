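test_that("generators are deterministic under a fixed seed", {
  d <- diurnal_design(seed = 5)
  tr <- oscillator_truth(40, seed = 6)
  a <- simulate_transcript_counts(d, tr, seed = 7)
  b <- simulate_transcript_counts(d, tr, seed = 7)
  expect_identical(a$counts, b$counts)
  ta <- simulate_asv_table(d, tr, seed = 8)
  tb <- simulate_asv_table(d, tr, seed = 8)
  expect_identical(ta$counts, tb$counts)
  ca <- simulate_calorimetry_trace(n_days = 1, seed = 9)
  cb <- simulate_calorimetry_trace(n_days = 1, seed = 9)
  expect_identical(ca$data, cb$data)
})

test_that("design invariants and input validation hold", {
  d <- diurnal_design(groups = c("A", "B"), timepoints_h = c(2, 8, 14, 20),
                      n_replicates = 7, n_cycles = 2)
  expect_equal(nrow(d$samples), 2 * 4 * 7 * 2)
  expect_false(anyDuplicated(d$samples$sample) > 0)
  expect_error(diurnal_design(timepoints_h = c(4, 2)), "diff")
  tr <- oscillator_truth(10, seed = 1)
  tr_bad <- tr; tr_bad$feature[2] <- tr_bad$feature[1]
  expect_error(simulate_transcript_counts(diurnal_design(), tr_bad),
               "duplicate")
  tr_bad2 <- tr; tr_bad2$dispersion <- -1
  expect_error(simulate_transcript_counts(diurnal_design(), tr_bad2),
               "dispersion")
  expect_error(simulate_asv_table(diurnal_design(), tr[1, , drop = FALSE]),
               "at least 2 features")
})

test_that("flat truth gives group means that differ only by sampling noise", {
  d <- diurnal_design(groups = "A", n_replicates = 40)
  tr <- oscillator_truth(30, groups = "A", frac_oscillating = 0,
                         baseline = 4, dispersion = 0.05, seed = 2)
  ex <- simulate_transcript_counts(d, tr, seed = 3)
  zt_means <- t(apply(ex$counts, 1, tapply, ex$samples$zt_mod, mean))
  # per-ZT means hover around the common NB mean exp(4)
  expect_lt(max(abs(zt_means / exp(4) - 1)), 0.25)
})

test_that("negative-binomial means match the closed form within MC error", {
  d <- diurnal_design(groups = "A", timepoints_h = c(0), n_replicates = 10000)
  tr <- oscillator_truth(2, groups = "A", frac_oscillating = 0,
                         baseline = 3, dispersion = 0.1, seed = 4)
  ex <- simulate_transcript_counts(d, tr, seed = 5)
  expect_lt(max(abs(rowMeans(ex$counts) / exp(3) - 1)), 0.02)
})

test_that("ASV tables conserve multinomial depths and flat compositions", {
  d <- diurnal_design(groups = "A", timepoints_h = c(2, 8, 14, 20),
                      n_replicates = 8, n_cycles = 2)
  tr <- oscillator_truth(25, groups = "A", frac_oscillating = 0, seed = 6)
  tab <- simulate_asv_table(d, tr, depth_range = c(5000, 9000), seed = 7)
  expect_identical(unname(colSums(tab$counts)), as.numeric(tab$depths))
  expect_true(all(tab$depths >= 5000 & tab$depths <= 9000))
  expect_equal(nrow(tab$taxonomy), 25)
  # flat truth: relative abundance has no ZT structure beyond noise
  rel <- sweep(tab$counts, 2, colSums(tab$counts), "/")
  zt_rel <- t(apply(rel, 1, tapply, tab$samples$zt_mod, mean))
  expect_lt(max(apply(zt_rel, 1, function(r) diff(range(r)) / mean(r))), 0.6)
})

test_that("a single planted ASV oscillator dominates the sinusoid fit R2", {
  d <- diurnal_design(groups = "A", timepoints_h = c(2, 8, 14, 20),
                      n_replicates = 8, n_cycles = 2)
  tr <- oscillator_truth(20, groups = "A", frac_oscillating = 0,
                         baseline = 4, seed = 8)
  tr$oscillates[1] <- TRUE
  tr$oscillates_in[1] <- "A"
  tr$amplitude[1] <- 2
  tab <- simulate_asv_table(d, tr, depth_range = c(20000, 30000), seed = 9)
  rel <- sweep(tab$counts, 2, colSums(tab$counts), "/")
  zt <- tab$samples$zt
  r2 <- apply(rel, 1, function(v) sinusoid_fit(v, zt)$r_squared)
  expect_gt(r2[1], quantile(r2[-1], 0.95))
})

test_that("calorimetry traces have exact 12:12 lux structure", {
  tr <- simulate_calorimetry_trace(n_days = 2, seed = 10)
  d <- tr$data
  expect_equal(nrow(d), 2 * 480)
  per_day <- split(d$lux > 0, rep(1:2, each = 480))
  for (day in per_day) {
    expect_equal(sum(day), 240)       # 12 h x 20 samples/h light
    expect_identical(day, rep(c(TRUE, FALSE), each = 240))
  }
})

test_that("zero-noise constant gas exchange gives constant Weir EE", {
  tr <- simulate_calorimetry_trace(n_days = 1, vo2_diel = 0, noise_sd = 0,
                                   rer_light = 0.8, rer_dark = 0.8,
                                   seed = 11)
  ee <- weir_ee(tr$data$vo2, tr$data$vco2)
  expect_lt(diff(range(ee)), 1e-9)
})

test_that("planted calorimetry spikes are recovered by the Sn mask", {
  tr <- simulate_calorimetry_trace(n_days = 1, n_spikes = 24,
                                   spike_size = 10, seed = 12)
  tr <- annotate_trace(tr, k = 3)
  mask <- tr$outlier[, "vo2"]
  sp <- tr$truth$spike_idx
  expect_gte(mean(mask[sp]), 0.95)
  expect_lte(mean(mask[-sp]), 0.02)
})

test_that("tolerance-curve truth AUC is exact at zero noise", {
  gm <- list(hi = c(100, 250, 200, 150, 120, 100),
             flat = rep(100, 6))
  sim <- simulate_tolerance_curves(gm, noise_sd = 0, n_per_group = 3,
                                   seed = 13)
  for (a in unique(sim$curves$animal)) {
    cur <- sim$curves[sim$curves$animal == a, ]
    expect_equal(baseline_auc(cur$glucose, cur$time),
                 unname(sim$truth_auc[cur$group[1]]))
  }
  expect_equal(unname(sim$truth_auc["flat"]), 0)
})

test_that("a 2x truth AUC ratio is detected by Welch t with high power", {
  gm <- list(a = c(100, 220, 180, 140, 110, 100),
             b = c(100, 340, 260, 180, 120, 100))
  stopifnot(abs(baseline_auc(gm$b, c(0, 15, 30, 60, 90, 120)) /
                baseline_auc(gm$a, c(0, 15, 30, 60, 90, 120)) - 2) < 0.05)
  set.seed(14)
  rej <- replicate(200, {
    sim <- simulate_tolerance_curves(gm, noise_sd = 15, n_per_group = 10,
                                     seed = sample.int(1e6, 1))
    aucs <- sapply(split(sim$curves, sim$curves$animal), function(cur)
      baseline_auc(cur$glucose, cur$time))
    grp <- sub("_a\\d+$", "", names(aucs))
    group_compare(aucs, grp, "welch_t")$p < 0.05
  })
  expect_gte(mean(rej), 0.9)
})
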