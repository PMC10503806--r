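zt6 <- rep(seq(2, 22, by = 4), each = 3)

test_that("waveform grid has one waveform per phase/asymmetry pair", {
  w <- build_reference_waveforms(zt6, period_h = 24, phase_step_h = 2)
  expect_equal(ncol(w$values), 12)
  expect_equal(w$phase_h, seq(0, 22, by = 2))
  w2 <- build_reference_waveforms(zt6, phase_step_h = 2,
                                  asymmetry_grid_h = c(6, 12, 18))
  expect_equal(ncol(w2$values), 36)
  expect_error(build_reference_waveforms(zt6, phase_step_h = 5), "divide")
  expect_error(build_reference_waveforms(rep(c(0, 6), each = 3)),
               "half a period")
})

test_that("phase-0 cosine is maximal at ZT0 and minimal at ZT12", {
  w <- build_reference_waveforms(c(0, 6, 12, 18), phase_step_h = 2)
  v <- w$values[, w$phase_h == 0]
  expect_equal(which.max(v), 1L)
  expect_equal(which.min(v), 3L)
  expect_equal(v, cos(2 * pi * c(0, 6, 12, 18) / 24))
})

test_that("waveforms half a period apart are exactly anti-monotone", {
  w <- build_reference_waveforms(zt6, phase_step_h = 2)
  for (p in seq(0, 10, by = 2)) {
    a <- w$values[, w$phase_h == p]
    b <- w$values[, w$phase_h == p + 12]
    expect_equal(unclass(kendall_tau(a, b)), -1,
                 ignore_attr = TRUE)
  }
})

test_that("kendall_tau handles the documented fixtures and degenerates", {
  expect_equal(as.numeric(kendall_tau(1:3, 1:3)), 1)
  expect_equal(as.numeric(kendall_tau(1:3, 3:1)), -1)
  expect_equal(as.numeric(kendall_tau(1:4, c(1, 3, 2, 4))), 2 / 3,
               tolerance = 1e-12)
  deg <- kendall_tau(c(1, 1, 1), c(1, 2, 3))
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
})

test_that("kendall_tau equals the pair-enumeration oracle with ties", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    x <- sample(0:5, n, replace = TRUE)
    y <- sample(0:5, n, replace = TRUE)
    if (diff(range(x)) == 0 || diff(range(y)) == 0) next
    expect_equal(as.numeric(kendall_tau(x, y)), kendall_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("a feature equal to a reference waveform scores tau 1", {
  w <- build_reference_waveforms(zt6)
  mat <- rbind(exact = w$values[, w$phase_h == 8],
               flat = rep(5, length(zt6)))
  res <- ejtk_scan(mat, w, n_null = 1000, seed = 42)
  expect_equal(res$tau_best[1], 1)
  expect_equal(res$phase_best_h[1], 8)
  expect_equal(res$p_empirical[1], 1 / 1001)
  expect_false(res$oscillating[2])
  expect_equal(res$p_gamma[2], 1)
})

test_that("the scan is invariant to strictly monotone transforms", {
  sim <- make_experiment(25, 0.4, seed = 50)
  w <- build_reference_waveforms(sim$zt)
  a <- ejtk_scan(sim$ex$counts, w, n_null = 1000, seed = 51)
  b <- ejtk_scan(sim$ex$counts^3 + 2, w, n_null = 1000, seed = 51)
  expect_equal(a$tau_best, b$tau_best)
  expect_equal(a$p_empirical, b$p_empirical)
  expect_equal(a$phase_best_h, b$phase_best_h)
})

test_that("gamma and empirical p agree in the well-sampled region", {
  sim <- make_experiment(300, 0.3, seed = 60)
  w <- build_reference_waveforms(sim$zt)
  # 10,000 permutations: the regime in which the gamma tail is meant to
  # stand in for the empirical one
  res <- ejtk_scan(log1p(sim$ex$counts), w, n_null = 10000, seed = 61)
  ok <- res$p_empirical >= 10 / 10000
  expect_gt(sum(ok), 50)
  expect_lt(max(abs(res$p_gamma[ok] - res$p_empirical[ok])), 0.02)
})

test_that("gamma null fitting recovers known parameters and is monotone", {
  set.seed(71)
  s <- rgamma(50000, shape = 2, scale = 0.1)
  fit <- fit_gamma_null(2 * s - 1)   # map so (1 + tau) / 2 recovers s
  expect_lt(abs(fit$shape / 2 - 1), 0.05)
  expect_lt(abs(fit$scale / 0.1 - 1), 0.05)
  tau <- 2 * s - 1
  expect_lte(fit$tail_prob(max(tau)), fit$tail_prob(median(tau)))
  grid <- seq(-0.5, 1, by = 0.05)
  expect_true(all(diff(fit$tail_prob(grid)) <= 0))
  expect_error(fit_gamma_null(rep(0.5, 2000)), "degenerate")
  expect_error(fit_gamma_null(runif(100)), "1000")
})

test_that("gamma tail tracks the empirical ECDF of a permutation null", {
  sim <- make_experiment(200, 0, seed = 80)
  w <- build_reference_waveforms(sim$zt)
  res <- ejtk_scan(log1p(sim$ex$counts), w, n_null = 10000, seed = 81)
  nt <- attr(res, "null_tau")
  fit <- fit_gamma_null(nt)
  grid <- seq(min(nt), max(nt), length.out = 100)
  emp <- vapply(grid, function(t) mean(nt >= t), numeric(1))
  expect_lt(max(abs(fit$tail_prob(grid) - emp)), 0.02)
})

test_that("harmonic regression is exact on noiseless cosinor input", {
  y <- 5 + 2 * cos(2 * pi * (zt6 - 8) / 24)
  fit <- harmonic_regression(y, zt6)
  expect_equal(fit$mesor, 5, tolerance = 1e-9)
  expect_equal(fit$amplitude, 2, tolerance = 1e-9)
  expect_equal(fit$acrophase_h, 8, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_lt(fit$p_value, 1e-12)
})

test_that("harmonic regression handles degenerate inputs per contract", {
  flat <- harmonic_regression(rep(3, length(zt6)), zt6)
  expect_equal(flat$amplitude, 0)
  expect_equal(flat$p_value, 1)
  expect_error(harmonic_regression(1:6, rep(c(0, 12), 3)), "4 distinct")
})

test_that("harmonic F test holds its nominal type-I rate on flat nulls", {
  set.seed(91)
  n_rep <- 5000
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    rej[i] <- harmonic_regression(rnorm(length(zt6)), zt6)$p_value < 0.05
  }
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("planted oscillators are detected with accurate phase", {
  sim <- make_experiment(120, 0.5, seed = 100, amplitude = 1.5,
                         dispersion = 0.05)
  w <- build_reference_waveforms(sim$zt)
  res <- ejtk_scan(log1p(sim$ex$counts), w, n_null = 2000, seed = 101)
  osc <- sim$truth$oscillates
  expect_gte(mean(res$oscillating[osc]), 0.8)
  det <- osc & res$oscillating
  err <- circular_phase_error(res$phase_best_h[det], sim$truth$phase_h[det])
  expect_gte(mean(err <= 2), 0.9)
})
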