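toy_table <- function(counts, zt = NULL, lineage = NULL) {
  nf <- nrow(counts); ns <- ncol(counts)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("asv", 1:nf)
  if (is.null(colnames(counts))) colnames(counts) <- paste0("s", 1:ns)
  meta <- data.frame(sample = colnames(counts), group = "A",
                     zt = zt %||% rep(2, ns),
                     zt_mod = (zt %||% rep(2, ns)) %% 24,
                     cycle = 1L, replicate = seq_len(ns))
  tax <- data.frame(feature = rownames(counts),
                    lineage = lineage %||% rep(
                      "d__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__g1; s__s1",
                      nf))
  dielmetrics:::new_asv_table(counts, meta, tax)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("depth filter computes the mean - 1.5 SD threshold", {
  counts <- rbind(rep(0, 5), c(1000, 1000, 1000, 1000, 100))
  tab <- toy_table(counts)
  out <- filter_samples_by_depth(tab)
  log <- out$filter_log[[1]]
  expect_equal(log$threshold, mean(c(rep(1000, 4), 100)) -
                 1.5 * sd(c(rep(1000, 4), 100)))
  expect_equal(log$threshold, 216.2573, tolerance = 1e-4)
  expect_equal(ncol(out$counts), 4)
  expect_equal(log$removed, "s5")
  # equal totals: nothing removed; re-application is a fixed point
  eq <- toy_table(matrix(100, 2, 4))
  out_eq <- filter_samples_by_depth(eq)
  expect_equal(ncol(out_eq$counts), 4)
  again <- filter_samples_by_depth(out_eq)
  expect_identical(again$counts, out_eq$counts)
})

test_that("prevalence filter keeps features present in >= min_samples", {
  counts <- matrix(0, 3, 12)
  counts[1, 1:9] <- 5    # present in 9: removed at min 10
  counts[2, 1:10] <- 1   # present in 10: kept
  counts[3, ] <- 2       # present in 12: kept
  tab <- toy_table(counts)
  out <- filter_features_by_prevalence(tab, min_samples = 10)
  expect_setequal(rownames(out$counts), c("asv2", "asv3"))
  # hand enumeration on a mixed toy
  set.seed(201)
  c2 <- matrix(rbinom(5 * 15, 1, 0.5), 5, 15,
               dimnames = list(paste0("f", 1:5), paste0("s", 1:15)))
  tab2 <- toy_table(c2)
  out2 <- filter_features_by_prevalence(tab2, min_samples = 8)
  expect_setequal(rownames(out2$counts),
                  rownames(c2)[rowSums(c2 > 0) >= 8])
})

test_that("rarefaction conserves depth and matches hypergeometric moments", {
  counts <- matrix(c(600, 300, 100), 3, 1,
                   dimnames = list(paste0("asv", 1:3), "s1"))
  counts <- counts[, rep(1, 10000), drop = FALSE]
  colnames(counts) <- paste0("s", 1:10000)
  tab <- toy_table(counts)
  # vegan warns that counts this large "don't look observed"; the fixture
  # is deliberately coarse so the hypergeometric moments are simple
  out <- suppressWarnings(rarefy(tab, depth = 200, seed = 5))
  expect_true(all(colSums(out$counts) == 200))
  # moments of the multivariate hypergeometric
  N <- 1000; n <- 200; K <- c(600, 300, 100)
  expect_mean <- n * K / N
  v <- n * (K / N) * (1 - K / N) * (N - n) / (N - 1)
  se <- sqrt(v / 10000)
  expect_true(all(abs(rowMeans(out$counts) - expect_mean) < 3 * se))
  # a sample already at the target depth passes through unchanged
  small <- toy_table(matrix(c(5, 7), 2, 3) * c(1, 1))
  out2 <- suppressWarnings(rarefy(small, depth = 12, seed = 6))
  expect_equal(unname(out2$counts), unname(small$counts),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(rarefy(small, depth = 0), "positive")
})

test_that("taxonomy collapse sums counts and conserves totals", {
  lin <- c(
    "d__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__a; s__x",
    "d__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__b; s__y",
    "d__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Ruminococcaceae; g__c; s__z",
    "d__Bacteria; p__Bacteroidota; c__Bacteroidia; o__Bacteroidales; f__; g__; s__")
  counts <- matrix(c(3, 4, 2, 1), 4, 2)
  counts[, 2] <- c(1, 1, 1, 1)
  tab <- toy_table(counts, lineage = lin)
  fam <- collapse_taxonomy(tab, "family")
  expect_equal(unname(fam$counts["Lachnospiraceae", ]), c(7, 2))
  expect_equal(unname(fam$counts["Ruminococcaceae", ]), c(2, 1))
  expect_equal(unname(fam$counts["unclassified-Bacteroidales", ]), c(1, 1))
  expect_equal(colSums(fam$counts), colSums(counts),
               ignore_attr = TRUE)
  ord <- collapse_taxonomy(tab, "order")
  expect_setequal(rownames(ord$counts), c("Clostridiales", "Bacteroidales"))
})

test_that("oscillating-fraction summary attributes abundance correctly", {
  lin <- rep(c(
    "d__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__a; s__x",
    "d__Bacteria; p__Bacteroidota; c__Bacteroidia; o__Bacteroidales; f__Muribaculaceae; g__b; s__y"),
    each = 3)
  counts <- matrix(10, 6, 4, dimnames = list(paste0("asv", 1:6), NULL))
  tab <- toy_table(counts, lineage = lin)
  rr <- data.frame(feature = rownames(counts),
                   oscillating = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  summ <- oscillating_fraction_summary(tab, rr, rank = "order")
  clo <- summ[summ$taxon == "Clostridiales", ]
  bac <- summ[summ$taxon == "Bacteroidales", ]
  expect_equal(clo$prop_oscillating, 2 / 3)
  expect_equal(bac$prop_oscillating, 0)
  expect_equal(bac$abundance_oscillating, 0)
  expect_equal(clo$abundance_oscillating, 2 / 6)
  expect_equal(clo$abundance_total + bac$abundance_total, 1)
  # all oscillate: oscillating abundance equals total
  rr$oscillating <- TRUE
  s2 <- oscillating_fraction_summary(tab, rr, rank = "order")
  expect_equal(s2$abundance_oscillating, s2$abundance_total)
})

test_that("two-feature differential toy recovers +/- ln(2)/2", {
  counts <- cbind(s1 = c(500, 500), s2 = c(500, 500),
                  s3 = c(666, 333), s4 = c(666, 333))
  rownames(counts) <- c("A", "B")
  res <- multinomial_differentials(counts, c("2", "2", "14", "14"),
                                   reference_zt = "2")
  expect_lt(abs(res$differentials["A", "14"] - log(2) / 2), 0.05)
  expect_lt(abs(res$differentials["B", "14"] + log(2) / 2), 0.05)
  expect_true(all(diff(res$loss) <= 1e-8 * abs(res$loss[1])))
})

test_that("differentials are null on identical compositions and scale-free", {
  base <- c(200, 300, 500)
  counts <- cbind(s1 = base, s2 = base, s3 = base, s4 = base)
  rownames(counts) <- paste0("f", 1:3)
  zt <- c("2", "2", "14", "14")
  res <- multinomial_differentials(counts, zt)
  expect_true(all(abs(res$differentials) < 0.05))
  # compositional scale invariance: multiplying one sample by 10
  counts2 <- counts; counts2[, 3] <- counts2[, 3] * 10
  res2 <- multinomial_differentials(counts2, zt)
  expect_true(all(abs(res2$differentials - res$differentials) < 0.05))
  # centred: differentials sum to zero per covariate
  expect_lt(max(abs(colSums(res$differentials))), 1e-8)
})

test_that("sinusoid fit is exact on family members and flat input", {
  t8 <- seq(0, 21, by = 3)
  y <- 5 + 2 * sin(2 * pi * t8 / 24)
  fit <- sinusoid_fit(y, t8)
  expect_equal(fit$m, 5, tolerance = 1e-9)
  expect_equal(fit$amplitude, 2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$phase_h, 6, tolerance = 1e-9)  # sin peaks at t = 6
  flat <- sinusoid_fit(rep(4, 8), t8)
  expect_equal(flat$amplitude, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(sinusoid_fit(1:3, c(0, 8, 16)), "4 points")
})

test_that("sinusoid fit agrees with harmonic regression", {
  set.seed(121)
  t <- rep(seq(2, 22, 4), each = 3)
  y <- 3 + 1.2 * cos(2 * pi * (t - 10) / 24) + rnorm(length(t), 0, 0.3)
  a <- sinusoid_fit(y, t)
  b <- harmonic_regression(y, t)
  expect_equal(a$m, b$mesor, tolerance = 1e-9)
  expect_equal(a$amplitude, b$amplitude, tolerance = 1e-9)
  expect_equal(a$phase_h, b$acrophase_h, tolerance = 1e-9)
})

test_that("amplitude estimates are unbiased on noisy planted sinusoids", {
  set.seed(122)
  t8 <- seq(0, 21, by = 3)
  amps <- replicate(1000, {
    y <- 2 + sin(2 * pi * t8 / 24) + rnorm(8, 0, 0.2)
    sinusoid_fit(y, t8)$amplitude
  })
  expect_lt(abs(mean(amps) - 1), 0.05)
})

test_that("sd outlier mask follows the single-pass mean +/- k SD rule", {
  expect_equal(sd_outlier_mask(rep(2, 5)), rep(FALSE, 5))
  # 5-point version is NOT flagged at k = 2 (bound exceeds the value)
  expect_false(any(sd_outlier_mask(c(0, 0, 0, 0, 10), k = 2)))
  # 10-point version flags the spike
  v <- c(rep(0, 9), 10)
  expect_equal(which(sd_outlier_mask(v, k = 2)), 10L)
  # translation equivariance
  set.seed(9)
  x <- rnorm(50)
  expect_identical(sd_outlier_mask(x), sd_outlier_mask(x + 100))
})

test_that("LOESS profile reproduces lines and tracks noisy sinusoids", {
  t <- seq(0, 23, length.out = 16)
  lin <- loess_profile(2 * t + 1, t, span = 0.75)
  expect_lt(max(abs(lin$fitted - (2 * lin$zt_h + 1))), 1e-9)
  const <- loess_profile(rep(3, 16), t, span = 0.75)
  expect_lt(max(abs(const$fitted - 3)), 1e-9)
  set.seed(10)
  y <- sin(2 * pi * t / 24) + rnorm(16, 0, 0.2)
  sm <- loess_profile(y, t, span = 0.5)
  truth <- sin(2 * pi * sm$zt_h / 24)
  expect_gte(cor(sm$fitted, truth), 0.95)
  expect_error(loess_profile(y[1:4], t[1:4], span = 0.2), "3 points")
})

test_that("paired R2 comparison handles identical, offset and shifted fits", {
  r2 <- c(0.5, 0.7, 0.9, 0.6)
  same <- compare_fit_quality(r2, r2)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  off <- compare_fit_quality(r2 + 0.05, r2)
  expect_true(off$degenerate)
  expect_equal(off$p, 0)
  set.seed(12)
  rej <- replicate(400, {
    a <- runif(20, 0.3, 0.7)
    compare_fit_quality(a + 0.2 + rnorm(20, 0, 0.1), a)$p < 0.05
  })
  expect_gte(mean(rej), 0.9)
  expect_error(compare_fit_quality(c(1, 2), c(1, 2)), "3 pairs")
})
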