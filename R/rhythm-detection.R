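#' Build a reference waveform set for the empirical JTK scan
#'
#' Evaluates a grid of period-24 h reference waveforms at the sampled
#' zeitgeber times. Each waveform is a cosine peaking at one grid phase;
#' optionally, asymmetric variants are generated by time-warping the cosine
#' so the rise from trough to peak takes `asymmetry` hours (12 h = symmetric).
#' Replicates sampled at the same ZT share the waveform value, so waveforms
#' are evaluated once per sample.
#'
#' @param timepoints_h Numeric vector of sample ZTs in hours, one per sample
#'   (replicates repeat the ZT; values beyond one period wrap around).
#' @param period_h Waveform period in hours (default 24).
#' @param phase_step_h Spacing of the peak-phase grid; must divide `period_h`.
#' @param asymmetry_grid_h Optional numeric vector of rise durations in hours
#'   (time from trough to peak). `NULL` or empty gives symmetric cosines only.
#' @return An object of class `reference_waveforms`: a list with `values`
#'   (samples x waveforms matrix), `phase_h`, `asymmetry_h`, `period_h`,
#'   `timepoints_h`.
#' @examples
#' w <- build_reference_waveforms(rep(seq(2, 22, by = 4), each = 3))
#' ncol(w$values) # 12 phases
#' @export
build_reference_waveforms <- function(timepoints_h, period_h = 24,
                                      phase_step_h = 2,
                                      asymmetry_grid_h = NULL) {
  stopifnot(is.numeric(timepoints_h), length(timepoints_h) >= 3L,
            period_h > 0, phase_step_h > 0)
  if (abs(period_h / phase_step_h - round(period_h / phase_step_h)) > 1e-9)
    stop("phase_step_h must divide period_h")
  if (diff(range(timepoints_h)) < period_h / 2)
    stop("timepoints span less than half a period; phase is unidentifiable")

  phases <- seq(0, period_h - phase_step_h, by = phase_step_h)
  asyms <- if (is.null(asymmetry_grid_h) || length(asymmetry_grid_h) == 0L) {
    period_h / 2
  } else {
    stopifnot(all(asymmetry_grid_h > 0), all(asymmetry_grid_h < period_h))
    asymmetry_grid_h
  }
  grid <- expand.grid(phase = phases, asym = asyms)
  vals <- mapply(function(ph, as_) {
    eval_warped_cosine(timepoints_h, ph, as_, period_h)
  }, grid$phase, grid$asym)
  vals <- matrix(vals, nrow = length(timepoints_h))
  const <- apply(vals, 2L, function(v) diff(range(v)) < 1e-12)
  if (all(const)) stop("all reference waveforms are constant at the sampled ZTs")
  structure(list(values = vals[, !const, drop = FALSE],
                 phase_h = grid$phase[!const],
                 asymmetry_h = grid$asym[!const],
                 period_h = period_h,
                 timepoints_h = timepoints_h),
            class = "reference_waveforms")
}

# cosine peaking at `phase`, falling over (period - asym) h, rising over
# `asym` h; asym = period/2 recovers the symmetric cosine exactly
eval_warped_cosine <- function(t, phase, asym, period) {
  fall <- period - asym
  tp <- (t - phase) %% period
  u <- ifelse(tp < fall, tp / fall, 1 + (tp - fall) / asym)
  cos(pi * u)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall tau between two equal-length vectors, the rank
#' kernel of the empirical JTK scan. If either vector is constant, tau-b is
#' undefined; the value 0 is returned with attribute `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Tau-b in \[-1, 1\], with a logical `degenerate` attribute.
#' @examples
#' kendall_tau(1:4, c(1, 3, 2, 4)) # 2/3
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    return(structure(0, degenerate = TRUE))
  structure(unname(stats::cor(x, y, method = "kendall")), degenerate = FALSE)
}

#' Empirical JTK-style rhythm scan
#'
#' For every feature, the maximal Kendall tau-b against a phase/asymmetry
#' grid of 24 h reference waveforms is computed. Significance comes from an
#' empirical null pooled across the run: the values of randomly chosen
#' features are permuted across samples `n_null` times and the max-tau
#' statistic recorded each time. The empirical p is
#' `(1 + #null >= tau) / (1 + n_null)`; a smooth tail p (`p_gamma`) comes
#' from a gamma distribution fitted by maximum likelihood to the shifted
#' null statistic `(1 + tau) / 2`, and features are called oscillating at
#' Benjamini-Hochberg adjusted `p_gamma` (GammaBH) < 0.05.
#'
#' @param mat Numeric features x samples matrix (rows named by feature).
#' @param waveforms A `reference_waveforms` object built at the sample ZTs
#'   (its rows must align with the columns of `mat`).
#' @param n_null Number of null permutations pooled into the empirical null
#'   (>= 1000; default 10000).
#' @param seed Integer seed for the permutation null.
#' @param alpha Call threshold on the BH-adjusted gamma p (default 0.05).
#' @return A data frame with one row per feature: `feature`, `tau_best`,
#'   `phase_best_h`, `asymmetry_best_h`, `p_empirical`, `p_gamma`, `q_bh`,
#'   `oscillating`. The pooled null statistics and the gamma fit are attached
#'   as attributes `null_tau` and `gamma_fit`.
#' @export
ejtk_scan <- function(mat, waveforms, n_null = 10000L, seed = 1L,
                      alpha = 0.05) {
  stopifnot(inherits(waveforms, "reference_waveforms"), is.matrix(mat))
  W <- waveforms$values
  if (ncol(mat) != nrow(W))
    stop("matrix columns and waveform evaluation points differ in number")
  if (length(unique(waveforms$timepoints_h)) < 3L)
    stop("need at least 3 distinct ZTs")
  n_null <- as.integer(n_null)
  if (n_null < 1000L) stop("n_null must be >= 1000")
  m <- nrow(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("f", seq_len(m))

  max_tau <- function(x) {
    taus <- suppressWarnings(stats::cor(x, W, method = "kendall"))
    k <- which.max(taus)
    c(taus[k], k)
  }

  const <- apply(mat, 1L, function(x) diff(range(x)) == 0)
  best <- matrix(NA_real_, m, 2L)
  for (i in seq_len(m)) if (!const[i]) best[i, ] <- max_tau(mat[i, ])

  usable <- which(!const)
  if (length(usable) == 0L) stop("all features are constant")
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  feat_cycle <- usable[((seq_len(n_null) - 1L) %% length(usable)) + 1L]
  null_tau <- vapply(feat_cycle, function(f) {
    max_tau(sample(mat[f, ]))[1L]
  }, numeric(1))

  gfit <- fit_gamma_null(null_tau)
  tau_best <- best[, 1L]
  p_emp <- p_gam <- rep(1, m)
  p_emp[usable] <- (1 + vapply(tau_best[usable],
                               function(t) sum(null_tau >= t), numeric(1))) /
    (1 + n_null)
  p_gam[usable] <- gfit$tail_prob(tau_best[usable])
  q <- bh_adjust(p_gam)

  res <- data.frame(
    feature = rownames(mat),
    tau_best = ifelse(const, 0, tau_best),
    phase_best_h = ifelse(const, NA_real_, waveforms$phase_h[best[, 2L]]),
    asymmetry_best_h = ifelse(const, NA_real_,
                              waveforms$asymmetry_h[best[, 2L]]),
    p_empirical = p_emp, p_gamma = p_gam, q_bh = q,
    oscillating = q < alpha & !const,
    row.names = NULL
  )
  attr(res, "null_tau") <- null_tau
  attr(res, "gamma_fit") <- gfit[c("shape", "scale")]
  res
}

#' Fit a gamma distribution to an empirical permutation null
#'
#' Null max-tau statistics are mapped to `s = (1 + tau) / 2` (support (0, 1])
#' and a three-parameter (location-shifted) gamma is fitted: for each shift
#' on a grid in `[0, min(s))`, shape and rate are estimated by maximum
#' likelihood on `s - shift` and the shift with the highest profile
#' likelihood is kept (shift 0 recovers the plain two-parameter fit). A
#' method-of-moments fallback is used if the optimiser fails at every shift.
#' The returned tail function gives the smooth upper-tail probability of an
#' observed tau and is continuous and decreasing.
#'
#' @param null_stats Numeric vector of >= 1000 null tau values in \[-1, 1\].
#' @return A list with `shape`, `scale`, `shift`, `method` ("mle" or
#'   "moments"), and `tail_prob(tau)`, a vectorised decreasing function.
#' @export
fit_gamma_null <- function(null_stats) {
  stopifnot(is.numeric(null_stats))
  if (length(null_stats) < 1000L) stop("need at least 1000 null values")
  s <- (1 + null_stats) / 2
  if (stats::var(s) == 0) stop("degenerate null: zero variance")
  s <- pmax(s, .Machine$double.eps)
  shifts <- unique(c(0, seq(0, max(min(s) - 1e-3, 0), length.out = 25L)))
  best <- NULL
  for (sh in shifts) {
    fit <- tryCatch(
      suppressWarnings(MASS::fitdistr(s - sh, "gamma")),
      error = function(e) NULL
    )
    if (!is.null(fit) && all(is.finite(fit$estimate)) &&
        all(fit$estimate > 0) &&
        (is.null(best) || fit$loglik > best$loglik)) {
      best <- list(shape = unname(fit$estimate["shape"]),
                   rate = unname(fit$estimate["rate"]),
                   shift = sh, loglik = fit$loglik)
    }
  }
  if (!is.null(best)) {
    shape <- best$shape; scale <- 1 / best$rate; shift <- best$shift
    method <- "mle"
  } else {
    mu <- mean(s); v <- stats::var(s)
    shape <- mu^2 / v
    scale <- v / mu
    shift <- 0
    method <- "moments"
  }
  list(shape = shape, scale = scale, shift = shift, method = method,
       tail_prob = function(tau) {
         stats::pgamma(pmax((1 + tau) / 2 - shift, 0), shape = shape,
                       scale = scale, lower.tail = FALSE)
       })
}

#' Harmonic (cosinor) regression rhythm test
#'
#' Least-squares fit of `y = mesor + a cos(wt) + b sin(wt)`, `w = 2 pi /
#' period`, with the overall F test of the two harmonic terms against the
#' intercept-only model — the classic single-harmonic cosinor criterion.
#'
#' @param series Numeric response values.
#' @param zt_hours ZT of each value in hours.
#' @param period_h Period in hours (default 24).
#' @return A list of class `harmonic_fit`: `mesor`, `amplitude`,
#'   `acrophase_h` (peak time in \[0, 24)), `r_squared`, `f_statistic`,
#'   `p_value`, `n`.
#' @examples
#' t <- rep(seq(2, 22, by = 4), each = 3)
#' y <- 5 + 2 * cos(2 * pi * (t - 8) / 24)
#' harmonic_regression(y, t)$acrophase_h # 8
#' @export
harmonic_regression <- function(series, zt_hours, period_h = 24) {
  stopifnot(length(series) == length(zt_hours))
  if (length(unique(zt_hours)) < 4L)
    stop("need at least 4 distinct ZTs")
  n <- length(series)
  w <- 2 * pi / period_h
  X <- cbind(1, cos(w * zt_hours), sin(w * zt_hours))
  fit <- stats::lm.fit(X, series)
  coefs <- fit$coefficients
  ssr1 <- sum(fit$residuals^2)
  ssr0 <- sum((series - mean(series))^2)
  a <- coefs[2L]; b <- coefs[3L]
  amplitude <- sqrt(a^2 + b^2)
  acrophase <- (atan2(b, a) / w) %% period_h
  if (ssr0 <= .Machine$double.eps * n * max(1, mean(series)^2)) {
    # constant input: nothing to explain
    return(structure(list(mesor = mean(series), amplitude = 0,
                          acrophase_h = 0, r_squared = 0, f_statistic = 0,
                          p_value = 1, n = n), class = "harmonic_fit"))
  }
  r2 <- 1 - ssr1 / ssr0
  if (ssr1 <= .Machine$double.eps * ssr0) {
    f <- Inf
    p <- .Machine$double.xmin
    r2 <- 1
  } else {
    f <- ((ssr0 - ssr1) / 2) / (ssr1 / (n - 3))
    p <- stats::pf(f, 2, n - 3, lower.tail = FALSE)
  }
  structure(list(mesor = unname(coefs[1L]), amplitude = unname(amplitude),
                 acrophase_h = unname(acrophase), r_squared = r2,
                 f_statistic = unname(f), p_value = p, n = n),
            class = "harmonic_fit")
}

# save/restore the RNG state so seeded helpers do not disturb callers
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
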