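#' Energy expenditure by the abbreviated Weir equation
#'
#' `EE (kcal/h) = 3.941 * VO2 + 1.106 * VCO2` with gas volumes in L/h
#' (protein oxidation term omitted, the standard abbreviated form).
#'
#' @param vo2_L_per_h,vco2_L_per_h Non-negative gas exchange rates (L/h).
#' @return Energy expenditure in kcal/h (vectorised).
#' @examples
#' weir_ee(1, 1) # 5.047
#' @export
weir_ee <- function(vo2_L_per_h, vco2_L_per_h) {
  if (any(vo2_L_per_h < 0, na.rm = TRUE) ||
      any(vco2_L_per_h < 0, na.rm = TRUE))
    stop("gas exchange rates must be non-negative")
  3.941 * vo2_L_per_h + 1.106 * vco2_L_per_h
}

#' Respiratory exchange ratio
#'
#' `RER = VCO2 / VO2`; undefined (NA) where VO2 is zero.
#'
#' @param vco2,vo2 Gas exchange rates, same units.
#' @return RER (vectorised), `NA` where VO2 <= 0.
#' @export
compute_rer <- function(vco2, vo2) {
  out <- ifelse(vo2 > 0, vco2 / vo2, NA_real_)
  unname(out)
}

#' Segment a trace into light/dark photoperiods from lux
#'
#' Labels each sample light (lux above threshold) or dark, merges runs
#' shorter than the debounce window into their neighbours (absorbing sensor
#' blips), and numbers periods by day: a new day starts at each lights-on
#' transition.
#'
#' @param lux Numeric lux series.
#' @param threshold Light when `lux > threshold` (default 0).
#' @param debounce_n Runs shorter than this many samples are merged into the
#'   preceding run (default 5, i.e. 15 min at 3-min cadence).
#' @return Character vector of period labels (`"light_d1"`, `"dark_d1"`, ...)
#'   with a `periods` attribute (data frame: `label`, `phase`, `day`,
#'   `start`, `end`). Constant lux yields a single period with a warning.
#' @export
segment_photoperiods <- function(lux, threshold = 0, debounce_n = 5L) {
  stopifnot(length(lux) >= 1L)
  light <- lux > threshold
  if (all(light) || all(!light)) {
    if (length(unique(lux)) == 1L)
      warning("constant lux: single photoperiod")
    lab <- if (light[1L]) "light_d1" else "dark_d1"
    out <- rep(lab, length(lux))
    attr(out, "periods") <- data.frame(
      label = lab, phase = if (light[1L]) "light" else "dark", day = 1L,
      start = 1L, end = length(lux))
    return(out)
  }
  r <- rle(light)
  # absorb short runs into the previous run (the first run is kept as-is)
  while (any(r$lengths < debounce_n & seq_along(r$lengths) > 1L)) {
    i <- which(r$lengths < debounce_n & seq_along(r$lengths) > 1L)[1L]
    r$values[i] <- r$values[i - 1L]
    r <- rle(inverse.rle(r))
  }
  phase <- ifelse(r$values, "light", "dark")
  day <- integer(length(phase))
  day[1L] <- 1L
  if (length(phase) > 1L) {
    for (i in 2L:length(phase)) {
      day[i] <- day[i - 1L] + as.integer(phase[i] == "light")
    }
  }
  label <- sprintf("%s_d%d", phase, day)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- rep(label, r$lengths)
  attr(out, "periods") <- data.frame(label = label, phase = phase, day = day,
                                     start = starts, end = ends)
  out
}

#' Robust Sn scale estimate
#'
#' Rousseeuw-Croux Sn: `c * lowmed_i { highmed_{j != i} |x_i - x_j| }` with
#' consistency factor `c = 1.1926`. Conventions used here: the inner median
#' is the high median (position `floor(m/2) + 1` of the m = n - 1 sorted
#' pairwise distances from point i, excluding the self distance); the outer
#' is the low median (position `floor((n + 1) / 2)`). An optional
#' finite-sample correction factor can be applied for small n.
#'
#' @param values Numeric vector, n >= 2.
#' @param consistency Consistency factor (default 1.1926, Gaussian).
#' @param finite_correction Apply the small-sample correction factor
#'   (default `FALSE`).
#' @return The Sn scale estimate (0 for constant input).
#' @export
sn_scale <- function(values, consistency = 1.1926,
                     finite_correction = FALSE) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  inner <- vapply(seq_len(n), function(i) {
    d <- sort(abs(values[i] - values[-i]))
    d[floor((n - 1L) / 2L) + 1L]          # high median of n - 1 values
  }, numeric(1))
  sn <- consistency * sort(inner)[floor((n + 1L) / 2L)]  # low median
  if (finite_correction) {
    cn <- if (n <= 9L) {
      c(NA, 0.743, 1.851, 0.954, 1.351, 0.993, 1.198, 1.005, 1.131)[n]
    } else if (n %% 2L == 1L) n / (n - 0.9) else 1
    sn <- sn * cn
  }
  sn
}

#' Flag outliers by the median +/- k Sn rule
#'
#' Values outside `median +/- k * Sn` are flagged. When Sn is 0 but the data
#' are not constant (a majority of identical values), every value different
#' from the median is flagged.
#'
#' @param values Numeric vector, n >= 3.
#' @param k Sn multiplier (default 3).
#' @param ... Passed to [sn_scale()].
#' @return Logical mask, `TRUE` = outlier.
#' @export
sn_outlier_mask <- function(values, k = 3, ...) {
  stopifnot(length(values) >= 3L)
  med <- stats::median(values)
  sn <- sn_scale(values, ...)
  if (sn == 0) {
    if (diff(range(values)) == 0) return(rep(FALSE, length(values)))
    return(values != med)
  }
  abs(values - med) > k * sn
}

#' Derive EE, RER and photoperiod labels on a calorimetry trace
#'
#' Adds Weir energy expenditure, RER and lux-derived photoperiod labels to a
#' trace, and computes per-channel Sn outlier masks within each photoperiod
#' (channels: VO2, VCO2, EE, RER).
#'
#' @param trace A `calorimetry_trace`.
#' @param k Sn multiplier for outlier masking (default 3).
#' @return The trace with `$data` gaining `ee`, `rer`, `period` columns and a
#'   logical `$outlier` matrix (samples x channels).
#' @export
annotate_trace <- function(trace, k = 3) {
  stopifnot(inherits(trace, "calorimetry_trace"))
  d <- trace$data
  d$ee <- weir_ee(d$vo2, d$vco2)
  d$rer <- compute_rer(d$vco2, d$vo2)
  d$period <- as.character(segment_photoperiods(d$lux))
  channels <- c("vo2", "vco2", "ee", "rer")
  mask <- sapply(channels, function(ch) {
    out <- logical(nrow(d))
    for (per in unique(d$period)) {
      i <- which(d$period == per & !is.na(d[[ch]]))
      if (length(i) >= 3L) out[i] <- sn_outlier_mask(d[[ch]][i], k = k)
    }
    out
  })
  trace$data <- d
  trace$outlier <- mask
  trace
}

#' Per-photoperiod aggregation of a calorimetry trace
#'
#' Within each light/dark period: sums for count channels (beam breaks),
#' ranges (max - min) for cumulative channels (food, water), and PRCF EC50
#' values for RER, VO2 and EE computed on outlier-masked samples. Outliers
#' are excluded from EC50 inputs but not from cumulative ranges.
#'
#' @param trace An annotated trace (see [annotate_trace()]; plain traces are
#'   annotated on the fly).
#' @return Data frame, one row per period: `period`, `phase`, `day`,
#'   `n_samples`, `n_retained`, `beam_breaks_sum`, `food_range_g`,
#'   `water_range_g`, `ec50_rer`, `ec50_vo2`, `ec50_ee`.
#' @export
period_aggregate <- function(trace) {
  if (is.null(trace$data$period)) trace <- annotate_trace(trace)
  d <- trace$data
  mask <- trace$outlier
  pers <- unique(d$period)
  do.call(rbind, lapply(pers, function(per) {
    i <- which(d$period == per)
    if (length(i) == 0L) return(NULL)
    keep <- function(ch) {
      j <- i[!mask[i, ch] & !is.na(d[[ch]][i])]
      d[[ch]][j]
    }
    ec <- function(ch) {
      v <- keep(ch)
      if (length(v) >= 20L) prcf_ec50(v) else NA_real_
    }
    data.frame(
      period = per,
      phase = sub("_d\\d+$", "", per),
      day = as.integer(sub("^.*_d", "", per)),
      n_samples = length(i),
      n_retained = sum(!mask[i, "ee"]),
      beam_breaks_sum = sum(d$beam_breaks[i]),
      food_range_g = max(d$food_g[i]) - min(d$food_g[i]),
      water_range_g = max(d$water_g[i]) - min(d$water_g[i]),
      ec50_rer = ec("rer"), ec50_vo2 = ec("vo2"), ec50_ee = ec("ee")
    )
  }))
}

#' EC50 of a measurement distribution via PRCF logistic fit
#'
#' Sorts the values, forms the percent relative cumulative frequency
#' `PRCF_i = 100 i / n`, fits a logistic curve of PRCF against value by
#' nonlinear least squares, and reports the value at fitted PRCF = 50 — a
#' smooth, outlier-resistant location summary of the period distribution.
#' Falls back to linear interpolation of the PRCF at 50% when the fit fails.
#'
#' @param values Numeric vector of >= 20 retained values (constant input is
#'   returned as-is).
#' @param n_pars 4 (default) or 5 (adds an asymmetry exponent).
#' @return The EC50 value.
#' @export
prcf_ec50 <- function(values, n_pars = 4L) {
  stopifnot(n_pars %in% c(4L, 5L))
  if (diff(range(values)) == 0) return(values[1L])
  if (length(values) < 20L) stop("need at least 20 retained values")
  x <- sort(values)
  n <- length(x)
  prcf <- 100 * seq_len(n) / n
  dat <- data.frame(x = x, y = prcf)
  iqr <- max(stats::IQR(x), diff(range(x)) / 10)
  start <- list(A = 0, D = 100, B = 4 / iqr, C = stats::median(x))
  if (n_pars == 5L) start$g <- 1
  form <- if (n_pars == 4L) {
    y ~ A + (D - A) / (1 + exp(-B * (x - C)))
  } else {
    y ~ A + (D - A) / (1 + exp(-B * (x - C)))^g
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    cf <- as.list(stats::coef(fit))
    g <- if (n_pars == 5L) cf$g else 1
    frac <- (cf$D - cf$A) / (50 - cf$A)
    if (is.finite(frac) && frac^(1 / g) > 1 && cf$B != 0) {
      ec50 <- cf$C - log(frac^(1 / g) - 1) / cf$B
      if (is.finite(ec50) && ec50 >= min(x) && ec50 <= max(x)) return(ec50)
    }
  }
  # fallback: linear interpolation of the PRCF curve at 50%
  stats::approx(prcf, x, xout = 50, rule = 2)$y
}

#' Basal metabolic rate from an energy-expenditure series
#'
#' The minimum over all contiguous windows of at least `window_min` minutes
#' (2 consecutive samples at 3-min cadence) of the window-mean EE, restricted
#' to the postabsorptive rest-phase window ZT `zt_window[1]`-`zt_window[2]`.
#'
#' @param ee_series Energy expenditure values (kcal/h).
#' @param zt_hours ZT of each sample.
#' @param window_min Minimum window duration in minutes (default 5).
#' @param zt_window Two-element ZT range searched (default c(7, 10)).
#' @param cadence_min Sampling cadence in minutes (default 3).
#' @return BMR in kcal/h.
#' @export
basal_metabolic_rate <- function(ee_series, zt_hours, window_min = 5,
                                 zt_window = c(7, 10), cadence_min = 3) {
  stopifnot(length(ee_series) == length(zt_hours))
  w <- as.integer(ceiling(window_min / cadence_min))
  in_win <- zt_hours >= zt_window[1L] & zt_hours <= zt_window[2L]
  if (sum(in_win) < w) stop("trace does not cover the ZT window")
  # contiguous runs within the window (guards against multi-day gaps)
  runs <- split(which(in_win), cumsum(c(1, diff(which(in_win)) != 1)))
  best <- Inf
  for (ix in runs) {
    v <- ee_series[ix]
    if (length(v) < w) next
    means <- stats::filter(v, rep(1 / w, w), sides = 1)
    best <- min(best, means[!is.na(means)])
  }
  if (!is.finite(best)) stop("no contiguous window of the required length")
  best
}

#' Body-weight-adjusted group comparison (ANCOVA)
#'
#' Linear model `value ~ body_weight + group` for two groups; reports the
#' weight-adjusted group difference and its F-test p-value. When body weight
#' is constant (collinear covariate) the model degrades to a two-sample
#' comparison with a warning.
#'
#' @param values Numeric response (e.g. per-period EC50 values).
#' @param group_labels Two-level group factor.
#' @param body_weight Numeric covariate, same length.
#' @return A list: `effect` (adjusted difference, second level minus first),
#'   `f_statistic`, `p`, `df`.
#' @export
ancova_compare <- function(values, group_labels, body_weight) {
  g <- factor(group_labels)
  stopifnot(nlevels(g) == 2L, length(values) == length(g),
            length(body_weight) == length(g))
  if (any(table(g) < 3L)) stop("need at least 3 observations per group")
  if (stats::var(body_weight) == 0) {
    warning("body weight constant: reducing to unadjusted comparison")
    fit <- stats::lm(values ~ g)
    an <- stats::anova(fit)
    return(list(effect = unname(stats::coef(fit)[2L]),
                f_statistic = an[["F value"]][1L], p = an[["Pr(>F)"]][1L],
                df = an$Df[nrow(an)]))
  }
  fit <- stats::lm(values ~ body_weight + g)
  an <- stats::anova(fit)
  list(effect = unname(stats::coef(fit)[3L]),
       f_statistic = an[["F value"]][2L],
       p = an[["Pr(>F)"]][2L],
       df = an$Df[nrow(an)])
}
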