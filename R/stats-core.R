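#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment. Thin, contract-checked wrapper
#' around [stats::p.adjust()] so every module shares one entry point.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\]. `NA`s are propagated.
#' @return Numeric vector of BH-adjusted q-values, same length and names.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  stopifnot(is.numeric(pvals))
  bad <- !is.na(pvals) & (pvals < 0 | pvals > 1)
  if (any(bad)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Baseline-normalised area under a tolerance curve
#'
#' Trapezoidal integral of the excursion above the t = 0 baseline, the
#' standard summary for glucose/pyruvate tolerance tests. Negative segments
#' (values below baseline) are included, giving a net (signed) AUC.
#'
#' @param values Numeric measurements (e.g. blood glucose, mg/dL).
#' @param times Numeric sampling times in minutes, strictly increasing,
#'   beginning at 0 (the baseline draw).
#' @return Net AUC in value-units x minutes.
#' @examples
#' baseline_auc(c(100, 200, 100), c(0, 30, 60)) # 3000
#' @export
baseline_auc <- function(values, times) {
  stopifnot(is.numeric(values), is.numeric(times),
            length(values) == length(times), length(values) >= 2L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (times[1L] != 0) stop("first time point must be 0 (baseline)")
  y <- values - values[1L]
  sum(diff(times) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Compare groups with Welch-type tests
#'
#' For two groups, a two-tailed unpaired Welch t test. For three or more
#' groups, a Welch (unequal-variance) one-way ANOVA omnibus followed by
#' Dunnett-style many-to-one Welch comparisons against a reference group,
#' with single-step familywise adjustment from the joint multivariate-t
#' distribution of the contrast statistics.
#'
#' @param values Numeric response vector.
#' @param labels Group labels (coerced to factor).
#' @param mode `"welch_t"` (exactly 2 groups) or `"welch_anova_dunnett"`
#'   (>= 3 groups).
#' @param reference Reference group for many-to-one comparisons; defaults to
#'   the first factor level.
#' @return A list with `statistic`, `df`, `p`, `effect` (difference in means)
#'   for `welch_t`; for the ANOVA mode additionally an `omnibus` list and a
#'   `comparisons` data frame with adjusted p-values.
#' @export
group_compare <- function(values, labels,
                          mode = c("welch_t", "welch_anova_dunnett"),
                          reference = NULL) {
  mode <- match.arg(mode)
  labels <- factor(labels)
  stopifnot(length(values) == length(labels))
  ns <- table(labels)
  if (any(ns < 2L)) stop("every group needs n >= 2")

  if (mode == "welch_t") {
    if (nlevels(labels) != 2L) stop("welch_t requires exactly 2 groups")
    tt <- stats::t.test(values ~ labels, var.equal = FALSE)
    return(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value,
                effect = unname(diff(rev(tt$estimate)))))
  }

  if (nlevels(labels) < 3L) stop("welch_anova_dunnett requires >= 3 groups")
  if (is.null(reference)) reference <- levels(labels)[1L]
  if (!reference %in% levels(labels)) stop("reference group not found")
  ow <- stats::oneway.test(values ~ labels, var.equal = FALSE)

  labels <- stats::relevel(labels, ref = reference)
  lev <- levels(labels)
  m <- tapply(values, labels, mean)
  v <- tapply(values, labels, stats::var)
  n <- tapply(values, labels, length)
  others <- lev[-1L]
  k <- length(others)
  diffs <- m[others] - m[[1L]]
  se2 <- v[others] / n[others] + v[[1L]] / n[[1L]]
  tstat <- diffs / sqrt(se2)
  # Welch-Satterthwaite df per contrast
  dfs <- se2^2 / ((v[others] / n[others])^2 / (n[others] - 1) +
                  (v[[1L]] / n[[1L]])^2 / (n[[1L]] - 1))
  # contrasts share the reference-group mean: Cov = s0^2/n0
  covr <- v[[1L]] / n[[1L]]
  R <- diag(k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      R[i, j] <- R[j, i] <- covr / sqrt(se2[i] * se2[j])
    }
  }
  nu <- max(2L, as.integer(round(min(dfs))))
  p_adj <- vapply(abs(tstat), function(ti) {
    1 - mvtnorm::pmvt(lower = rep(-ti, k), upper = rep(ti, k),
                      corr = R, df = nu)[1L]
  }, numeric(1))
  p_raw <- 2 * stats::pt(-abs(tstat), df = dfs)
  list(
    omnibus = list(statistic = unname(ow$statistic),
                   df = unname(ow$parameter), p = ow$p.value),
    comparisons = data.frame(
      group = others, reference = reference,
      effect = as.numeric(diffs), statistic = as.numeric(tstat),
      df = as.numeric(dfs), p = as.numeric(p_raw),
      p_adj = pmin(1, as.numeric(p_adj)), row.names = NULL
    )
  )
}
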