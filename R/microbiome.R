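#' Remove low-depth samples by the mean - 1.5 SD rule
#'
#' Drops samples whose total read count falls below `mean - k * SD` of the
#' per-sample totals (one-sided low-depth removal). The computed threshold
#' and removed samples are appended to the table's filter log.
#'
#' @param table An `asv_table`.
#' @param k Multiplier on the SD (default 1.5).
#' @return Filtered `asv_table`; attributes of the applied rule are in
#'   `$filter_log`.
#' @export
filter_samples_by_depth <- function(table, k = 1.5) {
  stopifnot(inherits(table, "asv_table"))
  totals <- colSums(table$counts)
  if (length(totals) < 3L) stop("need at least 3 samples")
  threshold <- mean(totals) - k * stats::sd(totals)
  keep <- totals >= threshold
  if (!any(keep)) stop("depth filter removed every sample")
  out <- subset_asv(table, features = NULL, samples = keep)
  out$filter_log <- c(table$filter_log, list(list(
    rule = "sample_depth", threshold = threshold, k = k,
    removed = colnames(table$counts)[!keep],
    n_before = length(totals), n_after = sum(keep))))
  out
}

#' Remove rare features by prevalence
#'
#' Keeps features observed (count > 0) in at least `min_samples` samples.
#'
#' @param table An `asv_table`.
#' @param min_samples Minimum number of samples a feature must appear in.
#' @return Filtered `asv_table` with the rule logged.
#' @export
filter_features_by_prevalence <- function(table, min_samples = 10L) {
  stopifnot(inherits(table, "asv_table"), min_samples >= 1L)
  prev <- rowSums(table$counts > 0)
  keep <- prev >= min_samples
  out <- subset_asv(table, features = keep, samples = NULL)
  out$filter_log <- c(table$filter_log, list(list(
    rule = "feature_prevalence", min_samples = min_samples,
    removed = rownames(table$counts)[!keep],
    n_before = nrow(table$counts), n_after = sum(keep))))
  out
}

subset_asv <- function(table, features = NULL, samples = NULL) {
  counts <- table$counts
  if (!is.null(features)) counts <- counts[features, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  tax <- table$taxonomy[table$taxonomy$feature %in% rownames(counts), ,
                        drop = FALSE]
  meta <- table$samples[table$samples$sample %in% colnames(counts), ,
                        drop = FALSE]
  new_asv_table(counts, meta, tax, filter_log = table$filter_log,
                truth = table$truth, depths = NULL)
}

#' Rarefy (subsample) an ASV table to even depth
#'
#' Subsamples every sample without replacement to exactly `depth` reads.
#' Samples below the target depth are dropped and logged. The default depth
#' follows the even-sampling rule `floor(mean - 1.5 SD)` of the retained
#' sample totals.
#'
#' @param table An `asv_table`.
#' @param depth Target depth; `NULL` applies the mean - 1.5 SD rule.
#' @param seed Integer seed (subsampling is deterministic given the seed).
#' @return Rarefied `asv_table`; every column sums to `depth`.
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  stopifnot(inherits(table, "asv_table"))
  totals <- colSums(table$counts)
  if (is.null(depth)) depth <- floor(mean(totals) - 1.5 * stats::sd(totals))
  depth <- as.integer(depth)
  if (depth <= 0) stop("depth must be positive")
  keep <- totals >= depth
  if (!any(keep)) stop("no sample reaches the target depth")
  counts <- table$counts[, keep, drop = FALSE]
  old <- withr_seed(seed); on.exit(restore_seed(old), add = TRUE)
  # vegan works on samples x features
  rar <- t(vegan::rrarefy(t(counts), sample = depth))
  storage.mode(rar) <- "integer"
  out <- subset_asv(table, samples = keep)
  out$counts <- rar
  out$filter_log <- c(table$filter_log, list(list(
    rule = "rarefaction", depth = depth,
    removed = colnames(table$counts)[!keep],
    n_before = length(totals), n_after = sum(keep))))
  out
}

rank_names <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")

split_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  t(vapply(parts, function(p) {
    p <- sub("^\\s*[a-z]__", "", trimws(p))
    length(p) <- 7L
    p[is.na(p)] <- ""
    p
  }, character(7)))
}

#' Collapse an ASV table at a taxonomic rank
#'
#' Sums counts over features sharing the lineage prefix down to `rank`
#' (QIIME-style 7-rank lineage strings). Features unassigned at the rank are
#' binned as `"unclassified-<parent>"`. Totals are conserved.
#'
#' @param table An `asv_table`.
#' @param rank Rank name (`"domain"` ... `"species"`) or index 1-7.
#' @return A list: `counts` (taxa x samples), `labels` (rank label per input
#'   feature), `rank`.
#' @export
collapse_taxonomy <- function(table, rank = "family") {
  stopifnot(inherits(table, "asv_table"))
  if (is.character(rank)) rank <- match(rank, rank_names)
  if (is.na(rank) || rank < 1L || rank > 7L) stop("unknown rank")
  tax <- split_lineage(table$taxonomy$lineage)
  rownames(tax) <- table$taxonomy$feature
  tax <- tax[rownames(table$counts), , drop = FALSE]
  lab <- tax[, rank]
  parent <- if (rank > 1L) tax[, rank - 1L] else rep("root", nrow(tax))
  lab <- ifelse(lab == "", paste0("unclassified-", parent), lab)
  counts <- rowsum(table$counts, group = lab)
  list(counts = counts, labels = stats::setNames(lab, rownames(tax)),
       rank = rank_names[rank])
}

#' Summarise oscillating vs total features per taxon group
#'
#' For each taxon at the chosen rank, reports how many features oscillate
#' (per the supplied rhythm calls), the proportion oscillating, and the
#' summed relative abundance of oscillating vs all features. Relative
#' abundance is count over sample total, averaged across samples.
#'
#' @param table An `asv_table` (filtered; pre-rarefaction by convention).
#' @param rhythm_results Data frame with `feature` and `oscillating` covering
#'   all features in the table.
#' @param rank Taxonomic rank to group by.
#' @return Data frame: `taxon`, `n_features`, `n_oscillating`,
#'   `prop_oscillating`, `abundance_total`, `abundance_oscillating` (mean
#'   relative abundances).
#' @export
oscillating_fraction_summary <- function(table, rhythm_results,
                                         rank = "order") {
  stopifnot(inherits(table, "asv_table"))
  idx <- match(rownames(table$counts), rhythm_results$feature)
  if (anyNA(idx)) stop("rhythm results do not cover all features")
  osc <- rhythm_results$oscillating[idx]
  lab <- collapse_taxonomy(table, rank)$labels
  rel <- sweep(table$counts, 2L, colSums(table$counts), "/")
  mean_rel <- rowMeans(rel)
  agg <- function(v, by) tapply(v, by, sum)
  taxa <- sort(unique(lab))
  data.frame(
    taxon = taxa,
    n_features = as.integer(agg(rep(1L, length(lab)), lab)[taxa]),
    n_oscillating = as.integer(agg(as.integer(osc), lab)[taxa]),
    prop_oscillating = as.numeric(agg(as.integer(osc), lab)[taxa] /
                                  agg(rep(1L, length(lab)), lab)[taxa]),
    abundance_total = as.numeric(agg(mean_rel, lab)[taxa]),
    abundance_oscillating = as.numeric(agg(mean_rel * osc, lab)[taxa]),
    row.names = NULL
  )
}

#' Reference-frame log-ratio differentials by multinomial regression
#'
#' Fits a multinomial regression of feature counts on categorical sampling
#' time (reference level first, conventionally ZT2) by full-batch gradient
#' descent on the negative log-likelihood with a small L2 penalty. The
#' returned per-feature coefficients ("differentials") are centred to mean
#' zero across features for each time level (CLR-style identifiability), so
#' they are interpretable as log fold changes relative to the reference time,
#' up to a constant — invariant to per-sample sequencing depth.
#'
#' @param counts Features x samples count matrix (or an `asv_table`).
#' @param zt_labels Sampling-time label per sample (coerced to factor).
#' @param reference_zt Reference level (default `"2"`, i.e. ZT2).
#' @param epochs Gradient-descent iterations (default 40000).
#' @param learning_rate Step size (default 1e-4). A step-halving safeguard
#'   keeps the recorded loss non-increasing.
#' @param l2 L2 penalty on coefficients (default 1e-4).
#' @param tol Relative loss-change convergence tolerance.
#' @return A list of class `differential_table`: `differentials` (features x
#'   non-reference levels, centred), `intercept_clr`, `loss` (checkpoint
#'   trace), `epochs_run`, `converged`.
#' @export
multinomial_differentials <- function(counts, zt_labels, reference_zt = "2",
                                      epochs = 40000L, learning_rate = 1e-4,
                                      l2 = 1e-4, tol = 1e-10) {
  if (inherits(counts, "asv_table")) {
    if (is.null(zt_labels)) zt_labels <- counts$samples$zt
    counts <- counts$counts
  }
  stopifnot(is.matrix(counts), nrow(counts) >= 2L)
  zt <- factor(as.character(zt_labels))
  reference_zt <- as.character(reference_zt)
  if (!reference_zt %in% levels(zt)) stop("reference level not present")
  zt <- stats::relevel(zt, ref = reference_zt)
  X <- stats::model.matrix(~zt)          # N x K, intercept + K-1 dummies
  Y <- counts                            # D x N
  D <- nrow(Y); N <- ncol(Y); K <- ncol(X)
  depth <- colSums(Y)
  B <- matrix(0, D, K)
  lr <- learning_rate
  nll <- function(B) {
    eta <- B %*% t(X)
    lse <- apply(eta, 2L, function(e) { m <- max(e); m + log(sum(exp(e - m))) })
    -sum(Y * eta) + sum(depth * lse) + l2 * sum(B^2)
  }
  grad <- function(B) {
    eta <- B %*% t(X)
    P <- exp(sweep(eta, 2L, apply(eta, 2L, max)))
    P <- sweep(P, 2L, colSums(P), "/")
    (sweep(P, 2L, depth, "*") - Y) %*% X + 2 * l2 * B
  }
  loss <- nll(B)
  trace <- loss
  converged <- FALSE
  for (e in seq_len(epochs)) {
    g <- grad(B)
    repeat {
      Bn <- B - lr * g
      ln <- nll(Bn)
      if (is.finite(ln) && ln <= loss + 1e-8 * abs(loss)) break
      lr <- lr / 2
      if (lr < 1e-16) stop("gradient descent failed to decrease the loss")
    }
    B <- Bn
    lr <- min(lr * 1.05, learning_rate)  # recover after safeguard halving
    if (e %% 1000L == 0L) trace <- c(trace, ln)
    if (abs(loss - ln) <= tol * (abs(loss) + 1)) {
      loss <- ln; converged <- TRUE; trace <- c(trace, ln); break
    }
    loss <- ln
  }
  diffs <- B[, -1L, drop = FALSE]
  diffs <- sweep(diffs, 2L, colMeans(diffs))     # CLR centring
  colnames(diffs) <- levels(zt)[-1L]
  rownames(diffs) <- rownames(Y)
  structure(list(differentials = diffs,
                 intercept_clr = B[, 1L] - mean(B[, 1L]),
                 loss = trace, epochs_run = e, converged = converged,
                 learning_rate_final = lr),
            class = "differential_table")
}

#' Nonzero-base sinusoid fit
#'
#' Least-squares fit of `y = m + a sin(wt) + b cos(wt)` (linear in m, a, b),
#' reported as baseline `m`, amplitude `A = sqrt(a^2 + b^2)`, peak phase
#' `phi` in hours, and R-squared against the intercept-only model (defined 0
#' when the total variance is 0).
#'
#' @param values Numeric response.
#' @param zt_hours Time of each value in hours.
#' @param period_h Period (default 24).
#' @return A list of class `sinusoid_fit`: `m`, `amplitude`, `phase_h`,
#'   `r_squared`, `n`.
#' @export
sinusoid_fit <- function(values, zt_hours, period_h = 24) {
  stopifnot(length(values) == length(zt_hours))
  if (length(values) < 4L) stop("need at least 4 points")
  if (length(unique(zt_hours)) < 3L) stop("need at least 3 distinct ZTs")
  w <- 2 * pi / period_h
  X <- cbind(1, sin(w * zt_hours), cos(w * zt_hours))
  fit <- stats::lm.fit(X, values)
  m <- fit$coefficients[1L]; a <- fit$coefficients[2L]
  b <- fit$coefficients[3L]
  ss0 <- sum((values - mean(values))^2)
  ss1 <- sum(fit$residuals^2)
  r2 <- if (ss0 <= 0) 0 else max(0, 1 - ss1 / ss0)
  amp <- sqrt(a^2 + b^2)
  # y = m + A cos(w (t - phi)) with cos coefficient b, sin coefficient a
  phase <- if (amp == 0) 0 else (atan2(a, b) / w) %% period_h
  structure(list(m = unname(m), amplitude = unname(amp),
                 phase_h = unname(phase), r_squared = r2,
                 n = length(values)),
            class = "sinusoid_fit")
}

#' Flag outliers by the mean +/- k SD rule
#'
#' Single-pass rule: values outside `mean +/- k * SD` (both computed on all
#' values) are flagged. Zero variance flags nothing.
#'
#' @param values Numeric vector, length >= 3.
#' @param k SD multiplier (default 2).
#' @return Logical mask, `TRUE` = outlier.
#' @export
sd_outlier_mask <- function(values, k = 2) {
  stopifnot(length(values) >= 3L)
  s <- stats::sd(values)
  if (s == 0) return(rep(FALSE, length(values)))
  abs(values - mean(values)) > k * s
}

#' LOESS profile over zeitgeber time
#'
#' Locally weighted linear regression (tricube weights, degree 1) of a series
#' on ZT, evaluated on a 0.5 h grid spanning the observed times.
#'
#' @param values Numeric response.
#' @param zt_hours Times in hours.
#' @param span LOESS span (fraction of points per local window).
#' @param grid_step_h Output grid spacing (default 0.5 h).
#' @return Data frame `zt_h`, `fitted`.
#' @export
loess_profile <- function(values, zt_hours, span = 0.75,
                          grid_step_h = 0.5) {
  stopifnot(length(values) == length(zt_hours), length(values) >= 4L)
  if (span * length(values) < 3)
    stop("span covers fewer than 3 points per window")
  fit <- stats::loess(values ~ zt_hours, span = span, degree = 1,
                      surface = "direct",
                      control = stats::loess.control(statistics = "none"))
  grid <- seq(min(zt_hours), max(zt_hours), by = grid_step_h)
  data.frame(zt_h = grid, fitted = stats::predict(fit, newdata =
                                                    data.frame(zt_hours = grid)))
}

#' Paired comparison of sinusoid fit quality
#'
#' Two-tailed paired t test on R-squared values of matched fits from two
#' conditions (e.g. the same taxa in two genotypes).
#'
#' @param fits_a,fits_b Numeric vectors of R-squared values, or lists of
#'   `sinusoid_fit` objects.
#' @param pairing Integer index mapping each element of `fits_a` to its pair
#'   in `fits_b` (default 1:1).
#' @return A list: `t`, `df`, `p`, `mean_difference`, `degenerate` (`TRUE`
#'   when the paired differences have zero variance).
#' @export
compare_fit_quality <- function(fits_a, fits_b,
                                pairing = seq_along(fits_a)) {
  r2 <- function(f) if (is.numeric(f)) f
    else vapply(f, function(x) x$r_squared, numeric(1))
  a <- r2(fits_a); b <- r2(fits_b)[pairing]
  if (length(a) < 3L) stop("need at least 3 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = length(d) - 1L, p = 1, mean_difference = 0,
                  degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_difference = mean(d), degenerate = FALSE)
}
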