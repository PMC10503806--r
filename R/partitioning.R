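#' Venn region counts of oscillation calls across groups
#'
#' Counts features in every region of the k-set Venn diagram formed by
#' per-group oscillation calls (features oscillating in exactly that subset
#' of groups). Regions are keyed by the group subset, `+`-separated.
#'
#' @param calls_by_group Named list of logical vectors (one per group), all
#'   with identical feature names/order, or a logical matrix
#'   (features x groups).
#' @return Named integer vector over all 2^k - 1 non-empty subsets, plus
#'   `"none"` for features oscillating nowhere. Non-`none` regions sum to the
#'   number of features oscillating in >= 1 group.
#' @examples
#' calls <- cbind(A = c(TRUE, TRUE, FALSE), B = c(TRUE, FALSE, FALSE))
#' overlap_counts(calls)
#' @export
overlap_counts <- function(calls_by_group) {
  M <- as_call_matrix(calls_by_group)
  groups <- colnames(M)
  k <- length(groups)
  subsets <- unlist(lapply(seq_len(k), function(r) {
    utils::combn(groups, r, paste, collapse = "+", simplify = FALSE)
  }))
  key <- apply(M, 1L, function(row) {
    if (!any(row)) "none" else paste(groups[row], collapse = "+")
  })
  counts <- stats::setNames(integer(length(subsets) + 1L),
                            c(subsets, "none"))
  tab <- table(key)
  counts[names(tab)] <- as.integer(tab)
  counts
}

as_call_matrix <- function(calls_by_group) {
  if (is.matrix(calls_by_group)) {
    M <- calls_by_group
  } else {
    stopifnot(is.list(calls_by_group), !is.null(names(calls_by_group)))
    lens <- lengths(calls_by_group)
    if (length(unique(lens)) != 1L)
      stop("groups cover different feature sets")
    nm <- lapply(calls_by_group, names)
    if (!is.null(nm[[1L]]) &&
        !all(vapply(nm, identical, logical(1), nm[[1L]])))
      stop("groups cover different feature sets")
    M <- do.call(cbind, calls_by_group)
  }
  stopifnot(is.logical(M), !is.null(colnames(M)))
  M
}

#' Classify oscillator drivers across the 2x2 factorial
#'
#' Assigns each feature one of the driver categories defined on the four
#' factorial groups (genotype: WT vs liver-clock knockout; microbial status:
#' SPF vs germ-free):
#' \describe{
#'   \item{system-driven}{oscillates in all four groups}
#'   \item{liver-clock-driven}{oscillates in both WT groups and neither LKO
#'     group}
#'   \item{liver-clock-independent}{oscillates in both LKO groups}
#'   \item{microbe-driven}{oscillates in both SPF groups and neither GF group}
#'   \item{microbe-independent}{oscillates in both GF groups}
#'   \item{none/other}{no rule matches}
#' }
#' Rules are table-driven (`rules` argument) so alternative definitions are a
#' configuration change. By default a feature may satisfy several rules
#' (`exclusive = FALSE`) and all matches are reported, with the first match
#' in rule order used as the primary `category`; `exclusive = TRUE` stops at
#' the first match.
#'
#' @param calls_by_group Logical matrix or named list as in
#'   [overlap_counts()]; must contain exactly the four factorial groups.
#' @param groups Named character vector mapping roles `spf_wt`, `spf_lko`,
#'   `gf_wt`, `gf_lko` to the column names.
#' @param rules Named list of rule functions taking the four logical calls
#'   (w_s, l_s, w_g, l_g = SPF-WT, SPF-LKO, GF-WT, GF-LKO) and returning a
#'   logical; evaluated in order.
#' @param exclusive If `TRUE`, a feature gets only its first matching label.
#' @return Data frame: `feature`, four call columns, `category` (primary
#'   label or `"none"`), `all_categories` (comma-separated matches).
#' @export
classify_drivers <- function(calls_by_group,
                             groups = c(spf_wt = "SPF-WT",
                                        spf_lko = "SPF-LKO",
                                        gf_wt = "GF-WT", gf_lko = "GF-LKO"),
                             rules = driver_rules(),
                             exclusive = FALSE) {
  M <- as_call_matrix(calls_by_group)
  if (!all(groups %in% colnames(M)))
    stop("missing factorial group(s): ",
         paste(setdiff(groups, colnames(M)), collapse = ", "))
  ws <- M[, groups[["spf_wt"]]]; ls <- M[, groups[["spf_lko"]]]
  wg <- M[, groups[["gf_wt"]]];  lg <- M[, groups[["gf_lko"]]]
  hits <- vapply(rules, function(f) f(ws, ls, wg, lg), logical(nrow(M)))
  if (nrow(M) == 1L) hits <- matrix(hits, nrow = 1L,
                                    dimnames = list(NULL, names(rules)))
  primary <- apply(hits, 1L, function(h) {
    i <- which(h)
    if (length(i) == 0L) "none" else names(rules)[i[1L]]
  })
  all_cat <- apply(hits, 1L, function(h) {
    i <- which(h)
    if (length(i) == 0L) "none"
    else if (exclusive) names(rules)[i[1L]]
    else paste(names(rules)[i], collapse = ",")
  })
  data.frame(
    feature = if (is.null(rownames(M))) seq_len(nrow(M)) else rownames(M),
    `SPF-WT` = ws, `SPF-LKO` = ls, `GF-WT` = wg, `GF-LKO` = lg,
    category = primary, all_categories = all_cat,
    check.names = FALSE, row.names = NULL
  )
}

#' Default driver-category rule set
#'
#' @return Named list of rule functions used by [classify_drivers()], in
#'   evaluation (precedence) order.
#' @export
driver_rules <- function() {
  list(
    `system-driven` = function(ws, ls, wg, lg) ws & ls & wg & lg,
    `liver-clock-driven` = function(ws, ls, wg, lg) ws & wg & !ls & !lg,
    `liver-clock-independent` = function(ws, ls, wg, lg) ls & lg,
    `microbe-driven` = function(ws, ls, wg, lg) ws & ls & !wg & !lg,
    `microbe-independent` = function(ws, ls, wg, lg) wg & lg
  )
}

#' Median-normalise a matrix and order rows by peak phase
#'
#' Divides each feature by its median across the samples (the heatmap
#' normalisation used for phase-ordered diurnal expression displays) and
#' sorts rows by estimated peak phase, breaking ties by feature id. Features
#' with a zero median cannot be normalised; they are flagged and placed last.
#'
#' @param mat Numeric features x samples matrix.
#' @param rhythm_results Data frame with `feature` and `phase_best_h`
#'   covering every row of `mat` (e.g. from [ejtk_scan()]).
#' @return A list: `normalized` (reordered normalised matrix), `order`
#'   (feature ids in display order), `phase_h`, `zero_median` (logical).
#' @export
median_normalize_and_order <- function(mat, rhythm_results) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  idx <- match(rownames(mat), rhythm_results$feature)
  if (anyNA(idx)) stop("rhythm results missing for some features")
  phase <- rhythm_results$phase_best_h[idx]
  med <- apply(mat, 1L, stats::median)
  zero <- med == 0
  norm <- mat
  norm[!zero, ] <- mat[!zero, , drop = FALSE] / med[!zero]
  ord <- order(zero, phase, rownames(mat))
  list(normalized = norm[ord, , drop = FALSE],
       order = rownames(mat)[ord],
       phase_h = phase[ord],
       zero_median = zero[ord])
}
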