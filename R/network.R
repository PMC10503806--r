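#' Configuration of the permutation-averaged coexpression network
#'
#' @param n_permutations Replicate resamplings to average (default 500).
#' @param p_threshold Edge p cutoff (default 0.001, strict `<`).
#' @param r_threshold Edge Spearman r cutoff (default 0.95, strict `>`).
#' @param min_total Low-count rule: drop features with count below this in
#'   every sample (default 50).
#' @param max_zero_per_timepoint Drop features with more zeros than this in
#'   any single timepoint (default 2).
#' @param seed Integer seed for replicate draws.
#' @param exhaustive If `TRUE`, average over all replicate combinations
#'   instead of random draws (feasible for small designs).
#' @return A `network_config` list.
#' @export
network_config <- function(n_permutations = 500L, p_threshold = 0.001,
                           r_threshold = 0.95, min_total = 50,
                           max_zero_per_timepoint = 2L, seed = 1L,
                           exhaustive = FALSE) {
  stopifnot(n_permutations >= 1L, p_threshold > 0, p_threshold < 1,
            r_threshold > 0, r_threshold < 1)
  structure(list(n_permutations = as.integer(n_permutations),
                 p_threshold = p_threshold, r_threshold = r_threshold,
                 min_total = min_total,
                 max_zero_per_timepoint = as.integer(max_zero_per_timepoint),
                 seed = as.integer(seed), exhaustive = exhaustive),
            class = "network_config")
}

#' Remove low-abundance transcripts before network construction
#'
#' Drops features whose count is below `min_total` in every sample, and
#' features with zero counts in more than `max_zero_per_timepoint` samples
#' within any single timepoint.
#'
#' @param mat Raw count matrix, features x samples.
#' @param timepoints Timepoint label per sample (column).
#' @param config A [network_config()].
#' @return Filtered matrix with a `removed` attribute naming dropped features.
#' @export
filter_low_count_transcripts <- function(mat, timepoints,
                                         config = network_config()) {
  stopifnot(is.matrix(mat), length(timepoints) == ncol(mat))
  low_everywhere <- apply(mat, 1L, function(x) all(x < config$min_total))
  too_many_zero <- apply(mat, 1L, function(x) {
    any(tapply(x == 0, timepoints, sum) > config$max_zero_per_timepoint)
  })
  keep <- !(low_everywhere | too_many_zero)
  out <- mat[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(mat)[!keep]
  out
}

#' Spearman correlation with t-approximation p-value
#'
#' Tie-corrected Spearman rank correlation with the two-sided p-value from
#' the t approximation `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 df — the
#' approximation used by standard correlation-matrix routines. With the
#' short series used here (n = 6 timepoints) an exact permutation p could
#' never reach the 0.001 edge threshold, so the smooth approximation is
#' load-bearing and intentional.
#'
#' @param x,y Numeric vectors, equal length >= 4.
#' @return A list: `r`, `p`, `n`, `degenerate` (`TRUE` if either input is
#'   constant; then r = 0, p = 1).
#' @export
spearman_with_p <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    return(list(r = 0, p = 1, n = length(x), degenerate = TRUE))
  r <- stats::cor(x, y, method = "spearman")
  list(r = r, p = spearman_t_p(r, length(x)), n = length(x),
       degenerate = FALSE)
}

spearman_t_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2))
  pmin(p, 1)
}

#' Replicate-resampled averaged correlation matrices
#'
#' For each permutation, one replicate is drawn uniformly at random per
#' timepoint; the resulting one-per-timepoint series per feature are
#' correlated pairwise (Spearman r with t-approximation p) and the r and p
#' matrices averaged element-wise across permutations. With
#' `config$exhaustive = TRUE` all replicate combinations are enumerated and
#' averaged exactly instead.
#'
#' @param mat Feature x sample matrix (raw counts; rank statistics make
#'   per-sample scale irrelevant within a series).
#' @param timepoints Timepoint label per sample.
#' @param config A [network_config()].
#' @return A list: `r` and `p` (symmetric feature x feature matrices, unit
#'   diagonal r and zero diagonal p excluded from interpretation),
#'   `n_combinations_used`.
#' @export
averaged_correlation_matrices <- function(mat, timepoints,
                                          config = network_config()) {
  stopifnot(is.matrix(mat), length(timepoints) == ncol(mat))
  tp <- factor(timepoints, levels = unique(timepoints))
  reps <- split(seq_len(ncol(mat)), tp)
  if (any(lengths(reps) == 0L)) stop("a timepoint has no replicates")
  m <- nrow(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("f", seq_len(m))
  n_tp <- length(reps)

  one_combo <- function(cols) {
    series <- mat[, cols, drop = FALSE]
    ranks <- t(apply(series, 1L, rank))
    r <- suppressWarnings(stats::cor(t(ranks)))
    # constant series give NA correlations: degenerate pairs -> r 0, p 1
    degen <- is.na(r)
    r[degen] <- 0
    p <- spearman_t_p(r, n_tp)
    p[degen] <- 1
    diag(p) <- 0
    list(r = r, p = p)
  }

  n_combos <- prod(lengths(reps))
  decode <- function(id) {          # mixed-radix index -> one column per tp
    vapply(seq_len(n_tp), function(t) {
      k <- length(reps[[t]])
      j <- id %% k
      id <<- id %/% k
      reps[[t]][j + 1L]
    }, integer(1))
  }
  if (config$exhaustive || config$n_permutations >= n_combos) {
    draws <- lapply(seq_len(n_combos) - 1L, decode)
  } else {
    # balanced draws: within each timepoint every replicate is used equally
    # often (up to rounding) in a shuffled order, independently across
    # timepoints -- uniform marginals with reduced Monte-Carlo variance
    old <- withr_seed(config$seed); on.exit(restore_seed(old), add = TRUE)
    np <- config$n_permutations
    cols_by_tp <- lapply(reps, function(ix) {
      v <- rep(ix, length.out = np + length(ix))
      sample(v)[seq_len(np)]
    })
    draws <- lapply(seq_len(np), function(i)
      vapply(cols_by_tp, `[`, integer(1), i))
  }
  R <- P <- matrix(0, m, m, dimnames = list(rownames(mat), rownames(mat)))
  for (cols in draws) {
    cp <- one_combo(cols)
    R <- R + cp$r
    P <- P + cp$p
  }
  list(r = R / length(draws), p = P / length(draws),
       n_combinations_used = length(draws))
}

#' Flatten averaged correlation matrices into an edge table
#'
#' Keeps upper-triangle pairs with `p < p_threshold` and `r > r_threshold`;
#' self pairs are excluded by construction and each unordered pair appears
#' once with endpoints sorted lexicographically.
#'
#' @param r_matrix,p_matrix Symmetric matrices from
#'   [averaged_correlation_matrices()].
#' @param config A [network_config()].
#' @return Data frame of class `edge_table`: `source`, `target`, `r`, `p`,
#'   sorted by (`source`, `target`).
#' @export
build_edge_table <- function(r_matrix, p_matrix,
                             config = network_config()) {
  stopifnot(identical(dim(r_matrix), dim(p_matrix)),
            nrow(r_matrix) == ncol(r_matrix))
  ut <- upper.tri(r_matrix)
  keep <- ut & p_matrix < config$p_threshold & r_matrix > config$r_threshold
  idx <- which(keep, arr.ind = TRUE)
  nm <- rownames(r_matrix)
  if (is.null(nm)) nm <- paste0("f", seq_len(nrow(r_matrix)))
  a <- nm[idx[, 1L]]; b <- nm[idx[, 2L]]
  src <- pmin(a, b); tgt <- pmax(a, b)
  out <- data.frame(source = src, target = tgt,
                    r = r_matrix[keep], p = p_matrix[keep])
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("edge_table", "data.frame")
  out
}

#' Summarise a coexpression network
#'
#' Node and edge counts, degree and betweenness on the undirected simple
#' graph, and per-category annotated node and edge counts. By default an edge
#' counts toward a category only when both endpoints carry it
#' (`edge_rule = "both"`); `"either"` counts edges with at least one
#' annotated endpoint.
#'
#' @param edges An `edge_table` (or data frame with `source`, `target`).
#' @param annotations Named list: feature -> character vector of categories
#'   (features may be absent or empty).
#' @param edge_rule `"both"` or `"either"`.
#' @return A list: `n_nodes`, `n_edges`, `degree` (named), `betweenness`
#'   (named), `categories` (data frame `category`, `n_nodes`, `n_edges`).
#' @export
network_summary <- function(edges, annotations = list(),
                            edge_rule = c("both", "either")) {
  edge_rule <- match.arg(edge_rule)
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = FALSE)
  g <- igraph::simplify(g)
  nodes <- igraph::V(g)$name
  cats <- sort(unique(unlist(annotations)))
  has_cat <- function(f, cat) !is.null(annotations[[f]]) &&
    cat %in% annotations[[f]]
  cat_df <- do.call(rbind, lapply(cats, function(cat) {
    node_in <- vapply(nodes, has_cat, logical(1), cat = cat)
    a_in <- vapply(edges$source, has_cat, logical(1), cat = cat)
    b_in <- vapply(edges$target, has_cat, logical(1), cat = cat)
    n_e <- if (edge_rule == "both") sum(a_in & b_in) else sum(a_in | b_in)
    data.frame(category = cat, n_nodes = sum(node_in), n_edges = n_e)
  }))
  list(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    degree = igraph::degree(g),
    betweenness = igraph::betweenness(g, directed = FALSE),
    categories = if (is.null(cat_df))
      data.frame(category = character(0), n_nodes = integer(0),
                 n_edges = integer(0)) else cat_df
  )
}
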