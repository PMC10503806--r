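# Independent brute-force oracles used to validate the fast implementations.
# These are written against the textbook definitions, not the package code.

# Kendall tau-b by O(n^2) pair enumeration with tie correction
kendall_oracle <- function(x, y) {
  n <- length(x)
  C <- D <- tie_x <- tie_y <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- x[i] - x[j]; dy <- y[i] - y[j]
      if (dx == 0) tie_x <- tie_x + 1
      if (dy == 0) tie_y <- tie_y + 1
      if (dx * dy > 0) C <- C + 1
      if (dx * dy < 0) D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tie_x) * (n0 - tie_y))
}

# Spearman r (Pearson on mid-ranks) and the two-sided t-approximation p
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else
    2 * pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2)
  list(r = r, p = min(p, 1))
}

# Sn by explicit double loop: inner high median over j != i, outer low median
sn_oracle <- function(x, consistency = 1.1926) {
  n <- length(x)
  inner <- numeric(n)
  for (i in seq_len(n)) {
    d <- numeric(0)
    for (j in seq_len(n)) if (j != i) d <- c(d, abs(x[i] - x[j]))
    d <- sort(d)
    inner[i] <- d[floor(length(d) / 2) + 1L]
  }
  inner <- sort(inner)
  consistency * inner[floor((n + 1) / 2)]
}

# BH step-up by the literal definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  running <- 1
  for (i in m:1) {
    running <- min(running, sorted[i] * m / i)
    q[i] <- running
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Betweenness centrality by explicit shortest-path counting (unit weights):
# BFS distances, DP path counts, and the pair-dependency definition
betweenness_oracle <- function(edges, nodes) {
  adj <- lapply(nodes, function(v) {
    union(edges$target[edges$source == v], edges$source[edges$target == v])
  })
  names(adj) <- nodes
  bfs <- function(s) {
    d <- setNames(rep(Inf, length(nodes)), nodes)
    sig <- setNames(rep(0, length(nodes)), nodes)
    d[s] <- 0; sig[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- character(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (is.infinite(d[w])) { d[w] <- d[v] + 1; nxt <- union(nxt, w) }
        if (d[w] == d[v] + 1) sig[w] <- sig[w] + sig[v]
      }
      frontier <- nxt
    }
    list(d = d, sig = sig)
  }
  sp <- lapply(nodes, bfs)
  names(sp) <- nodes
  bc <- setNames(rep(0, length(nodes)), nodes)
  for (s in nodes) for (t in nodes) {
    if (s >= t) next
    dst <- sp[[s]]$d[t]
    if (is.infinite(dst)) next
    for (v in setdiff(nodes, c(s, t))) {
      if (sp[[s]]$d[v] + sp[[v]]$d[t] == dst) {
        bc[v] <- bc[v] + sp[[s]]$sig[v] * sp[[v]]$sig[t] / sp[[s]]$sig[t]
      }
    }
  }
  bc
}

# minimal planted-oscillator experiment used across tests
make_experiment <- function(n_features, frac_osc, seed, amplitude = 1.5,
                            dispersion = 0.05, groups = "A",
                            n_replicates = 3L) {
  d <- diurnal_design(groups = groups, n_replicates = n_replicates,
                      seed = seed)
  tr <- oscillator_truth(n_features, groups = groups,
                         oscillates_in = groups,
                         frac_oscillating = frac_osc,
                         amplitude = amplitude, dispersion = dispersion,
                         seed = seed + 1L)
  ex <- simulate_transcript_counts(d, tr, seed = seed + 2L)
  list(design = d, truth = tr, ex = ex,
       zt = ex$samples$zt_mod)
}

circular_phase_error <- function(est, truth, period = 24) {
  d <- abs(est - truth) %% period
  pmin(d, period - d)
}
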