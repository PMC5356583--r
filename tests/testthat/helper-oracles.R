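## Independent oracle implementations used to cross-check the package.
## These deliberately avoid the code paths they verify (no igraph, no C++).

# depth-first-search cycle detector on a data.frame edge list
oracle_is_acyclic <- function(edges, nodes) {
  adj <- split(edges$target, factor(edges$regulator, levels = nodes))
  color <- setNames(rep(0L, length(nodes)), nodes)  # 0 white, 1 grey, 2 black
  visit <- function(u) {
    color[u] <<- 1L
    for (v in adj[[u]]) {
      if (color[v] == 1L) return(FALSE)
      if (color[v] == 0L && !visit(v)) return(FALSE)
    }
    color[u] <<- 2L
    TRUE
  }
  for (u in nodes) if (color[u] == 0L && !visit(u)) return(FALSE)
  TRUE
}

# all-pairs shortest path lengths by repeated boolean matrix products
oracle_shortest_paths <- function(edges, nodes, directed = TRUE) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      d[edges$regulator[i], edges$target[i]] <- 1
      if (!directed) d[edges$target[i], edges$regulator[i]] <- 1
    }
  }
  for (k in seq_len(n)) {          # Floyd-Warshall
    for (i in seq_len(n)) {
      nd <- d[i, k] + d[k, ]
      d[i, ] <- pmin(d[i, ], nd)
    }
  }
  d
}

# descendants of `u` within `hops` directed steps, by matrix powers of the
# boolean adjacency matrix
oracle_descendants <- function(edges, nodes, u, hops) {
  n <- length(nodes)
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) A[cbind(edges$regulator, edges$target)] <- 1L
  reach <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  P <- diag(1L, n); dimnames(P) <- list(nodes, nodes)
  for (h in seq_len(hops)) {
    P <- (P %*% A > 0) * 1L
    reach <- (reach + P > 0) * 1L
  }
  setdiff(nodes[reach[u, ] > 0], u)
}

# hypergeometric upper tail P(X >= k) by explicit summation of the pmf
oracle_hyper_tail <- function(k, size_a, size_b, universe) {
  i <- seq(from = k, to = min(size_a, size_b))
  if (k > min(size_a, size_b)) return(0)
  sum(choose(size_a, i) * choose(universe - size_a, size_b - i)) /
    choose(universe, size_b)
}

# closed-form BDeu family score from a table of counts; counts is a matrix
# with one row per parent configuration (q rows) and 3 columns (states)
oracle_bdeu_from_counts <- function(counts, ess) {
  q <- nrow(counts)
  aj <- ess / q
  ajk <- ess / (q * 3)
  sc <- 0
  for (j in seq_len(q)) {
    nj <- sum(counts[j, ])
    sc <- sc + lgamma(aj) - lgamma(aj + nj)
    for (k in 1:3) sc <- sc + lgamma(ajk + counts[j, k]) - lgamma(ajk)
  }
  sc
}

# BDeu family score straight from data (independent tabulation)
oracle_bdeu_from_data <- function(data, target, parents, ess) {
  if (length(parents) == 0L) {
    counts <- matrix(tabulate(data[target, ] + 1L, 3L), nrow = 1L)
  } else {
    cfg <- rep(0L, ncol(data))
    mult <- 1L
    for (p in parents) { cfg <- cfg + data[p, ] * mult; mult <- mult * 3L }
    q <- 3L^length(parents)
    counts <- matrix(0L, q, 3L)
    for (s in seq_len(ncol(data))) {
      counts[cfg[s] + 1L, data[target, s] + 1L] <-
        counts[cfg[s] + 1L, data[target, s] + 1L] + 1L
    }
  }
  oracle_bdeu_from_counts(counts, ess)
}

# best 3-cluster 1-D k-means assignment by exhaustive search over contiguous
# partitions of the sorted values (optimal clusters are contiguous in 1-D)
oracle_kmeans3 <- function(x) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  best <- NULL; best_ss <- Inf
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      g <- c(rep(0L, i), rep(1L, j - i), rep(2L, n - j))
      ss <- sum((xs - ave(xs, g))^2)
      if (ss < best_ss) { best_ss <- ss; best <- g }
    }
  }
  out <- integer(n)
  out[ord] <- best
  out
}

# dense numerical quadrature (composite trapezoid on a fine grid that also
# contains the curve knots) of the piecewise-linear ROC interpolation over
# [0, w], constant extension beyond the last point, normalized by w
oracle_pauc_quadrature <- function(points, spec_floor = 0.9, n_grid = 2e4) {
  w <- 1 - spec_floor
  pts <- unique(points)
  pts <- pts[order(pts$one_minus_specificity, pts$sensitivity), ]
  x <- pts$one_minus_specificity; y <- pts$sensitivity
  if (x[1] > 0) { x <- c(0, x); y <- c(0, y) }
  f <- function(xx) {
    vapply(xx, function(v) {
      if (v >= max(x)) return(y[length(y)])
      i <- findInterval(v, x)
      if (x[i + 1] == x[i]) return(y[i + 1])
      y[i] + (y[i + 1] - y[i]) * (v - x[i]) / (x[i + 1] - x[i])
    }, numeric(1))
  }
  grid <- sort(unique(c(seq(0, w, length.out = n_grid), x[x <= w], w)))
  fy <- f(grid)
  sum(diff(grid) * (head(fy, -1) + fy[-1]) / 2) / w
}

# small random DAG helper for property tests
random_dag_edges <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  ord <- sample(nodes)
  reg <- character(0); tgt <- character(0)
  for (i in 2:n) {
    for (j in 1:(i - 1)) {
      if (runif(1) < p) { reg <- c(reg, ord[j]); tgt <- c(tgt, ord[i]) }
    }
  }
  list(nodes = nodes,
       edges = data.frame(regulator = reg, target = tgt,
                          frequency = if (length(reg)) round(runif(length(reg)), 3) else numeric(0),
                          stringsAsFactors = FALSE))
}

# consensus_network wrapper for hand-built edge lists
make_net <- function(nodes, edges_df) {
  if (!"frequency" %in% names(edges_df)) edges_df$frequency <- 1
  imbnet:::new_consensus_network(nodes, edges_df)
}
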