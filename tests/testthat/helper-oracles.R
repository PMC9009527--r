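# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# All-pairs shortest-path distances by Floyd-Warshall.
oracle_distances <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# Closeness per the printed Eq 5: component size over summed distances.
oracle_closeness <- function(g) {
  D <- oracle_distances(g)
  n <- nrow(D)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    reach <- which(is.finite(D[i, ]))
    cc[i] <- if (length(reach) > 1L) length(reach) / sum(D[i, reach]) else 0
  }
  cc
}

# Raw betweenness over unordered pairs via shortest-path counting:
# sigma[s, t] = number of shortest s-t paths, built by dynamic programming
# in order of distance from s; dependency of v on pair (s, t) is
# sigma[s, v] * sigma[v, t] / sigma[s, t] when v lies on a shortest path.
oracle_betweenness <- function(g) {
  D <- oracle_distances(g)
  n <- nrow(D)
  A <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    for (v in order(D[s, ])) {
      if (v == s || !is.finite(D[s, v])) next
      preds <- which(A[, v] & D[s, ] == D[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, preds])
    }
  }
  cb <- numeric(n)
  for (v in seq_len(n)) {
    on_path <- is.finite(D) & outer(D[, v], D[v, ], "+") == D & sigma > 0
    contrib <- matrix(0, n, n)
    contrib[on_path] <- (outer(sigma[, v], sigma[v, ]) / sigma)[on_path]
    contrib[v, ] <- 0
    contrib[, v] <- 0
    cb[v] <- sum(contrib[upper.tri(contrib)])
  }
  cb
}

# Principal eigenvector of the adjacency matrix of the largest component
# by dense eigendecomposition; L2-normalized, non-negative, 0 elsewhere.
oracle_eigenvector <- function(g) {
  comp <- igraph::components(g)
  big <- which(comp$membership == which.max(comp$csize))
  A <- as.matrix(igraph::as_adjacency_matrix(g))[big, big, drop = FALSE]
  ev <- eigen(A, symmetric = TRUE)$vectors[, 1L]
  ev <- abs(ev)
  out <- numeric(igraph::vcount(g))
  out[big] <- ev / sqrt(sum(ev^2))
  out
}

# Random connected named graph: random recursive spanning tree plus extra
# uniform edges.
random_connected_graph <- function(n, seed, extra = 2 / n) {
  withr::with_seed(seed, {
    tree <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
    pool <- t(combn(n, 2L))
    pool <- pool[runif(nrow(pool)) < extra, , drop = FALSE]
    g <- igraph::simplify(igraph::graph_from_edgelist(rbind(tree, pool),
                                                      directed = FALSE))
    igraph::V(g)$name <- paste0("V", seq_len(n))
    g
  })
}

# All set partitions of n labeled items, as restricted-growth strings.
all_partitions <- function(n) {
  out <- vector("list", 0L)
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (l in seq_len(maxlab + 1L)) {
      rec(c(prefix, l), max(maxlab, l))
    }
  }
  rec(1L, 1L)
  out
}

# Exhaustive maximum modularity over every partition of the node set.
oracle_max_modularity <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 10)
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  m <- igraph::ecount(g)
  best <- -Inf
  for (p in all_partitions(n)) {
    ein <- sum(p[el[, 1L]] == p[el[, 2L]])
    dc <- rowsum(deg, p)
    q <- ein / m - sum((dc / (2 * m))^2)
    if (q > best) best <- q
  }
  best
}

# Two-sided permutation test on the difference of means of log2 values.
oracle_permutation_p <- function(x, y, n_perm = 10000L, seed = 99L) {
  lx <- log2(x); ly <- log2(y)
  obs <- abs(mean(lx) - mean(ly))
  all <- c(lx, ly)
  n1 <- length(lx)
  withr::with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(all), n1)
      if (abs(mean(all[idx]) - mean(all[-idx])) >= obs - 1e-12) hits <- hits + 1L
    }
    hits / n_perm
  })
}

# Small named graphs used across tests.
two_triangles <- function() {
  g <- igraph::make_graph(~ A - B, B - C, C - A, D - E, E - F, F - D, A - D)
  g
}

two_k5 <- function() {
  el <- rbind(t(combn(1:5, 2)), t(combn(6:10, 2)), c(1, 6))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$name <- paste0("K", 1:10)
  g
}

triangular_prism <- function() {
  igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d, a - d, b - e, c - f)
}
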