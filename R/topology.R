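#' Degree spectra: P(k), C(k), C_N(k)
#'
#' Computes the per-node degree \eqn{k_i}, the number of edges among each
#' node's nearest neighbors \eqn{m_i}, the local clustering coefficient
#' \eqn{c_i = 2 m_i / (k_i (k_i - 1))} (defined as 0 for \eqn{k_i < 2}), and
#' the per-degree aggregates: node count \eqn{N_k}, degree probability
#' \eqn{P(k) = N_k / N}, mean clustering \eqn{C(k)}, and mean neighborhood
#' connectivity \eqn{C_N(k)} (average neighbor degree, averaged over nodes of
#' degree k).
#'
#' @param net A curated InteractionNetwork.
#' @return A list with `nodes` (data.frame: node, k, m_i, c_i, knn) and
#'   `spectrum` (data.frame: k, N_k, P_k, C_k, C_N_k).
#' @export
degree_spectra <- function(net) {
  stop_if_not_igraph(net)
  k <- igraph::degree(net)
  m_i <- igraph::count_triangles(net)
  c_i <- ifelse(k >= 2, 2 * m_i / (k * (k - 1)), 0)
  knn_i <- vapply(seq_len(igraph::vcount(net)), function(v) {
    nb <- as.integer(igraph::neighbors(net, v))
    if (!length(nb)) return(NA_real_)
    mean(k[nb])
  }, numeric(1))
  nodes <- data.frame(node = node_names(net), k = as.integer(k),
                      m_i = as.integer(m_i), c_i = c_i, knn = knn_i,
                      stringsAsFactors = FALSE)
  ks <- sort(unique(k))
  spectrum <- data.frame(
    k = ks,
    N_k = vapply(ks, function(x) sum(k == x), integer(1)),
    C_k = vapply(ks, function(x) mean(c_i[k == x]), numeric(1)),
    C_N_k = vapply(ks, function(x) mean(knn_i[k == x]), numeric(1))
  )
  spectrum$P_k <- spectrum$N_k / igraph::vcount(net)
  spectrum <- spectrum[, c("k", "N_k", "P_k", "C_k", "C_N_k")]
  list(nodes = nodes, spectrum = spectrum)
}

#' Per-node centralities: closeness, betweenness, eigenvector
#'
#' Implements the study's printed formulas. Closeness (Eq 5 as printed) is
#' \eqn{C_C(i) = n / \sum_j d_{ij}} with numerator n the size of i's
#' connected component (not the conventional n - 1). Raw betweenness
#' \eqn{C_b(v)} sums pair-dependency fractions \eqn{d_{ij}(v)/d_{ij}} over
#' unordered pairs; normalized betweenness \eqn{C_B = C_b / M} with
#' \eqn{M = (n-1)(n-2)/2} unordered pairs excluding v (M clamped to >= 1).
#' Eigenvector centrality is the principal eigenvector of the adjacency
#' matrix, obtained by power iteration on the largest connected component,
#' L2-normalized and non-negative; nodes outside that component get 0.
#' Disconnected input triggers a warning and component-wise computation.
#'
#' @param net A curated InteractionNetwork.
#' @param tol Power-iteration convergence tolerance.
#' @param max_iter Power-iteration cap.
#' @return A list with `table` (data.frame: node, k, C_C, C_b, C_B, C_E,
#'   component) and `lambda_max` (principal adjacency eigenvalue of the
#'   largest component).
#' @export
centrality_table <- function(net, tol = 1e-12, max_iter = 10000L) {
  stop_if_not_igraph(net)
  n <- igraph::vcount(net)
  comp <- igraph::components(net)
  if (comp$no > 1L) {
    warning(sprintf(
      "network is disconnected (%d components); C_C and C_B computed per component, C_E on the largest",
      comp$no))
  }
  k <- igraph::degree(net)
  d <- igraph::distances(net)
  cc <- numeric(n)
  for (ci in seq_len(comp$no)) {
    mem <- which(comp$membership == ci)
    nc <- length(mem)
    if (nc == 1L) {
      cc[mem] <- 0
    } else {
      cc[mem] <- nc / rowSums(d[mem, mem, drop = FALSE])
    }
  }
  cb <- igraph::betweenness(net, directed = FALSE, weights = NA)
  m_norm <- pmax((comp$csize[comp$membership] - 1) *
                 (comp$csize[comp$membership] - 2) / 2, 1)
  cB <- cb / m_norm

  big <- which(comp$membership == which.max(comp$csize))
  a <- igraph::as_adjacency_matrix(net, sparse = TRUE)[big, big, drop = FALSE]
  v <- rep(1 / sqrt(length(big)), length(big))
  lambda <- 0
  for (it in seq_len(max_iter)) {
    w <- as.numeric(a %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    w <- w / nw
    if (sqrt(sum((w - v)^2)) < tol) { v <- w; lambda <- nw; break }
    v <- w
    lambda <- nw
  }
  v <- abs(v)
  ce <- numeric(n)
  ce[big] <- v / sqrt(sum(v^2))

  list(
    table = data.frame(node = node_names(net), k = as.integer(k),
                       C_C = cc, C_b = cb, C_B = cB, C_E = ce,
                       component = comp$membership,
                       stringsAsFactors = FALSE),
    lambda_max = lambda
  )
}

#' Fit a power law by log-log least squares
#'
#' Ordinary least squares of `log10(y)` on `log10(x)` over strictly positive
#' pairs; zero or negative `y` values are dropped before fitting (count
#' recorded in the result). The exponent is the magnitude of the slope, with
#' the slope's sign recorded separately.
#'
#' @param xs Degrees (strictly positive).
#' @param ys Positive quantity per degree (e.g. P(k), C(k), C_N(k)).
#' @return An object of class `power_law_fit`: list with `slope`, `exponent`
#'   (= |slope|), `sign` (-1, 0, +1), `intercept`, `slope_se`, `r_squared`,
#'   `n_points`, `n_dropped`, `k_range`.
#' @export
fit_power_law <- function(xs, ys) {
  stopifnot(length(xs) == length(ys))
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (any(xs <= 0)) stop("non-positive x values are not allowed")
  usable <- ys > 0
  n_dropped <- sum(!usable)
  xs <- xs[usable]; ys <- ys[usable]
  if (length(unique(xs)) < 3L) {
    stop(sprintf("need >= 3 usable points with distinct degrees, got %d",
                 length(unique(xs))))
  }
  lx <- log10(xs); ly <- log10(ys)
  fit <- lm(ly ~ lx)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  ss_res <- sum(fit$residuals^2)
  sxx <- sum((lx - mean(lx))^2)
  se <- sqrt(ss_res / (length(lx) - 2L) / sxx)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot < 1e-24) {
    if (ss_res < 1e-24) 1 else 0
  } else {
    1 - ss_res / ss_tot
  }
  structure(list(
    slope = slope,
    exponent = abs(slope),
    sign = sign(slope),
    intercept = intercept,
    slope_se = se,
    r_squared = max(0, min(1, r2)),
    n_points = length(xs),
    n_dropped = n_dropped,
    k_range = range(xs)
  ), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "power-law fit: exponent %.4f (slope %+.4f, se %.4f), R^2 %.3f, %d points on k in [%g, %g]\n",
    x$exponent, x$slope, x$slope_se, x$r_squared, x$n_points,
    x$k_range[1], x$k_range[2]))
  invisible(x)
}

#' Classify network topology from power-law fits
#'
#' Labels the network "hierarchical scale-free" when the P(k) and C(k) fits
#' both have negative slopes with R-squared at or above `r2_threshold` and
#' slope magnitude at or above `slope_threshold`; "scale-free" when only
#' P(k) qualifies; otherwise "non-scale-free". Assortativity is read from
#' the C_N(k) slope: positive (above threshold) is "assortative", negative
#' is "disassortative", magnitudes below `slope_threshold` are "neutral".
#'
#' @param fits Named list with elements `p_k`, `c_k`, `c_n_k`, each a
#'   [fit_power_law()] result.
#' @param r2_threshold Minimum R-squared for a power law to count.
#' @param slope_threshold Minimum |slope| for a non-neutral slope.
#' @return List with `label`, `assortativity`, and the thresholds used.
#' @export
classify_topology <- function(fits, r2_threshold = 0.5, slope_threshold = 0.05) {
  need <- c("p_k", "c_k", "c_n_k")
  missing_fits <- setdiff(need, names(fits))
  if (length(missing_fits)) {
    stop("missing fits: ", paste(missing_fits, collapse = ", "))
  }
  qualifies <- function(f) {
    f$slope < 0 && f$r_squared >= r2_threshold && abs(f$slope) >= slope_threshold
  }
  label <- if (qualifies(fits$p_k) && qualifies(fits$c_k)) {
    "hierarchical scale-free"
  } else if (qualifies(fits$p_k)) {
    "scale-free"
  } else {
    "non-scale-free"
  }
  s <- fits$c_n_k$slope
  assort <- if (abs(s) < slope_threshold) "neutral"
            else if (s > 0) "assortative" else "disassortative"
  list(label = label, assortativity = assort,
       r2_threshold = r2_threshold, slope_threshold = slope_threshold)
}
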