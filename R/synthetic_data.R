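#' Deterministic hierarchical network (five-node replication)
#'
#' Canonical deterministic hierarchical construction: start from a 5-clique
#' (node 1 central, nodes 2-5 peripheral); at each iteration make 4 copies
#' of the current network and connect the copies' peripheral (corner) nodes
#' to the original central hub. N = 5^iterations. This is the standard
#' testbed for the hierarchical clustering law C(k) ~ k^-1.
#'
#' @param iterations Integer in 1..5 (desk scale).
#' @return A `generated_network`: list with `network` (igraph, nodes named
#'   H1..HN), `truth = NULL` (construction is its own ground truth),
#'   `generator`, `params`, `seed = NA` (no randomness).
#' @export
make_deterministic_hierarchical <- function(iterations) {
  if (!is.numeric(iterations) || length(iterations) != 1L || iterations < 1) {
    stop("iterations must be a single integer >= 1")
  }
  if (iterations > 5) stop("iterations must be <= 5 (desk scale)")
  iterations <- as.integer(iterations)
  edges <- t(combn(1:5, 2))
  n <- 5L
  center <- 1L
  peripheral <- 2:5
  it <- 1L
  while (it < iterations) {
    base_edges <- edges
    base_n <- n
    all_edges <- list(base_edges)
    new_peripheral <- integer()
    for (r in 1:4) {
      off <- base_n * r
      all_edges[[r + 1L]] <- base_edges + off
      new_peripheral <- c(new_peripheral, peripheral + off)
    }
    edges <- do.call(rbind, all_edges)
    edges <- rbind(edges, cbind(new_peripheral, center))
    n <- base_n * 5L
    peripheral <- new_peripheral
    it <- it + 1L
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$name <- paste0("H", seq_len(igraph::vcount(g)))
  new_generated_network(g, truth = NULL,
                        generator = "deterministic_hierarchical",
                        params = list(iterations = iterations),
                        seed = NA_integer_)
}

#' Planted multi-level hierarchical network with designated regulators
#'
#' Generates a three-level nested community structure with known ground
#' truth: `branches_per_level[1]` level-1 blocks, each containing
#' `branches_per_level[2]` level-2 leaves of `leaf_size` nodes, each leaf
#' composed of `branches_per_level[3]` planted triangles (the level-3 motif
#' communities) joined by a perfect matching (a triangular prism for the
#' defaults). Leaves within a block are joined by load-balanced connector
#' edges; `n_regulators` designated nodes, spread round-robin across
#' blocks, receive extra degree through a regulator rich club (a cycle
#' among each block's regulators plus one global ring) and one cyclic
#' anchor edge each into a regulator-free triangle of the next leaf of
#' their home block, so they are the top-degree hubs and survive
#' decomposition to motif level. Sparse background noise (`p_out`) is
#' added between blocks only, capped at one extra edge per node, with
#' regulators excluded — this keeps the planted degree margin
#' deterministic.
#'
#' `p_in_by_level` is ordered from the deepest level up and is realized as
#' fixed per-pair edge budgets: element 1 is the within-triangle density
#' (must be 1: triangles are complete), element 2 the triangle-triangle
#' coupling density (must give the `branches_per_level[3]`-edge matching),
#' element 3 the leaf-pair connector density (defaults to 1 connector per
#' leaf pair).
#'
#' @param levels Number of planted levels; only 3 is supported.
#' @param branches_per_level Integer vector of length `levels`; defaults
#'   `c(4, 3, 2)`.
#' @param leaf_size Nodes per leaf; must equal `3 * branches_per_level[3]`.
#' @param p_in_by_level Decreasing within-community densities, deepest
#'   level first; all must exceed `p_out`.
#' @param p_out Between-block background edge probability.
#' @param n_regulators Number of designated regulator hubs (at most 2 per
#'   leaf-column, i.e. <= 2 * prod(branches_per_level[1:2])).
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @return A `generated_network`: `network` (igraph, nodes P1..Pn),
#'   `truth` (list: `level1`, `level2`, `level3` named membership vectors,
#'   `regulators` character vector), `generator`, `params`, `seed`.
#' @export
make_planted_hierarchy <- function(levels = 3L,
                                   branches_per_level = c(4L, 3L, 2L),
                                   leaf_size = 6L,
                                   p_in_by_level = c(1, 1 / 3, 1 / 36),
                                   p_out = 0.003,
                                   n_regulators = 15L,
                                   seed = 7L) {
  problems <- character()
  if (levels != 3L) {
    problems <- c(problems, sprintf("levels = %s (only the 3-level construction is implemented)", levels))
  }
  if (length(branches_per_level) != levels || any(branches_per_level < 2)) {
    problems <- c(problems, sprintf("branches_per_level = (%s): need %d entries, all >= 2",
                                    paste(branches_per_level, collapse = ","), levels))
  }
  if (leaf_size < 3) problems <- c(problems, sprintf("leaf_size = %s (< 3)", leaf_size))
  if (length(branches_per_level) == levels &&
      leaf_size != 3 * branches_per_level[levels]) {
    problems <- c(problems, sprintf(
      "leaf_size = %s but 3 * branches_per_level[%d] = %s (leaves are built from triangles)",
      leaf_size, levels, 3 * branches_per_level[levels]))
  }
  if (length(p_in_by_level) != levels) {
    problems <- c(problems, sprintf("p_in_by_level has %d entries, need %d",
                                    length(p_in_by_level), levels))
  } else {
    if (any(diff(p_in_by_level) >= 0)) {
      problems <- c(problems, sprintf("p_in_by_level = (%s) must strictly decrease from the deepest level up",
                                      paste(signif(p_in_by_level, 4), collapse = ",")))
    }
    if (any(p_in_by_level <= p_out)) {
      problems <- c(problems, sprintf("p_in_by_level = (%s) must all exceed p_out = %s",
                                      paste(signif(p_in_by_level, 4), collapse = ","), p_out))
    }
    if (p_in_by_level[1L] != 1) {
      problems <- c(problems, sprintf("p_in_by_level[1] = %s (deepest-level triangles must be complete: density 1)",
                                      p_in_by_level[1L]))
    }
  }
  if (p_out < 0 || p_out >= 1) problems <- c(problems, sprintf("p_out = %s not in [0, 1)", p_out))
  n_prisms <- branches_per_level[1L] * branches_per_level[2L]
  if (n_regulators < 1 || n_regulators > 2 * n_prisms) {
    problems <- c(problems, sprintf("n_regulators = %s not in 1..%d", n_regulators, 2 * n_prisms))
  }
  if (length(problems)) {
    stop("inconsistent generator parameters:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  branches <- as.integer(branches_per_level)
  leaf_size <- as.integer(leaf_size)
  n_regulators <- as.integer(n_regulators)
  n_pairs_in_leaf <- leaf_size^2
  connectors <- max(1L, as.integer(round(p_in_by_level[3L] * n_pairs_in_leaf)))

  n <- n_prisms * leaf_size
  prism_id <- rep(seq_len(n_prisms), each = leaf_size)
  l1_id <- ceiling(prism_id / branches[2L])
  tri_id <- (prism_id - 1L) * branches[3L] + rep(rep(seq_len(branches[3L]), each = 3L), n_prisms)

  build <- function() {
    # round-robin prism order so regulators spread one per leaf-column
    prism_order <- as.vector(t(matrix(seq_len(n_prisms), nrow = branches[2L])))
    regs <- integer(n_regulators)
    for (i in seq_len(n_regulators)) {
      pr <- prism_order[((i - 1L) %% n_prisms) + 1L]
      regs[i] <- which(prism_id == pr)[if (i > n_prisms) 4L else 1L]
    }
    edges <- list()
    # leaves: triangles + perfect matching between consecutive triangles
    for (pf in seq_len(n_prisms)) {
      mem <- which(prism_id == pf)
      tri_edges <- list()
      for (ti in seq_len(branches[3L])) {
        tri <- mem[(3L * (ti - 1L) + 1L):(3L * ti)]
        tri_edges[[ti]] <- t(combn(tri, 2L))
      }
      match_edges <- list()
      if (branches[3L] > 1L) {
        for (ti in seq_len(branches[3L] - 1L)) {
          a <- mem[(3L * (ti - 1L) + 1L):(3L * ti)]
          b <- mem[(3L * ti + 1L):(3L * (ti + 1L))]
          match_edges[[ti]] <- cbind(a, b)
        }
      }
      edges[[length(edges) + 1L]] <- do.call(rbind, c(tri_edges, match_edges))
    }
    # shared extra-edge budget for all non-regulator nodes
    load <- rep(0L, n)
    # connectors between leaf pairs within each block, load-balanced
    for (b1 in seq_len(branches[1L])) {
      prs <- unique(prism_id[l1_id == b1])
      for (pr2 in combn(prs, 2L, simplify = FALSE)) {
        ca <- setdiff(which(prism_id == pr2[1L]), regs)
        cb <- setdiff(which(prism_id == pr2[2L]), regs)
        for (q in seq_len(connectors)) {
          a <- ca[order(load[ca], sample(length(ca)))][1L]
          b <- cb[order(load[cb], sample(length(cb)))][1L]
          load[a] <- load[a] + 1L
          load[b] <- load[b] + 1L
          edges[[length(edges) + 1L]] <- cbind(a, b)
        }
      }
    }
    # hub rich club: cycle among each block's regulators + one global ring
    for (b1 in seq_len(branches[1L])) {
      br <- regs[l1_id[regs] == b1]
      if (length(br) == 2L) {
        edges[[length(edges) + 1L]] <- matrix(br, ncol = 2L)
      } else if (length(br) > 2L) {
        edges[[length(edges) + 1L]] <- cbind(br, br[c(2:length(br), 1L)])
      }
    }
    if (n_regulators >= 2L) {
      edges[[length(edges) + 1L]] <- cbind(regs, regs[c(2:n_regulators, 1L)])
    }
    # cyclic anchors: each regulator one edge into the next leaf of its
    # block, landing in a regulator-free triangle
    reg_tris <- unique(tri_id[regs])
    for (r in regs) {
      prs <- sort(unique(prism_id[l1_id == l1_id[r]]))
      k <- match(prism_id[r], prs)
      target <- prs[(k %% length(prs)) + 1L]
      cand <- which(prism_id == target & !(tri_id %in% reg_tris))
      if (!length(cand)) cand <- setdiff(which(prism_id == target), regs)
      cand <- cand[order(load[cand], sample(length(cand)))]
      load[cand[1L]] <- load[cand[1L]] + 1L
      edges[[length(edges) + 1L]] <- cbind(r, cand[1L])
    }
    # sparse background noise between blocks, capped at 1 extra edge/node
    pairs <- t(combn(seq_len(n), 2L))
    ok <- l1_id[pairs[, 1L]] != l1_id[pairs[, 2L]] &
      !(pairs[, 1L] %in% regs) & !(pairs[, 2L] %in% regs)
    keep <- which(ok & runif(nrow(pairs)) < p_out)
    noise_deg <- rep(0L, n)
    for (i in keep) {
      a <- pairs[i, 1L]
      b <- pairs[i, 2L]
      if (load[a] + noise_deg[a] < 2L && load[b] + noise_deg[b] < 2L) {
        noise_deg[a] <- noise_deg[a] + 1L
        noise_deg[b] <- noise_deg[b] + 1L
        edges[[length(edges) + 1L]] <- pairs[i, , drop = FALSE]
      }
    }
    el <- unique(t(apply(do.call(rbind, edges), 1L, sort)))
    el <- el[el[, 1L] != el[, 2L], , drop = FALSE]
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (igraph::vcount(g) < n) {
      g <- igraph::add_vertices(g, n - igraph::vcount(g))
    }
    g <- igraph::simplify(g)
    igraph::V(g)$name <- paste0("P", seq_len(n))
    list(g = g, regs = regs)
  }
  res <- withr::with_seed(as.integer(seed), build())
  nm <- paste0("P", seq_len(n))
  truth <- list(level1 = setNames(l1_id, nm),
                level2 = setNames(prism_id, nm),
                level3 = setNames(tri_id, nm),
                regulators = paste0("P", res$regs))
  new_generated_network(res$g, truth = truth,
                        generator = "planted_hierarchy",
                        params = list(levels = levels,
                                      branches_per_level = branches,
                                      leaf_size = leaf_size,
                                      p_in_by_level = p_in_by_level,
                                      p_out = p_out,
                                      n_regulators = n_regulators),
                        seed = as.integer(seed))
}

#' Control network generators
#'
#' Standard null models with no planted community structure: Erdos-Renyi
#' G(n, p) random graphs and Barabasi-Albert preferential-attachment
#' growth.
#'
#' @param model `"random"` (param = edge probability p in (0, 1]) or
#'   `"preferential_attachment"` (param = edges added per step, integer
#'   >= 1).
#' @param n Number of nodes, >= 10.
#' @param param Model parameter, see `model`.
#' @param seed Integer seed.
#' @return A `generated_network` with `truth = NULL`.
#' @export
make_control <- function(model = c("random", "preferential_attachment"),
                         n, param, seed = 1L) {
  model <- match.arg(model)
  if (!is.numeric(n) || length(n) != 1L || n < 10) {
    stop("n must be a single integer >= 10")
  }
  n <- as.integer(n)
  if (model == "random") {
    if (!is.numeric(param) || param <= 0 || param > 1) {
      stop("for model = 'random', param must be an edge probability in (0, 1]")
    }
    g <- withr::with_seed(as.integer(seed),
                          igraph::sample_gnp(n, param, directed = FALSE))
  } else {
    if (!is.numeric(param) || param < 1 || param != round(param)) {
      stop("for model = 'preferential_attachment', param must be an integer >= 1 (edges per step)")
    }
    g <- withr::with_seed(as.integer(seed),
                          igraph::sample_pa(n, m = as.integer(param),
                                            directed = FALSE))
  }
  igraph::V(g)$name <- paste0("N", seq_len(n))
  new_generated_network(g, truth = NULL, generator = model,
                        params = list(n = n, param = param),
                        seed = as.integer(seed))
}

#' Quantitation table with planted deregulation
#'
#' Long-format replicate ratio table for two groups (`case`, `control`).
#' Replicate ratios are log-normal: normal noise with standard deviation
#' `replicate_sd` on the log2 scale around the true log2 fold change (0 for
#' unplanted proteins). Planted true effects are drawn uniformly on
#' [log2(min_fold), max_log2_fc] with the planted direction, so every
#' planted member has |true log2 FC| >= log2(min_fold). Defaults mirror
#' the study's shape: 434 proteins, 65 deregulated (49 up, 16 down) at
#' fold >= 1.5.
#'
#' @param n_proteins Total number of proteins.
#' @param n_deregulated Number of planted deregulated proteins.
#' @param n_up Number of planted upregulated proteins (rest are down).
#' @param min_fold Minimum planted fold change (ratio scale, > 1).
#' @param replicate_sd Log2-scale replicate noise standard deviation.
#' @param n_replicates Replicates per group.
#' @param max_log2_fc Upper bound of planted |log2 FC|.
#' @param seed Integer seed.
#' @return A `generated_quant_table`: list with `table` (data.frame:
#'   protein_id, group, replicate, ratio), `truth` (data.frame:
#'   protein_id, true_log2_fc, direction for planted members), `params`,
#'   `seed`.
#' @export
make_quant_table <- function(n_proteins = 434L, n_deregulated = 65L,
                             n_up = 49L, min_fold = 1.5,
                             replicate_sd = 0.1, n_replicates = 3L,
                             max_log2_fc = 2.5, seed = 3L) {
  problems <- character()
  if (n_proteins < 1) problems <- c(problems, sprintf("n_proteins = %s (< 1)", n_proteins))
  if (n_deregulated < 0 || n_deregulated > n_proteins) {
    problems <- c(problems, sprintf("n_deregulated = %s not in 0..%s", n_deregulated, n_proteins))
  }
  if (n_up < 0 || n_up > n_deregulated) {
    problems <- c(problems, sprintf("n_up = %s not in 0..%s", n_up, n_deregulated))
  }
  if (min_fold <= 1) problems <- c(problems, sprintf("min_fold = %s (must be > 1)", min_fold))
  if (replicate_sd < 0) problems <- c(problems, sprintf("replicate_sd = %s (< 0)", replicate_sd))
  if (n_replicates < 1) problems <- c(problems, sprintf("n_replicates = %s (< 1)", n_replicates))
  if (max_log2_fc <= log2(min_fold)) {
    problems <- c(problems, sprintf("max_log2_fc = %s (must exceed log2(min_fold) = %.3f)",
                                    max_log2_fc, log2(min_fold)))
  }
  if (length(problems)) {
    stop("inconsistent generator parameters:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  n_proteins <- as.integer(n_proteins)
  n_deregulated <- as.integer(n_deregulated)
  n_up <- as.integer(n_up)
  n_replicates <- as.integer(n_replicates)
  ids <- sprintf("prot%04d", seq_len(n_proteins))

  gen <- function() {
    planted <- sample(ids, n_deregulated)
    up <- planted[seq_len(n_up)]
    magnitude <- runif(n_deregulated, log2(min_fold), max_log2_fc)
    true_lfc <- setNames(rep(0, n_proteins), ids)
    true_lfc[planted] <- ifelse(planted %in% up, magnitude, -magnitude)
    rows <- vector("list", 2L)
    for (gi in 1:2) {
      grp <- c("case", "control")[gi]
      shift <- if (grp == "case") true_lfc else rep(0, n_proteins)
      noise <- matrix(rnorm(n_proteins * n_replicates, 0, replicate_sd),
                      nrow = n_proteins)
      rows[[gi]] <- data.frame(
        protein_id = rep(ids, times = n_replicates),
        group = grp,
        replicate = rep(seq_len(n_replicates), each = n_proteins),
        ratio = 2^(rep(shift, times = n_replicates) + as.vector(noise)),
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    truth <- data.frame(protein_id = planted,
                        true_log2_fc = unname(true_lfc[planted]),
                        direction = ifelse(planted %in% up, "up", "down"),
                        stringsAsFactors = FALSE)
    truth <- truth[order(truth$protein_id), , drop = FALSE]
    rownames(truth) <- NULL
    list(table = tab, truth = truth)
  }
  res <- withr::with_seed(as.integer(seed), gen())
  structure(list(table = res$table, truth = res$truth,
                 params = list(n_proteins = n_proteins,
                               n_deregulated = n_deregulated,
                               n_up = n_up, n_down = n_deregulated - n_up,
                               min_fold = min_fold,
                               replicate_sd = replicate_sd,
                               n_replicates = n_replicates,
                               max_log2_fc = max_log2_fc),
                 seed = as.integer(seed)),
            class = "generated_quant_table")
}

new_generated_network <- function(g, truth, generator, params, seed) {
  structure(list(network = g, truth = truth, generator = generator,
                 params = params, seed = seed),
            class = "generated_network")
}

#' @export
print.generated_network <- function(x, ...) {
  cat(sprintf("generated network (%s): %d nodes, %d edges, seed %s\n",
              x$generator, igraph::vcount(x$network),
              igraph::ecount(x$network), format(x$seed)))
  if (!is.null(x$truth)) {
    cat(sprintf("  planted: %d levels, %d regulators\n",
                sum(grepl("^level", names(x$truth))),
                length(x$truth$regulators)))
  }
  invisible(x)
}

#' @export
print.generated_quant_table <- function(x, ...) {
  cat(sprintf(
    "generated quant table: %d proteins x %d replicates x 2 groups; %d planted deregulated (%d up, %d down), seed %d\n",
    x$params$n_proteins, x$params$n_replicates, x$params$n_deregulated,
    x$params$n_up, x$params$n_down, x$seed))
  invisible(x)
}

#' Write generator ground truth as a JSON sidecar
#'
#' @param generated A `generated_network` or `generated_quant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(generated, path) {
  if (inherits(generated, "generated_network")) {
    payload <- list(generator = generated$generator,
                    seed = generated$seed,
                    params = generated$params,
                    truth = if (is.null(generated$truth)) NULL else list(
                      levels = lapply(
                        generated$truth[grepl("^level", names(generated$truth))],
                        function(v) as.list(setNames(as.integer(v), names(v)))),
                      regulators = as.list(generated$truth$regulators)))
  } else if (inherits(generated, "generated_quant_table")) {
    payload <- list(generator = "quant_table",
                    seed = generated$seed,
                    params = generated$params,
                    truth = generated$truth)
  } else {
    stop("generated must be a generated_network or generated_quant_table")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a quant table as TSV
#'
#' @param quant A `generated_quant_table` or a long-format data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quant, path) {
  tab <- if (inherits(quant, "generated_quant_table")) quant$table else quant
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
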