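#' Detect communities by seeded modularity optimization
#'
#' Default backend is the Louvain heuristic with seeded multi-restart:
#' `restarts` runs with distinct derived seeds, keeping the partition with
#' the highest modularity (ties go to the first run that attained it, i.e.
#' the smallest restart index). Restarts are required for correctness at
#' small scale: a single Louvain run can return a modularity-0 local optimum
#' (e.g. the matching-pairs split of a triangular prism) that violates the
#' package invariant "modularity >= 0.95 x the exhaustive maximum on n <= 10
#' graphs". The Girvan-Newman edge-betweenness backend is provided as an
#' alternative honoring the method's original citation; it is deterministic
#' and ignores `seed`/`restarts`.
#'
#' @param net A curated InteractionNetwork with >= 1 node.
#' @param seed Integer seed controlling node-visit order (Louvain only).
#' @param resolution Positive resolution parameter (Louvain only).
#' @param method `"louvain"` (default) or `"girvan_newman"`.
#' @param restarts Number of seeded Louvain restarts.
#' @return A `community_partition`: list with `membership` (named integer
#'   vector), `modularity`, `n_communities`, `method`, `seed`, `resolution`.
#' @export
detect_communities <- function(net, seed = 42L, resolution = 1,
                               method = c("louvain", "girvan_newman"),
                               restarts = 10L) {
  method <- match.arg(method)
  stop_if_not_igraph(net)
  stopifnot(resolution > 0, restarts >= 1)
  if (igraph::vcount(net) < 2L) {
    mem <- setNames(rep(1L, igraph::vcount(net)), node_names(net))
    return(structure(list(membership = mem, modularity = 0,
                          n_communities = length(unique(mem)),
                          method = method, seed = seed,
                          resolution = resolution),
                     class = "community_partition"))
  }
  if (method == "girvan_newman") {
    cl <- igraph::cluster_edge_betweenness(net, weights = NA)
    mem <- igraph::membership(cl)
    q <- igraph::modularity(net, mem)
  } else {
    mem <- best_louvain(net, seed, restarts = restarts,
                        resolution = resolution)
    q <- igraph::modularity(net, mem)
  }
  mem <- setNames(as.integer(mem), node_names(net))
  structure(list(membership = mem, modularity = q,
                 n_communities = length(unique(mem)),
                 method = method, seed = seed, resolution = resolution),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community partition (%s): %d communities over %d nodes, Q = %.4f\n",
              x$method, x$n_communities, length(x$membership), x$modularity))
  invisible(x)
}

# Best-of-restarts seeded Louvain. Restart r runs under seed s*131 + r
# (reduced mod 2^31 - 19 so arbitrary user seeds stay in range); strict
# improvement by more than 1e-12 is required to replace the incumbent, so
# modularity ties resolve to the earliest restart. The winning partition
# gets a deterministic greedy single-node refinement pass: Louvain's
# aggregation phase can lock in partitions that a single node move on the
# original graph still improves (e.g. the 2+3+4 arc split of a 9-cycle).
best_louvain <- function(sub, s, restarts = 10L, resolution = 1) {
  best <- NULL
  bq <- -Inf
  for (r in seq_len(restarts)) {
    rs <- as.integer((abs(as.numeric(s)) * 131 + r) %% 2147483629)
    cl <- withr::with_seed(rs,
      igraph::cluster_louvain(sub, resolution = resolution))
    q <- igraph::modularity(cl)
    if (q > bq + 1e-12) {
      bq <- q
      best <- igraph::membership(cl)
    }
  }
  refine_partition(sub, best)
}

# Greedy single-node moves to a neighboring community, applied in fixed
# vertex order until no move strictly increases standard modularity.
# Deterministic; only ever improves the partition it is given.
refine_partition <- function(sub, mem) {
  mem <- as.integer(mem)
  m <- igraph::ecount(sub)
  if (m == 0L) return(mem)
  deg <- igraph::degree(sub)
  adj <- igraph::as_adj_list(sub)
  d_c <- unname(rowsum(deg, mem))
  labs <- sort(unique(mem))
  d_of <- setNames(as.numeric(d_c), as.character(labs))
  repeat {
    moved <- FALSE
    for (i in seq_along(mem)) {
      nb <- as.integer(adj[[i]])
      if (!length(nb)) next
      a <- mem[i]
      k_to <- table(mem[nb])
      k_ia <- if (as.character(a) %in% names(k_to)) k_to[[as.character(a)]] else 0
      cand <- setdiff(as.integer(names(k_to)), a)
      best_dq <- 0
      best_b <- a
      for (b in sort(cand)) {
        k_ib <- k_to[[as.character(b)]]
        d_a <- d_of[[as.character(a)]] - deg[i]
        d_b <- d_of[[as.character(b)]]
        dq <- (k_ib - k_ia) / m - deg[i] * (d_b - d_a) / (2 * m^2)
        if (dq > best_dq + 1e-12) {
          best_dq <- dq
          best_b <- b
        }
      }
      if (best_b != a) {
        d_of[[as.character(a)]] <- d_of[[as.character(a)]] - deg[i]
        bkey <- as.character(best_b)
        d_of[[bkey]] <- d_of[[bkey]] + deg[i]
        mem[i] <- best_b
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  mem
}

#' Does a member set qualify for further decomposition?
#'
#' A community qualifies iff its induced subgraph contains at least one
#' triangle (motif G(3,3)).
#'
#' @param net An InteractionNetwork.
#' @param member_set Character vector of node names (subset of the network).
#' @return `TRUE` iff the induced subgraph has >= 1 triangle.
#' @export
has_motif_qualification <- function(net, member_set) {
  stop_if_not_igraph(net)
  missing_nodes <- setdiff(member_set, node_names(net))
  if (length(missing_nodes)) {
    stop("member_set contains nodes absent from the network: ",
         paste(head(missing_nodes, 5L), collapse = ", "))
  }
  sub <- igraph::induced_subgraph(net, member_set)
  sum(igraph::count_triangles(sub)) > 0
}

#' Recursive multi-level community decomposition
#'
#' Starting from the full network (tree root, level 0), each qualifying
#' community (contains a triangle, more than 3 nodes, and splits into >= 2
#' communities under [detect_communities()]) is re-partitioned on its
#' induced subgraph to form the next level. Recursion stops at terminal
#' motifs G(3,3) (exactly 3 nodes, 3 edges), at communities with no
#' triangle, at communities that refuse to split, or at `max_levels`.
#' Sub-community seeds derive arithmetically from the parent seed (parent
#' seed + community label), so the whole tree is reproducible from one seed.
#'
#' @param net A curated InteractionNetwork.
#' @param seed Integer seed for the seeded Louvain runs.
#' @param resolution Positive Louvain resolution.
#' @param max_levels Maximum community depth (root excluded); must be >= 1.
#' @param method Community backend, see [detect_communities()].
#' @param restarts Louvain restarts per partition call.
#' @return A `community_tree`: list with `nodes` (list of records: `id`,
#'   `label`, `level`, `parent`, `members`, `n_edges`, `has_triangle`,
#'   `is_motif`, `terminal`, `children`), `max_depth`,
#'   `level_membership` (per level, named vector of community labels),
#'   `n_graph_nodes`, and the parameters used.
#' @export
decompose <- function(net, seed = 42L, resolution = 1, max_levels = 20L,
                      method = c("louvain", "girvan_newman"),
                      restarts = 10L) {
  method <- match.arg(method)
  stop_if_not_igraph(net)
  if (!is.numeric(max_levels) || length(max_levels) != 1L || max_levels < 1) {
    stop("max_levels must be a single integer >= 1")
  }
  max_levels <- as.integer(max_levels)

  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$max_depth <- 0L
  env$lv_mem <- list()
  all_names <- node_names(net)

  recurse <- function(sub, level, s, parent_id, label) {
    nv <- igraph::vcount(sub)
    ne <- igraph::ecount(sub)
    has_tri <- sum(igraph::count_triangles(sub)) > 0
    is_motif <- (nv == 3L && ne == 3L && level > 0L)
    id <- length(env$nodes) + 1L
    rec <- list(id = id, label = label, level = level, parent = parent_id,
                members = igraph::V(sub)$name, n_edges = ne,
                has_triangle = has_tri, is_motif = is_motif,
                terminal = TRUE, children = integer())
    env$nodes[[id]] <- rec
    if (level > 0L) {
      env$max_depth <- max(env$max_depth, level)
      if (length(env$lv_mem) < level) {
        env$lv_mem[[level]] <- setNames(rep(NA_character_, length(all_names)),
                                        all_names)
      }
      env$lv_mem[[level]][rec$members] <- label
    }
    if (is_motif || nv <= 3L || !has_tri || level >= max_levels) return(id)
    if (method == "louvain") {
      m <- best_louvain(sub, s, restarts = restarts, resolution = resolution)
    } else {
      m <- igraph::membership(igraph::cluster_edge_betweenness(sub, weights = NA))
    }
    labs <- unique(as.integer(m))
    if (length(labs) < 2L) return(id)
    kids <- integer()
    for (c in labs) {
      child <- recurse(igraph::induced_subgraph(sub, which(m == c)),
                       level + 1L, s + c, id, paste0(label, ".", c))
      kids <- c(kids, child)
    }
    env$nodes[[id]]$terminal <- FALSE
    env$nodes[[id]]$children <- kids
    id
  }
  recurse(net, 0L, seed, NA_integer_, "r")

  structure(list(nodes = env$nodes, max_depth = env$max_depth,
                 level_membership = env$lv_mem,
                 n_graph_nodes = length(all_names),
                 seed = seed, resolution = resolution, method = method,
                 restarts = restarts, max_levels = max_levels),
            class = "community_tree")
}

#' @export
print.community_tree <- function(x, ...) {
  n_motifs <- sum(vapply(x$nodes, `[[`, logical(1), "is_motif"))
  cat(sprintf(
    "community tree: %d graph nodes, depth %d, %d tree nodes (%d motifs G(3,3))\n",
    x$n_graph_nodes, x$max_depth, length(x$nodes) - 1L, n_motifs))
  invisible(x)
}

#' Per-level summary of a community tree
#'
#' @param tree A `community_tree` from [decompose()].
#' @return A data.frame with one row per level (1..depth): number of
#'   communities, smallest/largest size, number qualifying (has a triangle),
#'   number of motifs. Attributes `total_communities` (across all levels,
#'   root excluded) and `n_motif_chains` (complete root-to-motif chains).
#' @export
level_summary <- function(tree) {
  stopifnot(inherits(tree, "community_tree"))
  if (tree$max_depth == 0L) {
    out <- data.frame(level = integer(), n_communities = integer(),
                      min_size = integer(), max_size = integer(),
                      n_qualifying = integer(), n_motifs = integer())
    attr(out, "total_communities") <- 0L
    attr(out, "n_motif_chains") <- 0L
    return(out)
  }
  lv <- vapply(tree$nodes, `[[`, integer(1), "level")
  sz <- vapply(tree$nodes, function(nd) length(nd$members), integer(1))
  qual <- vapply(tree$nodes, `[[`, logical(1), "has_triangle")
  motif <- vapply(tree$nodes, `[[`, logical(1), "is_motif")
  levels <- seq_len(tree$max_depth)
  out <- data.frame(
    level = levels,
    n_communities = vapply(levels, function(l) sum(lv == l), integer(1)),
    min_size = vapply(levels, function(l) min(sz[lv == l]), integer(1)),
    max_size = vapply(levels, function(l) max(sz[lv == l]), integer(1)),
    n_qualifying = vapply(levels, function(l) sum(qual[lv == l]), integer(1)),
    n_motifs = vapply(levels, function(l) sum(motif[lv == l]), integer(1))
  )
  attr(out, "total_communities") <- sum(lv > 0L)
  attr(out, "n_motif_chains") <- sum(motif)
  out
}

#' Community labels of every graph node at one tree level
#'
#' @param tree A `community_tree`.
#' @param level Level index in `1..max_depth`.
#' @return Named character vector: community label per graph node; `NA` for
#'   nodes whose branch terminated above this level.
#' @export
tree_membership <- function(tree, level) {
  stopifnot(inherits(tree, "community_tree"))
  if (level < 1L || level > tree$max_depth) {
    stop(sprintf("level must be in 1..%d", tree$max_depth))
  }
  tree$level_membership[[level]]
}

#' Serialize a community tree
#'
#' JSON output is the nested tree (id, label, level, members, flags,
#' children). TSV output is flat: one row per graph node with its community
#' label at each level (`NA` where the branch ended).
#'
#' @param tree A `community_tree`.
#' @param path Output path.
#' @param format `"json"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(tree, "community_tree"))
  if (format == "json") {
    nest <- function(id) {
      nd <- tree$nodes[[id]]
      list(id = nd$id, label = nd$label, level = nd$level,
           members = nd$members, n_edges = nd$n_edges,
           has_triangle = nd$has_triangle, is_motif = nd$is_motif,
           terminal = nd$terminal,
           children = lapply(nd$children, nest))
    }
    jsonlite::write_json(nest(1L), path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    if (tree$max_depth == 0L) stop("tree has no community levels to serialize")
    tab <- data.frame(node = names(tree$level_membership[[1L]]),
                      stringsAsFactors = FALSE)
    for (l in seq_len(tree$max_depth)) {
      tab[[paste0("level_", l)]] <- unname(tree$level_membership[[l]])
    }
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
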