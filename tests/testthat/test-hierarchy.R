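test_that("two triangles joined by one edge split into the two triangles", {
  g <- two_triangles()
  part <- detect_communities(g)
  expect_equal(part$n_communities, 2)
  mem <- part$membership
  expect_equal(mem[["A"]], mem[["B"]])
  expect_equal(mem[["A"]], mem[["C"]])
  expect_equal(mem[["D"]], mem[["E"]])
  expect_false(mem[["A"]] == mem[["D"]])
})

test_that("K5 stays one community; the Girvan-Newman backend agrees on triangles", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("K", 1:5)
  expect_equal(detect_communities(k5)$n_communities, 1)
  gn <- detect_communities(two_triangles(), method = "girvan_newman")
  expect_equal(gn$n_communities, 2)
})

test_that("multi-restart Louvain escapes the prism's modularity-0 local optimum", {
  g <- triangular_prism()
  part <- detect_communities(g)
  expect_equal(part$modularity, oracle_max_modularity(g), tolerance = 1e-12)
  expect_equal(part$n_communities, 2)
})

test_that("motif qualification is triangle containment", {
  g <- igraph::make_graph(~ A - B, B - C, C - A, C - D, D - E, E - F, F - C,
                          X - Y)
  expect_true(has_motif_qualification(g, c("A", "B", "C")))
  expect_false(has_motif_qualification(g, c("A", "B", "D")))       # path
  expect_false(has_motif_qualification(g, c("C", "D", "E", "F")))  # 4-cycle
  expect_error(has_motif_qualification(g, c("A", "nope")), "absent")
})

test_that("decompose on two triangles gives depth 1 with two terminal motifs", {
  tree <- decompose(two_triangles())
  expect_equal(tree$max_depth, 1)
  motifs <- Filter(function(nd) nd$is_motif, tree$nodes)
  expect_equal(length(motifs), 2)
  expect_true(all(vapply(motifs, `[[`, logical(1), "terminal")))
  ls <- level_summary(tree)
  expect_equal(nrow(ls), 1)
  expect_equal(ls$n_communities, 2)
  expect_equal(ls$n_motifs, 2)
  expect_equal(attr(ls, "n_motif_chains"), 2)
})

test_that("triangle-free networks are never decomposed", {
  g <- igraph::make_graph(~ a - x, a - y, b - x, b - y, c - x, c - y)  # bipartite
  tree <- decompose(g)
  expect_equal(tree$max_depth, 0)
  expect_true(tree$nodes[[1]]$terminal)
  expect_false(tree$nodes[[1]]$has_triangle)
})

test_that("a community that refuses to split is terminal non-motif", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("K", 1:5)
  tree <- decompose(k5)
  expect_equal(tree$max_depth, 0)
  expect_length(tree$nodes, 1)
  expect_false(tree$nodes[[1]]$is_motif)
})

test_that("max_levels below 1 errors; max_levels truncates recursion", {
  expect_error(decompose(two_triangles(), max_levels = 0), "max_levels")
  gen <- make_planted_hierarchy()
  tree1 <- decompose(gen$network, max_levels = 1)
  expect_equal(tree1$max_depth, 1)
})

test_that("tree structure invariants hold on the planted network", {
  gen <- make_planted_hierarchy()
  tree <- decompose(gen$network)
  for (nd in tree$nodes) {
    if (length(nd$children)) {
      kids <- lapply(nd$children, function(i) tree$nodes[[i]]$members)
      # children partition the parent's member set
      expect_setequal(unlist(kids), nd$members)
      expect_equal(sum(lengths(kids)), length(nd$members))
      # levels increase by exactly 1; children never larger than the parent
      for (i in nd$children) {
        expect_equal(tree$nodes[[i]]$level, nd$level + 1)
        expect_lte(length(tree$nodes[[i]]$members), length(nd$members))
      }
      expect_true(nd$has_triangle)
    }
    if (nd$is_motif) {
      expect_equal(length(nd$members), 3)
      expect_equal(nd$n_edges, 3)
      expect_true(nd$terminal)
    }
  }
})

test_that("decompose is reproducible for a fixed seed and differs by seed input", {
  g <- make_planted_hierarchy()$network
  t1 <- decompose(g, seed = 42)
  t2 <- decompose(g, seed = 42)
  expect_identical(t1$level_membership, t2$level_membership)
  expect_identical(vapply(t1$nodes, `[[`, character(1), "label"),
                   vapply(t2$nodes, `[[`, character(1), "label"))
})

test_that("tree serialization writes valid JSON and a flat per-node TSV", {
  tree <- decompose(two_triangles())
  fj <- tempfile(fileext = ".json")
  write_tree(tree, fj, format = "json")
  parsed <- jsonlite::read_json(fj)
  expect_equal(parsed$level, 0)
  expect_length(parsed$children, 2)
  ft <- tempfile(fileext = ".tsv")
  write_tree(tree, ft, format = "tsv")
  tab <- read.delim(ft)
  expect_equal(nrow(tab), 6)
  expect_equal(ncol(tab), 2)  # node + level_1
  expect_equal(length(unique(tab$level_1)), 2)
})

test_that("tree_membership exposes per-level labels and validates the level", {
  tree <- decompose(two_triangles())
  mem <- tree_membership(tree, 1)
  expect_setequal(names(mem), c("A", "B", "C", "D", "E", "F"))
  expect_equal(length(unique(mem)), 2)
  expect_error(tree_membership(tree, 2), "level")
})
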