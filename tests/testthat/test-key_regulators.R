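# Degrees: A 5, B 4, C 4, D 1, E 3, F 3
hub_example_graph <- function() {
  igraph::make_graph(~ A - B, A - C, A - D, A - E, A - F,
                     B - C, B - E, B - F, C - E, C - F)
}

test_that("top_n hub selection is tie-inclusive", {
  hubs <- select_hubs(hub_example_graph(), top_n = 2)
  expect_setequal(hubs$node, c("A", "B", "C"))
  expect_equal(hubs$node[1], "A")
  expect_equal(attr(hubs, "rule"), "top_n")
})

test_that("min_degree hub selection applies the threshold", {
  hubs <- select_hubs(hub_example_graph(), min_degree = 5)
  expect_equal(hubs$node, "A")
  expect_equal(attr(hubs, "rule"), "min_degree")
})

test_that("top_n beyond the network size warns and returns all nodes", {
  expect_warning(hubs <- select_hubs(hub_example_graph(), top_n = 100),
                 "exceeds")
  expect_equal(nrow(hubs), 6)
})

test_that("on two triangles every node is a key regulator with its partners", {
  g <- two_triangles()
  tree <- decompose(g)
  rep <- trace_hubs(tree, select_hubs(g, top_n = 6))
  expect_true(all(rep$is_key_regulator))
  expect_setequal(key_regulators(rep), igraph::V(g)$name)
  a_row <- rep[rep$hub == "A", ]
  expect_setequal(strsplit(a_row$motif_partners, ",")[[1]], c("B", "C"))
})

test_that("triangle-free networks yield zero key regulators", {
  g <- igraph::make_graph(~ a - x, a - y, b - x, b - y, c - x, c - y)
  rep <- trace_hubs(decompose(g), select_hubs(g, top_n = 3))
  expect_length(key_regulators(rep), 0)
})

test_that("tracing a hub absent from the network errors with its name", {
  tree <- decompose(two_triangles())
  fake <- data.frame(node = "GHOST", degree = 99)
  expect_error(trace_hubs(tree, fake), "GHOST")
})

test_that("increasing top_n never removes a key regulator (monotonicity)", {
  gen <- make_planted_hierarchy()
  tree <- decompose(gen$network)
  kr_small <- key_regulators(trace_hubs(tree, select_hubs(gen$network, top_n = 5)))
  kr_large <- key_regulators(trace_hubs(tree, select_hubs(gen$network, top_n = 30)))
  expect_true(all(kr_small %in% kr_large))
})

test_that("key regulators are invariant under node relabeling", {
  gen <- make_planted_hierarchy()
  g <- gen$network
  kr <- key_regulators(trace_hubs(decompose(g), select_hubs(g, top_n = 15)))
  perm <- withr::with_seed(5, sample(igraph::vcount(g)))
  g2 <- igraph::permute(g, perm)
  kr2 <- key_regulators(trace_hubs(decompose(g2), select_hubs(g2, top_n = 15)))
  expect_setequal(kr2, kr)  # names travel with the nodes
})

test_that("hub ordering does not change the key-regulator set", {
  g <- two_triangles()
  tree <- decompose(g)
  hubs <- select_hubs(g, top_n = 6)
  shuffled <- hubs[rev(seq_len(nrow(hubs))), ]
  class(shuffled) <- class(hubs)
  expect_setequal(key_regulators(trace_hubs(tree, hubs)),
                  key_regulators(trace_hubs(tree, shuffled)))
})

test_that("per-level exponent table covers level-1 communities and skips tiny ones", {
  gen <- make_planted_hierarchy()
  tree <- decompose(gen$network)
  tab <- per_level_exponents(tree, gen$network)
  expect_equal(nrow(tab), 4)            # 4 planted level-1 blocks
  expect_true(all(!tab$skipped))
  expect_true(all(is.finite(tab$gamma_p_k)))

  small_tree <- decompose(two_triangles())
  tab2 <- per_level_exponents(small_tree, two_triangles())
  expect_true(all(tab2$skipped))        # 3-node communities: < 3 distinct degrees
  expect_true(all(is.na(tab2$gamma_p_k)))
})

test_that("report serialization round-trips the key-regulator set", {
  g <- two_triangles()
  rep <- trace_hubs(decompose(g), select_hubs(g, top_n = 6))
  fj <- tempfile(fileext = ".json")
  write_report(rep, fj, format = "json")
  parsed <- jsonlite::read_json(fj)
  expect_setequal(unlist(parsed$key_regulators), key_regulators(rep))
  ft <- tempfile(fileext = ".tsv")
  write_report(rep, ft, format = "tsv")
  tab <- read.delim(ft)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$is_key_regulator))
})
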