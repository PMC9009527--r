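test_that("deterministic hierarchical construction has the right base cases", {
  g1 <- make_deterministic_hierarchical(1)$network
  expect_equal(igraph::vcount(g1), 5)
  expect_equal(igraph::ecount(g1), 10)   # K5
  g2 <- make_deterministic_hierarchical(2)$network
  expect_equal(igraph::vcount(g2), 25)
  expect_error(make_deterministic_hierarchical(0), ">= 1")
  expect_error(make_deterministic_hierarchical(6), "<= 5")
})

test_that("the deterministic construction is invariant across runs", {
  a <- make_deterministic_hierarchical(3)$network
  b <- make_deterministic_hierarchical(3)$network
  expect_identical(igraph::as_edgelist(a), igraph::as_edgelist(b))
})

test_that("planted hierarchy records a valid nested ground truth", {
  gen <- make_planted_hierarchy()
  g <- gen$network
  expect_equal(igraph::vcount(g), 72)
  tr <- gen$truth
  expect_length(tr$regulators, 15)
  expect_true(all(tr$regulators %in% igraph::V(g)$name))
  # level-3 triangles nest inside level-2 leaves inside level-1 blocks
  expect_true(all(tapply(tr$level2, tr$level3,
                         function(v) length(unique(v))) == 1))
  expect_true(all(tapply(tr$level1, tr$level2,
                         function(v) length(unique(v))) == 1))
  expect_equal(length(unique(tr$level1)), 4)
  expect_equal(length(unique(tr$level2)), 12)
  expect_equal(length(unique(tr$level3)), 24)
  # every planted triangle is complete
  for (t3 in unique(tr$level3)) {
    members <- names(tr$level3)[tr$level3 == t3]
    sub <- igraph::induced_subgraph(g, members)
    expect_equal(igraph::ecount(sub), 3)
  }
  # regulators are the top-degree nodes
  deg <- igraph::degree(g)
  expect_gt(min(deg[tr$regulators]),
            max(deg[setdiff(names(deg), tr$regulators)]))
})

test_that("planted hierarchy is bit-reproducible and validates parameters", {
  a <- make_planted_hierarchy(seed = 11)
  b <- make_planted_hierarchy(seed = 11)
  expect_identical(igraph::as_edgelist(a$network), igraph::as_edgelist(b$network))
  expect_identical(a$truth, b$truth)
  expect_error(make_planted_hierarchy(p_in_by_level = c(1, 1/3, 0.003),
                                      p_out = 0.003), "exceed p_out")
  expect_error(make_planted_hierarchy(leaf_size = 9), "leaf_size")
  expect_error(make_planted_hierarchy(levels = 4), "levels")
  expect_error(make_planted_hierarchy(n_regulators = 100), "n_regulators")
})

test_that("control generators produce the stated null models", {
  k10 <- make_control("random", n = 10, param = 1, seed = 1)$network
  expect_equal(igraph::ecount(k10), choose(10, 2))
  expect_error(make_control("random", n = 5, param = 0.5), ">= 10")
  expect_error(make_control("random", n = 100, param = 2), "probability")
  expect_error(make_control("preferential_attachment", n = 100, param = 0.5),
               "integer")
  pa <- make_control("preferential_attachment", n = 2000, param = 3,
                     seed = 2)$network
  sp <- degree_spectra(pa)$spectrum
  fit <- fit_power_law(sp$k, sp$P_k)
  expect_lt(fit$slope, 0)
})

test_that("random controls do not pass the power-law classification", {
  er <- make_control("random", n = 1000, param = 0.01, seed = 1)$network
  er <- curate(er)
  sp <- degree_spectra(er)$spectrum
  fits <- list(p_k = fit_power_law(sp$k, sp$P_k),
               c_k = tryCatch(fit_power_law(sp$k, sp$C_k),
                              error = function(e) NULL),
               c_n_k = fit_power_law(sp$k, sp$C_N_k))
  # a Poisson-like peak is not a power law: either the fit fails the
  # R-squared gate or the slope gate
  expect_false(fits$p_k$r_squared >= 0.5 && fits$p_k$slope <= -0.05 &&
               !is.null(fits$c_k) && fits$c_k$r_squared >= 0.5 &&
               fits$c_k$slope <= -0.05)
})

test_that("quant generator defaults mirror the study's shape", {
  qt <- make_quant_table()
  expect_equal(length(unique(qt$table$protein_id)), 434)
  expect_equal(nrow(qt$truth), 65)
  expect_equal(sum(qt$truth$direction == "up"), 49)
  expect_equal(sum(qt$truth$direction == "down"), 16)
  expect_true(all(abs(qt$truth$true_log2_fc) >= log2(1.5)))
  expect_true(all(qt$table$ratio > 0))
  expect_identical(make_quant_table(seed = 3)$table, qt$table)
  expect_error(make_quant_table(n_deregulated = 500), "n_deregulated")
  expect_error(make_quant_table(n_up = 70), "n_up")
})

test_that("noiseless tables give perfect filter recovery", {
  qt <- make_quant_table(n_proteins = 50, n_deregulated = 10, n_up = 6,
                         replicate_sd = 0, seed = 5)
  de <- select_deregulated(qt$table, c("case", "control"))
  expect_setequal(de$protein_id, qt$truth$protein_id)
  dir <- setNames(qt$truth$direction, qt$truth$protein_id)
  expect_identical(de$direction, unname(dir[de$protein_id]))
})

test_that("ground-truth sidecars serialize for both generator families", {
  gen <- make_planted_hierarchy()
  f <- tempfile(fileext = ".json")
  write_truth(gen, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(unlist(parsed$truth$regulators), gen$truth$regulators)
  qt <- make_quant_table(n_proteins = 20, n_deregulated = 5, n_up = 3)
  f2 <- tempfile(fileext = ".json")
  write_truth(qt, f2)
  parsed2 <- jsonlite::read_json(f2)
  expect_equal(length(parsed2$truth), 5)
  expect_error(write_truth(list(), tempfile()), "generated")
})
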