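make_table <- function(case, control, ids = NULL) {
  # case/control: matrices or vectors, one row per protein
  case <- rbind(case); control <- rbind(control)
  if (is.null(ids)) ids <- sprintf("p%02d", seq_len(nrow(case)))
  rbind(
    data.frame(protein_id = rep(ids, ncol(case)), group = "case",
               replicate = rep(seq_len(ncol(case)), each = nrow(case)),
               ratio = as.vector(case)),
    data.frame(protein_id = rep(ids, ncol(control)), group = "control",
               replicate = rep(seq_len(ncol(control)), each = nrow(control)),
               ratio = as.vector(control))
  )
}

test_that("log2 fold change matches the printed thresholds", {
  expect_equal(round(log2_fold_change(1.5), 3), 0.585)
  expect_equal(log2_fold_change(1), 0)
  expect_equal(log2_fold_change(2), 1)
  expect_error(log2_fold_change(0), "positive")
  expect_error(log2_fold_change(-1.5), "positive")
})

test_that("identical groups give p = 1; separated groups give p < 0.001", {
  expect_equal(test_contrast(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  res <- test_contrast(c(10, 10.1, 9.9), c(1, 1.1, 0.9))
  expect_lt(res$p_value, 0.001)
  expect_false(res$flagged)
})

test_that("the t-test agrees with stats::t.test and a permutation oracle", {
  x <- c(3.1, 2.7, 3.5, 2.9)
  y <- c(1.2, 1.5, 1.1)
  for (ve in c(TRUE, FALSE)) {
    ours <- test_contrast(x, y, var_equal = ve)
    ref <- t.test(log2(x), log2(y), var.equal = ve)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
  # permutation oracle: both calls must agree the difference is real
  perm_p <- oracle_permutation_p(x, y)
  expect_lt(test_contrast(x, y)$p_value, 0.05)
  expect_lt(perm_p, 0.05)
})

test_that("single-replicate contrasts are flagged undefined", {
  res <- test_contrast(2, c(1, 1.1))
  expect_true(res$flagged)
  expect_true(is.na(res$p_value))
})

test_that("the deregulation filter applies thresholds and directions", {
  tab <- make_table(case = rbind(c(1.60, 1.62, 1.58),   # up, significant
                                 c(0.60, 0.61, 0.59),   # down, significant
                                 c(1.60, 1.10, 2.30),   # fold yes, p no
                                 c(1.05, 1.00, 0.95)),  # null
                    control = rbind(c(1.00, 1.01, 0.99),
                                    c(1.00, 1.01, 0.99),
                                    c(1.00, 1.01, 0.99),
                                    c(1.00, 1.01, 0.99)))
  de <- select_deregulated(tab, c("case", "control"))
  expect_setequal(de$protein_id, c("p01", "p02"))
  expect_equal(de$direction[de$protein_id == "p01"], "up")
  expect_equal(de$direction[de$protein_id == "p02"], "down")
  expect_equal(attr(de, "n_up"), 1)
  expect_equal(attr(de, "n_down"), 1)
  # fold-change-only mode readmits the noisy-but-large protein
  de_fc <- select_deregulated(tab, c("case", "control"), require_both = FALSE)
  expect_true("p03" %in% de_fc$protein_id)
  expect_error(select_deregulated(tab, c("case", "nope")), "unknown contrast")
})

test_that("tightening either threshold never adds a protein", {
  qt <- make_quant_table(n_proteins = 80, n_deregulated = 20, n_up = 12,
                         seed = 17)
  base <- select_deregulated(qt$table, c("case", "control"))
  tighter_fc <- select_deregulated(qt$table, c("case", "control"),
                                   fc_threshold = 2)
  tighter_p <- select_deregulated(qt$table, c("case", "control"),
                                  p_threshold = 0.01)
  expect_true(all(tighter_fc$protein_id %in% base$protein_id))
  expect_true(all(tighter_p$protein_id %in% base$protein_id))
})

test_that("BH adjustment is reported alongside and only tightens selection", {
  qt <- make_quant_table(n_proteins = 60, n_deregulated = 10, n_up = 5,
                         seed = 21)
  summ <- summarize_contrast(qt$table, c("case", "control"), adjust = "BH")
  expect_true(all(summ$p_adjusted >= summ$p_value - 1e-15))
  raw <- select_deregulated(qt$table, c("case", "control"))
  bh <- select_deregulated(qt$table, c("case", "control"), adjust = "BH")
  expect_true(all(bh$protein_id %in% raw$protein_id))
})

test_that("list intersection reproduces the four-list common-candidate shape", {
  lists <- list(de = c("C9", "A", "B"), net = c("C9", "D"),
                path = c("C9", "E"), lit = c("C9", "F"))
  vn <- intersect_lists(lists)
  expect_equal(vn$common, "C9")
  expect_equal(vn$membership_counts[["C9"]], 4)
  expect_equal(nrow(vn$pairwise), 6)
  expect_length(intersect_lists(list(a = "X", b = "Y"))$common, 0)
  expect_error(intersect_lists(list(a = "X")), "at least 2")
  expect_error(intersect_lists(list(a = "X", b = character())), "empty")
})

test_that("the DEList TSV records protein, fold change, p and direction", {
  qt <- make_quant_table(n_proteins = 40, n_deregulated = 8, n_up = 4,
                         seed = 9)
  de <- select_deregulated(qt$table, c("case", "control"))
  f <- tempfile(fileext = ".tsv")
  write_de_list(de, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), nrow(de))
  expect_true(all(c("protein_id", "log2_fc", "p_value", "direction") %in%
                  names(tab)))
})
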