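#' Log2 fold change of a ratio
#'
#' @param ratio Strictly positive ratio(s).
#' @return `log2(ratio)`. A 1.5-fold change maps to 0.585 (3 d.p.).
#' @export
log2_fold_change <- function(ratio) {
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("ratio must be strictly positive and finite")
  }
  log2(ratio)
}

#' Two-sample t-test on log2-transformed replicate ratios
#'
#' Two-sided two-sample t-test between case and control replicate ratios,
#' computed on the log2 scale (ratios are multiplicative). The default is
#' Student's pooled-variance form, which the source protocol states was
#' used and which holds its nominal size at very small n under the
#' equal-variance null; Welch's unequal-variance form is the config switch
#' `var_equal = FALSE`. With fewer than 2 replicates on either side the
#' p-value is undefined: `NA` with `flagged = TRUE`. If both groups are
#' constant the p-value degenerates to 1 (identical means) or 0 (different
#' means).
#'
#' @param case_reps Positive replicate ratios, case group.
#' @param control_reps Positive replicate ratios, control group.
#' @param var_equal `TRUE` (default) for Student's pooled t, `FALSE` for
#'   Welch.
#' @return List with `p_value`, `statistic`, `df`, `flagged`, `method`.
#' @export
test_contrast <- function(case_reps, control_reps, var_equal = TRUE) {
  if (any(c(case_reps, control_reps) <= 0)) {
    stop("replicate ratios must be strictly positive")
  }
  method <- if (var_equal) "student" else "welch"
  if (length(case_reps) < 2L || length(control_reps) < 2L) {
    return(list(p_value = NA_real_, statistic = NA_real_, df = NA_real_,
                flagged = TRUE, method = method))
  }
  res <- row_t_test(matrix(log2(case_reps), nrow = 1),
                    matrix(log2(control_reps), nrow = 1),
                    var_equal = var_equal)
  list(p_value = res$p[1L], statistic = res$t[1L], df = res$df[1L],
       flagged = FALSE, method = method)
}

# Vectorized row-wise two-sample t-test on matrices of (already
# log-transformed) values: one test per row. Degenerate rows (zero pooled
# variance) get p = 1 when means agree, p = 0 otherwise.
row_t_test <- function(x, y, var_equal = TRUE) {
  n1 <- ncol(x); n2 <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (n1 - 1)
  vy <- rowSums((y - my)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * vx + (n2 - 1) * vy) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(mx))
  } else {
    se2 <- vx / n1 + vy / n2
    se <- sqrt(se2)
    df <- se2^2 / ((vx / n1)^2 / (n1 - 1) + (vy / n2)^2 / (n2 - 1))
  }
  t <- (mx - my) / se
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  degen <- !is.finite(se) | se == 0
  p[degen] <- ifelse(abs(mx - my)[degen] < 1e-12, 1, 0)
  t[degen] <- ifelse(abs(mx - my)[degen] < 1e-12, 0, Inf)
  list(t = t, df = df, p = p)
}

#' Per-protein contrast summary of a long-format quant table
#'
#' @param table Long-format data.frame with columns `protein_id`, `group`,
#'   `replicate`, `ratio` (strictly positive ratio-to-reference values).
#' @param contrast Character vector of length 2: `c(case_group,
#'   control_group)`.
#' @param var_equal Passed to the row-wise t-test (see [test_contrast()]).
#' @param adjust `"none"` (default; the filter operates on raw p per the
#'   protocol) or `"BH"` for Benjamini-Hochberg, reported alongside in
#'   column `p_adjusted`.
#' @return data.frame: protein_id, mean_case, mean_control, fold_change
#'   (mean case ratio / mean control ratio), log2_fc, p_value, p_adjusted,
#'   p_flagged.
#' @export
summarize_contrast <- function(table, contrast, var_equal = TRUE,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  need <- c("protein_id", "group", "replicate", "ratio")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("quant table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (length(contrast) != 2L) stop("contrast must be c(case_group, control_group)")
  unknown <- setdiff(contrast, unique(table$group))
  if (length(unknown)) {
    stop("unknown contrast group(s): ", paste(unknown, collapse = ", "))
  }
  if (any(table$ratio <= 0)) stop("ratios must be strictly positive")

  sub <- table[table$group %in% contrast, , drop = FALSE]
  prot <- sort(unique(sub$protein_id))
  to_matrix <- function(grp) {
    g <- sub[sub$group == grp, , drop = FALSE]
    reps <- sort(unique(g$replicate))
    m <- matrix(NA_real_, nrow = length(prot), ncol = length(reps),
                dimnames = list(prot, reps))
    m[cbind(match(g$protein_id, prot), match(g$replicate, reps))] <- g$ratio
    if (anyNA(m)) stop(sprintf("group '%s' has missing replicate ratios", grp))
    m
  }
  mc <- to_matrix(contrast[1L])
  mk <- to_matrix(contrast[2L])
  mean_case <- rowMeans(mc)
  mean_control <- rowMeans(mk)
  fc <- mean_case / mean_control
  flagged <- ncol(mc) < 2L || ncol(mk) < 2L
  if (flagged) {
    p <- rep(NA_real_, length(prot))
  } else {
    p <- row_t_test(log2(mc), log2(mk), var_equal = var_equal)$p
  }
  out <- data.frame(protein_id = prot, mean_case = unname(mean_case),
                    mean_control = unname(mean_control),
                    fold_change = unname(fc),
                    log2_fc = unname(log2(fc)),
                    p_value = unname(p),
                    p_adjusted = if (adjust == "BH") p.adjust(p, "BH") else unname(p),
                    p_flagged = flagged,
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast
  out
}

#' Select deregulated proteins
#'
#' Applies the deregulation filter: |log2 fold change| >= log2(fc_threshold)
#' AND (when `require_both`) p <= p_threshold. Direction is `up` when
#' log2 FC >= +log2(fc_threshold) and `down` when <= -log2(fc_threshold).
#' With `require_both = FALSE` the p-value filter is dropped (fold-change
#' only mode).
#'
#' @param table Long-format quant table (see [summarize_contrast()]).
#' @param contrast `c(case_group, control_group)`.
#' @param fc_threshold Ratio-scale fold-change threshold (default 1.5).
#' @param p_threshold Raw p-value threshold (default 0.05).
#' @param require_both Require the p filter in addition to the fold filter
#'   (default `TRUE`).
#' @param var_equal,adjust Passed to [summarize_contrast()]. When `adjust =
#'   "BH"` the p filter uses the adjusted values.
#' @return A `de_list`: data.frame of selected proteins (protein_id,
#'   fold_change, log2_fc, p_value, direction) with attributes `contrast`,
#'   `fc_threshold`, `p_threshold`, `require_both`, `n_up`, `n_down`.
#' @export
select_deregulated <- function(table, contrast, fc_threshold = 1.5,
                               p_threshold = 0.05, require_both = TRUE,
                               var_equal = TRUE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(fc_threshold > 0, p_threshold > 0)
  summ <- summarize_contrast(table, contrast, var_equal = var_equal,
                             adjust = adjust)
  lfc_cut <- log2(fc_threshold)
  pass_fc <- abs(summ$log2_fc) >= lfc_cut
  p_used <- if (adjust == "BH") summ$p_adjusted else summ$p_value
  pass_p <- !is.na(p_used) & p_used <= p_threshold
  keep <- if (require_both) pass_fc & pass_p else pass_fc
  sel <- summ[keep, c("protein_id", "fold_change", "log2_fc", "p_value"),
              drop = FALSE]
  sel$direction <- ifelse(sel$log2_fc >= lfc_cut, "up", "down")
  rownames(sel) <- NULL
  attr(sel, "contrast") <- contrast
  attr(sel, "fc_threshold") <- fc_threshold
  attr(sel, "p_threshold") <- if (require_both) p_threshold else NA_real_
  attr(sel, "require_both") <- require_both
  attr(sel, "n_up") <- sum(sel$direction == "up")
  attr(sel, "n_down") <- sum(sel$direction == "down")
  class(sel) <- c("de_list", "data.frame")
  sel
}

#' @export
print.de_list <- function(x, ...) {
  cat(sprintf(
    "deregulated proteins (%s vs %s): %d selected (%d up, %d down) at fold >= %.3g%s\n",
    attr(x, "contrast")[1L], attr(x, "contrast")[2L], nrow(x),
    attr(x, "n_up"), attr(x, "n_down"), attr(x, "fc_threshold"),
    if (attr(x, "require_both")) sprintf(", p <= %.3g", attr(x, "p_threshold"))
    else " (fold-change only)"))
  if (nrow(x)) print(as.data.frame(head(x, 10L)), ...)
  invisible(x)
}

#' Intersect candidate protein lists
#'
#' @param named_lists Named list of at least 2 non-empty character vectors.
#' @return List with `common` (exact intersection across all lists),
#'   `membership_counts` (per element, in how many lists it appears — the
#'   Venn summary), and `pairwise` (data.frame of pairwise overlap sizes).
#' @export
intersect_lists <- function(named_lists) {
  if (!is.list(named_lists) || length(named_lists) < 2L) {
    stop("need at least 2 lists to intersect")
  }
  if (is.null(names(named_lists)) || any(!nzchar(names(named_lists)))) {
    stop("lists must be named")
  }
  empty <- names(named_lists)[lengths(named_lists) == 0L]
  if (length(empty)) stop("empty list(s): ", paste(empty, collapse = ", "))
  sets <- lapply(named_lists, unique)
  common <- Reduce(intersect, sets)
  counts <- table(unlist(sets))
  counts <- sort(counts, decreasing = TRUE)
  pairs <- combn(names(sets), 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(list_a = p[1L], list_b = p[2L],
               overlap = length(intersect(sets[[p[1L]]], sets[[p[2L]]])),
               stringsAsFactors = FALSE)
  }))
  list(common = common,
       membership_counts = setNames(as.integer(counts), names(counts)),
       pairwise = pairwise,
       n_lists = length(sets))
}

#' Write a DEList as TSV
#'
#' @param de A `de_list` from [select_deregulated()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_list <- function(de, path) {
  stopifnot(inherits(de, "de_list"))
  write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
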