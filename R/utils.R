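#' @importFrom stats var pt lm coef complete.cases runif rnorm setNames p.adjust na.omit
#' @importFrom utils combn head write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed
#'
#' Arithmetic derivation of child seeds from a parent seed so that all
#' randomness in the package funnels through a single user-visible seed.
#' Results stay within the 32-bit signed integer range R's RNG accepts.
#'
#' @param seed Parent seed (single integer-like number).
#' @param offset Non-negative integer offset distinguishing the child stream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(offset))
  as.integer(((abs(seed) %% 2147483 * 131) + offset) %% 2147483629 + 1)
}

#' Community-membership agreement (purity)
#'
#' Fraction of nodes whose recovered community's majority ground-truth label
#' matches their own ground-truth label. Equals 1 when every recovered
#' community is a subset of a single planted community.
#'
#' @param recovered Vector of recovered community labels, named by node.
#' @param truth Vector of ground-truth labels, named by node.
#' @return Agreement in `[0, 1]`.
#' @export
membership_agreement <- function(recovered, truth) {
  stopifnot(!is.null(names(recovered)), !is.null(names(truth)))
  common <- intersect(names(recovered), names(truth))
  if (!length(common)) stop("no common nodes between recovered and truth")
  rec <- recovered[common]
  tr <- truth[common]
  agree <- 0L
  for (cl in unique(rec)) {
    members <- which(rec == cl)
    agree <- agree + max(table(tr[members]))
  }
  agree / length(common)
}

stop_if_not_igraph <- function(net, arg = "net") {
  if (!igraph::is_igraph(net)) {
    stop(sprintf("`%s` must be an igraph object (InteractionNetwork)", arg))
  }
  if (is.null(igraph::V(net)$name)) {
    stop(sprintf("`%s` must have named nodes", arg))
  }
  invisible(net)
}

node_names <- function(net) igraph::V(net)$name
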