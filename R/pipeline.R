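#' Assemble a pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Defaults mirror the
#' study: hub rule top_n = 65, fold threshold 1.5, p threshold 0.05,
#' Louvain resolution 1.0. File existence is checked at run time, not here.
#'
#' @param edge_list Path to the network edge list (TSV or SIF).
#' @param quant_table Optional path to a long-format quant table TSV
#'   (protein_id, group, replicate, ratio). `NULL` enables network-only
#'   mode: the DE stages are skipped with a notice.
#' @param lists Optional named list of extra candidate lists to intersect;
#'   each element is a character vector of ids or a path to a one-id-per-line
#'   text file.
#' @param out_dir Output directory (created if missing).
#' @param hub_top_n,hub_min_degree Hub rule (see [select_hubs()]).
#' @param seed,resolution,max_levels,restarts Decomposition parameters
#'   (see [decompose()]).
#' @param contrast `c(case_group, control_group)` for the DE filter.
#' @param fc_threshold,p_threshold,require_both,var_equal DE-filter
#'   parameters (see [select_deregulated()]).
#' @param r2_threshold,slope_threshold Fit thresholds (see
#'   [classify_topology()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(edge_list, quant_table = NULL, lists = NULL,
                            out_dir = "results",
                            hub_top_n = 65L, hub_min_degree = NULL,
                            seed = 42L, resolution = 1, max_levels = 20L,
                            restarts = 10L,
                            contrast = c("case", "control"),
                            fc_threshold = 1.5, p_threshold = 0.05,
                            require_both = TRUE, var_equal = TRUE,
                            r2_threshold = 0.5, slope_threshold = 0.05) {
  stopifnot(is.character(edge_list), length(edge_list) == 1L)
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    stop("seed must be a single integer")
  }
  pos <- c(resolution = resolution, fc_threshold = fc_threshold,
           p_threshold = p_threshold, r2_threshold = r2_threshold,
           slope_threshold = slope_threshold)
  bad <- names(pos)[pos <= 0]
  if (length(bad)) stop("thresholds must be positive: ", paste(bad, collapse = ", "))
  structure(list(edge_list = edge_list, quant_table = quant_table,
                 lists = lists, out_dir = out_dir,
                 hub_top_n = hub_top_n, hub_min_degree = hub_min_degree,
                 seed = as.integer(seed), resolution = resolution,
                 max_levels = max_levels, restarts = restarts,
                 contrast = contrast, fc_threshold = fc_threshold,
                 p_threshold = p_threshold, require_both = require_both,
                 var_equal = var_equal, r2_threshold = r2_threshold,
                 slope_threshold = slope_threshold),
            class = "pipeline_config")
}

#' Run the full key-regulator discovery pipeline
#'
#' Executes curate, topology characterization, recursive decomposition,
#' hub tracing, the deregulation filter (per contrast, skipped with a
#' notice when no quant table is configured), and list intersection.
#' Writes every stage output plus a run log recording versions, seeds and
#' every parameter actually used, and a summary JSON naming the common
#' candidate(s). Reruns with an identical config are byte-identical. A
#' stage failure aborts with the stage name and cause; outputs of earlier
#' stages are retained.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the summary and the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  paths <- character()
  log_lines <- c(sprintf("hubtrace %s | R %s.%s | igraph %s",
                         as.character(utils::packageVersion("hubtrace")),
                         R.version$major, R.version$minor,
                         as.character(utils::packageVersion("igraph"))),
                 "parameters:",
                 vapply(setdiff(names(config), c("lists")), function(k) {
                   sprintf("  %s = %s", k,
                           paste(format(config[[k]]), collapse = " "))
                 }, character(1)))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  out <- function(name) {
    p <- file.path(config$out_dir, name)
    paths <<- c(paths, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  net <- stage("curate", {
    if (!file.exists(config$edge_list)) {
      stop(sprintf("edge list not found: %s", config$edge_list))
    }
    g <- curate(read_edge_list(config$edge_list))
    write_network(g, out("network_curated.tsv"))
    note("curate: %d nodes, %d edges (%d loops, %d isolated removed)",
         igraph::vcount(g), igraph::ecount(g),
         attr(g, "n_loops_removed"), attr(g, "n_isolated_removed"))
    g
  })

  topo <- stage("topology", {
    spectra <- degree_spectra(net)
    write.table(spectra$spectrum, out("degree_spectrum.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cen <- suppressWarnings(centrality_table(net))
    write.table(cen$table, out("centrality.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sp <- spectra$spectrum
    fit_or_null <- function(ys) {
      tryCatch(fit_power_law(sp$k, ys), error = function(e) NULL)
    }
    fits <- list(p_k = fit_or_null(sp$P_k), c_k = fit_or_null(sp$C_k),
                 c_n_k = fit_or_null(sp$C_N_k))
    cls <- if (any(vapply(fits, is.null, logical(1)))) {
      note("topology: too few degree classes for power-law fits; unclassified")
      list(label = "unclassified", assortativity = "unknown")
    } else {
      classify_topology(fits, config$r2_threshold, config$slope_threshold)
    }
    jsonlite::write_json(
      list(classification = cls,
           fits = lapply(fits, function(f) if (is.null(f)) NULL else
             f[c("slope", "exponent", "r_squared", "n_points")])),
      out("topology.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
    note("topology: %s (%s)", cls$label, cls$assortativity)
    list(spectra = spectra, fits = fits, classification = cls)
  })

  tree <- stage("decompose", {
    tr <- decompose(net, seed = config$seed, resolution = config$resolution,
                    max_levels = config$max_levels,
                    restarts = config$restarts)
    write_tree(tr, out("community_tree.json"), format = "json")
    if (tr$max_depth > 0L) {
      write_tree(tr, out("community_tree.tsv"), format = "tsv")
    }
    ls <- level_summary(tr)
    write.table(ls, out("level_summary.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("decompose: depth %d, %d communities, %d motif chains",
         tr$max_depth, attr(ls, "total_communities"),
         attr(ls, "n_motif_chains"))
    tr
  })

  report <- stage("regulators", {
    hubs <- if (!is.null(config$hub_min_degree)) {
      select_hubs(net, min_degree = config$hub_min_degree)
    } else {
      select_hubs(net, top_n = config$hub_top_n)
    }
    rep <- trace_hubs(tree, hubs)
    write_report(rep, out("key_regulators.tsv"), format = "tsv")
    write_report(rep, out("key_regulators.json"), format = "json")
    note("regulators: %d hubs (%s = %s), %d key regulators",
         nrow(rep), attr(hubs, "rule"), format(attr(hubs, "value")),
         length(key_regulators(rep)))
    rep
  })

  de <- NULL
  if (is.null(config$quant_table)) {
    note("filter: no quant table configured; DE stages skipped (network-only mode)")
  } else {
    de <- stage("filter", {
      if (!file.exists(config$quant_table)) {
        stop(sprintf("quant table not found: %s", config$quant_table))
      }
      tab <- utils::read.delim(config$quant_table, stringsAsFactors = FALSE)
      d <- select_deregulated(tab, config$contrast,
                              fc_threshold = config$fc_threshold,
                              p_threshold = config$p_threshold,
                              require_both = config$require_both,
                              var_equal = config$var_equal)
      write_de_list(d, out("deregulated.tsv"))
      note("filter: %d deregulated (%d up, %d down)", nrow(d),
           attr(d, "n_up"), attr(d, "n_down"))
      d
    })
  }

  venn <- stage("intersect", {
    lists <- list(key_regulators = key_regulators(report))
    if (!is.null(de)) lists$deregulated <- de$protein_id
    for (nm in names(config$lists)) {
      v <- config$lists[[nm]]
      if (is.character(v) && length(v) == 1L && file.exists(v)) {
        v <- readLines(v, warn = FALSE)
        v <- v[nzchar(trimws(v))]
      }
      lists[[nm]] <- v
    }
    lists <- Filter(length, lists)
    if (length(lists) < 2L) {
      note("intersect: fewer than 2 non-empty lists; skipped")
      NULL
    } else {
      vn <- intersect_lists(lists)
      jsonlite::write_json(
        list(lists = lapply(lists, as.list), common = as.list(vn$common),
             membership_counts = as.list(vn$membership_counts),
             pairwise = vn$pairwise),
        out("venn.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
      note("intersect: %d lists, %d common candidate(s)%s", vn$n_lists,
           length(vn$common),
           if (length(vn$common)) paste0(": ", paste(vn$common, collapse = ", "))
           else "")
      vn
    }
  })

  summary <- list(
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    topology = topo$classification$label,
    assortativity = topo$classification$assortativity,
    tree_depth = tree$max_depth,
    n_hubs = nrow(report),
    key_regulators = as.list(key_regulators(report)),
    n_deregulated = if (is.null(de)) NULL else nrow(de),
    common_candidates = if (is.null(venn)) list() else as.list(venn$common),
    seed = config$seed
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(log_lines, out("run_log.txt"))
  invisible(list(summary = summary, paths = paths, log = log_lines))
}
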