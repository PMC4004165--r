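#' Power-law fit of a degree distribution
#'
#' Computes the empirical degree distribution `P(k)` on the undirected
#' projection and fits `log10 P(k) ~ log10 k` by least squares over the
#' occupied degree bins, following the classic scale-free analysis of
#' metabolic networks. For a knowledge base the degree of a molecule is the
#' number of reactions it participates in (the molecule-reaction bipartite
#' degree); for a causality graph it is the undirected degree after
#' collapsing parallel edges.
#'
#' @param x A `reg_kb` or `causality_graph`.
#' @return A list with `gamma` (= minus the slope), `r` (absolute Pearson
#'   correlation of the log-log fit, on a 0-100 scale) and `n_bins`;
#'   `gamma` and `r` are `NA` with `available = FALSE` when fewer than three
#'   distinct nonzero degrees exist.
#' @export
degree_power_law_fit <- function(x) {
  deg <- node_degrees(x)
  deg <- deg[deg > 0]
  tab <- table(deg)
  k <- as.numeric(names(tab))
  if (length(k) < 3) {
    return(list(gamma = NA_real_, r = NA_real_, n_bins = length(k),
                available = FALSE))
  }
  pk <- as.numeric(tab) / sum(tab)
  fit <- lm(log10(pk) ~ log10(k))
  list(gamma = -unname(coef(fit)[2]),
       r = 100 * abs(cor(log10(k), log10(pk))),
       n_bins = length(k), available = TRUE)
}

node_degrees <- function(x) {
  if (inherits(x, "reg_kb")) {
    counts <- table(x$index$molecule)
    setNames(as.integer(counts), names(counts))
  } else if (inherits(x, "causality_graph")) {
    igraph::degree(as_undirected_igraph(x))
  } else {
    abort("expected a reg_kb or causality_graph")
  }
}

as_undirected_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("src", "dst")],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes$node)
  )
  igraph::simplify(g)
}

#' Characteristic path length and diameter
#'
#' On the undirected projection of the largest connected component, `L` is
#' the mean shortest-path length over connected ordered pairs and `D` the
#' maximum. When the component exceeds `sample` nodes, `L` is estimated and
#' `D` lower-bounded from breadth-first searches out of a seeded random
#' sample of sources, and the result is flagged as an estimate. Trivial
#' graphs (largest component of one node) report the metrics as unavailable.
#'
#' @param graph A `causality_graph` or `reg_kb` (for a knowledge base the
#'   molecule-reaction bipartite graph is used).
#' @param sample Maximum number of BFS sources before switching to
#'   estimation (`NULL` = always exact).
#' @param seed Seed for the source sample.
#' @return A list with `L`, `D`, `estimate`, `component_coverage` (fraction
#'   of nodes in the largest component) and `available`.
#' @export
path_metrics <- function(graph, sample = NULL, seed = 1) {
  g <- if (inherits(graph, "reg_kb")) {
    igraph::graph_from_data_frame(
      data.frame(from = graph$index$molecule,
                 to = paste0("R:", graph$index$reaction)),
      directed = FALSE
    )
  } else {
    as_undirected_igraph(graph)
  }
  nv <- igraph::vcount(g)
  if (nv == 0) {
    return(list(L = NA_real_, D = NA_real_, estimate = FALSE,
                component_coverage = NA_real_, available = FALSE))
  }
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  coverage <- length(keep) / nv
  if (length(keep) < 2) {
    return(list(L = NA_real_, D = NA_real_, estimate = FALSE,
                component_coverage = coverage, available = FALSE))
  }
  sub <- igraph::induced_subgraph(g, keep)
  ns <- igraph::vcount(sub)
  estimate <- !is.null(sample) && sample < ns
  sources <- if (estimate) {
    withr::with_seed(seed, sample.int(ns, sample))
  } else {
    seq_len(ns)
  }
  d <- igraph::distances(sub, v = sources, mode = "all",
                         algorithm = "unweighted")
  # mean over ordered connected pairs, excluding self-distances
  self <- cbind(seq_along(sources), sources)
  d[self] <- NA
  list(L = mean(d, na.rm = TRUE), D = max(d, na.rm = TRUE),
       estimate = estimate, component_coverage = coverage, available = TRUE)
}

#' One-row topology report
#'
#' Bundles node/edge counts, the power-law exponent `gamma` with its fit
#' quality `r`, the characteristic path length `L`, the diameter `D` and the
#' largest-component coverage into a tibble row, for either a regulated
#' reaction network (`reg_kb`) or a compiled causality graph.
#'
#' @inheritParams path_metrics
#' @return A one-row tibble of class `topology_report`.
#' @export
topology_report <- function(graph, sample = NULL, seed = 1) {
  fit <- degree_power_law_fit(graph)
  pm <- path_metrics(graph, sample = sample, seed = seed)
  counts <- if (inherits(graph, "reg_kb")) {
    c(n_nodes = nrow(graph$molecules) + nrow(graph$reactions),
      n_edges = nrow(graph$index))
  } else {
    c(n_nodes = nrow(graph$nodes), n_edges = nrow(graph$edges))
  }
  out <- tibble(
    network = if (inherits(graph, "reg_kb")) "regulated_reactions" else "causality_graph",
    n_nodes = as.integer(counts[["n_nodes"]]),
    n_edges = as.integer(counts[["n_edges"]]),
    gamma = fit$gamma, r = fit$r,
    L = pm$L, D = pm$D,
    path_estimate = pm$estimate,
    component_coverage = pm$component_coverage
  )
  class(out) <- c("topology_report", class(out))
  out
}
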