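#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a knowledge base into long role format
#'
#' @param x A `reg_kb`.
#' @param ... Unused.
#' @return A tibble (`reaction`, `role`, `molecule`), one row per molecule
#'   occurrence.
#' @export
#' @method tidy reg_kb
tidy.reg_kb <- function(x, ...) {
  purrr::map_dfr(
    c("substrates", "products", "activators", "inhibitors", "modulators"),
    function(col) {
      reaction <- rep(x$reactions$id, lengths(x$reactions[[col]]))
      molecule <- unlist(x$reactions[[col]], use.names = FALSE)
      tibble(reaction = reaction, role = sub("s$", "", col),
             molecule = molecule)
    }
  ) %>% arrange(.data$reaction, .data$role, .data$molecule)
}

#' One-row summary of a knowledge base
#'
#' @param x A `reg_kb`.
#' @param ... Unused.
#' @return A one-row tibble of census counts (molecules by kind, reactions
#'   by reversibility, regulator role totals).
#' @export
#' @method glance reg_kb
glance.reg_kb <- function(x, ...) {
  tibble(
    n_molecules = nrow(x$molecules),
    n_genes = sum(x$molecules$kind == "gene"),
    n_metabolites = sum(x$molecules$kind == "metabolite"),
    n_proteins = sum(x$molecules$kind == "protein"),
    n_reactions = nrow(x$reactions),
    n_reversible = sum(x$reactions$reversible),
    n_activator_roles = sum(lengths(x$reactions$activators)),
    n_inhibitor_roles = sum(lengths(x$reactions$inhibitors)),
    n_modulator_roles = sum(lengths(x$reactions$modulators))
  )
}

#' Tidy a causality graph into its edge list
#'
#' @param x A `causality_graph`.
#' @param ... Unused.
#' @return The edges tibble (`src`, `dst`, `sign`, `provenance`).
#' @export
#' @method tidy causality_graph
tidy.causality_graph <- function(x, ...) x$edges

#' One-row summary of a causality graph
#'
#' Node counts by kind and edge counts by sign, the census reported for
#' compiled causality graphs.
#'
#' @param x A `causality_graph`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
#' @method glance causality_graph
glance.causality_graph <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_quantity = sum(x$nodes$kind == "quantity"),
    n_availability = sum(x$nodes$kind == "availability"),
    n_speed = sum(x$nodes$kind == "speed"),
    n_edges = nrow(x$edges),
    n_positive = sum(x$edges$sign == "+"),
    n_negative = sum(x$edges$sign == "-"),
    n_unknown = sum(x$edges$sign == "?")
  )
}

#' Tidy an influence closure into labelled node pairs
#'
#' @param x An `influence_closure`.
#' @param ... Unused.
#' @return A tibble (`src`, `dst`, `positive`, `negative`, `unknown`)
#'   restricted to non-reflexive pairs with at least one label.
#' @export
#' @method tidy influence_closure
tidy.influence_closure <- function(x, ...) {
  any_lab <- x$P | x$N | x$U
  idx <- which(any_lab, arr.ind = TRUE)
  out <- tibble(
    src = x$sources[idx[, 1]],
    dst = x$nodes[idx[, 2]],
    positive = x$P[idx],
    negative = x$N[idx],
    unknown = x$U[idx]
  )
  out %>% filter(.data$src != .data$dst) %>% arrange(.data$src, .data$dst)
}

#' Tidy / summarise a benchmark result
#'
#' `tidy()` returns the per-case hit probabilities; `glance()` the one-row
#' summary with the headline success rates.
#'
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @export
#' @method tidy benchmark_result
tidy.benchmark_result <- function(x, ...) x$cases

#' @rdname tidy.benchmark_result
#' @export
#' @method glance benchmark_result
glance.benchmark_result <- function(x, ...) {
  agg <- x$aggregate
  pick <- function(k, v, t) {
    row <- agg[agg$key == k & agg$view == v & agg$top_n == t, ]
    if (nrow(row) == 0) NA_real_ else row$success_pct
  }
  t10 <- if (10 %in% agg$top_n) 10 else min(agg$top_n)
  tibble(
    n_cases = length(unique(x$cases$case)),
    n_dropped = x$n_dropped,
    shuffled = x$params$shuffled,
    success_specificity_molecule_top10 = pick("specificity", "molecule", t10),
    success_coverage_molecule_top10 = pick("coverage", "molecule", t10),
    success_specificity_gene_top10 = pick("specificity", "gene", t10)
  )
}
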