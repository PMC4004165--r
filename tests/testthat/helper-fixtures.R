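# Fixtures built in code: the two-reaction worked example, random knowledge
# bases and random signed graphs used by the property tests.

# Effect a -> g plus the enzyme-activated reaction {b, c} -> {d}.
toy_figure_kb <- function() {
  kb(
    molecules = tibble::tibble(
      id = c("a", "b", "c", "d", "e", "g"),
      kind = c("gene", "metabolite", "metabolite", "metabolite", "protein", "gene")
    ),
    reactions = dplyr::bind_rows(
      effect_to_reaction("a", "g", "+"),
      tibble::tibble(
        id = "r2", substrates = list(c("b", "c")), products = list("d"),
        activators = list("e"), inhibitors = list(character()),
        modulators = list(character()), reversible = FALSE
      )
    )
  )
}

# Chain of four single-substrate reactions t -> x -> y -> z -> w.
chain_kb <- function() {
  mols <- c("t", "x", "y", "z", "w")
  kb(
    molecules = tibble::tibble(id = mols, kind = "metabolite"),
    reactions = tibble::tibble(
      id = c("R1", "R2", "R3", "R4"),
      substrates = list("t", "x", "y", "z"),
      products = list("x", "y", "z", "w"),
      activators = list(character(), character(), character(), character()),
      inhibitors = list(character(), character(), character(), character()),
      modulators = list(character(), character(), character(), character()),
      reversible = FALSE
    )
  )
}

# Random small knowledge base exercising every role and both the regulated
# and unregulated compilation rules.
random_kb <- function(seed, n_mol = 12, n_rxn = 8) {
  withr::with_seed(seed, {
    mols <- sprintf("m%02d", seq_len(n_mol))
    kinds <- sample(c("gene", "metabolite", "protein", "complex", "other"),
                    n_mol, replace = TRUE)
    rxn <- purrr::map_dfr(seq_len(n_rxn), function(i) {
      ns <- sample(0:3, 1)
      subs <- if (ns > 0) sample(mols, ns) else character()
      prods <- sample(setdiff(mols, subs), sample(1:2, 1))
      free <- setdiff(mols, c(subs, prods))
      regs <- if (length(free) > 0) {
        sample(free, min(length(free), sample(0:3, 1)))
      } else {
        character()
      }
      role <- if (length(regs) > 0) {
        sample(c("act", "inh", "mod"), length(regs), replace = TRUE)
      } else {
        character()
      }
      tibble::tibble(
        id = sprintf("r%02d", i),
        substrates = list(subs), products = list(prods),
        activators = list(regs[role == "act"]),
        inhibitors = list(regs[role == "inh"]),
        modulators = list(regs[role == "mod"]),
        reversible = sample(c(TRUE, FALSE), 1)
      )
    })
    kb(tibble::tibble(id = mols, kind = kinds), rxn)
  })
}

# Random signed directed graph as a bare causality_graph (node kinds are
# irrelevant to sign propagation).
random_signed_graph <- function(seed, n_nodes = NULL, n_edges = NULL,
                                p_unknown = 0.15) {
  withr::with_seed(seed, {
    nv <- n_nodes %||% sample(2:12, 1)
    ne <- n_edges %||% sample(1:24, 1)
    nodes <- sprintf("n%02d", seq_len(nv))
    signs <- sample(c("+", "-", "?"), ne, replace = TRUE,
                    prob = c((1 - p_unknown) * 0.6, (1 - p_unknown) * 0.4,
                             p_unknown))
    edges <- tibble::tibble(
      src = sample(nodes, ne, replace = TRUE),
      dst = sample(nodes, ne, replace = TRUE),
      sign = signs,
      provenance = sprintf("e%02d", seq_len(ne))
    )
    structure(
      list(nodes = tibble::tibble(node = nodes, kind = "quantity", ref = nodes),
           edges = edges, universe = character()),
      class = "causality_graph"
    )
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Bare signed graph from an edge table, for closure and path-metric tests.
mk_graph <- function(edges_df, nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(edges_df$src, edges_df$dst)))
  structure(
    list(nodes = tibble::tibble(node = nodes, kind = "quantity", ref = nodes),
         edges = tibble::tibble(src = edges_df$src, dst = edges_df$dst,
                                sign = edges_df$sign, provenance = "t"),
         universe = character()),
    class = "causality_graph"
  )
}

# Independent oracle for neighborhood extraction: plain breadth-first
# search over the molecule-reaction bipartite graph, re-deriving at which
# level each reaction is first selectable.
bfs_neighborhood_oracle <- function(kb, seeds, levels, hubs) {
  members <- function(r) {
    i <- which(kb$reactions$id == r)
    unique(unlist(kb$reactions[i, c("substrates", "products", "activators",
                                    "inhibitors", "modulators")]))
  }
  frontier <- setdiff(intersect(seeds, kb$molecules$id), hubs)
  seen_mol <- frontier
  selected <- character()
  for (l in seq_len(levels)) {
    if (length(frontier) == 0) break
    sel <- kb$reactions$id[
      vapply(kb$reactions$id,
             function(r) length(intersect(members(r), frontier)) > 0,
             logical(1))
    ]
    selected <- union(selected, sel)
    mols <- unique(unlist(lapply(selected, members)))
    frontier <- setdiff(setdiff(mols, hubs), seen_mol)
    seen_mol <- union(seen_mol, frontier)
  }
  sort(selected)
}

# Exhaustive hypergeometric upper tail by direct summation of the density.
hyper_tail_oracle <- function(N, K, n, k) {
  if (k == 0) return(1)
  i <- seq(k, min(n, K))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Small synthetic configuration keeping unit tests fast.
small_config <- function(seed, ...) {
  synthesis_config(
    n_genes = 120, n_metabolites = 60, n_enzymes = 12, n_tfs = 6,
    n_reactions = 60, n_effects = 20, n_decoy_tfs = 8,
    targets_per_tf = c(5, 8), seed = seed, ...
  )
}
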