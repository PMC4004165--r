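#' @rdname build_causality_graph
#' @export
quantity_node <- function(molecule_id) paste0("Q:", molecule_id, recycle0 = TRUE)

#' @rdname build_causality_graph
#' @export
availability_node <- function(molecule_id) paste0("A:", molecule_id, recycle0 = TRUE)

#' @rdname build_causality_graph
#' @export
speed_node <- function(reaction_id) paste0("V:", reaction_id, recycle0 = TRUE)

#' Signed edges emitted by one regulated reaction
#'
#' Implements the compilation rules for a single reaction `R` with substrate
#' set `S`, activators `A`, inhibitors `I`, modulators `Mo` and products `P`:
#'
#' * `availability(M) -(+)-> v(R)` for every substrate `M`: the speed is an
#'   increasing function of substrate availability;
#' * `quantity(M) -> v(R)` with sign `+`/`-`/`?` for every activator /
#'   inhibitor / modulator;
#' * `v(R) -(+)-> quantity(P)` for every product, and
#'   `v(R) -(+)-> availability(P)` when `P` has an availability node (i.e.,
#'   `P` is a substrate somewhere in the compiled knowledge base);
#' * mass consumption: when `R` is explicitly regulated (at least one
#'   regulator), `v(R) -(-)-> quantity(M)` for every substrate; otherwise the
#'   speed is limited by substrate availability and a negative edge
#'   `availability(M1) -(-)-> quantity(M2)` is emitted for every ordered pair
#'   of distinct substrates.
#'
#' All reactions are compiled forward-only: the `reversible` flag does not
#' change the emitted edges. The number of emitted edges is exactly
#' `s + a + i + m + p + p' + (s if regulated else s*(s-1))` where `p'` counts
#' products with an availability node.
#'
#' @param reaction A one-row slice of a `reg_kb` reactions tibble (or a list
#'   with the same fields).
#' @param availability_universe Molecule ids that are substrates anywhere in
#'   the compiled knowledge base.
#' @return A tibble of edges (`src`, `dst`, `sign`, `provenance`).
#' @export
emit_reaction_edges <- function(reaction, availability_universe) {
  r <- as.list(reaction)
  for (col in c("substrates", "products", "activators", "inhibitors", "modulators")) {
    r[[col]] <- as.character(unlist(r[[col]], use.names = FALSE))
  }
  rid <- as.character(r$id)
  v <- speed_node(rid)
  s <- r$substrates
  regulated <- length(r$activators) + length(r$inhibitors) + length(r$modulators) > 0
  p_avail <- intersect(r$products, availability_universe)
  src <- c(availability_node(s),
           quantity_node(r$activators),
           quantity_node(r$inhibitors),
           quantity_node(r$modulators),
           rep(v, length(r$products)),
           rep(v, length(p_avail)))
  dst <- c(rep(v, length(s) + length(r$activators) + length(r$inhibitors) +
                 length(r$modulators)),
           quantity_node(r$products),
           availability_node(p_avail))
  sign <- c(rep("+", length(s)),
            rep("+", length(r$activators)),
            rep("-", length(r$inhibitors)),
            rep("?", length(r$modulators)),
            rep("+", length(r$products) + length(p_avail)))
  if (regulated) {
    src <- c(src, rep(v, length(s)))
    dst <- c(dst, quantity_node(s))
    sign <- c(sign, rep("-", length(s)))
  } else if (length(s) > 1) {
    pairs <- expand.grid(m1 = s, m2 = s, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$m1 != pairs$m2, ]
    src <- c(src, availability_node(pairs$m1))
    dst <- c(dst, quantity_node(pairs$m2))
    sign <- c(sign, rep("-", nrow(pairs)))
  }
  tibble(src = src, dst = dst, sign = sign, provenance = rid)
}

# Vectorised emission of the edge rules over a whole reactions table;
# produces exactly the union of emit_reaction_edges() over the rows.
emit_all_edges <- function(rxn, universe) {
  role_edges <- function(col, node_fun, sign, dst_is_v = TRUE) {
    mols <- unlist(rxn[[col]], use.names = FALSE)
    ids <- rep(rxn$id, lengths(rxn[[col]]))
    if (length(mols) == 0) {
      return(tibble(src = character(), dst = character(),
                    sign = character(), provenance = character()))
    }
    if (dst_is_v) {
      tibble(src = node_fun(mols), dst = speed_node(ids), sign = sign,
             provenance = ids)
    } else {
      tibble(src = speed_node(ids), dst = node_fun(mols), sign = sign,
             provenance = ids)
    }
  }
  prod_all <- unlist(rxn$products, use.names = FALSE)
  prod_ids <- rep(rxn$id, lengths(rxn$products))
  in_univ <- prod_all %in% universe
  regulated <- lengths(rxn$activators) + lengths(rxn$inhibitors) +
    lengths(rxn$modulators) > 0
  reg_sub <- rxn[regulated, ]
  couples <- rxn[!regulated & lengths(rxn$substrates) > 1, ]
  couple_edges <- if (nrow(couples) == 0) {
    tibble(src = character(), dst = character(), sign = character(),
           provenance = character())
  } else {
    purrr::map_dfr(seq_len(nrow(couples)), function(k) {
      s <- couples$substrates[[k]]
      pairs <- expand.grid(m1 = s, m2 = s, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$m1 != pairs$m2, ]
      tibble(src = availability_node(pairs$m1),
             dst = quantity_node(pairs$m2),
             sign = rep("-", nrow(pairs)), provenance = couples$id[[k]])
    })
  }
  bind_rows(
    role_edges("substrates", availability_node, "+"),
    role_edges("activators", quantity_node, "+"),
    role_edges("inhibitors", quantity_node, "-"),
    role_edges("modulators", quantity_node, "?"),
    tibble(src = speed_node(prod_ids), dst = quantity_node(prod_all),
           sign = rep("+", length(prod_all)), provenance = prod_ids),
    tibble(src = speed_node(prod_ids[in_univ]),
           dst = availability_node(prod_all[in_univ]),
           sign = rep("+", sum(in_univ)), provenance = prod_ids[in_univ]),
    {
      sub_all <- unlist(reg_sub$substrates, use.names = FALSE)
      sub_ids <- rep(reg_sub$id, lengths(reg_sub$substrates))
      tibble(src = speed_node(sub_ids), dst = quantity_node(sub_all),
             sign = rep("-", length(sub_all)), provenance = sub_ids)
    },
    couple_edges
  )
}

#' Compile a knowledge base into a signed causality graph
#'
#' The causality graph describes how variations propagate: one `quantity`
#' node per molecule (its amount), one `availability` node per molecule that
#' is a substrate of at least one reaction (the summed speed of the reactions
#' producing it), and one `speed` node per reaction. Edges carry a sign
#' (`+`, `-`, `?`) and the id of the reaction that produced them; see
#' [emit_reaction_edges()] for the rules.
#'
#' `quantity_node()`, `availability_node()` and `speed_node()` map molecule /
#' reaction ids to the node id strings used in the graph.
#'
#' @param x A `reg_kb` object, typically an [extract_neighborhood()] output.
#' @return An object of class `causality_graph`: a list with tibbles `nodes`
#'   (`node`, `kind`, `ref`) and `edges` (`src`, `dst`, `sign`,
#'   `provenance`), plus the availability `universe`.
#' @examples
#' toy <- kb(
#'   molecules = tibble::tibble(
#'     id = c("a", "b", "c", "d", "e", "g"),
#'     kind = c("gene", "metabolite", "metabolite", "metabolite", "protein", "gene")
#'   ),
#'   reactions = dplyr::bind_rows(
#'     effect_to_reaction("a", "g", "+"),
#'     tibble::tibble(
#'       id = "r2", substrates = list(c("b", "c")), products = list("d"),
#'       activators = list("e"), inhibitors = list(character()),
#'       modulators = list(character()), reversible = FALSE
#'     )
#'   )
#' )
#' g <- build_causality_graph(toy)
#' glance(g)
#' @export
build_causality_graph <- function(x) {
  stopifnot(inherits(x, "reg_kb"))
  universe <- roleset(unlist(x$reactions$substrates, use.names = FALSE))
  nodes <- bind_rows(
    tibble(node = quantity_node(x$molecules$id), kind = "quantity",
           ref = x$molecules$id),
    tibble(node = availability_node(universe), kind = "availability",
           ref = universe),
    tibble(node = speed_node(x$reactions$id), kind = "speed",
           ref = x$reactions$id)
  ) %>% arrange(.data$node)
  edges <- if (nrow(x$reactions) == 0) {
    tibble(src = character(), dst = character(), sign = character(),
           provenance = character())
  } else {
    emit_all_edges(x$reactions, universe) %>%
      distinct() %>%
      arrange(.data$src, .data$dst, .data$sign, .data$provenance)
  }
  structure(list(nodes = nodes, edges = edges, universe = universe),
            class = "causality_graph")
}

#' @export
print.causality_graph <- function(x, ...) {
  cat(sprintf("<causality_graph> %d nodes (%d quantity, %d availability, %d speed), %d edges (%d +, %d -, %d ?)\n",
              nrow(x$nodes),
              sum(x$nodes$kind == "quantity"),
              sum(x$nodes$kind == "availability"),
              sum(x$nodes$kind == "speed"),
              nrow(x$edges),
              sum(x$edges$sign == "+"),
              sum(x$edges$sign == "-"),
              sum(x$edges$sign == "?")))
  invisible(x)
}

#' Export a causality graph as a signed edge list
#'
#' Writes a SIF-like TSV (`src`, `sign`, `dst`) for external viewers,
#' deterministically ordered.
#'
#' @param graph A `causality_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(graph, path) {
  stopifnot(inherits(graph, "causality_graph"))
  edges <- graph$edges %>%
    select("src", "sign", "dst") %>%
    distinct() %>%
    arrange(.data$src, .data$dst, .data$sign)
  readr::write_tsv(edges, path)
  invisible(path)
}
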