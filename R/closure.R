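#' Signed reachability closure of a causality graph
#'
#' For every ordered pair of nodes, computes which path-sign labels are
#' achievable by a walk of length >= 1: `+` when a walk with an even number
#' of negative edges and no unknown edge exists, `-` for an odd number of
#' negatives and no unknown edge, and `?` when some walk traverses at least
#' one unknown-sign edge (unknown is absorbing). Influence is computed over
#' walks, not simple paths: with cycles, parity reachability over walks is
#' well defined and polynomial, whereas sign existence over simple paths is
#' NP-hard. A two-cycle `x -(+)-> y`, `y -(-)-> x` therefore yields both
#' labels for the pair `(x, y)`.
#'
#' Internally the graph is lifted to a product graph over states
#' (node, even / odd / unknown) and breadth-first reachability is computed
#' from each requested source, so the cost is O(|sources| * (|V| + |E|)).
#'
#' @param graph A `causality_graph`.
#' @param sources Optional character vector of node ids to restrict the
#'   closure rows to (default: all nodes).
#' @return An object of class `influence_closure`: logical matrices `P`,
#'   `N`, `U` (rows = sources, columns = all nodes) plus bookkeeping.
#'   Reflexive pairs are excluded by the accessors ([tidy()] and
#'   [influence_labels()]), matching the walk-length >= 1 convention.
#' @seealso [enumerate_walk_signs()] for the exhaustive small-graph oracle.
#' @export
signed_reachability_closure <- function(graph, sources = NULL) {
  stopifnot(inherits(graph, "causality_graph"))
  nodes <- graph$nodes$node
  if (is.null(sources)) sources <- nodes
  stopifnot(all(sources %in% nodes))
  sources <- unique(sources)
  nv <- length(nodes)
  empty <- matrix(FALSE, nrow = length(sources), ncol = nv,
                  dimnames = list(sources, nodes))
  if (nv == 0 || nrow(graph$edges) == 0 || length(sources) == 0) {
    return(structure(list(nodes = nodes, sources = sources,
                          P = empty, N = empty, U = empty),
                     class = "influence_closure"))
  }
  idx <- setNames(seq_len(nv), nodes)
  # Product-graph states: (node, even) = i, (node, odd) = nv + i,
  # (node, unknown) = 2 nv + i. Unknown is absorbing.
  su <- idx[graph$edges$src]
  dv <- idx[graph$edges$dst]
  sg <- graph$edges$sign
  from <- integer(0); to <- integer(0)
  pos <- sg == "+"; neg <- sg == "-"; unk <- sg == "?"
  add <- function(f, t) { from <<- c(from, f); to <<- c(to, t) }
  if (any(pos)) {
    add(su[pos], dv[pos])                    # even -> even
    add(nv + su[pos], nv + dv[pos])          # odd  -> odd
    add(2L * nv + su[pos], 2L * nv + dv[pos])
  }
  if (any(neg)) {
    add(su[neg], nv + dv[neg])               # even -> odd
    add(nv + su[neg], dv[neg])               # odd  -> even
    add(2L * nv + su[neg], 2L * nv + dv[neg])
  }
  if (any(unk)) {
    add(su[unk], 2L * nv + dv[unk])
    add(nv + su[unk], 2L * nv + dv[unk])
    add(2L * nv + su[unk], 2L * nv + dv[unk])
  }
  pg <- igraph::make_empty_graph(n = 3L * nv, directed = TRUE)
  pg <- igraph::add_edges(pg, rbind(from, to))
  d <- igraph::distances(pg, v = idx[sources], mode = "out",
                         algorithm = "unweighted")
  reach <- is.finite(d) & d >= 1
  dimnames(reach) <- NULL
  P <- reach[, seq_len(nv), drop = FALSE]
  N <- reach[, nv + seq_len(nv), drop = FALSE]
  U <- reach[, 2L * nv + seq_len(nv), drop = FALSE]
  dimnames(P) <- dimnames(N) <- dimnames(U) <- list(sources, nodes)
  # d >= 1 on the even diagonal distinguishes a genuine positive cycle back
  # to the source from the zero-length walk; off-diagonal entries always
  # have d >= 1.
  structure(list(nodes = nodes, sources = sources, P = P, N = N, U = U),
            class = "influence_closure")
}

#' @export
print.influence_closure <- function(x, ...) {
  cat(sprintf("<influence_closure> %d source(s) x %d nodes; labelled pairs: %d\n",
              length(x$sources), length(x$nodes), nrow(tidy(x))))
  invisible(x)
}

#' Look up the achievable sign labels for one ordered node pair
#'
#' @param closure An `influence_closure`.
#' @param src,dst Node ids (`src` must be one of the closure's sources).
#' @return A character vector, subset of `c("+", "-", "?")`; empty when the
#'   pair is unreachable or reflexive-with-no-cycle.
#' @export
influence_labels <- function(closure, src, dst) {
  stopifnot(inherits(closure, "influence_closure"))
  if (!src %in% closure$sources) abort(sprintf("unknown closure source '%s'", src))
  if (!dst %in% closure$nodes) abort(sprintf("unknown node '%s'", dst))
  if (identical(src, dst)) {
    abort("reflexive pairs are excluded from the closure (walk length >= 1, no self-influence)")
  }
  c("+", "-", "?")[c(closure$P[src, dst], closure$N[src, dst], closure$U[src, dst])]
}

#' Enumerate walk signs exhaustively (test oracle)
#'
#' Independent oracle for [signed_reachability_closure()]: enumerates, by
#' dynamic programming over exact walk lengths, every walk of length
#' `1..max_len` from `src` to `dst` and collects the achievable sign labels.
#' The default bound `3 * |V|` is sufficient for equality with the closure,
#' because the shortest walk witnessing any label visits at most the
#' `3 * |V|` states (node, parity). Only meant for small graphs; refuses
#' graphs with more than 12 nodes.
#'
#' @param graph A `causality_graph`.
#' @param src,dst Node ids.
#' @param max_len Maximum walk length to enumerate.
#' @return A character vector, subset of `c("+", "-", "?")`.
#' @export
enumerate_walk_signs <- function(graph, src, dst, max_len = NULL) {
  stopifnot(inherits(graph, "causality_graph"))
  nodes <- graph$nodes$node
  nv <- length(nodes)
  if (nv > 12) abort("enumerate_walk_signs is a small-graph oracle (|V| <= 12)")
  if (is.null(max_len)) max_len <- 3L * nv
  stopifnot(src %in% nodes, dst %in% nodes)
  idx <- setNames(seq_len(nv), nodes)
  eu <- idx[graph$edges$src]; ev <- idx[graph$edges$dst]; es <- graph$edges$sign
  # cur[node, state]: a walk of the current length ends here with this
  # parity state (1 = even negatives, 2 = odd, 3 = saw an unknown edge).
  cur <- matrix(FALSE, nv, 3)
  cur[idx[[src]], 1] <- TRUE
  found <- c("+" = FALSE, "-" = FALSE, "?" = FALSE)
  for (len in seq_len(max_len)) {
    nxt <- matrix(FALSE, nv, 3)
    for (k in seq_along(eu)) {
      u <- eu[[k]]; v <- ev[[k]]
      if (es[[k]] == "+") {
        if (cur[u, 1]) nxt[v, 1] <- TRUE
        if (cur[u, 2]) nxt[v, 2] <- TRUE
        if (cur[u, 3]) nxt[v, 3] <- TRUE
      } else if (es[[k]] == "-") {
        if (cur[u, 1]) nxt[v, 2] <- TRUE
        if (cur[u, 2]) nxt[v, 1] <- TRUE
        if (cur[u, 3]) nxt[v, 3] <- TRUE
      } else {
        if (any(cur[u, ])) nxt[v, 3] <- TRUE
      }
    }
    d <- idx[[dst]]
    found["+"] <- found[["+"]] || nxt[d, 1]
    found["-"] <- found[["-"]] || nxt[d, 2]
    found["?"] <- found[["?"]] || nxt[d, 3]
    cur <- nxt
    if (!any(cur)) break
  }
  names(found)[found]
}
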