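#' Find upstream regulator candidates for a target list
#'
#' Executes the whole pipeline: hub identification, neighborhood extraction,
#' causality-graph compilation, signed reachability closure, candidate
#' scoring and tie-aware ranking. Answer sets of 50 to 100 candidates are a
#' good trade-off between success rate and review effort; `top_n = 100` is
#' the default.
#'
#' @param kb A `reg_kb` or a path to a KB-JSON file.
#' @param targets A target-list tibble or a path to a target TSV.
#' @param hub_n Number of hub molecules excluded from neighborhood expansion
#'   (default 1000, intended for full-scale knowledge bases; scale it to the
#'   knowledge base at hand).
#' @param levels Neighborhood levels (default 3).
#' @param key Ranking score, `"specificity"` (default) or `"coverage"`.
#' @param top_n Number of candidates to retain.
#' @param candidate_kinds,urn_kinds,count_unknown Passed to
#'   [score_candidates()].
#' @param drop_hubs Delete hubs from selected reactions too (see
#'   [extract_neighborhood()]).
#' @param out_prefix When non-`NULL`, writes `<prefix>_candidates.tsv` and
#'   `<prefix>_metadata.json`; both are byte-deterministic for identical
#'   inputs.
#' @return A list with `candidates` (the [rank_with_ties()] tibble, empty
#'   when nothing is scorable) and `metadata` (parameters plus per-stage
#'   counts, including the percentage of molecules and reactions retained by
#'   the neighborhood step).
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
#' res <- find_regulators(toy, target_list("d", "+"), hub_n = 0)
#' res$candidates[, c("candidate", "sign", "coverage", "specificity")]
#' @export
find_regulators <- function(kb, targets, hub_n = 1000, levels = 3,
                            key = c("specificity", "coverage"), top_n = 100,
                            candidate_kinds = NULL, urn_kinds = "gene",
                            count_unknown = TRUE, drop_hubs = FALSE,
                            out_prefix = NULL) {
  key <- match.arg(key)
  if (is.character(kb)) kb <- read_knowledge_base(kb)
  if (is.character(targets)) targets <- read_target_list(targets)
  stopifnot(inherits(kb, "reg_kb"))
  hubs <- rank_hub_molecules(kb, hub_n)
  sub <- extract_neighborhood(kb, targets$molecule_id, levels = levels,
                              hubs = hubs, drop_hubs = drop_hubs)
  graph <- build_causality_graph(sub)
  metadata <- list(
    params = list(hub_n = hub_n, levels = levels, key = key, top_n = top_n,
                  candidate_kinds = candidate_kinds, urn_kinds = urn_kinds,
                  count_unknown = count_unknown, drop_hubs = drop_hubs),
    kb = list(n_molecules = nrow(kb$molecules), n_reactions = nrow(kb$reactions)),
    subnetwork = list(
      n_molecules = nrow(sub$molecules), n_reactions = nrow(sub$reactions),
      pct_molecules = round(100 * nrow(sub$molecules) / max(1, nrow(kb$molecules)), 2),
      pct_reactions = round(100 * nrow(sub$reactions) / max(1, nrow(kb$reactions)), 2)
    ),
    graph = list(n_nodes = nrow(graph$nodes), n_edges = nrow(graph$edges))
  )
  empty <- tibble(candidate = character(), kind = character(),
                  sign = character(), coverage = integer(),
                  n_influenced = integer(), p = double(),
                  specificity = double(), explained = list(),
                  score = double(), rank = integer(), group = integer(),
                  retained = logical(), partial = logical())
  ranked <- if (nrow(graph$edges) == 0) {
    warn("empty candidate set: the targets select no reactions")
    empty
  } else {
    qnodes <- graph$nodes$node[graph$nodes$kind == "quantity"]
    closure <- signed_reachability_closure(graph, sources = qnodes)
    view <- build_explanatory_view(closure, targets)
    if (!any(sub$molecules$kind %in% urn_kinds)) {
      warn(sprintf("no molecule of kind(s) %s in the sub-network; widening the urn to all kinds",
                   paste(urn_kinds, collapse = ", ")))
      urn_kinds <- unique(sub$molecules$kind)
      metadata$params$urn_kinds <- urn_kinds
    }
    scores <- score_candidates(view, sub, candidate_kinds = candidate_kinds,
                               urn_kinds = urn_kinds,
                               count_unknown = count_unknown)
    scores <- scores[scores$coverage > 0, ]
    metadata$n_candidates <- nrow(scores)
    if (nrow(scores) == 0) {
      warn("empty candidate set: no molecule explains any target")
      empty
    } else {
      rank_with_ties(scores, key = key, top_n = top_n)
    }
  }
  if (!is.null(out_prefix)) {
    write_candidates(ranked, paste0(out_prefix, "_candidates.tsv"))
    jsonlite::write_json(metadata, paste0(out_prefix, "_metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  list(candidates = ranked, metadata = metadata)
}

#' Write a ranked candidate table as TSV
#'
#' Columns: rank, tie group, candidate, kind, hypothesis sign, coverage,
#' number of urn members influenced, hypergeometric p, specificity, and the
#' explained targets as a comma-separated `target:label` list. Output is
#' deterministically ordered.
#'
#' @param ranked A [rank_with_ties()] tibble (or the empty candidates table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(ranked, path) {
  out <- tibble(
    rank = ranked$rank %||% integer(),
    tie_group = ranked$group %||% integer(),
    candidate = ranked$candidate,
    kind = ranked$kind,
    hypothesis_sign = ranked$sign,
    coverage = ranked$coverage,
    n_influenced = ranked$n_influenced,
    p = ranked$p,
    specificity = ranked$specificity,
    retained = ranked$retained %||% logical(),
    explained_targets = purrr::map_chr(ranked$explained %||% list(), function(e) {
      paste(sprintf("%s:%s", e$target, e$label), collapse = ",")
    })
  )
  readr::write_tsv(out, path)
  invisible(path)
}
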