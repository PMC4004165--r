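#' Build benchmark cases from the planted truth
#'
#' One case per planted TF: the derived target list ([derive_target_list()]),
#' the known regulator, and the set of acceptable solutions under "molecule"
#' terminology (the TF plus its protein form, when it has one). By default
#' signs are erased (`sign_noise = 1`, `"erase"`), matching benchmark lists
#' of regulated genes that carry no direction information.
#'
#' @param truth A `truth` list from [generate_knowledge_base()].
#' @param sign_noise,noise_mode,drop_tf,seed Passed to
#'   [derive_target_list()]; each case uses a sub-seed of `seed`.
#' @return A list of cases, each a list with `id`, `targets`, `known` and
#'   `accept`.
#' @export
benchmark_cases <- function(truth, sign_noise = 1, noise_mode = "erase",
                            drop_tf = TRUE, seed = 1) {
  tfs <- unique(truth$regulons$tf)
  purrr::map(seq_along(tfs), function(i) {
    tf <- tfs[i]
    form <- truth$forms$form[truth$forms$tf == tf]
    list(
      id = tf,
      targets = derive_target_list(truth, tf, sign_noise = sign_noise,
                                   noise_mode = noise_mode, drop_tf = drop_tf,
                                   seed = sub_seed(seed, 100 + i)),
      known = tf,
      accept = c(tf, form)
    )
  })
}

#' Read / write benchmark case files
#'
#' A case file starts with a `#known=<id>` line, optionally followed by
#' `#accept=<id,id,...>`, then the target list as TSV (see
#' [read_target_list()]).
#'
#' @param path File path (for [read_benchmark_case()]) or output path.
#' @return A case list, as in [benchmark_cases()].
#' @export
read_benchmark_case <- function(path) {
  lines <- readr::read_lines(path)
  header <- grep("^#", lines, value = TRUE)
  known <- sub("^#known=", "", grep("^#known=", header, value = TRUE))
  if (length(known) != 1) abort(sprintf("'%s' must contain one '#known=<id>' line", path))
  accept <- grep("^#accept=", header, value = TRUE)
  accept <- if (length(accept) == 1) {
    strsplit(sub("^#accept=", "", accept), ",", fixed = TRUE)[[1]]
  } else known
  body <- lines[!grepl("^#", lines)]
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  readr::write_lines(body, tmp)
  list(id = sub("\\.[^.]*$", "", basename(path)), targets = read_target_list(tmp),
       known = known, accept = unique(c(known, accept)))
}

#' @rdname read_benchmark_case
#' @param case A case list.
#' @export
write_benchmark_case <- function(case, path) {
  readr::write_lines(
    c(sprintf("#known=%s", case$known),
      sprintf("#accept=%s", paste(case$accept, collapse = ",")),
      "molecule_id\tsign",
      sprintf("%s\t%s", case$targets$molecule_id, case$targets$sign)),
    path
  )
  invisible(path)
}

#' Run the success-at-top-n benchmark protocol
#'
#' For each case the full pipeline is executed (neighborhood extraction with
#' hub exclusion, causality-graph compilation, signed closure, candidate
#' scoring over all molecule kinds) and the probability that the known
#' regulator falls within the retained candidate set is computed at every
#' cutoff, for both score keys (coverage, specificity) and two solution
#' terminologies: under the `gene` view only the regulator's gene-kind id
#' counts as a find, under the `molecule` view any molecule carrying it
#' (protein form, active complex) does as well. Both views read the same
#' ranking, so molecule-view success is at least gene-view success at every
#' cutoff by construction. Aggregates are means over cases, times 100
#' (percent success).
#' With `shuffled = TRUE` the target lists are first redealt between cases
#' ([shuffle_target_lists()]) to measure the chance-only control.
#'
#' Cases whose known regulator is absent from the knowledge base are dropped
#' (count reported in the result).
#'
#' @param kb A `reg_kb`.
#' @param cases A list of cases ([benchmark_cases()] /
#'   [read_benchmark_case()]).
#' @param tops Cutoffs at which success is evaluated.
#' @param hub_n Number of hub molecules excluded from neighborhood expansion.
#' @param levels Neighborhood levels.
#' @param urn_kinds,count_unknown Passed to [score_candidates()].
#' @param shuffled Run the shuffled-list control instead of the true lists.
#' @param seed Seed for the shuffle.
#' @return A `benchmark_result`: list with tibbles `cases` (per-case hit
#'   probabilities) and `aggregate` (percent success by key, view and
#'   cutoff), plus `n_dropped` and `params`.
#' @export
run_benchmark <- function(kb, cases, tops = c(1, 10, 20, 50, 100, 200, 500, 1000),
                          hub_n = 1000, levels = 3, urn_kinds = "gene",
                          count_unknown = TRUE, shuffled = FALSE, seed = 1) {
  stopifnot(inherits(kb, "reg_kb"), length(cases) >= 1)
  known_present <- vapply(cases, function(cs) cs$known %in% kb$molecules$id,
                          logical(1))
  n_dropped <- sum(!known_present)
  if (n_dropped > 0) {
    warn(sprintf("dropping %d case(s) whose known regulator is absent from the knowledge base",
                 n_dropped))
    cases <- cases[known_present]
  }
  if (shuffled) {
    redealt <- shuffle_target_lists(purrr::map(cases, "targets"), seed = seed)
    cases <- purrr::map2(cases, redealt, function(cs, t) {
      cs$targets <- t
      cs
    })
  }
  hubs <- rank_hub_molecules(kb, hub_n)
  kinds <- setNames(kb$molecules$kind, kb$molecules$id)
  per_case <- purrr::map_dfr(cases, function(cs) {
    grid <- tidyr::expand_grid(case = cs$id,
                               key = c("coverage", "specificity"),
                               view = c("gene", "molecule"),
                               top_n = tops)
    sub <- suppressWarnings(
      extract_neighborhood(kb, cs$targets$molecule_id, levels = levels,
                           hubs = hubs)
    )
    if (nrow(sub$reactions) == 0) return(mutate(grid, hit = 0))
    graph <- build_causality_graph(sub)
    qnodes <- graph$nodes$node[graph$nodes$kind == "quantity"]
    closure <- signed_reachability_closure(graph, sources = qnodes)
    view <- build_explanatory_view(closure, cs$targets)
    scores <- score_candidates(view, sub, candidate_kinds = NULL,
                               urn_kinds = urn_kinds,
                               count_unknown = count_unknown)
    if (nrow(scores) == 0) return(mutate(grid, hit = 0))
    ranked_by <- list(
      coverage = rank_with_ties(scores, key = "coverage", top_n = max(tops)),
      specificity = rank_with_ties(scores, key = "specificity",
                                   top_n = max(tops))
    )
    hits <- purrr::pmap_dbl(grid[c("key", "view", "top_n")],
                            function(key, view, top_n) {
      acc <- if (view == "gene") {
        intersect(cs$accept, names(kinds)[kinds == "gene"])
      } else {
        cs$accept
      }
      ranked <- ranked_by[[key]]
      if (length(acc) == 0 || !any(ranked$candidate %in% acc)) return(0)
      hit_probability(ranked, known = acc, top_n = top_n)
    })
    mutate(grid, hit = hits)
  })
  aggregate <- per_case %>%
    group_by(.data$key, .data$view, .data$top_n) %>%
    summarise(success_pct = 100 * mean(.data$hit), n_cases = n(),
              .groups = "drop") %>%
    arrange(.data$key, .data$view, .data$top_n)
  structure(
    list(cases = per_case, aggregate = aggregate, n_dropped = n_dropped,
         params = list(tops = tops, hub_n = hub_n, levels = levels,
                       urn_kinds = urn_kinds, count_unknown = count_unknown,
                       shuffled = shuffled, seed = seed)),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d case(s)%s, %d dropped%s\n",
              length(unique(x$cases$case)),
              if (x$params$shuffled) " (shuffled control)" else "",
              x$n_dropped, ""))
  print(tidyr::pivot_wider(x$aggregate,
                           id_cols = "top_n",
                           names_from = c("view", "key"),
                           values_from = "success_pct"))
  invisible(x)
}
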