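#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeom(N, K, n)`: the probability of drawing at
#' least `k` white balls in `n` draws without replacement from an urn of `N`
#' balls of which `K` are white. Used to judge how surprising a candidate's
#' overlap with the target list is, against random shuffling; the inclusive
#' tail (`>= k`) is the standard enrichment convention.
#'
#' @param N Urn size. @param K White balls. @param n Draws. @param k Observed
#'   successes.
#' @return A probability in `[0, 1]`.
#' @examples
#' hypergeometric_upper_tail(10, 5, 2, 2) # choose(5,2) / choose(10,2)
#' @export
hypergeometric_upper_tail <- function(N, K, n, k) {
  if (!(k >= 0 && k <= n && n <= N && K >= 0 && K <= N && k <= K)) {
    abort(sprintf("invalid hypergeometric arguments: N=%s K=%s n=%s k=%s",
                  N, K, n, k))
  }
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Coverage of a single signed candidate hypothesis
#'
#' Counts the targets that the hypothesis "`candidate` varies with sign
#' `sign`" explains: targets observed up (down) must be influenced in their
#' up (down) variant; for targets of unknown sign either variant counts.
#' Influence established only through unknown-sign walks counts when
#' `count_unknown = TRUE` (modulators are admitted as regulators) and is
#' labelled `?` in the returned detail. A candidate never explains itself.
#'
#' @param view An `explanatory_view`.
#' @param candidate Candidate molecule id.
#' @param sign Hypothesised candidate variation, `"+"` or `"-"`.
#' @param count_unknown Count unknown-label influence toward coverage.
#' @return A list with `coverage` (integer) and `explained`, a tibble
#'   (`target`, `label`) with label `+`, `-` or `?`.
#' @export
coverage_score <- function(view, candidate, sign, count_unknown = TRUE) {
  stopifnot(inherits(view, "explanatory_view"))
  sign <- match.arg(sign, c("+", "-"))
  targets <- view$targets
  out <- purrr::map_dfr(seq_len(nrow(targets)), function(i) {
    t_id <- targets$molecule_id[[i]]
    t_sign <- targets$sign[[i]]
    if (identical(t_id, candidate)) return(NULL)
    variations <- if (t_sign == "?") c("+", "-") else t_sign
    for (v in variations) {
      ans <- influences(view, candidate, sign, t_id, v)
      if (ans == "yes") {
        return(tibble(target = t_id, label = if (sign == v) "+" else "-"))
      }
    }
    if (count_unknown) {
      for (v in variations) {
        if (influences(view, candidate, sign, t_id, v) == "unknown") {
          return(tibble(target = t_id, label = "?"))
        }
      }
    }
    NULL
  })
  if (nrow(out) == 0) out <- tibble(target = character(), label = character())
  list(coverage = nrow(out), explained = out)
}

#' Score all candidate regulators by coverage and specificity
#'
#' For every molecule with a quantity node among the closure sources and
#' both variation hypotheses, computes:
#'
#' * `coverage`: number of targets explained with a consistent sign;
#' * `p`: [hypergeometric_upper_tail()] probability of the overlap between
#'   the urn members the candidate influences (`n_influenced`) and the
#'   targets inside the urn, in an urn holding one ball per molecule of the
#'   urn kinds present in the compiled sub-graph;
#' * `specificity = coverage * (1 - p)`, rewarding candidates specific to
#'   few targets.
#'
#' The two hypotheses are then collapsed: a candidate observed in the target
#' list with a known sign keeps only the concordant hypothesis, otherwise
#' the better-scoring one (higher coverage, then higher specificity, then
#' `+`) is reported.
#'
#' @param view An `explanatory_view` built over a closure whose sources
#'   include all quantity nodes.
#' @param kb The `reg_kb` the graph was compiled from (for molecule kinds).
#' @param candidate_kinds Restrict candidates to these molecule kinds
#'   (`NULL` = all kinds, the "molecule candidates" reading; `"gene"`
#'   reproduces the "gene candidates" reading).
#' @param urn_kinds Molecule kinds forming the urn population (default one
#'   ball per gene in the graph).
#' @param count_unknown Count unknown-label influence (see
#'   [coverage_score()]).
#' @return A tibble with one row per candidate: `candidate`, `kind`, `sign`,
#'   `coverage`, `n_influenced`, `p`, `specificity` and `explained`
#'   (list column of per-target labels), sorted by specificity then coverage
#'   descending, candidate id ascending.
#' @export
score_candidates <- function(view, kb, candidate_kinds = NULL,
                             urn_kinds = "gene", count_unknown = TRUE) {
  stopifnot(inherits(view, "explanatory_view"), inherits(kb, "reg_kb"))
  cl <- view$closure
  src_mol <- sub("^Q:", "", grep("^Q:", cl$sources, value = TRUE))
  kinds <- setNames(kb$molecules$kind, kb$molecules$id)
  candidates <- src_mol[src_mol %in% names(kinds)]
  if (!is.null(candidate_kinds)) {
    candidates <- candidates[kinds[candidates] %in% candidate_kinds]
  }
  node_mol <- sub("^Q:", "", grep("^Q:", cl$nodes, value = TRUE))
  urn <- sort(node_mol[kinds[node_mol] %in% urn_kinds])
  if (length(urn) == 0) abort("empty urn: no molecule of the urn kinds has a quantity node")
  targets <- view$targets
  qc <- quantity_node(candidates)
  P <- cl$P[qc, , drop = FALSE]
  N <- cl$N[qc, , drop = FALSE]
  U <- cl$U[qc, , drop = FALSE]
  any_influence <- P | N
  if (count_unknown) any_influence <- any_influence | U

  # Per-target explanation matrices over candidates, one pair of logical
  # matrices (hypothesis +, hypothesis -) plus the unknown-only fallback.
  t_in_graph <- targets$molecule_id[quantity_node(targets$molecule_id) %in% cl$nodes]
  expl <- list("+" = NULL, "-" = NULL)
  lab <- list("+" = NULL, "-" = NULL)
  nc <- length(candidates)
  for (hyp in c("+", "-")) {
    yes <- matrix(FALSE, nc, length(t_in_graph),
                  dimnames = list(candidates, t_in_graph))
    labm <- matrix(NA_character_, nc, length(t_in_graph),
                   dimnames = list(candidates, t_in_graph))
    for (t_id in t_in_graph) {
      qt <- quantity_node(t_id)
      t_sign <- targets$sign[targets$molecule_id == t_id][[1]]
      if (t_sign == "?") {
        pos_ok <- P[, qt]; neg_ok <- N[, qt]
      } else {
        needed <- if (hyp == t_sign) "+" else "-"
        pos_ok <- if (needed == "+") P[, qt] else logical(nc)
        neg_ok <- if (needed == "-") N[, qt] else logical(nc)
      }
      hit <- pos_ok | neg_ok
      labm[hit, t_id] <- ifelse(pos_ok[hit], "+", "-")
      if (count_unknown) {
        unk <- !hit & U[, qt]
        hit <- hit | unk
        labm[unk, t_id] <- "?"
      }
      hit[candidates == t_id] <- FALSE   # never explain oneself
      labm[candidates == t_id, t_id] <- NA
      yes[, t_id] <- hit
    }
    expl[[hyp]] <- yes
    lab[[hyp]] <- labm
  }

  urn_cols <- quantity_node(urn)
  infl_urn <- any_influence[, urn_cols, drop = FALSE]
  if (nc > 0) {
    self <- cbind(seq_len(nc), match(candidates, urn))
    self <- self[!is.na(self[, 2]), , drop = FALSE]
    infl_urn[self] <- FALSE              # candidate's own ball never drawn
  }
  n_influenced <- unname(rowSums(infl_urn))
  Nurn <- length(urn)
  Kurn <- length(intersect(targets$molecule_id, urn))

  rows <- purrr::map_dfr(c("+", "-"), function(hyp) {
    cov <- unname(rowSums(expl[[hyp]]))
    k <- unname(rowSums(expl[[hyp]][, intersect(t_in_graph, urn), drop = FALSE]))
    p <- purrr::map2_dbl(n_influenced, k, function(ni, ki) {
      hypergeometric_upper_tail(Nurn, Kurn, ni, min(ki, ni))
    })
    explained <- purrr::map(seq_len(nc), function(i) {
      hit <- expl[[hyp]][i, ]
      tibble(target = t_in_graph[hit], label = lab[[hyp]][i, hit])
    })
    tibble(candidate = candidates, kind = unname(kinds[candidates]),
           sign = hyp, coverage = as.integer(cov),
           n_influenced = as.integer(n_influenced),
           p = p, specificity = ifelse(cov == 0, 0, cov * (1 - p)),
           explained = explained)
  })

  # Collapse the two hypotheses per candidate.
  observed <- setNames(targets$sign, targets$molecule_id)
  rows %>%
    group_by(.data$candidate) %>%
    dplyr::group_modify(function(df, key) {
      cand <- key$candidate[[1]]
      obs <- if (cand %in% names(observed)) observed[[cand]] else "?"
      if (obs %in% c("+", "-")) {
        df <- df[df$sign == obs, , drop = FALSE]
      }
      df[order(-df$coverage, -df$specificity, df$sign != "+"), ][1, , drop = FALSE]
    }) %>%
    ungroup() %>%
    arrange(desc(.data$specificity), desc(.data$coverage), .data$candidate)
}

#' Rank scored candidates with explicit tie groups
#'
#' Candidates are sorted by the chosen score descending; candidates with
#' exactly equal scores form one *ex aequo* group. The retained list is the
#' smallest prefix of whole groups covering at least `top_n` candidates; the
#' boundary group, when it straddles the cutoff, is marked partial.
#'
#' @param scores A [score_candidates()] tibble.
#' @param key `"specificity"` or `"coverage"`.
#' @param top_n Number of candidates to retain.
#' @return The scores tibble with added columns `rank`, `group`, `score`,
#'   `retained` and `partial`, plus attributes `key` and `top_n`. All
#'   candidates are kept so tie probabilities stay computable; filter on
#'   `retained` for the answer set.
#' @export
rank_with_ties <- function(scores, key = c("specificity", "coverage"),
                           top_n = 100) {
  key <- match.arg(key)
  stopifnot(nrow(scores) > 0, top_n >= 1)
  out <- scores %>%
    mutate(score = .data[[key]]) %>%
    arrange(desc(.data$score), .data$candidate) %>%
    mutate(rank = row_number(), group = dense_rank(desc(.data$score)))
  sizes <- out %>% group_by(.data$group) %>% summarise(g = n(), .groups = "drop")
  before <- cumsum(c(0, sizes$g))[seq_len(nrow(sizes))]
  retained_groups <- sizes$group[before < top_n]
  boundary <- sizes$group[before < top_n & before + sizes$g > top_n]
  out <- out %>%
    mutate(retained = .data$group %in% retained_groups,
           partial = .data$group %in% boundary)
  attr(out, "key") <- key
  attr(out, "top_n") <- as.integer(top_n)
  out
}

#' Probability that a known regulator is in the retained candidate set
#'
#' Ex-aequo candidates are assumed randomly ordered within their tie group,
#' so a known regulator whose group lies fully inside the cutoff scores 1,
#' fully outside scores 0, and a boundary group of size `g` with `m`
#' retained slots contributes `m / g`. With several acceptable ids (e.g. a
#' transcription factor and the complexes carrying it), the probability that
#' at least one of the `a` acceptable members of the boundary group is
#' retained is `1 - choose(g - a, m) / choose(g, m)`.
#'
#' @param ranked A [rank_with_ties()] result.
#' @param known Character vector of acceptable candidate ids.
#' @param top_n Cutoff; defaults to the one the ranking was built with.
#' @return A probability in `[0, 1]`; 0 with a warning when no acceptable id
#'   was scored.
#' @export
hit_probability <- function(ranked, known, top_n = attr(ranked, "top_n")) {
  stopifnot(is.data.frame(ranked), !is.null(ranked$group))
  known <- as.character(known)
  hit_rows <- ranked[ranked$candidate %in% known, ]
  if (nrow(hit_rows) == 0) {
    warn(sprintf("known regulator(s) %s absent from the scored candidates",
                 paste(known, collapse = ", ")))
    return(0)
  }
  sizes <- ranked %>% group_by(.data$group) %>%
    summarise(g = n(), .groups = "drop") %>% arrange(.data$group)
  before <- cumsum(c(0, sizes$g))[seq_len(nrow(sizes))]
  names(before) <- sizes$group
  gsize <- setNames(sizes$g, sizes$group)
  for (grp in sort(unique(hit_rows$group))) {
    b <- before[[as.character(grp)]]
    g <- gsize[[as.character(grp)]]
    if (b + g <= top_n) return(1)
    if (b < top_n) {
      m <- top_n - b
      a <- sum(hit_rows$group == grp)
      return(1 - choose(g - a, m) / choose(g, m))
    }
  }
  0
}
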