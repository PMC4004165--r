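#' Build the explanatory view of a closure for a target list
#'
#' Conceptually every causality-graph node `N` is split into an up variant
#' `[N, +]` and a down variant `[N, -]`; when a target molecule is observed
#' up-regulated (resp. down-regulated) the contradicting variant of its
#' quantity node is removed. A candidate hypothesis `(C, s)` then influences
#' a target variant `[quantity(T), t]` when the closure holds the label
#' `s * t` for the pair `(quantity(C), quantity(T))`; an unknown (`?`) label
#' influences both variants, flagged unknown. Queries against a removed
#' variant always answer no, and a molecule never explains itself.
#'
#' @param closure An `influence_closure` whose sources include the candidate
#'   quantity nodes of interest.
#' @param targets A target-list tibble ([target_list()]). Targets without a
#'   quantity node in the closure are kept in the list but can never be
#'   explained.
#' @return An object of class `explanatory_view`.
#' @export
build_explanatory_view <- function(closure, targets) {
  stopifnot(inherits(closure, "influence_closure"))
  targets <- as_tibble(targets)
  targets$sign <- as_sign(targets$sign, "target sign")
  structure(list(closure = closure, targets = targets),
            class = "explanatory_view")
}

#' @export
print.explanatory_view <- function(x, ...) {
  cat(sprintf("<explanatory_view> %d target(s): %d up, %d down, %d unknown\n",
              nrow(x$targets), sum(x$targets$sign == "+"),
              sum(x$targets$sign == "-"), sum(x$targets$sign == "?")))
  invisible(x)
}

#' Does a signed candidate hypothesis influence a target variant?
#'
#' @param view An `explanatory_view`.
#' @param candidate Candidate molecule id (must have a quantity node among
#'   the closure sources).
#' @param candidate_sign Hypothesised variation of the candidate, `"+"` or
#'   `"-"`.
#' @param target Target molecule id.
#' @param variation Queried variation of the target, `"+"` or `"-"`; defaults
#'   to the observed sign when known.
#' @return `"no"`, `"yes"`, or `"unknown"` (influence only via an
#'   unknown-sign walk).
#' @export
influences <- function(view, candidate, candidate_sign, target,
                       variation = NULL) {
  stopifnot(inherits(view, "explanatory_view"))
  candidate_sign <- match.arg(candidate_sign, c("+", "-"))
  row <- which(view$targets$molecule_id == target)
  observed <- if (length(row) == 1) view$targets$sign[[row]] else "?"
  if (is.null(variation)) {
    if (observed == "?") abort("target sign unknown; supply `variation`")
    variation <- observed
  }
  variation <- match.arg(variation, c("+", "-"))
  # The removed node rule: the variant contradicting the observed sign is
  # absent from the explanatory graph, so it can never be influenced.
  if (observed != "?" && variation != observed) return("no")
  if (identical(candidate, target)) return("no")
  qc <- quantity_node(candidate)
  qt <- quantity_node(target)
  cl <- view$closure
  if (!qc %in% cl$sources) {
    abort(sprintf("candidate '%s' has no quantity node among the closure sources", candidate))
  }
  if (!qt %in% cl$nodes) return("no")
  needed <- if (candidate_sign == variation) "+" else "-"
  labels <- influence_labels(cl, qc, qt)
  if (needed %in% labels) return("yes")
  if ("?" %in% labels) return("unknown")
  "no"
}
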