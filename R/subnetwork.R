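#' Extract the reaction neighborhood of a target list
#'
#' Starting from the seed molecules, reactions are selected by iterative
#' frontier expansion: at each level every reaction containing at least one
#' frontier molecule (in any role, regardless of direction or reversibility)
#' is selected, and the next frontier is the set of molecules of the selected
#' reactions not yet visited. Hub molecules never enter a frontier, so they
#' block expansion, but they are retained inside selected reactions ("drop"
#' them entirely with `drop_hubs = TRUE`). Three levels of neighboring is the
#' recommended default: one selection repeated two more times.
#'
#' @param x A `reg_kb` object.
#' @param seeds Molecule ids to expand from (ids absent from the knowledge
#'   base are dropped with a warning).
#' @param levels Number of reaction-selection rounds (>= 1).
#' @param hubs Molecule ids excluded from expansion, typically
#'   [rank_hub_molecules()] output.
#' @param drop_hubs Delete hub molecules from the selected reactions as well;
#'   reactions left without products are then dropped.
#' @return The sub-`reg_kb` of selected reactions and every molecule they
#'   mention. Monotone in `levels`, anti-monotone in `hubs`.
#' @export
extract_neighborhood <- function(x, seeds, levels = 3, hubs = character(),
                                 drop_hubs = FALSE) {
  stopifnot(inherits(x, "reg_kb"), levels >= 1)
  seeds <- unique(as.character(seeds))
  missing <- setdiff(seeds, x$molecules$id)
  if (length(missing) > 0) {
    warn(sprintf("%d seed(s) absent from the knowledge base dropped: %s",
                 length(missing), paste(missing, collapse = ", ")))
    seeds <- setdiff(seeds, missing)
  }
  mol2rxn <- split(x$index$reaction, x$index$molecule)
  rxn2mol <- split(x$index$molecule, x$index$reaction)
  frontier <- setdiff(seeds, hubs)
  if (length(frontier) == 0) {
    warn("empty initial frontier (no non-hub seeds); returning empty sub-network")
  }
  visited <- frontier
  selected <- character()
  for (lvl in seq_len(levels)) {
    if (length(frontier) == 0) break
    selected <- union(selected, unique(unlist(mol2rxn[frontier], use.names = FALSE)))
    mols <- unique(unlist(rxn2mol[selected], use.names = FALSE))
    frontier <- setdiff(setdiff(mols, hubs), visited)
    visited <- union(visited, frontier)
  }
  rxn <- x$reactions[x$reactions$id %in% selected, ]
  if (drop_hubs && nrow(rxn) > 0) {
    for (col in c("substrates", "products", "activators", "inhibitors", "modulators")) {
      rxn[[col]] <- lapply(rxn[[col]], setdiff, y = hubs)
    }
    empty <- lengths(rxn$products) == 0
    if (any(empty)) {
      warn(sprintf("dropping %d reaction(s) left without products after hub removal",
                   sum(empty)))
      rxn <- rxn[!empty, ]
    }
  }
  mentioned <- unique(unlist(rxn2mol[rxn$id], use.names = FALSE))
  if (drop_hubs) mentioned <- setdiff(mentioned, hubs)
  kb(x$molecules[x$molecules$id %in% mentioned, ], rxn)
}
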