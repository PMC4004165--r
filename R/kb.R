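#' Construct a knowledge base of molecules and regulated reactions
#'
#' A *regulated reaction* unifies a biochemical transformation
#' (substrates -> products) with its regulators: activators (positive effect
#' on reaction speed), inhibitors (negative) and modulators (unknown sign).
#' Regulatory effects (e.g. a transcription factor inducing a gene) are
#' represented as product-only reactions whose unmodeled substrate is assumed
#' non-limiting; see [effect_to_reaction()].
#'
#' @param molecules A data frame with columns `id`, `kind` (one of `gene`,
#'   `metabolite`, `protein`, `complex`, `other`), optional `name` and
#'   `species` (list column of character tags).
#' @param reactions A data frame with columns `id`, list columns `substrates`,
#'   `products`, `activators`, `inhibitors`, `modulators` (character vectors
#'   of molecule ids), logical `reversible`, and optional `species`.
#' @return An object of class `reg_kb`: a list with tibbles `molecules` and
#'   `reactions` plus `index`, a tibble (`molecule`, `reaction`) listing every
#'   reaction a molecule participates in, in any role.
#' @examples
#' kb <- kb(
#'   molecules = tibble::tibble(id = c("a", "b"), kind = c("gene", "gene")),
#'   reactions = tibble::tibble(
#'     id = "r1", substrates = list(character()), products = list("b"),
#'     activators = list("a"), inhibitors = list(character()),
#'     modulators = list(character()), reversible = FALSE
#'   )
#' )
#' glance(kb)
#' @export
kb <- function(molecules, reactions = NULL) {
  molecules <- as_tibble(molecules)
  if (is.null(reactions) || nrow(as_tibble(reactions)) == 0) {
    reactions <- empty_reactions()
  }
  reactions <- as_tibble(reactions)
  if (!"name" %in% names(molecules)) molecules$name <- molecules$id
  if (!"species" %in% names(molecules)) {
    molecules$species <- rep(list(character()), nrow(molecules))
  }
  if (!"species" %in% names(reactions) && nrow(reactions) > 0) {
    reactions$species <- rep(list(character()), nrow(reactions))
  }
  for (col in c("substrates", "products", "activators", "inhibitors", "modulators")) {
    if (!col %in% names(reactions)) {
      reactions[[col]] <- rep(list(character()), nrow(reactions))
    }
    reactions[[col]] <- lapply(reactions[[col]], roleset)
  }
  molecules$species <- lapply(molecules$species, roleset)
  if (nrow(reactions) > 0) reactions$species <- lapply(reactions$species, roleset)
  molecules <- arrange(molecules[, c("id", "kind", "name", "species")], .data$id)
  if (nrow(reactions) > 0) {
    reactions <- arrange(
      reactions[, c("id", "substrates", "products", "activators",
                    "inhibitors", "modulators", "reversible", "species")],
      .data$id
    )
  }
  out <- structure(
    list(molecules = molecules, reactions = reactions,
         index = build_kb_index(reactions)),
    class = "reg_kb"
  )
  validate_kb(out)
  out
}

empty_reactions <- function() {
  tibble(
    id = character(), substrates = list(), products = list(),
    activators = list(), inhibitors = list(), modulators = list(),
    reversible = logical(), species = list()
  )
}

roleset <- function(x) {
  x <- unique(as.character(x))
  sort(x[!is.na(x) & nzchar(x)])
}

build_kb_index <- function(reactions) {
  if (nrow(reactions) == 0) {
    return(tibble(molecule = character(), reaction = character()))
  }
  members <- purrr::pmap(
    reactions[c("substrates", "products", "activators", "inhibitors", "modulators")],
    function(substrates, products, activators, inhibitors, modulators) {
      unique(c(substrates, products, activators, inhibitors, modulators))
    }
  )
  tibble(
    molecule = unlist(members),
    reaction = rep(reactions$id, lengths(members))
  ) %>% arrange(.data$molecule, .data$reaction)
}

#' Validate knowledge-base invariants
#'
#' Checks id uniqueness, the molecule-kind vocabulary, non-empty product
#' sets, pairwise-disjoint regulator roles, absence of dangling molecule
#' references and consistency of the participation index. Called by every
#' constructor; exported for use after manual edits.
#'
#' @param x A `reg_kb` object.
#' @return `x`, invisibly. Errors describe the offending ids.
#' @export
validate_kb <- function(x) {
  stopifnot(inherits(x, "reg_kb"))
  mol <- x$molecules
  rxn <- x$reactions
  if (anyDuplicated(mol$id)) {
    abort(paste("duplicated molecule ids:",
                paste(unique(mol$id[duplicated(mol$id)]), collapse = ", ")))
  }
  bad_kind <- setdiff(unique(mol$kind), MOLECULE_KINDS)
  if (length(bad_kind) > 0) {
    abort(paste("invalid molecule kind(s):", paste(bad_kind, collapse = ", ")))
  }
  if (nrow(rxn) == 0) return(invisible(x))
  if (anyDuplicated(rxn$id)) {
    abort(paste("duplicated reaction ids:",
                paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", ")))
  }
  if (any(lengths(rxn$products) == 0)) {
    abort(paste("reactions with empty product set:",
                paste(rxn$id[lengths(rxn$products) == 0], collapse = ", ")))
  }
  overlap <- purrr::pmap_lgl(
    rxn[c("activators", "inhibitors", "modulators")],
    function(activators, inhibitors, modulators) {
      length(intersect(activators, inhibitors)) > 0 ||
        length(intersect(activators, modulators)) > 0 ||
        length(intersect(inhibitors, modulators)) > 0
    }
  )
  if (any(overlap)) {
    abort(paste("regulator roles not disjoint in reaction(s):",
                paste(rxn$id[overlap], collapse = ", ")))
  }
  referenced <- unique(x$index$molecule)
  dangling <- setdiff(referenced, mol$id)
  if (length(dangling) > 0) {
    abort(paste("dangling molecule reference(s):",
                paste(sort(dangling), collapse = ", ")))
  }
  stopifnot(identical(x$index, build_kb_index(rxn)))
  invisible(x)
}

#' @export
print.reg_kb <- function(x, ...) {
  cat(sprintf("<reg_kb> %d molecules, %d regulated reactions\n",
              nrow(x$molecules), nrow(x$reactions)))
  invisible(x)
}

#' Convert a regulatory effect into a regulated reaction
#'
#' An effect `source -> target` with sign `+`, `-` or `?` becomes an
#' irreversible reaction producing `target` from the catabolism of an
#' unmodeled, non-limiting substrate, regulated by `source` as activator,
#' inhibitor or modulator respectively. The reaction id is deterministic in
#' `(source, target, sign)`.
#'
#' @param source,target Molecule ids.
#' @param sign `"+"`, `"-"` or `"?"` (aliases `up`/`down`/`unknown` accepted).
#' @return A one-row reactions tibble suitable for [kb()].
#' @examples
#' effect_to_reaction("a", "b", "+")
#' @export
effect_to_reaction <- function(source, target, sign) {
  sign <- as_sign(sign, "effect sign")
  stopifnot(length(source) == 1, length(target) == 1, length(sign) == 1)
  if (identical(source, target)) {
    warn(sprintf("self-regulation effect on '%s' kept as written", source))
  }
  role <- c("+" = "act", "-" = "inh", "?" = "mod")[[sign]]
  tibble(
    id = sprintf("effect_%s_%s_%s", source, role, target),
    substrates = list(character()),
    products = list(target),
    activators = list(if (sign == "+") source else character()),
    inhibitors = list(if (sign == "-") source else character()),
    modulators = list(if (sign == "?") source else character()),
    reversible = FALSE,
    species = list(character())
  )
}

# Vectorised builder for many effect-derived reactions at once (same
# contract as effect_to_reaction, without per-row tibble construction).
effects_block <- function(source, target, sign) {
  n <- length(source)
  if (n == 0) return(empty_reactions())
  sign <- as_sign(sign, "effect sign")
  role <- c("+" = "act", "-" = "inh", "?" = "mod")[sign]
  pick <- function(want) {
    unname(Map(function(s, sg) if (sg == want) s else character(), source, sign))
  }
  tibble(
    id = sprintf("effect_%s_%s_%s", source, role, target),
    substrates = rep(list(character()), n),
    products = lapply(target, identity),
    activators = pick("+"),
    inhibitors = pick("-"),
    modulators = pick("?"),
    reversible = FALSE,
    species = rep(list(character()), n)
  )
}

#' Read a knowledge base from KB-JSON
#'
#' KB-JSON is the package's interchange dialect:
#' `{"molecules": [{"id","kind","name","species":[...]}],`
#' `"reactions": [{"id","substrates":[...],"products":[...],"activators":[...],`
#' `"inhibitors":[...],"modulators":[...],"reversible":bool,"species":[...]}],`
#' `"effects": [{"source","target","sign":"+|-|?"}]}`.
#' Effect records are converted to regulated reactions on read via
#' [effect_to_reaction()], so the returned object contains reactions only.
#'
#' @param path Path to a KB-JSON file.
#' @param format Only `"kb-json"` is currently supported.
#' @return A `reg_kb` object.
#' @seealso [write_knowledge_base()] for the deterministic writer.
#' @examples
#' toy <- read_knowledge_base(
#'   system.file("extdata", "toy_kb.json", package = "keyreg")
#' )
#' toy
#' @export
read_knowledge_base <- function(path, format = "kb-json") {
  format <- match.arg(format, "kb-json")
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(sprintf("failed to parse '%s' as KB-JSON: %s",
                                      path, conditionMessage(e)))
  )
  mol_list <- raw$molecules %||% list()
  molecules <- tibble(
    id = purrr::map_chr(mol_list, function(m) m$id %||%
                          abort(sprintf("molecule without 'id' in '%s'", path))),
    kind = purrr::map_chr(mol_list, function(m) m$kind %||% "other"),
    name = purrr::map_chr(mol_list, function(m) m$name %||% m$id),
    species = purrr::map(mol_list, function(m) as.character(unlist(m$species)))
  )
  rxn_list <- raw$reactions %||% list()
  get_roles <- function(r, field) as.character(unlist(r[[field]]))
  reactions <- tibble(
    id = purrr::map_chr(rxn_list, function(r) r$id %||%
                          abort(sprintf("reaction without 'id' in '%s'", path))),
    substrates = purrr::map(rxn_list, get_roles, "substrates"),
    products = purrr::map(rxn_list, get_roles, "products"),
    activators = purrr::map(rxn_list, get_roles, "activators"),
    inhibitors = purrr::map(rxn_list, get_roles, "inhibitors"),
    modulators = purrr::map(rxn_list, get_roles, "modulators"),
    reversible = purrr::map_lgl(rxn_list, function(r) isTRUE(r$reversible)),
    species = purrr::map(rxn_list, get_roles, "species")
  )
  eff_list <- raw$effects %||% list()
  if (length(eff_list) > 0) {
    eff <- purrr::map_dfr(eff_list, function(e) {
      effect_to_reaction(
        e$source %||% abort(sprintf("effect without 'source' in '%s'", path)),
        e$target %||% abort(sprintf("effect without 'target' in '%s'", path)),
        e$sign %||% "?"
      )
    })
    reactions <- bind_rows(reactions, eff)
  }
  kb(molecules, reactions)
}

#' Write a knowledge base as canonical KB-JSON
#'
#' Molecules, reactions and all role sets are written sorted so output is
#' byte-deterministic; a read/write/read round trip is the identity.
#'
#' @param x A `reg_kb` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_knowledge_base <- function(x, path) {
  stopifnot(inherits(x, "reg_kb"))
  mol <- purrr::pmap(x$molecules, function(id, kind, name, species) {
    list(id = jsonlite::unbox(id), kind = jsonlite::unbox(kind),
         name = jsonlite::unbox(name), species = as.character(species))
  })
  rxn <- purrr::pmap(x$reactions, function(id, substrates, products, activators,
                                           inhibitors, modulators, reversible,
                                           species) {
    list(id = jsonlite::unbox(id),
         substrates = as.character(substrates),
         products = as.character(products),
         activators = as.character(activators),
         inhibitors = as.character(inhibitors),
         modulators = as.character(modulators),
         reversible = jsonlite::unbox(reversible),
         species = as.character(species))
  })
  json <- jsonlite::toJSON(list(molecules = mol, reactions = rxn),
                           pretty = TRUE, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Merge species-specific duplicate reactions
#'
#' Reactions sharing identical substrate and product sets are collapsed into
#' one reaction whose regulator sets are the per-role unions and whose
#' species tags are pooled; the merged reaction is reversible when at least
#' one original was. The smallest original id is kept.
#'
#' A molecule appearing with two different regulator roles among the
#' duplicates (e.g. activator in one, inhibitor in another) is a sign
#' conflict: an error by default, demoted to modulator when
#' `lenient = TRUE`.
#'
#' @param x A `reg_kb` object.
#' @param lenient Demote conflicting regulators to modulators instead of
#'   erroring.
#' @return A merged `reg_kb`. Idempotent.
#' @export
merge_cross_species <- function(x, lenient = FALSE) {
  stopifnot(inherits(x, "reg_kb"))
  rxn <- x$reactions
  if (nrow(rxn) == 0) return(x)
  key <- purrr::map2_chr(rxn$substrates, rxn$products, function(s, p) {
    paste(paste(s, collapse = "\x1f"), paste(p, collapse = "\x1f"), sep = "\x1e")
  })
  merged <- purrr::map_dfr(split(seq_len(nrow(rxn)), key), function(idx) {
    grp <- rxn[idx, ]
    if (nrow(grp) == 1) return(grp)
    act <- roleset(unlist(grp$activators))
    inh <- roleset(unlist(grp$inhibitors))
    mod <- roleset(unlist(grp$modulators))
    conflict <- unique(c(intersect(act, inh), intersect(act, mod),
                         intersect(inh, mod)))
    if (length(conflict) > 0) {
      if (!lenient) {
        abort(paste0("role conflict while merging reactions ",
                     paste(grp$id, collapse = ", "), ": ",
                     paste(conflict, collapse = ", "),
                     " (use lenient = TRUE to demote to modulator)"))
      }
      act <- setdiff(act, conflict)
      inh <- setdiff(inh, conflict)
      mod <- roleset(c(mod, conflict))
    }
    tibble(
      id = min(grp$id),
      substrates = grp$substrates[1], products = grp$products[1],
      activators = list(act), inhibitors = list(inh), modulators = list(mod),
      reversible = any(grp$reversible),
      species = list(roleset(unlist(grp$species)))
    )
  })
  kb(x$molecules, merged)
}

#' Default list of generic, non-limiting molecules
#'
#' Highly generic currency molecules participate in so many reactions that
#' they carry no regulatory information; they are removed from reaction role
#' sets before graph compilation. The default list has nine entries: ATP,
#' ADP, NTP, NDP, protein remnants, phosphate, Coenzyme A, water and H+.
#' `"protein_remnant"` is a reserved id that knowledge-base authors may map
#' to their own vocabulary; none of the ids is tied to an external namespace.
#'
#' @return A character vector of molecule ids.
#' @export
generic_molecule_ids <- function() {
  c("ATP", "ADP", "NTP", "NDP", "protein_remnant", "phosphate",
    "coenzyme_A", "water", "H+")
}

#' Remove generic molecules from all reaction roles
#'
#' Every occurrence of a generic id in any role of any reaction is deleted.
#' Reactions whose product set becomes empty are dropped (with a warning):
#' the regulated-reaction formalism requires every reaction to produce
#' something. The molecule table is left unchanged.
#'
#' @param x A `reg_kb` object.
#' @param generic_ids Molecule ids to strip; defaults to
#'   [generic_molecule_ids()].
#' @return A stripped `reg_kb`.
#' @export
strip_generic_molecules <- function(x, generic_ids = generic_molecule_ids()) {
  stopifnot(inherits(x, "reg_kb"))
  rxn <- x$reactions
  if (nrow(rxn) == 0 || length(generic_ids) == 0) return(x)
  for (col in c("substrates", "products", "activators", "inhibitors", "modulators")) {
    rxn[[col]] <- lapply(rxn[[col]], setdiff, y = generic_ids)
  }
  empty <- lengths(rxn$products) == 0
  if (any(empty)) {
    warn(sprintf("dropping %d reaction(s) with no product left after stripping: %s",
                 sum(empty), paste(rxn$id[empty], collapse = ", ")))
    rxn <- rxn[!empty, ]
  }
  kb(x$molecules, rxn)
}

#' Rank hub molecules by reaction participation
#'
#' Returns the `n` molecules involved in the most reactions (any role),
#' ordered by participation count descending with lexicographic id
#' tie-breaking, so the result is deterministic and
#' `rank_hub_molecules(x, n1)` is a prefix of `rank_hub_molecules(x, n2)`
#' for `n1 <= n2`. These hubs are the molecules excluded from neighborhood
#' expansion in [extract_neighborhood()].
#'
#' @param x A `reg_kb` object.
#' @param n Number of hubs; `n = 0` returns an empty vector.
#' @return A character vector of molecule ids.
#' @export
rank_hub_molecules <- function(x, n) {
  stopifnot(inherits(x, "reg_kb"), n >= 0)
  if (n == 0) return(character())
  counts <- x$index %>%
    dplyr::count(.data$molecule, name = "n_reactions") %>%
    arrange(desc(.data$n_reactions), .data$molecule)
  if (n > nrow(counts)) {
    warn(sprintf("n = %d exceeds the %d molecules participating in reactions; returning all",
                 n, nrow(counts)))
    n <- nrow(counts)
  }
  counts$molecule[seq_len(n)]
}
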