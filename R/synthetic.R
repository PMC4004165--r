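#' Configuration for the synthetic knowledge-base generator
#'
#' The generator emulates the qualitative regime of large curated
#' reaction-and-regulation knowledge bases: scale-free connectivity with a
#' degree exponent around 2 (hub metabolites created by preferential
#' attachment), a large excess of positive over negative regulatory edges,
#' enzymes regulating biochemical reactions, and planted transcription-factor
#' regulons (direct or once-indirected TF -> target chains) that serve as
#' ground truth for benchmarking. A fraction of the planted regulators are
#' protein-level molecules (complexes) with no gene counterpart, mirroring
#' regulators that only exist under "molecule" terminology.
#'
#' @param n_genes,n_metabolites,n_enzymes,n_tfs,n_reactions,n_effects Entity
#'   counts: genes, metabolites, enzyme proteins, planted transcription
#'   factors, metabolic reactions, and background gene-to-gene effects.
#' @param n_decoy_tfs Number of additional regulators with regulons of the
#'   same shape that are *not* part of the planted truth. Benchmarked TFs are
#'   a small subset of the regulators a knowledge base describes; without
#'   this background population, randomly shuffled target lists would still
#'   be dominated by the benchmark TFs themselves.
#' @param targets_per_tf Integer range (min, max) of targets per regulon.
#' @param indirection_depth Integer range of TF-to-target chain lengths
#'   (1 = direct effect, 2 = via one intermediate gene).
#' @param inhibitor_fraction,modulator_fraction Probability that a regulatory
#'   edge is negative / of unknown sign (the remainder is positive).
#' @param reversible_fraction Probability that a metabolic reaction is marked
#'   reversible.
#' @param enzyme_fraction Probability that a metabolic reaction carries an
#'   enzyme regulator.
#' @param protein_tf_fraction Fraction of planted regulators that are
#'   protein-kind molecules without a gene node.
#' @param hub_strength Preferential-attachment exponent: metabolite slots are
#'   drawn with weight `(participation + 1) ^ hub_strength`.
#' @param seed Integer seed; every random draw derives from it through
#'   per-phase sub-seeds, so identical configurations generate byte-identical
#'   knowledge bases.
#' @return A `synthesis_config` list.
#' @export
synthesis_config <- function(n_genes = 2400, n_metabolites = 400,
                             n_enzymes = 60, n_tfs = 20, n_reactions = 500,
                             n_effects = 80, n_decoy_tfs = 80,
                             targets_per_tf = c(10, 30),
                             indirection_depth = c(1, 2),
                             inhibitor_fraction = 0.05,
                             modulator_fraction = 0.05,
                             reversible_fraction = 0.1,
                             enzyme_fraction = 0.5,
                             protein_tf_fraction = 0.25,
                             hub_strength = 0.75,
                             seed = 1) {
  cfg <- list(
    n_genes = n_genes, n_metabolites = n_metabolites, n_enzymes = n_enzymes,
    n_tfs = n_tfs, n_reactions = n_reactions, n_effects = n_effects,
    n_decoy_tfs = n_decoy_tfs,
    targets_per_tf = as.integer(targets_per_tf),
    indirection_depth = as.integer(indirection_depth),
    inhibitor_fraction = inhibitor_fraction,
    modulator_fraction = modulator_fraction,
    reversible_fraction = reversible_fraction,
    enzyme_fraction = enzyme_fraction,
    protein_tf_fraction = protein_tf_fraction,
    hub_strength = hub_strength, seed = as.integer(seed)
  )
  probs <- c(inhibitor_fraction, modulator_fraction, reversible_fraction,
             enzyme_fraction, protein_tf_fraction)
  stopifnot(all(probs >= 0 & probs <= 1),
            inhibitor_fraction + modulator_fraction <= 1,
            all(unlist(cfg[1:6]) >= 0),
            length(cfg$targets_per_tf) == 2,
            cfg$targets_per_tf[1] <= cfg$targets_per_tf[2],
            length(cfg$indirection_depth) == 2)
  if (cfg$targets_per_tf[2] > n_genes) {
    abort("infeasible config: more planted targets per regulon than genes")
  }
  structure(cfg, class = "synthesis_config")
}

sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65011 * 31607 + k * 7919) %% 2147483629)
}

draw_signs <- function(n, cfg) {
  sample(c("-", "?", "+"), n, replace = TRUE,
         prob = c(cfg$inhibitor_fraction, cfg$modulator_fraction,
                  1 - cfg$inhibitor_fraction - cfg$modulator_fraction))
}

combine_signs <- function(s1, s2) {
  ifelse(s1 == "?" | s2 == "?", "?", ifelse(s1 == s2, "+", "-"))
}

#' Generate a synthetic knowledge base with planted regulons
#'
#' Builds, deterministically from `config$seed`: preferential-attachment
#' metabolic reactions (creating hub metabolites), enzyme regulators on a
#' fraction of reactions, enzyme-coding genes, planted TF regulons realised
#' as regulatory effects at the configured indirection depth, and background
#' gene-to-gene effects. The planted truth records, for every TF, its
#' targets and the sign implied by parity along the planted chain; a
#' generation-time self-check verifies that each planted target is reachable
#' from its TF in the compiled causality graph with that sign.
#'
#' @param config A [synthesis_config()].
#' @return A list with `kb` (a `reg_kb`) and `truth`, itself a list with
#'   `regulons` (tibble `tf`, `target`, `sign`) and `forms` (tibble `tf`,
#'   `form`: the protein form mediating a gene-kind TF's regulation).
#' @export
generate_knowledge_base <- function(config = synthesis_config()) {
  stopifnot(inherits(config, "synthesis_config"))
  cfg <- config
  genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  mets <- sprintf("M%03d", seq_len(cfg$n_metabolites))
  enzymes <- sprintf("E%03d", seq_len(cfg$n_enzymes))
  tfs <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  n_protein_tf <- round(cfg$protein_tf_fraction * cfg$n_tfs)
  tf_is_protein <- seq_len(cfg$n_tfs) <= n_protein_tf
  # A gene-kind regulator is expressed as a protein and acts through an
  # active complex (gene -> protein -> complex -> targets): three tied
  # molecule-level entry points for the same regulon, as complexes carrying
  # a TF do in curated knowledge bases. Protein-kind regulators act directly.
  proteins_of <- ifelse(tf_is_protein, tfs, paste0(tfs, "p"))
  forms <- ifelse(tf_is_protein, tfs, paste0(tfs, "c"))
  xtfs <- if (cfg$n_decoy_tfs > 0) sprintf("XTF%02d", seq_len(cfg$n_decoy_tfs)) else character()
  xtf_is_protein <- seq_len(cfg$n_decoy_tfs) <= round(cfg$protein_tf_fraction * cfg$n_decoy_tfs)
  xproteins_of <- ifelse(xtf_is_protein, xtfs, paste0(xtfs, "p"))
  xforms <- ifelse(xtf_is_protein, xtfs, paste0(xtfs, "c"))

  # Phase 1: metabolic reactions with preferential attachment on metabolites.
  part <- setNames(numeric(length(mets)), mets)   # participation counts
  reactions <- withr::with_seed(sub_seed(cfg$seed, 1), {
    purrr::map_dfr(seq_len(cfg$n_reactions), function(i) {
      w <- (part + 1)^cfg$hub_strength
      ns <- 1 + stats::rbinom(1, 2, 0.35)
      np <- 1 + stats::rbinom(1, 1, 0.35)
      picked <- sample(mets, ns + np, prob = w)
      subs <- picked[seq_len(ns)]
      prods <- picked[ns + seq_len(np)]
      part[picked] <<- part[picked] + 1
      has_enz <- stats::runif(1) < cfg$enzyme_fraction
      act <- inh <- mod <- character()
      if (has_enz) {
        enz <- sample(enzymes, 1)
        role <- draw_signs(1, cfg)
        if (role == "+") act <- enz else if (role == "-") inh <- enz else mod <- enz
      }
      tibble(id = sprintf("R%04d", i),
             substrates = list(subs), products = list(prods),
             activators = list(act), inhibitors = list(inh),
             modulators = list(mod),
             reversible = stats::runif(1) < cfg$reversible_fraction,
             species = list(sample(c("human", "mouse", "rat"), 1)))
    })
  })

  # Phase 2: enzyme-coding genes and TF protein forms.
  coding <- withr::with_seed(sub_seed(cfg$seed, 2), {
    effects_block(vapply(enzymes, function(e) sample(genes, 1), character(1)),
                  enzymes, rep("+", length(enzymes)))
  })
  form_fx <- bind_rows(
    effects_block(tfs[!tf_is_protein], proteins_of[!tf_is_protein],
                  rep("+", sum(!tf_is_protein))),
    effects_block(proteins_of[!tf_is_protein], forms[!tf_is_protein],
                  rep("+", sum(!tf_is_protein)))
  )

  # One regulon: direct effects or one-intermediate chains from the
  # regulator's acting form(s), with parity-implied target signs. When
  # several acting forms are supplied (a regulator working through multiple
  # complexes), targets are spread across them round-robin. Returns effect
  # triplets (source, target, sign) rather than built reactions.
  make_regulon <- function(reg_id, acting_forms) {
    n_t <- sample(seq(cfg$targets_per_tf[1], cfg$targets_per_tf[2]), 1)
    targets <- sample(genes, n_t)
    depth <- sample(seq(cfg$indirection_depth[1], cfg$indirection_depth[2]),
                    n_t, replace = TRUE)
    acting <- rep_len(acting_forms, n_t)
    fx_src <- fx_tgt <- fx_sgn <- character(0)
    implied <- character(n_t)
    for (j in seq_len(n_t)) {
      if (depth[j] == 1) {
        s <- draw_signs(1, cfg)
        fx_src <- c(fx_src, acting[j]); fx_tgt <- c(fx_tgt, targets[j])
        fx_sgn <- c(fx_sgn, s)
        implied[j] <- s
      } else {
        mid <- sample(setdiff(genes, targets[j]), 1)
        s1 <- draw_signs(1, cfg); s2 <- draw_signs(1, cfg)
        fx_src <- c(fx_src, acting[j], mid)
        fx_tgt <- c(fx_tgt, mid, targets[j])
        fx_sgn <- c(fx_sgn, s1, s2)
        implied[j] <- combine_signs(s1, s2)
      }
    }
    list(truth = tibble(tf = reg_id, target = targets, sign = implied),
         fx = tibble(src = fx_src, tgt = fx_tgt, sgn = fx_sgn))
  }

  # Phase 3: planted regulons (the benchmark truth).
  regulon <- withr::with_seed(sub_seed(cfg$seed, 3), {
    purrr::map(seq_len(cfg$n_tfs), function(i) make_regulon(tfs[i], forms[i]))
  })
  truth_regulons <- purrr::map_dfr(regulon, "truth") %>%
    arrange(.data$tf, .data$target)
  reg_fx <- bind_rows(purrr::map(regulon, "fx"))
  regulon_fx <- effects_block(reg_fx$src, reg_fx$tgt, reg_fx$sgn)

  # Phase 3b: decoy regulons: regulators with the same structure as the
  # planted TFs (acting through one protein form, or protein-kind outright)
  # that are not part of the benchmark truth.
  decoy_triplets <- withr::with_seed(sub_seed(cfg$seed, 7), {
    bind_rows(purrr::map(seq_len(cfg$n_decoy_tfs),
                         function(i) make_regulon(xtfs[i], xforms[i])$fx))
  })
  decoy_fx <- bind_rows(
    effects_block(xtfs[!xtf_is_protein], xproteins_of[!xtf_is_protein],
                  rep("+", sum(!xtf_is_protein))),
    effects_block(xproteins_of[!xtf_is_protein], xforms[!xtf_is_protein],
                  rep("+", sum(!xtf_is_protein))),
    effects_block(decoy_triplets$src, decoy_triplets$tgt, decoy_triplets$sgn)
  )

  # Phase 4: background regulatory noise.
  background <- withr::with_seed(sub_seed(cfg$seed, 4), {
    src <- tgt <- sgn <- character(cfg$n_effects)
    for (i in seq_len(cfg$n_effects)) {
      pair <- sample(genes, 2)
      src[i] <- pair[1]; tgt[i] <- pair[2]; sgn[i] <- draw_signs(1, cfg)
    }
    effects_block(src, tgt, sgn)
  })

  all_rxn <- bind_rows(reactions, coding, form_fx, regulon_fx,
                       decoy_fx, background)
  all_rxn <- all_rxn[!duplicated(all_rxn$id), ]
  molecules <- bind_rows(
    tibble(id = genes, kind = "gene"),
    tibble(id = mets, kind = "metabolite"),
    tibble(id = enzymes, kind = "protein"),
    tibble(id = tfs, kind = ifelse(tf_is_protein, "protein", "gene")),
    tibble(id = proteins_of[!tf_is_protein], kind = "protein"),
    tibble(id = forms[!tf_is_protein], kind = "complex"),
    tibble(id = xtfs, kind = ifelse(xtf_is_protein, "protein", "gene")),
    tibble(id = xproteins_of[!xtf_is_protein], kind = "protein"),
    tibble(id = xforms[!xtf_is_protein], kind = "complex")
  )
  out_kb <- kb(molecules, all_rxn)
  truth <- list(
    regulons = truth_regulons,
    forms = bind_rows(
      tibble(tf = tfs[!tf_is_protein], form = proteins_of[!tf_is_protein]),
      tibble(tf = tfs[!tf_is_protein], form = forms[!tf_is_protein])
    ) %>% arrange(.data$tf, .data$form)
  )
  check_planted_truth(out_kb, truth)
  list(kb = out_kb, truth = truth)
}

# Generation-time invariant: every planted target must be reachable from its
# TF's quantity node with the implied sign in the compiled causality graph.
check_planted_truth <- function(kb, truth) {
  graph <- build_causality_graph(kb)
  closure <- signed_reachability_closure(
    graph, sources = quantity_node(unique(truth$regulons$tf))
  )
  ok <- purrr::pmap_lgl(truth$regulons, function(tf, target, sign) {
    sign %in% influence_labels(closure, quantity_node(tf), quantity_node(target))
  })
  if (!all(ok)) {
    bad <- truth$regulons[!ok, ]
    abort(sprintf("planted-truth reachability violated for %d pair(s), e.g. %s -> %s (%s)",
                  nrow(bad), bad$tf[1], bad$target[1], bad$sign[1]))
  }
  invisible(TRUE)
}

#' Derive a benchmark target list from the planted truth
#'
#' Returns the TF's planted targets with their implied signs, optionally
#' perturbed: with probability `sign_noise` each sign is erased to `?`
#' (`noise_mode = "erase"`, emulating benchmark lists that carry no sign
#' information) or flipped (`noise_mode = "flip"`). `drop_tf` removes the TF
#' itself from the list when present, emulating the regulator being absent
#' from the differential-expression call.
#'
#' @param truth A `truth` list from [generate_knowledge_base()].
#' @param tf A TF id present in the truth.
#' @param sign_noise Per-target perturbation probability.
#' @param noise_mode `"erase"` or `"flip"`.
#' @param drop_tf Remove the TF from its own target list.
#' @param seed Seed for the noise draws.
#' @return A target-list tibble.
#' @export
derive_target_list <- function(truth, tf, sign_noise = 0,
                               noise_mode = c("erase", "flip"),
                               drop_tf = TRUE, seed = 1) {
  noise_mode <- match.arg(noise_mode)
  rows <- truth$regulons[truth$regulons$tf == tf, ]
  if (nrow(rows) == 0) abort(sprintf("unknown TF '%s'", tf))
  signs <- rows$sign
  if (sign_noise > 0) {
    signs <- withr::with_seed(sub_seed(seed, 5), {
      hit <- stats::runif(length(signs)) < sign_noise
      if (noise_mode == "erase") {
        ifelse(hit, "?", signs)
      } else {
        flip <- c("+" = "-", "-" = "+", "?" = "?")
        ifelse(hit, flip[signs], signs)
      }
    })
  }
  out <- target_list(rows$target, signs)
  if (drop_tf) out <- out[out$molecule_id != tf, ]
  out
}

#' Shuffle entries between target lists (negative control)
#'
#' Pools the entries of all lists and redeals them at random, preserving
#' each list's length, to build biologically irrelevant target lists with
#' the same size profile. Redealing is retried (up to 100 times) until no
#' list receives its original entry multiset.
#'
#' @param lists A list of target-list tibbles (at least two).
#' @param seed Seed for the permutation.
#' @return A list of shuffled target-list tibbles, same lengths, same pooled
#'   entries.
#' @export
shuffle_target_lists <- function(lists, seed = 1) {
  stopifnot(length(lists) >= 2)
  pool <- bind_rows(lists)
  sizes <- vapply(lists, nrow, integer(1))
  key <- function(df) paste(sort(paste(df$molecule_id, df$sign)), collapse = "|")
  orig <- vapply(lists, key, character(1))
  deal <- function() {
    # Redeal from a random permutation, taking for each list (largest first)
    # the first entries with pairwise-distinct molecule ids, so list lengths
    # are preserved and the within-list uniqueness invariant holds.
    remaining <- pool[sample.int(nrow(pool)), ]
    out <- vector("list", length(sizes))
    for (i in order(sizes, decreasing = TRUE)) {
      idx <- which(!duplicated(remaining$molecule_id))
      if (length(idx) < sizes[i]) return(NULL)
      idx <- idx[seq_len(sizes[i])]
      out[[i]] <- target_list(remaining$molecule_id[idx], remaining$sign[idx])
      remaining <- remaining[-idx, , drop = FALSE]
    }
    out
  }
  withr::with_seed(sub_seed(seed, 6), {
    last <- NULL
    for (try in seq_len(100)) {
      shuffled <- deal()
      if (is.null(shuffled)) next
      last <- shuffled
      if (!any(vapply(shuffled, key, character(1)) == orig)) return(shuffled)
    }
    if (is.null(last)) abort("could not redeal the pooled targets into valid lists")
    warn("a redealt list still matches its original entries after 100 tries")
    last
  })
}
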