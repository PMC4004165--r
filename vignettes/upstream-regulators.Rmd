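---
title: "Inferring upstream regulators from signed causality graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring upstream regulators from signed causality graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keyreg)
```

High-throughput experiments end in lists of differentially abundant
molecules — transcripts, proteins, metabolites — and the question that
matters is rarely "which pathways are enriched" but "what, upstream, could
have caused this". keyreg answers that question against a knowledge base of
biochemical reactions and regulatory effects: it proposes a ranked,
deliberately small set of candidate regulators (transcription factors,
enzymes, protein complexes) able to explain the observed variations with a
consistent sign.

This vignette is the package's account of the model, its parameters, the
numerical choices made where the design was genuinely open, and what the
synthetic benchmark does and does not demonstrate.

## The regulated-reaction formalism

Knowledge bases mix two kinds of records: *reactions* (substrates are
catabolized into products) and *effects* (a molecule changes the production
rate of another, with a positive, negative or unknown sign). Both are
unified here as **regulated reactions**: a substrate set, a non-empty
product set, three pairwise-disjoint regulator sets (activators, inhibitors,
modulators), and a reversibility flag. An effect `a -> b` becomes an
irreversible reaction producing `b` from an unmodeled, non-limiting
substrate, with `a` as the regulator in the role matching the effect's sign
(`effect_to_reaction()`). This keeps mass transfer (substrates/products)
cleanly separate from regulation (regulators are not consumed).

Two normalisations are applied before analysis:

* **Cross-species merging** (`merge_cross_species()`): reactions with
  identical substrate and product sets are collapsed; regulator sets are
  united per role, species tags pooled, and the merged reaction is
  reversible when any original was. A molecule appearing with two different
  roles across the duplicates is a sign conflict — an error by default,
  demoted to modulator under `lenient = TRUE`, because silently discarding a
  sign would bias downstream parity computations.
* **Generic-molecule stripping** (`strip_generic_molecules()`): currency
  molecules (ATP, ADP, NTP, NDP, protein remnants, phosphate, Coenzyme A,
  water, H+) participate in so many reactions that they connect everything
  to everything; they are removed from all role sets. A reaction left
  without products is dropped, since the formalism requires every reaction
  to produce something. `protein_remnant` is a reserved id the knowledge-base
  author may map to their own vocabulary.

## The causality graph

Under a quasi-stationary reading, each reaction's speed is an increasing
function of its substrates' availability and its activators' amounts, a
decreasing function of its inhibitors' amounts, and a monotone function of
unknown sign of its modulators'. `build_causality_graph()` encodes this as a
signed directed graph with three node kinds: `quantity(M)` (the amount of
molecule M), `availability(M)` (the summed speed of the reactions producing
M; created only for molecules that are a substrate somewhere), and `v(R)`
(the speed of reaction R). The per-reaction edge rules are documented in
`emit_reaction_edges()`; the only subtle ones are the mass-consumption
rules: an explicitly regulated reaction drains its substrates
(`v(R) -(-)-> quantity(S)`), while an unregulated reaction is limited by its
substrates, giving a negative edge between each ordered pair of distinct
substrates' availability and quantity. All reactions compile forward-only;
reversibility does not change the emitted edges. The per-reaction edge count
is exactly `s + a + i + m + p + p' + (s if regulated else s(s-1))`, which
the test suite checks on randomly generated knowledge bases.

A deliberate boundary case: a reaction with a single substrate and no
regulator triggers neither mass-consumption rule, and no feedback edge is
emitted for it.

## Sign propagation over walks

Influence between nodes is defined by path signs: a positive (negative)
influence exists when a path with an even (odd) number of negative edges and
no unknown edge exists; any path through an unknown-sign edge yields the
unknown label. `signed_reachability_closure()` computes, for every ordered
node pair, the full set of achievable labels, by breadth-first reachability
on the product graph over states (node, even/odd/unknown) — unknown is
absorbing.

The closure is over **walks**, not simple paths. With cycles, parity
reachability over walks is well defined and polynomial, whereas asking for a
simple path of a given sign is NP-hard; a two-cycle `x -(+)-> y, y -(-)-> x`
therefore carries both labels on `(x, y)`, which is the honest answer to
"could x drive y up or down". A pair can hold `+`, `-` and `?`
simultaneously; the labels are all kept and the scoring layer decides what
counts (see below). Self-influence is excluded throughout: a walk must have
length at least one, and a molecule never explains itself.

`enumerate_walk_signs()` is the independent test oracle: exhaustive
enumeration of walks up to length `3|V|` (the product graph has `3|V|`
states, so this bound guarantees equality with the closure) on graphs of at
most 12 nodes. The equivalence is asserted over 500 seeded random graphs.

## Explanatory view and scoring

Each node is conceptually split into an up and a down variant; the variant
contradicting a target's observed sign is removed
(`build_explanatory_view()`). A signed candidate hypothesis `(C, s)`
explains target `T` when the closure label from `quantity(C)` to
`quantity(T)` matches `s` times the observed variation; targets with unknown
signs accept either variation.

Two scores are attached to every candidate (`score_candidates()`):

* **coverage** — the number of targets explained with a consistent sign;
* **specificity** — `coverage × (1 − p)`, where `p` is the hypergeometric
  upper-tail probability `P(X ≥ k)` of drawing `k` targets in `n` draws from
  an urn with one ball per gene in the compiled sub-graph (`K` target balls,
  `N` total). A candidate that influences half the graph is penalised
  relative to one specific to the targets it explains.

Numerical and policy choices, each overridable:

* The inclusive tail (`P(X ≥ k)`) is used — the standard enrichment
  convention.
* `count_unknown = TRUE` by default: influence established only through
  modulator (unknown-sign) walks counts toward coverage, since modulators
  are admitted as regulators; `count_unknown = FALSE` restricts scoring to
  signed evidence.
* The urn holds genes by default (`urn_kinds = "gene"`); when the compiled
  sub-graph contains no gene at all (e.g. a purely metabolic neighborhood)
  `find_regulators()` widens the urn to all kinds with a warning rather
  than failing.
* A candidate's two sign hypotheses are collapsed to one reported row: the
  concordant one if the candidate itself was observed with a known sign,
  otherwise the better-scoring one (higher coverage, then specificity, tie
  to `+`). Ranking uses the collapsed score.

Ranking (`rank_with_ties()`) keeps tie groups whole: candidates with exactly
equal scores are *ex aequo*, and the retained list is the smallest prefix of
groups covering the requested size, with the boundary group marked partial.
Benchmark success treats ex-aequo candidates as randomly ordered: a known
regulator in a boundary group of size `g` with `m` retained slots scores
`m/g`, generalised to `1 − C(g−a, m)/C(g, m)` when `a` acceptable ids (the
regulator and the complexes carrying it) share the group. Answer sets of
50–100 candidates are a good trade-off between success rate and review
effort.

## Neighborhood extraction and hubs

The model is restricted to the targets' reaction neighborhood
(`extract_neighborhood()`): reactions containing a frontier molecule in any
role are selected, the frontier grows to the selected reactions' molecules,
and the process repeats for `levels` rounds (default 3). The most connected
molecules ("hubs", `rank_hub_molecules()`, ties broken lexicographically for
reproducibility) are excluded from the frontier — they would otherwise pull
in the whole knowledge base — but are retained *inside* selected reactions:
well-connected complexes can still be candidates. `drop_hubs = TRUE` gives
the stricter reading that deletes them outright.

`hub_n = 1000` (the default) is meant for knowledge bases with on the order
of 10^5 molecules, where it is the top ~0.6%. The synthetic benchmark
(~2,400 molecules) uses `hub_n = 10`, the same fraction at its scale.

## The synthetic knowledge bases and what the benchmark shows

No redistributable knowledge base at realistic scale exists, so the package
ships a generator (`generate_knowledge_base()`) whose defaults define the
benchmark's study conditions:

* a metabolic layer of 500 reactions over 400 metabolites, substrates and
  products drawn by preferential attachment (`hub_strength = 0.75`), half
  the reactions carrying an enzyme regulator, 10% reversible;
* 20 planted transcription factors with regulons of 10–30 gene targets at
  indirection depth 1–2, each gene-kind TF expressed as a protein that forms
  an active complex doing the regulating (gene → protein → complex →
  targets), so one regulator has three exactly-tied molecule-level entries —
  as TF-carrying complexes do in curated knowledge bases. A quarter of TFs
  are protein-kind outright, with no gene node: they are findable only under
  "molecule" terminology;
* 80 decoy regulators, structurally identical to the planted TFs but absent
  from the benchmark truth. They matter: benchmarked TFs are a small subset
  of the regulators a knowledge base describes, and without this background
  population randomly shuffled target lists would still be "explained" by
  the benchmark TFs themselves, flattening the true-vs-control gap;
* regulatory signs 90% positive, 5% negative, 5% unknown — curated
  knowledge bases show a strong excess of positive over negative edges;
* 1,100 genes, so the degree distribution keeps a heavy singleton mass.

At these defaults the molecule–reaction degree distribution fits a power law
with exponent gamma between roughly 1.85 and 2.0 across seeds (checked over
ten seeds against the 1.8–2.5 band), the same scale-free regime reported for
metabolic networks. `degree_power_law_fit()` fits `log10 P(k)` against
`log10 k` by least squares over occupied degree bins on the undirected
projection — a deliberate, documented simplification; rigorous
maximum-likelihood power-law fitting with cutoff selection is out of scope,
and the fit quality `r` is reported as |Pearson| × 100.

Planted target signs are the actual path parities of the planted chains
(verified at generation time), so a perfect method can score them; the
benchmark then erases signs (`sign_noise = 1`, mode `"erase"`) because
reference TF-target lists carry no direction information, and drops the TF
from its own list. `run_benchmark()` reproduces the published protocol
shape: success-at-top-n for both scores, under two solution terminologies —
the `gene` view counts a find only when the regulator's gene id is retained,
the `molecule` view also accepts the protein form or active complex carrying
it. Both views read the same ranking over all molecule kinds, so
molecule-view success dominates gene-view success at every cutoff by
construction. A shuffled-list control (`shuffle_target_lists()` pools and
redeals entries, preserving list lengths) measures chance-level success.

With the default conditions (seed 7), the planted regulator is recovered in
the top 10 by specificity with mean probability 1.0 in the molecule view,
while the shuffled control stays at or below 0.2 — the qualitative
true-vs-chance gap of the original evaluation at desk scale. The gene view
plateaus lower: protein-kind TFs have no gene id to find, and a TF whose
protein form lands in the hub list cannot be traced back to its gene within
the neighborhood bound. Both effects have real-world analogues (regulators
mappable only as complexes; well-connected regulators), and they are why
the molecule view dominates the gene view at every cutoff.

What passing this benchmark does *not* show: the generator's regulons are
cleaner than curated ones (no missing edges, no cross-species id noise, no
stoichiometry), its metabolic layer ignores mass balance, and its scale is
two orders of magnitude below a production knowledge base. The benchmark
validates the machinery — compilation, sign propagation, scoring, tie
handling — not biological recall on real data.

## Degenerate inputs and edge policies

* Empty knowledge base or empty neighborhood: empty graph, empty candidate
  table, warning — never an error.
* Seeds absent from the knowledge base are dropped with a counted warning.
* `rank_hub_molecules(x, n)` with `n` beyond the molecule count returns all
  molecules with a warning.
* Benchmark cases whose known regulator is missing from the knowledge base
  are dropped and counted, mirroring unmappable reference lists.
* Parallel edges with different signs are kept; exact duplicates are
  collapsed.
* All writers sort their output; identical inputs and seed give
  byte-identical files (the test suite asserts this for every CLI
  subcommand).

## Problem sizes used by the tests

The unit suite works on 8–14-molecule knowledge bases and 12-node signed
graphs where exhaustive oracles are feasible; the end-to-end benchmark runs
the 20-TF default configuration once (true and shuffled), and topology
checks span ten generator seeds. These sizes were chosen so the full
validation, including the 500-graph closure-equivalence sweep and the
exhaustive hypergeometric check up to N = 25, completes in minutes on one
CPU.

## Known limitations

* Sign prediction / consistency checking over the explanatory graph is not
  implemented; the closure exposes labels, it does not reconcile them.
* No multiple-testing correction across candidates — the specificity score
  is a ranking device, not a calibrated p-value.
* Stoichiometry is not modeled; duplicate reactions are merged on substrate
  and product sets alone.
* Identifier mapping across namespaces is the caller's responsibility;
  KB-JSON ids are opaque strings.
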