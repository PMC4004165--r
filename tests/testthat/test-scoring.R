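# Small knowledge base: TF activates g1 and g2; inhibitor chain to g3;
# bystander genes reachable from a broad regulator.
scoring_kb <- function() {
  kb(
    molecules = tibble::tibble(
      id = c("TF", "C", "B", "g1", "g2", "g3", "g4", "g5"),
      kind = c("gene", "gene", "gene", "gene", "gene", "gene", "gene", "gene")
    ),
    reactions = dplyr::bind_rows(
      effect_to_reaction("TF", "g1", "+"),
      effect_to_reaction("TF", "g2", "+"),
      effect_to_reaction("C", "g3", "-"),
      effect_to_reaction("B", "g1", "+"),
      effect_to_reaction("B", "g2", "+"),
      effect_to_reaction("B", "g4", "+"),
      effect_to_reaction("B", "g5", "+")
    )
  )
}

scoring_view <- function(x = scoring_kb(), targets) {
  g <- build_causality_graph(x)
  cl <- signed_reachability_closure(g)
  build_explanatory_view(cl, targets)
}

test_that("upper-tail probabilities match hand calculations and constraints", {
  expect_equal(hypergeometric_upper_tail(10, 5, 2, 2),
               choose(5, 2) / choose(10, 2))
  expect_equal(hypergeometric_upper_tail(10, 5, 2, 0), 1)
  expect_equal(hypergeometric_upper_tail(8, 8, 3, 2), 1)
  expect_error(hypergeometric_upper_tail(5, 6, 2, 1), "invalid")
  expect_error(hypergeometric_upper_tail(5, 3, 2, 3), "invalid")
})

test_that("upper tail agrees with exhaustive enumeration for small urns", {
  for (N in c(4, 7, 12)) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeometric_upper_tail(N, K, n, k),
                       hyper_tail_oracle(N, K, n, k), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("coverage counts sign-consistent explanations only", {
  v <- scoring_view(targets = target_list(c("g1", "g2"), "+"))
  expect_equal(coverage_score(v, "TF", "+")$coverage, 2)
  expect_equal(coverage_score(v, "TF", "-")$coverage, 0)
  # a candidate with no outgoing influence explains nothing
  expect_equal(coverage_score(v, "g3", "+")$coverage, 0)
  # target reachable only via an inhibitor edge needs the down hypothesis
  v3 <- scoring_view(targets = target_list("g3", "+"))
  expect_equal(coverage_score(v3, "C", "-")$coverage, 1)
  expect_equal(coverage_score(v3, "C", "+")$coverage, 0)
  # unknown target signs count either variation
  vu <- scoring_view(targets = target_list(c("g1", "g3"), "?"))
  expect_equal(coverage_score(vu, "TF", "+")$coverage, 1)
  expect_equal(coverage_score(vu, "C", "+")$coverage, 1)
})

test_that("modulator-mediated influence counts only when count_unknown", {
  x <- kb(
    molecules = tibble::tibble(id = c("M", "g1"), kind = "gene"),
    reactions = effect_to_reaction("M", "g1", "?")
  )
  v <- scoring_view(x, target_list("g1", "+"))
  cs <- coverage_score(v, "M", "+", count_unknown = TRUE)
  expect_equal(cs$coverage, 1)
  expect_equal(cs$explained$label, "?")
  expect_equal(coverage_score(v, "M", "+", count_unknown = FALSE)$coverage, 0)
})

test_that("candidate scores combine coverage with the hypergeometric tail", {
  v <- scoring_view(targets = target_list(c("g1", "g2"), "+"))
  sc <- score_candidates(v, scoring_kb())
  tf <- sc[sc$candidate == "TF", ]
  b <- sc[sc$candidate == "B", ]
  expect_equal(tf$coverage, 2)
  expect_equal(tf$sign, "+")
  expect_equal(b$coverage, 2)
  # urn: 8 genes, 2 white; TF influences 2, B influences 4
  expect_equal(tf$n_influenced, 2)
  expect_equal(b$n_influenced, 4)
  expect_equal(tf$p, hypergeometric_upper_tail(8, 2, 2, 2))
  expect_equal(b$p, hypergeometric_upper_tail(8, 2, 4, 2))
  expect_equal(tf$specificity, 2 * (1 - tf$p))
  # equal coverage, fewer influenced genes => strictly more specific
  expect_gt(tf$specificity, b$specificity)
  # zero coverage forces zero specificity
  expect_true(all(sc$specificity[sc$coverage == 0] == 0))
})

test_that("a candidate observed with a known sign keeps the concordant hypothesis", {
  x <- kb(
    molecules = tibble::tibble(id = c("TF", "g1"), kind = "gene"),
    reactions = effect_to_reaction("TF", "g1", "-")
  )
  # TF observed down; its down hypothesis explains g1 up
  v <- scoring_view(x, target_list(c("TF", "g1"), c("-", "+")))
  sc <- score_candidates(v, x)
  tf <- sc[sc$candidate == "TF", ]
  expect_equal(tf$sign, "-")
  expect_equal(tf$coverage, 1)
})

test_that("specificity decreases in the number of influenced urn members", {
  # direct parametric check of the tail monotonicity backing the invariant
  p <- vapply(2:7, function(n) hypergeometric_upper_tail(20, 3, n, 2), 1)
  expect_true(all(diff(p) > 0))
  spec <- 2 * (1 - p)
  expect_true(all(diff(spec) < 0))
})

test_that("tie groups are whole, ordered, and the boundary group is partial", {
  sc <- tibble::tibble(
    candidate = c("a", "b", "c", "d"),
    kind = "gene", sign = "+",
    coverage = c(5L, 5L, 5L, 2L), n_influenced = 5L,
    p = 0.5, specificity = c(5, 5, 5, 2), explained = list(tibble::tibble())
  )
  r <- rank_with_ties(sc, key = "specificity", top_n = 2)
  expect_equal(r$group, c(1L, 1L, 1L, 2L))
  expect_true(all(r$retained[1:3]))
  expect_false(r$retained[4])
  expect_true(all(r$partial[1:3]))
  # all distinct: plain truncation
  sc2 <- dplyr::mutate(sc, specificity = c(4, 3, 2, 1))
  r2 <- rank_with_ties(sc2, key = "specificity", top_n = 2)
  expect_equal(r2$retained, c(TRUE, TRUE, FALSE, FALSE))
  expect_false(any(r2$partial))
  # top_n beyond the total retains everything
  r3 <- rank_with_ties(sc2, key = "specificity", top_n = 99)
  expect_true(all(r3$retained))
})

test_that("hit probability follows the ex-aequo slot rule", {
  sc <- tibble::tibble(
    candidate = sprintf("c%02d", 1:12),
    kind = "gene", sign = "+",
    coverage = 1L, n_influenced = 1L, p = 0.5,
    specificity = c(9, rep(5, 10), 1), explained = list(tibble::tibble())
  )
  r <- rank_with_ties(sc, key = "specificity", top_n = 5)
  # boundary group of 10 with 4 retained slots
  expect_equal(hit_probability(r, "c05", top_n = 5), 4 / 10)
  expect_equal(hit_probability(r, "c01", top_n = 5), 1)
  expect_equal(hit_probability(r, "c12", top_n = 5), 0)
  expect_warning(p0 <- hit_probability(r, "nope", top_n = 5), "absent")
  expect_equal(p0, 0)
  # several acceptable ids in the boundary group: at least one retained
  expect_equal(hit_probability(r, c("c05", "c06"), top_n = 5),
               1 - choose(8, 4) / choose(10, 4))
  # summed singleton probabilities inside one boundary group never exceed slots
  singles <- vapply(sprintf("c%02d", 2:11),
                    function(id) hit_probability(r, id, top_n = 5), 1)
  expect_lte(sum(singles), 4 + 1e-9)
})
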