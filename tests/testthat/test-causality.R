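edge_key <- function(e) sprintf("%s %s %s", e$src, e$sign, e$dst)

test_that("a regulated two-substrate reaction emits exactly the six rule edges", {
  r2 <- tibble::tibble(
    id = "r2", substrates = list(c("b", "c")), products = list("d"),
    activators = list("e"), inhibitors = list(character()),
    modulators = list(character()), reversible = FALSE
  )
  e <- emit_reaction_edges(r2, availability_universe = c("b", "c"))
  expect_setequal(edge_key(e), c(
    "A:b + V:r2", "A:c + V:r2", "Q:e + V:r2",
    "V:r2 + Q:d", "V:r2 - Q:b", "V:r2 - Q:c"
  ))
  # no availability edge for d: d is not a substrate anywhere
  expect_false(any(grepl("A:d", edge_key(e))))
})

test_that("the unregulated variant swaps substrate feedback for availability couples", {
  r <- tibble::tibble(
    id = "r2", substrates = list(c("b", "c")), products = list("d"),
    activators = list(character()), inhibitors = list(character()),
    modulators = list(character()), reversible = FALSE
  )
  e <- emit_reaction_edges(r, availability_universe = c("b", "c"))
  expect_setequal(edge_key(e), c(
    "A:b + V:r2", "A:c + V:r2", "V:r2 + Q:d",
    "A:b - Q:c", "A:c - Q:b"
  ))
})

test_that("an effect-derived reaction compiles to regulator and product edges only", {
  r <- effect_to_reaction("a", "g", "+")
  e <- emit_reaction_edges(r, availability_universe = c("b", "c"))
  expect_setequal(edge_key(e), c(
    sprintf("Q:a + V:%s", r$id), sprintf("V:%s + Q:g", r$id)
  ))
})

test_that("the worked two-reaction example compiles to the expected graph", {
  g <- build_causality_graph(toy_figure_kb())
  gl <- glance(g)
  expect_equal(gl$n_nodes, 10)
  expect_equal(gl$n_quantity, 6)
  expect_equal(gl$n_availability, 2)
  expect_equal(gl$n_speed, 2)
  expect_equal(gl$n_edges, 8)
  expect_equal(gl$n_positive, 6)
  expect_equal(gl$n_negative, 2)
})

test_that("single unregulated substrate yields no couple edges; empty KB yields empty graph", {
  x <- kb(
    molecules = tibble::tibble(id = c("b", "d"), kind = "metabolite"),
    reactions = tibble::tibble(
      id = "r", substrates = list("b"), products = list("d"),
      activators = list(character()), inhibitors = list(character()),
      modulators = list(character()), reversible = FALSE
    )
  )
  g <- build_causality_graph(x)
  expect_setequal(g$nodes$node, c("Q:b", "Q:d", "A:b", "V:r"))
  expect_setequal(edge_key(g$edges), c("A:b + V:r", "V:r + Q:d"))
  empty <- build_causality_graph(kb(tibble::tibble(id = character(),
                                                   kind = character())))
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("per-reaction edge counts obey the compilation contract on random KBs", {
  for (seed in 1:12) {
    x <- random_kb(seed)
    universe <- sort(unique(unlist(x$reactions$substrates)))
    g <- build_causality_graph(x)
    expect_equal(nrow(g$nodes),
                 nrow(x$molecules) + length(universe) + nrow(x$reactions))
    for (i in seq_len(nrow(x$reactions))) {
      r <- x$reactions[i, ]
      s <- length(r$substrates[[1]]); a <- length(r$activators[[1]])
      ii <- length(r$inhibitors[[1]]); m <- length(r$modulators[[1]])
      p <- length(r$products[[1]])
      pp <- length(intersect(r$products[[1]], universe))
      expected <- s + a + ii + m + p + pp +
        if (a + ii + m > 0) s else s * (s - 1)
      expect_equal(nrow(emit_reaction_edges(r, universe)), expected)
    }
    # vectorised compilation equals the per-reaction reference
    ref <- dplyr::arrange(
      dplyr::distinct(purrr::map_dfr(
        seq_len(nrow(x$reactions)),
        function(i) emit_reaction_edges(x$reactions[i, ], universe)
      )), src, dst, sign, provenance)
    expect_equal(as.data.frame(g$edges), as.data.frame(ref))
  }
})

test_that("edges only connect the node kinds the rules allow", {
  for (seed in 1:6) {
    g <- build_causality_graph(random_kb(seed))
    kind_of <- setNames(g$nodes$kind, g$nodes$node)
    src_k <- kind_of[g$edges$src]; dst_k <- kind_of[g$edges$dst]
    expect_false(any(src_k == "quantity" & dst_k == "quantity"))
    expect_false(any(src_k == "availability" & dst_k == "availability"))
    # speed nodes never feed speed nodes either
    expect_false(any(src_k == "speed" & dst_k == "speed"))
  }
})

test_that("the sign census matches the substrate rules when regulator signs are fixed", {
  # all reactions regulated by activators only: negatives = sum of s
  x <- kb(
    molecules = tibble::tibble(id = c("s1", "s2", "p1", "e"), kind = "metabolite"),
    reactions = tibble::tibble(
      id = c("r1", "r2"),
      substrates = list(c("s1", "s2"), "s1"),
      products = list("p1", "p1"),
      activators = list("e", "e"),
      inhibitors = list(character(), character()),
      modulators = list(character(), character()),
      reversible = FALSE
    )
  )
  expect_equal(glance(build_causality_graph(x))$n_negative, 2 + 1)
  # none regulated: negatives = sum of s * (s - 1)
  y <- kb(
    x$molecules,
    dplyr::mutate(x$reactions, activators = list(character(), character()))
  )
  expect_equal(glance(build_causality_graph(y))$n_negative, 2 * 1 + 0)
})

test_that("the SIF export is deterministic and whole", {
  g <- build_causality_graph(toy_figure_kb())
  p1 <- withr::local_tempfile(fileext = ".sif")
  p2 <- withr::local_tempfile(fileext = ".sif")
  write_sif(g, p1); write_sif(g, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(length(readLines(p1)) - 1, nrow(g$edges))
})
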