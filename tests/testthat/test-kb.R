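test_that("KB-JSON round trip is the identity and is byte-deterministic", {
  for (seed in c(1, 2, 3)) {
    x <- random_kb(seed)
    p1 <- withr::local_tempfile(fileext = ".json")
    p2 <- withr::local_tempfile(fileext = ".json")
    write_knowledge_base(x, p1)
    y <- read_knowledge_base(p1)
    expect_equal(y$molecules, x$molecules)
    expect_equal(y$reactions, x$reactions)
    expect_identical(y$index, build_kb_index(y$reactions))
    write_knowledge_base(y, p2)
    expect_identical(readLines(p1), readLines(p2))
  }
})

test_that("effects in a KB-JSON file are converted to regulated reactions", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "molecules": [
      {"id": "a", "kind": "gene"}, {"id": "b", "kind": "metabolite"},
      {"id": "d", "kind": "metabolite"}
    ],
    "reactions": [
      {"id": "r1", "substrates": ["b"], "products": ["d"],
       "activators": [], "inhibitors": [], "modulators": [],
       "reversible": false, "species": []}
    ],
    "effects": [{"source": "a", "target": "b", "sign": "+"}]
  }', p)
  x <- read_knowledge_base(p)
  expect_equal(nrow(x$reactions), 2)
  eff <- x$reactions[x$reactions$id != "r1", ]
  expect_equal(eff$substrates[[1]], character(0))
  expect_equal(eff$products[[1]], "b")
  expect_equal(eff$activators[[1]], "a")
  expect_false(eff$reversible)
})

test_that("dangling molecule references are rejected, naming the offender", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "molecules": [{"id": "a", "kind": "gene"}],
    "reactions": [{"id": "r1", "substrates": [], "products": ["x"],
      "activators": ["a"], "inhibitors": [], "modulators": [],
      "reversible": false, "species": []}]
  }', p)
  expect_error(read_knowledge_base(p), "x")
})

test_that("effect conversion places the source in the role matching its sign", {
  for (case in list(list(sign = "+", role = "activators"),
                    list(sign = "-", role = "inhibitors"),
                    list(sign = "?", role = "modulators"))) {
    r <- effect_to_reaction("a", "b", case$sign)
    expect_equal(r$substrates[[1]], character(0))
    expect_equal(r$products[[1]], "b")
    expect_equal(r[[case$role]][[1]], "a")
    others <- setdiff(c("activators", "inhibitors", "modulators"), case$role)
    for (o in others) expect_length(r[[o]][[1]], 0)
    expect_false(r$reversible)
  }
})

test_that("species merge pools regulators, species and reversibility", {
  x <- kb(
    molecules = tibble::tibble(id = c("b", "c", "d", "e1", "e2"),
                               kind = "metabolite"),
    reactions = tibble::tibble(
      id = c("rA", "rB"),
      substrates = list(c("b", "c"), c("b", "c")),
      products = list("d", "d"),
      activators = list("e1", "e2"),
      inhibitors = list(character(), character()),
      modulators = list(character(), character()),
      reversible = c(FALSE, TRUE),
      species = list("human", "mouse")
    )
  )
  m <- merge_cross_species(x)
  expect_equal(nrow(m$reactions), 1)
  expect_equal(m$reactions$activators[[1]], c("e1", "e2"))
  expect_true(m$reactions$reversible)
  expect_equal(m$reactions$species[[1]], c("human", "mouse"))
  expect_equal(m$reactions$id, "rA")
  # idempotence, also on random knowledge bases
  expect_equal(merge_cross_species(m)$reactions, m$reactions)
  for (seed in c(5, 6)) {
    y1 <- merge_cross_species(random_kb(seed), lenient = TRUE)
    expect_equal(merge_cross_species(y1, lenient = TRUE)$reactions, y1$reactions)
  }
})

test_that("role conflicts on merge error by default and demote when lenient", {
  x <- kb(
    molecules = tibble::tibble(id = c("b", "d", "e"), kind = "metabolite"),
    reactions = tibble::tibble(
      id = c("rA", "rB"),
      substrates = list("b", "b"), products = list("d", "d"),
      activators = list("e", character()),
      inhibitors = list(character(), "e"),
      modulators = list(character(), character()),
      reversible = FALSE
    )
  )
  expect_error(merge_cross_species(x), "e")
  m <- merge_cross_species(x, lenient = TRUE)
  expect_equal(m$reactions$modulators[[1]], "e")
  expect_length(m$reactions$activators[[1]], 0)
  expect_length(m$reactions$inhibitors[[1]], 0)
})

test_that("generic stripping removes roles, drops product-less reactions, and shrinks only", {
  x <- kb(
    molecules = tibble::tibble(id = c("ATP", "b", "d"),
                               kind = c("metabolite", "metabolite", "metabolite")),
    reactions = tibble::tibble(
      id = c("r1", "r2"),
      substrates = list(c("ATP", "b"), "b"),
      products = list("d", "ATP"),
      activators = list(character(), character()),
      inhibitors = list(character(), character()),
      modulators = list(character(), character()),
      reversible = FALSE
    )
  )
  expect_warning(s <- strip_generic_molecules(x), "r2")
  expect_equal(s$reactions$id, "r1")
  expect_equal(s$reactions$substrates[[1]], "b")
  expect_equal(length(generic_molecule_ids()), 9)
  # identity when nothing to strip
  expect_equal(strip_generic_molecules(x, character())$reactions, x$reactions)
  # never increases reaction count or role sizes
  for (seed in 1:3) {
    y <- random_kb(seed)
    gen <- y$molecules$id[1:3]
    z <- suppressWarnings(strip_generic_molecules(y, gen))
    expect_lte(nrow(z$reactions), nrow(y$reactions))
    joint <- dplyr::inner_join(y$reactions, z$reactions, by = "id")
    for (col in c("substrates", "products", "activators", "inhibitors", "modulators")) {
      expect_true(all(lengths(joint[[paste0(col, ".y")]]) <=
                        lengths(joint[[paste0(col, ".x")]])))
    }
  }
})

test_that("hub ranking orders by participation with lexicographic ties and prefix property", {
  x <- kb(
    molecules = tibble::tibble(id = c("h", "u", "v", "w"), kind = "metabolite"),
    reactions = tibble::tibble(
      id = sprintf("r%d", 1:3),
      substrates = list("h", c("h", "u"), c("h", "v")),
      products = list("u", "v", "w"),
      activators = list(character(), character(), character()),
      inhibitors = list(character(), character(), character()),
      modulators = list(character(), character(), character()),
      reversible = FALSE
    )
  )
  expect_equal(rank_hub_molecules(x, 1), "h")
  expect_equal(rank_hub_molecules(x, 0), character(0))
  expect_warning(all_h <- rank_hub_molecules(x, 99), "exceeds")
  expect_equal(length(all_h), 4)
  # tie-break against an independent full sort
  y <- random_kb(7)
  counts <- table(y$index$molecule)
  full <- names(counts)[order(-as.integer(counts), names(counts))]
  expect_equal(rank_hub_molecules(y, length(full)), full)
  for (n1 in c(1, 3)) {
    expect_equal(rank_hub_molecules(y, n1), full[seq_len(n1)])
  }
})

test_that("target lists read and write TSV with optional header and unknown signs", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("molecule_id\tsign", "g1\t+", "g2\t-", "g3\t?"), p)
  t1 <- read_target_list(p)
  expect_equal(t1$molecule_id, c("g1", "g2", "g3"))
  expect_equal(t1$sign, c("+", "-", "?"))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\t+", "g2"), p2)          # no header, missing sign
  t2 <- read_target_list(p2)
  expect_equal(t2$sign, c("+", "?"))
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_target_list(t1, p3)
  expect_equal(read_target_list(p3), t1)
  expect_error(target_list(c("g1", "g1")), "duplicated")
})
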