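test_that("parse_obo builds typed edges, drops obsolete terms, flags bad input", {
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: U:1", "name: whole", "",
    "[Term]", "id: U:2", "name: part of whole",
    "relationship: part_of U:1", "",
    "[Term]", "id: U:3", "name: sub ! trailing comment", "is_a: U:1 ! whole", "",
    "[Term]", "id: U:4", "name: gone", "is_obsolete: true", "is_a: U:1"
  )
  g <- parse_obo(obo)
  expect_setequal(g$terms$term_id, c("U:1", "U:2", "U:3"))
  expect_equal(
    g$edges[g$edges$child == "U:2", ]$relation, "part_of")
  expect_equal(g$edges[g$edges$child == "U:3", ]$parent, "U:1")

  expect_warning(
    parse_obo(c("[Term]", "id: U:1", "",
                "[Term]", "id: U:2", "relationship: adjacent_to U:1")),
    "unknown relationship"
  )
  expect_error(parse_obo(c("[Term]", "name: anonymous")), "no id")
  expect_error(
    parse_obo(c("[Term]", "id: U:1", "is_a: U:2", "",
                "[Term]", "id: U:2", "is_a: U:1")),
    "cycle"
  )
})

test_that("ancestors closure is reflexive-transitive and relation-filtered", {
  g <- onto_graph(
    tibble::tibble(term_id = c("T:A", "T:B", "T:C"), name = c("a", "b", "c")),
    tibble::tibble(child = c("T:B", "T:C"), parent = c("T:A", "T:B"),
                   relation = c("is_a", "is_a"))
  )
  expect_equal(term_ancestors(g, "T:A"), "T:A")
  expect_setequal(term_ancestors(g, "T:C"), c("T:A", "T:B", "T:C"))
  expect_error(term_ancestors(g, "T:Z"), "unknown term")

  # develops_from is excluded from the default closure
  g2 <- onto_graph(
    tibble::tibble(term_id = c("T:A", "T:B"), name = c("a", "b")),
    tibble::tibble(child = "T:B", parent = "T:A", relation = "develops_from")
  )
  expect_equal(term_ancestors(g2, "T:B"), "T:B")
  expect_setequal(term_ancestors(g2, "T:B", relations = "develops_from"),
                  c("T:A", "T:B"))
})

test_that("ancestors equal an independent DFS oracle on random DAGs", {
  withr::with_seed(101, {
    for (i in 1:60) {
      g <- random_dag(sample(5:30, 1))
      rels <- sample(list(c("is_a"), c("is_a", "part_of"),
                          c("is_a", "part_of", "develops_from")), 1)[[1]]
      for (t in sample(g$terms$term_id, 4)) {
        expect_equal(term_ancestors(g, t, rels), oracle_ancestors(g, t, rels))
      }
    }
  })
})

test_that("original-annotation collection walks parts and precursors", {
  # fin <- radial skeleton (part_of), fin <- fin bud (develops_from)
  g <- onto_graph(
    tibble::tibble(term_id = c("U:fin", "U:rad", "U:bud", "U:other"),
                   name = c("fin", "radial skeleton", "fin bud", "other")),
    tibble::tibble(child = c("U:rad", "U:bud"), parent = "U:fin",
                   relation = c("part_of", "develops_from"))
  )
  ann <- tibble::tibble(
    protein_id = c("direct1", "partp", "budp", "offp"),
    term_id = c("U:fin", "U:rad", "U:bud", "U:other")
  )
  res <- collect_original_annotations(ann, g, "U:fin")
  expect_setequal(res$protein_id, c("direct1", "partp", "budp"))
  expect_equal(res$origin[res$protein_id == "direct1"], "original_direct")
  expect_equal(res$origin[res$protein_id == "partp"],
               "original_part_or_precursor")
  expect_equal(res$origin[res$protein_id == "budp"],
               "original_part_or_precursor")
  expect_error(collect_original_annotations(ann, g, "U:none"), "unknown term")
})

test_that("information content follows the pseudocounted -ln(p) with capping", {
  # one term carrying 9 of 100 proteins: p = (9+1)/100, IC = -ln(0.1)
  g <- onto_graph(
    tibble::tibble(term_id = c("T:root", "T:x"), name = c("root", "x")),
    tibble::tibble(child = "T:x", parent = "T:root", relation = "is_a")
  )
  ann <- tibble::tibble(
    protein_id = sprintf("p%03d", 1:100),
    term_id = c(rep("T:x", 9), rep("T:root", 91))
  )
  ic <- compute_ic(ann, g, constant = 1)
  expect_equal(ic$ic[ic$term_id == "T:x"], -log(0.1), tolerance = 1e-12)
  # root carries everyone; pseudocount pushes p past 1, capped to IC = 0
  expect_equal(ic$ic[ic$term_id == "T:root"], 0)
  expect_equal(attr(ic, "total"), 100)

  expect_error(compute_ic(ann[0, ], g), "empty annotation")
  ann2 <- tibble::tibble(protein_id = "p1", term_id = "T:root")
  expect_error(compute_ic(ann2, g, constant = 0), "constant > 0")
})

test_that("IC is anti-monotone in the propagated annotation count", {
  withr::with_seed(77, {
    for (i in 1:20) {
      g <- random_dag(sample(6:25, 1), relations = c("is_a", "part_of"))
      ann <- random_annotations(g)
      ic <- compute_ic(ann, g)
      ord <- order(ic$n_proteins)
      expect_true(all(diff(ic$ic[ord]) <= 1e-12))
    }
  })
})

test_that("term similarity matches the printed formulas on the chain fixture", {
  fx <- chain_fixture()
  expect_equal(term_similarity(fx$g, fx$ic, "T:B", "T:B", method = "lin"), 1)
  # common ancestors of B and C = {A}: lin = 2*1.0/(2.0+1.5)
  expect_equal(term_similarity(fx$g, fx$ic, "T:B", "T:C", method = "lin"),
               2 / 3.5, tolerance = 1e-12)
  # printed relevance variant multiplies by (1 + IC) and may exceed 1
  expect_equal(
    term_similarity(fx$g, fx$ic, "T:B", "T:C", method = "schlicker_printed"),
    (2 / 3.5) * 2, tolerance = 1e-12)
  expect_equal(
    term_similarity(fx$g, fx$ic, "T:B", "T:C", method = "schlicker_classic"),
    (2 / 3.5) * (1 - exp(-1)), tolerance = 1e-12)
})

test_that("term similarity equals brute-force enumeration on random DAGs", {
  withr::with_seed(303, {
    for (i in 1:30) {
      g <- random_dag(sample(5:30, 1), relations = c("is_a", "part_of"))
      ann <- random_annotations(g)
      ic <- compute_ic(ann, g)
      method <- sample(c("lin", "schlicker_printed", "schlicker_classic"), 1)
      pair <- sample(g$terms$term_id, 2)
      expect_equal(
        term_similarity(g, ic, pair[1], pair[2], method = method),
        oracle_term_similarity(g, ic, pair[1], pair[2], method = method),
        tolerance = 1e-12
      )
    }
  })
})

test_that("protein similarity aggregates term pairs; unannotated is undefined", {
  fx <- chain_fixture()
  ann <- tibble::tibble(protein_id = c("p1", "p2", "p3", "p3"),
                        term_id = c("T:B", "T:C", "T:B", "T:C"))
  expect_equal(protein_similarity(ann, fx$g, fx$ic, "p1", "p1"), 1)
  expect_equal(protein_similarity(ann, fx$g, fx$ic, "p1", "p2"),
               2 / 3.5, tolerance = 1e-12)
  # max aggregation: best term pair dominates
  expect_equal(protein_similarity(ann, fx$g, fx$ic, "p1", "p3"), 1)
  expect_warning(s <- protein_similarity(ann, fx$g, fx$ic, "p1", "ghost"),
                 "without annotations")
  expect_true(is.na(s))
})

test_that("Lin similarity is bounded, symmetric, and 1 on the diagonal", {
  withr::with_seed(99, {
    g <- random_dag(25, relations = c("is_a", "part_of"))
    ann <- random_annotations(g, n_proteins = 40)
    ic <- compute_ic(ann, g)
    terms <- g$terms$term_id
    for (i in 1:100) {
      pair <- sample(terms, 2)
      s12 <- term_similarity(g, ic, pair[1], pair[2])
      s21 <- term_similarity(g, ic, pair[2], pair[1])
      expect_equal(s12, s21, tolerance = 1e-12)
      expect_gte(s12, 0)
      expect_lte(s12, 1)
    }
  })
})
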