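test_that("ortholog table reader deduplicates and keeps one-to-many pairs", {
  f <- withr::local_tempfile(lines = c(
    "# ZFIN-style download",
    "m1\tz1", "m1\tz2", "m1\tz1", "m2\tz3"
  ))
  orth <- read_ortholog_table(f)
  expect_equal(nrow(orth), 3)
  expect_equal(sort(orth$protein_b[orth$protein_a == "m1"]), c("z1", "z2"))

  f2 <- withr::local_tempfile(lines = character())
  expect_warning(empty <- read_ortholog_table(f2), "empty")
  expect_equal(nrow(empty), 0)

  f3 <- withr::local_tempfile(lines = c("m1\t"))
  expect_error(read_ortholog_table(f3), "malformed")
})

test_that("conserved/specific partition follows the ortholog rule", {
  orth <- tibble::tibble(protein_a = c("p1", "p2"), protein_b = c("q1", "q2"))
  res <- classify_conserved(orth, c("p1", "p2", "p3"), c("q1", "q4"))
  part <- res$partition
  get <- function(sp, st) sort(part$protein_id[part$species == sp &
                                                 part$status == st])
  expect_equal(get("A", "conserved"), "p1")
  expect_equal(get("A", "specific"), c("p2", "p3"))
  expect_equal(get("B", "conserved"), "q1")
  expect_equal(get("B", "specific"), "q4")
  expect_equal(nrow(res$matched_pairs), 1)

  # one-to-many: both duplicated copies retained as conserved
  orth2 <- tibble::tibble(protein_a = c("z1", "z2"), protein_b = c("m1", "m1"))
  res2 <- classify_conserved(orth2, c("z1", "z2"), c("m1"))
  expect_equal(sort(res2$partition$protein_id[
    res2$partition$species == "A" & res2$partition$status == "conserved"]),
    c("z1", "z2"))

  # empty map: everything specific; partition exhaustive and disjoint
  res3 <- classify_conserved(orth[0, ], c("p1"), c("q1"))
  expect_true(all(res3$partition$status == "specific"))
  expect_equal(nrow(res3$partition), 2)
})

test_that("normalized weighted degree divides by module size and keeps order", {
  withr::with_seed(17, {
    net <- random_network(20, 0.4)
    members <- sample(net$nodes, 10)
    m <- assemble_module(net, "U:e", original = members)
    nwd <- normalized_weighted_degree(m)
    wd <- weighted_degree(m$edges, nwd$protein_id)
    expect_equal(nwd$normalized_weighted_degree, wd$weighted_degree / 10,
                 tolerance = 1e-12)
    expect_equal(order(-nwd$normalized_weighted_degree),
                 order(-wd$weighted_degree))
  })
  iso <- assemble_module(
    ppi_network(tibble::tibble(protein1 = "a", protein2 = "b", weight = 0.5),
                nodes = c("a", "b", "solo")),
    "U:e", original = "solo")
  expect_equal(normalized_weighted_degree(iso)$normalized_weighted_degree, 0)
})

test_that("rank-sum test: exact route, tie fallback and alternatives", {
  t1 <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t1$p_value, 0.1, tolerance = 1e-12)
  expect_equal(t1$method_used, "exact")

  # identical samples degenerate to p = 1 under the tie-corrected normal
  expect_warning(t2 <- wilcoxon_rank_sum(c(1, 1, 2), c(1, 2, 2),
                                         method = "exact"), "ties")
  expect_equal(t2$method_used, "normal_approx")
  t3 <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t3$p_value, 1)

  t4 <- wilcoxon_rank_sum(c(5, 6, 7), c(1, 2, 3), alternative = "greater")
  expect_equal(t4$p_value, 0.05, tolerance = 1e-12)
  expect_error(wilcoxon_rank_sum(numeric(), 1), "non-empty")
})

test_that("exact rank-sum p equals exhaustive permutation enumeration", {
  withr::with_seed(515, {
    for (i in 1:40) {
      n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
      x <- round(stats::rnorm(n1), 6)
      y <- round(stats::rnorm(n2, mean = stats::runif(1, -1, 1)), 6)
      t <- wilcoxon_rank_sum(x, y)
      expect_equal(t$method_used, "exact")
      expect_equal(t$p_value, oracle_wilcoxon_two_sided(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("module comparison partitions, attaches nwd and tests per species", {
  cfg <- synthetic_config(seed = 21, module_size = 40)
  w <- generate_world(cfg)
  wa <- world_members(w, "A"); wb <- world_members(w, "B")
  ma <- assemble_module(w$networks$A, "U:finA", original = wa$members)
  mb <- assemble_module(w$networks$B, "U:finB", original = wb$members)
  cmp <- compare_modules(ma, mb, w$orthologs)
  part <- cmp$partition
  # exhaustive & disjoint partitions matching the planted truth
  expect_setequal(part$protein_id[part$species == "A"], wa$members)
  expect_setequal(
    part$protein_id[part$species == "A" & part$status == "conserved"],
    wa$conserved)
  expect_setequal(
    part$protein_id[part$species == "B" & part$status == "conserved"],
    wb$conserved)
  expect_true(all(!is.na(part$normalized_weighted_degree)))
  expect_equal(nrow(cmp$tests), 2)
  # matched pairs carry both ranks
  expect_true(all(c("rank_a", "rank_b") %in% names(cmp$matched_pairs)))
  expect_true(all(cmp$matched_pairs$protein_a %in% wa$conserved))

  # hub-biased conserved members sit higher in both species
  expect_gt(cmp$tests$median_conserved[1], cmp$tests$median_specific[1])
  expect_gt(cmp$tests$median_conserved[2], cmp$tests$median_specific[2])
})

test_that("identical modules under an identity map leave no specific proteins", {
  net <- ppi_network(tibble::tibble(protein1 = "a", protein2 = "b",
                                    weight = 0.5))
  m <- assemble_module(net, "U:e", original = c("a", "b"))
  orth <- tibble::tibble(protein_a = c("a", "b"), protein_b = c("a", "b"))
  warns <- capture_warnings(cmp <- compare_modules(m, m, orth))
  expect_match(warns, "test skipped", all = TRUE)
  expect_true(all(cmp$partition$status == "conserved"))
  expect_true(all(is.na(cmp$tests$p_value)))
})
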