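test_that("config validates its probability and size parameters", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(p_in = 1.2), "probabilities")
  expect_error(synthetic_config(module_size = 600, n_proteins = 500),
               "module_size")
  expect_error(synthetic_config(w_in = c(0.5, 1.5)), "weight ranges")
  expect_error(synthetic_config(depth = 1), "depth")
})

test_that("generated ontology is an acyclic typed DAG with designated entities", {
  cfg <- synthetic_config(seed = 1, depth = 3, branching = 2)
  g <- generate_ontology(cfg)
  # complete binary tree of depth 3 (15 terms) + part/precursor per entity
  expect_equal(nrow(g$terms), 15 + 4)
  ents <- attr(g, "entities")
  expect_named(ents, c("A", "B"))
  for (e in ents) {
    expect_equal(
      g$edges$relation[g$edges$child == e$part & g$edges$parent == e$target],
      "part_of")
    expect_equal(
      g$edges$relation[g$edges$child == e$precursor &
                         g$edges$parent == e$target],
      "develops_from")
  }
  # determinism
  g2 <- generate_ontology(synthetic_config(seed = 1))
  expect_identical(g$edges, g2$edges)
  # acyclicity holds across random configs (constructor would error)
  withr::with_seed(7, {
    for (i in 1:20) {
      cfg_i <- synthetic_config(seed = sample.int(1e6, 1),
                                depth = sample(2:4, 1),
                                branching = sample(2:3, 1))
      expect_s3_class(generate_ontology(cfg_i), "onto_graph")
    }
  })
})

test_that("annotation generator splits original vs hidden and respects closure", {
  cfg <- synthetic_config(seed = 5, module_size = 40,
                          annotated_fraction = 0.75)
  g <- generate_ontology(cfg)
  prots <- sprintf("a%04d", 1:500)
  members <- prots[1:40]
  res <- generate_annotations(cfg, g, prots, members, entity = "A")
  expect_equal(sum(res$truth$annotation == "original"), 30)
  expect_equal(sum(res$truth$annotation == "hidden"), 10)
  # emitted table contains originals only (hidden members are ground truth)
  expect_setequal(intersect(res$table$protein_id, members),
                  res$truth$protein_id[res$truth$annotation == "original"])
  # closure through parts/precursors recovers every original member
  orig <- collect_original_annotations(res$table, g,
                                       attr(g, "entities")$A$target)
  expect_setequal(orig$protein_id,
                  res$truth$protein_id[res$truth$annotation == "original"])
  # same seed, same table
  res2 <- generate_annotations(cfg, g, prots, members, entity = "A")
  expect_identical(res$table, res2$table)
})

test_that("planted-partition network matches its declared densities", {
  cfg <- synthetic_config(seed = 9, module_size = 40, hub_bias = 0)
  prots <- sprintf("a%04d", 1:500)
  members <- prots[1:40]
  net <- generate_species_network(cfg, prots, members)
  e <- net$edges
  in_mod <- e$protein1 %in% members & e$protein2 %in% members
  n_in_pairs <- choose(40, 2)
  n_out_pairs <- choose(500, 2) - n_in_pairs
  # empirical densities within 3 sigma of p_in / p_out
  expect_lt(abs(sum(in_mod) - n_in_pairs * 0.3),
            3 * sqrt(n_in_pairs * 0.3 * 0.7))
  expect_lt(abs(sum(!in_mod) - n_out_pairs * 0.01),
            3 * sqrt(n_out_pairs * 0.01 * 0.99))
  # weight ranges respected
  expect_true(all(e$weight[in_mod] >= 0.6 & e$weight[in_mod] <= 0.9))
  expect_true(all(e$weight[!in_mod] >= 0.05 & e$weight[!in_mod] <= 0.2))
  # determinism of the edge list
  net2 <- generate_species_network(cfg, prots, members)
  expect_identical(net$edges, net2$edges)
  expect_warning(
    generate_species_network(synthetic_config(p_in = 0.005, p_out = 0.01),
                             prots, members),
    "undetectable")
})

test_that("hub bias raises conserved members' expected degree; zero bias is symmetric", {
  cfg <- synthetic_config(seed = 13, module_size = 80, hub_bias = 0.1)
  prots <- sprintf("a%04d", 1:500)
  members <- prots[1:80]
  conserved <- members[1:24]
  net <- generate_species_network(cfg, prots, members, conserved)
  wd <- weighted_degree(net, members)
  expect_gt(mean(wd$weighted_degree[wd$protein_id %in% conserved]),
            mean(wd$weighted_degree[!wd$protein_id %in% conserved]))
})

test_that("world-level ground truth is consistent and duplication-aware", {
  cfg <- synthetic_config(seed = 31, module_size = 40,
                          conserved_fraction = 0.3, duplication_rate = 0.25)
  w <- generate_world(cfg)
  tr <- w$truth
  # rho * module_size conserved B genes
  expect_equal(sum(tr$conserved & tr$species == "B"), 12)
  # every conserved member is linked through the ortholog map to the other
  # module, and conserved A counts include duplicated copies
  wa <- world_members(w, "A"); wb <- world_members(w, "B")
  expect_true(all(wa$conserved %in% w$orthologs$protein_a))
  expect_gte(length(wa$conserved), length(wb$conserved))
  cls <- classify_conserved(w$orthologs, wa$members, wb$members)
  part <- cls$partition
  expect_setequal(part$protein_id[part$species == "A" &
                                    part$status == "conserved"],
                  wa$conserved)
  expect_setequal(part$protein_id[part$species == "B" &
                                    part$status == "conserved"],
                  wb$conserved)
})

test_that("duplication rate shows up in the conserved ortholog map", {
  # binomial check pooled over worlds: ~delta of conserved B genes have 2 copies
  copies <- integer()
  for (s in 1:6) {
    cfg <- synthetic_config(seed = 1000 + s, module_size = 80,
                            duplication_rate = 0.25)
    w <- generate_world(cfg)
    wb <- world_members(w, "B")
    n_copies <- table(w$orthologs$protein_b[
      w$orthologs$protein_b %in% wb$conserved])
    copies <- c(copies, as.integer(n_copies))
  }
  frac2 <- mean(copies == 2)
  n <- length(copies)
  expect_lt(abs(frac2 - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("worlds round-trip through their standard-format files", {
  cfg <- synthetic_config(seed = 77, module_size = 40, n_proteins = 120)
  w <- generate_world(cfg)
  dir <- withr::local_tempdir()
  paths <- write_world(w, dir)
  expect_true(all(file.exists(paths)))

  g <- parse_obo(paths[["ontology"]])
  expect_identical(g$terms, w$ontology$terms)
  expect_identical(dplyr::arrange(g$edges, child, parent),
                   dplyr::arrange(w$ontology$edges, child, parent))
  ann <- read_annotations(paths[["annotations_a"]])
  expect_identical(dplyr::arrange(ann, protein_id, term_id),
                   dplyr::arrange(w$annotations$A, protein_id, term_id))
  net <- read_string_links(paths[["links_a"]])
  expect_equal(net$edges[, 1:3], w$networks$A$edges[, 1:3], tolerance = 1e-9)
  orth <- read_ortholog_table(paths[["orthologs"]])
  expect_identical(orth, w$orthologs)
  truth <- readr::read_tsv(paths[["truth"]], show_col_types = FALSE)
  expect_equal(nrow(truth), 240)

  # identical seeds give byte-identical files
  dir2 <- withr::local_tempdir()
  write_world(generate_world(cfg), dir2)
  for (f in basename(paths)) {
    expect_identical(readLines(file.path(dir, f), warn = FALSE),
                     readLines(file.path(dir2, f), warn = FALSE),
                     label = f)
  }
})
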