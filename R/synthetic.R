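# Seeded synthetic two-species worlds: an anatomy-style ontology, protein
# annotation tables, planted-partition networks with hub-biased conserved
# members, and a one-to-many ortholog map emulating a whole-genome
# duplication.  The generator defines the study conditions under which the
# workflow's inferences are recoverable; defaults are documented in the
# methods vignette.

#' Configuration for a synthetic world
#'
#' @param seed Integer RNG seed (< 2^31 - 10; per-stage sub-seeds are
#'   derived by small offsets).
#' @param depth,branching Ontology `is_a` backbone: a complete tree with
#'   `branching^l` terms at each level `l = 0..depth`.
#' @param n_proteins Proteins per species.
#' @param module_size Planted module size per species. Default 80, a
#'   scaled-down analogue of real anatomical-entity modules (hundreds of
#'   proteins).
#' @param conserved_fraction Fraction rho of module members conserved
#'   across the two species.
#' @param duplication_rate Fraction delta of conserved species-B genes with
#'   two species-A co-orthologs (teleost-style duplication; species A is
#'   the duplicated lineage).
#' @param p_in,p_out Within-module / background edge probabilities.
#' @param w_in,w_out Uniform weight ranges for module and background edges.
#' @param hub_bias Extra edge probability for within-module pairs touching
#'   a conserved member -- the planted "conserved proteins are hubs" effect.
#' @param annotated_fraction Fraction of module members given original
#'   annotations; the rest are hidden ground truth for prediction tests.
#' @param noise_edges Spurious edges added, as a fraction of the realised
#'   edge count.
#' @param origin_mix Probabilities that an annotated member is annotated to
#'   the target entity itself, its part, or its developmental precursor.
#' @param ortholog_coverage Probability that a non-conserved protein
#'   receives a background ortholog pair.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             depth = 3L, branching = 2L,
                             n_proteins = 500L, module_size = 80L,
                             conserved_fraction = 0.3,
                             duplication_rate = 0.25,
                             p_in = 0.3, p_out = 0.01,
                             w_in = c(0.6, 0.9), w_out = c(0.05, 0.2),
                             hub_bias = 0.1,
                             annotated_fraction = 0.75,
                             noise_edges = 0,
                             origin_mix = c(direct = 0.6, part = 0.2,
                                            precursor = 0.2),
                             ortholog_coverage = 0.5) {
  cfg <- list(seed = as.integer(seed), depth = as.integer(depth),
              branching = as.integer(branching),
              n_proteins = as.integer(n_proteins),
              module_size = as.integer(module_size),
              conserved_fraction = conserved_fraction,
              duplication_rate = duplication_rate,
              p_in = p_in, p_out = p_out, w_in = w_in, w_out = w_out,
              hub_bias = hub_bias,
              annotated_fraction = annotated_fraction,
              noise_edges = noise_edges,
              origin_mix = origin_mix / sum(origin_mix),
              ortholog_coverage = ortholog_coverage)
  probs <- c(cfg$conserved_fraction, cfg$duplication_rate, cfg$p_in,
             cfg$p_out, cfg$hub_bias, cfg$annotated_fraction,
             cfg$noise_edges, cfg$ortholog_coverage)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (any(cfg$w_in < 0 | cfg$w_in > 1) || any(cfg$w_out < 0 | cfg$w_out > 1)) {
    abort("weight ranges must lie within [0, 1]")
  }
  if (cfg$module_size > cfg$n_proteins) {
    abort("module_size cannot exceed n_proteins")
  }
  if (cfg$depth < 2L) abort("ontology depth must be at least 2")
  if (cfg$seed >= 2^31 - 10) abort("seed too large")
  structure(cfg, class = "synthetic_config")
}

syn_term <- function(i) sprintf("SYN:%07d", i)

#' Generate a synthetic anatomy ontology
#'
#' A complete `is_a` tree of the configured depth and branching, with two
#' designated anatomical target entities (distinct deepest-level terms in
#' different subtrees); each target gets a `part_of` child (its part) and a
#' `develops_from` child (its developmental precursor), mirroring the
#' fin / fin-radial-skeleton / fin-bud pattern.
#'
#' @param cfg A [synthetic_config()].
#' @return An [onto_graph] with attribute `entities`: a list of two lists
#'   (`target`, `part`, `precursor` term ids) named `"A"` and `"B"`.
#' @export
generate_ontology <- function(cfg) {
  b <- cfg$branching; d <- cfg$depth
  n_tree <- sum(b^(0:d))
  ids <- syn_term(seq_len(n_tree))
  # node i's parent in a complete b-ary tree laid out level by level
  parent_of <- function(i) ((i - 2L) %/% b) + 1L
  edges <- tibble(child = ids[2:n_tree],
                  parent = ids[parent_of(2:n_tree)],
                  relation = "is_a")
  level_start <- cumsum(c(1L, b^(0:(d - 1L))))
  leaves <- seq(level_start[d + 1L], n_tree)
  if (length(leaves) < 2L) abort("ontology too small for two target entities")
  # first and last deepest-level terms sit in different level-1 subtrees
  targets <- c(leaves[1L], leaves[length(leaves)])
  extra_ids <- syn_term(n_tree + seq_len(4L))
  entities <- list()
  extra_edges <- list()
  for (i in 1:2) {
    part <- extra_ids[2L * i - 1L]
    prec <- extra_ids[2L * i]
    tgt <- ids[targets[i]]
    extra_edges[[i]] <- tibble(
      child = c(part, prec), parent = tgt,
      relation = c("part_of", "develops_from")
    )
    entities[[c("A", "B")[i]]] <-
      list(target = tgt, part = part, precursor = prec)
  }
  terms <- tibble(
    term_id = c(ids, extra_ids),
    name = c(sprintf("anatomical structure %d", seq_len(n_tree)),
             sprintf("%s of entity %s", rep(c("part", "precursor"), 2),
                     rep(c("A", "B"), each = 2)))
  )
  g <- onto_graph(terms, bind_rows(edges, bind_rows(extra_edges)))
  attr(g, "entities") <- entities
  g
}

syn_protein <- function(species, i) sprintf("%s%04d", tolower(species), i)

#' Generate a species' annotation table
#'
#' Module members are annotated to the target entity, its part or its
#' precursor (proportions from `origin_mix`); an `annotated_fraction` of
#' members receive these "original" annotations while the remainder stay
#' hidden as prediction ground truth. Background proteins are annotated to
#' off-target terms so the annotation corpus and enrichment background are
#' realistic.
#'
#' @param cfg A [synthetic_config()].
#' @param g Ontology from [generate_ontology()].
#' @param proteins All protein ids of the species.
#' @param members Module member ids (subset of `proteins`).
#' @param entity `"A"` or `"B"`: which designated entity the module
#'   represents.
#' @param seed RNG seed for this stage.
#' @return A list: `table` (tibble `protein_id`, `term_id` of emitted
#'   annotations), `truth` (tibble `protein_id`, `term_id`, `annotation`
#'   in `original`/`hidden` for all members).
#' @export
generate_annotations <- function(cfg, g, proteins, members,
                                 entity = "A", seed = cfg$seed + 2L) {
  ent <- attr(g, "entities")[[entity]]
  if (is.null(ent)) abort("ontology lacks designated entities")
  withr::with_seed(seed, {
    n_orig <- round(cfg$annotated_fraction * length(members))
    shuffled <- sample(members)
    status <- ifelse(seq_along(shuffled) <= n_orig, "original", "hidden")
    slot <- sample(c("direct", "part", "precursor"), length(members),
                   replace = TRUE, prob = cfg$origin_mix)
    term <- c(direct = ent$target, part = ent$part,
              precursor = ent$precursor)[slot]
    truth <- tibble(protein_id = shuffled, term_id = unname(term),
                    annotation = status)
    off_target <- setdiff(
      g$terms$term_id,
      unlist(lapply(attr(g, "entities"), unlist), use.names = FALSE)
    )
    bg <- setdiff(proteins, members)
    bg_tab <- tibble(protein_id = bg,
                     term_id = sample(off_target, length(bg), replace = TRUE))
    table <- bind_rows(
      filter(truth, .data$annotation == "original")[, c("protein_id", "term_id")],
      bg_tab
    ) |> arrange(.data$protein_id)
  })
  list(table = table, truth = arrange(truth, .data$protein_id))
}

all_pairs <- function(n) {
  list(i = rep(seq_len(n - 1L), times = (n - 1L):1L),
       j = sequence((n - 1L):1L, from = 2:n))
}

#' Generate a species' network with a planted hub-biased module
#'
#' A planted-partition graph: pairs inside the module connect with
#' probability `p_in`, raised by `hub_bias` when either endpoint is a
#' conserved member; background pairs connect with `p_out`. Module edges
#' draw weights from `w_in`, background edges from `w_out`; a
#' `noise_edges` fraction of spurious background-weight edges is added
#' uniformly at random.
#'
#' @param cfg A [synthetic_config()].
#' @param proteins All protein ids of the species.
#' @param members Module member ids.
#' @param conserved Conserved member ids (subset of `members`).
#' @param seed RNG seed for this stage.
#' @return A `ppi_network` over all `proteins`.
#' @export
generate_species_network <- function(cfg, proteins, members,
                                     conserved = character(),
                                     seed = cfg$seed + 4L) {
  if (cfg$p_in <= cfg$p_out) {
    warn("p_in <= p_out: the planted module is undetectable by construction")
  }
  n <- length(proteins)
  member_idx <- match(members, proteins)
  cons_idx <- match(conserved, proteins)
  withr::with_seed(seed, {
    pr <- all_pairs(n)
    in_mod <- pr$i %in% member_idx & pr$j %in% member_idx
    touches_cons <- pr$i %in% cons_idx | pr$j %in% cons_idx
    p <- ifelse(in_mod, pmin(cfg$p_in + cfg$hub_bias * touches_cons, 1),
                cfg$p_out)
    keep <- runif(length(p)) < p
    w <- numeric(sum(keep))
    km <- in_mod[keep]
    w[km] <- runif(sum(km), cfg$w_in[1], cfg$w_in[2])
    w[!km] <- runif(sum(!km), cfg$w_out[1], cfg$w_out[2])
    edges <- tibble(protein1 = proteins[pr$i[keep]],
                    protein2 = proteins[pr$j[keep]], weight = w)
    n_noise <- round(cfg$noise_edges * nrow(edges))
    if (n_noise > 0L) {
      open <- which(!keep)
      pick <- sample(open, min(n_noise, length(open)))
      edges <- bind_rows(edges, tibble(
        protein1 = proteins[pr$i[pick]], protein2 = proteins[pr$j[pick]],
        weight = runif(length(pick), cfg$w_out[1], cfg$w_out[2])
      ))
    }
  })
  ppi_network(edges, nodes = proteins, provenance = "integrated")
}

#' Generate a complete synthetic two-species world
#'
#' Plants one module per species; a `conserved_fraction` of the species-B
#' module maps into the species-A module through the ortholog map, with a
#' `duplication_rate` fraction of conserved B genes receiving two A
#' co-orthologs (so conserved A members can outnumber conserved B members,
#' as after a whole-genome duplication). Module-specific and background
#' proteins receive background ortholog pairs at `ortholog_coverage`, so
#' fate/role analyses have material to map through.
#'
#' @param cfg A [synthetic_config()].
#' @return A `synthetic_world`: list with `ontology`, `annotations`
#'   (`$A`, `$B` tibbles), `networks` (`$A`, `$B` `ppi_network`s),
#'   `orthologs` (tibble `protein_a`, `protein_b`), `truth` (tibble
#'   `species`, `protein_id`, `in_module`, `conserved`, `annotation`,
#'   `entity`), and `config`.
#' @export
generate_world <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  g <- generate_ontology(cfg)
  ents <- attr(g, "entities")
  prot_a <- syn_protein("a", seq_len(cfg$n_proteins))
  prot_b <- syn_protein("b", seq_len(cfg$n_proteins))
  m <- cfg$module_size
  n_cons_b <- round(cfg$conserved_fraction * m)

  withr::with_seed(cfg$seed + 1L, {
    members_b <- sort(sample(prot_b, m))
    cons_b <- sort(sample(members_b, n_cons_b))
    # each conserved B gene gets 1 or 2 A co-orthologs inside the A module
    n_copies <- 1L + rbinom(n_cons_b, 1L, cfg$duplication_rate)
    while (sum(n_copies) > m) n_copies[which.max(n_copies)] <- 1L
    pool_a <- sample(prot_a)
    cons_a <- pool_a[seq_len(sum(n_copies))]
    spec_a <- pool_a[sum(n_copies) + seq_len(m - sum(n_copies))]
    members_a <- sort(c(cons_a, spec_a))
    cons_pairs <- tibble(protein_a = cons_a,
                         protein_b = rep(cons_b, times = n_copies))
    # Background orthology.  Module-specific members map only to the other
    # species' non-module proteins (their orthologs do something else
    # there, which is what the fate/role analysis interrogates), so the
    # planted conserved labels stay exact; leftover background proteins
    # pair up at random.
    spec_b <- setdiff(members_b, cons_b)
    bg_a <- sample(setdiff(prot_a, c(members_a)))
    bg_b <- sample(setdiff(prot_b, c(members_b)))
    take <- function(pool, k) if (k > 0L) pool[seq_len(k)] else character()
    n_sa <- round(cfg$ortholog_coverage * length(spec_a))
    n_sb <- round(cfg$ortholog_coverage * length(spec_b))
    sa_pairs <- tibble(protein_a = take(sample(spec_a), n_sa),
                       protein_b = take(bg_b, n_sa))
    sb_pairs <- tibble(protein_a = take(bg_a, n_sb),
                       protein_b = take(sample(spec_b), n_sb))
    rest_a <- sample(setdiff(bg_a, sb_pairs$protein_a))
    rest_b <- sample(setdiff(bg_b, sa_pairs$protein_b))
    n_bg <- round(cfg$ortholog_coverage * min(length(rest_a), length(rest_b)))
    bg_pairs <- tibble(protein_a = take(rest_a, n_bg),
                       protein_b = take(rest_b, n_bg))
    # duplication also applies to a slice of the background pairs
    dup <- runif(n_bg) < cfg$duplication_rate
    extra_a <- rest_a[n_bg + seq_len(sum(dup))]
    extra_a <- extra_a[!is.na(extra_a)]
    if (length(extra_a) > 0L) {
      bg_pairs <- bind_rows(bg_pairs, tibble(
        protein_a = extra_a,
        protein_b = rest_b[seq_len(n_bg)][dup][seq_along(extra_a)]
      ))
    }
    bg_pairs <- bind_rows(sa_pairs, sb_pairs, bg_pairs)
  })
  orthologs <- arrange(bind_rows(cons_pairs, bg_pairs),
                       .data$protein_a, .data$protein_b)

  ann_a <- generate_annotations(cfg, g, prot_a, members_a, entity = "A",
                                seed = cfg$seed + 2L)
  ann_b <- generate_annotations(cfg, g, prot_b, members_b, entity = "B",
                                seed = cfg$seed + 3L)
  net_a <- generate_species_network(cfg, prot_a, members_a,
                                    conserved = cons_a, seed = cfg$seed + 4L)
  net_b <- generate_species_network(cfg, prot_b, members_b,
                                    conserved = cons_b, seed = cfg$seed + 5L)

  truth <- bind_rows(
    tibble(species = "A", protein_id = prot_a,
           in_module = prot_a %in% members_a,
           conserved = prot_a %in% cons_a,
           entity = ents$A$target) |>
      left_join(select(ann_a$truth, "protein_id", "annotation"),
                by = "protein_id"),
    tibble(species = "B", protein_id = prot_b,
           in_module = prot_b %in% members_b,
           conserved = prot_b %in% cons_b,
           entity = ents$B$target) |>
      left_join(select(ann_b$truth, "protein_id", "annotation"),
                by = "protein_id")
  ) |>
    select("species", "protein_id", "in_module", "conserved",
           "annotation", "entity")

  structure(list(ontology = g,
                 annotations = list(A = ann_a$table, B = ann_b$table),
                 networks = list(A = net_a, B = net_b),
                 orthologs = orthologs, truth = truth, config = cfg),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> seed %d: %d terms, %d+%d proteins, modules %d/%d, %d ortholog pairs\n",
    x$config$seed, nrow(x$ontology$terms),
    x$config$n_proteins, x$config$n_proteins,
    sum(x$truth$in_module & x$truth$species == "A"),
    sum(x$truth$in_module & x$truth$species == "B"),
    nrow(x$orthologs)))
  invisible(x)
}

#' Write a synthetic world to standard input files
#'
#' Emits exactly the dialects the readers consume: an OBO ontology, two
#' annotation TSVs, two STRING-style protein-links TSVs (unit-scale
#' scores), an ortholog TSV, and the ground-truth TSV.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- c(ontology = p("ontology.obo"),
             annotations_a = p("annotations_a.tsv"),
             annotations_b = p("annotations_b.tsv"),
             links_a = p("links_a.tsv"), links_b = p("links_b.tsv"),
             orthologs = p("orthologs.tsv"), truth = p("truth.tsv"))
  g <- world$ontology
  rel_line <- function(rel, parent) {
    if (rel == "is_a") paste0("is_a: ", parent)
    else paste0("relationship: ", rel, " ", parent)
  }
  obo <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(g$terms))) {
    id <- g$terms$term_id[i]
    e <- g$edges[g$edges$child == id, , drop = FALSE]
    obo <- c(obo, "[Term]", paste0("id: ", id),
             paste0("name: ", g$terms$name[i]),
             if (nrow(e) > 0L) mapply(rel_line, e$relation, e$parent),
             "")
  }
  writeLines(obo, paths[["ontology"]])
  readr::write_tsv(world$annotations$A, paths[["annotations_a"]], progress = FALSE)
  readr::write_tsv(world$annotations$B, paths[["annotations_b"]], progress = FALSE)
  link_tab <- function(net) {
    net$edges |>
      select(protein1 = "protein1", protein2 = "protein2",
             combined_score = "weight")
  }
  readr::write_tsv(link_tab(world$networks$A), paths[["links_a"]], progress = FALSE)
  readr::write_tsv(link_tab(world$networks$B), paths[["links_b"]], progress = FALSE)
  readr::write_tsv(world$orthologs, paths[["orthologs"]], progress = FALSE)
  readr::write_tsv(world$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}
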