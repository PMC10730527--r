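#' Anatomy ontology graphs
#'
#' An `onto_graph` is a typed-relation directed acyclic graph over anatomy
#' terms: child-to-parent edges labelled `is_a`, `part_of` or `develops_from`.
#' It is the substrate for annotation closures, information content and
#' semantic similarity.
#'
#' @param terms A data frame with columns `term_id` and `name`.
#' @param edges A data frame with columns `child`, `parent`, `relation`.
#' @return An `onto_graph` object: a list with tibbles `terms` and `edges`.
#' @examples
#' g <- onto_graph(
#'   terms = tibble::tibble(term_id = c("T:1", "T:2"), name = c("root", "leaf")),
#'   edges = tibble::tibble(child = "T:2", parent = "T:1", relation = "is_a")
#' )
#' g
#' @export
onto_graph <- function(terms, edges) {
  terms <- as_tibble(terms)
  edges <- as_tibble(edges)
  stopifnot(all(c("term_id", "name") %in% names(terms)))
  if (nrow(edges) == 0L) {
    edges <- tibble(child = character(), parent = character(),
                    relation = character())
  }
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
  bad_rel <- setdiff(unique(edges$relation), ONTO_RELATIONS)
  if (length(bad_rel) > 0L) {
    abort(paste0("unknown relation type(s): ", paste(bad_rel, collapse = ", ")))
  }
  missing <- setdiff(unique(c(edges$child, edges$parent)), terms$term_id)
  if (length(missing) > 0L) {
    abort(paste0("edge endpoint(s) not declared as terms: ",
                 paste(missing, collapse = ", ")))
  }
  edges <- distinct(edges, .data$child, .data$parent, .data$relation)
  g <- structure(
    list(terms = arrange(terms, .data$term_id), edges = edges),
    class = "onto_graph"
  )
  cyc <- find_relation_cycle(g)
  if (!is.null(cyc)) {
    abort(paste0("ontology relations contain a cycle: ",
                 paste(cyc, collapse = " -> ")))
  }
  g
}

ONTO_RELATIONS <- c("is_a", "part_of", "develops_from")

#' @export
print.onto_graph <- function(x, ...) {
  cat(sprintf("<onto_graph> %d terms, %d typed edges\n",
              nrow(x$terms), nrow(x$edges)))
  if (nrow(x$edges) > 0L) {
    tab <- table(x$edges$relation)
    cat("  relations:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

# Locates one directed cycle over the union of all relation types, or NULL if
# the graph is acyclic.  igraph does the (fast) acyclicity check; the explicit
# DFS only runs to extract a cycle for the error message.
find_relation_cycle <- function(g) {
  if (nrow(g$edges) == 0L) return(NULL)
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("child", "parent")], directed = TRUE,
    vertices = g$terms$term_id
  )
  if (igraph::is_dag(ig)) return(NULL)
  parents <- split(g$edges$parent, g$edges$child)
  state <- new.env(parent = emptyenv())
  path <- character()
  dfs <- function(v) {
    st <- state[[v]] %||% "white"
    if (st == "grey") {
      i <- match(v, path)
      return(c(path[i:length(path)], v))
    }
    if (st == "black") return(NULL)
    state[[v]] <- "grey"
    path <<- c(path, v)
    for (p in parents[[v]] %||% character()) {
      res <- dfs(p)
      if (!is.null(res)) return(res)
    }
    path <<- path[-length(path)]
    state[[v]] <- "black"
    NULL
  }
  for (v in g$terms$term_id) {
    res <- dfs(v)
    if (!is.null(res)) return(res)
  }
  NULL
}

#' Parse an OBO document into an ontology graph
#'
#' Reads the OBO 1.2 subset used by anatomy ontologies: `[Term]` stanzas with
#' `id:`, `name:`, `is_a:` and `relationship: part_of` /
#' `relationship: develops_from` lines. Obsolete terms are dropped; unknown
#' relationship types are skipped with a warning.
#'
#' @param x Path to an OBO file, or a character vector of OBO lines.
#' @return An [onto_graph].
#' @examples
#' obo <- c(
#'   "[Term]", "id: T:0001", "name: body", "",
#'   "[Term]", "id: T:0002", "name: fin", "is_a: T:0001"
#' )
#' parse_obo(obo)
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  lines <- sub("\\s*!.*$", "", lines)   # strip OBO trailing comments
  lines <- trimws(lines)

  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) abort("no [Term] stanzas found")
  other <- which(grepl("^\\[", lines) & lines != "[Term]")
  bounds <- sort(c(starts, other, length(lines) + 1L))

  ids <- character(); nms <- character(); obsolete <- logical()
  ec <- list(); unknown_rel <- character()

  for (s in starts) {
    e <- min(bounds[bounds > s]) - 1L
    stanza <- lines[s:e]
    id <- sub("^id:\\s*", "", grep("^id:", stanza, value = TRUE))
    if (length(id) == 0L || !nzchar(id[1])) {
      abort(paste0("[Term] stanza starting at line ", s, " has no id:"))
    }
    id <- id[1]
    nm <- sub("^name:\\s*", "", grep("^name:", stanza, value = TRUE))
    obs <- any(grepl("^is_obsolete:\\s*true", stanza))
    ids <- c(ids, id)
    nms <- c(nms, if (length(nm) > 0L) nm[1] else id)
    obsolete <- c(obsolete, obs)
    if (obs) next
    isa <- sub("^is_a:\\s*", "", grep("^is_a:", stanza, value = TRUE))
    isa <- trimws(isa)
    rel_lines <- grep("^relationship:", stanza, value = TRUE)
    rel_type <- character(); rel_tgt <- character()
    for (rl in rel_lines) {
      parts <- strsplit(sub("^relationship:\\s*", "", rl), "\\s+")[[1]]
      if (length(parts) < 2L) next
      if (parts[1] %in% c("part_of", "develops_from")) {
        rel_type <- c(rel_type, parts[1]); rel_tgt <- c(rel_tgt, parts[2])
      } else {
        unknown_rel <- c(unknown_rel, parts[1])
      }
    }
    ec[[id]] <- tibble(
      child = id,
      parent = c(isa, rel_tgt),
      relation = c(rep("is_a", length(isa)), rel_type)
    )
  }

  if (length(unknown_rel) > 0L) {
    warn(paste0("ignoring unknown relationship type(s): ",
                paste(unique(unknown_rel), collapse = ", ")))
  }
  keep <- !obsolete & !duplicated(ids)
  terms <- tibble(term_id = ids[keep], name = nms[keep])
  edges <- if (length(ec) > 0L) bind_rows(ec) else
    tibble(child = character(), parent = character(), relation = character())
  # drop edges pointing at obsolete or undeclared parents
  edges <- filter(edges, .data$parent %in% terms$term_id,
                  .data$child %in% terms$term_id)
  onto_graph(terms, edges)
}

# child -> list of parents restricted to a relation subset
parent_map <- function(g, relations) {
  e <- g$edges[g$edges$relation %in% relations, , drop = FALSE]
  split(e$parent, factor(e$child, levels = unique(e$child)))
}

closure_over <- function(start, adj) {
  seen <- start
  frontier <- start
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Ancestors of a term
#'
#' Reflexive-transitive closure of the child-to-parent edges restricted to a
#' chosen subset of relation types. The result always contains the term
#' itself.
#'
#' @param g An [onto_graph].
#' @param term A term identifier present in `g`.
#' @param relations Relation types to traverse; defaults to subsumption-like
#'   relations (`is_a`, `part_of`).
#' @return Character vector of term ids (unordered, includes `term`).
#' @export
term_ancestors <- function(g, term,
                           relations = c("is_a", "part_of")) {
  if (!term %in% g$terms$term_id) {
    abort(paste0("unknown term: ", term))
  }
  adj <- parent_map(g, relations)
  sort(closure_over(term, adj))
}

#' Descendants of a term
#'
#' Reflexive-transitive closure in the parent-to-child direction, i.e. all
#' terms from which `term` is reachable over the chosen relations (plus the
#' term itself).
#'
#' @inheritParams term_ancestors
#' @return Character vector of term ids (includes `term`).
#' @export
term_descendants <- function(g, term,
                             relations = c("is_a", "part_of")) {
  if (!term %in% g$terms$term_id) {
    abort(paste0("unknown term: ", term))
  }
  e <- g$edges[g$edges$relation %in% relations, , drop = FALSE]
  adj <- split(e$child, factor(e$parent, levels = unique(e$parent)))
  sort(closure_over(term, adj))
}

# ancestor sets for every term at once (memoised walk, small ontologies)
all_ancestor_sets <- function(g, relations = c("is_a", "part_of")) {
  adj <- parent_map(g, relations)
  out <- lapply(g$terms$term_id, function(t) closure_over(t, adj))
  names(out) <- g$terms$term_id
  out
}

#' Read a protein-to-term annotation table
#'
#' Two tab-separated columns, `protein_id` and `term_id`; `#`-prefixed
#' comment lines and a possible header row are skipped; duplicate rows
#' collapse to one.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `protein_id`, `term_id`.
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, comment = "#", col_names = c("protein_id", "term_id"),
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (nrow(df) > 0L && identical(tolower(df$protein_id[1]), "protein_id")) {
    df <- df[-1L, , drop = FALSE]
  }
  distinct(df)
}

check_annotations <- function(ann, g) {
  ann <- distinct(as_tibble(ann)[, c("protein_id", "term_id")])
  bad <- setdiff(unique(ann$term_id), g$terms$term_id)
  if (length(bad) > 0L) {
    abort(paste0("annotation term(s) absent from ontology: ",
                 paste(head(bad, 5L), collapse = ", ")))
  }
  ann
}

#' Proteins with original annotations for an anatomical entity
#'
#' Collects every protein annotated to the target entity itself, or to any
#' term whose closure over `is_a`, `part_of` and `develops_from` reaches the
#' target -- i.e. parts of the entity (a fin radial skeleton for a fin) and
#' its developmental precursors (a fin bud). The result distinguishes direct
#' hits from part/precursor hits.
#'
#' @param ann Annotation data frame (`protein_id`, `term_id`).
#' @param g An [onto_graph].
#' @param target Term id of the anatomical entity.
#' @return A tibble `protein_id`, `origin` with origin
#'   `"original_direct"` or `"original_part_or_precursor"`.
#' @export
collect_original_annotations <- function(ann, g, target) {
  ann <- check_annotations(ann, g)
  if (!target %in% g$terms$term_id) {
    abort(paste0("unknown term: ", target))
  }
  reach <- term_descendants(g, target, relations = ONTO_RELATIONS)
  hits <- filter(ann, .data$term_id %in% reach)
  if (nrow(hits) == 0L) {
    return(tibble(protein_id = character(), origin = character()))
  }
  hits |>
    group_by(.data$protein_id) |>
    summarise(direct = any(.data$term_id == target), .groups = "drop") |>
    mutate(origin = ifelse(.data$direct, "original_direct",
                           "original_part_or_precursor")) |>
    select("protein_id", "origin") |>
    arrange(.data$protein_id)
}

#' Information content of ontology terms
#'
#' Annotations are first propagated up the hierarchy (true-path rule) over
#' the chosen relations, then each term's probability is the pseudocounted
#' fraction of all annotated proteins carrying it:
#' `p(t) = (count(t) + constant) / total`, `IC(t) = -ln p(t)` with `p`
#' capped at 1 so IC is non-negative.
#'
#' @param ann Annotation data frame (`protein_id`, `term_id`).
#' @param g An [onto_graph].
#' @param constant Non-negative pseudocount added to every term's propagated
#'   protein count (default 1, which keeps unannotated terms finite).
#' @param relations Relations over which annotations propagate.
#' @return An `ic_table`: a tibble `term_id`, `n_proteins`, `p`, `ic` with
#'   attributes `total` and `constant`.
#' @examples
#' g <- onto_graph(
#'   tibble::tibble(term_id = c("T:1", "T:2"), name = c("root", "leaf")),
#'   tibble::tibble(child = "T:2", parent = "T:1", relation = "is_a")
#' )
#' ann <- tibble::tibble(protein_id = c("p1", "p2"), term_id = c("T:2", "T:1"))
#' compute_ic(ann, g)
#' @export
compute_ic <- function(ann, g, constant = 1,
                       relations = c("is_a", "part_of")) {
  ann <- check_annotations(ann, g)
  if (nrow(ann) == 0L) abort("empty annotation table: total would be 0")
  if (constant < 0) abort("constant must be non-negative")
  anc <- all_ancestor_sets(g, relations)
  prop <- ann |>
    mutate(terms = anc[.data$term_id]) |>
    select("protein_id", "terms") |>
    tidyr::unnest_longer("terms", values_to = "term_id") |>
    distinct()
  counts <- prop |>
    group_by(.data$term_id) |>
    summarise(n_proteins = dplyr::n_distinct(.data$protein_id),
              .groups = "drop")
  total <- dplyr::n_distinct(ann$protein_id)
  out <- g$terms |>
    select("term_id") |>
    left_join(counts, by = "term_id") |>
    mutate(n_proteins = tidyr::replace_na(.data$n_proteins, 0L))
  raw_p <- (out$n_proteins + constant) / total
  if (any(raw_p == 0)) {
    abort("term probability is 0 (count and constant both 0); use constant > 0")
  }
  out$p <- pmin(raw_p, 1)
  out$ic <- -log(out$p)
  structure(out, total = total, constant = constant, class = c("ic_table", class(out)))
}

ic_lookup <- function(ic, term) {
  i <- match(term, ic$term_id)
  if (anyNA(i)) {
    abort(paste0("term(s) missing from IC table: ",
                 paste(term[is.na(i)], collapse = ", ")))
  }
  ic$ic[i]
}

#' Semantic similarity between two ontology terms
#'
#' Maximises over the common-ancestor set S(t1, t2). `"lin"` is
#' `2 IC(t) / (IC(t1) + IC(t2))`; `"schlicker_printed"` multiplies each
#' candidate by `(1 + IC(t))` (and can therefore exceed 1 -- downstream
#' network construction rescales it); `"schlicker_classic"` multiplies by
#' `(1 - p(t))`, the original relevance weighting. Returns 0 when
#' `IC(t1) + IC(t2) = 0`.
#'
#' @param g An [onto_graph].
#' @param ic An `ic_table` from [compute_ic()].
#' @param t1,t2 Term ids.
#' @param method One of `"lin"`, `"schlicker_printed"`, `"schlicker_classic"`.
#' @param relations Relations defining the ancestor closure.
#' @return A single numeric similarity.
#' @export
term_similarity <- function(g, ic, t1, t2,
                            method = c("lin", "schlicker_printed",
                                       "schlicker_classic"),
                            relations = c("is_a", "part_of")) {
  method <- match.arg(method)
  a1 <- term_ancestors(g, t1, relations)
  a2 <- term_ancestors(g, t2, relations)
  common <- intersect(a1, a2)
  if (length(common) == 0L) {
    abort(paste0("terms ", t1, " and ", t2,
                 " share no ancestors; disconnected ontology?"))
  }
  denom <- ic_lookup(ic, t1) + ic_lookup(ic, t2)
  if (denom == 0) return(0)
  ic_c <- ic_lookup(ic, common)
  base <- 2 * ic_c / denom
  cand <- switch(method,
    lin = base,
    schlicker_printed = base * (1 + ic_c),
    schlicker_classic = base * (1 - exp(-ic_c))
  )
  max(cand)
}

#' Semantic similarity between two proteins
#'
#' Aggregates [term_similarity()] over the cross product of the two
#' proteins' annotation sets: `"max"` takes the best term pair, `"bma"` the
#' best-match average (mean of row-wise and column-wise best matches).
#' Returns `NA` with a warning if either protein has no annotation.
#'
#' @param ann Annotation data frame (`protein_id`, `term_id`).
#' @param g An [onto_graph].
#' @param ic An `ic_table`.
#' @param protein_a,protein_b Protein ids.
#' @param method Passed to [term_similarity()].
#' @param aggregate `"max"` or `"bma"`.
#' @param relations Relations defining the ancestor closure.
#' @return A single numeric similarity, or `NA_real_` if undefined.
#' @export
protein_similarity <- function(ann, g, ic, protein_a, protein_b,
                               method = "lin",
                               aggregate = c("max", "bma"),
                               relations = c("is_a", "part_of")) {
  aggregate <- match.arg(aggregate)
  ta <- unique(ann$term_id[ann$protein_id == protein_a])
  tb <- unique(ann$term_id[ann$protein_id == protein_b])
  if (length(ta) == 0L || length(tb) == 0L) {
    warn(paste0("protein without annotations: ",
                if (length(ta) == 0L) protein_a else protein_b))
    return(NA_real_)
  }
  m <- outer(ta, tb, Vectorize(function(x, y)
    term_similarity(g, ic, x, y, method = method, relations = relations)))
  if (aggregate == "max") max(m) else
    mean(c(apply(m, 1L, max), apply(m, 2L, max)))
}
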