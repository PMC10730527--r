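#' Weighted protein networks
#'
#' A `ppi_network` is an undirected protein graph: a node set plus a
#' canonical edge tibble (`protein1 < protein2`, one row per unordered pair)
#' with weights in \[0, 1\] and a provenance tag (`"ppi"`, `"semantic"` or
#' `"integrated"`). Self-loops are dropped and duplicate pairs keep the
#' maximum weight.
#'
#' @param edges Data frame with columns `protein1`, `protein2`, `weight`
#'   (and optionally `provenance`).
#' @param nodes Optional character vector of node ids; defaults to the edge
#'   endpoints. Extra ids become isolated nodes.
#' @param provenance Default provenance tag for edges lacking one.
#' @return A `ppi_network` object (list with `nodes` and `edges`).
#' @examples
#' net <- ppi_network(tibble::tibble(
#'   protein1 = c("a", "b"), protein2 = c("b", "c"), weight = c(0.9, 0.4)
#' ))
#' weighted_degree(net)
#' @export
ppi_network <- function(edges, nodes = NULL, provenance = "ppi") {
  edges <- as_tibble(edges)
  if (nrow(edges) == 0L) {
    edges <- tibble(protein1 = character(), protein2 = character(),
                    weight = numeric(), provenance = character())
  }
  stopifnot(all(c("protein1", "protein2", "weight") %in% names(edges)))
  if (!"provenance" %in% names(edges)) edges$provenance <- provenance
  loops <- edges$protein1 == edges$protein2
  if (any(loops)) {
    warn(sprintf("dropping %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (any(edges$weight < 0 | edges$weight > 1)) {
    abort("edge weights must lie in [0, 1]")
  }
  # canonical unordered pairs, duplicates keep the max weight
  swap <- edges$protein1 > edges$protein2
  tmp <- edges$protein1[swap]
  edges$protein1[swap] <- edges$protein2[swap]
  edges$protein2[swap] <- tmp
  edges <- edges |>
    arrange(.data$protein1, .data$protein2, desc(.data$weight)) |>
    distinct(.data$protein1, .data$protein2, .keep_all = TRUE) |>
    select("protein1", "protein2", "weight", "provenance")
  nodes <- sort(unique(c(nodes, edges$protein1, edges$protein2)))
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges", length(x$nodes),
              nrow(x$edges)))
  if (nrow(x$edges) > 0L) {
    cat(sprintf(" (provenance: %s)",
                paste(unique(x$edges$provenance), collapse = "/")))
  }
  cat("\n")
  invisible(x)
}

#' Read a STRING-style protein-links table
#'
#' Whitespace- or tab-delimited rows `protein1 protein2 combined_score`,
#' with an optional header. Scores are accepted either on the STRING
#' 0--1000 integer scale (divided by 1000) or already in \[0, 1\];
#' `"auto"` picks the integer dialect when any score exceeds 1.
#'
#' @param path File path.
#' @param score_scale `"auto"`, `"1000"` or `"unit"`.
#' @return A `ppi_network` with provenance `"ppi"`.
#' @export
read_string_links <- function(path, score_scale = c("auto", "1000", "unit")) {
  score_scale <- match.arg(score_scale)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    warn("empty protein-links file")
    return(ppi_network(tibble(protein1 = character(), protein2 = character(),
                              weight = numeric())))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) {
    abort(paste0("malformed protein-links row at line ", bad[1]))
  }
  p1 <- vapply(parts, `[[`, "", 1L)
  p2 <- vapply(parts, `[[`, "", 2L)
  sc <- vapply(parts, `[[`, "", 3L)
  header <- suppressWarnings(is.na(as.numeric(sc[1])))
  if (header) { p1 <- p1[-1L]; p2 <- p2[-1L]; sc <- sc[-1L] }
  score <- suppressWarnings(as.numeric(sc))
  if (anyNA(score)) {
    abort(paste0("non-numeric score at line ", which(is.na(score))[1]))
  }
  if (score_scale == "auto") {
    score_scale <- if (any(score > 1)) "1000" else "unit"
  }
  hi <- if (score_scale == "1000") 1000 else 1
  if (any(score < 0 | score > hi)) {
    abort(paste0("score outside [0, ", hi, "] at line ",
                 which(score < 0 | score > hi)[1]))
  }
  w <- if (score_scale == "1000") score / 1000 else score
  ppi_network(tibble(protein1 = p1, protein2 = p2, weight = w),
              provenance = "ppi")
}

# pairwise term-similarity matrix for a term set (internal work-horse)
term_similarity_matrix <- function(g, ic, terms, method = "lin",
                                   relations = c("is_a", "part_of")) {
  anc <- all_ancestor_sets(g, relations)
  icv <- setNames(ic$ic, ic$term_id)
  k <- length(terms)
  m <- matrix(0, k, k, dimnames = list(terms, terms))
  for (i in seq_len(k)) {
    for (j in i:k) {
      common <- intersect(anc[[terms[i]]], anc[[terms[j]]])
      denom <- icv[[terms[i]]] + icv[[terms[j]]]
      s <- if (length(common) == 0L || denom == 0) 0 else {
        ic_c <- icv[common]
        base <- 2 * ic_c / denom
        max(switch(method,
          lin = base,
          schlicker_printed = base * (1 + ic_c),
          schlicker_classic = base * (1 - exp(-ic_c))
        ))
      }
      m[i, j] <- m[j, i] <- s
    }
  }
  m
}

#' Build an anatomy-semantic protein network
#'
#' Connects every pair of annotated proteins whose aggregated semantic
#' similarity is positive. When the similarity method can exceed 1
#' (`"schlicker_printed"`), edge scores are min--max rescaled to \[0, 1\]
#' across the network before the network is returned.
#'
#' @param ann Annotation data frame (`protein_id`, `term_id`).
#' @param g An [onto_graph].
#' @param ic An `ic_table` from [compute_ic()].
#' @param proteins Optional subset of proteins to consider; unannotated
#'   members are excluded from the node set.
#' @param method,aggregate,relations As in [protein_similarity()].
#' @return A `ppi_network` with provenance `"semantic"`.
#' @export
build_semantic_network <- function(ann, g, ic, proteins = NULL,
                                   method = "lin",
                                   aggregate = c("max", "bma"),
                                   relations = c("is_a", "part_of")) {
  aggregate <- match.arg(aggregate)
  ann <- check_annotations(ann, g)
  if (!is.null(proteins)) ann <- filter(ann, .data$protein_id %in% proteins)
  prots <- sort(unique(ann$protein_id))
  if (length(prots) < 2L) {
    warn("fewer than 2 annotated proteins; semantic network is empty")
    return(ppi_network(tibble(protein1 = character(), protein2 = character(),
                              weight = numeric()),
                       nodes = prots, provenance = "semantic"))
  }
  terms <- sort(unique(ann$term_id))
  simmat <- term_similarity_matrix(g, ic, terms, method = method,
                                   relations = relations)
  ann_idx <- split(match(ann$term_id, terms), ann$protein_id)[prots]
  np <- length(prots)
  i1 <- rep(seq_len(np - 1L), times = (np - 1L):1L)
  i2 <- sequence((np - 1L):1L, from = 2:np)
  sims <- vapply(seq_along(i1), function(k) {
    sa <- simmat[ann_idx[[i1[k]]], ann_idx[[i2[k]]], drop = FALSE]
    if (aggregate == "max") max(sa) else
      mean(c(apply(sa, 1L, max), apply(sa, 2L, max)))
  }, numeric(1))
  keep <- sims > 0
  w <- sims[keep]
  if (method == "schlicker_printed" && length(w) > 0L) {
    rng <- range(w)
    w <- if (rng[1] == rng[2]) rep(1, length(w)) else
      (w - rng[1]) / (rng[2] - rng[1])
  }
  ppi_network(tibble(protein1 = prots[i1[keep]], protein2 = prots[i2[keep]],
                     weight = w),
              nodes = prots, provenance = "semantic")
}

#' Integrate a PPI network with a semantic network
#'
#' The PPI edge set is the backbone: every PPI edge with a defined semantic
#' score for the same pair receives the convex combination
#' `alpha * w_ppi + (1 - alpha) * w_sem`; PPI edges without a semantic
#' counterpart keep their PPI weight; semantic-only pairs are not added.
#' Edges whose final weight falls below `min_weight` are removed (the
#' spurious-interaction filter).
#'
#' @param ppi,semantic `ppi_network` objects sharing an id space.
#' @param alpha Mixing weight in \[0, 1\] given to the PPI score.
#' @param min_weight Minimum retained integrated weight (default 0, keep
#'   everything).
#' @return A `ppi_network` with provenance `"integrated"`.
#' @export
integrate_networks <- function(ppi, semantic, alpha = 0.5, min_weight = 0) {
  stopifnot(inherits(ppi, "ppi_network"), inherits(semantic, "ppi_network"))
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  sem <- semantic$edges |>
    select("protein1", "protein2", w_sem = "weight")
  merged <- ppi$edges |>
    left_join(sem, by = c("protein1", "protein2")) |>
    mutate(weight = ifelse(is.na(.data$w_sem), .data$weight,
                           alpha * .data$weight + (1 - alpha) * .data$w_sem),
           provenance = "integrated") |>
    select("protein1", "protein2", "weight", "provenance") |>
    filter(.data$weight >= min_weight)
  ppi_network(merged, nodes = ppi$nodes, provenance = "integrated")
}

#' Weighted degree of network nodes
#'
#' The sum of the weights of a node's incident edges; isolated nodes score 0.
#'
#' @param net A `ppi_network`.
#' @param proteins Optional node subset (errors if any is unknown);
#'   defaults to all nodes.
#' @return A tibble `protein_id`, `weighted_degree`.
#' @export
weighted_degree <- function(net, proteins = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  if (is.null(proteins)) {
    proteins <- net$nodes
  } else {
    unknown <- setdiff(proteins, net$nodes)
    if (length(unknown) > 0L) {
      abort(paste0("unknown node(s): ", paste(head(unknown, 5L), collapse = ", ")))
    }
  }
  out <- tibble(protein_id = proteins, weighted_degree = 0)
  if (nrow(net$edges) > 0L) {
    inc <- c(tapply(net$edges$weight, net$edges$protein1, sum),
             tapply(net$edges$weight, net$edges$protein2, sum))
    wd <- tapply(inc, names(inc), sum)
    hit <- match(proteins, names(wd))
    out$weighted_degree <- ifelse(is.na(hit), 0, unname(wd)[hit])
  }
  out
}

#' Induced subgraph on a node set
#'
#' Keeps the intersection of `nodes` with the network's node set and every
#' edge internal to it; weights are preserved. Requested nodes missing from
#' the network are silently excluded (module assembly reports them as lost).
#'
#' @param net A `ppi_network`.
#' @param nodes Character vector of node ids.
#' @return A `ppi_network`.
#' @export
induced_subgraph <- function(net, nodes) {
  stopifnot(inherits(net, "ppi_network"))
  keep <- intersect(net$nodes, nodes)
  e <- filter(net$edges, .data$protein1 %in% keep, .data$protein2 %in% keep)
  ppi_network(e, nodes = keep)
}

#' Export a network to standard file formats
#'
#' `"sif"` writes Cytoscape SIF lines (`A pp B`); `"graphml"` writes a
#' GraphML document carrying the edge weight attribute at full double
#' precision; `"tsv"` writes the edge table. When `node_attrs` is supplied
#' with the SIF or TSV formats, a companion `<file>_nodes.tsv` is written.
#'
#' @param net A `ppi_network`.
#' @param file Output path.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @param node_attrs Optional data frame of node attributes (first column
#'   the protein id).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(net, file, format = c("sif", "graphml", "tsv"),
                           node_attrs = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  format <- match.arg(format)
  paths <- file
  if (format == "sif") {
    lines <- sprintf("%s pp %s", net$edges$protein1, net$edges$protein2)
    writeLines(lines, file)
  } else if (format == "tsv") {
    readr::write_tsv(net$edges, file, progress = FALSE)
  } else {
    writeLines(graphml_document(net), file)
  }
  if (!is.null(node_attrs) && format != "graphml") {
    npath <- paste0(sub("\\.[A-Za-z]+$", "", file), "_nodes.tsv")
    readr::write_tsv(as_tibble(node_attrs), npath, progress = FALSE)
    paths <- c(paths, npath)
  }
  invisible(paths)
}

graphml_document <- function(net) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph id="G" edgedefault="undirected">',
    sprintf('    <node id="%s"/>', esc(net$nodes)),
    if (nrow(net$edges) > 0L) {
      sprintf('    <edge source="%s" target="%s"><data key="w">%.17g</data></edge>',
              esc(net$edges$protein1), esc(net$edges$protein2),
              net$edges$weight)
    },
    "  </graph>",
    "</graphml>")
}

#' Read a GraphML network written by [export_network()]
#'
#' @param file Path to a GraphML file with an edge `weight` attribute.
#' @return A `ppi_network`.
#' @export
read_network_graphml <- function(file) {
  doc <- xml2::read_xml(file)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nodes <- xml2::xml_attr(xml2::xml_find_all(doc, ".//g:node", ns), "id")
  edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
  src <- xml2::xml_attr(edges, "source")
  tgt <- xml2::xml_attr(edges, "target")
  w <- as.numeric(xml2::xml_text(xml2::xml_find_first(edges, "./g:data", ns)))
  ppi_network(tibble(protein1 = src, protein2 = tgt,
                     weight = if (length(src)) w else numeric()),
              nodes = nodes)
}
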