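#' Assemble an anatomical entity's protein module
#'
#' Combines proteins with original annotations (direct, or via parts and
#' developmental precursors) with predicted candidates, takes the induced
#' subgraph of the network on that set, and ranks members by weighted
#' degree. Original proteins absent from the network are reported as lost
#' rather than silently dropped.
#'
#' @param net A `ppi_network`.
#' @param entity Term id of the anatomical entity the module represents.
#' @param original Either a character vector of protein ids (all treated as
#'   `"original_direct"`) or a data frame `protein_id`, `origin` as returned
#'   by [collect_original_annotations()].
#' @param predicted Character vector of predicted protein ids; must be
#'   disjoint from the originals.
#' @param degree_scope `"module"` ranks by weighted degree inside the
#'   module's induced subgraph (default); `"network"` uses the whole
#'   network.
#' @return A `network_module`: list with `entity`, `nodes` (tibble
#'   `protein_id`, `origin`, `weighted_degree`,
#'   `normalized_weighted_degree`, `rank`), `edges` (a `ppi_network`), and
#'   `lost` (character).
#' @export
assemble_module <- function(net, entity, original,
                            predicted = character(),
                            degree_scope = c("module", "network")) {
  degree_scope <- match.arg(degree_scope)
  stopifnot(inherits(net, "ppi_network"))
  if (is.character(original)) {
    original <- tibble(protein_id = original, origin = "original_direct")
  }
  original <- distinct(as_tibble(original)[, c("protein_id", "origin")])
  overlap <- intersect(original$protein_id, predicted)
  if (length(overlap) > 0L) {
    abort(paste0("proteins both original and predicted: ",
                 paste(head(overlap, 5L), collapse = ", ")))
  }
  members <- bind_rows(
    original,
    tibble(protein_id = unique(predicted), origin = "predicted")
  )
  lost <- sort(setdiff(original$protein_id, net$nodes))
  members <- filter(members, .data$protein_id %in% net$nodes)
  sub <- induced_subgraph(net, members$protein_id)
  deg_net <- if (degree_scope == "module") sub else net
  wd <- weighted_degree(deg_net, members$protein_id)
  nodes <- members |>
    left_join(wd, by = "protein_id") |>
    mutate(normalized_weighted_degree =
             if (nrow(members) > 0L) .data$weighted_degree / nrow(members)
           else numeric()) |>
    arrange(desc(.data$weighted_degree), .data$protein_id) |>
    mutate(rank = row_number())
  structure(list(entity = entity, nodes = nodes, edges = sub, lost = lost),
            class = "network_module")
}

#' @export
print.network_module <- function(x, ...) {
  org <- sum(x$nodes$origin != "predicted")
  cat(sprintf(
    "<network_module> entity %s: %d proteins (%d original, %d predicted), %d edges, %d lost\n",
    x$entity, nrow(x$nodes), org, nrow(x$nodes) - org,
    nrow(x$edges$edges), length(x$lost)))
  invisible(x)
}

#' Rank module members by weighted degree
#'
#' Descending weighted degree; ties broken lexicographically by protein id
#' so rank files are reproducible.
#'
#' @param module A `network_module`.
#' @return The module's `nodes` tibble ordered by rank.
#' @export
rank_by_weighted_degree <- function(module) {
  stopifnot(inherits(module, "network_module"))
  arrange(module$nodes, .data$rank)
}

five_number <- function(x) {
  q <- unname(quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  tibble(n = length(x), min = q[1], q1 = q[2], median = q[3], q3 = q[4],
         max = q[5], mean = mean(x))
}

#' Compare weighted-degree distributions of predicted vs original proteins
#'
#' Summarises the module-internal weighted degree separately for predicted
#' members and members with original annotations, and tests the two groups
#' with a Wilcoxon rank-sum test. If predicted proteins sit at least as
#' high as originals, they plausibly carry comparable functional weight in
#' the module.
#'
#' @param module A `network_module` containing at least one predicted and
#'   one original protein.
#' @param alternative Passed to [wilcoxon_rank_sum()].
#' @return A `degree_comparison`: list with `summary` (per-group
#'   five-number summary plus mean), `test` (a `rank_sum_test`), and `data`
#'   (boxplot-ready tibble `protein_id`, `group`, `weighted_degree`).
#' @export
compare_degree_distributions <- function(module, alternative = "two_sided") {
  stopifnot(inherits(module, "network_module"))
  data <- module$nodes |>
    mutate(group = ifelse(.data$origin == "predicted", "predicted",
                          "original")) |>
    select("protein_id", "group", "weighted_degree")
  for (grp in c("original", "predicted")) {
    if (!any(data$group == grp)) {
      abort(paste0("module has no ", grp, " proteins"))
    }
  }
  summ <- data |>
    group_by(.data$group) |>
    summarise(five_number(.data$weighted_degree), .groups = "drop")
  test <- wilcoxon_rank_sum(
    data$weighted_degree[data$group == "predicted"],
    data$weighted_degree[data$group == "original"],
    alternative = alternative
  )
  structure(list(summary = summ, test = test, data = data),
            class = "degree_comparison")
}

#' @export
print.degree_comparison <- function(x, ...) {
  cat("<degree_comparison> predicted vs original weighted degree\n")
  print(x$summary)
  cat(sprintf("rank-sum p = %.4g (%s)\n", x$test$p_value, x$test$method_used))
  invisible(x)
}

#' Write a module's files
#'
#' Writes the SIF and GraphML network exports, the node-attribute table
#' (origin, weighted degree, normalized weighted degree, rank) and the
#' lost-protein list under a common path prefix.
#'
#' @param module A `network_module`.
#' @param prefix Path prefix (directory must exist).
#' @return Invisibly, the paths written.
#' @export
write_module <- function(module, prefix) {
  stopifnot(inherits(module, "network_module"))
  paths <- c(
    sif = paste0(prefix, ".sif"),
    graphml = paste0(prefix, ".graphml"),
    nodes = paste0(prefix, "_nodes.tsv"),
    lost = paste0(prefix, "_lost.tsv")
  )
  export_network(module$edges, paths[["sif"]], format = "sif")
  export_network(module$edges, paths[["graphml"]], format = "graphml")
  readr::write_tsv(module$nodes, paths[["nodes"]], progress = FALSE)
  readr::write_tsv(tibble(protein_id = module$lost), paths[["lost"]],
                   progress = FALSE)
  invisible(paths)
}
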