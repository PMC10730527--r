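#' Read a cross-species ortholog table
#'
#' Tab-separated pairs of protein ids, one species per column; `#`-comment
#' and header lines are skipped and duplicate pairs collapse to one.
#' One-to-many and many-to-one mappings are allowed (whole-genome
#' duplication leaves many single-copy genes of one species with two
#' co-orthologs in the other).
#'
#' @param path Path to a TSV file.
#' @param col_a,col_b Column indices (or names) holding the species-A and
#'   species-B ids.
#' @return A tibble `protein_a`, `protein_b`.
#' @export
read_ortholog_table <- function(path, col_a = 1, col_b = 2) {
  df <- readr::read_tsv(path, comment = "#",
                        col_types = readr::cols(.default = readr::col_character()),
                        col_names = FALSE, progress = FALSE)
  if (nrow(df) == 0L) {
    warn("empty ortholog table")
    return(tibble(protein_a = character(), protein_b = character()))
  }
  if (ncol(df) < 2L) abort("ortholog table needs at least 2 columns")
  out <- tibble(protein_a = df[[col_a]], protein_b = df[[col_b]])
  # drop a header row if the first line is non-data
  if (nrow(out) > 0L && tolower(out$protein_a[1]) %in%
        c("protein_a", "protein1", "zebrafish", "gene_a", "id_a")) {
    out <- out[-1L, , drop = FALSE]
  }
  bad <- which(is.na(out$protein_a) | is.na(out$protein_b) |
                 out$protein_a == "" | out$protein_b == "")
  if (length(bad) > 0L) {
    abort(paste0("malformed ortholog row at line ", bad[1]))
  }
  distinct(out)
}

module_node_ids <- function(m) {
  if (inherits(m, "network_module")) m$nodes$protein_id else as.character(m)
}

#' Partition two homologous modules into conserved and specific proteins
#'
#' A species-A module protein is conserved iff at least one of its orthologs
#' lies in the species-B module (and symmetrically); when a single protein
#' has several in-module orthologs, all of them are retained. Everything
#' else is module-specific.
#'
#' @param orth Ortholog data frame (`protein_a`, `protein_b`).
#' @param module_a,module_b `network_module` objects (or plain character
#'   vectors of protein ids) from the two species.
#' @return A list with `partition` (tibble `species`, `protein_id`,
#'   `status` in `conserved`/`specific`) and `matched_pairs` (tibble
#'   `protein_a`, `protein_b` of ortholog pairs with both ends in-module).
#' @export
classify_conserved <- function(orth, module_a, module_b) {
  orth <- distinct(as_tibble(orth)[, c("protein_a", "protein_b")])
  na <- module_node_ids(module_a)
  nb <- module_node_ids(module_b)
  matched <- filter(orth, .data$protein_a %in% na, .data$protein_b %in% nb) |>
    arrange(.data$protein_a, .data$protein_b)
  partition <- bind_rows(
    tibble(species = "A", protein_id = sort(na),
           status = ifelse(sort(na) %in% matched$protein_a,
                           "conserved", "specific")),
    tibble(species = "B", protein_id = sort(nb),
           status = ifelse(sort(nb) %in% matched$protein_b,
                           "conserved", "specific"))
  )
  list(partition = partition, matched_pairs = matched)
}

#' Normalized weighted degree of module proteins
#'
#' Weighted degree divided by the number of proteins in the module, making
#' hub strength comparable between modules of different sizes.
#'
#' @param module A non-empty `network_module`.
#' @return A tibble `protein_id`, `normalized_weighted_degree`.
#' @export
normalized_weighted_degree <- function(module) {
  stopifnot(inherits(module, "network_module"))
  if (nrow(module$nodes) == 0L) abort("empty module")
  select(module$nodes, "protein_id", "normalized_weighted_degree")
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum distribution when the pooled sample
#' has at most 14 tie-free observations (`"auto"`); otherwise the normal
#' approximation with tie and continuity corrections. Ties always force the
#' approximation, as the exact distribution is defined for distinct values
#' only.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (x relative
#'   to y).
#' @param method `"auto"`, `"exact"` or `"normal_approx"`.
#' @return A `rank_sum_test`: list with `statistic` (the Mann--Whitney U of
#'   `x`), `p_value`, `method_used`, `alternative`, `n_x`, `n_y`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "greater", "less"),
                              method = c("auto", "exact", "normal_approx")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(x) == 0L || length(y) == 0L) abort("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  want_exact <- switch(method,
    auto = (length(x) + length(y) <= 14L) && !ties,
    exact = TRUE,
    normal_approx = FALSE
  )
  if (want_exact && ties) {
    warn("ties present; falling back to the normal approximation")
    want_exact <- FALSE
  }
  if (length(unique(c(x, y))) == 1L) {
    # every observation tied: the rank-sum statistic is degenerate
    return(structure(list(statistic = length(x) * length(y) / 2,
                          p_value = 1, method_used = "normal_approx",
                          alternative = alternative,
                          n_x = length(x), n_y = length(y)),
                     class = "rank_sum_test"))
  }
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[[alternative]]
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alt, exact = want_exact,
                correct = TRUE)
  )
  structure(list(statistic = unname(ht$statistic),
                 p_value = min(ht$p.value, 1),
                 method_used = if (want_exact) "exact" else "normal_approx",
                 alternative = alternative,
                 n_x = length(x), n_y = length(y)),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("<rank_sum_test> U = %g, p = %.4g (%s, %s; n = %d vs %d)\n",
              x$statistic, x$p_value, x$method_used, x$alternative,
              x$n_x, x$n_y))
  invisible(x)
}

#' Compare two homologous modules across species
#'
#' Partitions both modules into conserved and module-specific proteins via
#' the ortholog map, attaches each protein's normalized weighted degree,
#' tests conserved vs specific within each species with a Wilcoxon rank-sum
#' test, and tabulates matched ortholog pairs with their within-module
#' ranks. If a species lacks conserved or specific proteins its test is
#' skipped with a warning.
#'
#' @param module_a,module_b `network_module` objects.
#' @param orth Ortholog data frame (`protein_a`, `protein_b`).
#' @param species Length-2 character vector naming the species (labels used
#'   in the output).
#' @param alternative Passed to [wilcoxon_rank_sum()] (conserved vs
#'   specific).
#' @return A `module_comparison`: list with `partition` (tibble `species`,
#'   `protein_id`, `status`, `normalized_weighted_degree`, `rank`),
#'   `matched_pairs` (tibble with both ranks), `tests` (tibble per
#'   species), and `species`.
#' @export
compare_modules <- function(module_a, module_b, orth,
                            species = c("A", "B"),
                            alternative = "two_sided") {
  stopifnot(inherits(module_a, "network_module"),
            inherits(module_b, "network_module"))
  if (nrow(module_a$nodes) == 0L || nrow(module_b$nodes) == 0L) {
    abort("both modules must be non-empty")
  }
  cls <- classify_conserved(orth, module_a, module_b)
  nodes <- bind_rows(
    mutate(module_a$nodes, species = "A"),
    mutate(module_b$nodes, species = "B")
  )
  partition <- cls$partition |>
    left_join(select(nodes, "species", "protein_id", "origin",
                     "normalized_weighted_degree", "rank"),
              by = c("species", "protein_id"))
  matched <- cls$matched_pairs |>
    left_join(setNames(select(module_a$nodes, "protein_id", "rank"),
                       c("protein_a", "rank_a")), by = "protein_a") |>
    left_join(setNames(select(module_b$nodes, "protein_id", "rank"),
                       c("protein_b", "rank_b")), by = "protein_b")
  tests <- purrr::map_dfr(c("A", "B"), function(sp) {
    part <- filter(partition, .data$species == sp)
    cons <- part$normalized_weighted_degree[part$status == "conserved"]
    spec <- part$normalized_weighted_degree[part$status == "specific"]
    row <- tibble(species = sp, n_conserved = length(cons),
                  n_specific = length(spec),
                  statistic = NA_real_, p_value = NA_real_,
                  median_conserved = if (length(cons)) median(cons) else NA_real_,
                  median_specific = if (length(spec)) median(spec) else NA_real_)
    if (length(cons) == 0L || length(spec) == 0L) {
      warn(paste0("species ", sp,
                  ": no conserved or no specific proteins; test skipped"))
      return(row)
    }
    t <- wilcoxon_rank_sum(cons, spec, alternative = alternative)
    row$statistic <- t$statistic
    row$p_value <- t$p_value
    row
  })
  structure(list(partition = partition, matched_pairs = matched,
                 tests = tests, species = species),
            class = "module_comparison")
}

#' @export
print.module_comparison <- function(x, ...) {
  counts <- x$partition |>
    dplyr::count(.data$species, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
  cat(sprintf("<module_comparison> %s vs %s\n", x$species[1], x$species[2]))
  print(counts)
  print(x$tests)
  invisible(x)
}
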