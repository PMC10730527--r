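# broom-style tidiers so results drop into data-frame workflows

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The per-protein score table (`protein_id`, `score`,
#'   `is_annotated`, `held_out`).
#' @export
tidy.cv_result <- function(x, ...) x$scores

#' One-row summary of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A tibble with `auc`, `n_positive`, `n_negative`,
#'   `n_thresholds`.
#' @export
glance.cv_result <- function(x, ...) {
  tibble(auc = x$auc,
         n_positive = sum(x$scores$is_annotated),
         n_negative = sum(!x$scores$is_annotated),
         n_thresholds = nrow(x$pr))
}

#' Tidy a module: its ranked node table
#'
#' @param x A `network_module`.
#' @param ... Unused.
#' @return The `nodes` tibble ordered by rank.
#' @export
tidy.network_module <- function(x, ...) rank_by_weighted_degree(x)

#' One-row summary of a module
#'
#' @param x A `network_module`.
#' @param ... Unused.
#' @return A tibble with `entity`, size, origin counts, edge and lost
#'   counts.
#' @export
glance.network_module <- function(x, ...) {
  tibble(entity = x$entity,
         n_proteins = nrow(x$nodes),
         n_original = sum(x$nodes$origin != "predicted"),
         n_predicted = sum(x$nodes$origin == "predicted"),
         n_edges = nrow(x$edges$edges),
         n_lost = length(x$lost))
}

#' Tidy a cross-species module comparison
#'
#' @param x A `module_comparison`.
#' @param ... Unused.
#' @return The partition tibble (`species`, `protein_id`, `status`,
#'   `origin`, `normalized_weighted_degree`, `rank`).
#' @export
tidy.module_comparison <- function(x, ...) x$partition

#' Per-species summary of a module comparison
#'
#' @param x A `module_comparison`.
#' @param ... Unused.
#' @return The tests tibble: group sizes, medians, rank-sum statistic and
#'   p-value per species.
#' @export
glance.module_comparison <- function(x, ...) x$tests

#' Tidy a rank-sum test
#'
#' @param x A `rank_sum_test`.
#' @param ... Unused.
#' @return A one-row tibble (`statistic`, `p_value`, `method`,
#'   `alternative`, `n_x`, `n_y`).
#' @export
tidy.rank_sum_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         method = x$method_used, alternative = x$alternative,
         n_x = x$n_x, n_y = x$n_y)
}

#' Tidy a degree comparison
#'
#' @param x A `degree_comparison`.
#' @param ... Unused.
#' @return The boxplot-ready per-protein tibble.
#' @export
tidy.degree_comparison <- function(x, ...) x$data

#' Summary of a degree comparison
#'
#' @param x A `degree_comparison`.
#' @param ... Unused.
#' @return The per-group five-number summary joined with the test p-value.
#' @export
glance.degree_comparison <- function(x, ...) {
  mutate(x$summary, p_value = x$test$p_value)
}
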