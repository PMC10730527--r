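#' One-sided Fisher (hypergeometric) enrichment p-value
#'
#' Upper-tail probability `P(X >= k)` for drawing `k` term-carrying
#' proteins in a study set of size `n` from a background of `N` proteins of
#' which `K` carry the term. Vectorised over its arguments.
#'
#' @param k Study proteins carrying the term.
#' @param n Study-set size.
#' @param K Background proteins carrying the term.
#' @param N Background size.
#' @return Numeric vector of p-values in \[0, 1\].
#' @examples
#' fisher_exact_one_sided(3, 3, 5, 10)  # choose(5,3)/choose(10,3)
#' @export
fisher_exact_one_sided <- function(k, n, K, N) {
  args <- vctrs_recycle(k, n, K, N)
  k <- args[[1]]; n <- args[[2]]; K <- args[[3]]; N <- args[[4]]
  bad <- k < 0 | k > pmin(n, K) | n > N | K > N | n - k > N - K
  if (any(bad)) abort("contingency table invariants violated")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(lengths(xs))
  lapply(xs, rep_len, length.out = len)
}

# annotations propagated up the hierarchy (true-path rule)
propagate_annotations <- function(ann, g, relations = c("is_a", "part_of")) {
  ann <- check_annotations(ann, g)
  anc <- all_ancestor_sets(g, relations)
  ann |>
    mutate(terms = anc[.data$term_id]) |>
    select("protein_id", "terms") |>
    tidyr::unnest_longer("terms", values_to = "term_id") |>
    distinct()
}

#' Ontology term enrichment of a protein set
#'
#' Propagates annotations over `is_a`/`part_of` (so a protein annotated to
#' a part counts for the whole), builds the 2x2 table of each term against
#' the background, and applies the one-sided Fisher test. Terms are flagged
#' enriched at raw `p < alpha` (the over-representation convention used by
#' DAVID-style tools); Benjamini--Hochberg adjusted p-values are reported
#' alongside.
#'
#' @param ann Annotation data frame (`protein_id`, `term_id`).
#' @param study Character vector of study protein ids (must be contained in
#'   the background).
#' @param g An [onto_graph].
#' @param background Background protein ids; default all proteins in `ann`.
#' @param alpha Raw-p threshold for the `enriched` flag (default 0.05).
#' @param relations Relations for annotation propagation.
#' @return A tibble with columns `term_id`, `name`, `k`, `n`, `K`, `N`,
#'   `odds_ratio`, `p_value`, `p_adjust`, `enriched`, sorted by ascending
#'   p-value; only terms with `K >= 1` appear.
#' @export
enrich_terms <- function(ann, study, g, background = NULL, alpha = 0.05,
                         relations = c("is_a", "part_of")) {
  ann <- check_annotations(ann, g)
  if (is.null(background)) background <- unique(ann$protein_id)
  background <- unique(background)
  study <- unique(study)
  if (length(study) == 0L || length(background) == 0L) {
    abort("study and background must be non-empty")
  }
  outside <- setdiff(study, background)
  if (length(outside) > 0L) {
    abort(paste0("study proteins outside the background: ",
                 paste(head(outside, 5L), collapse = ", ")))
  }
  prop <- propagate_annotations(ann, g, relations) |>
    filter(.data$protein_id %in% background)
  counts <- prop |>
    group_by(.data$term_id) |>
    summarise(K = dplyr::n_distinct(.data$protein_id),
              k = dplyr::n_distinct(.data$protein_id[
                .data$protein_id %in% study]),
              .groups = "drop") |>
    filter(.data$K >= 1L)
  N <- length(background)
  n <- length(study)
  or_num <- counts$k * (N - counts$K - n + counts$k)
  or_den <- (n - counts$k) * (counts$K - counts$k)
  counts |>
    mutate(n = n, N = N,
           odds_ratio = ifelse(or_den == 0,
                               ifelse(or_num == 0, NaN, Inf),
                               or_num / or_den),
           p_value = fisher_exact_one_sided(.data$k, n, .data$K, N),
           p_adjust = p.adjust(.data$p_value, method = "BH"),
           enriched = .data$p_value < alpha) |>
    left_join(g$terms, by = "term_id") |>
    select("term_id", "name", "k", "n", "K", "N", "odds_ratio",
           "p_value", "p_adjust", "enriched") |>
    arrange(.data$p_value, .data$term_id)
}

#' Enriched terms shared by two protein sets
#'
#' Runs [enrich_terms()] on each set against the same background and
#' intersects the enriched term sets -- e.g. predicted proteins vs proteins
#' with original annotations, to check that predictions recapitulate the
#' originals' biology.
#'
#' @param ann,g,background,alpha,relations As in [enrich_terms()].
#' @param set_a,set_b Study protein sets.
#' @return Sorted character vector of term ids enriched in both sets.
#' @export
shared_enriched_terms <- function(ann, set_a, set_b, g, background = NULL,
                                  alpha = 0.05,
                                  relations = c("is_a", "part_of")) {
  ea <- enrich_terms(ann, set_a, g, background, alpha, relations)
  eb <- enrich_terms(ann, set_b, g, background, alpha, relations)
  sort(intersect(ea$term_id[ea$enriched], eb$term_id[eb$enriched]))
}

#' Fate/role enrichment of module-specific proteins in the other species
#'
#' Maps one species' module-specific proteins through the ortholog table
#' (retaining every target of one-to-many mappings), then enriches the
#' mapped set against the other species' annotations -- asking what the
#' lost (or gained) proteins do in the other organism.
#'
#' @param ann_other Annotation table of the *other* species.
#' @param specific Module-specific protein ids of the focal species.
#' @param orth Ortholog data frame (`protein_a`, `protein_b`).
#' @param g_other Ontology for `ann_other`.
#' @param from `"a"` if `specific` are species-A ids (mapped to B), `"b"`
#'   for the reverse.
#' @param background,alpha,relations As in [enrich_terms()].
#' @return The [enrich_terms()] tibble for the mapped set, with attributes
#'   `n_unmapped` (specific proteins without any ortholog) and `study`
#'   (the mapped ids used).
#' @export
fate_report <- function(ann_other, specific, orth, g_other,
                        from = c("a", "b"), background = NULL,
                        alpha = 0.05, relations = c("is_a", "part_of")) {
  from <- match.arg(from)
  if (length(specific) == 0L) abort("empty module-specific protein set")
  orth <- as_tibble(orth)
  src <- if (from == "a") orth$protein_a else orth$protein_b
  dst <- if (from == "a") orth$protein_b else orth$protein_a
  mapped <- unique(dst[src %in% specific])
  n_unmapped <- sum(!specific %in% src)
  if (n_unmapped > 0L) {
    inform(paste0(n_unmapped, " specific protein(s) had no ortholog"))
  }
  if (is.null(background)) background <- unique(ann_other$protein_id)
  mapped <- intersect(mapped, background)
  if (length(mapped) == 0L) {
    abort("no module-specific protein maps into the other species' background")
  }
  res <- enrich_terms(ann_other, mapped, g_other, background, alpha, relations)
  attr(res, "n_unmapped") <- n_unmapped
  attr(res, "study") <- mapped
  res
}
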