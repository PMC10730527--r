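# Fixtures and independent oracles used across the suite.  Oracles are
# deliberately written as brute-force enumerations, independent of the
# package's code paths.

# --- fixtures ---------------------------------------------------------------

# root A with children B and C; IC values injected directly
chain_fixture <- function() {
  g <- onto_graph(
    terms = tibble::tibble(term_id = c("T:A", "T:B", "T:C"),
                           name = c("A", "B", "C")),
    edges = tibble::tibble(child = c("T:B", "T:C"), parent = "T:A",
                           relation = "is_a")
  )
  ic <- inject_ic(g, c("T:A" = 1.0, "T:B" = 2.0, "T:C" = 1.5))
  list(g = g, ic = ic)
}

inject_ic <- function(g, values) {
  stopifnot(all(g$terms$term_id %in% names(values)))
  out <- tibble::tibble(term_id = g$terms$term_id,
                        n_proteins = NA_integer_,
                        p = exp(-unname(values[g$terms$term_id])),
                        ic = unname(values[g$terms$term_id]))
  structure(out, total = NA_integer_, constant = NA_real_,
            class = c("ic_table", class(out)))
}

# random DAG: terms t1..tn, each node beyond the first gets 1-2 parents
# among earlier nodes, relation drawn at random
random_dag <- function(n, p_extra = 0.3,
                       relations = c("is_a", "part_of", "develops_from")) {
  ids <- sprintf("T:%03d", seq_len(n))
  child <- character(); parent <- character(); rel <- character()
  for (i in 2:n) {
    k <- 1L + (stats::runif(1) < p_extra)
    par <- sample(seq_len(i - 1L), min(k, i - 1L))
    child <- c(child, rep(ids[i], length(par)))
    parent <- c(parent, ids[par])
    rel <- c(rel, sample(relations, length(par), replace = TRUE))
  }
  onto_graph(tibble::tibble(term_id = ids, name = ids),
             tibble::tibble(child = child, parent = parent, relation = rel))
}

random_annotations <- function(g, n_proteins = 20, per_protein = 2) {
  tibble::tibble(
    protein_id = rep(sprintf("p%03d", seq_len(n_proteins)), each = per_protein),
    term_id = sample(g$terms$term_id, n_proteins * per_protein, replace = TRUE)
  ) |> dplyr::distinct()
}

random_network <- function(n_nodes = 20, p_edge = 0.3) {
  ids <- sprintf("n%03d", seq_len(n_nodes))
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  ppi_network(tibble::tibble(protein1 = pairs[1, keep],
                             protein2 = pairs[2, keep],
                             weight = stats::runif(sum(keep))),
              nodes = ids)
}

# --- oracles ----------------------------------------------------------------

# recursive DFS over the raw edge table
oracle_ancestors <- function(g, term, relations) {
  e <- g$edges[g$edges$relation %in% relations, , drop = FALSE]
  seen <- character()
  visit <- function(t) {
    if (t %in% seen) return(invisible())
    seen <<- c(seen, t)
    for (p in e$parent[e$child == t]) visit(p)
  }
  visit(term)
  sort(seen)
}

# full enumeration over the common-ancestor set
oracle_term_similarity <- function(g, ic, t1, t2, method = "lin",
                                   relations = c("is_a", "part_of")) {
  common <- intersect(oracle_ancestors(g, t1, relations),
                      oracle_ancestors(g, t2, relations))
  icv <- stats::setNames(ic$ic, ic$term_id)
  denom <- icv[[t1]] + icv[[t2]]
  if (denom == 0) return(0)
  best <- -Inf
  for (t in common) {
    v <- 2 * icv[[t]] / denom
    if (method == "schlicker_printed") v <- v * (1 + icv[[t]])
    if (method == "schlicker_classic") v <- v * (1 - exp(-icv[[t]]))
    best <- max(best, v)
  }
  best
}

# Mann-Whitney pair counting with ties scored 1/2
oracle_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive rank-sum permutation distribution; two-sided doubling rule
oracle_wilcoxon_two_sided <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pool), n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# upper-tail hypergeometric probability by log-space summation of
# binomial coefficients
oracle_hypergeom_upper <- function(k, n, K, N) {
  j <- k:min(n, K)
  if (length(j) == 0L || k > min(n, K)) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# convenience: planted-module membership tables from a synthetic world
world_members <- function(world, sp) {
  tr <- world$truth[world$truth$species == sp, ]
  list(
    members = tr$protein_id[tr$in_module],
    conserved = tr$protein_id[tr$in_module & tr$conserved],
    original = tr$protein_id[!is.na(tr$annotation) & tr$annotation == "original"],
    hidden = tr$protein_id[!is.na(tr$annotation) & tr$annotation == "hidden"]
  )
}
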