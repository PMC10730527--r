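# Guilt-by-association candidate scoring and cross-validation.
#
# The chi-square neighbourhood statistic compares a protein's observed
# annotated-neighbour mass n to its expectation e under the background
# annotation frequency:  score = sign(n - e) (n - e)^2 / e.  The sign keeps
# depleted neighbourhoods from ranking spuriously high.

# per-node (annotated-neighbour mass, total incident mass) in one pass
neighbour_masses <- function(net, annotated, mode) {
  e <- net$edges
  val <- if (mode == "weighted") e$weight else rep(1, nrow(e))
  tot <- ann_mass <- setNames(numeric(length(net$nodes)), net$nodes)
  if (nrow(e) > 0L) {
    add <- function(acc, ids, v) {
      s <- tapply(v, ids, sum)
      acc[names(s)] <- acc[names(s)] + s
      acc
    }
    tot <- add(add(tot, e$protein1, val), e$protein2, val)
    in1 <- e$protein2 %in% annotated  # protein2 annotated -> mass for protein1
    in2 <- e$protein1 %in% annotated
    if (any(in1)) ann_mass <- add(ann_mass, e$protein1[in1], val[in1])
    if (any(in2)) ann_mass <- add(ann_mass, e$protein2[in2], val[in2])
  }
  list(total = tot, annotated = ann_mass)
}

chi_sq_signed <- function(n, e) {
  ifelse(e == 0, 0, sign(n - e) * (n - e)^2 / e)
}

#' Chi-square neighbourhood score for candidate proteins
#'
#' For each scored protein, `n` is the annotated-neighbour mass (edge-weight
#' sum in `"weighted"` mode, neighbour count in `"count"` mode) and `e` the
#' product of the protein's total incident mass with the background
#' annotation frequency `|annotated in network| / |network nodes|`. The score
#' is the signed chi-square `sign(n - e) (n - e)^2 / e` (0 when `e = 0`).
#'
#' @param net A `ppi_network`.
#' @param annotated Character vector of annotated protein ids.
#' @param proteins Proteins to score (must be network nodes); defaults to
#'   all network nodes.
#' @param mode `"weighted"` (default; uses edge weights) or `"count"`
#'   (original unweighted formulation).
#' @return A tibble `protein_id`, `score`, `is_annotated`.
#' @export
hishigaki_score <- function(net, annotated, proteins = NULL,
                            mode = c("weighted", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "ppi_network"))
  if (is.null(proteins)) proteins <- net$nodes
  unknown <- setdiff(proteins, net$nodes)
  if (length(unknown) > 0L) {
    abort(paste0("unknown node(s): ", paste(head(unknown, 5L), collapse = ", ")))
  }
  ann_in <- intersect(annotated, net$nodes)
  freq <- length(ann_in) / length(net$nodes)
  m <- neighbour_masses(net, ann_in, mode)
  n <- m$annotated[proteins]
  e <- m$total[proteins] * freq
  tibble(protein_id = proteins,
         score = unname(chi_sq_signed(n, e)),
         is_annotated = proteins %in% ann_in)
}

# threshold sweep over distinct scores, descending; ties grouped.
# Returns roc (with leading (0,0) anchor) and pr tables plus trapezoid AUC.
sweep_curves <- function(score, positive) {
  p_tot <- sum(positive)
  n_tot <- sum(!positive)
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  pos <- positive[o]
  last <- c(which(diff(s) != 0), length(s))  # last index of each tie group
  cuts <- s[last]
  tp <- cumsum(pos)[last]
  np <- last
  fp <- np - tp
  roc <- tibble(cutoff = c(Inf, cuts),
                fpr = c(0, fp / n_tot),
                tpr = c(0, tp / p_tot))
  pr <- tibble(cutoff = cuts,
               recall = tp / p_tot,
               precision = tp / np)
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(roc = roc, pr = pr, auc = auc)
}

#' Leave-one-out cross-validation of candidate prediction
#'
#' Every annotated network protein is re-scored with its own annotation
#' hidden (it leaves both the neighbour set and the background count), while
#' every non-annotated protein is scored once against the full annotation
#' set. ROC and precision--recall curves are built from the pooled ranking by
#' a threshold sweep over distinct scores (ties grouped) and the ROC AUC is
#' computed by the trapezoid rule.
#'
#' @inheritParams hishigaki_score
#' @return A `cv_result` object with elements `scores` (tibble
#'   `protein_id`, `score`, `is_annotated`, `held_out`), `roc`, `pr`
#'   (tibbles) and `auc`.
#' @export
loo_cross_validate <- function(net, annotated, mode = c("weighted", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "ppi_network"))
  ann_in <- intersect(annotated, net$nodes)
  if (length(ann_in) < 2L) {
    abort("leave-one-out needs at least 2 annotated proteins in the network")
  }
  nn <- length(net$nodes)
  m <- neighbour_masses(net, ann_in, mode)
  # Held-out protein u: annotated \ {u}.  u is never its own neighbour, so
  # its annotated-neighbour mass is unchanged; only the background frequency
  # drops by one protein.
  pos_ids <- sort(ann_in)
  neg_ids <- setdiff(net$nodes, ann_in)
  pos_score <- chi_sq_signed(m$annotated[pos_ids],
                             m$total[pos_ids] * (length(ann_in) - 1L) / nn)
  neg_score <- chi_sq_signed(m$annotated[neg_ids],
                             m$total[neg_ids] * length(ann_in) / nn)
  scores <- tibble(
    protein_id = c(pos_ids, neg_ids),
    score = unname(c(pos_score, neg_score)),
    is_annotated = c(rep(TRUE, length(pos_ids)), rep(FALSE, length(neg_ids))),
    held_out = c(rep(TRUE, length(pos_ids)), rep(FALSE, length(neg_ids)))
  )
  cur <- sweep_curves(scores$score, scores$is_annotated)
  structure(list(scores = scores, roc = cur$roc, pr = cur$pr, auc = cur$auc),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d positives, %d negatives, AUC = %.3f\n",
              sum(x$scores$is_annotated), sum(!x$scores$is_annotated), x$auc))
  invisible(x)
}

#' Score cutoff achieving a cross-validated precision
#'
#' Scans the precision--recall curve for the lowest score cutoff (i.e.
#' maximal recall) whose cross-validated precision is at least the
#' threshold.
#'
#' @param cv A `cv_result`.
#' @param precision_threshold Required precision in (0, 1\].
#' @return The score cutoff, or `NA_real_` if the precision is never
#'   reached.
#' @export
select_score_cutoff <- function(cv, precision_threshold) {
  stopifnot(inherits(cv, "cv_result"))
  if (precision_threshold <= 0 || precision_threshold > 1) {
    abort("precision_threshold must lie in (0, 1]")
  }
  ok <- cv$pr$precision >= precision_threshold
  if (!any(ok)) return(NA_real_)
  min(cv$pr$cutoff[ok])
}

#' Call candidate proteins at a score cutoff
#'
#' Scores every non-annotated network node against the full annotation set
#' and returns those at or above the cutoff.
#'
#' @inheritParams hishigaki_score
#' @param cutoff Finite score cutoff (e.g. from [select_score_cutoff()]).
#' @return Sorted character vector of candidate protein ids (never contains
#'   annotated proteins).
#' @export
predict_candidates <- function(net, annotated, cutoff,
                               mode = c("weighted", "count")) {
  mode <- match.arg(mode)
  if (is.na(cutoff)) abort("cutoff is NA (precision threshold never reached)")
  sc <- hishigaki_score(net, annotated, mode = mode)
  sort(sc$protein_id[!sc$is_annotated & sc$score >= cutoff])
}
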