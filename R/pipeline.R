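# End-to-end orchestration of the workflow: simulate (optional) -> read
# inputs -> integrate -> cross-validate -> predict -> assemble modules ->
# compare across species -> enrichment and homology validation.  Every stage
# writes plain-text result tables under the output directory, and a manifest
# records every parameter and seed, so a run is a pure function of
# (inputs, config, seed).

#' Default pipeline configuration
#'
#' Returns the nested configuration list consumed by [run_pipeline()]. With
#' `simulate = TRUE` the input files are generated by [generate_world()]
#' under `out_dir/inputs` before the analysis stages run; otherwise paths
#' to existing ontology/annotation/links/ortholog files must be supplied
#' under `$inputs`, and the two target entity ids under `$entities`.
#'
#' @param seed Integer seed controlling simulation and any randomized step.
#' @param out_dir Output directory.
#' @param simulate Generate the inputs synthetically?
#' @param world Arguments passed to [synthetic_config()] when simulating.
#' @param similarity,integration,prediction,enrichment Stage parameter
#'   lists; see the returned structure for the recognised fields.
#' @return A named list (class `pipeline_config`).
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("modcompare-run-"),
                            simulate = TRUE, world = list(),
                            similarity = list(), integration = list(),
                            prediction = list(), enrichment = list()) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = isTRUE(simulate),
    world = utils::modifyList(list(), world),
    inputs = list(),
    entities = list(a = NULL, b = NULL),
    similarity = utils::modifyList(
      list(method = "lin", aggregate = "max", ic_constant = 1), similarity),
    integration = utils::modifyList(
      list(alpha = 0.5, min_weight = 0), integration),
    prediction = utils::modifyList(
      list(mode = "weighted", precision_threshold = list(a = 0.7, b = 0.7)),
      prediction),
    enrichment = utils::modifyList(list(alpha = 0.05), enrichment)
  )
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys mirror [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    seed = y$seed %||% 1L,
    out_dir = y$out_dir %||% tempfile("modcompare-run-"),
    simulate = y$simulate %||% is.null(y$inputs),
    world = y$world %||% list(),
    similarity = y$similarity %||% list(),
    integration = y$integration %||% list(),
    prediction = y$prediction %||% list(),
    enrichment = y$enrichment %||% list()
  )
  cfg$inputs <- y$inputs %||% list()
  cfg$entities <- y$entities %||% list(a = NULL, b = NULL)
  thr <- unlist(cfg$prediction$precision_threshold)
  if (any(thr <= 0 | thr > 1)) abort("precision thresholds must lie in (0, 1]")
  cfg
}

pipeline_inputs <- function(cfg) {
  need <- c("ontology", "annotations_a", "annotations_b", "links_a",
            "links_b", "orthologs")
  missing <- setdiff(need, names(cfg$inputs))
  if (length(missing) > 0L) {
    abort(paste0("config lacks input path(s): ", paste(missing, collapse = ", ")))
  }
  for (f in unlist(cfg$inputs[need])) {
    if (!file.exists(f)) abort(paste0("input file not found: ", f))
  }
  cfg$inputs
}

#' Run the full comparison workflow
#'
#' Executes the stages of the workflow in order and writes all result
#' tables, network exports and a `manifest.json` under `cfg$out_dir`. The
#' run is deterministic: identical configuration and seed produce
#' byte-identical outputs.
#'
#' @param cfg A `pipeline_config` (or path to a YAML file).
#' @return Invisibly, a `pipeline_result`: list with the per-species
#'   integrated networks, `cv` results, `modules`, the `comparison`,
#'   enrichment tables, the homology `validation` report, and `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) inform(paste0("[modcompare] ", sprintf(...)))

  if (cfg$simulate) {
    log_stage("simulate: generating synthetic world (seed %d)", cfg$seed)
    wcfg <- do.call(synthetic_config, c(list(seed = cfg$seed), cfg$world))
    world <- generate_world(wcfg)
    cfg$inputs <- as.list(write_world(world, file.path(out, "inputs")))
    ents <- attr(world$ontology, "entities")
    cfg$entities <- list(a = ents$A$target, b = ents$B$target)
  }
  ins <- pipeline_inputs(cfg)
  if (is.null(cfg$entities$a) || is.null(cfg$entities$b)) {
    abort("config lacks target entity ids")
  }

  log_stage("integrate: reading inputs and building integrated networks")
  g <- parse_obo(ins$ontology)
  ann <- list(a = read_annotations(ins$annotations_a),
              b = read_annotations(ins$annotations_b))
  ppi <- list(a = read_string_links(ins$links_a),
              b = read_string_links(ins$links_b))
  orth <- read_ortholog_table(ins$orthologs)

  sim <- cfg$similarity
  networks <- list(); ics <- list()
  for (sp in c("a", "b")) {
    ics[[sp]] <- compute_ic(ann[[sp]], g, constant = sim$ic_constant)
    sem <- build_semantic_network(ann[[sp]], g, ics[[sp]],
                                  proteins = ppi[[sp]]$nodes,
                                  method = sim$method,
                                  aggregate = sim$aggregate)
    networks[[sp]] <- integrate_networks(ppi[[sp]], sem,
                                         alpha = cfg$integration$alpha,
                                         min_weight = cfg$integration$min_weight)
    export_network(networks[[sp]], file.path(out, paste0("network_", sp, ".tsv")),
                   format = "tsv")
  }

  thr <- cfg$prediction$precision_threshold
  cvs <- list(); modules <- list(); predicted <- list(); original <- list()
  for (sp in c("a", "b")) {
    entity <- cfg$entities[[sp]]
    original[[sp]] <- collect_original_annotations(ann[[sp]], g, entity)
    n_ann <- sum(original[[sp]]$protein_id %in% networks[[sp]]$nodes)
    if (n_ann < 2L) {
      abort(paste0("entity ", entity, " (species ", sp, ") has ", n_ann,
                   " annotated protein(s) in the network; need at least 2"))
    }
    log_stage("cv: %s (%d annotated)", entity, n_ann)
    cvs[[sp]] <- loo_cross_validate(networks[[sp]],
                                    original[[sp]]$protein_id,
                                    mode = cfg$prediction$mode)
    readr::write_tsv(cvs[[sp]]$scores,
                     file.path(out, paste0("cv_scores_", sp, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(cvs[[sp]]$roc,
                     file.path(out, paste0("cv_roc_", sp, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(cvs[[sp]]$pr,
                     file.path(out, paste0("cv_pr_", sp, ".tsv")),
                     progress = FALSE)
    cutoff <- select_score_cutoff(cvs[[sp]], thr[[sp]])
    predicted[[sp]] <- if (is.na(cutoff)) character() else
      predict_candidates(networks[[sp]], original[[sp]]$protein_id, cutoff,
                         mode = cfg$prediction$mode)
    log_stage("predict: %s cutoff %.4g -> %d candidates", entity,
              cutoff, length(predicted[[sp]]))
    modules[[sp]] <- assemble_module(networks[[sp]], entity,
                                     original[[sp]], predicted[[sp]])
    write_module(modules[[sp]], file.path(out, paste0("module_", sp)))
  }

  log_stage("compare: conserved vs module-specific proteins")
  comparison <- compare_modules(modules$a, modules$b, orth,
                                species = c("a", "b"))
  readr::write_tsv(comparison$partition, file.path(out, "comparison_partition.tsv"),
                   progress = FALSE)
  readr::write_tsv(comparison$matched_pairs,
                   file.path(out, "comparison_matched_pairs.tsv"),
                   progress = FALSE)
  readr::write_tsv(comparison$tests, file.path(out, "comparison_tests.tsv"),
                   progress = FALSE)

  log_stage("enrich: predicted vs original protein sets")
  alpha_e <- cfg$enrichment$alpha
  enrichments <- list()
  for (sp in c("a", "b")) {
    study_pred <- intersect(predicted[[sp]], unique(ann[[sp]]$protein_id))
    enrichments[[sp]] <- if (length(study_pred) > 0L) {
      enrich_terms(ann[[sp]], study_pred, g, alpha = alpha_e)
    } else {
      tibble()
    }
    if (nrow(enrichments[[sp]]) > 0L) {
      readr::write_tsv(enrichments[[sp]],
                       file.path(out, paste0("enrichment_predicted_", sp, ".tsv")),
                       progress = FALSE)
    }
  }

  log_stage("validate: homology check of predicted proteins")
  validation <- validate_predictions_by_homology(predicted$a, modules$b, orth,
                                                 from = "a")
  readr::write_tsv(validation$report, file.path(out, "homology_validation.tsv"),
                   progress = FALSE)

  manifest <- list(
    package = "modcompare",
    version = as.character(utils::packageVersion("modcompare")),
    seed = cfg$seed,
    entities = cfg$entities,
    parameters = cfg[c("similarity", "integration", "prediction",
                       "enrichment", "world")],
    # input paths relative to out_dir where possible, so identical runs in
    # different directories leave identical manifests
    inputs = lapply(cfg$inputs, function(pth) {
      root <- paste0(normalizePath(out, winslash = "/"), "/")
      full <- normalizePath(pth, winslash = "/", mustWork = FALSE)
      if (startsWith(full, root)) substring(full, nchar(root) + 1L) else pth
    }),
    counts = list(
      network_nodes = lapply(networks, function(n) length(n$nodes)),
      network_edges = lapply(networks, function(n) nrow(n$edges)),
      original = lapply(original, nrow),
      predicted = lapply(predicted, length),
      module_sizes = lapply(modules, function(m) nrow(m$nodes)),
      auc = lapply(cvs, function(cv) cv$auc),
      conserved = as.list(setNames(comparison$tests$n_conserved,
                                   comparison$tests$species))
    )
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(structure(
    list(config = cfg, networks = networks, cv = cvs, modules = modules,
         predicted = predicted, comparison = comparison,
         enrichment = enrichments, validation = validation,
         manifest = manifest),
    class = "pipeline_result"
  ))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n  out_dir:", x$config$out_dir, "\n")
  cat(sprintf("  modules: %d (a) / %d (b); predicted %d / %d\n",
              nrow(x$modules$a$nodes), nrow(x$modules$b$nodes),
              length(x$predicted$a), length(x$predicted$b)))
  print(x$comparison$tests)
  invisible(x)
}

#' Homology validation of predicted proteins
#'
#' For each protein predicted in one species' module, checks whether at
#' least one of its orthologs lies in the homologous module of the other
#' species, and if so under which origin label (directly annotated,
#' annotated to a part or precursor, or itself predicted). Orthologs of a
#' prediction landing in the homologous module corroborate the prediction.
#'
#' @param predicted Character vector of predicted protein ids.
#' @param module_other The other species' `network_module`.
#' @param orth Ortholog data frame (`protein_a`, `protein_b`).
#' @param from `"a"` if `predicted` are species-A ids, `"b"` otherwise.
#' @return A list with `report` (tibble `protein_id`, `n_orthologs`,
#'   `n_in_module`, `validated`, `origins`) and `counts` (tibble
#'   `origin`, `n` over validated predictions, plus totals).
#' @export
validate_predictions_by_homology <- function(predicted, module_other, orth,
                                             from = c("a", "b")) {
  from <- match.arg(from)
  stopifnot(inherits(module_other, "network_module"))
  orth <- as_tibble(orth)
  src <- if (from == "a") orth$protein_a else orth$protein_b
  dst <- if (from == "a") orth$protein_b else orth$protein_a
  origin_of <- setNames(module_other$nodes$origin,
                        module_other$nodes$protein_id)
  report <- purrr::map_dfr(sort(unique(predicted)), function(p) {
    tgt <- unique(dst[src == p])
    hit <- intersect(tgt, names(origin_of))
    tibble(protein_id = p,
           n_orthologs = length(tgt),
           n_in_module = length(hit),
           validated = length(hit) > 0L,
           origins = paste(sort(unique(unname(origin_of[hit]))),
                           collapse = ";"))
  })
  if (nrow(report) == 0L) {
    report <- tibble(protein_id = character(), n_orthologs = integer(),
                     n_in_module = integer(), validated = logical(),
                     origins = character())
  }
  validated_origins <- unlist(strsplit(report$origins[report$validated], ";"))
  counts <- tibble(
    origin = c("original_direct", "original_part_or_precursor", "predicted"),
  ) |>
    mutate(n = vapply(.data$origin,
                      function(o) sum(validated_origins == o), 0L,
                      USE.NAMES = FALSE))
  list(report = report, counts = counts,
       n_predicted = nrow(report), n_validated = sum(report$validated))
}
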