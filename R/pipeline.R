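#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis in one serializable
#' list: the data source (simulation configs, or paths to an expression TSV
#' + sample sheet and annotation/edge TSVs), the DEG caller's threshold and
#' permutation count, the SOM schedule, the gene-set threshold, and the
#' enrichment test/correction. One global `seed` deterministically derives a
#' seed per stage, so stages can be re-run in isolation and an identical
#' config reproduces an identical bundle.
#'
#' @param seed global seed.
#' @param sim [sim_config] used when no expression file is given.
#' @param ontology [onto_config] used when no annotation file is given.
#' @param expression_file,sample_sheet,annotation_file,edge_file optional
#'   input paths; when provided they replace the corresponding simulation.
#' @param normalize quantile-normalize before analysis (default `TRUE`).
#' @param alpha_adj,n_perm,wy_method,fold_filter DEG caller parameters
#'   (see [deg_anova()]).
#' @param som_grid,som_epochs,som_alpha,som_radius SOM schedule
#'   (see [som_fit()]).
#' @param tau,selection_rule gene-set selection (see [select_genesets()]).
#' @param go_test,go_correction,go_alpha,discard_iea enrichment parameters
#'   (see [enrich_geneset()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       sim = NULL, ontology = NULL,
                       expression_file = NULL, sample_sheet = NULL,
                       annotation_file = NULL, edge_file = NULL,
                       normalize = TRUE,
                       alpha_adj = 0.1, n_perm = 1000, wy_method = "maxT",
                       fold_filter = FALSE,
                       som_grid = c(3, 2), som_epochs = 500,
                       som_alpha = c(0.5, 0.01), som_radius = c(1, 0.5),
                       tau = 0.75, selection_rule = "box",
                       go_test = "binomial", go_correction = "bonferroni",
                       go_alpha = 0.05, discard_iea = TRUE) {
  if (is.null(sim) && is.null(expression_file))
    sim <- sim_config(seed = stage_seed(seed, "simulate"))
  if (is.null(ontology) && is.null(annotation_file))
    ontology <- onto_config(seed = stage_seed(seed, "ontology"))
  structure(as.list(environment()), class = "run_config")
}

#' Run the full temporal knockdown analysis
#'
#' Executes simulate/load -> quantile normalization -> two-model ANOVA DEG
#' detection with Westfall-Young adjustment -> SOM clustering of DEG ratio
#' profiles -> interquartile-box gene-set selection -> overrepresentation
#' analysis of each gene-set, and assembles a JSON-serializable summary
#' (DEG counts per model and overlap, cluster sizes, gene-set sizes,
#' significant terms). Identical config + seed reproduces an identical
#' bundle. If any stage fails the error is re-signalled with the stage name
#' and, when writing to `out_dir`, outputs of completed stages are kept.
#'
#' @param config a [run_config].
#' @param out_dir optional directory; when given, every stage's table is
#'   written there as TSV, the summary and resolved config as JSON.
#' @return Object of class `tempodeg_run`: list with `expr`, `truth`,
#'   `deg` ([deg_anova]), `som` ([som_fit] or `NULL`), `stats`, `selection`,
#'   `enrichment` (named list of [enrich_geneset] tables), `summary`,
#'   `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_stage <- function(...) message("[tempodeg] ", ...)

  # --- data -----------------------------------------------------------------
  truth <- NULL
  expr <- stage("data", {
    if (!is.null(config$expression_file)) {
      read_expression(config$expression_file, config$sample_sheet)
    } else {
      sim <- simulate_expression(config$sim)
      truth <- sim$truth
      sim$expr
    }
  })
  log_stage("data: ", nrow(expr$values), " genes x ", ncol(expr$values),
            " samples")

  onto <- stage("annotations", {
    if (!is.null(config$annotation_file)) {
      list(annotations = read_annotations(config$annotation_file),
           edges = if (!is.null(config$edge_file)) read_edges(config$edge_file)
                   else data.frame(child = character(0),
                                   parent = character(0)),
           planted_term = NA_character_, truth = truth)
    } else {
      simulate_ontology(config$ontology, truth = truth,
                        universe = rownames(expr$values))
    }
  })
  truth <- onto$truth %||% truth

  if (!is.null(out_dir)) {
    write_expression(expr, file.path(out_dir, "expression.tsv"),
                     file.path(out_dir, "samples.tsv"))
    write_tsv(onto$annotations, file.path(out_dir, "annotations.tsv"))
    write_tsv(onto$edges, file.path(out_dir, "edges.tsv"))
  }

  # --- normalize ------------------------------------------------------------
  if (isTRUE(config$normalize)) expr <- stage("normalize",
                                              quantile_normalize(expr))

  # --- DEG detection --------------------------------------------------------
  deg <- stage("deg", deg_anova(
    expr, alpha_adj = config$alpha_adj, n_perm = config$n_perm,
    seed = stage_seed(config$seed, "deg"), method = config$wy_method,
    fold_filter = config$fold_filter))
  log_stage("deg: ", deg$summary$n_deg, " DEGs (model 1: ",
            deg$summary$n_model1, ", model 2: ", deg$summary$n_model2, ")")
  if (!is.null(out_dir))
    write_deg(deg, file.path(out_dir, "deg_table.tsv"))

  # --- clustering + gene-sets ----------------------------------------------
  degs <- deg_genes(deg)
  som <- NULL; stats <- NULL; selection <- NULL
  if (length(degs)) {
    profiles <- stage("cluster", ratio_profiles(expr, degs))
    som <- stage("cluster", som_fit(
      profiles, grid = config$som_grid, epochs = config$som_epochs,
      alpha = config$som_alpha, radius = config$som_radius,
      seed = stage_seed(config$seed, "som")))
    log_stage("cluster: sizes ", paste(som$sizes, collapse = ", "))
    stats <- stage("genesets", cluster_box_stats(som$assignment, profiles,
                                                 prod(config$som_grid)))
    selection <- stage("genesets", select_genesets(
      stats, som$assignment, tau = config$tau, rule = config$selection_rule))
    if (!is.null(out_dir)) {
      write_tsv(data.frame(gene = names(som$assignment),
                           cluster = unname(som$assignment)),
                file.path(out_dir, "assignments.tsv"))
      write_genesets(selection, file.path(out_dir, "box_stats.tsv"),
                     file.path(out_dir, "genesets.tsv"))
    }
  } else {
    log_stage("cluster: no DEGs, skipping")
    selection <- structure(list(genesets = list(), stats = NULL,
                                tau = config$tau, rule = config$selection_rule),
                           class = "geneset_selection")
  }

  # --- enrichment -----------------------------------------------------------
  universe <- rownames(expr$values)
  enrichment <- list()
  for (gs in selection$genesets) {
    tab <- stage("enrich", enrich_geneset(
      gs$genes, onto$annotations, onto$edges, universe,
      test = config$go_test, correction = config$go_correction,
      alpha = config$go_alpha, discard_iea = config$discard_iea))
    enrichment[[gs$label]] <- tab
    if (!is.null(out_dir))
      write_tsv(as.data.frame(tab),
                file.path(out_dir, paste0("enrichment_", gs$label, ".tsv")))
  }
  log_stage("enrich: ", length(enrichment), " gene-sets tested")

  summary <- list(
    n_genes = nrow(expr$values),
    n_deg = deg$summary$n_deg,
    n_model1 = deg$summary$n_model1,
    n_model2 = deg$summary$n_model2,
    n_common = deg$summary$n_common,
    cluster_sizes = if (!is.null(som)) as.integer(som$sizes) else integer(0),
    geneset_sizes = lapply(selection$genesets,
                           function(gs) length(gs$genes)),
    significant_terms = lapply(enrichment,
                               function(t) t$term[t$significant]))
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    cfg <- config
    cfg$sim$archetypes <- lapply(cfg$sim$archetypes, unclass)
    jsonlite::write_json(lapply(cfg, function(z) if (is.null(z)) NA else z),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  structure(list(expr = expr, truth = truth, onto = onto, deg = deg,
                 som = som, stats = stats, selection = selection,
                 enrichment = enrichment, summary = summary,
                 config = config), class = "tempodeg_run")
}

#' @export
print.tempodeg_run <- function(x, ...) {
  s <- x$summary
  cat("tempodeg pipeline run\n")
  cat("  genes: ", s$n_genes, "; DEGs: ", s$n_deg, " (m1 ", s$n_model1,
      ", m2 ", s$n_model2, ", common ", s$n_common, ")\n", sep = "")
  if (length(s$cluster_sizes))
    cat("  cluster sizes: ", paste(s$cluster_sizes, collapse = ", "), "\n",
        sep = "")
  for (lbl in names(s$geneset_sizes))
    cat("  ", lbl, ": ", s$geneset_sizes[[lbl]], " genes, significant terms: ",
        paste(s$significant_terms[[lbl]], collapse = ", "), "\n", sep = "")
  invisible(x)
}
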