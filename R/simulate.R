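#' Temporal expression archetype
#'
#' An archetype is a planted temporal differential-expression shape: the mean
#' knockdown-minus-control log2 ratio at each sampled day, shared by a block
#' of genes. Archetypes are the planted truth the synthetic expression
#' generator builds into its matrices.
#'
#' @param label archetype name.
#' @param count number of genes carrying the shape.
#' @param ratio numeric vector of per-day mean log2 ratios (same length as
#'   the `days` of the simulation it is used with).
#' @return list of class `archetype`.
#' @export
archetype <- function(label, count, ratio) {
  stopifnot(is.character(label), length(label) == 1L,
            count >= 1, is.numeric(ratio))
  structure(list(label = label, count = as.integer(count),
                 ratio = as.numeric(ratio)), class = "archetype")
}

#' Default planted archetypes
#'
#' Six temporal shapes spanning the qualitative cluster morphologies seen in
#' short knockdown time courses: strong and moderate monotone up-regulation
#' (the strong class exceeds a 4-fold change, i.e. log2 ratio > 2, by the
#' last day), a transient down-then-up shape, an early drop that is then
#' maintained, and strong and moderate monotone down-regulation. Per-day mean
#' log2 ratios are given at days 1, 3 and 5; gene counts default to the
#' cluster sizes of the motivating knockdown experiment (33, 77, 9, 12, 27,
#' 80).
#'
#' @param counts integer vector of six gene counts.
#' @return list of six [archetype] objects.
#' @export
default_archetypes <- function(counts = c(33, 77, 9, 12, 27, 80)) {
  stopifnot(length(counts) == 6L)
  list(
    archetype("up_strong",     counts[1], c(0,  0.8,  2.2)),
    archetype("up_moderate",   counts[2], c(0,  0.5,  1.2)),
    archetype("down_up",       counts[3], c(0, -1.2,  0.6)),
    archetype("down_hold",     counts[4], c(0, -1.3, -1.2)),
    archetype("down_strong",   counts[5], c(0, -1.5, -2.5)),
    archetype("down_moderate", counts[6], c(0, -0.3, -1.2))
  )
}

#' Simulation configuration
#'
#' Describes a synthetic two-group time-course microarray experiment:
#' `n_genes` genes measured in `control` and `knockdown` groups on each of
#' `days`, with `n_replicates` arrays per group x day cell. A subset of genes
#' carries planted temporal archetypes (see [archetype]); everything else is
#' null. Values are log2 intensities: per-gene baselines are Gaussian
#' (`baseline_mean`, `baseline_sd`), a per-gene day effect of sd
#' `day_effect_sd` is shared by both groups (so it never contributes to the
#' knockdown/control ratio), and i.i.d. Gaussian measurement noise of sd
#' `noise_sd` is added to every observation.
#'
#' @param n_genes total genes on the array.
#' @param n_replicates arrays per group x day cell.
#' @param days strictly increasing sampling days.
#' @param archetypes list of [archetype] objects; their counts must sum to
#'   at most `n_genes`.
#' @param noise_sd log2-scale measurement noise sd (> 0).
#' @param baseline_mean,baseline_sd distribution of per-gene control means.
#' @param day_effect_sd sd of the per-gene common time trend (0 disables).
#' @param seed RNG seed; identical configs with identical seeds reproduce
#'   bit-identical matrices.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_replicates = 3, days = c(1, 3, 5),
                       archetypes = default_archetypes(), noise_sd = 0.3,
                       baseline_mean = 7, baseline_sd = 1.5,
                       day_effect_sd = 0.2, seed = 1) {
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (any(diff(days) <= 0)) stop("days must be strictly increasing", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (length(archetypes) && !all(vapply(archetypes, inherits, TRUE, "archetype")))
    stop("archetypes must be a list of archetype() objects", call. = FALSE)
  n_planted <- sum(vapply(archetypes, function(a) a$count, 1L))
  if (n_planted > n_genes)
    stop("configuration error: archetype gene counts (", n_planted,
         ") exceed n_genes (", n_genes, ")", call. = FALSE)
  for (a in archetypes)
    if (length(a$ratio) != length(days))
      stop("archetype '", a$label, "' has ", length(a$ratio),
           " ratios for ", length(days), " days", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 days = as.numeric(days), archetypes = archetypes,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, day_effect_sd = day_effect_sd,
                 seed = seed), class = "sim_config")
}

#' Generate a synthetic knockdown time-course expression matrix
#'
#' Builds the log2-intensity matrix described by a [sim_config] together with
#' a machine-readable truth record. For a planted gene the expected
#' knockdown-minus-control difference at day d equals its archetype's ratio
#' at d; for null genes it is 0 at every day. The truth record also lists the
#' planted early/down genes: members of archetypes whose second-day mean
#' ratio is at or below -0.75, the set a downstream interquartile-box
#' selection at the default threshold is expected to recover.
#'
#' @param config a [sim_config].
#' @return list with elements `expr` (an [expr_set]) and `truth` (list with
#'   `gene_archetype` -- named vector, `"null"` for unplanted genes --,
#'   `planted_genes`, `early_down_genes`, and `planted_term`, filled in by
#'   [simulate_ontology]).
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 100, seed = 7))
#' table(sim$truth$gene_archetype)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    g <- config$n_genes; r <- config$n_replicates; days <- config$days
    b <- length(days)
    genes <- sprintf("g%04d", seq_len(g))
    design <- data.frame(
      sample_id = paste0(rep(c("ctrl", "kd"), each = b * r),
                         "_d", rep(rep(days, each = r), 2),
                         "_r", rep(seq_len(r), times = 2 * b)),
      group = rep(c("control", "knockdown"), each = b * r),
      day = rep(rep(days, each = r), 2),
      replicate = rep(seq_len(r), times = 2 * b),
      stringsAsFactors = FALSE)

    # per-gene mean log2 ratio at each day: 0 unless planted
    ratio <- matrix(0, g, b)
    arch <- rep("null", g)
    at <- 1L
    for (a in config$archetypes) {
      idx <- seq.int(at, length.out = a$count)
      ratio[idx, ] <- matrix(a$ratio, a$count, b, byrow = TRUE)
      arch[idx] <- a$label
      at <- at + a$count
    }

    baseline <- rnorm(g, config$baseline_mean, config$baseline_sd)
    dayfx <- matrix(rnorm(g * b, 0, config$day_effect_sd), g, b)

    mu <- matrix(0, g, nrow(design))
    for (j in seq_len(nrow(design))) {
      d <- match(design$day[j], days)
      mu[, j] <- baseline + dayfx[, d] +
        if (design$group[j] == "knockdown") ratio[, d] else 0
    }
    values <- mu + matrix(rnorm(length(mu), 0, config$noise_sd), g)
    rownames(values) <- genes
    colnames(values) <- design$sample_id

    names(arch) <- genes
    early_idx <- vapply(config$archetypes,
                        function(a) length(a$ratio) >= 2 && a$ratio[2] <= -0.75,
                        TRUE)
    early_labels <- vapply(config$archetypes[early_idx],
                           function(a) a$label, "")
    truth <- list(
      gene_archetype = arch,
      planted_genes = genes[arch != "null"],
      early_down_genes = genes[arch %in% early_labels],
      planted_term = NA_character_)
    list(expr = expr_set(values, design), truth = truth)
  })
}

#' Ontology simulation configuration
#'
#' Describes a toy ontology: `n_terms` terms layered into `dag_depth` levels
#' (each non-root term has one parent in the level above, so the edge table
#' is acyclic by construction), gene-term annotations drawn so each gene
#' carries `annotations_per_gene` annotations on average, each tagged with an
#' evidence code drawn from `evidence_mix` (electronic `IEA` vs experimental
#' `EXP`). One deepest-level term is planted: inside a designated gene set
#' its annotation probability is multiplied by `enrichment_factor`.
#'
#' @param n_terms number of terms.
#' @param dag_depth number of levels; 1 gives a flat ontology with no edges.
#' @param annotations_per_gene mean annotations per gene.
#' @param evidence_mix named proportions over `c(IEA=, EXP=)`; must sum to 1.
#' @param enrichment_factor fold over-annotation of the planted term inside
#'   the planted set (>= 1).
#' @param seed RNG seed.
#' @return list of class `onto_config`.
#' @export
onto_config <- function(n_terms = 50, dag_depth = 3, annotations_per_gene = 3,
                        evidence_mix = c(IEA = 0.3, EXP = 0.7),
                        enrichment_factor = 8, seed = 1) {
  if (enrichment_factor < 1)
    stop("configuration error: enrichment_factor must be >= 1", call. = FALSE)
  if (abs(sum(evidence_mix) - 1) > 1e-8)
    stop("evidence_mix proportions must sum to 1", call. = FALSE)
  if (dag_depth < 1) stop("dag_depth must be >= 1", call. = FALSE)
  structure(list(n_terms = as.integer(n_terms), dag_depth = as.integer(dag_depth),
                 annotations_per_gene = annotations_per_gene,
                 evidence_mix = evidence_mix,
                 enrichment_factor = enrichment_factor, seed = seed),
            class = "onto_config")
}

#' Generate a toy ontology with a planted enriched term
#'
#' Draws an annotation table (gene, term, evidence code) and a child-parent
#' edge table over a layered acyclic term graph. The planted term -- chosen
#' from the deepest layer -- annotates genes of `truth$early_down_genes`
#' (or `planted_set`) at `enrichment_factor` times its background rate, and
#' is guaranteed at least two experimentally-coded annotations inside the
#' planted set so it survives electronic-evidence filtering.
#'
#' @param config an [onto_config].
#' @param truth truth record from [simulate_expression] (its
#'   `early_down_genes` is the planted set) or `NULL` if `planted_set` given.
#' @param universe character vector of all gene ids.
#' @param planted_set optional explicit planted gene set (subset of
#'   `universe`).
#' @return list with `annotations` (data.frame gene_id/term_id/evidence_code),
#'   `edges` (data.frame child/parent), `terms`, `planted_term`, and the
#'   updated `truth`.
#' @export
simulate_ontology <- function(config, truth = NULL, universe,
                              planted_set = NULL) {
  stopifnot(inherits(config, "onto_config"))
  if (is.null(planted_set)) planted_set <- truth$early_down_genes
  if (length(universe) == 0) stop("universe must be non-empty", call. = FALSE)
  if (!all(planted_set %in% universe))
    stop("planted set must be a subset of the universe", call. = FALSE)
  with_seed(config$seed, {
    nt <- config$n_terms
    terms <- sprintf("T%04d", seq_len(nt))
    depth <- ((seq_len(nt) - 1L) %% config$dag_depth) + 1L
    # each non-root term gets one parent in the layer above
    edges <- data.frame(child = character(0), parent = character(0),
                        stringsAsFactors = FALSE)
    if (config$dag_depth > 1L) {
      kid <- which(depth > 1L)
      par <- vapply(kid, function(i) {
        cand <- which(depth == depth[i] - 1L)
        terms[cand[sample.int(length(cand), 1L)]]
      }, "")
      edges <- data.frame(child = terms[kid], parent = par,
                          stringsAsFactors = FALSE)
    }
    deepest <- which(depth == max(depth))
    planted_term <- terms[deepest[sample.int(length(deepest), 1L)]]

    p0 <- min(1, config$annotations_per_gene / nt)
    prob <- matrix(p0, length(universe), nt,
                   dimnames = list(universe, terms))
    if (length(planted_set))
      prob[planted_set, planted_term] <-
        min(1, config$enrichment_factor * p0)
    hit <- matrix(runif(length(prob)) < prob, nrow(prob), ncol(prob))
    idx <- which(hit, arr.ind = TRUE)
    ann <- data.frame(gene_id = universe[idx[, 1]],
                      term_id = terms[idx[, 2]],
                      evidence_code = sample(names(config$evidence_mix),
                                             nrow(idx), replace = TRUE,
                                             prob = config$evidence_mix),
                      stringsAsFactors = FALSE)
    # the planted term must keep >= 2 experimentally-coded annotations in the
    # planted set (so the planted signal is observable after IEA filtering)
    if (length(planted_set) >= 2) {
      in_set <- ann$term_id == planted_term & ann$gene_id %in% planted_set &
        ann$evidence_code != "IEA"
      need <- 2L - sum(in_set)
      if (need > 0) {
        pick <- setdiff(planted_set,
                        ann$gene_id[ann$term_id == planted_term &
                                      ann$evidence_code != "IEA"])[seq_len(need)]
        extra <- data.frame(gene_id = pick, term_id = planted_term,
                            evidence_code = "EXP", stringsAsFactors = FALSE)
        ann <- rbind(ann, extra)
        ann <- ann[!duplicated(ann[c("gene_id", "term_id", "evidence_code")]), ]
      }
    }
    rownames(ann) <- NULL
    if (!is.null(truth)) truth$planted_term <- planted_term
    list(annotations = ann, edges = edges, terms = terms,
         planted_term = planted_term, truth = truth)
  })
}

#' Write simulated data to disk
#'
#' Writes the expression TSV + sample sheet, the GAF-like annotation TSV and
#' edge TSV, and the truth record as JSON.
#'
#' @param sim result of [simulate_expression].
#' @param onto result of [simulate_ontology] (optional).
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, onto = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(sim$expr, file.path(dir, "expression.tsv"),
                   file.path(dir, "samples.tsv"))
  truth <- if (!is.null(onto)) onto$truth %||% sim$truth else sim$truth
  truth$gene_archetype <- as.list(truth$gene_archetype)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(onto)) {
    write_tsv(onto$annotations, file.path(dir, "annotations.tsv"))
    write_tsv(onto$edges, file.path(dir, "edges.tsv"))
  }
  invisible(dir)
}
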