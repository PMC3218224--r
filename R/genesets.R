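#' Per-cluster per-day box-plot statistics
#'
#' For every cluster and sampling day, the quartiles (Q1, Q2, Q3) of the
#' member genes' log2 ratios at that day, computed by linear interpolation
#' between order statistics (the convention under which the quartiles of
#' (1,2,3,4) are 1.75 / 2.5 / 3.25; `stats::quantile` type 7). Empty
#' clusters are reported with `n = 0` and `NA` quartiles rather than being
#' dropped.
#'
#' @param assignment named integer vector (gene -> cluster), e.g.
#'   `som_fit(...)$assignment`.
#' @param profiles genes x days ratio matrix covering every assigned gene.
#' @param n_clusters total clusters (default: max assignment).
#' @return data.frame with columns `cluster, day, n, q1, q2, q3`. The `day`
#'   column carries the numeric day parsed from the profile column names.
#' @export
cluster_box_stats <- function(assignment, profiles,
                              n_clusters = max(assignment)) {
  profiles <- as.matrix(profiles)
  miss <- setdiff(names(assignment), rownames(profiles))
  if (length(miss))
    stop("assigned genes missing a profile: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  days <- as.numeric(sub("^day", "", colnames(profiles)))
  out <- expand.grid(cluster = seq_len(n_clusters), day = days)
  out <- out[order(out$cluster, out$day), ]
  out$n <- 0L; out$q1 <- NA_real_; out$q2 <- NA_real_; out$q3 <- NA_real_
  for (cl in seq_len(n_clusters)) {
    mem <- names(assignment)[assignment == cl]
    for (k in seq_along(days)) {
      i <- out$cluster == cl & out$day == days[k]
      out$n[i] <- length(mem)
      if (length(mem)) {
        q <- stats::quantile(profiles[mem, k], c(0.25, 0.5, 0.75),
                             type = 7, names = FALSE)
        out$q1[i] <- q[1]; out$q2[i] <- q[2]; out$q3[i] <- q[3]
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Select stage/direction gene-sets by the interquartile-box rule
#'
#' A cluster is selected as significantly changed at a day when its whole
#' interquartile box of log2 ratios lies beyond the threshold band: down when
#' Q3 <= -tau, up when Q1 >= +tau (default tau = 0.75). Selections at the
#' second sampled day form the early gene-sets and selections at the last
#' day form the late gene-sets; co-selected clusters of the same direction
#' are pooled into one set (e.g. `early_down`, `late_up`, `late_down`).
#' Selections at other days (notably day 1) are flagged in the returned
#' stats table but produce no gene-set. The alternative median reading
#' (|Q2| > tau) is available via `rule = "median"`.
#'
#' @param stats data.frame from [cluster_box_stats()].
#' @param assignment named integer vector (gene -> cluster).
#' @param tau positive threshold on the log2-ratio scale.
#' @param rule `"box"` (interquartile box beyond the band) or `"median"`.
#' @return Object of class `geneset_selection`: list with `genesets` (each a
#'   list `label, day, direction, clusters, genes`), `stats` (input stats
#'   with `selected` and `direction` columns), `tau`, `rule`.
#' @export
select_genesets <- function(stats, assignment, tau = 0.75,
                            rule = c("box", "median")) {
  rule <- match.arg(rule)
  if (!is.numeric(tau) || tau <= 0)
    stop("configuration error: tau must be > 0", call. = FALSE)
  need <- c("cluster", "day", "n", "q1", "q2", "q3")
  if (!all(need %in% names(stats)))
    stop("stats must come from cluster_box_stats()", call. = FALSE)
  nonempty <- stats$n > 0
  if (rule == "box") {
    down <- nonempty & !is.na(stats$q3) & stats$q3 <= -tau
    up <- nonempty & !is.na(stats$q1) & stats$q1 >= tau
  } else {
    down <- nonempty & !is.na(stats$q2) & stats$q2 < -tau
    up <- nonempty & !is.na(stats$q2) & stats$q2 > tau
  }
  stats$selected <- down | up
  stats$direction <- ifelse(down, "down", ifelse(up, "up", ""))

  days <- sort(unique(stats$day))
  stage_of <- c()
  if (length(days) >= 2) stage_of[as.character(days[2])] <- "early"
  stage_of[as.character(days[length(days)])] <- "late"

  genesets <- list()
  for (stage_day in names(stage_of)) {
    for (dir in c("up", "down")) {
      rows <- stats$selected & stats$day == as.numeric(stage_day) &
        stats$direction == dir
      if (!any(rows)) next
      cls <- stats$cluster[rows]
      genes <- names(assignment)[assignment %in% cls]
      label <- paste(stage_of[[stage_day]], dir, sep = "_")
      genesets[[label]] <- list(label = label,
                                day = as.numeric(stage_day),
                                direction = dir, clusters = cls,
                                genes = genes)
    }
  }
  structure(list(genesets = genesets, stats = stats, tau = tau, rule = rule),
            class = "geneset_selection")
}

#' @export
print.geneset_selection <- function(x, ...) {
  cat("Gene-set selection (", x$rule, " rule, tau = ", x$tau, ")\n", sep = "")
  if (!length(x$genesets)) {
    cat("  no cluster box lies beyond the threshold band\n")
  } else {
    for (gs in x$genesets)
      cat("  ", gs$label, ": ", length(gs$genes), " genes (clusters ",
          paste(gs$clusters, collapse = ","), ", day ", gs$day, ")\n",
          sep = "")
  }
  invisible(x)
}

#' Write selection outputs
#'
#' @param sel a [select_genesets] result.
#' @param stats_file TSV path for the per-cluster box statistics.
#' @param genesets_file TSV path for the member lists (columns
#'   `geneset, gene`).
#' @return invisibly, `genesets_file`.
#' @export
write_genesets <- function(sel, stats_file, genesets_file) {
  stopifnot(inherits(sel, "geneset_selection"))
  write_tsv(sel$stats, stats_file)
  rows <- do.call(rbind, lapply(sel$genesets, function(gs)
    if (length(gs$genes))
      data.frame(geneset = gs$label, gene = gs$genes,
                 stringsAsFactors = FALSE)))
  if (is.null(rows))
    rows <- data.frame(geneset = character(0), gene = character(0))
  write_tsv(rows, genesets_file)
  invisible(genesets_file)
}
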