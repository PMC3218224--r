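#' Quantile-normalize an expression matrix
#'
#' Forces every array (column) to share the same empirical intensity
#' distribution: each column's sorted values are replaced by the row-wise
#' mean of all columns' sorted values, assigned back by within-column rank.
#' Ties within a column receive the mean of the row-means they span. The
#' transform is idempotent. Computation is delegated to
#' [limma::normalizeQuantiles()].
#'
#' @param x an [expr_set] or a plain numeric matrix with at least 2 columns.
#' @return The same type as `x`, quantile-normalized.
#' @examples
#' m <- cbind(a = c(2, 4, 6), b = c(4, 8, 12))
#' rownames(m) <- paste0("g", 1:3)
#' quantile_normalize(m)  # both columns become (3, 6, 9)
#' @export
quantile_normalize <- function(x) {
  m <- if (inherits(x, "expr_set")) x$values else as.matrix(x)
  if (ncol(m) < 2L)
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  if (any(!is.finite(m)))
    stop("validation error: non-finite values in input", call. = FALSE)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  if (inherits(x, "expr_set")) expr_set(out, x$design) else out
}

#' Per-gene temporal knockdown/control log2-ratio profiles
#'
#' For each gene and each day, the mean log2 intensity over knockdown
#' replicates minus the mean over control replicates. These per-day ratio
#' vectors are the input to SOM temporal clustering and to the
#' interquartile-box gene-set selection.
#'
#' @param x an [expr_set]; both groups must be present at every day.
#' @param genes gene ids to profile (default: all).
#' @return numeric matrix, genes x days, columns named `day<d>`.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 20, seed = 1))
#' head(ratio_profiles(sim$expr))
#' @export
ratio_profiles <- function(x, genes = rownames(x$values)) {
  stopifnot(inherits(x, "expr_set"))
  d <- x$design
  days <- days_of(x)
  miss <- setdiff(genes, rownames(x$values))
  if (length(miss))
    stop("unknown genes: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  v <- x$values[genes, , drop = FALSE]
  out <- matrix(NA_real_, length(genes), length(days),
                dimnames = list(genes, paste0("day", days)))
  for (i in seq_along(days)) {
    kd <- d$group == "knockdown" & d$day == days[i]
    ct <- d$group == "control" & d$day == days[i]
    if (!any(kd) || !any(ct))
      stop("design error: a (group, day) cell has zero samples at day ",
           days[i], call. = FALSE)
    out[, i] <- rowMeans(v[, kd, drop = FALSE]) -
      rowMeans(v[, ct, drop = FALSE])
  }
  out
}
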