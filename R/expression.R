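#' Expression set container
#'
#' Bundles a gene x sample matrix of log2 intensities with its sample design
#' (group, day, replicate). All downstream steps -- normalization, ratio
#' profiles, the two-way ANOVA DEG caller -- operate on this container.
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns. Values are log2-scale intensities and must be finite.
#' @param design data.frame with one row per column of `values` and columns
#'   `sample_id`, `group` (one of `"control"`, `"knockdown"`), `day`
#'   (numeric), `replicate` (integer).
#' @return An object of class `expr_set`: a list with elements `values` and
#'   `design`.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 50, seed = 1))
#' es <- sim$expr
#' dim(es)
#' @export
expr_set <- function(values, design) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    stop("`values` must have gene ids as rownames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("gene ids must be unique", call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values contain missing or non-finite entries", call. = FALSE)
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "day", "replicate")
  if (!all(need %in% names(design)))
    stop("design must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(design) != ncol(values))
    stop("design has ", nrow(design), " rows but matrix has ",
         ncol(values), " columns", call. = FALSE)
  if (!all(design$group %in% c("control", "knockdown")))
    stop("group must be 'control' or 'knockdown'", call. = FALSE)
  design$day <- as.numeric(design$day)
  if (is.null(colnames(values))) colnames(values) <- design$sample_id
  # every (group, day) cell must be populated
  tab <- table(design$group, design$day)
  if (any(tab == 0))
    stop("every (group, day) cell needs at least one sample", call. = FALSE)
  structure(list(values = values, design = design), class = "expr_set")
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' @export
print.expr_set <- function(x, ...) {
  d <- x$design
  cat("expr_set: ", nrow(x$values), " genes x ", ncol(x$values), " samples\n",
      sep = "")
  cat("  days: ", paste(sort(unique(d$day)), collapse = ", "), "\n", sep = "")
  tab <- table(d$group, d$day)
  cat("  samples per (group, day):\n")
  print(tab)
  invisible(x)
}

#' @export
`[.expr_set` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  expr_set(v, x$design[match(colnames(v), x$design$sample_id), , drop = FALSE])
}

days_of <- function(x) sort(unique(x$design$day))

# replicates per (group, day) cell; errors unless balanced
balanced_reps <- function(x) {
  tab <- table(x$design$group, x$design$day)
  r <- unique(as.vector(tab))
  if (length(r) != 1L)
    stop("design is unbalanced (unequal replicates per group x day cell); ",
         "the ANOVA models require a balanced design", call. = FALSE)
  as.integer(r)
}

#' Read and write expression matrices
#'
#' The interchange format is a pair of TSV files: the expression table (first
#' column `gene_id`, remaining columns one per sample) and a sample sheet with
#' columns `sample_id`, `group`, `day`, `replicate`.
#'
#' @param x an [expr_set].
#' @param file path of the expression TSV.
#' @param sheet_file path of the sample-sheet TSV.
#' @return `read_expression()` returns an [expr_set]; `write_expression()`
#'   returns `file` invisibly.
#' @export
write_expression <- function(x, file, sheet_file) {
  stopifnot(inherits(x, "expr_set"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, file)
  write_tsv(x$design, sheet_file)
  invisible(file)
}

#' @rdname write_expression
#' @export
read_expression <- function(file, sheet_file) {
  df <- read_tsv(file)
  if (names(df)[1] != "gene_id")
    stop("expression TSV must start with a 'gene_id' column", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  design <- read_tsv(sheet_file)
  miss <- setdiff(design$sample_id, colnames(m))
  if (length(miss))
    stop("sample sheet lists samples missing from the matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  expr_set(m[, design$sample_id, drop = FALSE], design)
}

#' Read a GEO series-matrix-style expression table
#'
#' Parses the plain-text layout of GEO series matrices: metadata lines are
#' prefixed with `!`, and the expression table (first column the probe/gene
#' id, header row the sample ids) sits between the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers (or is
#' simply the non-`!` body of the file). The design is not inferred: pass the
#' sample sheet describing each column. No network access is performed.
#'
#' @param file path to the series-matrix TSV.
#' @param sample_sheet data.frame (or TSV path) with columns `sample_id`,
#'   `group`, `day`, `replicate` covering every data column.
#' @return An [expr_set].
#' @export
read_series_matrix <- function(file, sample_sheet) {
  lines <- readLines(file)
  body <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(body) < 2L)
    stop("series matrix format error: no data table found in ", file,
         call. = FALSE)
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.delim(con, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("series matrix format error: non-numeric sample columns; ",
         "offending columns: ",
         paste(colnames(m)[!apply(m, 2, is.numeric)], collapse = ", "),
         call. = FALSE)
  rownames(m) <- as.character(df[[1]])
  if (is.character(sample_sheet)) sample_sheet <- read_tsv(sample_sheet)
  miss <- setdiff(sample_sheet$sample_id, colnames(m))
  if (length(miss))
    stop("series matrix format error: sample sheet references absent columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  expr_set(m[, sample_sheet$sample_id, drop = FALSE], sample_sheet)
}
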