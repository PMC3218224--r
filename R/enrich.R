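#' Propagate annotations up an ontology DAG
#'
#' Applies the true-path rule: a gene annotated to a term is annotated to
#' every ancestor of that term. Propagation is the transitive closure over
#' the child -> parent edge table and is idempotent. A cycle in the edge
#' table is an input error and is reported with one offending cycle.
#'
#' @param annotations data.frame with columns `gene_id`, `term_id` and
#'   optionally `evidence_code` (propagated rows inherit the code of the
#'   original annotation).
#' @param edges data.frame with columns `child`, `parent`.
#' @return data.frame of the same shape with propagated rows added
#'   (duplicate gene/term pairs collapsed).
#' @export
propagate_annotations <- function(annotations, edges) {
  anc <- term_ancestors(edges)
  if (!nrow(annotations)) return(annotations)
  has_ev <- "evidence_code" %in% names(annotations)
  extra <- lapply(unique(annotations$term_id), function(t) {
    a <- anc[[t]]
    if (is.null(a) || !length(a)) return(NULL)
    rows <- annotations[annotations$term_id == t, , drop = FALSE]
    out <- data.frame(
      gene_id = rep(rows$gene_id, times = length(a)),
      term_id = rep(a, each = nrow(rows)),
      stringsAsFactors = FALSE)
    if (has_ev) out$evidence_code <- rep(rows$evidence_code,
                                         times = length(a))
    out
  })
  out <- rbind(annotations, do.call(rbind, extra))
  key <- if (has_ev) paste(out$gene_id, out$term_id, out$evidence_code)
         else paste(out$gene_id, out$term_id)
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ancestors of every term appearing in `edges`, with cycle detection;
# returns a named list term -> character vector of ancestors.
term_ancestors <- function(edges) {
  if (!nrow(edges)) return(list())
  parents <- split(edges$parent, edges$child)
  anc <- new.env(parent = emptyenv())
  visiting <- character(0)
  walk <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    if (t %in% visiting)
      stop("input error: ontology edge table contains a cycle: ",
           paste(c(visiting[which(visiting == t):length(visiting)], t),
                 collapse = " -> "), call. = FALSE)
    visiting <<- c(visiting, t)
    p <- parents[[t]]
    res <- if (is.null(p)) character(0)
           else unique(c(p, unlist(lapply(p, walk))))
    visiting <<- visiting[-length(visiting)]
    anc[[t]] <- res
    res
  }
  all_terms <- unique(c(edges$child, edges$parent))
  out <- lapply(all_terms, walk)
  names(out) <- all_terms
  out
}

#' Overrepresentation tail probability for one term
#'
#' Probability of observing at least `k` annotated genes in a set of size
#' `n`, given `K` of the `N` background genes carry the term. The binomial
#' test uses X ~ Binomial(n, K/N); the hypergeometric test uses
#' X ~ Hypergeometric(N, K, n). Both are exact upper-tail sums.
#'
#' @param N background universe size.
#' @param K background genes annotated to the term.
#' @param n gene-set size.
#' @param k gene-set genes annotated to the term.
#' @param test `"binomial"` or `"hypergeometric"`.
#' @return upper-tail probability P(X >= k).
#' @examples
#' enrich_term(20, 5, 4, 3, "binomial")        # 0.05078125
#' enrich_term(20, 5, 4, 3, "hypergeometric")  # 155 / choose(20, 4)
#' @export
enrich_term <- function(N, K, n, k, test = c("binomial", "hypergeometric")) {
  test <- match.arg(test)
  if (K > N || n > N) stop("input error: K and n must not exceed N", call. = FALSE)
  if (k > n || k > K) stop("input error: k must not exceed min(n, K)", call. = FALSE)
  if (k == 0) return(1)
  if (test == "binomial")
    stats::pbinom(k - 1, n, K / N, lower.tail = FALSE)
  else
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Multiple-testing correction across tested terms
#'
#' Bonferroni family-wise correction (`p_corr = min(1, m * p_raw)`) or
#' Benjamini-Hochberg step-up FDR, via [stats::p.adjust()]. The family size
#' m is the number of supplied p-values, i.e. the number of tested terms.
#'
#' @param p numeric vector of raw tail probabilities.
#' @param correction `"bonferroni"` (FWER) or `"BH"` (FDR).
#' @return adjusted p-values, same order as `p`.
#' @export
correct_terms <- function(p, correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = correction)
}

#' Ontology overrepresentation analysis of a gene-set
#'
#' BinGO-style enrichment: electronic (`IEA`) annotations are discarded,
#' remaining annotations are propagated up the DAG, per-term counts are
#' formed over the background universe, every term annotating at least one
#' set gene is tested with an exact upper tail (binomial by default,
#' hypergeometric optionally), and the raw probabilities are corrected
#' across the tested terms (Bonferroni FWER by default,
#' Benjamini-Hochberg FDR optionally). Genes with no surviving annotation
#' are dropped from both the set (n) and the background (N).
#'
#' @param genes character vector: the gene-set (or a geneset list from
#'   [select_genesets()]).
#' @param annotations data.frame `gene_id, term_id, evidence_code`.
#' @param edges data.frame `child, parent`.
#' @param universe character vector of background genes (must contain the
#'   set; typically every gene on the array).
#' @param test `"binomial"` or `"hypergeometric"`.
#' @param correction `"bonferroni"` or `"BH"`.
#' @param alpha significance level on the corrected scale (default 0.05).
#' @param discard_iea drop `IEA`-coded annotations first (default `TRUE`).
#' @return Object of class `go_enrichment`: data.frame with columns
#'   `term, N, K, n, k, p_raw, p_corr, significant, selected_genes`, sorted
#'   by `p_corr` then `p_raw`; attributes record the parameters. Empty if no
#'   set gene retains an annotation (with a warning).
#' @export
enrich_geneset <- function(genes, annotations, edges, universe,
                           test = c("binomial", "hypergeometric"),
                           correction = c("bonferroni", "BH"),
                           alpha = 0.05, discard_iea = TRUE) {
  test <- match.arg(test); correction <- match.arg(correction)
  if (is.list(genes) && !is.null(genes$genes)) genes <- genes$genes
  if (!all(genes %in% universe))
    stop("gene-set must be contained in the universe", call. = FALSE)
  ann <- annotations
  if (discard_iea && "evidence_code" %in% names(ann))
    ann <- ann[ann$evidence_code != "IEA", , drop = FALSE]
  ann <- ann[ann$gene_id %in% universe, , drop = FALSE]
  ann <- propagate_annotations(ann, edges)

  empty <- data.frame(term = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p_raw = numeric(0),
                      p_corr = numeric(0), significant = logical(0),
                      selected_genes = character(0), stringsAsFactors = FALSE)
  result <- function(df) structure(df, class = c("go_enrichment", "data.frame"),
                                   test = test, correction = correction,
                                   alpha = alpha)
  if (!length(genes) || !nrow(ann)) return(result(empty))

  annotated <- unique(ann$gene_id)
  bg <- intersect(universe, annotated)
  set <- intersect(genes, bg)
  if (!length(set)) {
    warning("gene-set has no annotated member; empty enrichment table")
    return(result(empty))
  }
  N <- length(bg); n <- length(set)
  term2genes <- split(ann$gene_id, ann$term_id)
  term2genes <- lapply(term2genes, unique)
  k_set <- vapply(term2genes, function(g) length(intersect(g, set)), 1L)
  tested <- names(k_set)[k_set >= 1]         # BinGO family: terms hit by the set
  if (!length(tested)) return(result(empty))
  K <- vapply(term2genes[tested], length, 1L)
  k <- k_set[tested]
  p_raw <- vapply(seq_along(tested),
                  function(i) enrich_term(N, K[i], n, k[i], test), 1.0)
  p_corr <- correct_terms(p_raw, correction)
  sel <- vapply(term2genes[tested],
                function(g) paste(sort(intersect(g, set)), collapse = ","), "")
  out <- data.frame(term = tested, N = N, K = as.integer(K), n = n,
                    k = as.integer(k), p_raw = p_raw, p_corr = p_corr,
                    significant = p_corr < alpha, selected_genes = sel,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_corr, out$p_raw, out$term), , drop = FALSE]
  rownames(out) <- NULL
  result(out)
}

#' @export
print.go_enrichment <- function(x, ...) {
  cat("Overrepresentation analysis (", attr(x, "test"), " test, ",
      attr(x, "correction"), " correction, alpha = ", attr(x, "alpha"),
      ")\n", sep = "")
  cat("  terms tested: ", nrow(x), ", significant: ", sum(x$significant),
      "\n", sep = "")
  if (nrow(x)) {
    show <- utils::head(as.data.frame(x)[c("term", "N", "K", "n", "k",
                                           "p_raw", "p_corr")], 10)
    print(show, digits = 4)
  }
  invisible(x)
}

#' Read a minimal OBO subset
#'
#' Parses only `[Term]` stanzas with their `id:` and `is_a:` lines, returning
#' the term list and a child/parent edge table. Everything else in the file
#' is ignored.
#'
#' @param file OBO path.
#' @return list with `terms` (character) and `edges` (data.frame
#'   `child, parent`).
#' @export
read_obo_subset <- function(file) {
  lines <- readLines(file)
  terms <- character(0)
  edges <- list()
  cur <- NA_character_
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { in_term <- TRUE; cur <- NA; next }
    if (startsWith(ln, "[")) { in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      cur <- trimws(sub("^id:", "", ln))
      terms <- c(terms, cur)
    } else if (startsWith(ln, "is_a:") && !is.na(cur)) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      edges[[length(edges) + 1L]] <- c(cur, parent)
    }
  }
  ed <- if (length(edges))
    stats::setNames(as.data.frame(do.call(rbind, edges),
                                  stringsAsFactors = FALSE),
                    c("child", "parent"))
  else data.frame(child = character(0), parent = character(0))
  list(terms = unique(terms), edges = ed)
}

#' Read GAF-like annotation and edge tables
#'
#' @param file annotation TSV with columns `gene_id, term_id, evidence_code`.
#' @return data.frame.
#' @export
read_annotations <- function(file) {
  df <- read_tsv(file)
  need <- c("gene_id", "term_id")
  if (!all(need %in% names(df)))
    stop("annotation TSV needs columns gene_id, term_id", call. = FALSE)
  df
}

#' @rdname read_annotations
#' @export
read_edges <- function(file) {
  df <- read_tsv(file)
  if (!all(c("child", "parent") %in% names(df)))
    stop("edge TSV needs columns child, parent", call. = FALSE)
  df
}
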