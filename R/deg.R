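# Day-dependent quantities of the two-way layout that are invariant under
# relabeling of the group factor: grand means, total SS, day SS. Computed
# once and reused across all label permutations.
anova_prep <- function(values, day) {
  day <- factor(day)
  b <- nlevels(day); di <- as.integer(day); N <- ncol(values)
  grand <- rowMeans(values)
  Md <- matrix(0, N, b)
  Md[cbind(seq_len(N), di)] <- 1
  nd <- tabulate(di, b)
  dm <- sweep(values %*% Md, 2, nd, "/")
  ss_b <- rowSums(sweep((dm - grand)^2, 2, nd, "*"))
  list(b = b, di = di, grand = grand,
       ss_tot = rowSums((values - grand)^2), ss_b = ss_b)
}

# Balanced two-way ANOVA F statistics, vectorized over genes.
#
# Model 1 is the full two-way model (group + time + group:time); its test
# statistic is the interaction F on ((a-1)(b-1), ab(r-1)) df. Model 2 is the
# additive model (group + time); its statistic is the group-effect F on
# (a-1, N-a-b+1) df. The design must be balanced, where the classical
# sequential/marginal sum-of-squares decompositions coincide.
#
# values: genes x samples matrix; group, day: factors of length ncol(values).
# Returns list(F1, p1, F2, p2, zero_var1, zero_var2, df1, df2).
anova_f_stats <- function(values, group, day, prep = NULL) {
  if (is.null(prep)) prep <- anova_prep(values, day)
  group <- factor(group); day <- factor(day)
  a <- nlevels(group); b <- prep$b; N <- ncol(values)
  gi <- as.integer(group); di <- prep$di
  cell_idx <- gi + a * (di - 1L)
  cnt <- tabulate(cell_idx, a * b)
  r <- cnt[1]
  if (any(cnt != r))
    stop("design is unbalanced (unequal replicates per cell)", call. = FALSE)
  r <- as.integer(r)

  # sample -> cell mean operator (group-dependent, rebuilt per labeling);
  # group and day means are then cell-mean averages of the balanced layout
  Mc <- matrix(0, N, a * b)
  Mc[cbind(seq_len(N), cell_idx)] <- 1 / r
  cm <- values %*% Mc
  Ag <- matrix(0, a * b, a); Ag[cbind(seq_len(a * b),
                                      rep(seq_len(a), b))] <- 1 / b
  gm <- cm %*% Ag

  grand <- prep$grand
  ss_tot <- prep$ss_tot
  ss_b <- prep$ss_b
  ss_a <- b * r * rowSums((gm - grand)^2)
  ss_cells <- r * rowSums((cm - grand)^2)
  ss_ab <- pmax(ss_cells - ss_a - ss_b, 0)
  sse_full <- pmax(ss_tot - ss_cells, 0)
  sse_add <- pmax(ss_tot - ss_a - ss_b, 0)

  df_ab <- (a - 1L) * (b - 1L)
  df_e1 <- a * b * (r - 1L)
  df_a <- a - 1L
  df_e2 <- N - a - b + 1L

  eps <- 1e-12
  zero1 <- sse_full <= eps * pmax(ss_tot, 1)
  zero2 <- sse_add <= eps * pmax(ss_tot, 1)

  F1 <- ifelse(zero1, 0, (ss_ab / df_ab) / (sse_full / df_e1))
  F2 <- ifelse(zero2, 0, (ss_a / df_a) / (sse_add / df_e2))
  p1 <- ifelse(zero1, 1, stats::pf(F1, df_ab, df_e1, lower.tail = FALSE))
  p2 <- ifelse(zero2, 1, stats::pf(F2, df_a, df_e2, lower.tail = FALSE))
  list(F1 = F1, p1 = p1, F2 = F2, p2 = p2,
       zero_var1 = zero1, zero_var2 = zero2,
       df1 = c(df_ab, df_e1), df2 = c(df_a, df_e2))
}

#' Two-way ANOVA F test for one gene
#'
#' Fits the chosen model to a single gene's expression and returns its F
#' statistic and the upper-tail F probability. Model 1 tests the group x time
#' interaction in the full two-way layout; model 2 tests the group effect in
#' the additive layout. Genes with zero residual variance get `p = 1` and a
#' `zero_var` flag rather than an undefined ratio.
#'
#' @param x an [expr_set] with a balanced design.
#' @param gene gene id.
#' @param model 1 (interaction) or 2 (additive group effect).
#' @return list with `F`, `p`, `df` (numerator, denominator), `zero_var`.
#' @export
fit_anova <- function(x, gene, model = 1) {
  stopifnot(inherits(x, "expr_set"), model %in% c(1, 2))
  r <- balanced_reps(x)
  if (model == 1 && r < 2)
    stop("model 1 (interaction) requires >= 2 replicates per cell",
         call. = FALSE)
  v <- x$values[gene, , drop = FALSE]
  s <- anova_f_stats(v, x$design$group, x$design$day)
  if (model == 1)
    list(F = unname(s$F1), p = unname(s$p1), df = s$df1,
         zero_var = unname(s$zero_var1))
  else
    list(F = unname(s$F2), p = unname(s$p2), df = s$df2,
         zero_var = unname(s$zero_var2))
}

# All distinct permutations of group labels within day strata for a balanced
# two-group design: per day, every choice of which r of the 2r samples carry
# the "knockdown" label. Returns a matrix, one column per permutation, each
# column a permuted group-label vector. Column 1 is the identity only by
# coincidence of enumeration order; the identity is always among them.
enumerate_strata_perms <- function(group, day) {
  days <- sort(unique(day))
  per_day <- lapply(days, function(d) {
    idx <- which(day == d)
    k <- sum(group[idx] == "knockdown")
    utils::combn(idx, k, simplify = FALSE)
  })
  combos <- expand.grid(lapply(per_day, seq_along))
  out <- matrix("control", length(group), nrow(combos))
  for (j in seq_len(nrow(combos))) {
    lab <- rep("control", length(group))
    for (i in seq_along(days)) lab[per_day[[i]][[combos[j, i]]]] <- "knockdown"
    out[, j] <- lab
  }
  out
}

n_strata_perms <- function(group, day) {
  days <- unique(day)
  prod(vapply(days, function(d) {
    idx <- day == d
    choose(sum(idx), sum(group[idx] == "knockdown"))
  }, 1))
}

# Westfall-Young step-down adjustment from an observed statistic vector and a
# genes x B matrix of permutation statistics. `exact` divides by B (the
# permutation set includes the identity); otherwise the add-one estimator
# (b+1)/(B+1) is used, flooring adjusted p at 1/(B+1).
wy_stepdown <- function(Fobs, Fperm, exact = FALSE) {
  m <- length(Fobs); B <- ncol(Fperm)
  ord <- order(Fobs, decreasing = TRUE)
  Fo <- Fobs[ord]
  # ties between permuted and observed statistics count as exceedances;
  # the tolerance absorbs float jitter between algebraically equal labelings
  tol <- 1e-9 * (1 + abs(Fo))
  cnt_adj <- numeric(m)
  cnt_raw <- numeric(m)
  for (bb in seq_len(B)) {
    v <- Fperm[ord, bb]
    u <- rev(cummax(rev(v)))          # successive maxima over lower ranks
    cnt_adj <- cnt_adj + (u >= Fo - tol)
    cnt_raw <- cnt_raw + (v >= Fo - tol)
  }
  if (exact) {
    adj <- cnt_adj / B
    raw <- cnt_raw / B
  } else {
    adj <- (cnt_adj + 1) / (B + 1)
    raw <- (cnt_raw + 1) / (B + 1)
  }
  adj <- cummax(adj)                  # step-down monotonicity enforcement
  out_adj <- numeric(m); out_adj[ord] <- adj
  out_raw <- numeric(m); out_raw[ord] <- raw
  list(adjusted = pmin(out_adj, 1), raw_perm = pmin(out_raw, 1))
}

# step-down minP on a matrix of permutation statistics: convert each gene's
# statistics to permutation p-values, then apply the step-down min over
# lower-ranked genes. Used behind method = "minP".
wy_stepdown_minp <- function(Fobs, Fperm, exact = FALSE) {
  B <- ncol(Fperm)
  # per-gene marginal permutation p of every permuted statistic and of the
  # observed one, computed from the same permutation distribution
  m <- length(Fobs)
  Pobs <- numeric(m)
  Pperm <- matrix(0, m, B)
  for (i in seq_len(m)) {
    f <- Fperm[i, ]
    tol <- 1e-9 * (1 + abs(Fobs[i]))
    Pobs[i] <- if (exact) mean(f >= Fobs[i] - tol)
               else (sum(f >= Fobs[i] - tol) + 1) / (B + 1)
    rk <- rank(-f, ties.method = "max")
    Pperm[i, ] <- if (exact) rk / B else (rk + 1) / (B + 1)
  }
  ord <- order(Pobs)
  Po <- Pobs[ord]
  cnt <- numeric(m)
  for (bb in seq_len(B)) {
    v <- Pperm[ord, bb]
    u <- rev(cummin(rev(v)))
    cnt <- cnt + (u <= Po)
  }
  adj <- if (exact) cnt / B else (cnt + 1) / (B + 1)
  adj <- cummax(adj)
  out <- numeric(m); out[ord] <- pmin(adj, 1)
  list(adjusted = out, raw_perm = Pobs)
}

#' Westfall-Young permutation adjustment of per-gene ANOVA p-values
#'
#' Step-down maxT family-wise error adjustment: group labels are permuted
#' within each day stratum (preserving the time effect under the null of no
#' group or interaction effect), the chosen model's F statistic is recomputed
#' for every gene under each permutation -- the same relabeling is applied to
#' all genes jointly, preserving inter-gene correlation -- and the adjusted p
#' for the gene ranked i is the permutation frequency with which the maximum
#' F over genes ranked >= i meets or exceeds its observed F, with step-down
#' monotonicity enforced. When the number of distinct stratified label
#' assignments is at most `n_perm` (or `exhaustive = TRUE`), all of them are
#' enumerated and exact permutation fractions are returned; otherwise
#' `n_perm` random permutations are drawn and the add-one estimator is used,
#' so adjusted p lies in [1/(n_perm+1), 1].
#'
#' @param x an [expr_set] with a balanced design.
#' @param model 1 (interaction F) or 2 (additive group F).
#' @param n_perm number of random permutations.
#' @param seed RNG seed for the permutation draw.
#' @param method `"maxT"` (default) or `"minP"`.
#' @param exhaustive force (or forbid) exhaustive enumeration; default
#'   `NULL` enumerates exactly when feasible within `n_perm`.
#' @return list with `adjusted`, `raw_perm` (marginal permutation p), `F`
#'   (observed statistics), `n_perm_used`, `exact`.
#' @export
westfall_young <- function(x, model = 1, n_perm = 1000, seed = NULL,
                           method = c("maxT", "minP"), exhaustive = NULL) {
  stopifnot(inherits(x, "expr_set"), model %in% c(1, 2))
  method <- match.arg(method)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  group <- x$design$group; day <- x$design$day
  obs <- anova_f_stats(x$values, group, day)
  Fobs <- if (model == 1) obs$F1 else obs$F2

  n_exact <- n_strata_perms(group, day)
  use_exact <- isTRUE(exhaustive) ||
    (is.null(exhaustive) && n_exact <= n_perm)
  if (use_exact) {
    labs <- enumerate_strata_perms(group, day)
  } else {
    labs <- with_seed(seed, {
      days <- unique(day)
      vapply(seq_len(n_perm), function(b) {
        g <- group
        for (d in days) {
          idx <- which(day == d)
          g[idx] <- g[idx][sample.int(length(idx))]
        }
        g
      }, character(length(group)))
    })
  }
  B <- ncol(labs)
  prep <- anova_prep(x$values, day)
  Fperm <- matrix(0, nrow(x$values), B)
  for (bb in seq_len(B)) {
    s <- anova_f_stats(x$values, labs[, bb], day, prep = prep)
    Fperm[, bb] <- if (model == 1) s$F1 else s$F2
  }
  res <- if (method == "maxT") wy_stepdown(Fobs, Fperm, exact = use_exact)
         else wy_stepdown_minp(Fobs, Fperm, exact = use_exact)
  res$F <- Fobs
  res$n_perm_used <- B
  res$exact <- use_exact
  res
}

#' Call differentially expressed genes with two ANOVA models
#'
#' The package's central fit: for every gene, the group x time interaction F
#' (model 1) and the additive group-effect F (model 2) are computed, each
#' model's p-values are adjusted separately by Westfall-Young step-down maxT
#' over stratified permutations, and a gene is flagged as a DEG when either
#' model's adjusted p falls below `alpha_adj` (default 0.1). A post-hoc
#' fold-change annotation (max |log2 ratio| over days) is reported, and can
#' optionally gate the DEG flag at >= 1 (2-fold) via `fold_filter`.
#'
#' @param x an [expr_set] with a balanced design and >= 2 replicates per cell.
#' @param alpha_adj adjusted-p threshold in (0, 1).
#' @param n_perm permutations per model.
#' @param seed RNG seed (permutations for the two models are drawn from
#'   deterministic per-model substreams of this seed).
#' @param method `"maxT"` or `"minP"`.
#' @param exhaustive see [westfall_young()].
#' @param fold_filter if `TRUE`, additionally require
#'   max |log2 ratio| >= 1 for the DEG flag. Default off: the DEG definition
#'   is by adjusted p alone.
#' @return An object of class `deg_anova`: list with `table` (per-gene
#'   data.frame: `gene, F1, p1, p1_perm, p1_adj, F2, p2, p2_perm, p2_adj,
#'   flag_m1, flag_m2, flag_deg, max_abs_log2_ratio, zero_var`), `summary`
#'   (counts `n_deg, n_model1, n_model2, n_common`), and the call parameters.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 60,
#'   archetypes = default_archetypes(c(3, 3, 1, 1, 3, 3)), seed = 2))
#' fit <- deg_anova(sim$expr, n_perm = 50, seed = 2)
#' fit
#' @export
deg_anova <- function(x, alpha_adj = 0.1, n_perm = 1000, seed = NULL,
                      method = c("maxT", "minP"), exhaustive = NULL,
                      fold_filter = FALSE) {
  stopifnot(inherits(x, "expr_set"))
  method <- match.arg(method)
  if (alpha_adj <= 0 || alpha_adj >= 1)
    stop("alpha_adj must be in (0, 1)", call. = FALSE)
  r <- balanced_reps(x)
  if (r < 2)
    stop("model 1 (interaction) requires >= 2 replicates per cell",
         call. = FALSE)
  obs <- anova_f_stats(x$values, x$design$group, x$design$day)
  s1 <- if (is.null(seed)) NULL else stage_seed(seed, "wy_model1")
  s2 <- if (is.null(seed)) NULL else stage_seed(seed, "wy_model2")
  w1 <- westfall_young(x, model = 1, n_perm = n_perm, seed = s1,
                       method = method, exhaustive = exhaustive)
  w2 <- westfall_young(x, model = 2, n_perm = n_perm, seed = s2,
                       method = method, exhaustive = exhaustive)
  ratios <- ratio_profiles(x)
  max_abs <- apply(abs(ratios), 1, max)
  flag1 <- w1$adjusted < alpha_adj
  flag2 <- w2$adjusted < alpha_adj
  flag <- flag1 | flag2
  if (fold_filter) flag <- flag & max_abs >= 1
  tab <- data.frame(
    gene = rownames(x$values),
    F1 = obs$F1, p1 = obs$p1, p1_perm = w1$raw_perm, p1_adj = w1$adjusted,
    F2 = obs$F2, p2 = obs$p2, p2_perm = w2$raw_perm, p2_adj = w2$adjusted,
    flag_m1 = flag1, flag_m2 = flag2, flag_deg = flag,
    max_abs_log2_ratio = max_abs,
    zero_var = obs$zero_var1 & obs$zero_var2,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    table = tab,
    summary = list(n_deg = sum(flag), n_model1 = sum(flag1),
                   n_model2 = sum(flag2), n_common = sum(flag1 & flag2)),
    alpha_adj = alpha_adj, n_perm = n_perm, seed = seed, method = method,
    exact = w1$exact, fold_filter = fold_filter,
    call = match.call()), class = "deg_anova")
}

#' @export
print.deg_anova <- function(x, ...) {
  s <- x$summary
  cat("Two-model ANOVA DEG fit (", x$method,
      if (x$exact) ", exhaustive permutations" else
        paste0(", ", x$n_perm, " permutations"),
      ", adjusted p < ", x$alpha_adj, ")\n", sep = "")
  cat("  genes tested: ", nrow(x$table), "\n", sep = "")
  cat("  DEGs: ", s$n_deg, " (model 1: ", s$n_model1, ", model 2: ",
      s$n_model2, ", common: ", s$n_common, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.deg_anova <- function(object, ...) {
  out <- object$summary
  out$alpha_adj <- object$alpha_adj
  out$n_genes <- nrow(object$table)
  class(out) <- "summary.deg_anova"
  out
}

#' @export
print.summary.deg_anova <- function(x, ...) {
  cat("n_genes:", x$n_genes, "\nn_deg:", x$n_deg,
      "\nn_model1:", x$n_model1, "\nn_model2:", x$n_model2,
      "\nn_common:", x$n_common, "\nalpha_adj:", x$alpha_adj, "\n")
  invisible(x)
}

#' @export
as.data.frame.deg_anova <- function(x, ...) x$table

#' DEG gene ids of a fit
#'
#' @param fit a [deg_anova] fit.
#' @return character vector of flagged genes.
#' @export
deg_genes <- function(fit) {
  stopifnot(inherits(fit, "deg_anova"))
  fit$table$gene[fit$table$flag_deg]
}

#' Write a DEG fit to disk
#'
#' @param fit a [deg_anova] fit.
#' @param file TSV path for the per-gene table.
#' @param summary_file optional JSON path for the count summary.
#' @return `file`, invisibly.
#' @export
write_deg <- function(fit, file, summary_file = NULL) {
  stopifnot(inherits(fit, "deg_anova"))
  write_tsv(fit$table, file)
  if (!is.null(summary_file))
    jsonlite::write_json(fit$summary, summary_file, auto_unbox = TRUE,
                         digits = NA)
  invisible(file)
}
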