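# Shared fixtures and independent oracles for the test suite.

# a tiny balanced expr_set built directly from a value matrix laid out as
# control then knockdown, days in order, replicates within day
toy_expr <- function(values, days, r) {
  b <- length(days)
  design <- data.frame(
    sample_id = paste0(rep(c("c", "k"), each = b * r),
                       "_d", rep(rep(days, each = r), 2),
                       "_r", rep(seq_len(r), 2 * b)),
    group = rep(c("control", "knockdown"), each = b * r),
    day = rep(rep(days, each = r), 2),
    replicate = rep(seq_len(r), 2 * b))
  colnames(values) <- design$sample_id
  expr_set(values, design)
}

# brute-force two-way ANOVA oracle via R's lm/anova on one gene
oracle_anova <- function(x, gene, model) {
  d <- x$design
  df <- data.frame(y = x$values[gene, ], g = factor(d$group),
                   t = factor(d$day))
  if (model == 1) {
    a <- stats::anova(stats::lm(y ~ g * t, data = df))
    list(F = a["g:t", "F value"], p = a["g:t", "Pr(>F)"])
  } else {
    a <- stats::anova(stats::lm(y ~ g + t, data = df))
    list(F = a["g", "F value"], p = a["g", "Pr(>F)"])
  }
}

# exhaustive Westfall-Young maxT oracle: enumerate every stratified group
# relabeling with utils::combn/expand.grid independently of the package's
# enumerator, recompute per-gene F via the lm oracle, and apply the
# step-down maxima definition directly.
oracle_wy_exhaustive <- function(x, model) {
  d <- x$design
  days <- sort(unique(d$day))
  per_day <- lapply(days, function(dd) {
    idx <- which(d$day == dd)
    k <- sum(d$group[idx] == "knockdown")
    utils::combn(idx, k, simplify = FALSE)
  })
  combos <- expand.grid(lapply(per_day, seq_along))
  genes <- rownames(x$values)
  fstat <- function(labels) {
    vapply(genes, function(g) {
      df <- data.frame(y = x$values[g, ], g = factor(labels),
                       t = factor(d$day))
      a <- if (model == 1) stats::anova(stats::lm(y ~ g * t, data = df))
           else stats::anova(stats::lm(y ~ g + t, data = df))
      row <- if (model == 1) "g:t" else "g"
      f <- a[row, "F value"]
      if (!is.finite(f)) 0 else f
    }, 1.0)
  }
  Fobs <- fstat(d$group)
  B <- nrow(combos)
  Fperm <- matrix(0, length(genes), B)
  for (j in seq_len(B)) {
    lab <- rep("control", nrow(d))
    for (i in seq_along(days)) lab[per_day[[i]][[combos[j, i]]]] <- "knockdown"
    Fperm[, j] <- fstat(lab)
  }
  ord <- order(Fobs, decreasing = TRUE)
  cnt <- numeric(length(genes))
  tol <- 1e-9 * (1 + abs(Fobs[ord]))   # count float-level ties as exceedances
  for (j in seq_len(B)) {
    u <- rev(cummax(rev(Fperm[ord, j])))
    cnt <- cnt + (u >= Fobs[ord] - tol)
  }
  adj <- cummax(cnt / B)
  out <- numeric(length(genes)); out[ord] <- pmin(adj, 1)
  names(out) <- genes
  out
}

# adjusted Rand index between two labelings (independent of the package)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# archetype set used for recovery experiments: the three early-down shapes
# at day-3 mean ratio -1.5
recovery_archetypes <- function() {
  list(archetype("up_strong", 33, c(0, 0.8, 2.2)),
       archetype("up_moderate", 77, c(0, 0.5, 1.2)),
       archetype("down_up", 9, c(0, -1.5, 0.6)),
       archetype("down_hold", 12, c(0, -1.5, -1.2)),
       archetype("down_strong", 27, c(0, -1.5, -2.5)),
       archetype("down_moderate", 80, c(0, -0.3, -1.2)))
}
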