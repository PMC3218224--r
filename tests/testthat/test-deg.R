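test_that("single-gene F statistics match the lm decomposition exactly", {
  set.seed(31)
  v <- matrix(rnorm(12, 8, 1), 1, dimnames = list("g1", NULL))
  x <- toy_expr(v, days = c(1, 3, 5), r = 2)
  for (m in 1:2) {
    mine <- fit_anova(x, "g1", m)
    ref <- oracle_anova(x, "g1", m)
    expect_equal(mine$F, ref$F, tolerance = 1e-10)
    expect_equal(mine$p, ref$p, tolerance = 1e-10)
  }
})

test_that("F decomposition matches an explicit sums-of-squares oracle on a 2x3x2 table", {
  # hand-specified cell values: 2 groups x 3 days x 2 replicates
  v <- matrix(c(4, 6, 5, 7, 6, 8,     # control: d1, d3, d5
                5, 7, 9, 11, 6, 10),  # knockdown
              1, dimnames = list("g1", NULL))
  x <- toy_expr(v, days = c(1, 3, 5), r = 2)
  y <- as.vector(v)
  g <- rep(c(0, 1), each = 6); d <- rep(rep(1:3, each = 2), 2)
  grand <- mean(y)
  cellm <- tapply(y, list(g, d), mean)
  gm <- tapply(y, g, mean); dm <- tapply(y, d, mean)
  ss_tot <- sum((y - grand)^2)
  ss_a <- 6 * sum((gm - grand)^2)
  ss_b <- 4 * sum((dm - grand)^2)
  ss_cells <- 2 * sum((cellm - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  sse <- ss_tot - ss_cells
  F1_oracle <- (ss_ab / 2) / (sse / 6)
  F2_oracle <- (ss_a / 1) / ((ss_tot - ss_a - ss_b) / 8)
  expect_equal(fit_anova(x, "g1", 1)$F, F1_oracle, tolerance = 1e-10)
  expect_equal(fit_anova(x, "g1", 2)$F, F2_oracle, tolerance = 1e-10)
})

test_that("zero residual variance yields p = 1 with a flag", {
  v <- matrix(5, 1, 12, dimnames = list("g1", NULL))
  x <- toy_expr(v, days = c(1, 3, 5), r = 2)
  for (m in 1:2) {
    f <- fit_anova(x, "g1", m)
    expect_equal(f$p, 1)
    expect_true(f$zero_var)
  }
})

test_that("null raw p-values are uniform", {
  sim <- simulate_expression(sim_config(n_genes = 2000, archetypes = list(),
                                        seed = 41))
  s <- tempodeg:::anova_f_stats(sim$expr$values, sim$expr$design$group,
                                sim$expr$design$day)
  expect_gt(stats::ks.test(s$p1, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(s$p2, "punif")$p.value, 0.01)
})

test_that("unbalanced designs are rejected rather than silently decomposed", {
  sim <- simulate_expression(sim_config(n_genes = 5, archetypes = list(),
                                        seed = 1))
  x <- sim$expr
  drop <- which(x$design$group == "control" & x$design$day == 1)[1]
  y <- expr_set(x$values[, -drop], x$design[-drop, ])
  expect_error(deg_anova(y, n_perm = 5), "unbalanced")
})

test_that("single-gene adjustment reduces to the marginal stratified permutation p", {
  set.seed(51)
  v <- matrix(rnorm(8), 1, dimnames = list("g1", NULL))
  x <- toy_expr(v, days = c(1, 3), r = 2)
  w <- westfall_young(x, model = 1, n_perm = 1e6)  # forces exhaustive (36)
  expect_true(w$exact)
  expect_identical(w$n_perm_used, 36L)
  expect_equal(w$adjusted, w$raw_perm)
})

test_that("exhaustive Westfall-Young equals the brute-force enumeration oracle", {
  set.seed(61)
  v <- matrix(rnorm(24, 7, 1), 3, dimnames = list(paste0("g", 1:3), NULL))
  v[2, ] <- v[2, ] + rep(c(0, 0, 0, 0, 1.5, 1.5, 0, 0), 1)  # some signal
  x <- toy_expr(v, days = c(1, 3), r = 2)
  for (m in 1:2) {
    mine <- westfall_young(x, model = m, exhaustive = TRUE)
    ref <- oracle_wy_exhaustive(x, m)
    expect_true(mine$exact)
    expect_equal(mine$adjusted, unname(ref[rownames(v)]), tolerance = 1e-10)
  }
})

test_that("step-down contracts hold: adjusted >= raw, monotone in rank", {
  sim <- simulate_expression(sim_config(n_genes = 150, seed = 71,
    archetypes = default_archetypes(c(5, 5, 2, 2, 5, 5))))
  w <- westfall_young(sim$expr, model = 1, n_perm = 99, seed = 7)
  expect_true(all(w$adjusted >= w$raw_perm - 1e-12))
  expect_true(all(w$adjusted >= 1 / 100 - 1e-12))
  expect_true(all(w$adjusted <= 1 + 1e-12))
  ord <- order(w$F, decreasing = TRUE)
  expect_true(all(diff(w$adjusted[ord]) >= -1e-12))
  # minP variant obeys the same contracts
  wm <- westfall_young(sim$expr, model = 1, n_perm = 99, seed = 7,
                       method = "minP")
  expect_true(all(wm$adjusted >= wm$raw_perm - 1e-12))
  expect_true(all(diff(wm$adjusted[order(wm$raw_perm)]) >= -1e-12))
})

test_that("relabeling replicates within a cell leaves all F statistics unchanged", {
  sim <- simulate_expression(sim_config(n_genes = 40, archetypes = list(),
                                        seed = 81))
  x <- sim$expr
  d <- x$design
  perm <- seq_len(nrow(d))
  cellidx <- which(d$group == "knockdown" & d$day == 3)
  perm[cellidx] <- rev(cellidx)
  y <- expr_set(x$values[, perm], d)  # values shuffled within one cell
  a <- tempodeg:::anova_f_stats(x$values, d$group, d$day)
  b <- tempodeg:::anova_f_stats(y$values, d$group, d$day)
  expect_equal(a$F1, b$F1, tolerance = 1e-12)
  expect_equal(a$F2, b$F2, tolerance = 1e-12)
})

test_that("DEG flags follow the adjusted-p threshold and the union identity", {
  sim <- simulate_expression(sim_config(n_genes = 120, seed = 91,
    archetypes = default_archetypes(c(4, 4, 2, 2, 4, 4))))
  fit <- deg_anova(sim$expr, n_perm = 99, seed = 9)
  tab <- fit$table
  expect_identical(tab$flag_m1, tab$p1_adj < 0.1)
  expect_identical(tab$flag_m2, tab$p2_adj < 0.1)
  expect_identical(tab$flag_deg, tab$flag_m1 | tab$flag_m2)
  s <- fit$summary
  expect_identical(s$n_deg, s$n_model1 + s$n_model2 - s$n_common)
  # threshold membership is strict: adjusted p = 0.05 is flagged, 0.1 is not
  expect_true(all(tab$flag_m1[tab$p1_adj <= 0.05]))
  expect_false(any(tab$flag_m1[tab$p1_adj >= 0.1]))
})

test_that("strong planted signal is recovered with high power", {
  # day-5 |log2 shift| of 3 (8-fold), r = 3, noise 0.3: conditions under
  # which the FWER-adjusted caller keeps high per-gene power
  arch <- list(archetype("up", 80, c(0, 1.5, 3.0)),
               archetype("dn", 80, c(0, -1.5, -3.0)))
  sim <- simulate_expression(sim_config(n_genes = 500, archetypes = arch,
                                        noise_sd = 0.3, seed = 101))
  fit <- deg_anova(sim$expr, n_perm = 200, seed = 101)
  planted <- sim$truth$planted_genes
  power <- mean(fit$table$flag_deg[fit$table$gene %in% planted])
  expect_gte(power, 0.8)
  # false flags stay FWER-rare
  expect_lte(sum(fit$table$flag_deg[!fit$table$gene %in% planted]), 2)
})

test_that("fold-change annotation is reported and optionally gates the flag", {
  arch <- list(archetype("up", 10, c(0, 1.5, 3.0)))
  sim <- simulate_expression(sim_config(n_genes = 60, archetypes = arch,
                                        noise_sd = 0.2, seed = 111))
  plain <- deg_anova(sim$expr, n_perm = 99, seed = 3)
  gated <- deg_anova(sim$expr, n_perm = 99, seed = 3, fold_filter = TRUE)
  expect_true(all(gated$table$flag_deg <= plain$table$flag_deg))
  expect_true(all(gated$table$max_abs_log2_ratio[gated$table$flag_deg] >= 1))
  expect_equal(plain$table$max_abs_log2_ratio,
               unname(apply(abs(ratio_profiles(sim$expr)), 1, max)),
               tolerance = 1e-12)
})

test_that("deg fits are reproducible under a fixed seed", {
  sim <- simulate_expression(sim_config(n_genes = 80, seed = 121,
    archetypes = default_archetypes(c(3, 3, 1, 1, 3, 3))))
  a <- deg_anova(sim$expr, n_perm = 50, seed = 42)
  b <- deg_anova(sim$expr, n_perm = 50, seed = 42)
  expect_identical(a$table, b$table)
})
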