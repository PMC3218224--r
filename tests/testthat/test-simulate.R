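test_that("null configuration plants nothing and centres group differences at zero", {
  cfg <- sim_config(n_genes = 200, archetypes = list(), noise_sd = 0.3,
                    seed = 11)
  sim <- simulate_expression(cfg)
  expect_identical(sim$truth$planted_genes, character(0))
  expect_true(all(sim$truth$gene_archetype == "null"))
  prof <- ratio_profiles(sim$expr)
  # per-gene per-day group differences: mean ~ 0, almost all within the
  # 4 * noise_sd / sqrt(r) band
  bound <- 4 * cfg$noise_sd / sqrt(cfg$n_replicates)
  expect_lt(abs(mean(prof)), 0.05)
  expect_gt(mean(abs(prof) <= bound), 0.98)
})

test_that("planted archetype means are recovered by direct averaging", {
  cfg <- sim_config(n_genes = 100,
                    archetypes = list(archetype("cluster1_like", 30,
                                                c(0, 1.0, 2.2))),
                    noise_sd = 0.3, seed = 21)
  sim <- simulate_expression(cfg)
  planted <- sim$truth$planted_genes
  expect_length(planted, 30)
  prof <- ratio_profiles(sim$expr, planted)
  expect_lt(abs(mean(prof[, "day5"]) - 2.2), 0.2)
  expect_lt(abs(mean(prof[, "day1"]) - 0), 0.2)
})

test_that("identical config and seed reproduce bit-identical output", {
  cfg <- sim_config(n_genes = 50, seed = 5,
                    archetypes = default_archetypes(c(2, 2, 1, 1, 2, 2)))
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)
  o1 <- simulate_ontology(onto_config(seed = 2), a$truth,
                          rownames(a$expr$values))
  o2 <- simulate_ontology(onto_config(seed = 2), b$truth,
                          rownames(b$expr$values))
  expect_identical(o1$annotations, o2$annotations)
  expect_identical(o1$edges, o2$edges)
})

test_that("planted-effect calibration improves with replication", {
  # empirical mean ratio converges to the configured value as r grows
  err <- vapply(c(3, 30, 300), function(r) {
    cfg <- sim_config(n_genes = 40, n_replicates = r,
                      archetypes = list(archetype("a", 20, c(0, -1.5, 1.0))),
                      noise_sd = 0.5, seed = 100 + r)
    sim <- simulate_expression(cfg)
    prof <- ratio_profiles(sim$expr, sim$truth$planted_genes)
    mean(abs(sweep(prof, 2, c(0, -1.5, 1.0))))
  }, 1.0)
  expect_true(err[3] < err[1])
  expect_lt(err[3], 0.05)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_genes = 10,
                          archetypes = list(archetype("a", 20, c(0, 1, 2)))),
               "exceed")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(days = c(1, 1, 5)), "increasing")
  expect_error(sim_config(archetypes = list(archetype("a", 2, c(0, 1)))),
               "days")
})

test_that("truth bookkeeping is consistent with archetype counts", {
  cfg <- sim_config(n_genes = 300, seed = 3)
  sim <- simulate_expression(cfg)
  counts <- vapply(cfg$archetypes, function(a) a$count, 1L)
  expect_length(sim$truth$planted_genes, sum(counts))
  tab <- table(sim$truth$gene_archetype)
  for (a in cfg$archetypes)
    expect_equal(unname(tab[a$label]), a$count, ignore_attr = TRUE)
  # each planted gene appears in exactly one archetype
  expect_false(anyDuplicated(sim$truth$planted_genes) > 0)
})

test_that("ontology generator respects its configuration", {
  universe <- sprintf("g%04d", 1:500)
  planted <- universe[1:40]

  # flat ontology: no edges
  flat <- simulate_ontology(onto_config(dag_depth = 1, seed = 1),
                            planted_set = planted, universe = universe)
  expect_identical(nrow(flat$edges), 0L)

  # annotations reference only universe genes and existing terms
  o <- simulate_ontology(onto_config(seed = 4), planted_set = planted,
                         universe = universe)
  expect_true(all(o$annotations$gene_id %in% universe))
  expect_true(all(o$annotations$term_id %in% o$terms))
  expect_true(all(o$edges$child %in% o$terms) &&
                all(o$edges$parent %in% o$terms))
  expect_true(all(o$annotations$evidence_code %in% c("IEA", "EXP")))
  # acyclic by construction: propagation must not error
  expect_silent(propagate_annotations(o$annotations, o$edges))

  # planted term keeps >= 2 experimentally-coded planted-set annotations
  keep <- o$annotations$term_id == o$planted_term &
    o$annotations$gene_id %in% planted & o$annotations$evidence_code != "IEA"
  expect_gte(sum(keep), 2)

  expect_error(onto_config(enrichment_factor = 0.5), "enrichment_factor")
})

test_that("enrichment_factor = 1 gives equal in-set and background rates", {
  universe <- sprintf("g%05d", 1:5000)
  planted <- universe[1:1000]
  o <- simulate_ontology(onto_config(enrichment_factor = 1, n_terms = 10,
                                     seed = 8),
                         planted_set = planted, universe = universe)
  a <- o$annotations[o$annotations$term_id == o$planted_term, ]
  rate_in <- length(unique(a$gene_id[a$gene_id %in% planted])) / 1000
  rate_bg <- length(unique(a$gene_id[!a$gene_id %in% planted])) / 4000
  # both are binomial proportions around annotations_per_gene / n_terms
  expect_lt(abs(rate_in - rate_bg), 0.05)
})

test_that("simulation bundle round-trips through the TSV writers", {
  sim <- simulate_expression(sim_config(n_genes = 30, seed = 6,
    archetypes = default_archetypes(c(2, 2, 1, 1, 2, 2))))
  onto <- simulate_ontology(onto_config(seed = 6), sim$truth,
                            rownames(sim$expr$values))
  dir <- withr::local_tempdir()
  write_simulation(sim, onto, dir)
  back <- read_expression(file.path(dir, "expression.tsv"),
                          file.path(dir, "samples.tsv"))
  expect_equal(back$values, sim$expr$values, tolerance = 1e-12)
  expect_identical(back$design$group, sim$expr$design$group)
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  expect_identical(nrow(ann), nrow(onto$annotations))
})
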