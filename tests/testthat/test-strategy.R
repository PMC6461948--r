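test_that("strategy configurations enforce the AHS/AWHS semantics", {
  ahs <- strategy_config("AHS")
  expect_equal(ahs$within_family_mode, "random")
  awhs <- strategy_config("AWHS")
  expect_equal(awhs$within_family_mode, "best_phenotype")
  expect_error(strategy_config("AHS", within_family_mode = "best_phenotype"),
               "random")
  expect_error(strategy_config("AWHS", family_selection_proportion = 0),
               "\\(0, 1\\]")
  expect_error(strategy_config("RRS"))
})

test_that("among-family selection takes the top share with stable ties", {
  means <- c(3, 9, 1, 7, 5, 8, 2, 6, 4, 0)
  expect_equal(select_among_families(means, 0.2), c(2L, 6L))
  expect_equal(sort(select_among_families(means, 1)), 1:10)
  # ties resolve to the lower family index
  expect_equal(select_among_families(c(5, 7, 7, 1), 0.5), c(2L, 3L))
  # round-half-up with a floor of one family
  expect_length(select_among_families(means, 0.25), 3)  # round(2.5) -> 3
  expect_length(select_among_families(c(1, 2), 0.1), 1)
  expect_error(select_among_families(numeric(0), 0.2), "no families")
})

test_that("within-family selection is random for AHS and best for AWHS", {
  ges <- toy_ges(6, 0, seed = 80)
  set.seed(81)
  block <- initial_population(ges, 4)
  fams <- make_halfsib_families(block, 30, ges)
  fam <- fams[[1]]

  set.seed(82)
  r5 <- select_within_family(fam, NULL, 5, "random")
  expect_equal(pop_size(r5), 5)
  expect_false(anyDuplicated(r5$id) > 0)
  expect_true(all(r5$id %in% fam$members$id))

  # noise-free best-phenotype selection picks the top genotypic values
  g <- genotypic_value(fam$members, ges)
  b5 <- select_within_family(fam, g, 5, "best_phenotype")
  expect_equal(sort(genotypic_value(b5, ges), decreasing = TRUE),
               sort(g, decreasing = TRUE)[1:5])

  whole <- select_within_family(fam, g, 40, "best_phenotype")
  expect_equal(pop_size(whole), 30)
})

test_that("crossing-block updates preserve size for every proportion", {
  ges <- toy_ges(5, 0, seed = 83)
  set.seed(84)
  old <- initial_population(ges, 10)
  fresh <- make_halfsib_families(old, 2, ges)
  pool <- concat_populations(lapply(fresh, `[[`, "members"))

  full <- update_crossing_block(old, subset_population(pool, 1:10), 1)
  expect_equal(sort(full$id), sort(pool$id[1:10]))

  # minimal positive proportion swaps exactly one member
  one <- update_crossing_block(old, subset_population(pool, 1), 0.01)
  expect_equal(pop_size(one), 10)
  expect_equal(sum(!(one$id %in% old$id)), 1)

  set.seed(85)
  for (p in runif(10, 0.05, 1)) {
    upd <- update_crossing_block(old, pool, p)
    expect_equal(pop_size(upd), 10)
  }
  expect_error(update_crossing_block(old, subset_population(pool, 1), 1),
               "available")
})

test_that("a cycle restores the parent count and a run is deterministic", {
  ges <- toy_ges(10, 4, seed = 86)
  design <- trial_design(1, 1, 1, 15)
  cfg <- strategy_config("AWHS", n_parents = 10, cycles = 5)
  set.seed(87)
  r1 <- run_strategy(cfg, ges, design, 0.5)
  expect_equal(nrow(r1$stats), 6)  # cycle 0 plus 5 cycles
  expect_equal(pop_size(r1$final_block), 10)  # 2 families x 5 = 10 parents

  set.seed(87)
  r2 <- run_strategy(cfg, ges, design, 0.5)
  expect_identical(r1$stats, r2$stats)
  expect_identical(r1$final_block$h1, r2$final_block$h1)

  # parent-count conservation at the case-study sizes
  for (N in c(10, 50)) {
    set.seed(88)
    cfgN <- strategy_config("AHS", n_parents = N, cycles = 2)
    rN <- run_strategy(cfgN, ges, trial_design(1, 1, 1, 10), 0.5)
    expect_equal(pop_size(rN$final_block), N)
  }
})

test_that("without selection pressure the genotypic mean shows no trend", {
  ges <- toy_ges(10, 0, n_groups = 2, seed = 89)
  design <- trial_design(1, 1, 1, 5)
  # proportion 1 and random within-family picks = pure drift
  cfg <- strategy_config("AHS", n_parents = 8,
                         family_selection_proportion = 1,
                         within_family_count = 1, cycles = 4)
  set.seed(90)
  slopes <- replicate(100, {
    res <- run_strategy(cfg, ges, design, 0.5)
    unname(stats::coef(stats::lm(mean_g ~ cycle, res$stats))[2])
  })
  ci <- mean(slopes) + c(-1, 1) * 1.96 * stats::sd(slopes) / 10
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("selection lifts the genotypic mean and AWHS beats AHS", {
  set.seed(91)
  # monotone-gain check under high heritability
  up_frac <- replicate(5, {
    ges <- toy_ges(20, 0, n_groups = 4)
    cfg <- strategy_config("AWHS", n_parents = 20, cycles = 10)
    res <- run_strategy(cfg, ges, trial_design(1, 1, 1, 25), 0.9)
    mean(diff(res$stats$mean_g) >= 0)
  })
  expect_gte(mean(up_frac), 0.95)

  # paired AWHS vs AHS comparison at moderate heritability
  set.seed(92)
  gains <- t(replicate(10, {
    seed <- sample.int(1e6, 1)
    ges <- toy_ges(20, 0, n_groups = 4)
    design <- trial_design(1, 1, 1, 20)
    set.seed(seed)
    aw <- run_strategy(strategy_config("AWHS", n_parents = 20, cycles = 10),
                       ges, design, 0.5)
    set.seed(seed)
    ah <- run_strategy(strategy_config("AHS", n_parents = 20, cycles = 10),
                       ges, design, 0.5)
    c(aw = sum(aw$stats$delta_g_pct), ah = sum(ah$stats$delta_g_pct))
  }))
  expect_gte(mean(gains[, "aw"]), mean(gains[, "ah"]))
})

test_that("strategy configs load from YAML and reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("kind: AWHS", "n_parents: 20", "cycles: 10",
               "target_h2_fm: 0.9"), path)
  cfg <- read_strategy_config(path)
  expect_equal(cfg$kind, "AWHS")
  expect_equal(cfg$n_parents, 20L)
  expect_equal(attr(cfg, "target_h2_fm"), 0.9)

  writeLines(c("kind: AHS", "selection_pressure: 3"), path)
  expect_error(read_strategy_config(path), "unknown configuration keys")
})
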