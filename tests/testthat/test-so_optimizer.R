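test_that("bounds and config constructors validate their inputs", {
  expect_error(so_bounds(c(0, 1), c(1)), "equal length")
  expect_error(so_bounds(c(0, 2), c(1, 1)), "lower bound")
  expect_error(so_bounds(c(-Inf, 0), c(1, 1)), "finite")
  expect_error(so_config(population_size = 1), ">= 2")
  expect_error(so_config(fe_budget = 10, population_size = 50), "at least")
  expect_error(so_config(renew_rate = 1.5), "renew_rate")
  expect_error(so_config(competition_rate = 0), "competition_rate")
  expect_error(so_config(growth_scale = 0), "positive")
})

test_that("initialization respects bounds, seeds and the evaluation count", {
  b <- so_bounds(rep(0, 5), rep(1, 5))
  cfg <- so_config(population_size = 50, fe_budget = 3000)
  fn <- counting_strength(sphere_strength)
  set.seed(11)
  f1 <- so_init_forest(b, cfg, fn)
  expect_equal(nrow(f1$positions), 50)
  expect_true(all(f1$positions >= 0 & f1$positions <= 1))
  expect_identical(attr(fn, "count")(), 50L)  # one evaluation per tree
  expect_true(all(is.finite(f1$strengths)))
  set.seed(11)
  f2 <- so_init_forest(b, cfg, sphere_strength)
  expect_identical(f1$positions, f2$positions)

  # degenerate interval: every tree is the constant vector
  bd <- so_bounds(rep(0.3, 4), rep(0.3, 4))
  fd <- so_init_forest(bd, so_config(population_size = 5, fe_budget = 10),
                       sphere_strength)
  expect_true(all(fd$positions == 0.3))
})

test_that("normalized strength follows the printed shifted-over-sum rule", {
  mk <- function(s) {
    f <- so_init_forest(so_bounds(0, 1),
                        so_config(population_size = max(2, length(s)),
                                  fe_budget = 10),
                        function(x) 0)
    f$positions <- matrix(seq_along(s), ncol = 1)
    f$strengths <- s
    f
  }
  expect_equal(so_normalized_strength(mk(c(2, 1, 1))), c(0.25, 0, 0))
  expect_equal(so_normalized_strength(mk(rep(3.7, 4))), rep(0, 4))
  f1 <- mk(c(5, 1)); f1$strengths <- c(5)
  f1$positions <- matrix(1, 1, 1)
  expect_equal(so_normalized_strength(f1), 0)
  # zero denominator
  expect_equal(so_normalized_strength(mk(c(1, -1))), c(0, 0))
})

test_that("renew is a no-op at generation zero and sows ceil(p_r * A) after", {
  b <- so_bounds(c(0, 0), c(1, 1))
  cfg <- so_config(population_size = 10, fe_budget = 1000, renew_rate = 0.1)
  set.seed(2)
  f <- so_init_forest(b, cfg, sphere_strength)
  f$A <- 10L
  expect_identical(so_renew(f, b, cfg, sphere_strength)$positions,
                   f$positions)  # y == 0
  f$y <- 1L
  grown <- so_renew(f, b, cfg, sphere_strength)
  expect_equal(nrow(grown$positions), 11)  # ceil(0.1 * 10) = 1 seedling
  cfg0 <- so_config(population_size = 10, fe_budget = 1000, renew_rate = 0)
  expect_identical(so_renew(f, b, cfg0, sphere_strength)$positions,
                   f$positions)
})

test_that("crowding index matches the printed arithmetic", {
  # one neighbor with S_k = 1 at distance 1 and full effect: Lambda = 1,
  # so the growth increment is damped by 1 / (Lambda + 1) = 1/2
  pos <- rbind(c(0, 0), c(1, 0))
  lam <- soanfis:::crowding_index(1, zone = c(1, 2), positions = pos,
                                  strengths = c(0.5, 1), gamma = 0.5)
  expect_equal(lam, 1)
  # weaker neighbor discounted by 1 - gamma
  lam2 <- soanfis:::crowding_index(2, zone = c(1, 2), positions = pos,
                                   strengths = c(0.5, 1), gamma = 0.25)
  expect_equal(lam2, 0.5 * (1 - 0.25))
})

test_that("competition replaces a cored tree on ties and spares it otherwise", {
  # step objective: strength 2 on [0, 0.6), strength 1 above
  step_fn <- function(x) if (x[1] < 0.6) 2 else 1
  b <- so_bounds(0, 1)
  cfg <- so_config(population_size = 4, fe_budget = 1e6,
                   competition_rate = 0.3, growth_scale = 1e-9,
                   asymmetry = 0.5)
  set.seed(5)
  f <- so_init_forest(b, cfg, step_fn)
  f$positions <- matrix(c(0.10, 0.50, 0.11, 0.90), ncol = 1)
  f$strengths <- c(2, 2, 2, 1)
  out <- so_competition(f, b, cfg, step_fn)
  # cored tree 1's nearest neighbor (tree 3) has equal strength -> replaced
  expect_equal(out$positions[1, 1], out$positions[3, 1])
  expect_equal(out$strengths[1], 2)
  # cored tree 2's only remaining neighbor is weaker -> kept in place
  expect_equal(out$positions[2, 1], 0.50)
  # zero normalized strength means zero neighbors: weakest-cored scenario
  f2 <- f
  f2$strengths <- c(2, 1, 1, 1)  # tau of min-strength trees is 0
  out2 <- so_competition(f2, b, cfg, step_fn)
  expect_equal(nrow(out2$positions), 4)
})

test_that("seeding produces ceil(p_s * N) offspring inside bounds and sets A", {
  b <- so_bounds(c(-2, -2, -2), c(2, 2, 2))
  cfg <- so_config(population_size = 10, fe_budget = 1e6, seeding_rate = 0.5)
  set.seed(8)
  f <- so_init_forest(b, cfg, sphere_strength)
  out <- so_seeding(f, b, cfg, sphere_strength)
  expect_equal(nrow(out$positions), 15)  # 5 offspring appended
  expect_equal(out$A, 5L)
  expect_true(all(out$positions >= -2 & out$positions <= 2))
  cfg0 <- so_config(population_size = 10, fe_budget = 1e6, seeding_rate = 0)
  out0 <- so_seeding(f, b, cfg0, sphere_strength)
  expect_equal(nrow(out0$positions), 10)
  expect_equal(out0$A, 0L)
})

test_that("resistance culls, restores capacity and never empties the forest", {
  b <- so_bounds(c(0, 0), c(1, 1))
  cfg <- so_config(population_size = 10, fe_budget = 1e6, seeding_rate = 0.3)
  set.seed(3)
  f <- so_init_forest(b, cfg, sphere_strength)
  f <- so_seeding(f, b, cfg, sphere_strength)   # 13 trees
  out <- so_resistance(f, cfg)
  expect_equal(nrow(out$positions), 10)
  expect_equal(out$y, 1L)
  expect_gte(max(out$strengths), max(f$strengths))  # strongest kept
  # resistance_rate override decouples p_w from p_s
  cfg2 <- so_config(population_size = 10, fe_budget = 1e6,
                    seeding_rate = 0.3, resistance_rate = 0)
  out2 <- so_resistance(f, cfg2)
  expect_equal(nrow(out2$positions), 10)  # only the capacity trim
  # removal never empties: 2 trees, aggressive rate
  tiny <- f; tiny$positions <- f$positions[1:2, ]; tiny$strengths <-
    f$strengths[1:2]
  cfg3 <- so_config(population_size = 2, fe_budget = 1e6, seeding_rate = 1)
  expect_gte(nrow(so_resistance(tiny, cfg3)$positions), 1)
})

test_that("optimize is deterministic, elitist, budgeted and restores capacity", {
  b <- so_bounds(c(-5, -5), c(5, 5))
  cfg <- so_config(population_size = 20, fe_budget = 600, seed = 7)
  fn <- counting_strength(sphere_strength)
  r1 <- so_optimize(fn, b, cfg)
  r2 <- so_optimize(sphere_strength, b, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_position, r2$best_position)
  expect_true(all(diff(r1$trace$best_strength) >= 0))
  expect_lte(attr(fn, "count")(), cfg$fe_budget + cfg$population_size)
  expect_equal(nrow(r1$forest$positions), 20)
  expect_true(all(r1$forest$positions >= -5 & r1$forest$positions <= 5))
  # the incumbent matches the best strength seen in the final forest
  expect_gte(r1$best_strength, max(r1$forest$strengths))
})

test_that("non-finite strengths are demoted with a warning, not propagated", {
  flaky <- function(x) if (x[1] > 0) NaN else -sum(x^2)
  b <- so_bounds(-1, 1)
  cfg <- so_config(population_size = 5, fe_budget = 60, seed = 2)
  expect_warning(res <- so_optimize(flaky, b, cfg), "non-finite")
  expect_true(is.finite(res$best_strength))
})

test_that("optimizer config reads from JSON and YAML mappings", {
  js <- tempfile(fileext = ".json")
  writeLines('{"population_size": 12, "fe_budget": 100, "seed": 4}', js)
  cfg <- so_config_from_file(js)
  expect_s3_class(cfg, "so_config")
  expect_equal(cfg$population_size, 12L)
  expect_equal(cfg$fe_budget, 100L)
  bad <- tempfile(fileext = ".json")
  writeLines('{"popsize": 12}', bad)
  expect_error(so_config_from_file(bad), "unknown")
  if (requireNamespace("yaml", quietly = TRUE)) {
    ym <- tempfile(fileext = ".yaml")
    writeLines(c("population_size: 8", "fe_budget: 90"), ym)
    expect_equal(so_config_from_file(ym)$population_size, 8L)
  }
})

test_that("trace export writes the generation log as CSV", {
  res <- so_optimize(sphere_strength, so_bounds(-1, 1),
                     so_config(population_size = 5, fe_budget = 50, seed = 1))
  path <- tempfile(fileext = ".csv")
  write_so_trace(res, path)
  back <- read.csv(path)
  expect_identical(names(back), c("generation", "best_strength", "fe_used"))
  expect_equal(nrow(back), nrow(res$trace))
})

test_that("property: bounds containment and capacity hold across many cycles", {
  for (seed in 1:5) {
    b <- so_bounds(c(-3, 0, 1), c(3, 10, 1.5))
    cfg <- so_config(population_size = 8, fe_budget = 300, seed = seed)
    res <- so_optimize(sphere_strength, b, cfg)
    expect_true(all(sweep(res$forest$positions, 2, b$lower, `>=`)))
    expect_true(all(sweep(res$forest$positions, 2, b$upper, `<=`)))
    expect_equal(nrow(res$forest$positions), 8)
    expect_true(all(diff(res$trace$best_strength) >= 0))
    expect_lte(res$fe_used, cfg$fe_budget + cfg$population_size)
  }
})
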