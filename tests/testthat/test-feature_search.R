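test_that("search space size is exact, including beyond double precision", {
  expect_identical(search_space_size(0), 1)
  expect_identical(search_space_size(3), 8)
  expect_identical(search_space_size(47), 140737488355328)
  expect_identical(search_space_size(100),
                   "1267650600228229401496703205376")
})

test_that("heuristic desirability is the rescaled Fisher ratio", {
  # hand case: feature 1 has ratio (0.5-3.5)^2/(0.5+0.5) = 9, feature 2 has
  # ratio (0.5-1.5)^2/(0.5+0.5) = 1, feature 3 is class-identical
  X <- cbind(c(0, 1, 3, 4), c(0, 1, 1, 2), c(5, 6, 5, 6))
  y <- c("A", "A", "B", "B")
  eta <- heuristic_desirability(X, y)
  expect_equal(eta[1], 1)
  expect_equal(eta[2], 1 / 9, tolerance = 1e-9)
  expect_lt(eta[3], 1e-9)
  expect_error(heuristic_desirability(X, rep("A", 4)), "two classes")
  # all-flat input degrades to uniform desirability
  expect_equal(heuristic_desirability(matrix(1, 4, 2), y), c(1, 1))
})

test_that("subset construction follows the transition probabilities", {
  cfg <- colony_config(subset_size_range = c(1, 1))
  ph <- pheromone_state(3, cfg)
  ph$tau <- c(1, 2, 1)
  eta <- c(1, 1, 1)
  set.seed(11)
  draws <- replicate(10000, construct_subset(ph, eta, cfg, sigma = 1, v = 1))
  freq <- tabulate(draws, 3) / 10000
  sig <- sqrt(c(.25, .5, .25) * c(.75, .5, .75) / 10000)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * sig))
})

test_that("zero-desirability features are never chosen while others remain", {
  cfg <- colony_config(subset_size_range = c(2, 2))
  ph <- pheromone_state(4, cfg)
  eta <- c(1, 0, 1, 1)
  set.seed(12)
  for (i in 1:300) {
    s <- construct_subset(ph, eta, cfg, sigma = 1, v = 1)
    expect_false(2 %in% s)
    expect_length(s, 2)
    expect_true(all(s %in% 1:4))
  }
})

test_that("with v = 0 and uniform pheromone, k-subsets are uniform", {
  cfg <- colony_config(subset_size_range = c(2, 2))
  ph <- pheromone_state(6, cfg)
  eta <- runif(6)  # irrelevant at v = 0
  set.seed(13)
  draws <- replicate(5000, construct_subset(ph, eta, cfg, sigma = 1, v = 0))
  counts <- tabulate(as.vector(draws), 6)
  expected <- 5000 * 2 / 6
  chisq <- sum((counts - expected)^2 / expected)
  expect_lt(chisq, qchisq(0.999, df = 5))
})

test_that("fitness rewards accuracy and parsimony as specified", {
  fc <- fitness_config()
  expect_equal(fc$m_weight, 0.92)
  expect_equal(fc$n_weight, 0.78)
  expect_equal(subset_fitness(1, 1, fc), 1.70)
  expect_equal(subset_fitness(0.5, 2, fc), 0.92 * 0.5 + 0.78 / 2)
  expect_error(subset_fitness(0.5, 0, fc), "at least one")
  expect_error(subset_fitness(1.2, 5, fc), "\\[0, 1\\]")
})

test_that("pheromone updates match hand-worked evaporation and deposits", {
  cfg <- colony_config(rho = 0.5, delta = 1)
  ph <- pheromone_state(3, cfg)
  # pure evaporation at rho = 0.5: 1.0 -> 0.5
  ph2 <- update_pheromone(ph, list(), cfg)
  expect_equal(ph2$tau, rep(0.5, 3))
  # single deposit, rho = 0: 1.0 + 1 * 0.8 = 1.8 on the used feature
  ph3 <- update_pheromone(ph, list(list(subset = 2L, fitness = 0.8)),
                          cfg, rho = 0)
  expect_equal(ph3$tau, c(1, 1.8, 1))
  # clamping to tau_min is exact
  cfg2 <- colony_config(rho = 0.99, tau_min = 0.1)
  ph4 <- update_pheromone(pheromone_state(2, cfg2), list(), cfg2)
  expect_equal(ph4$tau, rep(0.1, 2))
})

test_that("pheromone stays inside its bounds under random updates", {
  cfg <- colony_config(tau_min = 0.1, tau_max = 5)
  ph <- pheromone_state(10, cfg)
  set.seed(14)
  for (i in 1:50) {
    sols <- lapply(seq_len(sample(0:5, 1)), function(j)
      list(subset = sample(10, sample(1:6, 1)), fitness = runif(1, 0, 1.7)))
    ph <- update_pheromone(ph, sols, cfg, rho = runif(1, 0.01, 1))
    expect_true(all(ph$tau >= 0.1 - 1e-12 & ph$tau <= 5 + 1e-12))
  }
})

test_that("the IACO schedule interpolates and boosts evaporation", {
  cfg <- colony_config(n_iter = 20, rho = 0.4, sigma_range = c(1, 2),
                       v_range = c(2, 0.5), stagnation_patience = 5)
  s0 <- iaco_schedule(cfg, 0)
  expect_equal(unname(s0), c(1, 2, 0.4))
  s_end <- iaco_schedule(cfg, 19)
  expect_equal(unname(s_end[c("sigma", "v")]), c(2, 0.5))
  expect_equal(unname(iaco_schedule(cfg, 10, stagnation = 5)["rho"]), 0.8)
  cfg2 <- colony_config(rho = 0.7)
  expect_equal(unname(iaco_schedule(cfg2, 0, stagnation = 9)["rho"]), 1)
})

test_that("the colony is deterministic and its record is monotone", {
  feats <- make_planted_matrix(seed = 21)
  ev <- make_centroid_evaluator(feats$values, feats$labels)
  cfg <- colony_config(n_ants = 8, n_iter = 12, seed = 33)
  r1 <- run_colony(feats$values, feats$labels, cfg, evaluator = ev)
  r2 <- run_colony(feats$values, feats$labels, cfg, evaluator = ev)
  expect_identical(r1$best$subset, r2$best$subset)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history$best_fitness) >= 0))
  expect_gte(r1$best$n_selected, 1)
  expect_equal(r1$best$fitness,
               subset_fitness(r1$best$accuracy, r1$best$n_selected))
})

test_that("the colony recovers planted features", {
  feats <- make_planted_matrix(seed = 22)
  ev <- make_centroid_evaluator(feats$values, feats$labels)
  hits <- vapply(1:20, function(s) {
    cfg <- colony_config(n_ants = 20, n_iter = 30, seed = s)
    r <- run_colony(feats$values, feats$labels, cfg, evaluator = ev)
    sum(1:5 %in% r$best$subset)
  }, numeric(1))
  expect_gte(mean(hits >= 4), 0.8)
})

test_that("the GA finds a single perfect feature among noise", {
  set.seed(23)
  n <- 60
  X <- matrix(rnorm(n * 11), n, 11)
  y <- rep(c("A", "B"), each = n / 2)
  X[, 4] <- ifelse(y == "A", 1, -1) + rnorm(n, 0, 0.05)
  colnames(X) <- paste0("f", 1:11)
  ev <- make_centroid_evaluator(X, y)
  hits <- vapply(1:20, function(s) {
    r <- ga_select(X, y, ga_config(pop_size = 20, n_iter = 40, seed = s),
                   evaluator = ev)
    expect_true(all(r$best$subset %in% 1:11))
    4 %in% r$best$subset
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  r1 <- ga_select(X, y, ga_config(seed = 5), evaluator = ev)
  r2 <- ga_select(X, y, ga_config(seed = 5), evaluator = ev)
  expect_identical(r1$best, r2$best)
})

test_that("binary PSO uses the sigmoid transfer and recovers the signal", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(4), 1 / (1 + exp(-4)))
  expect_equal(sigmoid(4), 0.982, tolerance = 1e-3)
  set.seed(24)
  n <- 60
  X <- matrix(rnorm(n * 11), n, 11)
  y <- rep(c("A", "B"), each = n / 2)
  X[, 7] <- ifelse(y == "A", 1, -1) + rnorm(n, 0, 0.05)
  colnames(X) <- paste0("f", 1:11)
  ev <- make_centroid_evaluator(X, y)
  hits <- vapply(1:20, function(s) {
    r <- pso_select(X, y, pso_config(n_particles = 16, n_iter = 25, seed = s),
                    evaluator = ev)
    7 %in% r$best$subset
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  r1 <- pso_select(X, y, pso_config(seed = 6), evaluator = ev)
  r2 <- pso_select(X, y, pso_config(seed = 6), evaluator = ev)
  expect_identical(r1$best, r2$best)
})
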