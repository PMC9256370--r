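#' Genetic-algorithm baseline configuration
#'
#' Binary-chromosome GA over feature inclusion bits: tournament selection
#' (size 2), two-point crossover applied with probability `crossover_p`,
#' per-chromosome mutation flipping one uniformly chosen bit with probability
#' `mutation_p`, and single-individual elitism. All-zero chromosomes are
#' repaired by setting one random bit.
#'
#' @param pop_size Population size.
#' @param n_iter Generation budget.
#' @param crossover_p Crossover probability.
#' @param mutation_p Per-chromosome mutation probability.
#' @param objective `"fitness"` scores individuals with the accuracy +
#'   parsimony objective of [subset_fitness()]; `"accuracy"` uses raw
#'   classification accuracy.
#' @param patience_stop Stop after this many generations without improvement.
#' @param seed Optional integer seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 20, n_iter = 50, crossover_p = 0.8,
                      mutation_p = 0.2, objective = c("fitness", "accuracy"),
                      patience_stop = 10, seed = NULL) {
  stopifnot(pop_size >= 2, n_iter >= 1,
            crossover_p >= 0, crossover_p <= 1,
            mutation_p >= 0, mutation_p <= 1)
  structure(list(pop_size = pop_size, n_iter = n_iter,
                 crossover_p = crossover_p, mutation_p = mutation_p,
                 objective = match.arg(objective),
                 patience_stop = patience_stop, seed = seed),
            class = "ga_config")
}

#' Binary particle-swarm baseline configuration
#'
#' Binary PSO with real-valued velocities and a sigmoid transfer: bit `j` of
#' a particle is set with probability `sigmoid(velocity_j)`. Inertia descends
#' linearly over `w_range`, cognitive/social coefficients are `c1`/`c2`, and
#' velocities are clamped to `[-v_clamp, v_clamp]`.
#'
#' @param n_particles Swarm size.
#' @param n_iter Iteration budget.
#' @param w_range Start/end inertia weights.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param v_clamp Velocity clamp.
#' @param objective `"fitness"` (accuracy + parsimony) or `"accuracy"`.
#' @param patience_stop Stop after this many iterations without improvement.
#' @param seed Optional integer seed.
#' @return A `pso_config` list.
#' @export
pso_config <- function(n_particles = 20, n_iter = 50,
                       w_range = c(0.9, 0.4), c1 = 2, c2 = 2, v_clamp = 4,
                       objective = c("fitness", "accuracy"),
                       patience_stop = 10, seed = NULL) {
  stopifnot(n_particles >= 2, n_iter >= 1, v_clamp > 0)
  structure(list(n_particles = n_particles, n_iter = n_iter,
                 w_range = w_range, c1 = c1, c2 = c2, v_clamp = v_clamp,
                 objective = match.arg(objective),
                 patience_stop = patience_stop, seed = seed),
            class = "pso_config")
}

#' Sigmoid transfer function
#'
#' @param x Numeric vector.
#' @return `1 / (1 + exp(-x))`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

.repair_mask <- function(mask) {
  if (!any(mask)) mask[sample.int(length(mask), 1L)] <- TRUE
  mask
}

.score_mask <- function(mask, X, y, evaluator, fc, objective) {
  subset <- which(mask)
  acc <- evaluator(subset, X, y)
  fit <- subset_fitness(acc, length(subset), fc)
  list(subset = subset, accuracy = acc, n_selected = length(subset),
       fitness = fit,
       objective = if (objective == "fitness") fit else acc)
}

.as_search_result <- function(best, hist, evaluations, method, X) {
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  best$objective <- NULL
  best$feature_names <- colnames(X)[best$subset]
  structure(list(best = best, history = history, evaluations = evaluations,
                 method = method),
            class = "search_result")
}

#' Genetic-algorithm wrapper feature selection
#'
#' @param X Feature matrix (subjects x features).
#' @param y Two-level class labels.
#' @param config A [ga_config()].
#' @param fc A [fitness_config()].
#' @param evaluator `function(subset, X, y) -> accuracy`; see
#'   [make_svm_evaluator()].
#' @return A `search_result` (same shape as [run_colony()]).
#' @export
ga_select <- function(X, y, config = ga_config(), fc = fitness_config(),
                      evaluator = make_svm_evaluator(X, y)) {
  if (!is.null(config$seed)) .local_seed(config$seed)
  n <- ncol(X)
  pop <- lapply(seq_len(config$pop_size), function(i)
    .repair_mask(runif(n) < 0.5))
  scores <- lapply(pop, .score_mask, X, y, evaluator, fc, config$objective)
  evaluations <- length(scores)
  obj <- vapply(scores, `[[`, numeric(1), "objective")
  best <- scores[[which.max(obj)]]
  stagnation <- 0L
  hist <- vector("list", config$n_iter)
  tournament <- function() {
    cand <- sample.int(config$pop_size, 2L)
    cand[which.max(obj[cand])]
  }
  for (g in seq_len(config$n_iter)) {
    newpop <- list(pop[[which.max(obj)]])  # elitism
    while (length(newpop) < config$pop_size) {
      p1 <- pop[[tournament()]]
      p2 <- pop[[tournament()]]
      if (runif(1) < config$crossover_p && n >= 3) {
        cut <- sort(sample.int(n - 1L, 2L))
        mid <- (cut[1] + 1L):cut[2]
        c1 <- p1; c1[mid] <- p2[mid]
        c2 <- p2; c2[mid] <- p1[mid]
      } else {
        c1 <- p1; c2 <- p2
      }
      for (child in list(c1, c2)) {
        if (runif(1) < config$mutation_p) {
          flip <- sample.int(n, 1L)
          child[flip] <- !child[flip]
        }
        newpop[[length(newpop) + 1L]] <- .repair_mask(child)
        if (length(newpop) == config$pop_size) break
      }
    }
    pop <- newpop
    scores <- lapply(pop, .score_mask, X, y, evaluator, fc, config$objective)
    evaluations <- evaluations + length(scores)
    obj <- vapply(scores, `[[`, numeric(1), "objective")
    gen_best <- scores[[which.max(obj)]]
    if (gen_best$objective > best$objective) {
      best <- gen_best
      stagnation <- 0L
    } else stagnation <- stagnation + 1L
    hist[[g]] <- data.frame(iteration = g, best_fitness = best$fitness,
                            mean_fitness = mean(vapply(scores, `[[`,
                                                       numeric(1), "fitness")))
    if (stagnation >= config$patience_stop) break
  }
  .as_search_result(best, hist, evaluations, "ga", X)
}

#' Binary particle-swarm wrapper feature selection
#'
#' @inheritParams ga_select
#' @param config A [pso_config()].
#' @return A `search_result` (same shape as [run_colony()]).
#' @export
pso_select <- function(X, y, config = pso_config(), fc = fitness_config(),
                       evaluator = make_svm_evaluator(X, y)) {
  if (!is.null(config$seed)) .local_seed(config$seed)
  n <- ncol(X)
  np <- config$n_particles
  vel <- matrix(runif(np * n, -1, 1), np, n)
  pos <- matrix(runif(np * n) < 0.5, np, n)
  pos <- t(apply(pos, 1, .repair_mask))
  scores <- lapply(seq_len(np), function(i)
    .score_mask(pos[i, ], X, y, evaluator, fc, config$objective))
  evaluations <- np
  pbest_pos <- pos
  pbest_obj <- vapply(scores, `[[`, numeric(1), "objective")
  gidx <- which.max(pbest_obj)
  best <- scores[[gidx]]
  gbest_pos <- pos[gidx, ]
  stagnation <- 0L
  hist <- vector("list", config$n_iter)
  for (t in seq_len(config$n_iter)) {
    frac <- if (config$n_iter == 1) 0 else (t - 1) / (config$n_iter - 1)
    w <- config$w_range[1] + frac * (config$w_range[2] - config$w_range[1])
    r1 <- matrix(runif(np * n), np, n)
    r2 <- matrix(runif(np * n), np, n)
    vel <- w * vel +
      config$c1 * r1 * (pbest_pos - pos) +
      config$c2 * r2 * (matrix(gbest_pos, np, n, byrow = TRUE) - pos)
    vel <- pmin(pmax(vel, -config$v_clamp), config$v_clamp)
    pos <- matrix(runif(np * n), np, n) < sigmoid(vel)
    pos <- t(apply(pos, 1, .repair_mask))
    scores <- lapply(seq_len(np), function(i)
      .score_mask(pos[i, ], X, y, evaluator, fc, config$objective))
    evaluations <- evaluations + np
    obj <- vapply(scores, `[[`, numeric(1), "objective")
    improved <- obj > pbest_obj
    pbest_pos[improved, ] <- pos[improved, , drop = FALSE]
    pbest_obj[improved] <- obj[improved]
    it_best <- which.max(pbest_obj)
    if (pbest_obj[it_best] > best$objective) {
      best <- scores[[which.max(obj)]]
      gbest_pos <- pbest_pos[it_best, ]
      stagnation <- 0L
    } else stagnation <- stagnation + 1L
    hist[[t]] <- data.frame(iteration = t, best_fitness = best$fitness,
                            mean_fitness = mean(vapply(scores, `[[`,
                                                       numeric(1), "fitness")))
    if (stagnation >= config$patience_stop) break
  }
  .as_search_result(best, hist, evaluations, "pso", X)
}
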