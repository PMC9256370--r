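#' Ant colony configuration
#'
#' Parameters of the ant-colony wrapper search. `sigma` and `v` weight the
#' influence of learned pheromone versus the filter-style heuristic when an
#' ant picks its next feature; `rho` is the evaporation rate and `delta`
#' scales fitness-proportional pheromone deposits. Pheromone is clamped to
#' `[tau_min, tau_max]` (max-min style) to keep stagnated trails recoverable.
#'
#' In improved-ACO mode (`iaco = TRUE`) the heuristic parameters are varied
#' during the run: `sigma` ramps linearly over `sigma_range` and `v` over
#' `v_range` across the iteration budget (exploration by prior relevance
#' first, exploitation of learned trails later), and the evaporation rate is
#' temporarily doubled (capped at 1) while the best fitness has stagnated
#' for at least `stagnation_patience` iterations.
#'
#' @param n_ants Ants per iteration.
#' @param n_iter Iteration budget.
#' @param sigma Pheromone exponent (fixed-mode value).
#' @param v Heuristic exponent (fixed-mode value).
#' @param rho Evaporation rate in `(0, 1]`.
#' @param delta Deposit scale.
#' @param tau_init,tau_min,tau_max Initial value and clamp bounds for
#'   pheromone.
#' @param subset_size_range Inclusive `(k_min, k_max)` for the per-ant target
#'   subset size, drawn uniformly.
#' @param iaco Enable the dynamic-heuristic schedule.
#' @param sigma_range,v_range Start/end values of the linear schedules.
#' @param stagnation_patience Stagnant iterations before the evaporation
#'   boost kicks in.
#' @param patience_stop Stop after this many iterations without improvement
#'   of the best fitness.
#' @param seed Optional integer seed for the run.
#' @return A `colony_config` list.
#' @export
colony_config <- function(n_ants = 20, n_iter = 50,
                          sigma = 1, v = 1, rho = 0.2, delta = 1,
                          tau_init = 1, tau_min = 0.1, tau_max = 5,
                          subset_size_range = c(10, 35),
                          iaco = FALSE,
                          sigma_range = c(1, 2), v_range = c(2, 0.5),
                          stagnation_patience = 5,
                          patience_stop = 10,
                          seed = NULL) {
  stopifnot(n_ants >= 1, n_iter >= 1, sigma >= 0, v >= 0,
            rho > 0, rho <= 1, delta > 0,
            tau_min > 0, tau_min <= tau_init, tau_init <= tau_max,
            length(subset_size_range) == 2L,
            subset_size_range[1] >= 1,
            subset_size_range[1] <= subset_size_range[2])
  structure(list(n_ants = n_ants, n_iter = n_iter, sigma = sigma, v = v,
                 rho = rho, delta = delta, tau_init = tau_init,
                 tau_min = tau_min, tau_max = tau_max,
                 subset_size_range = subset_size_range, iaco = iaco,
                 sigma_range = sigma_range, v_range = v_range,
                 stagnation_patience = stagnation_patience,
                 patience_stop = patience_stop, seed = seed),
            class = "colony_config")
}

#' Initialize a pheromone state
#'
#' @param n_features Number of features.
#' @param cfg A [colony_config()].
#' @return A `pheromone_state` with per-feature `tau` and the clamp bounds.
#' @export
pheromone_state <- function(n_features, cfg = colony_config()) {
  structure(list(tau = rep(cfg$tau_init, n_features),
                 tau_min = cfg$tau_min, tau_max = cfg$tau_max,
                 iteration = 0L),
            class = "pheromone_state")
}

#' Filter-style heuristic desirability of each feature
#'
#' Per-feature Fisher discriminant ratio
#' `(mu1 - mu2)^2 / (s1^2 + s2^2 + eps)` between the two classes, rescaled to
#' `(0, 1]` by its maximum. This plays the role of the prior "closeness"
#' heuristic in the ant transition rule: cheap, classifier-free evidence of
#' single-feature relevance.
#'
#' @param X Numeric feature matrix (subjects x features).
#' @param y Two-level class labels.
#' @param eps Variance regularizer.
#' @return Numeric vector of desirabilities in `[0, 1]`, max exactly 1
#'   (uniform 1s if all ratios are 0).
#' @export
heuristic_desirability <- function(X, y, eps = 1e-12) {
  y <- factor(y)
  if (nlevels(y) != 2) stop("exactly two classes are required")
  if (any(table(y) < 2)) stop("each class needs at least 2 samples")
  a <- X[y == levels(y)[1], , drop = FALSE]
  b <- X[y == levels(y)[2], , drop = FALSE]
  num <- (colMeans(a) - colMeans(b))^2
  den <- apply(a, 2, var) + apply(b, 2, var) + eps
  eta <- num / den
  m <- max(eta)
  if (m <= 0) return(rep(1, ncol(X)))
  eta / m
}

#' Construct one ant's feature subset
#'
#' Draws a target size `k` uniformly from the configured range, then selects
#' `k` distinct features by sequential roulette: at each step feature `j` is
#' chosen from the not-yet-selected set with probability proportional to
#' `tau_j^sigma * eta_j^v`.
#'
#' @param ph A [pheromone_state()].
#' @param eta Heuristic desirabilities from [heuristic_desirability()].
#' @param cfg A [colony_config()].
#' @param sigma,v Exponents to use (default: the fixed values in `cfg`;
#'   overridden per-iteration in IACO mode).
#' @param k Optional fixed subset size (otherwise drawn).
#' @return Integer vector of selected feature indices (sorted).
#' @export
construct_subset <- function(ph, eta, cfg, sigma = cfg$sigma, v = cfg$v,
                             k = NULL) {
  n <- length(ph$tau)
  if (length(eta) != n) stop("eta and tau must have equal length")
  kr <- pmin(cfg$subset_size_range, n)
  if (kr[2] > n) stop("k_max exceeds the number of features")
  if (is.null(k)) k <- if (kr[1] == kr[2]) kr[1] else
    sample(seq(kr[1], kr[2]), 1L)
  k <- min(k, n)
  remaining <- seq_len(n)
  picked <- integer(0)
  w_all <- ph$tau^sigma * eta^v
  for (step in seq_len(k)) {
    w <- w_all[remaining]
    if (all(w <= 0)) w <- rep(1, length(w))  # only zero-weight features left
    pick <- remaining[sample.int(length(remaining), 1L, prob = w)]
    picked <- c(picked, pick)
    remaining <- remaining[remaining != pick]
  }
  sort(picked)
}

#' Evaporate and deposit pheromone
#'
#' `tau_j <- (1 - rho) * tau_j + sum_r delta * f(A_r) * [j in A_r]`, then
#' clamp to `[tau_min, tau_max]`. Every solution in `solutions` deposits on
#' the features it used, proportionally to its fitness. An empty solution
#' list performs pure evaporation.
#'
#' @param ph A [pheromone_state()].
#' @param solutions List of ant solutions, each with `subset` (indices) and
#'   `fitness`.
#' @param cfg A [colony_config()].
#' @param rho Evaporation rate (default from `cfg`; overridden per-iteration
#'   in IACO mode).
#' @return The updated `pheromone_state`.
#' @export
update_pheromone <- function(ph, solutions, cfg, rho = cfg$rho) {
  tau <- (1 - rho) * ph$tau
  for (s in solutions) {
    tau[s$subset] <- tau[s$subset] + cfg$delta * s$fitness
  }
  ph$tau <- pmin(pmax(tau, ph$tau_min), ph$tau_max)
  ph$iteration <- ph$iteration + 1L
  ph
}

#' Dynamic heuristic parameters of the improved ACO
#'
#' Linear interpolation of `sigma` and `v` across the iteration budget, plus
#' a stagnation-triggered evaporation boost: while the best fitness has not
#' improved for `stagnation_patience` iterations, `rho` is doubled (capped
#' at 1) to decay stale trails faster.
#'
#' @param cfg A [colony_config()].
#' @param t Zero-based iteration index, `0 <= t < n_iter`.
#' @param stagnation Number of consecutive iterations without improvement.
#' @return Named numeric vector `c(sigma, v, rho)`.
#' @export
iaco_schedule <- function(cfg, t, stagnation = 0) {
  stopifnot(t >= 0, t < cfg$n_iter)
  frac <- if (cfg$n_iter == 1) 0 else t / (cfg$n_iter - 1)
  sigma <- cfg$sigma_range[1] + frac * (cfg$sigma_range[2] - cfg$sigma_range[1])
  v <- cfg$v_range[1] + frac * (cfg$v_range[2] - cfg$v_range[1])
  rho <- if (stagnation >= cfg$stagnation_patience)
    min(2 * cfg$rho, 1) else cfg$rho
  c(sigma = sigma, v = v, rho = rho)
}

#' Run the ant-colony wrapper search
#'
#' Per iteration, each ant constructs a subset, the evaluator returns its
#' classification accuracy `J`, fitness is `m * J + n / |A|`, and all ants
#' deposit pheromone. In IACO mode the exponents and evaporation follow
#' [iaco_schedule()]; standard ACO keeps them fixed. The search stops at the
#' iteration budget or after `patience_stop` iterations without improvement.
#'
#' @param X Feature matrix (subjects x features).
#' @param y Two-level class labels.
#' @param cfg A [colony_config()].
#' @param fc A [fitness_config()].
#' @param evaluator `function(subset, X, y) -> accuracy in [0, 1]`; see
#'   [make_svm_evaluator()].
#' @return A `search_result`: `best` (subset indices, names, accuracy,
#'   fitness, n_selected), `history` (per-iteration best-so-far and mean
#'   fitness), `evaluations`, `method`.
#' @export
run_colony <- function(X, y, cfg = colony_config(), fc = fitness_config(),
                       evaluator = make_svm_evaluator(X, y)) {
  if (!is.null(cfg$seed)) .local_seed(cfg$seed)
  n_feat <- ncol(X)
  eta <- heuristic_desirability(X, y)
  ph <- pheromone_state(n_feat, cfg)
  best <- NULL
  stagnation <- 0L
  evaluations <- 0L
  hist <- vector("list", cfg$n_iter)
  for (t in seq_len(cfg$n_iter) - 1L) {
    par <- if (cfg$iaco) iaco_schedule(cfg, t, stagnation) else
      c(sigma = cfg$sigma, v = cfg$v, rho = cfg$rho)
    ants <- vector("list", cfg$n_ants)
    for (a in seq_len(cfg$n_ants)) {
      subset <- construct_subset(ph, eta, cfg,
                                 sigma = par[["sigma"]], v = par[["v"]])
      acc <- evaluator(subset, X, y)
      evaluations <- evaluations + 1L
      ants[[a]] <- list(subset = subset, accuracy = acc,
                        n_selected = length(subset),
                        fitness = subset_fitness(acc, length(subset), fc))
    }
    fits <- vapply(ants, `[[`, numeric(1), "fitness")
    it_best <- ants[[which.max(fits)]]
    if (is.null(best) || it_best$fitness > best$fitness) {
      best <- it_best
      stagnation <- 0L
    } else {
      stagnation <- stagnation + 1L
    }
    ph <- update_pheromone(ph, ants, cfg, rho = par[["rho"]])
    hist[[t + 1L]] <- data.frame(iteration = t + 1L,
                                 best_fitness = best$fitness,
                                 mean_fitness = mean(fits),
                                 sigma = par[["sigma"]], v = par[["v"]],
                                 rho = par[["rho"]])
    if (stagnation >= cfg$patience_stop) break
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  best$feature_names <- colnames(X)[best$subset]
  structure(list(best = best, history = history, evaluations = evaluations,
                 method = if (cfg$iaco) "iaco" else "aco"),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(
    "<search_result> %s: %d features, accuracy %.3f, fitness %.3f (%d evals)\n",
    x$method, x$best$n_selected, x$best$accuracy, x$best$fitness,
    x$evaluations))
  invisible(x)
}
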