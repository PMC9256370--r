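#' Stratified k-fold partition
#'
#' Shuffles each class separately (seeded) and deals it across `k` folds,
#' assigning per-class remainders to the currently smallest folds so that
#' class proportions per fold stay within one subject of the global
#' proportions.
#'
#' @param labels Class labels, one per subject.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return List of `k` integer index vectors partitioning
#'   `seq_along(labels)`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- factor(labels)
  if (any(table(labels) < k))
    stop(sprintf("each class needs at least %d members for %d folds", k, k))
  .local_seed(seed)
  folds <- rep(list(integer(0)), k)
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    base <- length(idx) %/% k
    extra <- length(idx) %% k
    # folds with the fewest subjects so far absorb this class's remainder
    sizes <- lengths(folds)
    order_f <- order(sizes, seq_len(k))
    take <- rep(base, k)
    if (extra > 0) take[order_f[seq_len(extra)]] <- base + 1L
    pos <- 0L
    for (f in seq_len(k)) {
      if (take[f] > 0) {
        folds[[f]] <- c(folds[[f]], idx[pos + seq_len(take[f])])
        pos <- pos + take[f]
      }
    }
  }
  lapply(folds, sort)
}

#' Classification metrics from decision scores
#'
#' Accuracy at the sign threshold (scores `>= 0` predict the positive
#' class), sensitivity as the true-positive rate of the positive class, and
#' AUC as the Mann-Whitney statistic of the scores with ties counted one
#' half.
#'
#' @param scores Numeric decision values, higher favoring the positive
#'   class.
#' @param truth True labels.
#' @param positive The positive class (default: first factor level).
#' @return List with `accuracy`, `sensitivity`, `auc`.
#' @export
classification_metrics <- function(scores, truth, positive = NULL) {
  truth <- factor(truth)
  if (is.null(positive)) positive <- levels(truth)[1]
  is_pos <- truth == positive
  if (!any(is_pos) || all(is_pos))
    stop("both classes must be present for AUC")
  pred_pos <- scores >= 0
  accuracy <- mean(pred_pos == is_pos)
  sensitivity <- mean(pred_pos[is_pos])
  r <- rank(scores)
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  auc <- (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(accuracy = accuracy, sensitivity = sensitivity, auc = auc)
}

#' Nested cross-validation configuration
#'
#' @param outer_k,inner_k Outer and inner fold counts.
#' @param colony A [colony_config()] (used for both `"aco"` and `"iaco"`;
#'   the IACO flag is set from the method).
#' @param ga A [ga_config()].
#' @param pso A [pso_config()].
#' @param fc A [fitness_config()].
#' @param kernel A [kernel_spec()].
#' @param C SVM box penalty.
#' @param positive Positive class for sensitivity (default: first level).
#' @param seed Integer seed driving fold assignment and the searches.
#' @return A `cv_config` list.
#' @export
cv_config <- function(outer_k = 6, inner_k = 5,
                      colony = colony_config(),
                      ga = ga_config(), pso = pso_config(),
                      fc = fitness_config(),
                      kernel = kernel_spec(), C = 10,
                      positive = NULL, seed = 1L) {
  structure(list(outer_k = outer_k, inner_k = inner_k, colony = colony,
                 ga = ga, pso = pso, fc = fc, kernel = kernel, C = C,
                 positive = positive, seed = as.integer(seed)),
            class = "cv_config")
}

.run_fs_method <- function(fs_method, X, y, config, evaluator, seed) {
  switch(fs_method,
         none = {
           subset <- seq_len(ncol(X))
           acc <- evaluator(subset, X, y)
           structure(list(best = list(subset = subset, accuracy = acc,
                                      n_selected = length(subset),
                                      fitness = subset_fitness(acc, length(subset),
                                                               config$fc),
                                      feature_names = colnames(X)),
                          history = NULL, evaluations = 1L, method = "none"),
                     class = "search_result")
         },
         aco = ,
         iaco = {
           cfg <- config$colony
           cfg$iaco <- fs_method == "iaco"
           cfg$seed <- seed
           run_colony(X, y, cfg, config$fc, evaluator)
         },
         ga = {
           cfg <- config$ga
           cfg$seed <- seed
           ga_select(X, y, cfg, config$fc, evaluator)
         },
         pso = {
           cfg <- config$pso
           cfg$seed <- seed
           pso_select(X, y, cfg, config$fc, evaluator)
         },
         stop(sprintf("unknown feature-selection method '%s'", fs_method)))
}

#' Inner-loop model selection
#'
#' Runs the wrapper search once per inner split (training on the remaining
#' `inner_k - 1` folds, scoring candidate subsets on the verification fold),
#' ranks the split winners by their verification fitness (so subset size
#' breaks accuracy ties), and refits the top subset's SVM on all inner data.
#'
#' @param X,y Training portion of one outer cycle.
#' @param fs_method One of `"iaco"`, `"aco"`, `"ga"`, `"pso"`, `"none"`.
#' @param config A [cv_config()].
#' @param seed Seed for the inner fold assignment and searches.
#' @return List with `model` (a [svm_train()] fit on all inner data),
#'   `scaler`, `subset`, `feature_names`, `fitness`, and `inner_results`
#'   (one `search_result` per split).
#' @export
inner_select <- function(X, y, fs_method, config = cv_config(), seed = 1L) {
  y <- factor(y)
  folds <- stratified_folds(y, config$inner_k, seed = seed)
  results <- vector("list", config$inner_k)
  for (s in seq_len(config$inner_k)) {
    val_idx <- folds[[s]]
    train_idx <- setdiff(seq_len(nrow(X)), val_idx)
    evaluator <- make_svm_evaluator(X, y, spec = config$kernel, C = config$C,
                                    train_idx = train_idx, val_idx = val_idx,
                                    positive = config$positive)
    results[[s]] <- .run_fs_method(fs_method, X, y, config, evaluator,
                                   seed = seed + s)
  }
  fits <- vapply(results, function(r) r$best$fitness, numeric(1))
  winner <- results[[which.max(fits)]]
  subset <- winner$best$subset
  scaler <- scale_fit(X)
  model <- svm_train(scale_apply(scaler, X)[, subset, drop = FALSE], y,
                     spec = config$kernel, C = config$C,
                     positive = config$positive)
  list(model = model, scaler = scaler, subset = subset,
       feature_names = colnames(X)[subset],
       fitness = winner$best$fitness, inner_results = results)
}

#' Run the nested cross-validation protocol
#'
#' Outer 6-fold cross-validation around an inner 5-fold cycle: for each
#' outer cycle the feature search and all model fitting see only the
#' training folds (standardization parameters included), and the selected
#' model is evaluated once on the untouched outer test fold. Per-fold
#' accuracy, sensitivity and AUC are reported together with their arithmetic
#' means and the global best fold model (ranked by the accuracy + parsimony
#' fitness of its outer-fold performance).
#'
#' @param features A `coherence_features` object.
#' @param fs_method One of `"iaco"`, `"aco"`, `"ga"`, `"pso"`, `"none"`.
#' @param config A [cv_config()].
#' @return A `cv_report`: `folds` (per-fold subset, metrics, scores),
#'   `aggregate` (mean metrics), `global_best`, `fs_method`, `seed`.
#' @export
run_nested_cv <- function(features, fs_method = "iaco",
                          config = cv_config()) {
  stopifnot(inherits(features, "coherence_features"))
  X <- features$values
  y <- features$labels
  if (nlevels(y) != 2) stop("exactly two classes are required")
  positive <- if (is.null(config$positive)) levels(y)[1] else config$positive
  outer <- stratified_folds(y, config$outer_k, seed = config$seed)
  folds <- vector("list", config$outer_k)
  for (f in seq_len(config$outer_k)) {
    test_idx <- outer[[f]]
    train_idx <- setdiff(seq_len(nrow(X)), test_idx)
    sel <- inner_select(X[train_idx, , drop = FALSE], y[train_idx],
                        fs_method, config,
                        seed = config$seed * 1000L + f)
    .assert_no_leakage(train_idx, test_idx)
    Xte <- scale_apply(sel$scaler, X[test_idx, , drop = FALSE])
    scores <- decision_values(sel$model, Xte[, sel$subset, drop = FALSE])
    met <- classification_metrics(scores, y[test_idx], positive)
    folds[[f]] <- list(fold = f, test_idx = test_idx,
                       subset = sel$subset,
                       feature_names = sel$feature_names,
                       n_selected = length(sel$subset),
                       inner_fitness = sel$fitness,
                       accuracy = met$accuracy,
                       sensitivity = met$sensitivity,
                       auc = met$auc,
                       scores = scores,
                       truth = as.character(y[test_idx]),
                       model = sel$model, scaler = sel$scaler)
  }
  agg <- list(
    accuracy = mean(vapply(folds, `[[`, numeric(1), "accuracy")),
    sensitivity = mean(vapply(folds, `[[`, numeric(1), "sensitivity")),
    auc = mean(vapply(folds, `[[`, numeric(1), "auc")),
    n_selected = mean(vapply(folds, `[[`, numeric(1), "n_selected")))
  outer_fit <- vapply(folds, function(f)
    subset_fitness(f$accuracy, f$n_selected, config$fc), numeric(1))
  structure(list(folds = folds, aggregate = agg,
                 global_best = folds[[which.max(outer_fit)]],
                 global_best_fitness = max(outer_fit),
                 fs_method = fs_method, positive = positive,
                 seed = config$seed),
            class = "cv_report")
}

# outer test rows must never reach feature selection or training
.assert_no_leakage <- function(train_idx, test_idx) {
  if (length(intersect(train_idx, test_idx)) > 0)
    stop("leakage: outer test indices appear in the training cycle")
  invisible(TRUE)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %s: mean accuracy %.3f, sensitivity %.3f, AUC %.3f (%d folds, mean %.1f features)\n",
    x$fs_method, x$aggregate$accuracy, x$aggregate$sensitivity,
    x$aggregate$auc, length(x$folds), x$aggregate$n_selected))
  invisible(x)
}

#' Compare feature-selection methods under nested cross-validation
#'
#' Runs [run_nested_cv()] once per method and assembles the standard
#' comparison table: method, number of features of the global best model,
#' mean sensitivity, mean accuracy (percent), fitness of the global best
#' model, and mean AUC.
#'
#' @param features A `coherence_features` object.
#' @param methods Methods to compare.
#' @param config A [cv_config()].
#' @return A data.frame with one row per method; the full `cv_report`s are
#'   attached as the `"reports"` attribute.
#' @export
compare_methods <- function(features,
                            methods = c("none", "ga", "pso", "aco", "iaco"),
                            config = cv_config()) {
  reports <- lapply(methods, function(m)
    run_nested_cv(features, fs_method = m, config = config))
  names(reports) <- methods
  tab <- data.frame(
    method = methods,
    n_features = vapply(reports, function(r) r$global_best$n_selected,
                        numeric(1)),
    sensitivity = vapply(reports, function(r) r$aggregate$sensitivity,
                         numeric(1)),
    accuracy = vapply(reports, function(r) 100 * r$aggregate$accuracy,
                      numeric(1)),
    fitness = vapply(reports, function(r) r$global_best_fitness, numeric(1)),
    auc = vapply(reports, function(r) r$aggregate$auc, numeric(1)),
    row.names = NULL)
  attr(tab, "reports") <- reports
  tab
}
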