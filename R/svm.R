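#' Kernel specification
#'
#' Supported kernels: linear `x . x'`, polynomial `(x . x' + coef)^degree`,
#' and the radial basis function `exp(-||x - x'||^2 / (2 width^2))`. For the
#' RBF kernel either `width` (the sigma in the denominator) or
#' `gamma = 1 / (2 width^2)` may be given; the default is `gamma = 0.2`.
#'
#' @param kind One of `"rbf"`, `"linear"`, `"polynomial"`.
#' @param width RBF width sigma (`> 0`).
#' @param gamma RBF exponent coefficient (`> 0`); overrides `width`.
#' @param degree,coef Polynomial degree (`>= 1`) and additive constant.
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(kind = c("rbf", "linear", "polynomial"),
                        width = NULL, gamma = NULL, degree = 3, coef = 1) {
  kind <- match.arg(kind)
  if (kind == "rbf") {
    if (is.null(gamma)) gamma <- if (is.null(width)) 0.2 else 1 / (2 * width^2)
    if (gamma <= 0) stop("gamma must be positive")
    width <- sqrt(1 / (2 * gamma))
  }
  if (kind == "polynomial" && degree < 1) stop("degree must be >= 1")
  structure(list(kind = kind, width = width, gamma = gamma,
                 degree = degree, coef = coef),
            class = "kernel_spec")
}

#' Evaluate a kernel
#'
#' `kernel_eval()` computes the kernel value of two feature vectors;
#' `kernel_matrix()` the full cross-kernel matrix of two sample matrices.
#'
#' @param spec A [kernel_spec()].
#' @param p,q Feature vectors of equal length.
#' @return Scalar kernel value.
#' @export
kernel_eval <- function(spec, p, q) {
  if (length(p) != length(q)) stop("feature dimension mismatch")
  kernel_matrix(spec, matrix(p, 1), matrix(q, 1))[1, 1]
}

#' @rdname kernel_eval
#' @param X,Y Numeric matrices (samples x features, equal feature count).
#' @return `kernel_matrix()`: `nrow(X) x nrow(Y)` kernel matrix.
#' @export
kernel_matrix <- function(spec, X, Y = X) {
  stopifnot(inherits(spec, "kernel_spec"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("feature dimension mismatch")
  switch(spec$kind,
         rbf = .cpp_rbf_kernel(X, Y, spec$gamma),
         linear = .cpp_linear_kernel(X, Y),
         polynomial = .cpp_poly_kernel(X, Y, spec$degree, spec$coef))
}

.to_pm1 <- function(y, positive = NULL) {
  if (is.numeric(y) && all(y %in% c(-1, 1)))
    return(list(y = as.numeric(y), levels = NULL, positive = 1))
  y <- factor(y)
  if (nlevels(y) != 2) stop("exactly two classes are required")
  if (is.null(positive)) positive <- levels(y)[1]
  if (!positive %in% levels(y)) stop("positive class not found in labels")
  list(y = ifelse(y == positive, 1, -1), levels = levels(y),
       positive = positive)
}

#' Train a soft-margin SVM
#'
#' Solves the dual problem
#' `max sum(alpha) - 1/2 sum alpha_i alpha_j q_i q_j K(p_i, p_j)` subject to
#' `sum(alpha_i q_i) = 0`, `0 <= alpha_i <= C`, with a maximal-violating-pair
#' SMO solver. The contract is the dual optimum; the model keeps only the
#' support vectors.
#'
#' @param X Training matrix (samples x features).
#' @param y Labels: a two-level factor/character, or numeric in `{-1, +1}`.
#' @param spec A [kernel_spec()].
#' @param C Box penalty (`> 0`), trading margin width against training
#'   errors.
#' @param positive Which factor level maps to `+1` (default: first level).
#' @param tol KKT gap tolerance of the solver.
#' @param max_iter Pair-update budget; non-convergence raises an error that
#'   reports the iteration count.
#' @return A `coh_svm` model: `support_vectors`, `alpha`, `sv_labels`
#'   (+/-1), `bias`, `kernel`, `C`, class-level mapping.
#' @export
svm_train <- function(X, y, spec = kernel_spec(), C = 10, positive = NULL,
                      tol = 1e-5, max_iter = NULL) {
  X <- as.matrix(X)
  lab <- .to_pm1(y, positive)
  if (length(unique(lab$y)) < 2) stop("both classes must be present")
  if (C <= 0) stop("C must be positive")
  n <- nrow(X)
  if (is.null(max_iter)) max_iter <- max(20000L, 300L * n)
  K <- kernel_matrix(spec, X)
  fit <- .cpp_smo(K, lab$y, C, tol, max_iter)
  if (!fit$converged)
    stop(sprintf("SMO did not converge within %d iterations", fit$iterations))
  sv <- which(fit$alpha > 1e-10)
  structure(list(support_vectors = X[sv, , drop = FALSE],
                 alpha = fit$alpha[sv],
                 sv_index = sv,
                 sv_labels = lab$y[sv],
                 bias = fit$bias,
                 kernel = spec, C = C,
                 levels = lab$levels, positive = lab$positive,
                 n_features = ncol(X),
                 iterations = fit$iterations),
            class = "coh_svm")
}

#' @export
print.coh_svm <- function(x, ...) {
  cat(sprintf("<coh_svm> %s kernel, C = %g, %d support vectors\n",
              x$kernel$kind, x$C, length(x$alpha)))
  invisible(x)
}

#' SVM decision values and class predictions
#'
#' `decision_values()` returns `f(p) = sum_i alpha_i q_i K(p_i, p) + b`;
#' `predict()` returns the sign (ties map to the positive class), as the
#' original factor levels when the model was trained on a factor.
#'
#' @param model A [svm_train()] model.
#' @param X Matrix of samples to score (samples x features).
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, X) {
  stopifnot(inherits(model, "coh_svm"))
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop("feature dimension differs from training")
  K <- kernel_matrix(model$kernel, X, model$support_vectors)
  drop(K %*% (model$alpha * model$sv_labels)) + model$bias
}

#' @rdname decision_values
#' @param object A `coh_svm` model.
#' @param newdata Matrix of samples to classify.
#' @param ... Unused.
#' @export
predict.coh_svm <- function(object, newdata, ...) {
  f <- decision_values(object, newdata)
  pm <- ifelse(f >= 0, 1, -1)
  if (is.null(object$levels)) return(pm)
  neg <- setdiff(object$levels, object$positive)
  factor(ifelse(pm > 0, object$positive, neg), levels = object$levels)
}

#' Standardization helper
#'
#' Column means/SDs learned on training data, applied to any matrix.
#' Constant columns get unit scale.
#'
#' @param X Training matrix.
#' @return A `coh_scaler`; apply with [scale_apply()].
#' @export
scale_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv < 1e-12] <- 1
  structure(list(center = mu, scale = sdv), class = "coh_scaler")
}

#' @rdname scale_fit
#' @param scaler A `coh_scaler` from [scale_fit()].
#' @param X Matrix to standardize.
#' @export
scale_apply <- function(scaler, X) {
  sweep(sweep(as.matrix(X), 2, scaler$center), 2, scaler$scale, "/")
}

#' Build an SVM wrapper evaluator
#'
#' Returns the accuracy oracle used by the wrapper searches: a function
#' `(subset, X, y) -> accuracy` that standardizes on a fixed internal
#' training split, trains an SVM on the subset columns, and scores the
#' held-out validation part. The split is stratified and frozen when the
#' evaluator is created, so every candidate subset is judged on the same
#' partition.
#'
#' When explicit `train_idx`/`val_idx` are supplied (as the nested
#' cross-validation does), those rows define the split instead.
#'
#' @param X Feature matrix the evaluator will be used with.
#' @param y Two-level labels.
#' @param spec A [kernel_spec()] (RBF evaluators use a fast combined
#'   train-and-score path).
#' @param C Box penalty.
#' @param val_fraction Held-out fraction for the internal split.
#' @param train_idx,val_idx Optional explicit row indices.
#' @param seed Seed for the internal split.
#' @param positive Positive class (first level by default).
#' @return `function(subset, X, y)` returning validation accuracy.
#' @export
make_svm_evaluator <- function(X, y, spec = kernel_spec(), C = 10,
                               val_fraction = 0.2,
                               train_idx = NULL, val_idx = NULL,
                               seed = 1L, positive = NULL) {
  lab <- .to_pm1(y, positive)
  if (is.null(train_idx) || is.null(val_idx)) {
    folds <- stratified_folds(factor(lab$y), k = max(2L, round(1 / val_fraction)),
                              seed = seed)
    val_idx <- folds[[1]]
    train_idx <- setdiff(seq_len(nrow(X)), val_idx)
  }
  scaler <- scale_fit(X[train_idx, , drop = FALSE])
  Xs <- scale_apply(scaler, X)
  Xtr <- Xs[train_idx, , drop = FALSE]
  Xval <- Xs[val_idx, , drop = FALSE]
  ytr <- lab$y[train_idx]
  yval <- lab$y[val_idx]
  if (length(unique(ytr)) < 2 || length(unique(yval)) < 2)
    stop("degenerate split: a fold contains a single class")
  force(spec); force(C)
  function(subset, ...) {
    if (length(subset) < 1) stop("empty feature subset")
    a <- Xtr[, subset, drop = FALSE]
    b <- Xval[, subset, drop = FALSE]
    if (spec$kind == "rbf")
      return(.cpp_rbf_holdout_accuracy(a, ytr, b, yval, spec$gamma, C,
                                       1e-5, 20000L))
    model <- svm_train(a, ytr, spec, C)
    mean(ifelse(decision_values(model, b) >= 0, 1, -1) == yval)
  }
}
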