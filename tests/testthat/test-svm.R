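dual_objective <- function(alpha, y, K) {
  sum(alpha) - 0.5 * drop(t(alpha * y) %*% K %*% (alpha * y))
}

test_that("kernel evaluations match their closed forms", {
  rbf <- kernel_spec("rbf", width = 1)
  p <- c(0.3, -1.2, 2)
  expect_equal(kernel_eval(rbf, p, p), 1.0)
  expect_equal(kernel_eval(rbf, c(0, 0), c(sqrt(2), 0)), exp(-1))
  lin <- kernel_spec("linear")
  expect_equal(kernel_eval(lin, c(1, 0), c(0, 1)), 0)
  poly <- kernel_spec("polynomial", degree = 2, coef = 1)
  expect_equal(kernel_eval(poly, c(1, 1), c(2, 0)), (2 + 1)^2)
  expect_error(kernel_eval(rbf, c(1, 2), c(1, 2, 3)), "dimension")
  # default follows gamma = 0.2
  expect_equal(kernel_spec("rbf")$gamma, 0.2)
})

test_that("kernel matrices are symmetric positive semidefinite", {
  set.seed(31)
  X <- matrix(rnorm(15 * 4), 15, 4)
  for (spec in list(kernel_spec("rbf", gamma = 0.7), kernel_spec("linear"),
                    kernel_spec("polynomial", degree = 3))) {
    K <- kernel_matrix(spec, X)
    expect_equal(K, t(K), tolerance = 1e-10)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("the two-point problem has the analytic max-margin solution", {
  m <- svm_train(matrix(c(-1, 1), 2, 1), c(-1, 1), kernel_spec("linear"),
                 C = 100)
  expect_equal(m$alpha, c(0.5, 0.5), tolerance = 1e-3)
  expect_equal(m$bias, 0, tolerance = 1e-3)
  expect_equal(decision_values(m, matrix(0)), 0, tolerance = 1e-3)
  expect_equal(decision_values(m, matrix(c(-2, 2), 2, 1)), c(-2, 2),
               tolerance = 1e-3)
})

test_that("separable data is fit without training errors", {
  set.seed(32)
  X <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
  y <- rep(c(-1, 1), each = 20)
  m <- svm_train(X, y, kernel_spec("linear"), C = 100)
  expect_equal(unname(predict(m, X)), y)
})

test_that("the solver lands on the dual optimum", {
  set.seed(33)
  for (rep in 1:3) {
    n <- 16
    X <- matrix(rnorm(n * 3), n, 3)
    y <- rep(c(-1, 1), each = n / 2)
    C <- 10
    spec <- kernel_spec("rbf", gamma = 0.5)
    K <- kernel_matrix(spec, X)
    m <- svm_train(X, y, spec, C, tol = 1e-7)
    alpha <- numeric(n)
    alpha[m$sv_index] <- m$alpha
    expect_lt(abs(sum(alpha * y)), 1e-6)
    expect_true(all(alpha >= -1e-9 & alpha <= C + 1e-9))
    obj <- dual_objective(alpha, y, K)
    # no random feasible point may beat the solver
    for (i in 1:100) {
      a <- runif(n, 0, C)
      sp <- sum(a[y == 1]); sn <- sum(a[y == -1])
      if (sp > sn) a[y == 1] <- a[y == 1] * sn / sp
      else a[y == -1] <- a[y == -1] * sp / sn
      expect_lte(dual_objective(a, y, K), obj + 1e-6)
    }
    # free support vectors sit on the margin
    free <- which(alpha > 1e-6 & alpha < C - 1e-6)
    if (length(free))
      expect_lt(max(abs(abs(decision_values(m, X[free, , drop = FALSE])) - 1)),
                1e-3)
  }
})

test_that("decision values agree with an independent solver", {
  library(e1071)
  set.seed(34)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- factor(rep(c("a", "b"), 30))
  mc <- svm_train(X, y, kernel_spec("rbf", gamma = 0.2), C = 10, tol = 1e-7)
  me <- e1071::svm(X, y, scale = FALSE, kernel = "radial", gamma = 0.2,
                   cost = 10, tolerance = 1e-7)
  fe <- drop(attr(predict(me, X, decision.values = TRUE), "decision.values"))
  fc <- decision_values(mc, X)
  # e1071 signs its decision values by its own level ordering
  if (cor(fc, fe) < 0) fe <- -fe
  expect_lt(max(abs(fc - fe)), 1e-4)
})

test_that("predictions respect symmetry and consistent permutation", {
  set.seed(35)
  X <- matrix(rnorm(40 * 4), 40, 4)
  y <- rep(c(-1, 1), 20)
  spec <- kernel_spec("rbf", gamma = 0.3)
  m1 <- svm_train(X, y, spec, C = 5)
  # mirrored inputs with flipped labels mirror the decision values
  m2 <- svm_train(-X, -y, spec, C = 5)
  expect_equal(decision_values(m2, -X), -decision_values(m1, X),
               tolerance = 1e-4)
  # permuting feature order consistently changes nothing
  perm <- sample(4)
  m3 <- svm_train(X[, perm], y, spec, C = 5)
  expect_equal(decision_values(m3, X[, perm]), decision_values(m1, X),
               tolerance = 1e-4)
})

test_that("factor labels map through the positive class", {
  set.seed(36)
  X <- rbind(matrix(rnorm(20, -2), 10, 2), matrix(rnorm(20, 2), 10, 2))
  y <- factor(rep(c("BD", "MDD"), each = 10))
  m <- svm_train(X, y, kernel_spec("linear"), C = 10)
  expect_identical(m$positive, "BD")
  p <- predict(m, X)
  expect_s3_class(p, "factor")
  expect_identical(as.character(p), as.character(y))
  expect_error(svm_train(X, factor(rep("BD", 20)), kernel_spec("linear")),
               "two classes")
})

test_that("non-convergence is reported with the iteration count", {
  set.seed(37)
  X <- matrix(rnorm(30 * 2), 30, 2)
  y <- rep(c(-1, 1), 15)
  expect_error(svm_train(X, y, kernel_spec("rbf"), C = 10, max_iter = 2),
               "converge")
})
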