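toy_gram <- function(X, ids = NULL) {
  new_gram <- pbdtss:::new_kernel_gram
  new_gram(tcrossprod(X), ids %||% as.character(seq_len(nrow(X))),
           list(kind = "linear", normalize = FALSE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the symmetric two-point problem puts the boundary at zero", {
  X <- matrix(c(-1, 1), 2, 1)
  m <- svm_train(toy_gram(X), c(-1, 1), C = 100)
  expect_equal(length(m$support_indices), 2)
  expect_equal(m$bias, 0, tolerance = 1e-6)
  sc <- svm_score(m, tcrossprod(X, matrix(c(-1, 0, 1), 3, 1)))
  expect_equal(sign(sc[c(1, 3)]), c(-1, 1))
  expect_equal(sc[2], m$bias, tolerance = 1e-9)
})

test_that("dual solution is feasible and matches the interior-point QP reference", {
  set.seed(31)
  for (rep in 1:4) {
    n <- 8
    X <- rbind(matrix(rnorm(n / 2 * 2, mean = 1.5), ncol = 2),
               matrix(rnorm(n / 2 * 2, mean = -1.5), ncol = 2))
    y <- c(rep(1, n / 2), rep(-1, n / 2))
    K <- tcrossprod(X)
    C <- sample(c(0.5, 1, 10), 1)
    m <- svm_train(toy_gram(X), y, C = C)
    # box and equality constraints of the dual
    expect_true(all(m$alphas >= -1e-8 & m$alphas <= C + 1e-8))
    expect_lt(abs(sum(m$alphas * y)), 1e-6 * C * n)
    # objective agrees with an independent generic QP solution
    oracle <- qp_svm_oracle(K, y, C)
    obj <- svm_dual_objective(m, K)
    expect_equal(obj, oracle$objective, tolerance = 1e-4)
    # decision values agree where the oracle's alphas are interior
    b_or <- {
      marg <- which(oracle$alpha > 1e-4 * C & oracle$alpha < C * (1 - 1e-4))
      mean(y[marg] - drop(K[marg, , drop = FALSE] %*% (oracle$alpha * y)))
    }
    sc <- svm_score(m, K)
    sc_or <- drop(K %*% (oracle$alpha * y)) + b_or
    expect_equal(sc, sc_or, tolerance = 1e-3)
  }
})

test_that("margin support vectors score near their labels on separable data", {
  set.seed(32)
  X <- rbind(matrix(rnorm(10, mean = 3), 5, 2), matrix(rnorm(10, mean = -3), 5, 2))
  y <- c(rep(1, 5), rep(-1, 5))
  m <- svm_train(toy_gram(X), y, C = 1000)
  sc <- svm_score(m, tcrossprod(X))
  expect_true(all(sign(sc) == y))  # zero training error, separable + large C
  marg <- which(m$alphas > 1e-6 & m$alphas < 1000 * (1 - 1e-6))
  expect_equal(sc[marg], y[marg], tolerance = 1e-3)
})

test_that("duplicating a training instance leaves the decision function unchanged", {
  set.seed(33)
  X <- rbind(matrix(rnorm(12, 1.2), 6, 2), matrix(rnorm(12, -1.2), 6, 2))
  y <- rep(c(1, -1), each = 6)
  m1 <- svm_train(toy_gram(X), y, C = 1)
  X2 <- rbind(X, X[1, ]); y2 <- c(y, y[1])
  m2 <- svm_train(toy_gram(X2), y2, C = 1)
  Q <- matrix(rnorm(10), 5, 2)
  expect_equal(svm_score(m1, tcrossprod(X, Q)),
               svm_score(m2, tcrossprod(X2, Q)), tolerance = 1e-3)
})

test_that("training validates its inputs", {
  X <- matrix(rnorm(8), 4, 2)
  expect_error(svm_train(toy_gram(X), c(1, 1, 1, 1), C = 1), "both classes")
  expect_error(svm_train(toy_gram(X), c(1, -1, 1, -1), C = -2), "positive")
  expect_error(svm_train(toy_gram(X), c(1, -1), C = 1), "one label per")
  g <- toy_gram(X)
  g$values[1, 2] <- g$values[1, 2] + 1
  expect_error(svm_train(g, c(1, -1, 1, -1), C = 1), "symmetric")
})

test_that("JSON serialization round-trips scores", {
  set.seed(34)
  X <- rbind(matrix(rnorm(12, 1), 6, 2), matrix(rnorm(12, -1), 6, 2))
  y <- rep(c(1, -1), each = 6)
  m <- svm_train(toy_gram(X), y, C = 2)
  path <- tempfile(fileext = ".json")
  write_svm(m, path)
  m2 <- read_svm(path)
  Q <- matrix(rnorm(10), 5, 2)
  expect_equal(svm_score(m2, tcrossprod(X, Q)),
               svm_score(m, tcrossprod(X, Q)), tolerance = 1e-12)
  expect_identical(m2$support_indices, m$support_indices)
  unlink(path)
})

test_that("retraining on identical inputs is deterministic", {
  set.seed(35)
  X <- rbind(matrix(rnorm(20, 1), 10, 2), matrix(rnorm(20, -1), 10, 2))
  y <- rep(c(1, -1), each = 10)
  m1 <- svm_train(toy_gram(X), y, C = 5)
  m2 <- svm_train(toy_gram(X), y, C = 5)
  expect_identical(m1$alphas, m2$alphas)
  expect_identical(m1$bias, m2$bias)
})
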