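# Soft-margin SVM on precomputed kernel matrices.
#
# The dual problem
#   max_alpha sum_i alpha_i - 1/2 sum_ij alpha_i alpha_j y_i y_j K_ij
#   s.t. 0 <= alpha_i <= C,  sum_i alpha_i y_i = 0
# is solved by sequential minimal optimization (kernlab's C-svc on a
# precomputed kernel matrix). The model keeps the dual coefficients, bias,
# and support-vector indices, so scoring needs only the kernel values
# between support vectors and queries.

#' Train a soft-margin SVM on a precomputed kernel Gram
#'
#' @param gram A symmetric `kernel_gram` over the training instances.
#' @param labels Labels in \{-1, +1\} (numeric, or a factor with those
#'   levels), one per instance, both classes present.
#' @param C Regularization parameter (> 0).
#' @param tol Solver stopping tolerance on KKT violation.
#' @param repair_psd Clip tiny negative eigen-components (possible after
#'   hybrid averaging round-off) before solving.
#' @return An object of class `trained_svm` with fields `alphas` (unsigned
#'   dual coefficients, full length), `coef` (signed `alpha_i y_i`),
#'   `bias`, `support_indices`, `C`, `kernel_config`, `train_ids`.
#' @export
svm_train <- function(gram, labels, C = 1, tol = 1e-6, repair_psd = FALSE) {
  stopifnot(inherits(gram, "kernel_gram"))
  K <- gram$values
  if (nrow(K) != ncol(K) || max(abs(K - t(K))) > 1e-8) {
    stop("training Gram must be symmetric")
  }
  y <- .check_labels(labels, nrow(K))
  if (length(unique(y)) < 2) stop("both classes must be present in the training set")
  if (C <= 0) stop("C must be positive")
  if (repair_psd) {
    e <- eigen(K, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values))) {
      ev <- pmax(e$values, 0)
      K <- e$vectors %*% (ev * t(e$vectors))
      K <- (K + t(K)) / 2
      message("repaired non-PSD Gram by clipping negative eigenvalues")
    }
  }
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K),
                       factor(y, levels = c(-1, 1)),
                       type = "C-svc", C = C, tol = tol)
  sv <- kernlab::SVindex(fit)
  coef_sv <- kernlab::coef(fit)[[1]]
  bias <- -kernlab::b(fit)
  scores <- drop(K[, sv, drop = FALSE] %*% coef_sv) + bias
  if (sum(scores * y) < 0) {       # defensive: fix the class orientation
    coef_sv <- -coef_sv
    bias <- -bias
  }
  alphas <- numeric(length(y))
  alphas[sv] <- abs(coef_sv)
  coefs <- numeric(length(y))
  coefs[sv] <- coef_sv
  ids <- if (is.list(gram$instance_ids)) gram$instance_ids$rows else gram$instance_ids
  structure(list(alphas = alphas, coef = coefs, bias = bias,
                 support_indices = sv, labels = y, C = C,
                 kernel_config = gram$config, train_ids = ids),
            class = "trained_svm")
}

.check_labels <- function(labels, n) {
  y <- if (is.factor(labels)) as.numeric(as.character(labels)) else as.numeric(labels)
  if (length(y) != n) stop("one label per training instance required")
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1")
  y
}

#' Decision scores for query instances
#'
#' `f(x) = sum_{j in SV} alpha_j y_j k(x_j, x) + b`. The raw score is the
#' ROC threshold variable; its sign is the predicted class.
#'
#' @param model A [svm_train()] result.
#' @param gram_cross Kernel values between training and query instances:
#'   an `n_train x n_query` matrix (or a rectangular `kernel_gram` whose
#'   rows follow `model$train_ids`).
#' @return Numeric scores, one per query.
#' @export
svm_score <- function(model, gram_cross) {
  stopifnot(inherits(model, "trained_svm"))
  if (inherits(gram_cross, "kernel_gram")) {
    ids <- gram_cross$instance_ids
    if (is.list(ids) && !identical(ids$rows, model$train_ids)) {
      stop("rows of the cross Gram are not aligned with the model's training instances")
    }
    gram_cross <- gram_cross$values
  }
  gram_cross <- as.matrix(gram_cross)
  if (nrow(gram_cross) != length(model$alphas)) {
    stop("cross Gram must have one row per training instance")
  }
  sv <- model$support_indices
  drop(crossprod(gram_cross[sv, , drop = FALSE], model$coef[sv])) + model$bias
}

#' Dual objective value of a trained model
#'
#' `sum_i alpha_i - 1/2 sum_ij alpha_i alpha_j y_i y_j K_ij`, useful for
#' comparing against an independent quadratic-programming solution.
#'
#' @param model A `trained_svm`.
#' @param gram The training `kernel_gram` (or matrix).
#' @export
svm_dual_objective <- function(model, gram) {
  K <- if (inherits(gram, "kernel_gram")) gram$values else as.matrix(gram)
  a <- model$alphas
  u <- model$coef   # alpha_i y_i
  sum(a) - 0.5 * drop(t(u) %*% K %*% u)
}

#' @export
print.trained_svm <- function(x, ...) {
  cat(sprintf("SVM (%s kernel): %d training instances, %d support vectors, C = %g, b = %.4f\n",
              x$kernel_config$kind %||% "?", length(x$alphas),
              length(x$support_indices), x$C, x$bias))
  invisible(x)
}

#' Serialize / restore a trained SVM
#'
#' JSON round trip preserving dual coefficients, bias, support indices,
#' labels, and the kernel configuration; restored models reproduce scores
#' exactly at double precision.
#'
#' @param model A `trained_svm`.
#' @param path File path.
#' @export
write_svm <- function(model, path) {
  stopifnot(inherits(model, "trained_svm"))
  obj <- unclass(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_svm
#' @export
read_svm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$kernel_config <- as.list(obj$kernel_config)
  structure(obj, class = "trained_svm")
}
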