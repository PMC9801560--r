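# Kernels over sequence windows and probability profiles.

# k-mer weights beta_k = 2 (d - k + 1) / (d (d + 1)); sum to 1 for every d.
.wd_beta <- function(d) 2 * (d - seq_len(d) + 1) / (d * (d + 1))

# run-length weight table: w_d(r) = sum_{k <= min(r, d)} beta_k (r - k + 1)
.wd_runweights <- function(L, d_values) {
  vapply(d_values, function(d) {
    beta <- .wd_beta(d)
    vapply(seq_len(L), function(r) {
      k <- seq_len(min(r, d))
      sum(beta[k] * (r - k + 1))
    }, numeric(1))
  }, numeric(L))
}

.encode_seqs <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("all sequences must have equal length")
  m <- matrix(match(unlist(strsplit(seqs, "")), c("A", "C", "G", "T")),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  if (anyNA(m)) stop("sequences contain characters outside ACGT")
  storage.mode(m) <- "integer"
  m
}

#' Weighted degree (WD) string kernel
#'
#' Position-anchored similarity between two equal-length sequences:
#' a weighted sum over all k-mer orders `k = 1..d` of the number of
#' positions at which both sequences carry the same k-mer, with weights
#' `beta_k = 2 (d - k + 1) / (d (d + 1))`. The self-similarity has the
#' closed form `sum_k beta_k (L - k + 1)`, identical for every sequence of
#' length `L`.
#'
#' @param s1,s2 Equal-length ACGT strings.
#' @param d Maximum k-mer order (`1 <= d <= L`).
#' @return Similarity value.
#' @examples
#' wd_kernel("ACGT", "ACTT", d = 1)  # 3 matching positions
#' @export
wd_kernel <- function(s1, s2, d) {
  X <- .encode_seqs(c(s1, s2))
  L <- ncol(X)
  if (d < 1 || d > L) stop("order d must be in 1..L")
  wd_gram_cpp(X[1, , drop = FALSE], X[2, , drop = FALSE],
              .wd_runweights(L, d), FALSE)[[1]][1, 1]
}

#' WD kernel with shifts (WDS)
#'
#' Relaxes the positional rigidity of the WD kernel: k-mers in one sequence
#' may match k-mers of the other shifted by up to `shift_max` positions,
#' with shift weight `1/(2(s+1))` and optional per-position weights
#' `gamma_l`. With `shift_max = 0` and unit position weights it reduces
#' exactly to [wd_kernel()].
#'
#' @inheritParams wd_kernel
#' @param shift_max Maximum shift (>= 0), applied uniformly at every
#'   position.
#' @param position_weights Optional numeric vector `gamma_l` of length `L`
#'   (default all 1).
#' @return Similarity value.
#' @export
wds_kernel <- function(s1, s2, d, shift_max = 0, position_weights = NULL) {
  X <- .encode_seqs(c(s1, s2))
  L <- ncol(X)
  if (d < 1 || d > L) stop("order d must be in 1..L")
  if (shift_max < 0) stop("shift_max must be >= 0")
  if (is.null(position_weights)) position_weights <- rep(1, L)
  stopifnot(length(position_weights) == L)
  beta <- .wd_beta(d)
  x1 <- X[1, ]; x2 <- X[2, ]
  total <- 0
  for (k in seq_len(d)) {
    np <- L - k + 1
    # integer codes of the k-mers of each sequence at every start
    c1 <- x1[seq_len(np)]; c2 <- x2[seq_len(np)]
    if (k > 1) {
      for (off in 1:(k - 1)) {
        c1 <- c1 * 4L + x1[seq_len(np) + off]
        c2 <- c2 * 4L + x2[seq_len(np) + off]
      }
    }
    for (l in seq_len(np)) {
      for (s in 0:min(shift_max, L - l)) {
        if (l + s > np) next
        total <- total + beta[k] * position_weights[l] / (2 * (s + 1)) *
          ((c1[l + s] == c2[l]) + (c1[l] == c2[l + s]))
      }
    }
  }
  total
}

#' Gaussian (RBF) kernel
#'
#' `k(x1, x2) = exp(-gamma ||x1 - x2||^2)`; equals 1 iff `x1 == x2`.
#'
#' @param x1,x2 Numeric vectors of equal length.
#' @param gamma Positive width parameter (inverse squared feature units).
#' @export
rbf_kernel <- function(x1, x2, gamma) {
  if (length(x1) != length(x2)) stop("feature vectors have different dimensions")
  if (gamma <= 0) stop("gamma must be positive")
  exp(-gamma * sum((x1 - x2)^2))
}

new_kernel_gram <- function(values, ids, config) {
  dimnames(values) <- NULL
  structure(list(values = values, instance_ids = ids, config = config),
            class = "kernel_gram")
}

#' @export
print.kernel_gram <- function(x, ...) {
  cat(sprintf("kernel Gram: %s, %d x %d%s\n", x$config$kind,
              nrow(x$values), ncol(x$values),
              if (isTRUE(x$config$normalize)) ", unit diagonal" else ""))
  invisible(x)
}

#' WD-kernel Gram matrix over sets of sequences
#'
#' Computes the weighted degree kernel between all pairs of `x` (or between
#' `x` and `y` for a rectangular train/query matrix), for one or several
#' orders `d` in a single pass. Because the WD self-similarity depends only
#' on the common length `L`, unit-diagonal normalization amounts to
#' dividing by `sum_k beta_k (L - k + 1)`.
#'
#' @param x,y Character vectors of equal-length ACGT sequences (`y = NULL`
#'   for the symmetric Gram over `x`).
#' @param d Integer vector of k-mer orders.
#' @param ids,ids_y Instance identifiers (default names or indices).
#' @param normalize Normalize to unit diagonal.
#' @return A `kernel_gram` if `d` is scalar, otherwise a named list of
#'   `kernel_gram` objects (one per order).
#' @export
wd_gram <- function(x, y = NULL, d = 12, ids = NULL, ids_y = NULL,
                    normalize = TRUE) {
  X <- .encode_seqs(x)
  L <- ncol(X)
  if (any(d < 1 | d > L)) stop("order d must be in 1..L")
  sym <- is.null(y)
  Y <- if (sym) X else .encode_seqs(y)
  ids <- ids %||% names(x) %||% as.character(seq_along(x))
  ids_y <- if (sym) ids else ids_y %||% names(y) %||% as.character(seq_along(y))
  wt <- .wd_runweights(L, d)
  Ks <- wd_gram_cpp(X, Y, wt, sym)
  selfsim <- vapply(d, function(dd) {
    k <- seq_len(dd)
    sum(.wd_beta(dd) * (L - k + 1))
  }, numeric(1))
  out <- lapply(seq_along(d), function(t) {
    V <- Ks[[t]]
    if (normalize) V <- V / selfsim[t]
    rownames(V) <- ids
    new_kernel_gram(V, if (sym) ids else list(rows = ids, cols = ids_y),
                    list(kind = "WD", d = d[t], normalize = normalize))
  })
  names(out) <- as.character(d)
  if (length(d) == 1L) out[[1]] else out
}

#' RBF Gram matrix over probability-profile feature vectors
#'
#' @param x,y Numeric feature matrices (rows = instances); `y = NULL` for
#'   the symmetric Gram.
#' @param gamma RBF width; default `1 / (p * mean feature variance)` with
#'   `p` the feature dimension, computed from `x`.
#' @param ids,ids_y Instance identifiers.
#' @return A `kernel_gram` (RBF Grams have unit diagonal by construction).
#' @export
rbf_gram <- function(x, y = NULL, gamma = NULL, ids = NULL, ids_y = NULL) {
  x <- as.matrix(x)
  sym <- is.null(y)
  y <- if (sym) x else as.matrix(y)
  if (ncol(x) != ncol(y)) stop("feature dimensions differ")
  if (is.null(gamma)) gamma <- rbf_gamma_heuristic(x)
  if (gamma <= 0) stop("gamma must be positive")
  sq <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  sq[sq < 0] <- 0
  V <- exp(-gamma * sq)
  ids <- ids %||% rownames(x) %||% as.character(seq_len(nrow(x)))
  ids_y <- if (sym) ids else ids_y %||% rownames(y) %||% as.character(seq_len(nrow(y)))
  new_kernel_gram(V, if (sym) ids else list(rows = ids, cols = ids_y),
                  list(kind = "RBF", gamma = gamma, normalize = TRUE))
}

#' Default RBF width for profile features
#'
#' `gamma = 1 / (p * mean pooled feature variance)`, a median-heuristic
#' style default that adapts the kernel width to the scale of the opening
#' probabilities (which vary strongly with temperature).
#'
#' @param x Feature matrix (rows = instances).
#' @export
rbf_gamma_heuristic <- function(x) {
  x <- as.matrix(x)
  v <- mean(apply(x, 2, stats::var))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(x) * v)
}

#' Unit-diagonal normalization of a Gram matrix
#'
#' `k~(x, y) = k(x, y) / sqrt(k(x, x) k(y, y))`; idempotent and bounded in
#' `[-1, 1]` for PSD kernels.
#'
#' @param gram A symmetric `kernel_gram`.
#' @export
normalize_gram <- function(gram) {
  stopifnot(inherits(gram, "kernel_gram"))
  if (isTRUE(gram$config$normalize)) return(gram)
  dg <- sqrt(diag(gram$values))
  V <- gram$values / outer(dg, dg)
  cfg <- gram$config; cfg$normalize <- TRUE
  new_kernel_gram(V, gram$instance_ids, cfg)
}

#' Hybrid (multiple-kernel) combination of two Gram matrices
#'
#' Elementwise weighted sum of a sequence-kernel Gram and a profile-kernel
#' Gram over the same instances, the fixed-weight special case of multiple
#' kernel learning. Both components are brought to unit diagonal first so
#' that a count-valued string kernel cannot swamp a bounded RBF kernel;
#' the default is the equal-weight average.
#'
#' @param seq_gram,prof_gram `kernel_gram` objects with identical instance
#'   ordering.
#' @param weights Two nonnegative weights summing to 1.
#' @return A `kernel_gram` of kind `"hybrid"`.
#' @export
hybrid_gram <- function(seq_gram, prof_gram, weights = c(0.5, 0.5)) {
  stopifnot(inherits(seq_gram, "kernel_gram"), inherits(prof_gram, "kernel_gram"))
  if (length(weights) != 2 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be two nonnegative values summing to 1")
  }
  if (!identical(seq_gram$instance_ids, prof_gram$instance_ids)) {
    stop("instance orderings of the two Gram matrices do not match")
  }
  g1 <- if (is.list(seq_gram$instance_ids)) seq_gram else normalize_gram(seq_gram)
  g2 <- if (is.list(prof_gram$instance_ids)) prof_gram else normalize_gram(prof_gram)
  V <- weights[1] * g1$values + weights[2] * g2$values
  new_kernel_gram(V, seq_gram$instance_ids,
                  list(kind = "hybrid", weights = weights,
                       components = list(g1$config, g2$config),
                       normalize = TRUE))
}

#' Export / import a symmetric Gram matrix as tab-separated text
#'
#' The matrix is written with an instance-id header row and id-labelled
#' rows; the kernel configuration is serialized alongside as JSON in a
#' `#config:` comment line, so a round trip restores both values and
#' provenance.
#'
#' @param gram A symmetric `kernel_gram`.
#' @param path Output path.
#' @export
write_gram <- function(gram, path) {
  stopifnot(inherits(gram, "kernel_gram"), !is.list(gram$instance_ids))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#config: ",
                    jsonlite::toJSON(gram$config, auto_unbox = TRUE, digits = NA)),
             con)
  tab <- as.data.frame(gram$values)
  names(tab) <- gram$instance_ids
  utils::write.table(cbind(id = gram$instance_ids, tab), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gram
#' @export
read_gram <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#config: ")) stop("missing #config header line")
  config <- jsonlite::fromJSON(sub("^#config: ", "", first), simplifyVector = TRUE)
  tab <- utils::read.delim(path, skip = 1, check.names = FALSE)
  ids <- as.character(tab$id)
  V <- as.matrix(tab[, -1, drop = FALSE])
  new_kernel_gram(unname(V), ids, as.list(config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
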