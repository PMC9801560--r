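# Independent oracles used across the suite. All deliberately brute-force:
# dense N-dimensional quadrature for the chain statistics, exhaustive
# enumeration for string kernels, an interior-point QP for the SVM dual,
# and pairwise counting for auROC.

random_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")

# Dense quadrature over the full N-dimensional grid: returns per-config
# Boltzmann weights (including quadrature weights) and the open indicator
# matrix, so any event probability can be read off by masking.
brute_chain <- function(sequence, temperature, grid, params) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  N <- length(bases)
  beta <- 1 / (params$kB * temperature)
  pair <- ifelse(bases %in% c("A", "T"), "AT", "GC")
  y <- grid$nodes
  w <- grid$weights
  M <- length(y)
  site <- lapply(seq_len(N), function(i) {
    w * exp(-beta * onsite_potential(y, pair[i], params))
  })
  idx <- as.matrix(expand.grid(rep(list(seq_len(M)), N)))
  wt <- rep(1, nrow(idx))
  for (i in seq_len(N)) wt <- wt * site[[i]][idx[, i]]
  for (i in 2:N) {
    Wm <- exp(-beta * outer(y, y, function(a, b) {
      stacking_potential(a, b, paste0(bases[i - 1], bases[i]), params)
    }))
    wt <- wt * Wm[cbind(idx[, i], idx[, i - 1])]
  }
  list(wt = wt, open = matrix(grid$open[idx], nrow(idx), N), N = N)
}

# partition value of an event (logical vector over configurations)
brute_Z <- function(bc, event = TRUE) sum(bc$wt[event & rep(TRUE, length(bc$wt))])

brute_mu <- function(bc) rowSums(bc$open) < bc$N   # not all open

# exact-size-m bubble centred at k (virtual closed flanks beyond the ends)
brute_bubble_event <- function(bc, k, m) {
  if (m %% 2 == 0) { lo <- k - m / 2 + 1; hi <- k + m / 2 }
  else { lo <- k - (m - 1) / 2; hi <- k + (m - 1) / 2 }
  if (lo < 1 || hi > bc$N) return(rep(FALSE, length(bc$wt)))
  ev <- rep(TRUE, length(bc$wt))
  for (j in lo:hi) ev <- ev & bc$open[, j]
  if (lo - 1 >= 1) ev <- ev & !bc$open[, lo - 1]
  if (hi + 1 <= bc$N) ev <- ev & !bc$open[, hi + 1]
  ev
}

# k inside an all-open window of length m
brute_part_event <- function(bc, k, m) {
  ev <- rep(FALSE, length(bc$wt))
  for (a in max(1, k - m + 1):min(k, bc$N - m + 1)) {
    g <- rep(TRUE, length(bc$wt))
    for (j in a:(a + m - 1)) g <- g & bc$open[, j]
    ev <- ev | g
  }
  ev
}

# exhaustive WD kernel: enumerate every (k, l) and compare k-mers
wd_naive <- function(s1, s2, d) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  L <- length(a)
  beta <- 2 * (d - seq_len(d) + 1) / (d * (d + 1))
  tot <- 0
  for (k in seq_len(d)) {
    for (l in seq_len(L - k + 1)) {
      u1 <- paste(a[l:(l + k - 1)], collapse = "")
      u2 <- paste(b[l:(l + k - 1)], collapse = "")
      tot <- tot + beta[k] * (u1 == u2)
    }
  }
  tot
}

# exhaustive WDS kernel
wds_naive <- function(s1, s2, d, shift_max) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  L <- length(a)
  beta <- 2 * (d - seq_len(d) + 1) / (d * (d + 1))
  kmer <- function(x, l, k) {
    if (l < 1 || l + k - 1 > L) return(NA_character_)
    paste(x[l:(l + k - 1)], collapse = "")
  }
  tot <- 0
  for (k in seq_len(d)) {
    for (l in seq_len(L - k + 1)) {
      for (s in 0:shift_max) {
        if (s + l > L) next
        u1s <- kmer(a, l + s, k); u2 <- kmer(b, l, k)
        u1 <- kmer(a, l, k); u2s <- kmer(b, l + s, k)
        m1 <- !is.na(u1s) && u1s == u2
        m2 <- !is.na(u2s) && u1 == u2s
        tot <- tot + beta[k] * (m1 + m2) / (2 * (s + 1))
      }
    }
  }
  tot
}

# generic-QP reference for the SVM dual: kernlab's interior-point solver
# (independent of the SMO path used by svm_train)
qp_svm_oracle <- function(K, y, C) {
  n <- length(y)
  H <- (y %*% t(y)) * K
  sol <- kernlab::ipop(c = rep(-1, n), H = H,
                       A = matrix(y, 1, n), b = 0, r = 0,
                       l = rep(0, n), u = rep(C, n),
                       sigf = 9, maxiter = 200)
  alpha <- kernlab::primal(sol)
  obj <- sum(alpha) - 0.5 * drop(t(alpha * y) %*% K %*% (alpha * y))
  list(alpha = alpha, objective = obj)
}

# Mann-Whitney pairwise statistic: wins + half-ties over pos-neg pairs
auroc_pairwise <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == -1]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
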