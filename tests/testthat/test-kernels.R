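test_that("WD kernel matches exhaustive k-mer enumeration", {
  expect_equal(wd_kernel("AAAA", "CCCC", d = 2), 0)
  expect_equal(wd_kernel("ACGT", "ACTT", d = 1), 3)
  # closed-form self similarity: sum_k beta_k (L - k + 1)
  s <- "ACGTA"
  expect_equal(wd_kernel(s, s, d = 2), (2 / 3) * 5 + (1 / 3) * 4)
  set.seed(21)
  for (i in 1:8) {
    L <- sample(6:15, 1)
    d <- sample(1:5, 1)
    s1 <- random_seq(L); s2 <- random_seq(L)
    expect_equal(wd_kernel(s1, s2, d), wd_naive(s1, s2, d))
    expect_equal(wd_kernel(s1, s2, d), wd_kernel(s2, s1, d))
  }
  expect_error(wd_kernel("ACGT", "ACG", d = 1), "equal length")
  expect_error(wd_kernel("ACG", "ACT", d = 5), "1..L")
})

test_that("k-mer weights sum to one for every order", {
  for (d in c(1, 2, 6, 12, 24)) {
    beta <- 2 * (d - seq_len(d) + 1) / (d * (d + 1))
    expect_equal(sum(beta), 1)
  }
})

test_that("WDS kernel reduces to WD at zero shift and matches enumeration", {
  set.seed(22)
  for (i in 1:5) {
    s1 <- random_seq(8); s2 <- random_seq(8)
    d <- sample(1:4, 1)
    expect_equal(wds_kernel(s1, s2, d, shift_max = 0), wd_kernel(s1, s2, d))
    sm <- sample(1:3, 1)
    expect_equal(wds_kernel(s1, s2, d, shift_max = sm),
                 wds_naive(s1, s2, d, sm))
    expect_equal(wds_kernel(s1, s2, d, shift_max = sm),
                 wds_kernel(s2, s1, d, shift_max = sm))
  }
  # shifted matches give a nonzero value where rigid matching finds none
  expect_gt(wds_kernel("ACGT", "CACG", d = 1, shift_max = 1), 0)
  expect_equal(wds_kernel("ACGT", "CACG", d = 1, shift_max = 1),
               wds_naive("ACGT", "CACG", 1, 1))
})

test_that("RBF kernel has unit self-similarity and the Gaussian form", {
  x <- c(0.2, 0.4); y <- c(1.2, 0.4)
  expect_equal(rbf_kernel(x, x, gamma = 3), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), gamma = 1), exp(-1))
  expect_equal(rbf_kernel(x, y, 0.5), rbf_kernel(y, x, 0.5))
  expect_error(rbf_kernel(1:3, 1:2, 1), "dimensions")
  expect_error(rbf_kernel(x, y, gamma = -1), "positive")
})

test_that("Gram matrices are symmetric, normalized, and numerically PSD", {
  set.seed(23)
  seqs <- vapply(1:30, function(i) random_seq(50), character(1))
  for (d in c(6, 12)) {
    gr <- wd_gram(seqs, d = d, normalize = TRUE)
    V <- gr$values
    expect_lt(max(abs(V - t(V))), 1e-10)
    expect_equal(unname(diag(V)), rep(1, 30), tolerance = 1e-10)
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
    # Cauchy-Schwarz bound follows from PSD + unit diagonal
    expect_lte(max(abs(V)), 1 + 1e-10)
  }
  X <- matrix(rnorm(30 * 5), 30, 5)
  gr <- rbf_gram(X, gamma = 0.3)
  expect_lt(max(abs(gr$values - t(gr$values))), 1e-10)
  ev <- eigen(gr$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
})

test_that("unnormalized WD Gram entries equal the scalar kernel", {
  set.seed(24)
  seqs <- vapply(1:6, function(i) random_seq(12), character(1))
  gr <- wd_gram(seqs, d = 4, normalize = FALSE)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(gr$values[i, j], wd_naive(seqs[i], seqs[j], 4))
  }
  # cross gram against another set
  qs <- vapply(1:3, function(i) random_seq(12), character(1))
  cr <- wd_gram(seqs, qs, d = 4, normalize = FALSE)
  expect_equal(dim(cr$values), c(6, 3))
  expect_equal(cr$values[2, 3], wd_naive(seqs[2], qs[3], 4))
})

test_that("Gram matrices round-trip through tab-separated text with config", {
  set.seed(27)
  seqs <- vapply(1:8, function(i) random_seq(20), character(1))
  gr <- wd_gram(seqs, d = 5, ids = sprintf("w%02d", 1:8))
  path <- tempfile(fileext = ".tsv")
  write_gram(gr, path)
  back <- read_gram(path)
  expect_identical(back$instance_ids, gr$instance_ids)
  expect_equal(back$values, gr$values, tolerance = 1e-12)
  expect_equal(back$config$kind, "WD")
  expect_equal(back$config$d, 5)
  unlink(path)
})

test_that("normalization is idempotent and bounded", {
  set.seed(25)
  seqs <- vapply(1:10, function(i) random_seq(30), character(1))
  raw <- wd_gram(seqs, d = 6, normalize = FALSE)
  n1 <- normalize_gram(raw)
  n2 <- normalize_gram(n1)
  expect_equal(n1$values, n2$values)
  expect_true(all(abs(n1$values) <= 1 + 1e-10))
  expect_equal(unname(diag(n1$values)), rep(1, 10))
})

test_that("hybrid combination averages normalized components", {
  set.seed(26)
  seqs <- vapply(1:15, function(i) random_seq(40), character(1))
  X <- matrix(rnorm(15 * 8), 15, 8)
  gs <- wd_gram(seqs, d = 6, ids = as.character(1:15))
  gp <- rbf_gram(X, gamma = 0.2, ids = as.character(1:15))
  h <- hybrid_gram(gs, gp)
  expect_equal(h$values, 0.5 * gs$values + 0.5 * gp$values)
  expect_equal(unname(diag(h$values)), rep(1, 15))
  ev <- eigen(h$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
  # identical inputs pass through unchanged
  expect_equal(hybrid_gram(gp, gp)$values, gp$values)
  # weight (1, 0) reproduces the sequence component exactly
  expect_equal(hybrid_gram(gs, gp, weights = c(1, 0))$values, gs$values)
  expect_error(hybrid_gram(gs, gp, weights = c(0.7, 0.7)), "summing to 1")
  gp2 <- rbf_gram(X, gamma = 0.2, ids = as.character(15:1))
  expect_error(hybrid_gram(gs, gp2), "orderings")
})
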