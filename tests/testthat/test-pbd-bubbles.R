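params <- pbd_params()
g64 <- quad_grid(64)

test_that("bubble matrix on a 3-base chain matches dense quadrature", {
  bc <- brute_chain("GAT", 345, g64, params)
  mu <- brute_mu(bc)
  den <- brute_Z(bc, mu)
  b <- bubble_matrix("GAT", 345, g64, params, m_max = 3)
  for (m in 1:3) {
    for (k in 1:3) {
      expect_equal(b$values[k, m],
                   brute_Z(bc, brute_bubble_event(bc, k, m) & mu) / den,
                   tolerance = 1e-9,
                   label = sprintf("P_bub(%d, %d)", k, m))
    }
  }
})

test_that("the exact-size-N column is zero (all-open excluded from dsDNA ensemble)", {
  b <- bubble_matrix("ATAT", 355, g64, params, m_max = 4)
  expect_true(all(abs(b$values[, 4]) < 1e-12))
  expect_true(all(b$values >= 0 & b$values <= 1))
})

test_that("homopolymer bubble matrix is symmetric under position reversal", {
  N <- 8
  b <- bubble_matrix(strrep("A", N), 350, g64, params, m_max = N)
  for (m in 1:N) {
    # odd m: centre maps k -> N+1-k; even m (centre = left of midpoint):
    # centre maps k -> N-k
    km <- if (m %% 2 == 1) N + 1 - seq_len(N) else N - seq_len(N)
    ok <- km >= 1 & km <= N
    expect_equal(b$values[seq_len(N)[ok], m], b$values[km[ok], m],
                 tolerance = 1e-9)
  }
})

test_that("participation by summation over bubbles matches brute force and nesting", {
  bc <- brute_chain("GAT", 345, g64, params)
  mu <- brute_mu(bc)
  den <- brute_Z(bc, mu)
  b <- bubble_matrix("GAT", 345, g64, params, m_max = 3)
  for (m in 1:3) {
    pp <- participation_profile(b, m)
    for (k in 1:3) {
      expect_equal(pp$values[k],
                   brute_Z(bc, brute_part_event(bc, k, m) & mu) / den,
                   tolerance = 1e-9)
    }
  }
  # P_part(k, 1) is the plain opening, which contains the exact-size-1 event
  pp1 <- participation_profile(b, 1)
  expect_true(all(pp1$values >= b$values[, 1] - 1e-12))
  expect_error(participation_profile(b, 9), "1..m_max")
})

test_that("direct participation route agrees with the bubble-matrix summation", {
  set.seed(11)
  s <- random_seq(12)
  b <- bubble_matrix(s, 345, g64, params, m_max = 12)
  for (m in c(1, 2, 3, 5, 8)) {
    op <- opening_profile(s, 345, g64, params, m = m)
    pp <- participation_profile(b, m)
    expect_equal(op$values, pp$values, tolerance = 1e-9,
                 label = sprintf("m = %d", m))
  }
})

test_that("participation is nonincreasing in bubble size at every position", {
  set.seed(3)
  s <- random_seq(20)
  prev <- NULL
  for (m in 1:6) {
    op <- opening_profile(s, 350, g64, params, m = m)
    if (!is.null(prev)) expect_true(all(op$values <= prev + 1e-10))
    prev <- op$values
  }
})

test_that("window profiles are trimmed to the 200 central probabilities", {
  set.seed(5)
  s300 <- random_seq(300)
  pr <- profile_for_window(s300, 345, quad_grid(96), params, m = 8)
  expect_length(pr$values, 200)
  expect_true(pr$trimmed)
  expect_true(all(pr$values >= 0 & pr$values <= 1))
  # trimming removes the first and last 50 of the untrimmed profile
  full <- opening_profile(s300, 345, quad_grid(96), params, m = 8)
  expect_equal(pr$values, full$values[51:250])
  expect_error(profile_for_window(random_seq(299), 345), "exactly 300")
  expect_error(profile_for_window(gsub("A", "N", s300), 345), "outside ACGT")
})

test_that("grid refinement leaves reported probabilities stable", {
  set.seed(9)
  s <- random_seq(40)
  a <- opening_profile(s, 345, quad_grid(192), params, m = 8)
  b <- opening_profile(s, 345, quad_grid(384), params, m = 8)
  expect_lt(max(abs(a$values - b$values)), 1e-4)
})
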