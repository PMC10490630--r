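# Simulator front end: baseband superposition, range DFT, range gating.

params_small <- radar_params(num_chirps = 64L)

static_sc <- function(r0, amp = 1) {
  scatterer(function(t) rep_len(r0, length(t)), amplitude = amp,
            velocity_fn = function(t) rep_len(0, length(t)))
}

test_that("empty scatterer list yields the all-zero baseband matrix", {
  s <- simulate_baseband(list(), params_small)
  expect_equal(dim(s), c(params_small$n1, params_small$n2))
  expect_true(all(s == 0))
})

test_that("baseband superposition is linear in the scatterer set", {
  sc1 <- static_sc(2.5)
  sc2 <- scatterer(function(t) 3 + 0.2 * sin(2 * pi * t),
                   velocity_fn = function(t) 0.2 * 2 * pi * cos(2 * pi * t))
  joint <- simulate_baseband(list(sc1, sc2), params_small)
  solo <- simulate_baseband(list(sc1), params_small) +
    simulate_baseband(list(sc2), params_small)
  expect_equal(joint, solo, tolerance = 1e-12)
})

test_that("non-finite trajectories are rejected", {
  bad <- scatterer(function(t) ifelse(t > 0.01, 3, NaN),
                   velocity_fn = function(t) rep_len(0, length(t)))
  expect_error(simulate_baseband(list(bad), params_small), "non-finite")
  neg <- static_sc(-1)
  expect_error(simulate_baseband(list(neg), params_small), "positive")
})

test_that("a static scatterer peaks at the predicted beat bin (DFT oracle)", {
  for (r0 in c(1.8, 3.2, 4.5)) {
    s <- simulate_baseband(list(static_sc(r0)), params_small)
    col <- s[, 1]
    # brute-force DFT of the analytic column signal
    n1 <- params_small$n1
    dft <- vapply(0:(n1 - 1), function(p)
      Mod(sum(col * exp(-2i * pi * p * (0:(n1 - 1)) / n1))), numeric(1))
    expect_equal(which.max(dft) - 1L, range_to_bin(r0, params_small))
    R <- compute_range_map(s, params_small)
    expect_equal(which.max(Mod(R[, 1])) - 1L, range_to_bin(r0, params_small))
  }
})

test_that("range map implements the normalized fast-time DFT", {
  p <- params_small
  s <- matrix(1 + 0i, p$n1, p$n2)
  R <- compute_range_map(s, p)
  expect_equal(Re(R[1, ]), rep(1, p$n2), tolerance = 1e-12)
  expect_lt(max(Mod(R[-1, ])), 1e-12)

  # a tone on the p0-th DFT basis function concentrates at row p0 + 1
  # (the analysis kernel is exp(-j 2 pi p n1 / N1))
  p0 <- 7L
  s <- matrix(exp(2i * pi * p0 * (0:(p$n1 - 1)) / p$n1), p$n1, p$n2)
  R <- compute_range_map(s, p)
  expect_equal(Mod(R[p0 + 1L, 1]), 1, tolerance = 1e-12)
  expect_lt(max(Mod(R[-(p0 + 1L), 1])), 1e-12)

  expect_error(compute_range_map(matrix(0i, 3, 3), p), "shape")
})

test_that("Parseval holds through the normalized range DFT", {
  set.seed(42)
  p <- params_small
  s <- matrix(complex(real = rnorm(p$n1 * p$n2),
                      imaginary = rnorm(p$n1 * p$n2)), p$n1, p$n2)
  R <- compute_range_map(s, p)
  for (j in c(1L, 17L, p$n2)) {
    lhs <- sum(Mod(R[, j])^2)
    rhs <- sum(Mod(s[, j])^2) / p$n1   # brute-force sum oracle
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("range-bin summation matches an explicit loop", {
  set.seed(7)
  R <- matrix(complex(real = rnorm(40), imaginary = rnorm(40)), 8, 5)
  v <- sum_range_bins(R, 2, 5)
  vloop <- rep(0 + 0i, 5)
  for (p in 2:5) vloop <- vloop + R[p + 1L, ]
  expect_equal(v, vloop)
  expect_equal(sum_range_bins(R, 3, 3), R[4, ])
  expect_error(sum_range_bins(R, 5, 2), "p1")
})

test_that("summing all range bins of a constant baseband recovers ones", {
  p <- params_small
  R <- compute_range_map(matrix(1 + 0i, p$n1, p$n2), p)
  v <- sum_range_bins(R, 0, p$n1 - 1L)
  expect_equal(Re(v), rep(1, p$n2), tolerance = 1e-10)
})

test_that("the range gate covers every scatterer's peak bin", {
  p <- radar_params(num_chirps = 128L)
  scs <- list(static_sc(2.2), static_sc(4.7))
  g <- range_gate(scs, p)
  bins <- range_to_bin(c(2.2, 4.7), p)
  expect_true(all(bins >= g$p1 & bins <= g$p2))
})
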