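ring2 <- connection_matrix(rbind(c(0, 1), c(1, 0)))

test_that("spike probabilities over an attractor are exact rationals", {
  r <- simulate_assembly(ring2, steps = 21, init = c(1, 0))
  s <- spike_probabilities(r)
  expect_true(s$exact_over_cycle)
  expect_equal(s$period, 2L)
  expect_equal(s$p, c(0.5, 0.5))
  expect_equal(s$xbar, c(0.5, 0.5))
  z <- simulate_assembly(connection_matrix(matrix(0, 4, 4)), steps = 10,
                         init = c(1, 0, 1, 0))
  expect_equal(spike_probabilities(z)$p, rep(0, 4))
})

test_that("probabilities over one period equal probabilities over k periods", {
  for (k in 1:10) {
    n <- 5 + (k %% 12)
    m <- random_connection_matrix(n, e1 = 0.5, density = 0.8, seed = 600 + k)
    r <- simulate_assembly(m, steps = 2000, init = "single", seed = k)
    s <- suppressWarnings(spike_probabilities(r))
    if (!s$exact_over_cycle) next
    a <- s$window[1]
    for (periods in 2:3) {
      to <- a + periods * s$period
      if (to - 1 > r$steps) break
      rows <- (a:(to - 1)) + 1L
      expect_equal(colSums(r$spikes[rows, , drop = FALSE]) / (periods * s$period),
                   s$p)
    }
  }
})

test_that("no attractor in the run falls back to the trailing half with a warning", {
  m <- random_connection_matrix(200, e1 = 0.5, density = 1, seed = 4)
  r <- simulate_assembly(m, steps = 200, init = "single", seed = 4)
  expect_warning(s <- spike_probabilities(r), "trailing half")
  expect_false(s$exact_over_cycle)
  expect_true(all(s$p >= 0 & s$p <= 1))
})

test_that("the conservation identity Xbar = P x M holds exactly over a period", {
  # hand case: the 2-ring
  s <- spike_probabilities(simulate_assembly(ring2, steps = 11, init = c(1, 0)))
  expect_identical(accumulation_residual(s, ring2), c(0, 0))
  # zero matrix
  z <- connection_matrix(matrix(0, 3, 3))
  sz <- spike_probabilities(simulate_assembly(z, steps = 8, init = c(1, 1, 0)))
  expect_identical(accumulation_residual(sz, z), c(0, 0, 0))
  # random n = 50, exact integer counting
  m <- random_connection_matrix(50, e1 = 0.5, density = 0.8, seed = 12)
  r <- simulate_assembly(m, steps = 4000, init = "single", seed = 12)
  s50 <- spike_probabilities(r)
  expect_true(s50$exact_over_cycle)
  expect_identical(accumulation_residual(s50, m), rep(0, 50))
  # a non-cycle window is flagged as approximate
  sw <- spike_probabilities(r, burn_in = 100)
  expect_warning(accumulation_residual(sw, m), "approximate")
})

test_that("entropy variants agree with closed forms", {
  expect_equal(shannon_entropy(c(1, 0, 1)), 0)
  expect_equal(shannon_entropy(c(1, 0, 1), "bernoulli"), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2))
  expect_equal(shannon_entropy(0.5, "bernoulli"), log(2))
  # bernoulli term is maximized at p = 1/2
  grid <- seq(0.01, 0.99, by = 0.01)
  h <- vapply(grid, shannon_entropy, numeric(1), variant = "bernoulli")
  expect_equal(grid[which.max(h)], 0.5)
  expect_error(shannon_entropy(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("boltzmann entropy is k ln T", {
  expect_equal(boltzmann_entropy(1), 0)
  expect_equal(boltzmann_entropy(exp(1)), 1)
  expect_equal(boltzmann_entropy(10, k = 2), 2 * log(10))
  expect_error(boltzmann_entropy(0), ">= 1")
})

test_that("exact logistic data is recovered to numerical precision", {
  xbar <- seq(-5, 5, length.out = 30)
  p <- 1 / (1 + exp(-2 * xbar + 1))
  f <- fit_logistic(p, xbar)
  expect_lt(abs(f$a - (-2)) / 2, 1e-6)
  expect_lt(abs(f$c - 1), 1e-6)
  expect_gt(f$r2, 1 - 1e-10)
  fn <- fit_logistic(p, xbar, method = "nls")
  expect_lt(abs(fn$a - (-2)) / 2, 1e-4)
})

test_that("flat data yields a null slope and degenerate inputs error", {
  xbar <- seq(-3, 3, length.out = 20)
  f <- fit_logistic(rep(0.5, 20), xbar)
  expect_lt(abs(f$a), 1e-10)
  expect_lt(f$r2, 1e-10)
  expect_error(fit_logistic(c(0.2, 0.4, 0.6), rep(1, 3)), "constant")
  expect_error(fit_logistic(c(0, 1, 0), 1:3), "saturated")
  expect_error(fit_logistic(c(0.2, 0.4), 1:2), "3 points")
})

test_that("increasing clamped stimulation polarizes the observed neurons", {
  m <- random_connection_matrix(120, e1 = 0.53, density = 1, seed = 21)
  pol <- polarization_experiment(m, list(integer(), 1:12, 1:24, 1:36),
                                 steps = 600, seed = 21)
  expect_equal(pol$n_clamped, c(0, 12, 24, 36))
  expect_equal(pol$n_free, 120 - pol$n_clamped)
  expect_true(all(pol$entropy >= 0))
  # clamping everything leaves nothing observable: entropy 0
  all_cl <- polarization_experiment(m, list(1:120), steps = 50, seed = 21)
  expect_equal(all_cl$entropy, 0)
  expect_equal(all_cl$n_free, 0)
  # the schedule must be nested
  expect_error(polarization_experiment(m, list(1:10, 5:8), steps = 10), "nested")
})
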