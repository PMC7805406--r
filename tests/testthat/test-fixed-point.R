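ring2 <- connection_matrix(rbind(c(0, 1), c(1, 0)))

test_that("the residual vanishes where symmetry makes the root explicit", {
  # P x M has zero columns, logit(0.5) = 0: residual identically zero
  m <- connection_matrix(rbind(c(0, 1), c(0, -1)), meta = list())
  expect_equal(fixed_point_residual(c(0.5, 0.5), m, a = -1, c = 0), c(0, 0))
  expect_error(fixed_point_residual(c(0, 0.5), ring2, a = -1, c = 0), "logit")
  expect_error(fixed_point_residual(c(0.5, 0.5), ring2, a = 0, c = 0), "nonzero")
})

test_that("perturbing one coordinate away from a root grows its residual", {
  p_star <- uniroot(function(p) logit(p) - p, c(0.5, 0.9), tol = 1e-12)$root
  base <- abs(fixed_point_residual(rep(p_star, 2), ring2, a = -1, c = 0))
  for (d in c(-0.05, 0.05, 0.1)) {
    p <- c(p_star + d, p_star)
    expect_gt(abs(fixed_point_residual(p, ring2, a = -1, c = 0)[1]), base[1] + 1e-6)
  }
})

test_that("the 2-ring symmetric root matches a scalar bisection oracle", {
  # symmetric root solves p = logit(p); bisection gives ~0.659
  p_star <- uniroot(function(p) logit(p) - p, c(0.5, 0.9), tol = 1e-12)$root
  expect_equal(p_star, 0.659, tolerance = 1e-3)
  sol <- solve_fixed_point(ring2, a = -1, c = 0)
  expect_true(sol$converged)
  expect_equal(sol$p_star, rep(p_star, 2), tolerance = 1e-6)
  expect_lt(sol$residual_norm, 1e-8)
})

test_that("a single isolated neuron has the closed-form solution", {
  m1 <- connection_matrix(matrix(0, 1, 1))
  for (cc in c(-1, 0, 0.7, 2)) {
    sol <- solve_fixed_point(m1, a = -2, c = cc)
    expect_equal(sol$p_star, 1 / (1 + exp(cc)), tolerance = 1e-7)
  }
})

test_that("different starts converge to the same root on small instances", {
  m <- random_connection_matrix(30, e1 = 0.5, density = 1, seed = 3)
  s1 <- solve_fixed_point(m, a = -0.5, c = 0.1, init = "uniform", tol = 1e-10)
  for (k in 1:3) {
    p0 <- 0.2 + 0.6 * ((seq_len(30) * k * 7919) %% 100) / 100
    s2 <- solve_fixed_point(m, a = -0.5, c = 0.1, init = p0, tol = 1e-10)
    expect_true(s2$converged)
    expect_equal(s2$p_star, s1$p_star, tolerance = 1e-8)
  }
})

test_that("pilot estimation is deterministic and rejects dead assemblies", {
  m <- random_connection_matrix(150, e1 = 0.5, density = 1, seed = 6)
  f1 <- estimate_ac_from_pilot(m, steps = 1200, seed = 6)
  f2 <- estimate_ac_from_pilot(m, steps = 1200, seed = 6)
  expect_identical(coef(f1), coef(f2))
  expect_lt(f1$a, 0)
  z <- connection_matrix(matrix(0, 10, 10))
  expect_error(estimate_ac_from_pilot(z, steps = 100, seed = 1), "degenerate")
})

test_that("solved and simulated probabilities agree; shuffling destroys it", {
  m <- random_connection_matrix(150, e1 = 0.5, density = 1, seed = 17)
  cmp <- compare_with_simulation(m, steps = 3000, seed = 17)
  expect_gt(cmp$r, 0.9)
  expect_equal(cor(cmp$p_star, cmp$p_star), 1)
  set.seed(99)
  rs <- vapply(1:20, function(k) {
    perm <- sample(length(cmp$p_star))
    cor(cmp$p_star[perm], cmp$p_empirical)
  }, numeric(1))
  expect_lt(abs(median(rs)), 0.3)
})

test_that("an empirical solution beats a random probability vector as a root", {
  m <- random_connection_matrix(100, e1 = 0.5, density = 1, seed = 23)
  fit <- estimate_ac_from_pilot(m, steps = 2500, seed = 23)
  st <- attr(fit, "stats")
  eps <- 1e-4
  p_emp <- pmin(pmax(st$p, eps), 1 - eps)
  res_emp <- median(abs(fixed_point_residual(p_emp, m, fit$a, fit$c)))
  res_rand <- vapply(1:10, function(k) {
    set.seed(1000 + k)
    p_r <- runif(100, eps, 1 - eps)
    median(abs(fixed_point_residual(p_r, m, fit$a, fit$c)))
  }, numeric(1))
  expect_true(all(res_emp < res_rand))
})

test_that("linear summaries fail to predict probabilities; no-op swap agrees", {
  m <- random_connection_matrix(150, e1 = 0.5, density = 1, seed = 31)
  rep <- linear_predictor_checks(m, steps = 3000, seed = 31)
  expect_true(rep$active)
  expect_lt(abs(rep$r_colsum), 1)
  expect_lt(abs(rep$r_increment), 1)
  # matrix with two identical columns: swapping them is a no-op
  mm <- unclass(random_connection_matrix(20, e1 = 0.5, seed = 41))
  mm[, 2] <- mm[, 1]
  rep2 <- linear_predictor_checks(connection_matrix(mm), steps = 500, seed = 41,
                                  swap = c(1L, 2L))
  expect_true(rep2$swap_identical)
  if (rep2$active) expect_equal(rep2$r_swap, 1, tolerance = 1e-12)
  # a silent assembly yields flagged, undefined diagnostics
  z <- linear_predictor_checks(connection_matrix(matrix(0, 5, 5)), steps = 50,
                               seed = 1)
  expect_false(z$active)
  expect_true(is.na(z$r_colsum))
})
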