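test_that("closed form is the identity at t = 0 and fixed at the roots", {
  sc <- worked_scenarios()
  for (i in seq_len(nrow(sc))) {
    p <- model_params(sc$sigma_I[i], sc$alpha[i], sc$beta[i])
    sigma_P0 <- 1 - sc$sigma_I[i] - sc$sigma_O0[i]
    expect_equal(closed_form_sigma_P(p, sigma_P0, 0), sigma_P0)
  }
  # starting exactly on a root stays there forever
  p <- model_params(0.1, 12, 2) # p1 = 0.9, p2 = 0.6
  expect_equal(closed_form_sigma_P(p, 0.9, c(0, 1, 50)), rep(0.9, 3))
  expect_equal(closed_form_sigma_P(p, 0.6, c(0, 1, 50)), rep(0.6, 3))
})

test_that("closed form and numerical integrator agree on all benchmarks", {
  sc <- worked_scenarios()
  for (i in seq_len(nrow(sc))) {
    p <- model_params(sc$sigma_I[i], sc$alpha[i], sc$beta[i])
    traj <- integrate_trajectory(p, sc$sigma_O0[i])
    analytic <- closed_form_sigma_P(p, 1 - sc$sigma_I[i] - sc$sigma_O0[i],
                                    traj$t)
    expect_lt(max(abs(analytic - traj$sigma_P)), 1e-8)
  }
})

test_that("double-root closed form matches the integrator", {
  # marginal threshold: p1 = p2 = 0.5; approach is algebraic, not exponential
  p <- model_params(0.5, 1, 1)
  traj <- integrate_trajectory(p, sigma_O0 = 0.3, t_max = 200)
  analytic <- closed_form_sigma_P(p, 0.2, traj$t)
  expect_lt(max(abs(analytic - traj$sigma_P)), 1e-8)
  # power-law tail: still short of equilibrium at t = 200
  expect_gt(traj$sigma_O[nrow(traj)], 1e-4)
})

test_that("large-time evaluation is overflow-guarded", {
  p <- model_params(0.5, 5, 0.5) # p1 = 0.5 < p2 = 5: exponent grows with t
  p2_side <- model_params(0.1, 12, 2) # p2 = 0.6 stable, positive exponent
  out <- closed_form_sigma_P(p2_side, 0.1, c(1e4, 1e6, 1e9))
  expect_true(all(is.finite(out)))
  expect_equal(out, rep(0.6, 3))
  expect_equal(closed_form_sigma_P(p, 0.2, 1e9), 0.5)
})

test_that("trajectories conserve the population and stay monotone", {
  sc <- worked_scenarios()
  for (i in seq_len(nrow(sc))) {
    p <- model_params(sc$sigma_I[i], sc$alpha[i], sc$beta[i])
    traj <- integrate_trajectory(p, sc$sigma_O0[i])
    expect_lt(max(abs(traj$sigma_I + traj$sigma_P + traj$sigma_O - 1)),
              1e-12)
    d <- diff(traj$sigma_P)
    start_below <- traj$sigma_P[1] < stability(p)$sigma_P_eq
    if (start_below) expect_true(all(d >= -1e-12))
    else expect_true(all(d <= 1e-12))
  }
})

test_that("every trajectory relaxes to the stable root", {
  sc <- worked_scenarios()
  for (i in seq_len(nrow(sc))) {
    p <- model_params(sc$sigma_I[i], sc$alpha[i], sc$beta[i])
    traj <- integrate_trajectory(p, sc$sigma_O0[i])
    expect_equal(traj$sigma_P[nrow(traj)], stability(p)$sigma_P_eq,
                 tolerance = 1e-6)
  }
  # in particular the extinction scenario kills the opponents ...
  h <- benchmark_params("h")
  traj <- integrate_trajectory(h$params, h$sigma_O0)
  expect_lt(traj$sigma_O[nrow(traj)], 1e-6)
  # ... and the equal-rate minority-core scenario lands on sigma_P = sigma_I
  d <- benchmark_params("d")
  traj <- integrate_trajectory(d$params, d$sigma_O0)
  expect_equal(traj$sigma_P[nrow(traj)], 0.28, tolerance = 1e-6)
})

test_that("stability selection matches long-time limits on a random sweep", {
  set.seed(907)
  for (p in random_params(50)) {
    traj <- integrate_trajectory(p, sigma_O0 = 0.9 * (1 - p$sigma_I),
                                 n_out = 64)
    expect_equal(traj$sigma_P[nrow(traj)], stability(p)$sigma_P_eq,
                 tolerance = 1e-6)
  }
})

test_that("equilibrium detection reports convergence honestly", {
  g <- benchmark_params("g")
  eq <- equilibrium_from_trajectory(integrate_trajectory(g$params,
                                                         g$sigma_O0))
  expect_true(eq$converged)
  expect_equal(eq$sigma_P_eq, 0.6, tolerance = 1e-6)
  expect_equal(eq$sigma_O_eq, 0.3, tolerance = 1e-6)

  h <- benchmark_params("h")
  eq <- equilibrium_from_trajectory(integrate_trajectory(h$params,
                                                         h$sigma_O0))
  expect_true(eq$converged)
  expect_equal(eq$sigma_P_eq, 0.9, tolerance = 1e-6)

  short <- integrate_trajectory(g$params, g$sigma_O0, t_max = 0.01)
  eq <- equilibrium_from_trajectory(short, tol = 1e-8)
  expect_false(eq$converged) # horizon too short; values still reported
  expect_true(is.finite(eq$sigma_P_eq))
})

test_that("constant trajectory from an initial state exactly at a root", {
  p <- model_params(0.1, 12, 2)
  traj <- integrate_trajectory(p, sigma_O0 = 0.3) # sigma_P0 = p2 = 0.6
  expect_lt(max(abs(traj$sigma_P - 0.6)), 1e-9)
})

test_that("trajectory inputs are validated", {
  p <- model_params(0.3, 1, 1)
  expect_error(integrate_trajectory(p, sigma_O0 = 0.9), "sigma_O0")
  expect_error(integrate_trajectory(p, 0.3, t_max = -1), "t_max")
  expect_error(closed_form_sigma_P(p, 0.9, 1), "sigma_P0")
  expect_error(closed_form_sigma_P(model_params(0.3, 1, 0), 0.2, 1),
               "beta > 0")
  expect_error(closed_form_sigma_P(p, 0.2, -1), "t")
})
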