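test_that("parameter construction validates its domain", {
  expect_s3_class(model_params(0.3, 1, 1), "model_params")
  expect_error(model_params(-0.1, 1, 1), "sigma_I")
  expect_error(model_params(1.2, 1, 1), "sigma_I")
  expect_error(model_params(0.3, -1, 1), "alpha")
  expect_error(model_params(0.3, 1, -1), "beta")
  expect_error(model_params(NaN, 1, 1), "finite")
  expect_error(model_params(0.3, NA_real_, 1), "finite")
})

test_that("population state enforces conservation", {
  expect_error(population_state(0, 0.5, 0.5, sigma_I = 0.3), "satisfy")
  st <- population_state(0, 0.4, 0.3, sigma_I = 0.3)
  expect_equal(st$sigma_P + st$sigma_O + st$sigma_I, 1)
})

test_that("reduced ODE right-hand side matches hand evaluation", {
  p <- model_params(0.3, 1, 1)
  # 1 * 0.3 * 0.3 - 1 * 0.3 * 0.4
  expect_equal(rhs(p, 0.4), -0.03)
  # both equilibrium roots annihilate the rate
  expect_equal(rhs(p, 0.7), 0)
  expect_equal(rhs(p, 0.3), 0)
  expect_error(rhs(p, 0.8), "domain")
  expect_error(rhs(p, -0.1), "domain")
})

test_that("equilibrium roots take the closed-form values", {
  r <- equilibrium_roots(model_params(0.1, 22, 2))
  expect_equal(r$p1, 0.9)
  expect_equal(r$p2, 1.1)
  expect_equal(equilibrium_roots(model_params(0, 3, 2))[c("p1", "p2")],
               list(p1 = 1, p2 = 0))
  r <- equilibrium_roots(model_params(0.28, 0.5, 0.5))
  expect_equal(r$p1, 0.72)
  expect_equal(r$p2, 0.28)
})

test_that("beta = 0 is reported as a degenerate decay, not an error", {
  r <- equilibrium_roots(model_params(0.3, 2, 0))
  expect_true(r$degenerate)
  expect_true(is.na(r$p2))
  rep <- stability(model_params(0.3, 2, 0))
  expect_true(rep$degenerate)
  expect_identical(rep$stable_root, "p1")
  expect_equal(rep$sigma_O_eq, 0)
  expect_true(rep$thwarted)
  expect_equal(rep$lambda1, -0.6) # decay of sigma_O at rate alpha * sigma_I
})

test_that("critical threshold beta/(alpha + beta) and its edge cases", {
  expect_equal(critical_threshold(model_params(0.3, 2, 2)), 0.5)
  expect_equal(critical_threshold(model_params(0.1, 22, 2)), 1 / 12)
  expect_equal(critical_threshold(model_params(0.1, 0, 3)), 1)
  expect_error(critical_threshold(model_params(0.1, 0, 0)), "undefined")
})

test_that("minimum core engagement (1/sigma_I - 1) * beta", {
  expect_equal(min_core_engagement(0.5, 2), 2)
  expect_equal(min_core_engagement(1, 7), 0)
  expect_equal(min_core_engagement(0.25, 1), 3)
  expect_error(min_core_engagement(0, 1), "sigma_I")
})

test_that("minimum engagement inverts the critical threshold", {
  for (sigma_I in c(0.05, 0.28, 0.5, 0.9)) {
    beta <- 1.7
    alpha_star <- min_core_engagement(sigma_I, beta)
    expect_equal(critical_threshold(model_params(sigma_I, alpha_star, beta)),
                 sigma_I)
  }
})

test_that("stability selects the smaller root and fills the equilibrium", {
  rep <- stability(model_params(0.1, 22, 2)) # core above threshold
  expect_identical(rep$stable_root, "p1")
  expect_equal(rep$sigma_P_eq, 0.9)
  expect_equal(rep$sigma_O_eq, 0)
  expect_equal(rep$lambda1, 2 * (0.9 - 1.1))
  expect_true(rep$thwarted)

  rep <- stability(model_params(0.1, 12, 2)) # coexistence
  expect_identical(rep$stable_root, "p2")
  expect_equal(rep$sigma_P_eq, 0.6)
  expect_equal(rep$sigma_O_eq, 1 - (14 / 2) * 0.1)
  expect_false(rep$thwarted)

  rep <- stability(model_params(0.5, 1.3, 1.3)) # symmetric boundary
  expect_identical(rep$stable_root, "marginal")
  expect_equal(rep$lambda1, 0)
  expect_equal(rep$lambda2, 0)
  expect_true(rep$marginal)
  expect_equal(rep$sigma_O_eq, 0)
})

test_that("case label and thwarted flag are independent classifications", {
  # core majority yet not thwarted: very large beta
  r <- classify_regime(model_params(0.6, 0.5, 2))
  expect_identical(r$case, "case1")
  expect_false(r$thwarted) # I_c = 2/2.5 = 0.8 > 0.6

  r <- classify_regime(model_params(0.5, 1, 1))
  expect_identical(r$case, "case2")
  expect_true(r$thwarted)
  expect_true(r$marginal)

  r <- classify_regime(model_params(0.28, 0.5, 0.5))
  expect_identical(r$case, "case3")
  expect_false(r$thwarted)
  expect_equal(stability(model_params(0.28, 0.5, 0.5))$sigma_P_eq, 0.28)
})

test_that("algebraic invariants hold on a random parameter sweep", {
  set.seed(4021)
  for (p in random_params(200)) {
    roots <- equilibrium_roots(p)
    expect_lt(abs(rhs(p, min(roots$p1, 1 - p$sigma_I))), 1e-12)
    if (roots$p2 <= 1 - p$sigma_I)
      expect_lt(abs(rhs(p, roots$p2)), 1e-12)
    rep <- stability(p)
    expect_identical(rep$lambda1 + rep$lambda2, 0) # exact antisymmetry
    expect_equal(rep$sigma_P_eq + rep$sigma_O_eq + p$sigma_I, 1)
    # thwarted flag: sign test on the roots and the threshold agree
    expect_identical(rep$thwarted, roots$p1 <= roots$p2 + p$tol)
    expect_identical(rep$thwarted,
                     p$sigma_I >= p$beta / (p$alpha + p$beta) - p$tol)
  }
})
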