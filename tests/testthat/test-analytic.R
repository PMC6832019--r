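test_that("ZNGI intersection solves the 2x2 system", {
  cp <- coexistence_point(default_params)
  expect_equal(cp$C_star, 1, tolerance = 1e-12)
  expect_equal(cp$P_star, 4, tolerance = 1e-12)
  # hand Gaussian elimination: 1.2C - 0.3P = 0.2; 0.9C - 0.1P = 0.2
  # => P = 9C - 2; 1.2C - 2.7C + 0.6 = 0.2 => C = 4/15, P = 2/5
  p2 <- model_params(lambda1 = 1.2, lambda2 = 0.9, eta1 = 0.3, eta2 = 0.1,
                     deltaB = 0.2)
  cp2 <- coexistence_point(p2)
  expect_equal(cp2$C_star, 4 / 15, tolerance = 1e-12)
  expect_equal(cp2$P_star, 2 / 5, tolerance = 1e-12)
  expect_error(coexistence_point(model_params(lambda2 = 1, eta2 = 0.2)),
               "degenerate")
})

test_that("regime thresholds reproduce their closed forms", {
  th <- phi_thresholds(default_params)
  expect_equal(th$phi_B1, 0.04, tolerance = 1e-12)
  expect_equal(th$phi_P1, 0.14, tolerance = 1e-12)
  expect_equal(th$phi1, 0.7, tolerance = 1e-12)
  expect_equal(th$phi2, 17 / 75, tolerance = 1e-12)  # prints as 0.2266
  # perfect abortive infection in B1: phage never persists on B1 alone
  th0 <- phi_thresholds(model_params(beta1 = 0))
  expect_identical(th0$phi_P1, Inf)
  expect_identical(th0$phi1, Inf)
  expect_equal(th0$phi2, 17 / 75, tolerance = 1e-12)
})

test_that("the three bistability inequalities classify regimes", {
  expect_identical(bistability_class(default_params)$regime, "bistable")
  # weaker slow-grower phage production flips the stoichiometry inequality
  expect_identical(bistability_class(model_params(beta2 = 2))$regime,
                   "stable_coexistence")
  # equal growth rates: the first inequality fails strictly
  expect_identical(bistability_class(model_params(lambda1 = 0.8))$regime,
                   "neither")
  # zero denominators are infinite-ratio comparisons, never faults: with
  # beta1 = 0 the stoichiometry inequality holds trivially and the
  # alternative states (B1-only vs S) persist for every phi above phi2
  expect_identical(bistability_class(model_params(beta1 = 0))$regime,
                   "bistable")
})

test_that("phage persistence across the window follows phi2 > phi_P1", {
  expect_true(phage_persists_in_F(default_params))   # 0.2267 > 0.14
  expect_false(phage_persists_in_F(model_params(beta1 = 0)))
  # small beta1*eta1 pushes phi_P1 = 0.44 into the window (0.2267, 2.2)
  p <- model_params(beta1 = 0.5)
  th <- phi_thresholds(p)
  expect_gt(th$phi_P1, th$phi2)
  expect_lt(th$phi_P1, th$phi1)
  expect_false(phage_persists_in_F(p))
})

test_that("steady states reproduce the printed abundances", {
  for (phi in c(0.25, 0.45, 0.65)) {
    ss <- steady_states(default_params, phi)
    labs <- vapply(ss, function(s) s$label, "")
    F <- ss[[match("F", labs)]]$state
    S <- ss[[match("S", labs)]]$state
    expect_equal(unname(F[["B1"]]), 0.5, tolerance = 1e-12)
    expect_equal(unname(S[["B2"]]), 1 / 30, tolerance = 1e-12)
  }
  ss <- steady_states(default_params, 0.25)
  labs <- vapply(ss, function(s) s$label, "")
  F <- ss[[match("F", labs)]]$state
  expect_equal(unname(F[["C"]]), 0.25 / 0.7, tolerance = 1e-12)   # 0.357
  expect_equal(unname(F[["P"]]), (0.25 / 0.7 - 0.2) / 0.2,
               tolerance = 1e-12)                                  # 0.786
  U <- ss[[match("U", labs)]]$state
  expect_equal(unname(U[["B1"]]), 0.0246, tolerance = 2e-3)
  expect_equal(unname(U[["B2"]]), 0.0317, tolerance = 2e-3)
  expect_equal(unname(U[["C"]]), 1)
  expect_equal(unname(U[["P"]]), 4)
})

test_that("below the survival threshold only the abiotic state remains", {
  ss <- steady_states(default_params, 0.02)
  expect_length(ss, 1)
  expect_identical(ss[[1]]$label, "ABIOTIC")
  expect_true(isTRUE(ss[[1]]$stable))
})

test_that("every enumerated steady state is an exact fixed point", {
  for (phi in c(0.02, 0.1, 0.18, 0.25, 0.5, 0.69, 0.8)) {
    p <- modifyList(default_params, list(phi = phi))
    for (s in steady_states(default_params, phi))
      expect_lt(max(abs(model_rhs(s$state, p))), 1e-10)
  }
})

test_that("hysteresis jump states match the printed cross points", {
  js <- jump_states(default_params)
  expect_equal(js$C2x, 3.09, tolerance = 1e-3)
  expect_equal(js$P2x, 15.14, tolerance = 1e-3)
  expect_equal(js$C1x, 0.3238, tolerance = 1e-3)
  expect_equal(js$P1x, 0.6190, tolerance = 1e-3)
  # C2x is exactly C(S) evaluated at phi1
  th <- phi_thresholds(default_params)
  S_at_phi1 <- analytic_state(default_params, th$phi1, "S")
  expect_equal(js$C2x, S_at_phi1[1], tolerance = 1e-12)
  expect_error(jump_states(model_params(beta2 = 2)), "bistable")
})

test_that("random bistable parameter sets have consistent analytic structure", {
  set.seed(7)
  for (p in random_bistable_params(50)) {
    th <- phi_thresholds(p)
    # the two formulations of bistability agree
    expect_lt(th$phi2, th$phi1)
    phi <- (max(th$phi2, th$phi_P1) + th$phi1) / 2
    pp <- modifyList(p, list(phi = phi))
    ss <- steady_states(p, phi)
    labs <- vapply(ss, function(s) s$label, "")
    expect_true(all(c("F", "S", "U") %in% labs))
    for (s in ss) {
      expect_lt(max(abs(model_rhs(s$state, pp))), 1e-10)
      if (s$label %in% c("F", "S")) expect_true(isTRUE(s$stable))
      if (s$label == "U") expect_true(isFALSE(s$stable))
    }
    # saddle abundances interpolate linearly in phi across the window
    eps <- 1e-9 * (th$phi1 - th$phi2)
    U2 <- analytic_state(p, th$phi2 + 2e3 * eps, "U")
    expect_equal(U2[2], 0, tolerance = 1e-4)
    U1 <- analytic_state(p, th$phi1 - 2e3 * eps, "U")
    expect_equal(U1[3], 0, tolerance = 1e-4)
  }
})

test_that("stable coexistence abundances solve the two balance lines", {
  p <- model_params(beta2 = 2)  # coexistence window (0.7, 0.7333)
  th <- phi_thresholds(p)
  expect_lt(th$phi1, th$phi2)
  phi <- (th$phi1 + th$phi2) / 2
  ab <- coexistence_abundances(p, phi)
  expect_true(all(ab > 0))
  # independent numeric check of the 2x2 system
  A <- rbind(c(p$beta1 * p$eta1, p$beta2 * p$eta2),
             c(p$lambda1 / p$Y1, p$lambda2 / p$Y2))
  cp <- coexistence_point(p)
  expect_equal(unname(A %*% ab)[, 1],
               c(p$deltaP, phi / cp$C_star - p$deltaC), tolerance = 1e-12)
  # and the full state is a fixed point reported by steady_states
  ss <- steady_states(p, phi)
  labs <- vapply(ss, function(s) s$label, "")
  expect_true("COEX" %in% labs)
  cx <- ss[[match("COEX", labs)]]
  expect_lt(max(abs(model_rhs(cx$state, modifyList(p, list(phi = phi))))),
            1e-10)
  expect_true(isTRUE(cx$stable))
  # outside the window the intersection leaves the positive quadrant
  expect_true(any(coexistence_abundances(p, th$phi1 - 0.01) < 0))
  expect_true(any(coexistence_abundances(p, th$phi2 + 0.01) < 0))
})
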