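test_that("a zero-magnitude pulse never switches", {
  for (phi in c(0.3, 0.5)) {
    expect_identical(apply_pulse(default_params, phi, "F", "P", 0)[1], "F")
    expect_identical(apply_pulse(default_params, phi, "S", "B1", 0)[1], "S")
  }
})

test_that("no single pulse of C, P or B2 switches F at phi = 0.25", {
  mags <- exp(seq(log(0.05), log(3), length.out = 12))
  for (v in c("C", "P", "B2"))
    for (m in mags)
      expect_identical(apply_pulse(default_params, 0.25, "F", v, m)[1], "F")
})

test_that("pulse switching agrees with the separatrix crossed by the pulse", {
  phi <- 0.4
  F <- analytic_state(default_params, phi, "F")
  S <- analytic_state(default_params, phi, "S")
  # full-state placements along the F -> S segment flip classification once
  lams <- seq(0, 1, by = 0.1)
  labs <- vapply(lams, function(l)
    place_state(default_params, phi,
                as_eco_state(pmax(F + l * (S - F), 0)))[1], "")
  expect_identical(labs[1], "F")
  expect_identical(labs[length(labs)], "S")
  expect_identical(sum(labs[-1] != labs[-length(labs)]), 1L)
  # bisection localizes the crossing; both endpoints classify consistently
  b <- bisect_boundary(default_params, phi, F, S, "F", iter = 12)
  expect_lt(b["hi"] - b["lo"], 1e-3)
  i <- max(which(lams < b["lo"]))
  expect_true(all(labs[seq_len(i)] == "F"))
})

test_that("a P pulse along the phage axis matches a basin bisection oracle", {
  phi <- 0.4
  F <- analytic_state(default_params, phi, "F")
  S <- analytic_state(default_params, phi, "S")
  F[c(3, 4)] <- pmax(F[c(3, 4)], 4e-4)
  # scan P pulses; find the smallest switching magnitude
  mags <- seq(0.5, 2.5, by = 0.125)
  out <- vapply(mags, function(m)
    apply_pulse(default_params, phi, "F", "P", m)[1], "")
  expect_true(any(out == "S") && any(out == "F"))
  m_lo <- max(mags[out == "F" & mags < min(mags[out == "S"])])
  m_hi <- min(mags[out == "S"])
  # independent check: placing the post-pulse states directly reproduces it
  top <- F; top[4] <- top[4] + m_hi * S[4]
  bot <- F; bot[4] <- bot[4] + m_lo * S[4]
  expect_identical(place_state(default_params, phi, as_eco_state(top))[1], "S")
  expect_identical(place_state(default_params, phi, as_eco_state(bot))[1], "F")
})

test_that("B1-pulse switching region is bounded and reentrant", {
  mags <- exp(seq(log(0.05), log(10), length.out = 40))
  # at phi = 0.40: switching succeeds at moderate magnitude but oversized
  # pulses fail again (too much B1 crashes the nutrient, then phage rebound)
  out40 <- vapply(mags, function(m)
    apply_pulse(default_params, 0.40, "S", "B1", m)[1], "")
  s40 <- out40 == "F"
  expect_true(any(s40))
  expect_true(any(cummax(s40) == 1 & !s40))  # failure above a success
  # at phi = 0.50 (> 0.46) pulses within the protocol range (<= 2x the
  # target-state abundance) never switch, and at phi = 0.60 no pulse does
  out50 <- vapply(mags[mags <= 2], function(m)
    apply_pulse(default_params, 0.50, "S", "B1", m)[1], "")
  expect_true(all(out50 == "S"))
  out60 <- vapply(mags, function(m)
    apply_pulse(default_params, 0.60, "S", "B1", m)[1], "")
  expect_true(all(out60 == "S"))
})

test_that("outside the bistable window the outcome ignores the pulse", {
  # only S exists at phi = 0.75; raw B1 pulses of any size fall back to it
  out <- vapply(c(0.1, 0.5, 1, 2), function(m)
    apply_pulse(default_params, 0.75, "S", "B1", m, normalize = "raw")[1], "")
  expect_true(all(out == "S"))
})

test_that("switching boundaries are stable under magnitude-grid refinement", {
  phis <- seq(0.43, 0.49, by = 0.01)
  b <- vapply(c(20, 40), function(nm) {
    g <- pulse_scan(default_params, phis,
                    magnitudes = exp(seq(log(0.2), log(2), length.out = nm)),
                    start = "S", variable = "B1")
    switching_boundary(g, "max_phi")
  }, numeric(1))
  expect_lte(abs(b[1] - b[2]), 0.01)
  expect_lt(abs(b[2] - 0.46), 0.011)
})

test_that("placements bracketing the saddle settle on opposite sides", {
  phi <- 0.3
  U <- analytic_state(default_params, phi, "U")
  S <- analytic_state(default_params, phi, "S")
  F <- analytic_state(default_params, phi, "F")
  toS <- U + 0.05 * (S - U)
  toF <- U + 0.05 * (F - U)
  expect_identical(place_state(default_params, phi, as_eco_state(toS))[1], "S")
  expect_identical(place_state(default_params, phi, as_eco_state(toF))[1], "F")
  # exactly at the saddle with the floor off: a fixed point
  lab <- place_state(default_params, phi, as_eco_state(U), t_relax = 1000,
                     floor = 0)
  expect_identical(lab[1], "U")
})

test_that("perfect abortive infection: joint pulses beat single pulses", {
  abi <- model_params(beta1 = 0)
  th <- phi_thresholds(abi)
  expect_identical(th$phi1, Inf)
  phi <- 0.4  # inside (phi2, inf): S exists but B1_ONLY is never displaced
  # B2 alone fails at every scanned magnitude
  for (m in c(0.5, 1, 2, 3))
    expect_identical(apply_pulse(abi, phi, "B1_ONLY", "B2", m)[1], "B1_ONLY")
  # moderate P alone fails ...
  expect_identical(apply_pulse(abi, phi, "B1_ONLY", "P", 2)[1], "B1_ONLY")
  # ... but the same phage dose together with B2 switches to S
  expect_identical(
    combined_pulse(abi, phi, "B1_ONLY", c(B2 = 1, P = 2))[1], "S")
  # below phi2 the S state does not exist and nothing switches
  expect_error(combined_pulse(abi, 0.2, "B1_ONLY", c(B2 = 1, P = 2)),
               "no 'S' steady state|no 'B1_ONLY'")
  expect_identical(
    combined_pulse(abi, 0.25, "B1_ONLY", c(B2 = 2, P = 2))[1], "B1_ONLY")
})

test_that("pulse argument validation", {
  expect_error(apply_pulse(default_params, 0.4, "F", "X", 1), "variable")
  expect_error(apply_pulse(default_params, 0.4, "F", "P", -1), "magnitude")
  expect_error(apply_pulse(default_params, 0.1, "S", "B1", 1),
               "no 'S' steady state")
  expect_error(combined_pulse(default_params, 0.4, "F", c(Z = 1)), "names")
})
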