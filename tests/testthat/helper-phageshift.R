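# shared fixtures and oracles

default_params <- model_params()

# random non-negative state away from axes
rand_state <- function() {
  as_eco_state(c(runif(1, 0.05, 3), runif(1, 0.01, 2), runif(1, 0.01, 2),
                 runif(1, 0.01, 10)))
}

# central finite-difference Jacobian of model_rhs (independent oracle)
fd_jacobian <- function(state, params, h = 1e-6) {
  s <- as.numeric(state)
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    hp <- h * max(1, abs(s[j]))
    up <- s; up[j] <- up[j] + hp
    dn <- s; dn[j] <- max(dn[j] - hp, 0)
    J[, j] <- (model_rhs(up, params) - model_rhs(dn, params)) / (up[j] - dn[j])
  }
  J
}

# analytic state vector by label (numeric, no floor lift)
analytic_state <- function(params, phi, label) {
  for (s in steady_states(params, phi, include_invadable = TRUE))
    if (s$label == label) return(as.numeric(s$state))
  stop("no state ", label, " at phi = ", phi)
}

# bisection along the straight segment x0 -> x1 for the point where the
# settled classification flips away from `from`; an independent separatrix
# oracle for the pulse machinery
bisect_boundary <- function(params, phi, x0, x1, from, t_relax = 1000,
                            floor = 4e-4, iter = 25) {
  lo <- 0; hi <- 1
  stopifnot(place_state(params, phi, as_eco_state(x0), t_relax, floor) == from)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    lab <- place_state(params, phi,
                       as_eco_state(x0 + mid * (x1 - x0)), t_relax, floor)
    if (lab == from) lo <- mid else hi <- mid
  }
  c(lo = lo, hi = hi)
}
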