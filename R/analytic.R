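#' Coexistence point of the two zero-net-growth isoclines
#'
#' Each bacterial species has a zero net growth isocline (ZNGI) in the
#' `(C, P)` environment plane: the line `lambda_i C - eta_i P = deltaB` on
#' which its per-capita growth exactly balances its loss rate.  The unique
#' intersection `(C*, P*)` of the two ZNGIs is the only environment in which
#' the two species can coexist; it is computed here by solving the 2x2
#' linear system directly.
#'
#' @param params a [model_params()] object.
#' @return A list of class `coexistence_point` with elements `C_star`,
#'   `P_star`, and `positive` (`TRUE` when the intersection lies in the
#'   positive quadrant, i.e. an ecologically meaningful coexistence point
#'   exists).
#' @examples
#' coexistence_point(model_params())  # (C*, P*) = (1, 4)
#' @export
coexistence_point <- function(params) {
  A <- with(params, rbind(c(lambda1, -eta1), c(lambda2, -eta2)))
  d <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  scale <- max(abs(A))
  if (abs(d) <= 1e-12 * scale^2)
    stop("degenerate ZNGI geometry: the two isoclines are parallel ",
         "(lambda1*eta2 == lambda2*eta1)", call. = FALSE)
  sol <- solve(A, c(params$deltaB, params$deltaB))
  structure(list(C_star = sol[1], P_star = sol[2],
                 positive = sol[1] > 0 && sol[2] > 0),
            class = "coexistence_point")
}

#' @export
print.coexistence_point <- function(x, ...) {
  cat(sprintf("ZNGI intersection: C* = %g, P* = %g%s\n", x$C_star, x$P_star,
              if (x$positive) "" else "  (outside the positive quadrant)"))
  invisible(x)
}

#' Nutrient-supply-rate regime boundaries
#'
#' The four critical nutrient supply rates of the model:
#' \describe{
#'   \item{`phi_B1`}{`deltaC*deltaB/lambda1` - below it the environment is
#'     abiotic; above it the fast grower B1 survives.}
#'   \item{`phi_P1`}{supply rate above which the phage persists in the
#'     B1-dominated ecosystem.}
#'   \item{`phi1`}{upper end of the bistable window: above it the
#'     B1-dominated state is invadable by B2 and disappears.}
#'   \item{`phi2`}{lower end of the bistable window: below it the
#'     B2-dominated state is invadable by B1 and disappears.}
#' }
#' `phi_P1` and `phi1` are `+Inf` when `beta1*eta1 == 0` (perfect abortive
#' infection in B1: the phage never persists on B1 alone and B1 is never
#' displaced), and likewise `phi2` is `+Inf` when `beta2*eta2 == 0`.  When
#' the ZNGI intersection is not in the positive quadrant, `phi1`/`phi2` are
#' undefined and returned as `NA` with a `note` explaining why.
#'
#' @param params a [model_params()] object with `lambda1 > 0`.
#' @return A list of class `phi_thresholds` with elements `phi_B1`, `phi_P1`,
#'   `phi1`, `phi2` and possibly `note`.
#' @examples
#' phi_thresholds(model_params())
#' @export
phi_thresholds <- function(params) {
  if (params$lambda1 <= 0)
    stop("phi thresholds require lambda1 > 0", call. = FALSE)
  th <- with(params, {
    phi_B1 <- deltaC * deltaB / lambda1
    s1 <- if (beta1 * eta1 > 0) lambda1 / (Y1 * beta1 * eta1) else Inf
    s2 <- if (beta2 * eta2 > 0) lambda2 / (Y2 * beta2 * eta2) else Inf
    phi_P1 <- if (is.finite(s1)) phi_B1 * (1 + (deltaP / deltaC) * s1) else Inf
    list(phi_B1 = phi_B1, phi_P1 = phi_P1, s1 = s1, s2 = s2)
  })
  cp <- coexistence_point(params)
  if (!cp$positive) {
    th$phi1 <- NA_real_
    th$phi2 <- NA_real_
    th$note <- "no positive coexistence point: phi1 and phi2 are undefined"
  } else {
    th$phi1 <- with(params,
                    if (is.finite(th$s1)) cp$C_star * deltaP * (th$s1 + deltaC / deltaP)
                    else Inf)
    th$phi2 <- with(params,
                    if (is.finite(th$s2)) cp$C_star * deltaP * (th$s2 + deltaC / deltaP)
                    else Inf)
  }
  th$s1 <- th$s2 <- NULL
  structure(th, class = "phi_thresholds")
}

#' @export
print.phi_thresholds <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else format(v, digits = 6)
  cat("Nutrient-supply regime boundaries:\n")
  cat("  phi_B1 (B1 survival)        :", fmt(x$phi_B1), "\n")
  cat("  phi_P1 (phage persistence)  :", fmt(x$phi_P1), "\n")
  cat("  phi2   (lower window edge)  :", fmt(x$phi2), "\n")
  cat("  phi1   (upper window edge)  :", fmt(x$phi1), "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Classify the competition regime
#'
#' Evaluates the three inequalities that govern whether the two species can
#' mutually exclude each other: (i) `lambda1 > lambda2` (species 1 grows
#' faster), (ii) `lambda1/eta1 < lambda2/eta2` (species 1 is more susceptible
#' per unit growth), and (iii) `lambda1/(Y1 beta1 eta1) >
#' lambda2/(Y2 beta2 eta2)` (species 2 converts nutrient into phage more
#' efficiently).  All three true gives bistability; (i) and (ii) true with
#' (iii) reversed gives dynamically stable coexistence; anything else is
#' neither.  Zero denominators are treated as infinite ratios, never as
#' division faults.
#'
#' @param params a [model_params()] object.
#' @return A list with `regime` (one of `"bistable"`,
#'   `"stable_coexistence"`, `"neither"`) and the logical vector
#'   `conditions` (`growth`, `susceptibility`, `stoichiometry`).
#' @examples
#' bistability_class(model_params())$regime            # "bistable"
#' bistability_class(model_params(beta2 = 2))$regime   # "stable_coexistence"
#' @export
bistability_class <- function(params) {
  ratio <- function(num, den) {
    if (den > 0) num / den else if (num > 0) Inf else NaN
  }
  cond <- with(params, c(
    growth = lambda1 > lambda2,
    susceptibility = ratio(lambda1, eta1) < ratio(lambda2, eta2),
    stoichiometry = ratio(lambda1, Y1 * beta1 * eta1) >
                    ratio(lambda2, Y2 * beta2 * eta2)
  ))
  cond[is.na(cond)] <- FALSE
  regime <- if (cond[["growth"]] && cond[["susceptibility"]]) {
    if (cond[["stoichiometry"]]) "bistable" else "stable_coexistence"
  } else "neither"
  list(regime = regime, conditions = cond)
}

#' Does the phage persist throughout the bistable window?
#'
#' `TRUE` when the phage is present in both alternative stable states for
#' every supply rate in the bistable window, i.e. `phi2 > phi_P1`.  When
#' false (e.g. in the abortive-infection limit where `phi_P1 = Inf`), the
#' lower part of the window has a phage-free B1-dominated state.
#'
#' @param params a [model_params()] object.
#' @return Logical scalar.
#' @export
phage_persists_in_F <- function(params) {
  th <- phi_thresholds(params)
  isTRUE(th$phi2 > th$phi_P1)
}

#' Abundances of the stable coexistence state
#'
#' In the stable-coexistence regime the two bacterial abundances solve the
#' linear system `beta1 eta1 B1 + beta2 eta2 B2 = deltaP` (phage balance)
#' and `lambda1 B1/Y1 + lambda2 B2/Y2 = phi/C* - deltaC` (nutrient balance
#' at `C = C*`).
#'
#' @param params a [model_params()] object.
#' @param phi nutrient supply rate.
#' @return Named numeric vector `c(B1, B2)` (components may be negative when
#'   `phi` lies outside the coexistence window; callers check positivity).
#' @export
coexistence_abundances <- function(params, phi = params$phi) {
  cp <- coexistence_point(params)
  if (!cp$positive)
    stop("no positive coexistence point: coexistence abundances undefined",
         call. = FALSE)
  A <- with(params, rbind(c(beta1 * eta1, beta2 * eta2),
                          c(lambda1 / Y1, lambda2 / Y2)))
  rhs <- c(params$deltaP, phi / cp$C_star - params$deltaC)
  sol <- solve(A, rhs)
  c(B1 = sol[1], B2 = sol[2])
}

# eigenvalue-based stability verdict; strict threshold with a tolerance band
# for marginal cases (reported as NA, never silently classified)
stability_verdict <- function(eigenvalues, tol = 1e-9) {
  m <- max(Re(eigenvalues))
  if (m < -tol) TRUE else if (m > tol) FALSE else NA
}

make_report <- function(label, state, params) {
  state <- as_eco_state(pmax(state, 0))
  ev <- eigen(model_jacobian(state, params), only.values = TRUE)$values
  structure(list(label = label, state = state, eigenvalues = ev,
                 max_re = max(Re(ev)), stable = stability_verdict(ev)),
            class = "steady_state_report")
}

#' @export
print.steady_state_report <- function(x, ...) {
  st <- if (isTRUE(x$stable)) "stable" else if (isFALSE(x$stable)) "unstable"
        else "marginal"
  cat(sprintf("%-8s C=%-9.4g B1=%-9.4g B2=%-9.4g P=%-9.4g  max Re(eig)=%.3g (%s)\n",
              x$label, x$state[1], x$state[2], x$state[3], x$state[4],
              x$max_re, st))
  invisible(x)
}

#' Closed-form steady states at a given nutrient supply rate
#'
#' Enumerates the uninvadable steady states of the ecosystem at supply rate
#' `phi`:
#' \describe{
#'   \item{ABIOTIC}{`C = phi/deltaC`, everything else absent.}
#'   \item{B1_ONLY}{fast grower alone, phage not yet sustainable.}
#'   \item{F}{B1 + phage: `B1 = deltaP/(beta1 eta1)`,
#'     `C = phi/(deltaC + lambda1 B1/Y1)`, `P = (lambda1 C - deltaB)/eta1`.}
#'   \item{S}{B2 + phage, by the same formulas with species-2 constants.}
#'   \item{U}{the dynamically unstable coexistence state inside the bistable
#'     window, at `(C*, P*)` with bacterial abundances interpolating linearly
#'     between the window edges.}
#'   \item{COEX}{the stable coexistence state, in the stable-coexistence
#'     regime.}
#' }
#' States whose abundances would be negative at this `phi` are omitted; the
#' abiotic state always exists.  Each state is reported with the eigenvalues
#' of the Jacobian and a strict stability verdict (marginal spectra give
#' `stable = NA`).
#'
#' @param params a [model_params()] object.
#' @param phi nutrient supply rate (defaults to `params$phi`).
#' @param include_invadable also return invadable single-species and
#'   single-species-plus-phage states (e.g. B2-only at low `phi`, B1 + phage
#'   above the window); by default only uninvadable states are returned.
#' @return A list of `steady_state_report` objects, class
#'   `steady_state_list`; convert with [as.data.frame()].
#' @examples
#' steady_states(model_params(), phi = 0.25)
#' @export
steady_states <- function(params, phi = params$phi, include_invadable = FALSE) {
  if (phi < 0) stop("phi must be non-negative", call. = FALSE)
  p <- with_phi(params, phi)
  tol <- 1e-12
  out <- list()
  add <- function(label, C, B1, B2, P) {
    out[[length(out) + 1L]] <<- make_report(label, c(C, B1, B2, P), p)
  }

  add("ABIOTIC", phi / p$deltaC, 0, 0, 0)

  single <- function(lambda, Y) {
    # species alone at its break-even nutrient level C = deltaB/lambda
    C <- p$deltaB / lambda
    B <- Y * (phi - p$deltaC * C) / (C * lambda)
    c(C = C, B = B)
  }
  phage_state <- function(lambda, Y, eta, beta) {
    # species + phage: B pinned by phage balance, C by nutrient balance
    B <- p$deltaP / (beta * eta)
    C <- phi / (p$deltaC + lambda * B / Y)
    P <- (lambda * C - p$deltaB) / eta
    c(C = C, B = B, P = P)
  }
  uninv <- function(state) all(invasion_rates(state, p) <= tol)

  # B1 alone
  s <- single(p$lambda1, p$Y1)
  if (s[["B"]] > tol) {
    st <- c(s[["C"]], s[["B"]], 0, 0)
    if (include_invadable || uninv(st)) add("B1_ONLY", st[1], st[2], st[3], st[4])
  }
  # B2 alone (invadable whenever lambda1 > lambda2; kept behind the flag)
  if (include_invadable && p$lambda2 > 0) {
    s <- single(p$lambda2, p$Y2)
    if (s[["B"]] > tol) add("B2_ONLY", s[["C"]], 0, s[["B"]], 0)
  }
  # F: B1 + phage
  if (p$beta1 * p$eta1 > 0) {
    s <- phage_state(p$lambda1, p$Y1, p$eta1, p$beta1)
    if (s[["P"]] > tol) {
      st <- c(s[["C"]], s[["B"]], 0, s[["P"]])
      if (include_invadable || uninv(st)) add("F", st[1], st[2], st[3], st[4])
    }
  }
  # S: B2 + phage
  if (p$beta2 * p$eta2 > 0) {
    s <- phage_state(p$lambda2, p$Y2, p$eta2, p$beta2)
    if (s[["P"]] > tol) {
      st <- c(s[["C"]], 0, s[["B"]], s[["P"]])
      if (include_invadable || uninv(st)) add("S", st[1], st[2], st[3], st[4])
    }
  }
  # coexistence states at (C*, P*)
  cls <- bistability_class(p)
  th <- phi_thresholds(p)
  if (!is.na(th$phi1) && !is.na(th$phi2)) {
    cp <- coexistence_point(p)
    if (cls$regime == "bistable" &&
        is.finite(th$phi1) && is.finite(th$phi2) &&
        phi > th$phi2 + tol && phi < th$phi1 - tol) {
      B1u <- (p$deltaP / (p$beta1 * p$eta1)) *
        (phi - th$phi2) / (th$phi1 - th$phi2)
      B2u <- (p$deltaP / (p$beta2 * p$eta2)) *
        (th$phi1 - phi) / (th$phi1 - th$phi2)
      add("U", cp$C_star, B1u, B2u, cp$P_star)
    }
    if (cls$regime == "stable_coexistence" &&
        phi > th$phi1 + tol && phi < th$phi2 - tol) {
      ab <- coexistence_abundances(p, phi)
      if (all(ab > tol)) add("COEX", cp$C_star, ab[["B1"]], ab[["B2"]],
                             cp$P_star)
    }
  }
  structure(out, class = "steady_state_list", phi = phi, params = params)
}

#' @export
print.steady_state_list <- function(x, ...) {
  cat(sprintf("Steady states at phi = %g:\n", attr(x, "phi")))
  for (s in x) print(s)
  invisible(x)
}

#' @export
as.data.frame.steady_state_list <- function(x, ...) {
  do.call(rbind, lapply(x, function(s) {
    data.frame(label = s$label, C = s$state[[1]], B1 = s$state[[2]],
               B2 = s$state[[3]], P = s$state[[4]], max_re = s$max_re,
               stable = s$stable)
  }))
}

#' Environment jumps at the edges of the hysteresis loop
#'
#' The `(C, P)` environment points the ecosystem lands on immediately after
#' the two discontinuous regime shifts of the hysteresis loop: just above
#' `phi1` species 2 takes over and the environment jumps to
#' `(C2x, P2x)` on the slow grower's ZNGI; just below `phi2` species 1 takes
#' over and the environment jumps to `(C1x, P1x)` on the fast grower's ZNGI.
#'
#' @param params a bistable [model_params()] object (error otherwise).
#' @return Named list with `C1x`, `P1x`, `C2x`, `P2x`.
#' @examples
#' jump_states(model_params())  # C2x = 3.09, P2x = 15.14, ...
#' @export
jump_states <- function(params) {
  if (bistability_class(params)$regime != "bistable")
    stop("jump states are defined only for bistable parameter sets",
         call. = FALSE)
  th <- phi_thresholds(params)
  with(params, {
    C2x <- th$phi1 / (deltaC + deltaP * lambda2 / (Y2 * beta2 * eta2))
    P2x <- (lambda2 * C2x - deltaB) / eta2
    C1x <- th$phi2 / (deltaC + deltaP * lambda1 / (Y1 * beta1 * eta1))
    P1x <- (lambda1 * C1x - deltaB) / eta1
    list(C1x = C1x, P1x = P1x, C2x = C2x, P2x = P2x)
  })
}
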