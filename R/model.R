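#' Ecosystem state
#'
#' One point in the four-dimensional phase space of the model: nutrient
#' concentration `C`, bacterial densities `B1` and `B2`, phage density `P`
#' (all in dimensionless model units, all non-negative).  State vectors are
#' ordered `(C, B1, B2, P)` everywhere in the package, including file output.
#'
#' @param C nutrient concentration.
#' @param B1,B2 bacterial population densities.
#' @param P phage population density.
#' @return A named numeric vector of class `eco_state`.
#' @examples
#' eco_state(C = 1, B1 = 0.3, B2 = 0.1, P = 2)
#' @export
eco_state <- function(C = 0, B1 = 0, B2 = 0, P = 0) {
  as_eco_state(c(C, B1, B2, P))
}

#' @rdname eco_state
#' @param x a numeric vector of length 4 in `(C, B1, B2, P)` order.
#' @export
as_eco_state <- function(x) {
  x <- unclass(x)
  if (!is.numeric(x) || length(x) != 4L || any(!is.finite(x)))
    stop("an ecosystem state is 4 finite numbers (C, B1, B2, P)", call. = FALSE)
  structure(as.numeric(x), names = c("C", "B1", "B2", "P"),
            class = "eco_state")
}

#' @export
print.eco_state <- function(x, ...) {
  cat(sprintf("eco_state: C = %g, B1 = %g, B2 = %g, P = %g\n",
              x[1], x[2], x[3], x[4]))
  invisible(x)
}

check_state <- function(state) {
  state <- as_eco_state(state)
  if (any(state < 0))
    stop("negative state component (", paste(signif(state, 6), collapse = ", "),
         "): states must be non-negative", call. = FALSE)
  state
}

#' Right-hand side of the ecosystem dynamics
#'
#' Time derivatives of `(C, B1, B2, P)`: nutrient is supplied at rate `phi`,
#' diluted at `deltaC` and consumed at `lambda_i C B_i / Y_i`; each bacterial
#' species grows at `lambda_i C`, is adsorbed by phage at `eta_i P` and dies
#' at `deltaB`; phage gain `beta_i eta_i B_i` per unit phage and decay at
#' `deltaP`.
#'
#' @param state an [eco_state()] (or numeric vector of length 4); components
#'   must be non-negative.
#' @param params a [model_params()] object; `params$phi` is the supply rate
#'   used.
#' @return Named numeric vector of the four derivatives.
#' @examples
#' model_rhs(eco_state(1, 0.3, 0.1, 2), model_params())
#' @export
model_rhs <- function(state, params) {
  s <- check_state(state)
  C <- s[[1]]; B1 <- s[[2]]; B2 <- s[[3]]; P <- s[[4]]
  with(params, c(
    C  = phi - deltaC * C - C * (lambda1 * B1 / Y1 + lambda2 * B2 / Y2),
    B1 = B1 * (lambda1 * C - eta1 * P - deltaB),
    B2 = B2 * (lambda2 * C - eta2 * P - deltaB),
    P  = P * (beta1 * eta1 * B1 + beta2 * eta2 * B2 - deltaP)
  ))
}

#' Jacobian of the ecosystem dynamics
#'
#' Analytic 4x4 matrix of partial derivatives of [model_rhs()] with respect
#' to the state, used for linear stability analysis of steady states and as
#' the stiff-solver Jacobian.
#'
#' @inheritParams model_rhs
#' @return A 4x4 numeric matrix with rows/columns named `C, B1, B2, P`.
#' @export
model_jacobian <- function(state, params) {
  s <- check_state(state)
  C <- s[[1]]; B1 <- s[[2]]; B2 <- s[[3]]; P <- s[[4]]
  with(params, {
    J <- matrix(0, 4, 4, dimnames = list(names(s), names(s)))
    J[1, 1] <- -deltaC - (lambda1 * B1 / Y1 + lambda2 * B2 / Y2)
    J[1, 2] <- -C * lambda1 / Y1
    J[1, 3] <- -C * lambda2 / Y2
    J[2, 1] <- B1 * lambda1
    J[2, 2] <- lambda1 * C - eta1 * P - deltaB
    J[2, 4] <- -B1 * eta1
    J[3, 1] <- B2 * lambda2
    J[3, 3] <- lambda2 * C - eta2 * P - deltaB
    J[3, 4] <- -B2 * eta2
    J[4, 2] <- P * beta1 * eta1
    J[4, 3] <- P * beta2 * eta2
    J[4, 4] <- beta1 * eta1 * B1 + beta2 * eta2 * B2 - deltaP
    J
  })
}

# per-capita net growth rates of (B1, B2, P) in the environment set by `state`;
# what an infinitesimal inoculum of each species would experience
invasion_rates <- function(state, params) {
  C <- state[[1]]; B1 <- state[[2]]; B2 <- state[[3]]; P <- state[[4]]
  with(params, c(
    B1 = lambda1 * C - eta1 * P - deltaB,
    B2 = lambda2 * C - eta2 * P - deltaB,
    P  = beta1 * eta1 * B1 + beta2 * eta2 * B2 - deltaP
  ))
}
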