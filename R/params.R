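#' @useDynLib phageshift
#' @importFrom stats simulate
#' @keywords internal
"_PACKAGE"

# canonical parameter order; the C code and all serialization rely on it
.param_names <- c("lambda1", "lambda2", "Y1", "Y2", "eta1", "eta2",
                  "beta1", "beta2", "deltaC", "deltaB", "deltaP", "phi")

#' Model parameters for the phage-bacterium ecosystem
#'
#' Bundles the eleven rate/stoichiometry constants of the two-bacteria /
#' one-phage / one-nutrient model together with the nutrient supply rate
#' `phi`.  The defaults are the bistable reference parameter set used
#' throughout the package's examples and tests.
#'
#' The dynamics they parameterize are
#' \deqn{dC/dt   = \phi - \delta_C C - C(\lambda_1 B_1/Y_1 + \lambda_2 B_2/Y_2)}
#' \deqn{dB_i/dt = B_i(\lambda_i C - \eta_i P - \delta_B)}
#' \deqn{dP/dt   = P(\beta_1\eta_1 B_1 + \beta_2\eta_2 B_2 - \delta_P)}
#'
#' All quantities are in dimensionless model units.
#'
#' @param lambda1,lambda2 growth-rate coefficients (per nutrient per time);
#'   species 1 is the fast grower (`lambda1 > lambda2` in the regimes of
#'   interest).
#' @param Y1,Y2 nutrient yields (biomass produced per unit nutrient consumed);
#'   must be positive.
#' @param eta1,eta2 phage adsorption coefficients (per phage per time).
#' @param beta1,beta2 burst sizes (phage progeny per lysed cell).  A burst
#'   size of 0 with positive adsorption is the perfect abortive-infection
#'   limit.
#' @param deltaC,deltaB,deltaP dilution/death rates of nutrient, bacteria and
#'   phage (per time).
#' @param phi nutrient supply rate (nutrient per time).
#' @return An object of class `model_params` (a named list).
#' @seealso [fig1_defaults()], [read_params()], [steady_states()]
#' @examples
#' p <- model_params()
#' p
#' phi_thresholds(p)
#' @export
model_params <- function(lambda1 = 1, lambda2 = 0.8, Y1 = 1, Y2 = 1,
                         eta1 = 0.2, eta2 = 0.15, beta1 = 2, beta2 = 40,
                         deltaC = 0.2, deltaB = 0.2, deltaP = 0.2,
                         phi = 0.66) {
  p <- list(lambda1 = lambda1, lambda2 = lambda2, Y1 = Y1, Y2 = Y2,
            eta1 = eta1, eta2 = eta2, beta1 = beta1, beta2 = beta2,
            deltaC = deltaC, deltaB = deltaB, deltaP = deltaP, phi = phi)
  validate_params(p)
}

validate_params <- function(p) {
  for (nm in .param_names) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be non-negative (got ", v, ")",
           call. = FALSE)
  }
  if (p$Y1 <= 0 || p$Y2 <= 0)
    stop("yields Y1 and Y2 must be strictly positive", call. = FALSE)
  structure(lapply(p[.param_names], as.numeric), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Phage-bacterium ecosystem parameters\n")
  cat(sprintf("  growth      lambda1 = %-8g lambda2 = %g\n", x$lambda1, x$lambda2))
  cat(sprintf("  yield       Y1      = %-8g Y2      = %g\n", x$Y1, x$Y2))
  cat(sprintf("  adsorption  eta1    = %-8g eta2    = %g\n", x$eta1, x$eta2))
  cat(sprintf("  burst size  beta1   = %-8g beta2   = %g\n", x$beta1, x$beta2))
  cat(sprintf("  loss rates  deltaC  = %-8g deltaB  = %-8g deltaP = %g\n",
              x$deltaC, x$deltaB, x$deltaP))
  cat(sprintf("  supply      phi     = %g\n", x$phi))
  invisible(x)
}

# numeric vector in canonical order, as passed to the compiled code
param_vector <- function(p) {
  vapply(.param_names, function(nm) p[[nm]], numeric(1))
}

# copy of params with a different nutrient supply rate
with_phi <- function(p, phi) {
  p$phi <- phi
  p
}

#' Reference parameter set of the bistable ecosystem
#'
#' Loads the packaged `fig1_defaults` fixture: the parameter set
#' (lambda1 = 1, lambda2 = 0.8, Y1 = Y2 = 1, eta1 = 0.2, eta2 = 0.15,
#' beta1 = 2, beta2 = 40, deltaC = deltaB = deltaP = 0.2, phi = 0.66)
#' for which the ecosystem is bistable for nutrient supply rates between
#' about 0.227 and 0.7.  Identical to `model_params()` called with no
#' arguments, but read from the shipped config file so the file and the
#' code cannot drift apart silently.
#'
#' @return A `model_params` object.
#' @export
fig1_defaults <- function() {
  read_params(system.file("extdata", "fig1_defaults.yaml",
                          package = "phageshift", mustWork = TRUE))
}

#' Random parameter sets satisfying the bistability inequalities
#'
#' Draws parameter sets in the bistable regime: fast grower more susceptible
#' per unit growth (`lambda1/eta1 < lambda2/eta2`) and producing fewer phage
#' per unit nutrient (`lambda1/(Y1 beta1 eta1) > lambda2/(Y2 beta2 eta2)`).
#' Used for property-style testing of the analytic machinery; sets with a
#' degenerate or extremely narrow bistable window are rejected and redrawn.
#'
#' @param n number of parameter sets.
#' @param phage_in_both if `TRUE` (default) additionally require the phage to
#'   persist in the fast-grower state throughout the bistable window
#'   (`phi_P1` below `phi2`), so both alternative states carry phage.
#' @return A list of `n` `model_params` objects.
#' @export
random_bistable_params <- function(n = 1, phage_in_both = TRUE) {
  draw <- function() {
    l1 <- stats::runif(1, 0.8, 1.5)
    l2 <- l1 * stats::runif(1, 0.6, 0.95)
    e1 <- stats::runif(1, 0.1, 0.4)
    e2 <- e1 * (l2 / l1) * stats::runif(1, 0.4, 0.9)
    b1 <- stats::runif(1, 1, 5)
    b2min <- l2 * b1 * e1 / (e2 * l1)
    b2 <- b2min * stats::runif(1, 2, 8)
    dl <- stats::runif(3, 0.1, 0.3)
    model_params(lambda1 = l1, lambda2 = l2, Y1 = 1, Y2 = 1,
                 eta1 = e1, eta2 = e2, beta1 = b1, beta2 = b2,
                 deltaC = dl[1], deltaB = dl[2], deltaP = dl[3], phi = 0.5)
  }
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    p <- draw()
    cls <- bistability_class(p)
    if (cls$regime != "bistable") next
    th <- phi_thresholds(p)
    if (!is.finite(th$phi1) || !is.finite(th$phi2)) next
    if (th$phi1 - th$phi2 < 0.05 * th$phi2) next
    if (phage_in_both && th$phi_P1 >= th$phi2 - 0.02 * (th$phi1 - th$phi2)) next
    out[[i]] <- p
    i <- i + 1L
  }
  out
}
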