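# exact steady state used as the launch point of a pulse experiment;
# absent species sit at the influx floor
start_state <- function(params, phi, label, floor = 4e-4) {
  ss <- steady_states(params, phi)
  hit <- Filter(function(s) s$label == label, ss)
  if (!length(hit))
    stop("no '", label, "' steady state exists at phi = ", phi, call. = FALSE)
  st <- as.numeric(hit[[1]]$state)
  st[2:4] <- pmax(st[2:4], floor)
  as_eco_state(st)
}

# the stable state a pulse experiment tries to reach; B1_ONLY stands in for
# the B1-dominated state when the phage cannot persist on B1 (abortive limit)
opposite_label <- function(start) switch(start,
  F = "S", B1_ONLY = "S", S = "F", B2_ONLY = "F",
  stop("pulse experiments start from a B1- or B2-dominated state",
       call. = FALSE))

pulse_amount <- function(params, phi, variable, magnitude, normalize,
                         target) {
  if (normalize == "raw") return(magnitude)
  tg <- start_state(params, phi, target, floor = 0)
  magnitude * tg[[variable]]
}

#' Apply a single population pulse and classify the outcome
#'
#' Starts the system in the exact analytic stable state `start` (absent
#' species at the influx floor), instantaneously adds a pulse to one
#' variable, integrates for `t_relax` time units with the floor on, and
#' classifies the final state.  With `normalize = "target"` (the default)
#' the magnitude is expressed as a multiple of that variable's value in the
#' opposite (target) stable state at the same supply rate; `"raw"` adds the
#' magnitude as-is.
#'
#' @param params a [model_params()] object.
#' @param phi nutrient supply rate.
#' @param start label of the starting stable state, `"F"` or `"S"`.
#' @param variable which variable to pulse: `"C"`, `"B1"`, `"B2"` or `"P"`.
#' @param magnitude pulse size (non-negative), interpreted per `normalize`.
#' @param normalize `"target"` or `"raw"`.
#' @param t_relax post-pulse relaxation time (default 1000).
#' @param floor influx floor during relaxation (default `4e-4`).
#' @param classify_tol relative tolerance for [classify_state()].
#' @return The final regime label (character), with the final state in
#'   attribute `"final"`.
#' @examples
#' p <- model_params()
#' apply_pulse(p, phi = 0.4, start = "F", variable = "P", magnitude = 2)
#' @export
apply_pulse <- function(params, phi, start = "F", variable = "P", magnitude,
                        normalize = c("target", "raw"), t_relax = 1000,
                        floor = 4e-4, classify_tol = 0.05) {
  normalize <- match.arg(normalize)
  stopifnot(magnitude >= 0, variable %in% c("C", "B1", "B2", "P"))
  target <- opposite_label(start)
  init <- start_state(params, phi, start, floor)
  init[[variable]] <- init[[variable]] +
    pulse_amount(params, phi, variable, magnitude, normalize, target)
  fin <- relax_state(params, init, phi, t_relax, floor, extend = 1)
  structure(classify_state(fin, params, phi, floor, classify_tol),
            final = fin)
}

#' Pulse outcome over a (phi, magnitude) grid
#'
#' Runs [apply_pulse()] on every cell of a rectangular grid of supply rates
#' and pulse magnitudes, recording the final regime label of each cell.
#'
#' @inheritParams apply_pulse
#' @param phi_values grid of supply rates.
#' @param magnitudes grid of pulse magnitudes; the default is 200
#'   log-spaced values between 0.01 and 3 times the target-state value.
#' @return A `pulse_grid`: list with `phi`, `magnitudes`, `start`, `target`,
#'   `variable`, `normalize` and the character `outcome` matrix
#'   (rows = magnitudes, columns = phi values).
#' @seealso [switching_boundary()]
#' @export
pulse_scan <- function(params, phi_values,
                       magnitudes = exp(seq(log(0.01), log(3),
                                            length.out = 200)),
                       start = "F", variable = "P",
                       normalize = c("target", "raw"), t_relax = 1000,
                       floor = 4e-4, classify_tol = 0.05) {
  normalize <- match.arg(normalize)
  stopifnot(length(phi_values) > 0, length(magnitudes) > 0)
  target <- opposite_label(start)
  out <- matrix(NA_character_, length(magnitudes), length(phi_values),
                dimnames = list(NULL, signif(phi_values, 8)))
  for (j in seq_along(phi_values)) {
    phi <- phi_values[j]
    init0 <- start_state(params, phi, start, floor)
    amt1 <- pulse_amount(params, phi, variable, 1, normalize, target)
    for (i in seq_along(magnitudes)) {
      init <- init0
      init[[variable]] <- init[[variable]] + magnitudes[i] * amt1
      fin <- relax_state(params, init, phi, t_relax, floor, extend = 1)
      out[i, j] <- classify_state(fin, params, phi, floor, classify_tol)
    }
  }
  structure(list(phi = phi_values, magnitudes = magnitudes, start = start,
                 target = target, variable = variable, normalize = normalize,
                 outcome = out, params = params,
                 settings = list(t_relax = t_relax, floor = floor)),
            class = "pulse_grid")
}

#' @export
print.pulse_grid <- function(x, ...) {
  succ <- x$outcome == x$target
  cat(sprintf("pulse grid: %s pulses on state %s (target %s), %d phi x %d magnitudes\n",
              x$variable, x$start, x$target, length(x$phi),
              length(x$magnitudes)))
  cat(sprintf("  switching cells: %d of %d\n", sum(succ), length(succ)))
  ok <- colSums(succ) > 0
  if (any(ok))
    cat(sprintf("  switching possible for phi in [%g, %g]\n",
                min(x$phi[ok]), max(x$phi[ok])))
  else cat("  no switching possible anywhere on the grid\n")
  invisible(x)
}

#' @export
plot.pulse_grid <- function(x, ...) {
  succ <- t(x$outcome == x$target)  # phi on x, magnitude on y
  graphics::image(x$phi, x$magnitudes, succ + 0, log = "y",
                  col = c("grey85", "dodgerblue3"), xlab = "phi",
                  ylab = sprintf("pulse of %s (x target value)", x$variable),
                  main = sprintf("switch %s -> %s", x$start, x$target), ...)
  invisible(x)
}

#' Extremal supply rate at which pulse switching succeeds
#'
#' Scans the columns of a [pulse_scan()] grid for cells whose final label is
#' the target state and returns the largest (`"max_phi"`) or smallest
#' (`"min_phi"`) supply rate whose column contains at least one switching
#' cell.  The answer is resolved to one grid step.
#'
#' @param grid a `pulse_grid`.
#' @param which `"max_phi"` or `"min_phi"`.
#' @return The boundary supply rate, or `NA` (with a message attribute) when
#'   no cell switches anywhere.
#' @export
switching_boundary <- function(grid, which = c("max_phi", "min_phi")) {
  which <- match.arg(which)
  ok <- colSums(grid$outcome == grid$target) > 0
  if (!any(ok))
    return(structure(NA_real_, note = "no switching possible"))
  if (which == "max_phi") max(grid$phi[ok]) else min(grid$phi[ok])
}

#' Simultaneous pulses of several variables
#'
#' Applies pulses to several variables at once before integrating - e.g. the
#' phage-therapy scenario where phage and a slower-growing susceptible
#' competitor are introduced together into the fast-grower-dominated state.
#'
#' @inheritParams apply_pulse
#' @param magnitudes named numeric vector of pulse sizes, names among
#'   `C, B1, B2, P`; interpreted per `normalize` (target-state multiples or
#'   raw amounts).
#' @return The final regime label with the final state in attribute
#'   `"final"`.
#' @examples
#' abi <- model_params(beta1 = 0)  # perfect abortive infection in B1
#' combined_pulse(abi, phi = 0.4, start = "B1_ONLY",
#'                magnitudes = c(B2 = 0.05, P = 8), normalize = "raw")
#' @export
combined_pulse <- function(params, phi, start = "F", magnitudes,
                           normalize = c("target", "raw"), t_relax = 1000,
                           floor = 4e-4, classify_tol = 0.05) {
  normalize <- match.arg(normalize)
  stopifnot(length(magnitudes) > 0, !is.null(names(magnitudes)),
            all(names(magnitudes) %in% c("C", "B1", "B2", "P")),
            all(magnitudes >= 0))
  init <- start_state(params, phi, start, floor)
  if (normalize == "target") {
    target <- opposite_label(start)
    tg <- start_state(params, phi, target, floor = 0)
    for (v in names(magnitudes))
      init[[v]] <- init[[v]] + magnitudes[[v]] * tg[[v]]
  } else {
    for (v in names(magnitudes))
      init[[v]] <- init[[v]] + magnitudes[[v]]
  }
  fin <- relax_state(params, init, phi, t_relax, floor, extend = 1)
  structure(classify_state(fin, params, phi, floor, classify_tol),
            final = fin)
}

#' Place the system at an arbitrary state and classify where it settles
#'
#' The full-state control operation: set all four variables to chosen
#' values, integrate for `t_relax`, classify.  With the floor disabled this
#' also serves as a basin-membership oracle.
#'
#' @inheritParams apply_pulse
#' @param state the post-intervention [eco_state()].
#' @return The final regime label with the final state in attribute
#'   `"final"`.
#' @export
place_state <- function(params, phi, state, t_relax = 1000, floor = 4e-4,
                        classify_tol = 0.05) {
  fin <- relax_state(params, state, phi, t_relax, floor, extend = 1)
  structure(classify_state(fin, params, phi, floor, classify_tol),
            final = fin)
}
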