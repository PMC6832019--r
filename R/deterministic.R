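#' Integrate the ecosystem dynamics
#'
#' Solves the four coupled ODEs with `deSolve::ode` (lsoda, analytic
#' Jacobian supplied) from `init` to `t_end`.  Unless disabled, a weak
#' species influx is emulated by clamping `B1`, `B2` and `P` up to `floor`
#' at regular intervals (`clamp_dt`), so any species whose net growth rate
#' turns positive can (re)invade; the nutrient is never clamped above 0.
#'
#' @param params a [model_params()] object (`params$phi` is the supply rate).
#' @param init initial [eco_state()]; non-negative.
#' @param t_end integration time (model time units).
#' @param floor minimum species level maintained by the influx (default
#'   `4e-4`); `0` or `NULL` disables the floor.
#' @param clamp_dt interval between clamp events (default 1 time unit).
#' @param sample_dt optional output thinning: keep only rows on this grid.
#' @param rtol,atol integrator tolerances.
#' @return An `eco_trajectory`: a data frame with columns
#'   `time, C, B1, B2, P` and the run settings in attributes.
#' @examples
#' p <- model_params(phi = 0.4)
#' tr <- integrate_model(p, eco_state(2, 4e-4, 4e-4, 4e-4), t_end = 200)
#' final_state(tr)
#' @export
integrate_model <- function(params, init, t_end = 1000, floor = 4e-4,
                            clamp_dt = 1, sample_dt = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  init <- check_state(init)
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be positive",
                                             call. = FALSE)
  if (is.null(floor) || isFALSE(floor)) floor <- 0
  times <- seq(0, t_end, by = clamp_dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  pv <- c(param_vector(params), floor)
  ev <- if (floor > 0) list(func = "ps_event", time = times[-1]) else NULL
  out <- deSolve::ode(y = unclass(init), times = times, func = "ps_derivs",
                      parms = pv, jacfunc = "ps_jac", jactype = "fullusr",
                      dllname = "phageshift", initfunc = "ps_initmod",
                      events = ev, rtol = rtol, atol = atol)
  m <- unclass(out)
  if (any(!is.finite(m)))
    stop("integration failure: non-finite state reached (phi = ", params$phi,
         ", init = ", paste(signif(init, 4), collapse = ", "), ")",
         call. = FALSE)
  df <- as.data.frame(m)
  names(df) <- c("time", "C", "B1", "B2", "P")
  if (floor > 0) {
    # states are recorded before the clamp fires; report the maintained levels
    for (v in c("B1", "B2", "P")) df[[v]] <- pmax(df[[v]], floor)
    df$C <- pmax(df$C, 0)
  }
  if (!is.null(sample_dt)) {
    keep <- abs(df$time / sample_dt - round(df$time / sample_dt)) < 1e-9
    keep[c(1, length(keep))] <- TRUE
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, class = c("eco_trajectory", "data.frame"),
            params = params, floor = floor, kind = "deterministic")
}

#' Final state of a trajectory
#'
#' @param traj an `eco_trajectory`.
#' @return The last recorded [eco_state()].
#' @export
final_state <- function(traj) {
  n <- nrow(traj)
  as_eco_state(as.numeric(traj[n, c("C", "B1", "B2", "P")]))
}

#' @export
print.eco_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("eco_trajectory (%s): %d records, t in [%g, %g]\n",
              attr(x, "kind"), n, x$time[1], x$time[n]))
  fs <- final_state(x)
  cat(sprintf("  final state: C = %.4g, B1 = %.4g, B2 = %.4g, P = %.4g\n",
              fs[1], fs[2], fs[3], fs[4]))
  invisible(x)
}

#' @export
summary.eco_trajectory <- function(object, ...) {
  s <- apply(object[c("C", "B1", "B2", "P")], 2, function(v)
    c(min = min(v), mean = mean(v), max = max(v), final = v[length(v)]))
  cat(sprintf("eco_trajectory over t in [%g, %g] (%d records)\n",
              object$time[1], object$time[nrow(object)], nrow(object)))
  print(signif(s, 5))
  invisible(s)
}

#' @export
plot.eco_trajectory <- function(x, log = "y", ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- c(C = "darkgreen", B1 = "firebrick", B2 = "dodgerblue3", P = "black")
  for (v in names(cols)) {
    y <- x[[v]]
    if (log == "y") y <- pmax(y, 1e-12)
    graphics::plot(x$time, y, type = "l", col = cols[[v]], log = log,
                   xlab = "time", ylab = v, main = v, ...)
  }
  invisible(x)
}

#' Classify a converged state against the analytic steady states
#'
#' Compares a (converged) state with every analytic steady state at this
#' supply rate and returns the label of the closest one, or `"OTHER"` when
#' none is within the relative tolerance.  A species sitting at (or below
#' twice) the influx floor counts as absent.  The distance is a relative
#' L-infinity norm: the largest relative deviation over the components
#' present in the candidate state; candidates that disagree about which
#' species are present are rejected outright.
#'
#' @param final the state to classify ([eco_state()] or length-4 numeric).
#' @param params a [model_params()] object.
#' @param phi supply rate at which the analytic states are enumerated.
#' @param floor influx floor used in the run that produced `final`.
#' @param tol relative-distance acceptance threshold (default 0.05, far
#'   below the contrast between the alternative states yet tolerant of
#'   integrator residue).
#' @return A regime label: one of `"ABIOTIC", "B1_ONLY", "B2_ONLY", "F",
#'   "S", "U", "COEX", "OTHER"`.
#' @examples
#' classify_state(c(0.357, 0.5, 4e-4, 0.786), model_params(), phi = 0.25)
#' @export
classify_state <- function(final, params, phi = params$phi, floor = 4e-4,
                           tol = 0.05) {
  f <- as.numeric(as_eco_state(final))
  absent_below <- max(2 * floor, 1e-9)
  f[f <= absent_below] <- 0
  cands <- steady_states(params, phi)
  best <- "OTHER"; bestd <- Inf
  for (s in cands) {
    sv <- as.numeric(s$state)
    if (any(sv == 0 & f > 0) || any(sv > 0 & f == 0)) next
    pres <- sv > 0
    d <- if (any(pres)) max(abs(f[pres] - sv[pres]) / sv[pres]) else 0
    if (d < bestd) { bestd <- d; best <- s$label }
  }
  if (bestd < tol) best else "OTHER"
}

# max |rhs| over components not held at the floor (convergence diagnostic)
residual_off_floor <- function(state, params, floor) {
  r <- model_rhs(state, params)
  held <- c(FALSE, as.numeric(state)[2:4] <= 2 * floor)
  max(abs(r[!held]), 0)
}

# relax from `state` at supply rate phi for t_relax; near a regime boundary
# the endpoint may still be in slow transit (a floor-held species invading at
# a tiny per-capita rate, or a slowly decaying spiral), in which case
# integration continues in t_relax chunks up to extend * t_relax total
relax_state <- function(params, state, phi, t_relax = 1000, floor = 4e-4,
                        extend = 10) {
  p <- with_phi(params, phi)
  cur <- as_eco_state(pmax(as.numeric(state), if (floor > 0) c(0, rep(floor, 3)) else 0))
  total <- 0
  repeat {
    tr <- integrate_model(p, cur, t_end = t_relax, floor = floor)
    cur <- final_state(tr)
    total <- total + t_relax
    if (total >= extend * t_relax) break
    inv <- invasion_rates(cur, p)
    held <- as.numeric(cur)[2:4] <= 2 * max(floor, 1e-9)
    invading <- floor > 0 && any(held & inv > 1e-7)
    if (!invading && residual_off_floor(cur, p, floor) < 1e-6) break
  }
  cur
}
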