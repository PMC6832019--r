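#' Quasi-static sweep of the nutrient supply rate
#'
#' Changes `phi` along a grid in steps of `dphi`, integrating the dynamics
#' for `t_relax` time units at every grid point with the endpoint of the
#' previous point as a warm start (the first point starts from the
#' nutrient-only state with all species at the floor unless `init` is
#' given).  Near a regime boundary the invasion of a floor-held species can
#' be slower than `t_relax` (critical slowing down); when a floor-held
#' species still has positive per-capita growth after `t_relax`, integration
#' continues in `t_relax` chunks up to `extend * t_relax` so the detected
#' jump is not dragged past the boundary by the protocol.
#'
#' @param params a [model_params()] object.
#' @param phi_start,phi_stop sweep range; direction follows their order.
#' @param dphi grid step (positive; default 0.01).
#' @param t_relax relaxation time per grid point (default 1000).
#' @param floor influx floor (default `4e-4`).
#' @param init optional starting [eco_state()] for the first grid point.
#' @param extend maximum relaxation extension factor near slow invasions.
#' @param classify_tol relative tolerance for [classify_state()].
#' @return A `phi_sweep`: list with `direction`, `phi`, `states` (matrix,
#'   one row per grid point), `labels`, `jump_phi` (midpoints of consecutive
#'   grid points whose labels differ), `converged` (off-floor residual below
#'   `1e-4`), and the settings.
#' @seealso [hysteresis_loop()]
#' @export
sweep_phi <- function(params, phi_start, phi_stop, dphi = 0.01,
                      t_relax = 1000, floor = 4e-4, init = NULL,
                      extend = 10, classify_tol = 0.05) {
  stopifnot(dphi > 0, t_relax > 0)
  up <- phi_stop >= phi_start
  grid <- seq(phi_start, phi_stop, by = if (up) dphi else -dphi)
  if (grid[length(grid)] != phi_stop) grid <- c(grid, phi_stop)
  n <- length(grid)
  if (is.null(init))
    init <- eco_state(grid[1] / params$deltaC, floor, floor, floor)
  states <- matrix(NA_real_, n, 4,
                   dimnames = list(NULL, c("C", "B1", "B2", "P")))
  labels <- character(n)
  conv <- logical(n)
  cur <- as_eco_state(init)
  for (i in seq_len(n)) {
    cur <- relax_state(params, cur, grid[i], t_relax, floor, extend)
    states[i, ] <- as.numeric(cur)
    labels[i] <- classify_state(cur, params, grid[i], floor, classify_tol)
    conv[i] <- residual_off_floor(cur, with_phi(params, grid[i]), floor) < 1e-4
  }
  ch <- which(labels[-1] != labels[-n])
  structure(list(direction = if (up) "up" else "down", phi = grid,
                 states = states, labels = labels,
                 jump_phi = (grid[ch] + grid[ch + 1]) / 2,
                 converged = conv, params = params,
                 settings = list(dphi = dphi, t_relax = t_relax,
                                 floor = floor, extend = extend)),
            class = "phi_sweep")
}

#' @export
print.phi_sweep <- function(x, ...) {
  cat(sprintf("phi sweep (%s): %d points, phi in [%g, %g], dphi = %g\n",
              x$direction, length(x$phi), min(x$phi), max(x$phi),
              x$settings$dphi))
  tr <- rle(x$labels)
  cat("  branch labels:", paste(tr$values, collapse = " -> "), "\n")
  if (length(x$jump_phi))
    cat("  label changes at phi =", paste(signif(x$jump_phi, 4),
                                          collapse = ", "), "\n")
  if (!all(x$converged))
    cat("  note:", sum(!x$converged), "grid point(s) flagged unconverged\n")
  invisible(x)
}

#' @export
plot.phi_sweep <- function(x, vars = c("P", "B1", "B2", "C"), ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (v in vars) {
    graphics::plot(x$phi, x$states[, v], type = "l", xlab = "phi", ylab = v,
                   main = v, ...)
    graphics::abline(v = x$jump_phi, lty = 3, col = "grey40")
  }
  invisible(x)
}

#' Full hysteresis loop in the nutrient supply rate
#'
#' Runs an upward sweep from `0` to `phi_max` and then a downward sweep back
#' to `0`, warm-starting the downward branch from the upward branch's final
#' state, and extracts the bistable interval: the supply rates of the
#' downward (S to F) and upward (F to S) regime shifts.
#'
#' @inheritParams sweep_phi
#' @param phi_max top of the loop (default 1).
#' @return A `hysteresis_loop`: list with the two `phi_sweep` branches
#'   (`up`, `down`), `jump_up` (supply rate of the F to S shift on the way
#'   up, `NA` if none), `jump_down` (S to F on the way down), `phage_onset`
#'   (supply rate at which the phage population first rises above the
#'   influx-maintained level on the way up), and
#'   `bistable_interval = c(jump_down, jump_up)`.
#' @examples
#' \donttest{
#' hl <- hysteresis_loop(model_params(), dphi = 0.05, t_relax = 300)
#' hl$bistable_interval
#' }
#' @export
hysteresis_loop <- function(params, phi_max = 1, dphi = 0.01, t_relax = 1000,
                            floor = 4e-4, extend = 10) {
  up <- sweep_phi(params, 0, phi_max, dphi, t_relax, floor, extend = extend)
  n <- length(up$phi)
  down <- sweep_phi(params, phi_max, 0, dphi, t_relax, floor,
                    init = as_eco_state(up$states[n, ]), extend = extend)
  jump_at <- function(sw, from, to) {
    i <- which(sw$labels[-length(sw$labels)] == from &
               sw$labels[-1] == to)
    if (length(i)) (sw$phi[i[1]] + sw$phi[i[1] + 1]) / 2 else NA_real_
  }
  jup <- jump_at(up, "F", "S")
  jdown <- jump_at(down, "S", "F")
  # supply rate at which the phage first becomes sustainable on the way up:
  # its standing population rises above the influx-maintained level
  ponset <- {
    above <- up$states[, "P"] > 10 * floor
    i <- which(!above[-n] & above[-1])
    if (length(i)) (up$phi[i[1]] + up$phi[i[1] + 1]) / 2 else NA_real_
  }
  structure(list(up = up, down = down, jump_up = jup, jump_down = jdown,
                 phage_onset = ponset,
                 bistable_interval = c(jdown, jup)),
            class = "hysteresis_loop")
}

#' @export
print.hysteresis_loop <- function(x, ...) {
  cat("Hysteresis loop in the nutrient supply rate\n")
  cat("  up-sweep   :", paste(rle(x$up$labels)$values, collapse = " -> "), "\n")
  cat("  down-sweep :", paste(rle(x$down$labels)$values, collapse = " -> "), "\n")
  cat(sprintf("  regime shifts: F->S at phi = %s (up), S->F at phi = %s (down)\n",
              format(x$jump_up), format(x$jump_down)))
  if (!any(is.na(x$bistable_interval)))
    cat(sprintf("  bistable interval: [%g, %g]\n",
                x$bistable_interval[1], x$bistable_interval[2]))
  invisible(x)
}

#' @export
plot.hysteresis_loop <- function(x, var = "P", ...) {
  graphics::plot(x$up$phi, x$up$states[, var], type = "l", col = "firebrick",
                 xlab = "phi", ylab = var,
                 ylim = range(x$up$states[, var], x$down$states[, var]), ...)
  graphics::lines(x$down$phi, x$down$states[, var], col = "dodgerblue3")
  graphics::legend("topleft", c("up", "down"), lty = 1, bty = "n",
                   col = c("firebrick", "dodgerblue3"))
  invisible(x)
}
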