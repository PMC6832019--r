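#' Propensities of the nine elementary processes
#'
#' The stochastic model quantizes every population in units of `quantum`
#' and turns each deterministic flux into an event rate: rate = flux /
#' quantum, so that rate x quantum recovers the flux and the
#' propensity-weighted sum of event effects equals the deterministic
#' right-hand side exactly (the drift identity).
#'
#' The nine processes are: (1) nutrient introduction, (2) nutrient dilution,
#' (3) B1 replication, (4) B2 replication, (5) phage infection of B1,
#' (6) phage infection of B2, (7) B1 death, (8) B2 death, (9) phage decay.
#'
#' @param state an [eco_state()]; non-negative.
#' @param params a [model_params()] object.
#' @param quantum population increment per event (default `2e-4`).
#' @return Named numeric vector of nine event rates (events per time).
#' @seealso [event_effects()], [simulate_gillespie()]
#' @export
event_propensities <- function(state, params, quantum = 2e-4) {
  s <- check_state(state)
  C <- s[[1]]; B1 <- s[[2]]; B2 <- s[[3]]; P <- s[[4]]
  with(params, c(
    nutrient_in  = phi / quantum,
    nutrient_out = deltaC * C / quantum,
    B1_growth    = lambda1 * C * B1 / quantum,
    B2_growth    = lambda2 * C * B2 / quantum,
    P_infect_B1  = eta1 * B1 * P / quantum,
    P_infect_B2  = eta2 * B2 * P / quantum,
    B1_death     = deltaB * B1 / quantum,
    B2_death     = deltaB * B2 / quantum,
    P_decay      = deltaP * P / quantum
  ))
}

#' State increments of the nine elementary processes
#'
#' One row per process, one column per state variable.  Replication events
#' consume `quantum / Y` of nutrient (keeping the stochastic drift identical
#' to the deterministic nutrient equation); an infection event removes one
#' quantum of the host and releases `beta * quantum` of phage.
#'
#' @param params a [model_params()] object.
#' @param quantum population increment per event.
#' @return A 9 x 4 numeric matrix (rows = events, columns `C, B1, B2, P`).
#' @export
event_effects <- function(params, quantum = 2e-4) {
  q <- quantum
  E <- with(params, rbind(
    nutrient_in  = c(q, 0, 0, 0),
    nutrient_out = c(-q, 0, 0, 0),
    B1_growth    = c(-q / Y1, q, 0, 0),
    B2_growth    = c(-q / Y2, 0, q, 0),
    P_infect_B1  = c(0, -q, 0, beta1 * q),
    P_infect_B2  = c(0, 0, -q, beta2 * q),
    B1_death     = c(0, -q, 0, 0),
    B2_death     = c(0, 0, -q, 0),
    P_decay      = c(0, 0, 0, -q)
  ))
  colnames(E) <- c("C", "B1", "B2", "P")
  E
}

#' Stochastic simulation of the ecosystem (exact SSA)
#'
#' Event-driven simulation of the nine elementary processes on populations
#' quantized in units of `quantum`: exponential waiting times drawn from the
#' total propensity, categorical event choice, state updated by
#' [event_effects()], and species clamped up to `floor` after every event
#' (the weak-influx floor; the nutrient is clamped at 0).  Randomness comes
#' from R's global RNG, so `set.seed()` (or the `seed` argument) makes runs
#' bitwise reproducible.
#'
#' @param params a [model_params()] object.
#' @param init initial [eco_state()].
#' @param t_end duration of the run (model time units).
#' @param quantum population increment per event (default `2e-4`).
#' @param floor minimum species level (default `4e-4`; must be at least
#'   `quantum` so a single death event cannot cross it to a negative value).
#' @param record_dt output sampling interval.
#' @param seed optional integer seed (`set.seed` is called when supplied).
#' @return An `eco_trajectory` data frame (`time, C, B1, B2, P`) with
#'   attributes `event_counts` (events executed per process), `halted`
#'   (`TRUE` if the total propensity reached zero), `quantum`, `floor`,
#'   `seed`.
#' @examples
#' p <- model_params(phi = 0.66)
#' tr <- simulate_gillespie(p, eco_state(0.943, 0.5, 4e-4, 3.71),
#'                          t_end = 20, seed = 1)
#' attr(tr, "event_counts")
#' @export
simulate_gillespie <- function(params, init, t_end, quantum = 2e-4,
                               floor = 4e-4, record_dt = 1, seed = NULL) {
  init <- check_state(init)
  stopifnot(quantum > 0, floor >= quantum, record_dt > 0, t_end > 0)
  if (!is.null(seed)) set.seed(seed)
  res <- .Call("ps_ssa", param_vector(params), unclass(init),
               as.numeric(t_end), as.numeric(quantum), as.numeric(floor),
               as.numeric(record_dt), PACKAGE = "phageshift")
  df <- as.data.frame(res$trajectory)
  names(df) <- c("time", "C", "B1", "B2", "P")
  counts <- res$event_counts
  names(counts) <- rownames(event_effects(params, quantum))
  structure(df, class = c("eco_trajectory", "data.frame"),
            params = params, floor = floor, quantum = quantum,
            seed = seed, event_counts = counts, halted = res$halted,
            kind = "stochastic")
}

#' Simulate method for model parameter objects
#'
#' Convenience wrapper running [simulate_gillespie()] `nsim` times from the
#' same initial state.
#'
#' @param object a [model_params()] object.
#' @param nsim number of replicate trajectories.
#' @param seed optional seed for the whole batch.
#' @param init initial state (defaults to the nutrient-only state
#'   `C = phi/deltaC` with all species at the floor).
#' @param t_end,quantum,floor,record_dt passed to [simulate_gillespie()].
#' @param ... unused.
#' @return A single `eco_trajectory` if `nsim = 1`, else a list of them.
#' @export
simulate.model_params <- function(object, nsim = 1, seed = NULL,
                                  init = NULL, t_end = 1000, quantum = 2e-4,
                                  floor = 4e-4, record_dt = 1, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init))
    init <- eco_state(object$phi / object$deltaC, floor, floor, floor)
  runs <- lapply(seq_len(nsim), function(i)
    simulate_gillespie(object, init, t_end, quantum, floor, record_dt))
  if (nsim == 1) runs[[1]] else runs
}
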