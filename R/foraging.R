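## Foraging: random deposition of discrete portions, proximity-gated
## consumption proportional to accumulated mass, portion depletion, and a
## baseline proportional mass loss. Pure-R reference versions of the engine
## phases.

#' Stochastic food deposition (one trial per step)
#'
#' With probability `p_food`, appends one food portion at a uniform-random
#' position with `remaining = q_food`. Draws, in order: the Bernoulli test,
#' then (only on success) `x` and `y`.
#'
#' @param state a [SimulationState-class] object.
#' @param p a [SimulationParams-class] object.
#' @return the (possibly grown) state.
#' @export
maybeDepositFood <- function(state, p) {
  if (runif(1) < p@p_food) {
    row <- c(id = state@nextFoodId,
             x = runif(1, 0, p@Lx), y = runif(1, 0, p@Ly),
             remaining = p@q_food)
    state@food <- rbind(state@food, row)
    rownames(state@food) <- NULL
    state@nextFoodId <- state@nextFoodId + 1
    if (is.finite(p@q_food)) state@totalDeposited <- state@totalDeposited +
        p@q_food
  }
  state
}

#' Consumption, growth and baseline mass loss
#'
#' Each animal strictly within `R_food_thres` of at least one portion eats
#' from its nearest portion only (ties go to the lowest portion id), with
#' per-step demand `mu * m_j * dt` (consumption proportional to accumulated
#' mass). If a portion cannot cover the combined demand, the remainder is
#' split proportionally to demand and the portion is exactly emptied;
#' exhausted portions are removed. Afterwards every animal, feeding or not,
#' loses the fraction `lam * dt` of its mass. Assimilation efficiency is 1:
#' intake equals body mass gained, so with `lam = 0` the total food mass is
#' conserved.
#'
#' @param state a [SimulationState-class] object.
#' @param p a [SimulationParams-class] object.
#' @return the updated state.
#' @export
consumeAndGrow <- function(state, p) {
  a <- state@animals
  n <- nrow(a)
  if (n == 0L) return(state)
  f <- state@food
  if (nrow(f)) {
    gate2 <- p@R_food_thres^2
    d2 <- outer(a[, "x"], f[, "x"], "-")^2 + outer(a[, "y"], f[, "y"], "-")^2
    best <- apply(d2, 1, min)
    target <- apply(d2, 1, which.min)  # first minimum = lowest id on ties
    eats <- best < gate2
    demand <- ifelse(eats, p@mu * a[, "m"] * p@dt, 0)
    intake <- numeric(n)
    for (q in unique(target[eats])) {
      sel <- eats & target == q
      tot <- sum(demand[sel])
      if (tot <= f[q, "remaining"]) {
        f[q, "remaining"] <- f[q, "remaining"] - tot
        intake[sel] <- demand[sel]
      } else {
        intake[sel] <- demand[sel] * f[q, "remaining"] / tot
        f[q, "remaining"] <- 0
      }
    }
    a[, "m"] <- a[, "m"] + intake
    state@totalIntake <- state@totalIntake + sum(intake)
    state@food <- f[f[, "remaining"] > 0, , drop = FALSE]
  }
  a[, "m"] <- a[, "m"] * (1 - p@lam * p@dt)
  state@animals <- a
  state
}
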