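## Demography: one recruitment trial per step at a small random mass, and
## immediate removal at the critical masses. Pure-R reference versions of the
## engine phases, exported for inspection and testing.

#' Stochastic recruitment (one trial per step)
#'
#' With probability `p_birth`, appends one animal at a uniform-random
#' position with zero velocity and mass uniform on `m_s` +/- `m_s_spread`,
#' and increments the birth counter. Draws, in order: the Bernoulli test,
#' then (only on success) `x`, `y` and the mass.
#'
#' @param state a [SimulationState-class] object.
#' @param p a [SimulationParams-class] object.
#' @return the (possibly grown) state.
#' @export
maybeRecruit <- function(state, p) {
  if (runif(1) < p@p_birth) {
    row <- c(id = state@nextAnimalId,
             x = runif(1, 0, p@Lx), y = runif(1, 0, p@Ly),
             vx = 0, vy = 0,
             m = p@m_s + (2 * runif(1) - 1) * p@m_s_spread,
             t_birth = state@t)
    state@animals <- rbind(state@animals, row)
    rownames(state@animals) <- NULL
    state@nextAnimalId <- state@nextAnimalId + 1
    state@nBorn <- state@nBorn + 1
  }
  state
}

#' Remove animals at critical masses
#'
#' Every animal with `m <= m_min` or `m >= m_max` disappears from the
#' population (inclusive comparisons: reaching the critical size is fatal).
#' The two kinds of removal are tallied separately.
#'
#' @param state a [SimulationState-class] object.
#' @param p a [SimulationParams-class] object.
#' @return the culled state.
#' @export
cull <- function(state, p) {
  m <- state@animals[, "m"]
  hi <- m >= p@m_max
  lo <- !hi & m <= p@m_min
  if (any(hi) || any(lo)) {
    state@nDiedMax <- state@nDiedMax + sum(hi)
    state@nDiedMin <- state@nDiedMin + sum(lo)
    state@animals <- state@animals[!(hi | lo), , drop = FALSE]
  }
  state
}

#' Size class of a mass
#'
#' The population is formally divided into three subgroups by the class
#' boundaries `m_class12` and `m_class23`, with left-closed intervals:
#' small `< m_class12`, medium `[m_class12, m_class23)`, large
#' `>= m_class23`.
#'
#' @param m mass (vectorised).
#' @param p a [SimulationParams-class] object.
#' @return factor with levels `small`, `medium`, `large`.
#' @export
classifySize <- function(m, p) {
  cls <- ifelse(m < p@m_class12, "small",
                ifelse(m < p@m_class23, "medium", "large"))
  factor(cls, levels = c("small", "medium", "large"))
}
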