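#' Canned scenario configurations
#'
#' Named parameter sets for the standard numerical experiments:
#' \describe{
#'   \item{baseline}{package defaults; balanced demography, no wave.}
#'   \item{all_small_start}{initial population entirely of small
#'     individuals (the recruit mass range).}
#'   \item{all_large_start}{initial population entirely of large
#'     individuals (top size class), for the convergence experiment.}
#'   \item{fear_wave}{baseline plus periodic waves of fear from the wall at
#'     `x = 0`.}
#'   \item{extinction}{no recruitment and no food with ongoing mass loss,
#'     so the population shrinks to zero.}
#' }
#'
#' @param name scenario name.
#' @param ... parameter overrides applied on top of the scenario.
#' @return a valid [SimulationParams-class] object.
#' @examples
#' waveEnabled(scenarioParams("fear_wave"))
#' @export
scenarioParams <- function(name = c("baseline", "all_small_start",
                                    "all_large_start", "fear_wave",
                                    "extinction"), ...) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% eval(formals(scenarioParams)$name))
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; valid names: baseline, all_small_start, all_large_start, ",
         "fear_wave, extinction")
  base <- switch(name,
    baseline = list(),
    all_small_start = list(m_init = 1, m_init_spread = 0.25),
    all_large_start = list(m_init = 4.8, m_init_spread = 0.5),
    fear_wave = list(B_wave = 100, R_wave = 8,
                     wave_period = 50, wave_duration = 5),
    extinction = list(p_birth = 0, p_food = 0, lam = 0.02))
  over <- list(...)
  base[names(over)] <- over
  do.call(simulationParams, base)
}

#' Write a canned scenario config file
#'
#' @param name scenario name (see [scenarioParams()]).
#' @param path output config path.
#' @param ... overrides passed to [scenarioParams()].
#' @return `path`, invisibly.
#' @export
writeScenario <- function(name, path, ...) {
  writeParams(scenarioParams(name, ...), path)
}
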