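## Step schedule (fixed; part of the reproducibility contract):
##   1 force evaluation    2 integration      3 consumption & mass update
##   4 cull                5 recruitment      6 food deposition  7 recording
## Consumption precedes culling so that a starving animal eats before it is
## judged; recruitment follows culling so that a newborn cannot die in its
## birth step. All random draws come from the single R RNG stream in the
## order: birth test, (x, y, mass), food test, (x, y).

.emptyAnimals <- function() {
  matrix(numeric(0), ncol = 7, dimnames = list(NULL, .animalCols))
}
.emptyFood <- function() {
  matrix(numeric(0), ncol = 4, dimnames = list(NULL, .foodCols))
}

#' Initialise a simulation state
#'
#' Places `N0` animals at uniform-random positions in the arena with zero
#' velocities and masses uniform on `m_init` +/- `m_init_spread` (the recruit
#' range unless overridden); the food array starts empty, time and all
#' counters at zero. Draws `x`, then `y`, then mass, each as a vector of
#' length `N0`, from the current RNG stream.
#'
#' @param p a valid [SimulationParams-class] object.
#' @param seed optional; if given, `set.seed(seed)` is called first. When
#'   absent the current RNG state is used (as [runSimulation()] does after
#'   seeding the run).
#' @return a [SimulationState-class] object at `t = 0`.
#' @export
initState <- function(p, seed = NULL) {
  validateParams(p)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(p@N0)
  if (n > 0L) {
    x <- runif(n, 0, p@Lx)
    y <- runif(n, 0, p@Ly)
    m <- runif(n, p@m_init - p@m_init_spread, p@m_init + p@m_init_spread)
    a <- cbind(id = seq_len(n), x = x, y = y, vx = 0, vy = 0, m = m,
               t_birth = 0)
  } else {
    a <- .emptyAnimals()
  }
  new("SimulationState", t = 0, animals = a, food = .emptyFood(),
      nBorn = 0, nDiedMin = 0, nDiedMax = 0,
      nextAnimalId = n + 1, nextFoodId = 1,
      totalDeposited = 0, totalIntake = 0)
}

.stateFromCore <- function(res) {
  a <- res$animals
  colnames(a) <- .animalCols
  f <- res$food
  colnames(f) <- .foodCols
  new("SimulationState", t = res$t, animals = a, food = f,
      nBorn = res$nBorn, nDiedMin = res$nDiedMin, nDiedMax = res$nDiedMax,
      nextAnimalId = res$nextAnimalId, nextFoodId = res$nextFoodId,
      totalDeposited = res$totalDeposited, totalIntake = res$totalIntake)
}

.callCore <- function(state, p, nSteps, recordEvery, recordInitial) {
  .simCore(paramList(p), state@animals, state@food,
           state@t, state@nBorn, state@nDiedMin, state@nDiedMax,
           state@nextAnimalId, state@nextFoodId,
           state@totalDeposited, state@totalIntake,
           as.integer(nSteps), as.integer(recordEvery), recordInitial)
}

#' Advance the simulation by one step
#'
#' Executes the full phase schedule once using the compiled engine and the
#' current RNG stream; `t` advances by `dt`. Composing `n` calls is
#' bit-identical to `runSimulation(..., nSteps = n)` from the same RNG
#' state.
#'
#' @param state a [SimulationState-class] object.
#' @param p a valid [SimulationParams-class] object.
#' @return the advanced state.
#' @export
stepState <- function(state, p) {
  .stateFromCore(.callCore(state, p, 1L, 0L, FALSE))
}

#' Run the simulation and record it
#'
#' Seeds the RNG, builds the initial state (unless one is supplied), runs
#' `nSteps` steps in the compiled engine and records animal/food snapshots
#' and counter rows at step 0 and every `recordEvery` steps thereafter.
#' Population extinction is recorded, not an error: food keeps depositing
#' and recruitment continues, so the population can re-establish.
#'
#' @param p a valid [SimulationParams-class] object.
#' @param nSteps number of steps (>= 1).
#' @param recordEvery recording stride in steps.
#' @param seed RNG seed; defaults to the `seed` field of `p`.
#' @param state optional starting [SimulationState-class]; when supplied it
#'   is used as-is (its `t` need not be 0).
#' @return a [RunRecord-class] object.
#' @examples
#' p <- simulationParams(N0 = 20, seed = 3)
#' rec <- runSimulation(p, nSteps = 200, recordEvery = 100)
#' counters(rec)
#' @export
runSimulation <- function(p, nSteps, recordEvery = 100L,
                          seed = p@seed, state = NULL) {
  validateParams(p)
  stopifnot(nSteps >= 1, recordEvery >= 1)
  set.seed(as.integer(seed))
  if (is.null(state)) state <- initState(p)
  res <- .callCore(state, p, nSteps, recordEvery, TRUE)
  new("RunRecord", params = p, seed = as.numeric(seed),
      nSteps = as.numeric(nSteps), recordEvery = as.numeric(recordEvery),
      snapshots = res$snapshots, foodSnapshots = res$foodSnapshots,
      counters = res$counters, foodEvents = res$foodEvents,
      finalState = .stateFromCore(res))
}

#' Reference single-phase integrator (pure R)
#'
#' Semi-implicit Euler update of the damped equations of motion
#' `m dv/dt = F - eta(m) v`:
#' `v <- (v + dt F / m) / (1 + dt eta / m)`, then `r <- r + dt v`.
#' Masses are unchanged in this phase. Used for closed-form checks and to
#' cross-validate the compiled engine.
#'
#' @param state a [SimulationState-class] object.
#' @param forces `N x 2` matrix of per-animal forces (e.g.
#'   `forceField(state, p)$total`).
#' @param p a [SimulationParams-class] object.
#' @return the state with updated velocities and positions.
#' @export
integrateStep <- function(state, forces, p) {
  a <- state@animals
  n <- nrow(a)
  if (n == 0L) return(state)
  stopifnot(nrow(forces) == n)
  if (any(!is.finite(forces))) {
    bad <- which(!is.finite(forces[, 1]) | !is.finite(forces[, 2]))[1]
    stop("non-finite force for animal id ", a[bad, "id"],
         " (force phase)")
  }
  m <- a[, "m"]
  eta <- dampingCoefficient(m, p)
  den <- 1 + p@dt * eta / m
  a[, "vx"] <- (a[, "vx"] + p@dt * forces[, 1] / m) / den
  a[, "vy"] <- (a[, "vy"] + p@dt * forces[, 2] / m) / den
  a[, "x"] <- a[, "x"] + p@dt * a[, "vx"]
  a[, "y"] <- a[, "y"] + p@dt * a[, "vy"]
  if (any(!is.finite(a[, c("x", "y")]))) {
    bad <- which(!is.finite(a[, "x"]) | !is.finite(a[, "y"]))[1]
    stop("non-finite position for animal id ", a[bad, "id"],
         " (integration phase)")
  }
  state@animals <- a
  state
}

## ---- accessors -------------------------------------------------------------

#' @describeIn SimulationState-class living animals as a data.frame.
#' @param state,object a `SimulationState`.
#' @export
animals <- function(state) as.data.frame(state@animals)

#' @describeIn SimulationState-class remaining food portions as a data.frame.
#' @export
foodItems <- function(state) as.data.frame(state@food)

#' @describeIn SimulationState-class current population size.
#' @export
population <- function(state) nrow(state@animals)

setMethod("show", "SimulationState", function(object) {
  cat(sprintf(
    "SimulationState at t = %.4g: %d animals, %d food portions\n",
    object@t, nrow(object@animals), nrow(object@food)))
  cat(sprintf("  born %d, removed %d at m_min + %d at m_max\n",
              as.integer(object@nBorn), as.integer(object@nDiedMin),
              as.integer(object@nDiedMax)))
  invisible(object)
})

#' @describeIn RunRecord-class recorded animal snapshots.
#' @param record,object a `RunRecord`.
#' @export
snapshots <- function(record) record@snapshots

#' @describeIn RunRecord-class recorded food snapshots.
#' @export
foodSnapshots <- function(record) record@foodSnapshots

#' @describeIn RunRecord-class counter time series.
#' @export
counters <- function(record) record@counters

#' @describeIn RunRecord-class food deposit/exhaust event log.
#' @export
foodEvents <- function(record) record@foodEvents

#' @describeIn RunRecord-class state after the last step.
#' @export
finalState <- function(record) record@finalState

#' @describeIn RunRecord-class parameters of the run.
#' @export
runParams <- function(record) record@params

setMethod("show", "RunRecord", function(object) {
  cc <- object@counters
  cat(sprintf(
    "RunRecord: %d steps (dt = %g), recorded every %d steps, seed %d\n",
    as.integer(object@nSteps), object@params@dt,
    as.integer(object@recordEvery), as.integer(object@seed)))
  cat(sprintf("  N: %d -> %d; born %d, removed %d (m_min) + %d (m_max)\n",
              as.integer(cc$N[1]), as.integer(cc$N[nrow(cc)]),
              as.integer(object@finalState@nBorn),
              as.integer(object@finalState@nDiedMin),
              as.integer(object@finalState@nDiedMax)))
  if (any(cc$N == 0)) cat("  extinction recorded during the run\n")
  invisible(object)
})

## ---- exports ---------------------------------------------------------------

#' Write the tabular exports of a run
#'
#' Writes `snapshots.csv`, `food_snapshots.csv`, `counters.csv`,
#' `food_events.csv` and `params.cfg` into a directory, plus `run_log.txt`
#' with the seed, a parameter checksum and any extinction events.
#'
#' @param record a [RunRecord-class] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeRunRecord <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f)
    write.csv(df, file.path(dir, f), row.names = FALSE, quote = FALSE)
  wr(record@snapshots, "snapshots.csv")
  wr(record@foodSnapshots, "food_snapshots.csv")
  wr(record@counters, "counters.csv")
  wr(record@foodEvents, "food_events.csv")
  cfg <- file.path(dir, "params.cfg")
  writeParams(record@params, cfg)
  ext <- record@counters$t[record@counters$N == 0]
  log <- c(
    sprintf("seed: %d", as.integer(record@seed)),
    sprintf("steps: %d  record_every: %d", as.integer(record@nSteps),
            as.integer(record@recordEvery)),
    sprintf("params_md5: %s", unname(tools::md5sum(cfg))),
    sprintf("package: striderSwarm %s",
            as.character(utils::packageVersion("striderSwarm"))),
    if (length(ext)) sprintf("extinction at t = %.6g", ext[1])
    else "extinction: none")
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
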