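#' @import methods
#' @importFrom stats runif rnorm setNames aggregate cor ecdf lm coef uniroot
#' @importFrom utils read.csv write.csv
#' @useDynLib striderSwarm, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## All model constants live in one flat container so that a run is fully
## specified by (params, seed) and round-trips through a key = value config.
.paramFields <- c(
  "Lx", "Ly", "dt",
  "B_repuls0", "R_repuls0", "B_attract0", "R_attract0",
  "B_bound", "R_bound",
  "B_food0", "R_food", "R_food_thres",
  "alpha_exp", "beta_exp", "eta0",
  "mu", "lam",
  "m_s", "m_s_spread", "m_init", "m_init_spread", "m_min", "m_max",
  "p_birth", "p_food", "q_food",
  "B_wave", "R_wave", "wave_period", "wave_duration",
  "m_class12", "m_class23",
  "N0", "seed"
)

#' Simulation parameter container
#'
#' Holds every model constant of the swarm simulation: arena geometry,
#' Gaussian pair-force amplitudes and radii, soft-wall and fear-wave forcing,
#' foraging and demographic rates, mass thresholds and the RNG seed. Objects
#' are created with [simulationParams()]; validity enforces the structural
#' inequalities the model requires (weak long-range attraction, hard narrow
#' walls, a mass window containing the recruitment mass).
#'
#' @slot Lx,Ly arena side lengths (model length units).
#' @slot dt integration time step (model time units).
#' @slot B_repuls0,R_repuls0 unit-mass repulsion amplitude and radius.
#' @slot B_attract0,R_attract0 unit-mass attraction amplitude and radius.
#' @slot B_bound,R_bound boundary wall amplitude and decay length.
#' @slot B_food0,R_food food-attraction amplitude prefactor and radius.
#' @slot R_food_thres proximity gate inside which a portion can be eaten.
#' @slot alpha_exp mass exponent of the food/wave force amplitude (2/3).
#' @slot beta_exp mass exponent of the damping coefficient (1/3).
#' @slot eta0 unit-mass damping prefactor.
#' @slot mu food assimilation rate (1/time).
#' @slot lam stored-mass loss rate (1/time).
#' @slot m_s,m_s_spread recruit mass: uniform on `m_s` +/- `m_s_spread`.
#' @slot m_init,m_init_spread initial-population mass range (defaults to the
#'   recruit range; set differently to start from an extreme population).
#' @slot m_min,m_max critical removal masses.
#' @slot p_birth per-step recruitment probability.
#' @slot p_food per-step food-deposition probability.
#' @slot q_food capacity of one food portion (mass; may be `Inf`).
#' @slot B_wave,R_wave fear-wave amplitude and decay length (`B_wave = 0`
#'   disables the wave).
#' @slot wave_period,wave_duration periodic wave schedule (time units).
#' @slot m_class12,m_class23 small/medium and medium/large class boundaries.
#' @slot N0 initial population size.
#' @slot seed default RNG seed used by [runSimulation()].
#'
#' @export
setClass("SimulationParams",
  representation = do.call(representation,
    as.list(setNames(rep("numeric", length(.paramFields)), .paramFields)))
)

#' Simulation state
#'
#' A snapshot of the system: time, the variable-length animal array, the
#' variable-length food array, demographic counters and id/mass bookkeeping.
#' The animal matrix has columns `id, x, y, vx, vy, m, t_birth`; the food
#' matrix has columns `id, x, y, remaining`.
#'
#' @slot t current simulation time.
#' @slot animals numeric matrix, one row per living animal.
#' @slot food numeric matrix, one row per remaining food portion.
#' @slot nBorn cumulative recruitments.
#' @slot nDiedMin cumulative removals at the minimal critical mass.
#' @slot nDiedMax cumulative removals at the maximal critical mass.
#' @slot nextAnimalId,nextFoodId next unused integer ids.
#' @slot totalDeposited cumulative finite food mass deposited.
#' @slot totalIntake cumulative food mass assimilated.
#'
#' @export
setClass("SimulationState",
  representation(
    t = "numeric", animals = "matrix", food = "matrix",
    nBorn = "numeric", nDiedMin = "numeric", nDiedMax = "numeric",
    nextAnimalId = "numeric", nextFoodId = "numeric",
    totalDeposited = "numeric", totalIntake = "numeric"
  )
)

.animalCols <- c("id", "x", "y", "vx", "vy", "m", "t_birth")
.foodCols <- c("id", "x", "y", "remaining")

setValidity("SimulationState", function(object) {
  msg <- character()
  if (ncol(object@animals) != 7L ||
      !identical(colnames(object@animals), .animalCols))
    msg <- c(msg, "animals matrix must have columns id,x,y,vx,vy,m,t_birth")
  if (ncol(object@food) != 4L ||
      !identical(colnames(object@food), .foodCols))
    msg <- c(msg, "food matrix must have columns id,x,y,remaining")
  if (nrow(object@animals) && any(!is.finite(object@animals)))
    msg <- c(msg, "animal state contains non-finite values")
  if (length(msg)) msg else TRUE
})

#' Record of a simulation run
#'
#' Returned by [runSimulation()]. Carries the recorded animal and food
#' snapshots, the counter time series, the food event log, and the final
#' state, together with the parameters and seed that reproduce the run.
#'
#' @slot params the [SimulationParams-class] used.
#' @slot seed the RNG seed used.
#' @slot nSteps,recordEvery run length and recording stride (steps).
#' @slot snapshots data.frame `step, t, id, x, y, vx, vy, m, t_birth`.
#' @slot foodSnapshots data.frame `step, t, id, x, y, remaining`.
#' @slot counters data.frame `step, t, N, N_c1, N_c2, N_c3, n_born,
#'   n_died_min, n_died_max, n_food, food_mass`.
#' @slot foodEvents data.frame `t, event, id, x, y` with event one of
#'   `deposit`, `exhaust`.
#' @slot finalState the [SimulationState-class] after the last step.
#'
#' @export
setClass("RunRecord",
  representation(
    params = "SimulationParams", seed = "numeric",
    nSteps = "numeric", recordEvery = "numeric",
    snapshots = "data.frame", foodSnapshots = "data.frame",
    counters = "data.frame", foodEvents = "data.frame",
    finalState = "SimulationState"
  )
)

#' Histogram accumulator
#'
#' Fixed-edge histogram that keeps both the counts of the most recent
#' snapshot (`instant`) and the counts accumulated over all folded snapshots
#' (`longRun`), mirroring the instant vs long-run curves used to characterise
#' the population. Observations falling outside the edges are tallied in
#' underflow/overflow counters rather than silently dropped.
#'
#' @slot edges strictly increasing bin edges; bins are left-open,
#'   right-closed `(e[i], e[i+1]]`.
#' @slot instant counts of the last folded snapshot.
#' @slot longRun counts summed over all folded snapshots.
#' @slot nFolds number of snapshots folded in.
#' @slot nObs total observations folded (including out-of-range).
#' @slot underflow,overflow out-of-range tallies.
#'
#' @export
setClass("HistogramAccumulator",
  representation(
    edges = "numeric", instant = "numeric", longRun = "numeric",
    nFolds = "numeric", nObs = "numeric",
    underflow = "numeric", overflow = "numeric"
  ),
  validity = function(object) {
    if (length(object@edges) < 2L || any(diff(object@edges) <= 0))
      return("edges must be strictly increasing with >= 2 values")
    nb <- length(object@edges) - 1L
    if (length(object@instant) != nb || length(object@longRun) != nb)
      return("count vectors must have length(edges) - 1")
    TRUE
  }
)

#' Camera parameters for the perspective ground-plane transform
#'
#' Geometry of a tilted camera looking at a flat water surface, used to map
#' pixel detections to field coordinates and back.
#'
#' @slot tilt angle between the ground plane and the camera-plane normal
#'   (radians, in (0, pi/2)).
#' @slot hfov horizontal view angle of the camera (radians, in (0, pi)).
#' @slot h camera height over the ground (field length units).
#' @slot x_cm,y_cm horizontal and vertical sensor resolution (pixels).
#'
#' @export
setClass("CameraParams",
  representation(tilt = "numeric", hfov = "numeric", h = "numeric",
                 x_cm = "numeric", y_cm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@tilt > 0 && object@tilt < pi / 2))
      msg <- c(msg, "tilt must lie in (0, pi/2)")
    if (!(object@hfov > 0 && object@hfov < pi))
      msg <- c(msg, "hfov must lie in (0, pi)")
    if (!(object@h > 0)) msg <- c(msg, "h must be positive")
    if (object@x_cm < 1 || object@y_cm < 1 ||
        object@x_cm != round(object@x_cm) || object@y_cm != round(object@y_cm))
      msg <- c(msg, "resolutions must be positive integers")
    if (length(msg)) msg else TRUE
  }
)
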