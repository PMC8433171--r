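## Default constants. The model is formulated in dimensionless "model units":
## lengths of order one body spacing, times of order one damping time
## (m/eta ~ 1 for a recruit), masses with the recruit near 1. See the methods
## vignette for how each value was chosen.
.paramDefaults <- list(
  Lx = 20, Ly = 20, dt = 0.01,
  B_repuls0 = 10, R_repuls0 = 0.7, B_attract0 = 0.2, R_attract0 = 1.4,
  B_bound = 50, R_bound = 0.1,
  B_food0 = 2, R_food = 5, R_food_thres = 0.5,
  alpha_exp = 2 / 3, beta_exp = 1 / 3, eta0 = 1,
  mu = 0.2, lam = 0.011,
  m_s = 1, m_s_spread = 0.25, m_init = NA_real_, m_init_spread = NA_real_,
  m_min = 0.5, m_max = 6,
  p_birth = 0.006, p_food = 0.013, q_food = 2,
  B_wave = 0, R_wave = 8, wave_period = 50, wave_duration = 5,
  m_class12 = NA_real_, m_class23 = NA_real_,
  N0 = 100, seed = 1
)

#' Construct a validated simulation parameter set
#'
#' Builds a [SimulationParams-class] object from the package defaults,
#' overridden by any named arguments, and validates it with
#' [validateParams()] before returning. Class boundaries `m_class12`,
#' `m_class23` default to equal thirds of the mass window
#' `[m_min, m_max]`; the initial-mass range `m_init` +/- `m_init_spread`
#' defaults to the recruit range `m_s` +/- `m_s_spread`.
#'
#' @param ... named scalar overrides of any parameter field (see
#'   [SimulationParams-class]).
#' @return a valid `SimulationParams` object.
#' @examples
#' p <- simulationParams(N0 = 50, seed = 7)
#' equilibriumDistance(1, p)
#' @export
simulationParams <- function(...) {
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all arguments to simulationParams() must be named")
  unknown <- setdiff(names(over), .paramFields)
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  vals <- .paramDefaults
  vals[names(over)] <- over
  if (is.na(vals$m_init)) vals$m_init <- vals$m_s
  if (is.na(vals$m_init_spread)) vals$m_init_spread <- vals$m_s_spread
  if (is.na(vals$m_class12))
    vals$m_class12 <- vals$m_min + (vals$m_max - vals$m_min) / 3
  if (is.na(vals$m_class23))
    vals$m_class23 <- vals$m_min + 2 * (vals$m_max - vals$m_min) / 3
  p <- do.call(new, c(list("SimulationParams"), lapply(vals, as.numeric)))
  validateParams(p)
}

#' Extract parameter values
#'
#' @param p a [SimulationParams-class] object.
#' @param name field name; omit to get all fields as a named list.
#' @return a numeric scalar, or a named list of all fields.
#' @export
param <- function(p, name) {
  stopifnot(is(p, "SimulationParams"))
  if (!name %in% .paramFields) stop("unknown parameter field: ", name)
  slot(p, name)
}

#' @rdname param
#' @export
paramList <- function(p) {
  stopifnot(is(p, "SimulationParams"))
  setNames(lapply(.paramFields, function(f) slot(p, f)), .paramFields)
}

#' Replace parameter fields, revalidating
#'
#' @param p a [SimulationParams-class] object.
#' @param ... named scalar replacements.
#' @return the modified, revalidated object.
#' @export
setParams <- function(p, ...) {
  over <- list(...)
  unknown <- setdiff(names(over), .paramFields)
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  for (f in names(over)) slot(p, f) <- as.numeric(over[[f]])
  validateParams(p)
}

#' Is the fear wave enabled?
#'
#' The wave forcing is active for a parameter set when its amplitude is
#' positive and the schedule has a positive period and duration.
#'
#' @param p a [SimulationParams-class] object.
#' @return logical scalar.
#' @export
waveEnabled <- function(p) {
  p@B_wave > 0 && p@wave_period > 0 && p@wave_duration > 0
}

#' Validate a parameter set
#'
#' Checks positivity of every amplitude, radius and rate, and the structural
#' inequalities of the model: weak long-range attraction
#' (`B_attract0 < B_repuls0`, `R_attract0 > R_repuls0`), hard narrow walls
#' (`B_bound > B_repuls0`, `R_bound` below the equilibrium spacing), a wave
#' stronger and longer-ranged than the wall when enabled, and a mass window
#' that strictly contains the recruitment and initial mass ranges. A
#' descriptive error names the first violated condition.
#'
#' @param p a [SimulationParams-class] object.
#' @return `p`, unchanged, if valid.
#' @export
validateParams <- function(p) {
  stopifnot(is(p, "SimulationParams"))
  v <- paramList(p)
  bad <- vapply(v, function(x) length(x) != 1L || is.na(x), TRUE)
  if (any(bad))
    stop("parameter field(s) must be finite scalars: ",
         paste(names(v)[bad], collapse = ", "))
  chk <- function(cond, what) if (!cond) stop("invalid parameters: ", what,
                                              call. = FALSE)
  pos <- c("Lx", "Ly", "dt", "B_repuls0", "R_repuls0", "B_attract0",
           "R_attract0", "B_bound", "R_bound", "B_food0", "R_food",
           "R_food_thres", "eta0", "mu", "m_s", "q_food")
  for (f in pos) chk(v[[f]] > 0, paste0(f, " must be > 0"))
  chk(v$lam >= 0, "lam must be >= 0")
  chk(v$B_wave >= 0, "B_wave must be >= 0")
  chk(v$N0 >= 0 && v$N0 == round(v$N0), "N0 must be a nonnegative integer")
  chk(v$p_birth >= 0 && v$p_birth <= 1, "p_birth must lie in [0, 1]")
  chk(v$p_food >= 0 && v$p_food <= 1, "p_food must lie in [0, 1]")
  chk(v$B_attract0 < v$B_repuls0,
      "attraction must be weaker than repulsion (B_attract0 < B_repuls0)")
  chk(v$R_attract0 > v$R_repuls0,
      "attraction must be longer-ranged than repulsion (R_attract0 > R_repuls0)")
  chk(v$B_bound > v$B_repuls0,
      "boundary walls must overpower pair repulsion (B_bound > B_repuls0)")
  chk(v$m_s_spread >= 0 && v$m_s_spread < v$m_s,
      "m_s_spread must satisfy 0 <= m_s_spread < m_s")
  chk(v$m_init_spread >= 0, "m_init_spread must be >= 0")
  chk(v$m_min < v$m_max, "mass window must be non-degenerate (m_min < m_max)")
  chk(v$m_min < v$m_s - v$m_s_spread,
      "recruit masses must exceed m_min (m_min < m_s - m_s_spread)")
  chk(v$m_s + v$m_s_spread < v$m_max,
      "recruit masses must stay below m_max (m_s + m_s_spread < m_max)")
  chk(v$m_min < v$m_init - v$m_init_spread &&
      v$m_init + v$m_init_spread < v$m_max,
      "initial masses must lie strictly inside (m_min, m_max)")
  chk(v$m_min < v$m_class12 && v$m_class12 < v$m_class23 &&
      v$m_class23 < v$m_max,
      "class boundaries must satisfy m_min < m_class12 < m_class23 < m_max")
  ## equilibrium spacing exists and dwarfs the wall decay length
  rmin <- equilibriumDistance(max(v$m_min, v$m_s - v$m_s_spread), p,
                              .validated = FALSE)
  chk(v$R_bound < rmin,
      "wall decay length must be below the equilibrium spacing (R_bound < R_min)")
  if (v$B_wave > 0 && v$wave_period > 0 && v$wave_duration > 0) {
    chk(v$B_wave > v$B_bound,
        "an enabled fear wave must exceed the wall amplitude (B_wave > B_bound)")
    chk(v$R_wave > v$R_bound,
        "an enabled fear wave must decay over a longer range (R_wave > R_bound)")
    chk(v$wave_duration < v$wave_period,
        "wave_duration must be shorter than wave_period")
  }
  p
}

#' Read and write flat key = value parameter configs
#'
#' One line per field, `key = value`; blank lines and `#` comments are
#' ignored. `readParams()` requires every field to be present exactly once
#' and rejects unknown keys; `writeParams()` emits all fields, so the two
#' functions round-trip any valid parameter set.
#'
#' @param path config file path.
#' @return `readParams()` returns a validated [SimulationParams-class];
#'   `writeParams()` returns `path` invisibly.
#' @export
readParams <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(\\S+)$", lines))
  bad <- lines[vapply(kv, length, 0L) != 3L]
  if (length(bad))
    stop("malformed config line(s): ", paste(bad, collapse = "; "))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  unknown <- setdiff(keys, .paramFields)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicated config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  missing <- setdiff(.paramFields, keys)
  if (length(missing))
    stop("missing required config key(s): ", paste(missing, collapse = ", "))
  num <- suppressWarnings(as.numeric(vals))
  nonnum <- keys[is.na(num) & vals != "NA" & vals != "Inf"]
  if (length(nonnum))
    stop("non-numeric value for key(s): ", paste(nonnum, collapse = ", "))
  num[vals == "Inf"] <- Inf
  do.call(simulationParams, setNames(as.list(num), keys))
}

#' @rdname readParams
#' @param p a [SimulationParams-class] object to write.
#' @export
writeParams <- function(p, path) {
  stopifnot(is(p, "SimulationParams"))
  v <- paramList(p)
  writeLines(sprintf("%s = %.17g", names(v), unlist(v)), path)
  invisible(path)
}

setMethod("show", "SimulationParams", function(object) {
  v <- paramList(object)
  cat("SimulationParams (water-strider swarm model)\n")
  cat(sprintf("  arena %g x %g, dt = %g, N0 = %d, seed = %d\n",
              v$Lx, v$Ly, v$dt, as.integer(v$N0), as.integer(v$seed)))
  cat(sprintf("  pair forces: B_rep %g / R_rep %g, B_att %g / R_att %g (R_min(m=1) = %.4g)\n",
              v$B_repuls0, v$R_repuls0, v$B_attract0, v$R_attract0,
              equilibriumDistance(1, object)))
  cat(sprintf("  walls: B %g / R %g;  food: B %g, R %g, gate %g, q %g\n",
              v$B_bound, v$R_bound, v$B_food0, v$R_food, v$R_food_thres,
              v$q_food))
  cat(sprintf("  rates: mu %g, lam %g, p_birth %g, p_food %g\n",
              v$mu, v$lam, v$p_birth, v$p_food))
  cat(sprintf("  masses: window (%g, %g), recruit %g +/- %g, classes at %.3g / %.3g\n",
              v$m_min, v$m_max, v$m_s, v$m_s_spread, v$m_class12, v$m_class23))
  if (waveEnabled(object))
    cat(sprintf("  fear wave: B %g / R %g, period %g, duration %g\n",
                v$B_wave, v$R_wave, v$wave_period, v$wave_duration))
  else cat("  fear wave: disabled\n")
  invisible(object)
})
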