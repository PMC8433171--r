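## Gaussian pair forces. Both laws share the kernel
##   f(r_j, r_k) = +/- B (r_j - r_k) exp(-|r_j - r_k|^2 / R^2),
## which vanishes at contact, peaks at separation R/sqrt(2) and is smooth
## everywhere -- the property that keeps the dynamics stable at a relatively
## large time step.

#' Pairwise Gaussian repulsion force
#'
#' Force on animal `j` exerted by animal `k`:
#' `B * (r_j - r_k) * exp(-|r_j - r_k|^2 / R^2)`, pointing from `k` toward
#' `j` for positive amplitude.
#'
#' @param r_j,r_k length-2 position vectors.
#' @param B amplitude (force / length).
#' @param R interaction radius (> 0).
#' @return length-2 force vector acting on `j`.
#' @examples
#' pairRepulsion(c(1, 0), c(0, 0), B = 1, R = 1)  # exp(-1) along +x
#' @export
pairRepulsion <- function(r_j, r_k, B, R) {
  if (!(R > 0)) stop("interaction radius must be positive")
  d <- r_j - r_k
  B * d * exp(-sum(d^2) / R^2)
}

#' Pairwise Gaussian attraction force
#'
#' Same kernel as [pairRepulsion()] with the overall sign attracting: the
#' force on `j` points toward `k`. The stored amplitude `B` is positive.
#'
#' @inheritParams pairRepulsion
#' @return length-2 force vector acting on `j`.
#' @export
pairAttraction <- function(r_j, r_k, B, R) {
  if (!(R > 0)) stop("interaction radius must be positive")
  d <- r_j - r_k
  -B * d * exp(-sum(d^2) / R^2)
}

#' Mass-resolved pair amplitudes and radii
#'
#' Animals of different size interact with different strength and reach.
#' The interaction *range* is a property of the pair: radii take the
#' arithmetic mean of the two partners' body-length scales,
#' `R_jk = R0 * (m_j^(1/3) + m_k^(1/3)) / 2`, so both partners share one
#' Gaussian kernel. The *amplitude* is a property of the responding animal:
#' these are behavioural response forces, and each animal responds to the
#' shared signal with its own strength, `B_jk = B0 * m_j^(2/3)` for the
#' force acting on `j` (the first argument is the receiver). For equal
#' masses the pair force is exactly antisymmetric; for unequal masses the
#' stronger partner responds more strongly, which is what makes the big
#' animals the fast ones.
#'
#' @param m_j mass of the animal receiving the force (> 0).
#' @param m_k mass of the partner (> 0).
#' @param p a [SimulationParams-class] object.
#' @return named list `B_repuls, R_repuls, B_attract, R_attract` for the
#'   force acting on `j`.
#' @export
pairAmplitudeRadius <- function(m_j, m_k, p) {
  stopifnot(m_j > 0, m_k > 0)
  s13 <- (m_j^(1 / 3) + m_k^(1 / 3)) / 2
  list(B_repuls = p@B_repuls0 * m_j^(2 / 3), R_repuls = p@R_repuls0 * s13,
       B_attract = p@B_attract0 * m_j^(2 / 3), R_attract = p@R_attract0 * s13)
}

#' Soft boundary wall force
#'
#' The arena `[0, Lx] x [0, Ly]` is closed by four mathematically soft but
#' high and narrow exponential walls. Each wall pushes inward along its
#' normal with magnitude `B_bound * exp(-d / R_bound)` where `d` is the
#' perpendicular (signed) distance to that wall; the four contributions are
#' superposed. Outside the arena the force grows exponentially, returning
#' strays.
#'
#' @param r_j length-2 position.
#' @param p a [SimulationParams-class] object.
#' @return length-2 force vector.
#' @export
boundaryForce <- function(r_j, p) {
  B <- p@B_bound; R <- p@R_bound
  c(B * exp(-r_j[1] / R) - B * exp(-(p@Lx - r_j[1]) / R),
    B * exp(-r_j[2] / R) - B * exp(-(p@Ly - r_j[2]) / R))
}

#' Food attraction force
#'
#' Gaussian attraction of animal `j` toward food portion `n`, with amplitude
#' growing with the animal's strength, `B_food0 * m_j^alpha_exp` (default
#' exponent 2/3), and fixed radius `R_food`.
#'
#' @param r_j animal position (length 2).
#' @param m_j animal mass (> 0).
#' @param r_n portion position (length 2).
#' @param p a [SimulationParams-class] object.
#' @return length-2 force vector acting on `j`.
#' @export
foodForce <- function(r_j, m_j, r_n, p) {
  stopifnot(m_j > 0)
  d <- r_j - r_n
  -p@B_food0 * m_j^p@alpha_exp * d * exp(-sum(d^2) / p@R_food^2)
}

#' Effective damping coefficient on the water surface
#'
#' `eta_j = eta0 * m_j^beta_exp` with default exponent 1/3 (drag grows with
#' the wetted perimeter, i.e. with body length).
#'
#' @param m_j positive mass (vectorised).
#' @param p a [SimulationParams-class] object.
#' @return damping coefficient(s).
#' @export
dampingCoefficient <- function(m_j, p) {
  stopifnot(all(m_j > 0))
  p@eta0 * m_j^p@beta_exp
}

#' Wave-of-fear force
#'
#' Transient long-range repulsion from the dangerous shore (the wall at
#' `x = 0` by convention). Active while `t mod wave_period < wave_duration`;
#' during a wave the force pushes inward (+x) with magnitude
#' `B_wave * m_j^alpha_exp * exp(-d / R_wave)`, `d` the distance to the
#' dangerous wall. It has the same exponential form as the wall force but a
#' larger amplitude and a much longer decay length, so it reaches animals far
#' from the shore; its amplitude grows with strength so that big animals
#' escape faster and farther.
#'
#' @param r_j animal position (length 2).
#' @param m_j animal mass (> 0).
#' @param t current simulation time.
#' @param p a [SimulationParams-class] object.
#' @return length-2 force vector.
#' @export
waveForce <- function(r_j, m_j, t, p) {
  if (!waveEnabled(p)) return(c(0, 0))
  if (t %% p@wave_period >= p@wave_duration) return(c(0, 0))
  c(p@B_wave * m_j^p@alpha_exp * exp(-r_j[1] / p@R_wave), 0)
}

#' Equilibrium pair separation
#'
#' Separation at which repulsion and attraction balance for two equal-mass
#' animals. With the mass-resolved amplitudes `B_rep, B_att` and radii
#' `R_rep, R_att` of [pairAmplitudeRadius()], the net radial force changes
#' sign at
#' `R_min = sqrt( log(B_rep / B_att) / (1 / R_rep^2 - 1 / R_att^2) )`.
#' Because both radii scale as `m^(1/3)` and the amplitude ratio is
#' mass-independent, `R_min(m) = R_min(1) * m^(1/3)`.
#'
#' @param m mass of both animals.
#' @param p a [SimulationParams-class] object.
#' @param .validated internal; skip the `is()` check when called during
#'   validation.
#' @return the equilibrium separation (length units).
#' @export
equilibriumDistance <- function(m, p, .validated = TRUE) {
  ar <- pairAmplitudeRadius(m, m, p)
  num <- log(ar$B_repuls / ar$B_attract)
  den <- 1 / ar$R_repuls^2 - 1 / ar$R_attract^2
  if (!(num > 0) || !(den > 0))
    stop("no positive equilibrium separation: requires B_repuls > B_attract ",
         "and R_attract > R_repuls")
  sqrt(num / den)
}

#' Per-animal force field, labelled by source
#'
#' Reference (pure R) evaluation of the total force of the equations of
#' motion on every animal in a state: the sum over pair repulsion and
#' attraction, boundary walls, food attraction and the fear wave. The
#' compiled engine evaluates exactly the same expressions; this version is
#' exposed for diagnostics and cross-checking.
#'
#' @param state a [SimulationState-class] object.
#' @param p a [SimulationParams-class] object.
#' @param t time at which to evaluate (defaults to `state@t`; only the wave
#'   schedule depends on it).
#' @return list of `N x 2` matrices `pair`, `boundary`, `food`, `wave`,
#'   `total`.
#' @export
forceField <- function(state, p, t = state@t) {
  a <- state@animals
  n <- nrow(a)
  zero <- matrix(0, n, 2)
  out <- list(pair = zero, boundary = zero, food = zero, wave = zero)
  if (n == 0L) {
    out$total <- zero
    return(out)
  }
  pos <- a[, c("x", "y"), drop = FALSE]
  m <- a[, "m"]
  if (n >= 2L) {
    for (j in seq_len(n - 1L)) for (k in seq.int(j + 1L, n)) {
      aj <- pairAmplitudeRadius(m[j], m[k], p)
      ak <- pairAmplitudeRadius(m[k], m[j], p)
      out$pair[j, ] <- out$pair[j, ] +
        pairRepulsion(pos[j, ], pos[k, ], aj$B_repuls, aj$R_repuls) +
        pairAttraction(pos[j, ], pos[k, ], aj$B_attract, aj$R_attract)
      out$pair[k, ] <- out$pair[k, ] +
        pairRepulsion(pos[k, ], pos[j, ], ak$B_repuls, ak$R_repuls) +
        pairAttraction(pos[k, ], pos[j, ], ak$B_attract, ak$R_attract)
    }
  }
  for (j in seq_len(n)) {
    out$boundary[j, ] <- boundaryForce(pos[j, ], p)
    if (nrow(state@food)) {
      for (q in seq_len(nrow(state@food)))
        out$food[j, ] <- out$food[j, ] +
          foodForce(pos[j, ], m[j], state@food[q, c("x", "y")], p)
    }
    out$wave[j, ] <- waveForce(pos[j, ], m[j], t, p)
  }
  out$total <- out$pair + out$boundary + out$food + out$wave
  out
}
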