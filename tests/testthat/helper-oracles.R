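## Independent oracles used across the suite. Deliberately naive: they take
## different computational routes than the package implementations.

# O(n^2) double-loop nearest-neighbour distances
bruteNND <- function(pos) {
  n <- nrow(pos)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((pos[i, 1] - pos[j, 1])^2 + (pos[i, 2] - pos[j, 2])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# exhaustive ECDF evaluation of the two-sample KS statistic
bruteKSD <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(x) abs(mean(a <= x) - mean(b <= x)), 0))
}

# net radial pair force between two equal-mass animals at separation d
netPairForce <- function(d, m, p) {
  ar <- pairAmplitudeRadius(m, m, p)
  ar$B_repuls * d * exp(-d^2 / ar$R_repuls^2) -
    ar$B_attract * d * exp(-d^2 / ar$R_attract^2)
}

# small helper: a state with given animal rows (id, x, y, vx, vy, m, t_birth)
makeState <- function(animals = NULL, food = NULL, t = 0) {
  a <- if (is.null(animals))
    matrix(numeric(0), ncol = 7) else as.matrix(animals)
  colnames(a) <- c("id", "x", "y", "vx", "vy", "m", "t_birth")
  f <- if (is.null(food)) matrix(numeric(0), ncol = 4) else as.matrix(food)
  colnames(f) <- c("id", "x", "y", "remaining")
  new("SimulationState", t = t, animals = a, food = f,
      nBorn = 0, nDiedMin = 0, nDiedMax = 0,
      nextAnimalId = if (nrow(a)) max(a[, "id"]) + 1 else 1,
      nextFoodId = if (nrow(f)) max(f[, "id"]) + 1 else 1,
      totalDeposited = if (nrow(f)) sum(f[, "remaining"]) else 0,
      totalIntake = 0)
}
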