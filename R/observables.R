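## Observables: nearest-neighbour distances, instant + long-run histograms,
## velocity-vs-mass curves, time-volume maps, size-class series and 1D
## density profiles. All work from recorded snapshots, so they can be applied
## to a live state, a finished run, or reduced field detections alike.

#' Nearest-neighbour distances
#'
#' For each point, the Euclidean distance to its closest other point.
#'
#' @param positions numeric matrix (or data.frame) with two columns `x, y`
#'   and at least two rows.
#' @return numeric vector, one distance per point.
#' @examples
#' nearestNeighborDistances(cbind(c(0, 3), c(0, 4)))  # c(5, 5)
#' @export
nearestNeighborDistances <- function(positions) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2L) stop("nearest-neighbour distances need at least 2 points")
  dm <- as.matrix(dist(positions[, 1:2, drop = FALSE]))
  diag(dm) <- Inf
  unname(apply(dm, 1L, min))
}

#' Create a histogram accumulator
#'
#' @param edges strictly increasing bin edges; bins are `(e[i], e[i+1]]`.
#' @return a [HistogramAccumulator-class] with zero counts.
#' @export
histogramAccumulator <- function(edges) {
  nb <- length(edges) - 1L
  new("HistogramAccumulator", edges = as.numeric(edges),
      instant = numeric(nb), longRun = numeric(nb),
      nFolds = 0, nObs = 0, underflow = 0, overflow = 0)
}

#' Fold one snapshot of observations into an accumulator
#'
#' Replaces the `instant` counts with this snapshot's histogram and adds it
#' to the `longRun` counts. Observations at or below the first edge go to
#' the underflow tally, above the last edge to the overflow tally; nothing
#' is silently dropped.
#'
#' @param acc a [HistogramAccumulator-class] object.
#' @param x numeric observations (may be empty).
#' @return the updated accumulator.
#' @export
foldObservations <- function(acc, x) {
  stopifnot(is(acc, "HistogramAccumulator"))
  x <- as.numeric(x)
  e <- acc@edges
  nb <- length(e) - 1L
  idx <- findInterval(x, e, left.open = TRUE, rightmost.closed = FALSE)
  under <- sum(x <= e[1])
  over <- sum(idx > nb & x > e[1])
  inb <- idx[idx >= 1L & idx <= nb & x > e[1]]
  counts <- tabulate(inb, nbins = nb)
  acc@instant <- as.numeric(counts)
  acc@longRun <- acc@longRun + counts
  acc@nFolds <- acc@nFolds + 1
  acc@nObs <- acc@nObs + length(x)
  acc@underflow <- acc@underflow + under
  acc@overflow <- acc@overflow + over
  acc
}

#' @describeIn foldObservations bin midpoints of the accumulator.
#' @export
binMidpoints <- function(acc) {
  (acc@edges[-1] + acc@edges[-length(acc@edges)]) / 2
}

#' @describeIn foldObservations midpoint of the most populated long-run bin
#'   (ties: the first).
#' @export
histogramMode <- function(acc) {
  binMidpoints(acc)[which.max(acc@longRun)]
}

setMethod("show", "HistogramAccumulator", function(object) {
  cat(sprintf(
    "HistogramAccumulator: %d bins on [%g, %g], %d snapshot(s), %d obs",
    length(object@edges) - 1L, min(object@edges), max(object@edges),
    as.integer(object@nFolds), as.integer(object@nObs)))
  if (object@underflow + object@overflow > 0)
    cat(sprintf(" (%d out of range)",
                as.integer(object@underflow + object@overflow)))
  cat("\n")
  invisible(object)
})

#' Default bin edges for the standard observables
#'
#' Nearest-neighbour bins are `R_min/10` wide, spanning from 0 to the arena
#' diagonal; mass bins are `(m_max - m_min)/40` wide, spanning `(0, m_max]`.
#'
#' @param p a [SimulationParams-class] object.
#' @return numeric edge vector.
#' @export
nndBinEdges <- function(p) {
  w <- equilibriumDistance(p@m_s, p) / 10
  seq(0, ceiling(sqrt(p@Lx^2 + p@Ly^2) / w) * w, by = w)
}

#' @rdname nndBinEdges
#' @export
massBinEdges <- function(p) {
  w <- (p@m_max - p@m_min) / 40
  seq(0, ceiling(p@m_max / w) * w, by = w)
}

#' Fold a state's masses / nearest-neighbour distances into an accumulator
#'
#' `massHistogram()` folds the current animal masses; `nndHistogram()` folds
#' the current nearest-neighbour distances (states with fewer than two
#' animals fold an empty snapshot).
#'
#' @param state a [SimulationState-class] object.
#' @param acc a [HistogramAccumulator-class]; defaults to the standard edges
#'   of [massBinEdges()] / [nndBinEdges()].
#' @param p parameters used only to build the default accumulator.
#' @return the updated accumulator.
#' @export
massHistogram <- function(state, acc = histogramAccumulator(massBinEdges(p)),
                          p = NULL) {
  foldObservations(acc, state@animals[, "m"])
}

#' @rdname massHistogram
#' @export
nndHistogram <- function(state, acc = histogramAccumulator(nndBinEdges(p)),
                         p = NULL) {
  if (nrow(state@animals) < 2L) return(foldObservations(acc, numeric(0)))
  foldObservations(acc, nearestNeighborDistances(
    state@animals[, c("x", "y"), drop = FALSE]))
}

#' Fold every recorded snapshot of a run into an accumulator
#'
#' @param record a [RunRecord-class] object.
#' @param acc a [HistogramAccumulator-class] object.
#' @param what `"mass"` or `"nnd"`.
#' @param tMin fold only snapshots with `t >= tMin`.
#' @return the updated accumulator.
#' @export
foldRun <- function(record, acc, what = c("mass", "nnd"), tMin = -Inf) {
  what <- match.arg(what)
  sn <- record@snapshots
  sn <- sn[sn$t >= tMin, , drop = FALSE]
  for (s in unique(sn$step)) {
    rows <- sn[sn$step == s, , drop = FALSE]
    if (what == "mass") {
      acc <- foldObservations(acc, rows$m)
    } else {
      if (nrow(rows) >= 2L)
        acc <- foldObservations(acc,
                                nearestNeighborDistances(rows[, c("x", "y")]))
      else acc <- foldObservations(acc, numeric(0))
    }
  }
  acc
}

#' Mass-binned mean speed
#'
#' Bins the animals of the given snapshots by mass and averages their speeds
#' `|v|`, pooling all supplied snapshot rows (use one recorded step for an
#' instant curve, many for a run-accumulated curve). Empty bins are reported
#' with `n = 0` and `NA` mean, not zero.
#'
#' @param snapshots data.frame with columns `m, vx, vy` (e.g. from
#'   [snapshots()]).
#' @param massEdges bin edges for the mass axis.
#' @return data.frame `m_mid, mean_speed, n`.
#' @export
velocityVsMass <- function(snapshots, massEdges) {
  stopifnot(nrow(snapshots) >= 1L)
  nb <- length(massEdges) - 1L
  idx <- findInterval(snapshots$m, massEdges, left.open = TRUE)
  speed <- sqrt(snapshots$vx^2 + snapshots$vy^2)
  keep <- idx >= 1L & idx <= nb
  n <- tabulate(idx[keep], nbins = nb)
  sums <- vapply(seq_len(nb), function(b) sum(speed[keep & idx == b]), 0)
  data.frame(m_mid = (massEdges[-1] + massEdges[-nb - 1L]) / 2,
             mean_speed = ifelse(n > 0, sums / pmax(n, 1), NA_real_),
             n = n)
}

#' Time-volume (time-mass) map
#'
#' Per-recorded-step mass histograms stacked into a matrix (rows = recorded
#' steps, columns = mass bins), the numeric content of a gray-scale
#' time-volume map. Volume is taken proportional to mass with unit density.
#' Each row sums to the population size at that recorded step (masses
#' outside the bin range are not possible for `(0, m_max]` edges).
#'
#' @param record a [RunRecord-class] object.
#' @param massEdges bin edges; default [massBinEdges()] of the run's params.
#' @return numeric matrix with rownames the recorded times and an attribute
#'   `edges`.
#' @export
timeVolumeMap <- function(record, massEdges = massBinEdges(record@params)) {
  sn <- record@snapshots
  steps <- unique(sn$step)
  nb <- length(massEdges) - 1L
  out <- matrix(0, length(steps), nb,
                dimnames = list(format(
                  sn$t[match(steps, sn$step)], trim = TRUE), NULL))
  for (i in seq_along(steps)) {
    m <- sn$m[sn$step == steps[i]]
    idx <- findInterval(m, massEdges, left.open = TRUE)
    out[i, ] <- tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
  }
  attr(out, "edges") <- massEdges
  out
}

#' Write a time-volume map as a dense text matrix
#'
#' Tab-separated, one recorded step per row, bin midpoints in the header.
#'
#' @param map matrix from [timeVolumeMap()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTimeVolumeMap <- function(map, path) {
  e <- attr(map, "edges")
  mid <- (e[-1] + e[-length(e)]) / 2
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("t", format(mid)), collapse = "\t"), con)
  utils::write.table(cbind(rownames(map), format(map, trim = TRUE)), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' One-dimensional density profiles along the dangerous axis
#'
#' Time-averaged histograms of position `x` (the axis perpendicular to the
#' dangerous wall at `x = 0`) for each size class, the total population and
#' the food portions, normalised to mean counts per snapshot per bin.
#'
#' @param record a [RunRecord-class] object.
#' @param nBinsX number of bins across `[0, Lx]`.
#' @param tMin use only snapshots with `t >= tMin` (e.g. to drop the initial
#'   transient).
#' @return data.frame `x_mid, small, medium, large, total, food`.
#' @export
densityProfiles <- function(record, nBinsX = 40L, tMin = -Inf) {
  p <- record@params
  edges <- seq(0, p@Lx, length.out = nBinsX + 1L)
  sn <- record@snapshots[record@snapshots$t >= tMin, , drop = FALSE]
  fs <- record@foodSnapshots[record@foodSnapshots$t >= tMin, , drop = FALSE]
  nSnap <- length(unique(sn$step))
  if (nSnap == 0L) stop("no recorded snapshots at t >= tMin")
  binc <- function(x) {
    idx <- findInterval(x, edges, left.open = TRUE, rightmost.closed = TRUE)
    idx[x <= edges[1]] <- 1L
    tabulate(pmin(pmax(idx, 1L), nBinsX), nbins = nBinsX) / nSnap
  }
  cls <- classifySize(sn$m, p)
  data.frame(
    x_mid = (edges[-1] + edges[-nBinsX - 1L]) / 2,
    small = binc(sn$x[cls == "small"]),
    medium = binc(sn$x[cls == "medium"]),
    large = binc(sn$x[cls == "large"]),
    total = binc(sn$x),
    food = binc(fs$x))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic Kolmogorov distribution at the effective sample size
#' `n_a n_b / (n_a + n_b)` (with the standard small-sample correction of the
#' evaluation point).
#'
#' @param a,b non-empty numeric samples.
#' @return list with `D`, `p.value` and `n.eff`.
#' @export
ksTwoSample <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  pooled <- sort(unique(c(a, b)))
  Fa <- ecdf(a)(pooled)
  Fb <- ecdf(b)(pooled)
  D <- max(abs(Fa - Fb))
  ne <- length(a) * length(b) / (length(a) + length(b))
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  k <- 1:100
  pval <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(D = D, p.value = max(0, min(1, pval)), n.eff = ne)
}
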