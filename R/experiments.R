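## Canned numerical experiments. These reproduce, at package scale, the
## study designs behind the published figures: long-run nearest-neighbour
## statistics of a non-growing swarm, convergence of the mass distribution
## from two extreme initial populations, the velocity-mass relation at
## stationarity, and the spatial redistribution under periodic waves of
## fear. Both the test suite and scripts/acceptance.R drive these.

#' Long-run nearest-neighbour spacing of a non-growing swarm
#'
#' Runs the swarm with demography and foraging disabled and all masses equal,
#' folds the nearest-neighbour distances of every recorded snapshot after the
#' relaxation transient into a histogram with bins of width `R_min/10`, and
#' compares the histogram mode against the analytic equilibrium separation.
#'
#' @param p parameter set; demography/foraging/mass spread are switched off
#'   internally.
#' @param nSteps run length (default 50000 steps).
#' @param seed RNG seed.
#' @param tMin transient to discard before folding (time units).
#' @return list with `rmin`, `mode`, `offsetBins` (signed distance of the
#'   mode from `R_min` in bin widths) and the accumulator `acc`.
#' @export
nndModeExperiment <- function(p = simulationParams(), nSteps = 50000,
                              seed = 21, tMin = 100) {
  p <- setParams(p, p_birth = 0, p_food = 0, lam = 0, m_s_spread = 0,
                 m_init = p@m_s, m_init_spread = 0, B_wave = 0)
  rec <- runSimulation(p, nSteps = nSteps, recordEvery = 500, seed = seed)
  acc <- foldRun(rec, histogramAccumulator(nndBinEdges(p)), "nnd",
                 tMin = tMin)
  rmin <- equilibriumDistance(p@m_s, p)
  mode <- histogramMode(acc)
  list(rmin = rmin, mode = mode,
       offsetBins = (mode - rmin) / (rmin / 10), acc = acc)
}

#' Convergence of the mass distribution from two extreme initial populations
#'
#' For each seed, runs one population started from small individuals only and
#' one from large individuals only, and compares their final-quarter mass
#' distributions: the two-sample KS distance over all pooled final-quarter
#' animal-snapshots, and the long-run histogram modes. Also returns the
#' pooled stationary snapshots (used for the velocity-mass relation) and the
#' time-averaged size-class counts.
#'
#' @param seeds integer seeds, one pair of runs each.
#' @param nSteps steps per run.
#' @param ... parameter overrides applied to both scenarios.
#' @return list with per-seed `ks` (D values), `modeSmall`, `modeLarge`
#'   (histogram modes per seed), `modeBinWidth`, `classMeans` (time-averaged
#'   small/medium/large counts, all runs), and `pooled` stationary snapshots.
#' @export
convergenceExperiment <- function(seeds = 1:3, nSteps = 100000, ...) {
  pS <- scenarioParams("all_small_start", ...)
  pL <- scenarioParams("all_large_start", ...)
  tq <- 0.75 * nSteps * pS@dt
  edges <- massBinEdges(pS)
  ks <- modeS <- modeL <- numeric(0)
  classMeans <- c(small = 0, medium = 0, large = 0)
  pooled <- NULL
  for (sd in seeds) {
    rs <- runSimulation(pS, nSteps, recordEvery = 500, seed = sd)
    rl <- runSimulation(pL, nSteps, recordEvery = 500, seed = sd + 1000)
    lateS <- snapshots(rs); lateS <- lateS[lateS$t >= tq, ]
    lateL <- snapshots(rl); lateL <- lateL[lateL$t >= tq, ]
    ks <- c(ks, ksTwoSample(lateS$m, lateL$m)$D)
    hS <- foldRun(rs, histogramAccumulator(edges), "mass", tMin = tq)
    hL <- foldRun(rl, histogramAccumulator(edges), "mass", tMin = tq)
    modeS <- c(modeS, histogramMode(hS))
    modeL <- c(modeL, histogramMode(hL))
    for (r in list(rs, rl)) {
      cc <- counters(r); cc <- cc[cc$t >= tq, ]
      classMeans <- classMeans +
        c(mean(cc$N_c1), mean(cc$N_c2), mean(cc$N_c3)) /
          (2 * length(seeds))
    }
    pooled <- rbind(pooled, lateS, lateL)
  }
  list(ks = ks, modeSmall = modeS, modeLarge = modeL,
       modeBinWidth = diff(edges)[1], classMeans = classMeans,
       pooled = pooled)
}

#' Velocity-mass monotonicity at stationarity
#'
#' Bins the pooled stationary snapshots by mass, averages speeds per bin and
#' computes the Spearman rank correlation between bin mass and mean speed.
#' Bins with fewer than `minCount` observations carry too little information
#' to estimate a mean and are excluded (they are reported as missing by
#' [velocityVsMass()]).
#'
#' @param pooled stationary snapshot rows (e.g. from
#'   [convergenceExperiment()]).
#' @param p parameter set whose mass-bin edges to use.
#' @param minCount minimum observations per bin (default 50; the pooled
#'   stationary data hold hundreds of thousands of animal-snapshots, so
#'   sparser bins are dominated by a handful of autocorrelated tracks).
#' @return list with `rho`, the curve `vm`, and `nBins` used.
#' @export
speedMassExperiment <- function(pooled, p = simulationParams(),
                                minCount = 50) {
  vm <- velocityVsMass(pooled, massBinEdges(p))
  use <- vm[vm$n >= minCount, ]
  list(rho = cor(use$m_mid, use$mean_speed, method = "spearman"),
       vm = vm, nBins = nrow(use))
}

#' Spatial redistribution under periodic waves of fear
#'
#' Runs the fear-wave scenario, accumulates the time-averaged density
#' profiles along the axis perpendicular to the dangerous wall, and reports
#' the ratio of animal density in the quarter nearest the danger to the
#' farthest quarter together with the Pearson correlation between the food
#' and total-animal profiles.
#'
#' @param nSteps run length.
#' @param seed RNG seed.
#' @param ... overrides applied to the `fear_wave` scenario.
#' @return list with `nearFarRatio`, `foodAnimalCor`, the `profiles`
#'   data.frame, and the run's mean population `meanN`.
#' @export
waveExperiment <- function(nSteps = 100000, seed = 5, ...) {
  p <- scenarioParams("fear_wave", ...)
  rec <- runSimulation(p, nSteps = nSteps, recordEvery = 500, seed = seed)
  prof <- densityProfiles(rec, nBinsX = 40, tMin = 100)
  near <- prof$x_mid <= p@Lx / 4
  far <- prof$x_mid >= 3 * p@Lx / 4
  cc <- counters(rec)
  list(nearFarRatio = sum(prof$total[near]) / sum(prof$total[far]),
       foodAnimalCor = cor(prof$food, prof$total),
       profiles = prof, meanN = mean(cc$N[cc$t >= 100]))
}
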