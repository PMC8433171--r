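test_that("initial state honours the construction contract", {
  p <- simulationParams(N0 = 100)
  st <- initState(p, seed = 3)
  expect_equal(population(st), 100)
  a <- animals(st)
  expect_true(all(a$vx == 0 & a$vy == 0))        # all initial velocities zero
  expect_true(all(a$x >= 0 & a$x <= p@Lx & a$y >= 0 & a$y <= p@Ly))
  expect_true(all(abs(a$m - p@m_s) <= p@m_s_spread))
  expect_equal(nrow(st@food), 0L)
  expect_equal(st@t, 0)
  # empty population
  st0 <- initState(simulationParams(N0 = 0), seed = 3)
  expect_equal(population(st0), 0)
  expect_equal(st0@nBorn + st0@nDiedMin + st0@nDiedMax, 0)
  # determinism of construction
  expect_identical(initState(p, seed = 7), initState(p, seed = 7))
})

test_that("a lone centred animal stays put; free motion decays as e^(-eta t/m)", {
  p <- simulationParams(N0 = 0, p_birth = 0, p_food = 0, lam = 0)
  still <- makeState(cbind(1, p@Lx / 2, p@Ly / 2, 0, 0, 1, 0))
  out <- still
  for (i in 1:100) out <- stepState(out, p)
  expect_equal(animals(out)$x, p@Lx / 2, tolerance = 1e-9)
  expect_equal(animals(out)$vx, 0, tolerance = 1e-12)
  # free damped motion against the closed form, T = 0.25 m/eta
  m <- 2
  eta <- dampingCoefficient(m, p)
  v0 <- 3
  st <- makeState(cbind(1, p@Lx / 2, p@Ly / 2, v0, 0, m, 0))
  Tn <- round(0.25 * m / eta / p@dt)
  for (i in seq_len(Tn)) st <- stepState(st, p)
  expect_equal(animals(st)$vx, v0 * exp(-eta * Tn * p@dt / m),
               tolerance = 1e-3)
})

test_that("two equal animals relax to the analytic equilibrium separation", {
  p <- simulationParams(N0 = 0, p_birth = 0, p_food = 0, lam = 0)
  rmin <- equilibriumDistance(1, p)
  cx <- p@Lx / 2; cy <- p@Ly / 2
  st <- makeState(cbind(1:2, c(cx - rmin, cx + rmin), cy, 0, 0, 1, 0))
  for (i in 1:20000) st <- stepState(st, p)
  a <- animals(st)
  sep <- sqrt(diff(a$x)^2 + diff(a$y)^2)
  expect_equal(sep, rmin, tolerance = 0.01)
})

test_that("single steps compose into runs and match the pure-R phases", {
  p <- simulationParams(N0 = 15, p_birth = 0.3, p_food = 0.3, seed = 9)
  # composition: n stepState calls == one runSimulation of n steps
  set.seed(9); st <- initState(p)
  for (i in 1:50) st <- stepState(st, p)
  rec <- runSimulation(p, nSteps = 50, recordEvery = 50, seed = 9)
  expect_identical(st@animals, finalState(rec)@animals)
  expect_identical(st@food, finalState(rec)@food)
  expect_equal(st@nBorn, finalState(rec)@nBorn)
  # engine step vs composition of the documented R phases, same RNG draws
  set.seed(21); st0 <- initState(p)
  rng <- .Random.seed
  engine <- stepState(st0, p)
  .Random.seed <<- rng
  ref <- integrateStep(st0, forceField(st0, p)$total, p)
  ref@t <- st0@t + p@dt
  ref <- consumeAndGrow(ref, p)
  ref <- cull(ref, p)
  ref <- maybeRecruit(ref, p)
  ref <- maybeDepositFood(ref, p)
  expect_equal(engine@animals, ref@animals, tolerance = 1e-10)
  expect_equal(engine@food, ref@food, tolerance = 1e-12)
  expect_equal(engine@nBorn, ref@nBorn)
  expect_equal(engine@nDiedMin + engine@nDiedMax,
               ref@nDiedMin + ref@nDiedMax)
})

test_that("same seed gives bit-identical runs; records honour record_every", {
  p <- simulationParams(N0 = 20, seed = 11)
  r1 <- runSimulation(p, nSteps = 400, recordEvery = 100)
  r2 <- runSimulation(p, nSteps = 400, recordEvery = 100)
  expect_identical(snapshots(r1), snapshots(r2))
  expect_identical(counters(r1), counters(r2))
  r3 <- runSimulation(p, nSteps = 400, recordEvery = 100, seed = 12)
  expect_false(identical(snapshots(r1), snapshots(r3)))
  # record_every > nSteps: only the initial snapshot
  r4 <- runSimulation(p, nSteps = 50, recordEvery = 100)
  expect_equal(unique(snapshots(r4)$step), 0)
  expect_equal(nrow(counters(r4)), 1L)
})

test_that("population bookkeeping balances at every recorded step", {
  p <- simulationParams(N0 = 30, p_birth = 0.2, lam = 0.05, seed = 13)
  rec <- runSimulation(p, nSteps = 3000, recordEvery = 1)
  cc <- counters(rec)
  expect_true(all(cc$N == p@N0 + cc$n_born - cc$n_died_min - cc$n_died_max))
  expect_true(all(cc$N_c1 + cc$N_c2 + cc$N_c3 == cc$N))
})

test_that("containment: no animal strays beyond 3 R_bound over a long run", {
  p <- simulationParams(N0 = 80, seed = 15)
  rec <- runSimulation(p, nSteps = 20000, recordEvery = 200)
  sn <- snapshots(rec)
  expect_gt(min(sn$x), -3 * p@R_bound)
  expect_lt(max(sn$x), p@Lx + 3 * p@R_bound)
  expect_gt(min(sn$y), -3 * p@R_bound)
  expect_lt(max(sn$y), p@Ly + 3 * p@R_bound)
})

test_that("with all stochastics off the dynamics dissipate kinetic energy", {
  p <- simulationParams(N0 = 60, p_birth = 0, p_food = 0, lam = 0,
                        seed = 19)
  rec <- runSimulation(p, nSteps = 20000, recordEvery = 200)
  sn <- snapshots(rec)
  ke <- vapply(split(sn, sn$step), function(s)
    sum(s$m * (s$vx^2 + s$vy^2) / 2), 0)
  ke <- ke[order(as.integer(names(ke)))]
  # relaxation passes through metastable cluster rearrangements, so KE is
  # only envelope-monotone: maxima over successive quarters must decay,
  # and almost all the initial kinetic energy must be dissipated
  blocks <- split(ke, cut(seq_along(ke), 4, labels = FALSE))
  expect_true(all(diff(vapply(blocks, max, 0)) < 0))
  expect_lt(ke[length(ke)], 1e-3 * max(ke))
})

test_that("extinction is recorded, not fatal, and the run continues", {
  p <- simulationParams(N0 = 5, p_birth = 0, p_food = 0, lam = 0.05,
                        seed = 23)
  rec <- runSimulation(p, nSteps = 40000, recordEvery = 500)
  cc <- counters(rec)
  expect_equal(cc$N[nrow(cc)], 0)
  expect_true(any(cc$N == 0))
  # once extinct with no recruitment it stays extinct
  first0 <- min(which(cc$N == 0))
  expect_true(all(cc$N[first0:nrow(cc)] == 0))
})

test_that("run exports are written completely and reproducibly", {
  p <- simulationParams(N0 = 10, seed = 27)
  rec <- runSimulation(p, nSteps = 200, recordEvery = 100)
  d <- withr::local_tempdir()
  writeRunRecord(rec, d)
  expect_true(all(file.exists(file.path(d,
    c("snapshots.csv", "food_snapshots.csv", "counters.csv",
      "food_events.csv", "params.cfg", "run_log.txt")))))
  back <- read.csv(file.path(d, "counters.csv"))
  expect_equal(back$N, counters(rec)$N)
  expect_identical(paramList(readParams(file.path(d, "params.cfg"))),
                   paramList(p))
})
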