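test_that("Gaussian pair force kernels evaluate exactly", {
  # coincident points: the (r_j - r_k) prefactor vanishes
  expect_identical(pairRepulsion(c(1, 1), c(1, 1), 1, 1), c(0, 0))
  expect_identical(pairAttraction(c(1, 1), c(1, 1), 1, 1), c(0, 0))
  # direct evaluation at unit separation
  expect_equal(pairRepulsion(c(1, 0), c(0, 0), B = 1, R = 1),
               c(exp(-1), 0))
  expect_equal(pairAttraction(c(1, 0), c(0, 0), B = 1, R = 2),
               c(-exp(-1 / 4), 0))
  expect_error(pairRepulsion(c(1, 0), c(0, 0), 1, 0), "radius")
})

test_that("pair force magnitude peaks at R/sqrt(2) (grid-scan oracle)", {
  R <- 1.7
  d <- seq(0.01, 5, by = 0.001)
  mag <- vapply(d, function(x)
    sqrt(sum(pairRepulsion(c(x, 0), c(0, 0), 2, R)^2)), 0)
  expect_equal(d[which.max(mag)], R / sqrt(2), tolerance = 1e-3)
})

test_that("mass scaling of amplitudes, radii and damping", {
  p <- simulationParams()
  # unit-mass identity
  ar <- pairAmplitudeRadius(1, 1, p)
  expect_equal(unlist(ar),
               c(B_repuls = p@B_repuls0, R_repuls = p@R_repuls0,
                 B_attract = p@B_attract0, R_attract = p@R_attract0))
  # m = 8: strength x4 (8^(2/3)), reach x2 (8^(1/3))
  ar8 <- pairAmplitudeRadius(8, 8, p)
  expect_equal(ar8$B_repuls, 4 * p@B_repuls0)
  expect_equal(ar8$R_repuls, 2 * p@R_repuls0)
  expect_equal(ar8$B_attract, 4 * p@B_attract0)
  expect_equal(ar8$R_attract, 2 * p@R_attract0)
  # radii are pair-symmetric; amplitudes belong to the receiver
  a12 <- pairAmplitudeRadius(1, 8, p)
  a21 <- pairAmplitudeRadius(8, 1, p)
  expect_equal(a12$R_repuls, a21$R_repuls)
  expect_equal(a12$B_repuls, p@B_repuls0)
  expect_equal(a21$B_repuls, 4 * p@B_repuls0)
  # damping
  expect_equal(dampingCoefficient(1, p), p@eta0)
  expect_equal(dampingCoefficient(8, p), 2 * p@eta0)
  m <- sort(runif(50, 0.5, 10))
  expect_true(all(diff(dampingCoefficient(m, p)) >= 0))
})

test_that("boundary force pushes inward and decays into the arena", {
  p <- simulationParams()
  centre <- boundaryForce(c(p@Lx / 2, p@Ly / 2), p)
  expect_lt(sqrt(sum(centre^2)),
            2 * p@B_bound * exp(-p@Lx / (2 * p@R_bound)) + 1e-300)
  onWall <- boundaryForce(c(0, p@Ly / 2), p)
  expect_equal(onWall[1], p@B_bound, tolerance = 1e-12)
  corner <- boundaryForce(c(0, 0), p)
  expect_equal(corner, c(p@B_bound, p@B_bound), tolerance = 1e-12)
})

test_that("food force: zero at contact, 2^(2/3) mass scaling, direct value", {
  p <- simulationParams(B_food0 = 1, R_food = 1)
  expect_identical(foodForce(c(2, 3), 1, c(2, 3), p), c(0, 0))
  f1 <- foodForce(c(1, 0), 1, c(0, 0), p)
  f2 <- foodForce(c(1, 0), 2, c(0, 0), p)
  expect_equal(sqrt(sum(f2^2)) / sqrt(sum(f1^2)), 2^(2 / 3))
  expect_equal(f1, c(-exp(-1), 0))
})

test_that("wave force obeys its schedule and closed-form drift scaling", {
  p0 <- simulationParams()          # disabled by default
  expect_identical(waveForce(c(1, 1), 5, t = 10, p0), c(0, 0))
  p <- scenarioParams("fear_wave")  # period 50, duration 2.5
  expect_identical(waveForce(c(1, 1), 5, t = 10, p), c(0, 0))
  active <- waveForce(c(1, 1), 5, t = 51, p)
  expect_gt(active[1], 0)
  expect_equal(active[2], 0)
  # terminal drift speed F/eta at fixed distance grows as m^(1/3)
  d <- 2
  drift <- vapply(c(1, 8), function(m)
    waveForce(c(d, 0), m, t = 50.1, p)[1] / dampingCoefficient(m, p), 0)
  expect_equal(drift[2] / drift[1], 8^(1 / 3), tolerance = 1e-12)
  expect_equal(active[1], p@B_wave * 5^(2 / 3) * exp(-1 / p@R_wave))
})

test_that("equilibrium distance matches a bracketing root of the net force", {
  # spec-style example with prefactors absorbed at unit mass
  p <- simulationParams(B_repuls0 = 2, B_attract0 = 1, R_repuls0 = 1,
                        R_attract0 = 2, R_bound = 0.05)
  expect_equal(equilibriumDistance(1, p), sqrt(log(2) / 0.75),
               tolerance = 1e-12)
  # independent bracketing oracle on the net radial force
  root <- uniroot(netPairForce, c(0.1, 10), m = 1, p = p, tol = 1e-12)$root
  expect_equal(equilibriumDistance(1, p), root, tolerance = 1e-9)
  # R_min scales as m^(1/3); oracle again at a different mass
  root8 <- uniroot(netPairForce, c(0.1, 10), m = 8, p = p, tol = 1e-12)$root
  expect_equal(equilibriumDistance(8, p), root8, tolerance = 1e-9)
  expect_equal(equilibriumDistance(8, p), 2 * equilibriumDistance(1, p),
               tolerance = 1e-12)
  # degenerate: equal amplitudes leave no interior minimum
  pbad <- simulationParams()
  pbad@B_attract0 <- pbad@B_repuls0
  expect_error(equilibriumDistance(1, pbad), "no positive equilibrium")
})

test_that("net pair force changes sign exactly at R_min on a grid", {
  p <- simulationParams()
  rmin <- equilibriumDistance(1, p)
  d <- seq(0.05, 3 * rmin, by = 0.01)
  f <- vapply(d, netPairForce, 0, m = 1, p = p)
  expect_true(all(f[d < rmin - 0.01] > 0))
  expect_true(all(f[d > rmin + 0.01] < 0))
})

test_that("equal-mass pair forces inject zero net momentum; unequal masses
           favour the stronger responder", {
  p <- simulationParams()
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    st <- makeState(cbind(seq_len(n), runif(n, 0, p@Lx), runif(n, 0, p@Ly),
                          0, 0, rep(2, n), 0))
    ff <- forceField(st, p)
    expect_equal(colSums(ff$pair), c(0, 0), tolerance = 1e-10)
  }
  # two unequal animals: forces are antiparallel, the heavier responds harder
  st <- makeState(cbind(1:2, c(9, 10.5), 10, 0, 0, c(1, 8), 0))
  ff <- forceField(st, p)$pair
  expect_lt(ff[1, 1], 0)  # light one pushed away (toward -x)
  expect_gt(ff[2, 1], 0)
  expect_gt(abs(ff[2, 1]) / abs(ff[1, 1]), 3.9)  # ~ 8^(2/3) = 4
})

test_that("pair kernels decay below 1e-12 of their peak beyond 6 radii", {
  B <- 3; R <- 1.3
  peak <- sqrt(sum(pairRepulsion(c(R / sqrt(2), 0), c(0, 0), B, R)^2))
  far <- sqrt(sum(pairRepulsion(c(6 * R, 0), c(0, 0), B, R)^2))
  expect_lt(far / peak, 1e-12)
})
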