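test_that("state energies match a hand-summed double loop", {
  set.seed(21)
  n <- 3L
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(3, 0, 2)
  W <- W + t(W)
  sys <- titrationSystem(
    data.frame(kind = c("acid", "base", "acid"), pkaIntr = c(4, 10.4, 9.5)),
    wMatrix = W, pH = 6.2, temperature = 310)
  kT <- 0.0019872 * 310
  g <- log(10) * kT * (6.2 - c(4, 10.4, 9.5))
  qd <- c(-1, 0, -1)
  for (k in 0:7) {
    x <- as.integer(intToBits(k))[1:3]
    # independent scalar summation of the microstate energy
    E <- 0
    for (m in 1:3) {
      E <- E + x[m] * g[m]
      for (v in 1:3) if (v != m)
        E <- E + 0.5 * (qd[m] + x[m]) * (qd[v] + x[v]) * W[m, v]
    }
    expect_equal(stateEnergy(sys, x), E, tolerance = 1e-12)
  }
  # additivity when W = 0
  sys0 <- titrationSystem(
    data.frame(kind = c("acid", "base"), pkaIntr = c(4, 10)), pH = 7)
  expect_equal(stateEnergy(sys0, c(1, 1)),
               stateEnergy(sys0, c(1, 0)) + stateEnergy(sys0, c(0, 1)),
               tolerance = 1e-12)
  # midpoint degeneracy for a single acid
  sys1 <- titrationSystem(data.frame(kind = "acid", pkaIntr = 4), pH = 4)
  expect_equal(stateEnergy(sys1, 1) - stateEnergy(sys1, 0), 0,
               tolerance = 1e-12)
  expect_error(stateEnergy(sys1, c(1, 0)), "length")
})

test_that("exact enumeration reproduces Henderson-Hasselbalch", {
  # isolated Asp-type site at its reference pKa titrates to one half
  sys <- titrationSystem(data.frame(kind = "acid", pkaIntr = 4.0), pH = 4.0)
  expect_equal(unname(probabilities(enumerateExact(sys))), 0.5,
               tolerance = 1e-12)
  # two pK units above the midpoint
  sys2 <- titrationSystem(data.frame(kind = "acid", pkaIntr = 4.0),
                          pH = 6.0)
  expect_equal(unname(probabilities(enumerateExact(sys2))), 1 / 101,
               tolerance = 1e-9)
  # every isolated site (acid or base) follows the closed form
  for (pka in c(3.5, 7.0, 10.4)) for (kind in c("acid", "base"))
    for (pH in c(3, 7, 11)) {
      sys3 <- titrationSystem(data.frame(kind = kind, pkaIntr = pka),
                              pH = pH)
      expect_equal(unname(probabilities(enumerateExact(sys3))),
                   hh(pH, pka), tolerance = 1e-9)
    }
})

test_that("two coupled acids match the hand-evaluated 4-state partition", {
  W <- matrix(c(0, 1.36, 1.36, 0), 2, 2)
  sys <- titrationSystem(
    data.frame(kind = c("acid", "acid"), pkaIntr = c(4, 5)),
    wMatrix = W, pH = 4.5)
  kT <- 0.0019872 * 300
  g <- log(10) * kT * (4.5 - c(4, 5))
  states <- expand.grid(x1 = 0:1, x2 = 0:1)
  E <- apply(states, 1L, function(x)
    sum(x * g) + (x[1] - 1) * (x[2] - 1) * 1.36)
  w <- exp(-E / kT)
  hand <- c(sum(w[states$x1 == 1]) / sum(w),
            sum(w[states$x2 == 1]) / sum(w))
  expect_equal(unname(probabilities(enumerateExact(sys))), hand,
               tolerance = 1e-9)
})

test_that("enumeration is guarded at 20 sites and normalises correctly", {
  big <- titrationSystem(data.frame(kind = rep("acid", 21),
                                    pkaIntr = rep(7, 21)), pH = 7)
  expect_error(enumerateExact(big), "mcTitrate")
  # weights sum to one: symmetric two-site system at the midpoint
  sys <- titrationSystem(data.frame(kind = c("acid", "acid"),
                                    pkaIntr = c(5, 5)), pH = 5)
  p <- probabilities(enumerateExact(sys))
  expect_equal(unname(p[1]), unname(p[2]), tolerance = 1e-12)
})

test_that("fixture ground truth agrees with exact enumeration", {
  for (seed in c(7, 23)) {
    fx <- makeFixture("titration_system", params = list(n = 6), seed = seed)
    gt <- groundTruth(fx)
    sys <- titrationSystem(gt$sites, wMatrix = gt$w_matrix, pH = gt$pH,
                           temperature = gt$temperature)
    expect_equal(unname(probabilities(enumerateExact(sys))),
                 unname(gt$probabilities), tolerance = 1e-9)
  }
})

test_that("Monte Carlo titration agrees with exact enumeration", {
  fx <- makeFixture("titration_system", params = list(n = 5), seed = 31)
  gt <- groundTruth(fx)
  sys <- titrationSystem(gt$sites, wMatrix = gt$w_matrix, pH = gt$pH)
  ex <- probabilities(enumerateExact(sys))
  mc <- mcTitrate(sys, sweeps = 50000L, burnIn = 5000L, seed = 2)
  z <- abs(probabilities(mc) - ex) / pmax(mcError(mc), 1e-9)
  expect_true(all(z < 3))
  # independence limit: W = 0 reduces to Henderson-Hasselbalch
  sys0 <- titrationSystem(data.frame(
    kind = rep(c("acid", "base"), 5),
    pkaIntr = seq(5, 9, length.out = 10)), pH = 7)
  mc0 <- mcTitrate(sys0, sweeps = 40000L, burnIn = 4000L, seed = 9)
  expected <- hh(7, seq(5, 9, length.out = 10))
  z0 <- abs(probabilities(mc0) - expected) / pmax(mcError(mc0), 1e-9)
  expect_true(all(z0 < 3.5))
})

test_that("Monte Carlo results are bitwise reproducible under a seed", {
  fx <- makeFixture("titration_system", params = list(n = 8), seed = 5)
  gt <- groundTruth(fx)
  sys <- titrationSystem(gt$sites, wMatrix = gt$w_matrix, pH = gt$pH)
  a <- mcTitrate(sys, sweeps = 20000L, burnIn = 2000L, seed = 17)
  b <- mcTitrate(sys, sweeps = 20000L, burnIn = 2000L, seed = 17)
  expect_identical(probabilities(a), probabilities(b))
  expect_identical(mcError(a), mcError(b))
  c <- mcTitrate(sys, sweeps = 20000L, burnIn = 2000L, seed = 18)
  expect_false(identical(probabilities(a), probabilities(c)))
})

test_that("titration curves are monotone where thermodynamics requires", {
  # every isolated site titrates monotonically (Henderson-Hasselbalch),
  # and the TOTAL protonation of any coupled system is non-increasing in
  # pH (its derivative is proportional to -Var(sum x)); individual sites
  # of strongly coupled systems may legitimately show local bumps
  grid <- seq(1, 13, by = 0.5)
  iso <- titrationSystem(data.frame(kind = "acid", pkaIntr = 6), pH = 7)
  isoCurve <- vapply(grid, function(ph) {
    s2 <- iso; s2@conditions$pH <- ph
    unname(probabilities(enumerateExact(s2)))
  }, numeric(1L))
  expect_true(all(diff(isoCurve) < 0))
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(2:4, 1L)
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- runif(n * (n - 1) / 2, 0, 1.5)
    W <- W + t(W)
    sys <- titrationSystem(
      data.frame(kind = rep("acid", n), pkaIntr = runif(n, 3, 9)),
      wMatrix = W, pH = 7)
    total <- vapply(grid, function(ph) {
      s2 <- sys; s2@conditions$pH <- ph
      sum(probabilities(enumerateExact(s2)))
    }, numeric(1L))
    expect_true(all(diff(total) <= 1e-12))
  }
})

test_that("symmetric sites titrate identically (exact and MC)", {
  W <- matrix(c(0, 0.8, 0.8, 0), 2, 2)
  sys <- titrationSystem(data.frame(kind = c("acid", "acid"),
                                    pkaIntr = c(6, 6)), wMatrix = W,
                         pH = 6.5)
  p <- probabilities(enumerateExact(sys))
  expect_equal(unname(p[1]), unname(p[2]), tolerance = 1e-12)
  mc <- mcTitrate(sys, sweeps = 60000L, burnIn = 6000L, seed = 4)
  expect_lt(abs(probabilities(mc)[1] - probabilities(mc)[2]),
            3 * sqrt(sum(mcError(mc)^2)))
})

test_that("pKa curves locate half-protonation points", {
  # an isolated histidine N-epsilon site titrates at its reference 7.0
  his <- titrationSystem(data.frame(kind = "base", pkaIntr = 7.0,
                                    siteId = "HIS-NE2"), pH = 7)
  pc <- pkaCurve(his, "HIS-NE2")
  expect_true(pc$crossed)
  expect_equal(pc$pkaHalf, 7.0, tolerance = 0.05)
  # a +1 intrinsic shift moves the half-point by one pK unit
  shifted <- titrationSystem(data.frame(kind = "acid", pkaRef = 4.4,
                                        pkaIntr = 5.4), pH = 7)
  expect_equal(pkaCurve(shifted, 1L)$pkaHalf, 5.4, tolerance = 0.05)
  # a fixed negative background folded into the intrinsic term raises the
  # pKa and the curve still matches the exact backend
  raised <- titrationSystem(data.frame(kind = "acid", pkaRef = 4.4,
                                       pkaIntr = 6.9), pH = 7)
  pcr <- pkaCurve(raised, 1L)
  expect_gt(pcr$pkaHalf, 5.4)
  expect_equal(pcr$pkaHalf, 6.9, tolerance = 0.05)
  # no crossing in range is flagged, not fabricated
  out <- pkaCurve(titrationSystem(data.frame(kind = "acid", pkaIntr = 4),
                                  pH = 7), 1L, phGrid = seq(8, 12, 0.5))
  expect_false(out$crossed)
  expect_true(is.na(out$pkaHalf))
})

test_that("protonation-pattern deviations mirror the reference table", {
  # all sites at their reference pKa at pH 7: nothing deviates
  sites <- data.frame(kind = c("acid", "acid", "base", "base", "acid",
                               "acid"),
                      pkaIntr = c(4.0, 4.4, 10.4, 12.0, 9.5, 9.6),
                      siteId = c("ASP", "GLU", "LYS", "ARG", "CYS", "TYR"))
  sys <- titrationSystem(sites, pH = 7)
  expect_identical(nrow(reportPattern(enumerateExact(sys), sys)), 0L)
  # a glutamate with a +4 pK intrinsic shift (phosphate proximity) is the
  # single deviation: expected deprotonated, observed protonated
  glu <- titrationSystem(data.frame(kind = "acid", pkaRef = 4.4,
                                    pkaIntr = 8.4, siteId = "GLU-298-A"),
                         pH = 7)
  dev <- reportPattern(enumerateExact(glu), glu)
  expect_identical(nrow(dev), 1L)
  expect_identical(dev$site_id, "GLU-298-A")
  expect_identical(dev$expected_state, "deprotonated")
  expect_gt(dev$observed_probability, 0.5)
  # empty system
  esys <- titrationSystem(data.frame(kind = "acid", pkaIntr = 4), pH = 7)
  expect_identical(nrow(reportPattern(enumerateExact(esys), esys)), 0L)
})
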