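test_that("dielectric map: empty structure is uniform solvent", {
  model <- continuumModel()
  grid <- gridSpec(1.0, 33)
  dm <- buildDielectricMap(emptyStructure(), model, grid)
  expect_true(all(dm$epsNode == 80))
  expect_true(all(dm$epsX == 80))
  expect_true(all(dm$lambda == 1))
})

test_that("dielectric map volume matches the analytic sphere fraction", {
  model <- continuumModel()
  grid <- gridSpec(0.25, 81)  # 20 A box
  sphere <- proteinStructure(data.frame(
    name = "ION", resid = "ION", chain = "A", resno = 1L,
    x = 0, y = 0, z = 0, elem = "X", het = TRUE))
  radii <- c(defaultRadii(), X = 2.0)
  dm <- buildDielectricMap(sphere, model, grid, radii)
  frac <- mean(dm$epsNode == model@epsProtein)
  box <- (0.25 * 80)^3
  expect_equal(frac, (4 / 3) * pi * 2^3 / box, tolerance = 0.05)
  # sub-grid shift changes the interior count by at most a surface layer
  sphere2 <- sphere
  coords(sphere2) <- matrix(c(0.125, 0, 0), 1L)
  dm2 <- buildDielectricMap(sphere2, model, grid, radii)
  n1 <- sum(dm$epsNode == model@epsProtein)
  n2 <- sum(dm2$epsNode == model@epsProtein)
  surface <- 4 * pi * 2^2 / 0.25^2  # nodes in one surface layer
  expect_lt(abs(n1 - n2), surface)
  # grid too small for the solute is a configuration error
  expect_error(buildDielectricMap(sphere, model, gridSpec(0.1, 33), radii),
               "grid smaller")
})

test_that("zero charges give an identically zero potential", {
  model <- uniformModel()
  grid <- gridSpec(1.0, 33)
  dm <- buildDielectricMap(emptyStructure(), model, grid)
  sol <- solveLPB(data.frame(x = numeric(), y = numeric(), z = numeric(),
                             q = numeric()), dm, model)
  expect_true(all(sol@potential == 0))
})

test_that("a unit charge in uniform dielectric reproduces Coulomb within 2%", {
  model <- uniformModel(eps = 80, I = 0)
  grid <- gridSpec(0.5, 65)
  dm <- buildDielectricMap(emptyStructure(), model, grid)
  ch <- data.frame(x = 0, y = 0, z = 0, q = 1)
  sol <- solveLPB(ch, dm, model)
  expect_true(sol@converged)
  for (r in c(4, 6, 8, 10, 12)) {
    pts <- rbind(c(r, 0, 0), c(0, 0, r), c(r / sqrt(2), r / sqrt(2), 0))
    expect_equal(potentialAt(sol, pts),
                 rep(332.06 / (80 * r), 3L), tolerance = 0.02)
  }
  # linearity: doubling the charge doubles the potential
  sol2 <- solveLPB(transform(ch, q = 2), dm, model)
  pts <- rbind(c(5, 0, 0), c(0, 7, 0))
  expect_equal(potentialAt(sol2, pts), 2 * potentialAt(sol, pts),
               tolerance = 1e-6)
})

test_that("Born ion: focused solution within 3% and monotone in spacing", {
  fx <- makeFixture("born_ion", seed = 1)
  gt <- groundTruth(fx)
  s <- structures(fx)[[1]]
  radii <- c(defaultRadii(), X = gt$radius)
  model <- continuumModel(epsProtein = gt$eps_in, epsSolvent = gt$eps_out,
                          ionicStrength = 0)
  errs <- vapply(list(c(2.5), c(2.5, 1.0), c(2.5, 1.0, 0.3)),
                 function(lv) {
                   dg <- solvationEnergy(gt$charges, s, model, levels = lv,
                                         radii = radii)
                   abs(dg - gt$dg_born) / abs(gt$dg_born)
                 }, numeric(1L))
  expect_lt(errs[3L], 0.03)
  # each focusing level improves on the coarser result
  expect_true(all(diff(errs) < 0))
})

test_that("degenerate focusing with one level equals a direct solve", {
  model <- uniformModel(eps = 80)
  ch <- data.frame(x = 0, y = 0, z = 0, q = 1)
  s <- emptyStructure()
  sol <- focusSolve(ch, s, model, levels = c(1.0))
  dm <- buildDielectricMap(s, model, sol@grid)
  direct <- solveLPB(ch, dm, model)
  expect_equal(sol@potential, direct@potential, tolerance = 1e-12)
})

test_that("focused and unfocused fine-grid solutions agree within 1%", {
  fx <- makeFixture("born_ion", seed = 1)
  gt <- groundTruth(fx)
  s <- structures(fx)[[1]]
  radii <- c(defaultRadii(), X = gt$radius)
  model <- continuumModel(epsProtein = gt$eps_in, epsSolvent = gt$eps_out,
                          ionicStrength = 0)
  foc <- focusSolve(gt$charges, s, model, levels = c(2.0, 0.5),
                    radii = radii)
  dmFine <- buildDielectricMap(s, model, foc@grid, radii)
  direct <- solveLPB(gt$charges, dmFine, model)
  pts <- rbind(c(2, 0, 0), c(0, 3, 0), c(0, 0, 5), c(4.5, 0, 0))
  pf <- potentialAt(foc, pts)
  pd <- potentialAt(direct, pts)
  expect_lt(max(abs(pf - pd) / pmax(abs(pd), 1e-9)), 0.01)
})

test_that("site energies: W matches Coulomb, is reciprocal, salt screens", {
  fx <- makeFixture("coulomb_pair", seed = 1)
  gt <- groundTruth(fx)
  s <- structures(fx)[[1]]
  model <- uniformModel(eps = gt$eps, I = 0)
  se <- computeSiteEnergies(s, gt$sites, model, levels = c(2.0, 0.8))
  W <- wMatrix(se)
  expect_equal(W[1, 2], gt$w_analytic, tolerance = 0.05)
  expect_identical(W, t(W))
  expect_identical(diag(W), c(0, 0))
  # a lone site in its own model-compound environment has ~zero shift
  expect_lt(max(abs(deltaGIntr(se))), 0.1)
  expect_lt(max(abs(siteTable(se)$pkaIntr - siteTable(se)$pkaRef)), 0.2)
  # screening: |W| non-increasing in ionic strength
  Ws <- vapply(c(0, 0.1, 0.3), function(I) {
    m <- uniformModel(eps = gt$eps, I = I)
    wMatrix(computeSiteEnergies(s, gt$sites, m, levels = c(2.0, 0.8)))[1, 2]
  }, numeric(1L))
  expect_true(all(diff(abs(Ws)) <= 1e-9))
})

test_that("site-energy shifts feed a titration system with His coupling", {
  # two-histidine-site bookkeeping: the imidazolate microstate is penalised
  sites <- data.frame(
    siteId = c("HIS-9-A-NE2", "HIS-9-A-ND1"), kind = "base",
    pkaRef = c(7.0, 6.6), qProt = 0.5, qDeprot = -0.5,
    hisGroup = "HIS-9-A", pkaIntr = c(7.0, 6.6),
    stringsAsFactors = FALSE)
  se <- new("SiteEnergies", sites = sites, deltaGIntr = c(0, 0),
            wMatrix = matrix(0, 2, 2))
  sys <- titrationSystemFromEnergies(se, pH = 7.0)
  expect_identical(nrow(sys@statePenalties), 1L)
  expect_equal(sys@statePenalties$energy, 10)
  # probability of the doubly deprotonated (imidazolate) state is tiny
  p00 <- local({
    kT <- 0.0019872 * 300
    states <- expand.grid(x1 = 0:1, x2 = 0:1)
    E <- apply(states, 1L, function(x) stateEnergy(sys, x))
    w <- exp(-(E - min(E)) / kT)
    w[1L] / sum(w)
  })
  expect_lt(p00, 1e-4)
})
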