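test_that("fixture generation is bit-identical under a fixed seed", {
  for (kind in c("ploop_peptide", "displaced_pair", "crowded_pocket",
                 "titration_system", "variant_pair")) {
    a <- makeFixture(kind, seed = 42)
    b <- makeFixture(kind, seed = 42)
    expect_identical(lapply(structures(a), atoms),
                     lapply(structures(b), atoms), info = kind)
    expect_identical(groundTruth(a), groundTruth(b), info = kind)
  }
  # different seeds change stochastic fixtures
  t1 <- makeFixture("titration_system", seed = 1)
  t2 <- makeFixture("titration_system", seed = 2)
  expect_false(identical(groundTruth(t1)$probabilities,
                         groundTruth(t2)$probabilities))
  expect_error(makeFixture("nonsense"), "unknown fixture kind")
})

test_that("the P-loop peptide fixture honours its numbering offset", {
  fx <- makeFixture("ploop_peptide", params = list(offset = 649), seed = 1)
  sq <- extractSequence(structures(fx)[[1]], "A")
  expect_identical(sq$sequence, "GMPGTGKT")
  expect_identical(sq$numbering, 649:656)
  expect_identical(groundTruth(fx)$k_resno, 655L)
  # human numbering: one lower
  fx2 <- makeFixture("ploop_peptide", params = list(offset = 648), seed = 1)
  expect_identical(groundTruth(fx2)$k_resno, 654L)
})

test_that("displaced-pair ground truth is honoured by construction", {
  fx <- makeFixture("displaced_pair", seed = 9,
                    params = list(window = 5:7, shift = c(1, 2, 2)))
  gt <- groundTruth(fx)
  expect_equal(gt$magnitude, 3)
  a <- atoms(structures(fx)[[1]]); b <- atoms(structures(fx)[[2]])
  d <- sqrt(rowSums((as.matrix(a[, c("x", "y", "z")]) -
                       as.matrix(b[, c("x", "y", "z")]))^2))
  expect_equal(unique(round(d[a$resno %in% 5:7], 9)), 3)
  expect_true(all(d[!a$resno %in% 5:7] == 0))
})

test_that("Born and Coulomb fixtures carry the analytic closed forms", {
  fx <- makeFixture("born_ion", seed = 1,
                    params = list(radius = 3, q = 1, eps_in = 2,
                                  eps_out = 80))
  gt <- groundTruth(fx)
  expect_equal(gt$dg_born, (332.06 / (2 * 3)) * (1 / 80 - 1 / 2),
               tolerance = 1e-12)
  fc <- makeFixture("coulomb_pair", seed = 1,
                    params = list(distance = 8, eps = 40))
  expect_equal(groundTruth(fc)$w_analytic, 332.06 / (40 * 8),
               tolerance = 1e-12)
})

test_that("fixtures serialise as PDB plus ground-truth JSON", {
  fx <- makeFixture("ploop_peptide", seed = 3)
  d <- tempfile()
  paths <- writeFixture(fx, d)
  expect_true(file.exists(paths[[1L]]))
  expect_true(file.exists(paths$ground_truth))
  s <- readStructure(paths[[1L]])
  expect_identical(extractSequence(s, "A")$sequence,
                   groundTruth(fx)$sequence)
  gt <- jsonlite::fromJSON(paths$ground_truth)
  expect_identical(gt$k_resno, 655L)
})

test_that("the variant-pair fixture encodes the described geometry", {
  fx <- makeFixture("variant_pair", seed = 1)
  gt <- groundTruth(fx)
  wt <- structures(fx)[[1]]; mut <- structures(fx)[[2]]
  wa <- atoms(wt); ma <- atoms(mut)
  # identities at the variant site
  expect_identical(unique(wa$resid[wa$resno == 652 & !wa$het]), "THR")
  expect_identical(unique(ma$resid[ma$resno == 652 & !ma$het]), "ARG")
  # the wild-type lysine salt-bridges the gamma phosphate; the mutant
  # cannot (the phosphate moved away)
  expect_lt(gt$lys_o1g_wt, 3.0)
  expect_gt(gt$lys_o1g_mut, 4.0)
  # distant glutamate sits ~50 A from the ATP
  expect_equal(gt$glu_min_dist_atp, 50, tolerance = 0.05)
})
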