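test_that("superposition of identical structures is the identity", {
  s <- buildPeptide("ADKRE", 1, "A")
  sup <- superpose(s, s)
  expect_equal(sup@rmsd, 0, tolerance = 1e-10)
  expect_equal(sup@rotation, diag(3), tolerance = 1e-8)
  expect_equal(sup@translation, c(0, 0, 0), tolerance = 1e-8)
})

test_that("superposition RMSD is invariant under rigid motion", {
  s <- buildPeptide("ADKREAG", 1, "A")
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  moved <- s
  coords(moved) <- sweep(coords(s) %*% t(R), 2L, -c(1, 2, 3))
  sup <- superpose(s, moved)
  expect_lt(sup@rmsd, 1e-8)
  expect_equal(det(sup@rotation), 1, tolerance = 1e-9)
  # noisy case agrees with an independent implementation (bio3d)
  set.seed(4)
  noisy <- moved
  coords(noisy) <- coords(moved) + matrix(rnorm(3 * nAtoms(s), 0, 0.3),
                                          ncol = 3L)
  sup2 <- superpose(s, noisy, selectAll())
  fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(coords(s))),
                   mobile = as.vector(t(coords(noisy)))))
  rmsdOracle <- sqrt(mean(colSums(
    (matrix(fit, nrow = 3) - t(coords(s)))^2)))
  expect_equal(sup2@rmsd, rmsdOracle, tolerance = 1e-8)
})

test_that("degenerate superpositions raise geometry errors", {
  line <- mkStructure(data.frame(
    name = paste0("C", 1:5), resid = "CLD", chain = "X", resno = 1:5,
    x = 1:5, y = 0, z = 0, elem = "C", het = TRUE))
  expect_error(superpose(line, line, selectAll()), "collinear")
  two <- mkStructure(data.frame(
    name = c("C1", "C2"), resid = "CLD", chain = "X", resno = 1:2,
    x = c(0, 1), y = 0, z = 0, elem = "C", het = TRUE))
  expect_error(superpose(two, two, selectAll()), ">= 3")
})

test_that("displacement profiles recover constructed ground truth", {
  fx <- makeFixture("displaced_pair", seed = 3,
                    params = list(window = 10:13, shift = c(0, 0, 3.5)))
  gt <- groundTruth(fx)
  pr <- displacementProfile(structures(fx)[[1]], structures(fx)[[2]],
                            fitSelection = selectResidues(gt$window,
                                                          exclude = TRUE))
  e <- profileEntries(pr)
  expect_equal(e$displacement[e$resno %in% gt$window],
               rep(gt$magnitude, length(gt$window)), tolerance = 1e-9)
  expect_lt(max(e$displacement[!e$resno %in% gt$window]), 1e-9)
  # whole-body translation with a held-fixed anchor reports it everywhere
  a <- structures(fx)[[1]]
  at <- atoms(a)
  b2 <- at
  moving <- b2$resno > 15
  b2$x[moving] <- b2$x[moving] + 2
  pr2 <- displacementProfile(a, proteinStructure(b2),
                             fitSelection = selectResidues(1:15),
                             reportSelection = selectResidues(16:30))
  expect_equal(unique(round(profileEntries(pr2)$displacement, 9)), 2)
})

test_that("clash detection equals the brute-force all-pairs oracle", {
  for (seed in c(7, 19, 42)) {
    df <- randomCloud(50, box = 12, seed = seed)
    got <- findClashes(proteinStructure(df))
    oracle <- bruteClashes(df)
    expect_identical(nrow(got), nrow(oracle))
    if (nrow(got)) {
      keyG <- sort(paste(pmin(got$resno_a, got$resno_b),
                         pmax(got$resno_a, got$resno_b)))
      keyO <- sort(paste(df$resno[oracle$i], df$resno[oracle$j]))
      expect_identical(keyG, keyO)
    }
  }
  # atoms >= 5 A apart never clash
  far <- randomCloud(4, box = 1, seed = 1)
  far$x <- c(0, 10, 20, 30)
  expect_identical(nrow(findClashes(proteinStructure(far))), 0L)
})

test_that("clash detection is invariant to atom order and flags 1.8 A", {
  fx <- makeFixture("clash_probe", seed = 1)
  s <- structures(fx)[[1]]
  gt <- groundTruth(fx)
  cl <- findClashes(s, focus = selectResidues(gt$arg_resno))
  hit <- cl[cl$name_a == "NH1" & cl$name_b == "O" |
              cl$name_a == "O" & cl$name_b == "NH1", ]
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$distance, 1.8, tolerance = 1e-9)
  expect_equal(hit$vdw_sum, 3.07, tolerance = 1e-9)
  expect_equal(hit$overlap, 1.27, tolerance = 1e-9)
  # permuted atom order gives the same clash set
  at <- atoms(s)
  set.seed(5)
  perm <- proteinStructure(at[sample(nrow(at)), ])
  cl2 <- findClashes(perm, focus = selectResidues(gt$arg_resno))
  expect_setequal(paste(cl2$atom_a, cl2$atom_b),
                  paste(cl$atom_a, cl$atom_b))
  # sorted by descending overlap
  expect_false(is.unsorted(rev(cl$overlap)))
})

test_that("missing vdW radius is reported as a configuration error", {
  df <- randomCloud(3, seed = 2)
  df$elem[2] <- "QQ"
  expect_error(findClashes(proteinStructure(df)), "QQ")
})

test_that("polar interactions follow the charge-class energy scale", {
  fx <- makeFixture("variant_pair", seed = 1)
  gt <- groundTruth(fx)
  mut <- structures(fx)[[2]]
  im <- findPolarInteractions(mut, gt$regions)
  sb <- im[im$donor_atom == "A:ARG652:NH1" &
             im$acceptor_atom == "A:ASP973:OD1", ]
  expect_identical(nrow(sb), 1L)
  expect_identical(sb$kind, "salt-bridge")
  expect_identical(sb$charge_class, "charged-charged")
  expect_identical(sb$energy_scale, 4)
  expect_true(sb$inter_region)
  expect_identical(sort(c(sb$region_donor, sb$region_acceptor)),
                   c("helicase-1A", "helicase-2A"))
  # backbone-backbone hydrogen bonds in the helix are uncharged, 1 kcal/mol
  hb <- im[im$name_d == "N" & im$name_a == "O", ]
  expect_true(nrow(hb) > 0)
  expect_true(all(hb$energy_scale == 1))
  expect_true(all(hb$kind == "h-bond"))
  # energy scale is a pure function of charge class
  expect_identical(unname(c("uncharged-uncharged" = 1,
                            "charged-uncharged" = 2,
                            "charged-charged" = 4)[im$charge_class]),
                   im$energy_scale)
})

test_that("interaction detection respects distance cutoffs", {
  # donor-acceptor pair at 6 A with 4 A salt-bridge cutoff: nothing
  df <- rbind(
    data.frame(name = "NZ", resid = "LYS", chain = "A", resno = 1L,
               x = 0, y = 0, z = 0, elem = "N", het = FALSE),
    data.frame(name = "OD1", resid = "ASP", chain = "A", resno = 5L,
               x = 6, y = 0, z = 0, elem = "O", het = FALSE))
  expect_identical(nrow(findPolarInteractions(proteinStructure(df))), 0L)
  df$x[2] <- 3.8  # beyond h-bond cutoff but inside salt-bridge cutoff
  one <- findPolarInteractions(proteinStructure(df))
  expect_identical(one$kind, "salt-bridge")
  df2 <- df
  df2$resid[1] <- "SER"; df2$name[1] <- "OG"; df2$elem[1] <- "O"
  expect_identical(nrow(findPolarInteractions(proteinStructure(df2))), 0L)
  df2$x[2] <- 2.8
  hb <- findPolarInteractions(proteinStructure(df2))
  expect_identical(hb$energy_scale, 2)  # Ser OG donor to charged Asp O
})

test_that("interaction diffing is a symmetric set difference on atom keys", {
  fx <- makeFixture("variant_pair", seed = 1)
  gt <- groundTruth(fx)
  iw <- findPolarInteractions(structures(fx)[[1]], gt$regions)
  im <- findPolarInteractions(structures(fx)[[2]], gt$regions)
  expect_identical(diffInteractions(iw, iw),
                   list(gained = iw[0, ], lost = iw[0, ]))
  d <- diffInteractions(iw, im)
  expect_identical(d$gained$donor_atom, "A:ARG652:NH1")
  expect_identical(d$gained$acceptor_atom, "A:ASP973:OD1")
  expect_identical(d$lost$donor_atom, "A:LYS654:NZ")
  expect_identical(d$lost$acceptor_atom, "L:ATP1:O1G")
  # gained and lost are disjoint
  keyOf <- function(x) paste(x$donor_atom, x$acceptor_atom)
  expect_length(intersect(keyOf(d$gained), keyOf(d$lost)), 0L)
  # order independence
  d2 <- diffInteractions(im, iw)
  expect_identical(d2$gained, d$lost)
  expect_identical(d2$lost, d$gained)
})

test_that("rotamer enumeration spans the chi grid and scores clashes", {
  expect_error(enumerateRotamers(buildPeptide("GAG", 1, "A"), 2),
               "unsupported")
  # arginine in empty surroundings reaches clash score zero
  free <- enumerateRotamers(buildPeptide("GRG", 1, "A"), 2, chiGrid = 120)
  expect_identical(nrow(free), as.integer((360 / 120)^4))
  expect_identical(min(free$clash_score), 0)
  expect_identical(free$n_clashes[1L], 0L)
  # clash_score = 0 <=> n_clashes = 0
  expect_identical(free$clash_score == 0, free$n_clashes == 0L)
  # serine: single chi
  ser <- enumerateRotamers(buildPeptide("GSG", 1, "A"), 2, chiGrid = 30)
  expect_identical(nrow(ser), 12L)
})

test_that("a crowded pocket clashes at every grid rotamer", {
  fx <- makeFixture("crowded_pocket", seed = 1)
  gt <- groundTruth(fx)
  expect_true(gt$all_sampled_rotamers_clash)
  rot <- enumerateRotamers(structures(fx)[[1]], gt$arg_resno, chiGrid = 60)
  expect_identical(nrow(rot), as.integer((360 / 60)^4))
  expect_gt(min(rot$clash_score), 0)
  expect_true(all(rot$n_clashes > 0L))
  # deterministic order: score-sorted
  expect_false(is.unsorted(rot$clash_score))
})

test_that("rotamer chi labels equal the rebuilt dihedral angles", {
  # build an arginine at known chi angles and check the enumerator's labels
  # against dihedrals measured on independently rebuilt coordinates
  target <- c(60, 180, 300, 120)
  pep <- buildPeptide("GRG", 1, "A", chi = list("2" = target))
  a <- atoms(pep)
  g <- function(nm) unlist(a[a$resno == 2 & a$name == nm,
                             c("x", "y", "z")])
  dihedrals <- c(
    VariantLens:::.dihedral(g("N"), g("CA"), g("CB"), g("CG")),
    VariantLens:::.dihedral(g("CA"), g("CB"), g("CG"), g("CD")),
    VariantLens:::.dihedral(g("CB"), g("CG"), g("CD"), g("NE")),
    VariantLens:::.dihedral(g("CG"), g("CD"), g("NE"), g("CZ")))
  expect_equal((dihedrals + 360) %% 360, target, tolerance = 1e-6)
})
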