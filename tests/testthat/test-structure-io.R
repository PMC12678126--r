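test_that("PDB round trip preserves atoms and coordinates to 3 decimals", {
  fx <- makeFixture("ploop_peptide", seed = 1)
  s <- structures(fx)[[1]]
  f <- tempfile(fileext = ".pdb")
  writeStructure(s, f)
  s2 <- readStructure(f)
  expect_identical(nAtoms(s2), nAtoms(s))
  expect_identical(atoms(s2)$name, atoms(s)$name)
  expect_identical(atoms(s2)$resno, atoms(s)$resno)
  expect_identical(atoms(s2)$resid, atoms(s)$resid)
  expect_lt(max(abs(coords(s2) - coords(s))), 5e-4 + 1e-12)
})

test_that("mmCIF round trip preserves coordinates at full precision", {
  fx <- makeFixture("variant_pair", seed = 1)
  s <- structures(fx)[[1]]  # includes ATP with primed atom names
  f <- tempfile(fileext = ".cif")
  writeStructure(s, f)
  s2 <- suppressWarnings(readStructure(f))
  expect_identical(atoms(s2)$name, atoms(s)$name)
  expect_identical(atoms(s2)$het, atoms(s)$het)
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-5)
})

test_that("duplicate atom identifiers are rejected as a parse error", {
  df <- data.frame(name = c("CA", "CA"), resid = "ALA", chain = "A",
                   resno = 1L, x = c(0, 1), y = 0, z = 0, elem = "C",
                   het = FALSE)
  expect_error(proteinStructure(df), "duplicate")
  f <- tempfile(fileext = ".pdb")
  ok <- buildPeptide("AG", 1, "A")
  writeStructure(ok, f)
  lines <- readLines(f)
  caLine <- grep("^ATOM.*CA", lines, value = TRUE)[1L]
  writeLines(append(lines, caLine, after = grep("^ATOM.*CA", lines)[1L]), f)
  expect_error(suppressWarnings(readStructure(f)), "duplicate")
})

test_that("sequence extraction excludes hetero residues and keeps numbering", {
  fx <- makeFixture("ploop_peptide", seed = 2)
  s <- structures(fx)[[1]]
  gt <- groundTruth(fx)
  sq <- extractSequence(s, "A")
  expect_identical(sq$sequence, gt$sequence)
  expect_identical(sq$numbering, gt$numbering)
  # auto-select on single-chain structures
  expect_identical(extractSequence(s, "")$sequence, gt$sequence)
  # ATP must not appear in the sequence
  vp <- makeFixture("variant_pair", seed = 1)
  sq2 <- extractSequence(structures(vp)[[1]], "A")
  expect_false(grepl("X", sq2$sequence))
  expect_identical(nchar(sq2$sequence),
                   length(unique(atoms(structures(vp)[[1]])$resno[
                     !atoms(structures(vp)[[1]])$het])))
  expect_error(extractSequence(s, "Z"), "chain")
})

test_that("non-standard residues become X with a warning", {
  df <- rbind(
    atoms(buildPeptide("AGA", 1, "A"))[, c("name", "resid", "chain",
                                           "resno", "x", "y", "z", "elem",
                                           "het")],
    data.frame(name = "C1", resid = "UNK", chain = "A", resno = 4L,
               x = 20, y = 0, z = 0, elem = "C", het = FALSE))
  s <- proteinStructure(df)
  expect_warning(sq <- extractSequence(s, "A"), "non-standard")
  expect_identical(sq$sequence, "AGAX")
})

test_that("numbering shifts are explicit and exact", {
  # the human/mouse correspondence: an offset of +1 maps human 652 to
  # mouse 653
  s <- buildPeptide("GMPGTGKT", 648, "A", sideChains = FALSE)
  s2 <- shiftNumbering(s, 1L)
  expect_identical(extractSequence(s2, "A")$numbering, 649:656)
  expect_identical(extractSequence(shiftNumbering(s2, -1L), "A")$numbering,
                   648:655)
})

test_that("region annotations parse from YAML and JSON and validate", {
  regs <- list(list(label = "helicase-1A", chain = "A", start = 600,
                    end = 800),
               list(label = "helicase-2A", chain = "A", start = 900,
                    end = 1100))
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(regs, fy)
  ry <- readRegions(fy)
  expect_identical(ry$label, c("helicase-1A", "helicase-2A"))
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(regs, fj, auto_unbox = TRUE)
  expect_identical(readRegions(fj), ry)
  bad <- list(list(label = "x", chain = "A", start = 10, end = 5))
  expect_error(regionTable(bad), "start")
})

test_that("altloc reduction keeps the highest-occupancy conformer", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.30  0.00           C",
    "ATOM      3  CA BALA A   1       1.500   0.100   0.000  0.70  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"), f)
  s <- readStructure(f)
  ca <- atoms(s)[atoms(s)$name == "CA", ]
  expect_identical(nrow(ca), 1L)
  expect_equal(ca$x, 1.5)
})
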