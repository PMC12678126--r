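test_that("the DNA2 P-loop octapeptide yields one hit with K at 655", {
  hits <- findWalkerA("GMPGTGKT", 649:656, "A")
  expect_length(hits, 1L)
  h <- hits[[1L]]
  expect_identical(h@sequence, "GMPGTGKT")
  expect_identical(h@resno[h@roles == "K"], 655L)
  expect_identical(h@resno[h@roles == "TS"], 656L)
})

test_that("empty and hit-free sequences give an empty result", {
  expect_identical(findWalkerA("", integer(), "A"), list())
  expect_identical(findWalkerA("AAAAAAAAAA", 1:10, "A"), list())
  expect_error(findWalkerA("GG", 1:3, "A"), "length")
})

test_that("scanner agrees with independent oracles on random sequences", {
  set.seed(11)
  alph <- c("G", "K", "T", "S", "A", "M", "P")  # motif-rich alphabet
  for (rep in 1:200) {
    n <- sample(8:30, 1L)
    sq <- paste(sample(alph, n, replace = TRUE), collapse = "")
    numb <- seq(100L, length.out = n)
    hits <- findWalkerA(sq, numb, "A")
    # regex oracle with overlap-permitting lookahead
    m <- gregexpr("(?=G....GK[TS])", sq, perl = TRUE)[[1L]]
    regexStarts <- if (m[1L] == -1L) integer() else numb[as.integer(m)]
    got <- vapply(hits, function(h) h@resno[1L], integer(1L))
    expect_identical(got, regexStarts)
    # brute-force sliding window oracle
    expect_identical(got, bruteWalkerA(sq, numb))
  }
})

test_that("overlapping motif instances are all reported", {
  # GKT starting a second motif inside the first: GxxxxGKT GxxxxGKT overlap
  sq <- "GAAAAGKTGAAAAGKT"
  hits <- findWalkerA(sq, 1:16, "A")
  expect_length(hits, 2L)
  sq2 <- "GGKTAGKTGKSAAAAA"  # motif at 1? no; construct true overlap
  hits2 <- findWalkerA("GGGGGGKTGKT", 1:11, "A")
  expect_true(all(vapply(hits2, function(h)
    grepl("^G.{4}GK[TS]$", h@sequence), logical(1L))))
})

test_that("position classification is total and unique over the motif", {
  hit <- findWalkerA("GMPGTGKT", 648:655, "A")[[1L]]
  got <- vapply(648:655, function(r) classifyPosition(hit, r), character(1L))
  expect_identical(got, c("G1", "x1 (P-loop)", "x2 (P-loop)", "x3 (P-loop)",
                          "x4 (P-loop)", "G2", "K", "TS"))
  # the human variant position 652 is the x4 P-loop slot; 654 is K
  expect_identical(classifyPosition(hit, 652L), "x4 (P-loop)")
  expect_identical(classifyPosition(hit, 654L), "K")
  expect_identical(classifyPosition(hit, 900L), "outside")
})

test_that("structure-level scan works through sequence extraction", {
  fx <- makeFixture("ploop_peptide", seed = 1)
  hits <- scanWalkerA(structures(fx)[[1]])
  expect_length(hits, 1L)
  expect_identical(hits[[1L]]@resno[7L], groundTruth(fx)$k_resno)
})
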