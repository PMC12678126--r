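# shared helpers for the test suite: tiny builders and independent oracles

# structure from a minimal atom table
mkStructure <- function(df, modelId = "test") {
  proteinStructure(df, modelId = modelId)
}

# random hetero-atom point cloud (no covalent bonds at minDist >= 2.1)
randomCloud <- function(n, box = 12, seed = 1, elem = "C") {
  set.seed(seed)
  data.frame(name = paste0("C", seq_len(n)), resid = "CLD", chain = "X",
             resno = seq_len(n), x = runif(n, 0, box), y = runif(n, 0, box),
             z = runif(n, 0, box), elem = elem, het = TRUE,
             stringsAsFactors = FALSE)
}

# brute-force O(n^2) clash oracle replicating the documented rule:
# heavy-atom pairs, overlap > tolerance, excluding pairs joined by a
# covalent path of <= 3 bonds (bonds: intra-residue distance-inferred plus
# peptide C-N links), using igraph for the path lengths
bruteClashes <- function(df, tolerance = 0.4, radii = defaultRadii()) {
  n <- nrow(df)
  xyz <- as.matrix(df[, c("x", "y", "z")])
  rv <- unname(radii[toupper(df$elem)])
  covr <- c(C = 0.77, N = 0.70, O = 0.66, S = 1.04, P = 1.10)
  rc <- unname(covr[toupper(df$elem)])
  rc[is.na(rc)] <- 0.77
  edges <- integer()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    intra <- df$chain[i] == df$chain[j] && df$resno[i] == df$resno[j]
    pept <- df$chain[i] == df$chain[j] &&
      abs(df$resno[i] - df$resno[j]) == 1L &&
      sort(c(df$name[i], df$name[j]))[1L] == "C" &&
      sort(c(df$name[i], df$name[j]))[2L] == "N"
    if (d > 0.4 && d <= rc[i] + rc[j] + 0.45 && (intra || (pept && d <= 2)))
      edges <- c(edges, i, j)
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  pl <- igraph::distances(g)
  out <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    ov <- rv[i] + rv[j] - d
    if (d > 0 && ov > tolerance && pl[i, j] > 3)
      out <- rbind(out, data.frame(i = i, j = j, distance = d,
                                   overlap = ov))
  }
  if (is.null(out)) data.frame(i = integer(), j = integer(),
                               distance = numeric(), overlap = numeric())
  else out
}

# sliding-window Walker A oracle (independent of the scanner)
bruteWalkerA <- function(sequence, numbering) {
  ch <- strsplit(sequence, "")[[1L]]
  hits <- integer()
  if (length(ch) >= 8L) {
    for (i in seq_len(length(ch) - 7L)) {
      ok <- ch[i] == "G" && ch[i + 5L] == "G" && ch[i + 6L] == "K" &&
        ch[i + 7L] %in% c("T", "S")
      if (ok) hits <- c(hits, numbering[i])
    }
  }
  hits
}

# empty structure (uniform solvent)
emptyStructure <- function() {
  proteinStructure(data.frame(
    name = character(), resid = character(), chain = character(),
    resno = integer(), x = numeric(), y = numeric(), z = numeric(),
    elem = character(), het = logical(), stringsAsFactors = FALSE))
}

# uniform-dielectric continuum (Coulomb regime)
uniformModel <- function(eps = 80, I = 0) {
  continuumModel(epsProtein = eps, epsSolvent = eps, ionicStrength = I)
}

# Henderson-Hasselbalch protonation probability
hh <- function(pH, pka) 1 / (1 + 10^(pH - pka))
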