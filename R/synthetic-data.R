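## Synthetic-structure generator. Every fixture the pipeline needs is built
## from ideal bond lengths/angles (no dependence on experimental
## coordinates) and carries machine-readable ground truth computed by an
## independent in-module oracle at generation time -- never by the pipeline
## operations under test. Identical (kind, params, seed) reproduce
## bit-identical coordinates and ground truth.

# side-chain construction recipes: atom, three reference atoms, bond length,
# angle, dihedral ("chiK" optionally +offset, or a fixed number)
.SC_BUILD <- list(
  ARG = list(
    list("CG", c("N", "CA", "CB"), 1.52, 114.1, "chi1"),
    list("CD", c("CA", "CB", "CG"), 1.52, 111.3, "chi2"),
    list("NE", c("CB", "CG", "CD"), 1.46, 112.0, "chi3"),
    list("CZ", c("CG", "CD", "NE"), 1.33, 124.2, "chi4"),
    list("NH1", c("CD", "NE", "CZ"), 1.33, 120.0, 0),
    list("NH2", c("CD", "NE", "CZ"), 1.33, 120.0, 180)),
  LYS = list(
    list("CG", c("N", "CA", "CB"), 1.52, 114.1, "chi1"),
    list("CD", c("CA", "CB", "CG"), 1.52, 111.3, "chi2"),
    list("CE", c("CB", "CG", "CD"), 1.52, 111.3, "chi3"),
    list("NZ", c("CG", "CD", "CE"), 1.47, 110.0, "chi4")),
  ASP = list(
    list("CG", c("N", "CA", "CB"), 1.52, 112.6, "chi1"),
    list("OD1", c("CA", "CB", "CG"), 1.25, 118.4, "chi2"),
    list("OD2", c("CA", "CB", "CG"), 1.25, 118.4, "chi2+180")),
  GLU = list(
    list("CG", c("N", "CA", "CB"), 1.52, 114.1, "chi1"),
    list("CD", c("CA", "CB", "CG"), 1.52, 112.6, "chi2"),
    list("OE1", c("CB", "CG", "CD"), 1.25, 118.4, "chi3"),
    list("OE2", c("CB", "CG", "CD"), 1.25, 118.4, "chi3+180")),
  SER = list(
    list("OG", c("N", "CA", "CB"), 1.417, 110.8, "chi1")),
  THR = list(
    list("OG1", c("N", "CA", "CB"), 1.433, 109.6, "chi1"),
    list("CG2", c("N", "CA", "CB"), 1.52, 110.5, "chi1-120")),
  MET = list(
    list("CG", c("N", "CA", "CB"), 1.52, 114.1, "chi1"),
    list("SD", c("CA", "CB", "CG"), 1.80, 112.7, "chi2"),
    list("CE", c("CB", "CG", "SD"), 1.79, 100.9, "chi3")),
  LEU = list(
    list("CG", c("N", "CA", "CB"), 1.53, 116.3, "chi1"),
    list("CD1", c("CA", "CB", "CG"), 1.52, 110.7, "chi2"),
    list("CD2", c("CA", "CB", "CG"), 1.52, 110.7, "chi2+120")))

.resolveDihedral <- function(spec, chi) {
  if (is.numeric(spec)) return(spec)
  m <- regmatches(spec, regexec("^chi([0-9])([+-][0-9]+)?$", spec))[[1L]]
  val <- chi[as.integer(m[2L])]
  if (nzchar(m[3L])) val <- val + as.numeric(m[3L])
  val
}

#' Build an ideal-geometry peptide
#'
#' Constructs a peptide backbone (N, CA, C, O, and CB for non-glycine
#' residues) from ideal bond lengths and angles at the given backbone
#' dihedrals, with optional full side chains for residues with a
#' construction recipe (Arg, Lys, Asp, Glu, Ser, Thr, Met, Leu).
#'
#' @param sequence one-letter sequence
#' @param startRes author number of the first residue
#' @param chain chain identifier
#' @param phi,psi,omega backbone dihedrals, degrees (default alpha-helical)
#' @param sideChains logical: build full side chains where a recipe exists
#' @param chi named list: residue index (as character) -> chi vector,
#'   degrees, overriding the default all-180 side-chain conformation
#' @return a \code{ProteinStructure}
#' @export
buildPeptide <- function(sequence, startRes = 1L, chain = "A",
                         phi = -60, psi = -45, omega = 180,
                         sideChains = TRUE, chi = list()) {
  seq1 <- strsplit(sequence, "")[[1L]]
  n <- length(seq1)
  res3 <- .AA1TO3[seq1]
  if (anyNA(res3)) stop("unknown amino-acid code in sequence")
  # backbone trace for n+1 residues (the extra one positions the last O/psi)
  Npos <- CApos <- Cpos <- vector("list", n + 1L)
  Npos[[1L]] <- c(0, 0, 0)
  CApos[[1L]] <- c(1.458, 0, 0)
  th <- (180 - 111.2) * pi / 180
  Cpos[[1L]] <- CApos[[1L]] + 1.525 * c(cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    Npos[[i + 1L]] <- .placeAtom(Npos[[i]], CApos[[i]], Cpos[[i]],
                                 1.329, 116.2, psi)
    CApos[[i + 1L]] <- .placeAtom(CApos[[i]], Cpos[[i]], Npos[[i + 1L]],
                                  1.458, 121.7, omega)
    Cpos[[i + 1L]] <- .placeAtom(Cpos[[i]], Npos[[i + 1L]], CApos[[i + 1L]],
                                 1.525, 111.2, phi)
  }
  rows <- list()
  addAtom <- function(name, pos, resno, resid) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, resid = resid, chain = chain, resno = resno,
      x = pos[1L], y = pos[2L], z = pos[3L],
      elem = guessElement(name), het = FALSE, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    resno <- startRes + i - 1L
    addAtom("N", Npos[[i]], resno, res3[i])
    addAtom("CA", CApos[[i]], resno, res3[i])
    addAtom("C", Cpos[[i]], resno, res3[i])
    O <- .placeAtom(Npos[[i]], CApos[[i]], Cpos[[i]], 1.231, 120.5,
                    psi + 180)
    addAtom("O", O, resno, res3[i])
    if (res3[i] != "GLY") {
      CB <- .placeAtom(Cpos[[i]], Npos[[i]], CApos[[i]], 1.53, 110.5,
                       -122.6)
      addAtom("CB", CB, resno, res3[i])
      recipe <- .SC_BUILD[[res3[i]]]
      if (sideChains && !is.null(recipe)) {
        chis <- chi[[as.character(i)]]
        if (is.null(chis)) chis <- rep(180, 4L)
        placed <- list(N = Npos[[i]], CA = CApos[[i]], C = Cpos[[i]],
                       CB = CB)
        for (step in recipe) {
          refs <- lapply(step[[2L]], function(nm) placed[[nm]])
          pos <- .placeAtom(refs[[1L]], refs[[2L]], refs[[3L]],
                            step[[3L]], step[[4L]],
                            .resolveDihedral(step[[5L]], chis))
          placed[[step[[1L]]]] <- pos
          addAtom(step[[1L]], pos, resno, res3[i])
        }
      }
    }
  }
  proteinStructure(do.call(rbind, rows), modelId = "synthetic-peptide")
}

# row-bind atom tables that may differ in optional columns
.bindAtoms <- function(...) {
  keep <- c("name", "resid", "chain", "resno", "x", "y", "z", "elem", "het")
  do.call(rbind, lapply(list(...), function(d) d[, keep, drop = FALSE]))
}

# orthonormal frame from a direction
.frameFrom <- function(u) {
  u <- .unit(u)
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- .unit(ref - sum(ref * u) * u)
  w <- c(u[2L] * v[3L] - u[3L] * v[2L],
         u[3L] * v[1L] - u[1L] * v[3L],
         u[1L] * v[2L] - u[2L] * v[1L])
  list(u = u, v = v, w = w)
}

# simplified ATP (triphosphate tail + ribose/adenine stand-ins) laid out
# along direction u starting with O1G at p0
.buildATP <- function(p0, u, chain = "L", resno = 1L) {
  f <- .frameFrom(u)
  u <- f$u; v <- f$v
  pos <- list()
  pos[["O1G"]] <- p0
  pos[["PG"]] <- p0 + 1.55 * u
  pos[["O2G"]] <- pos[["PG"]] + 1.45 * v
  pos[["O3G"]] <- pos[["PG"]] - 1.45 * v
  pos[["O3B"]] <- pos[["PG"]] + 1.6 * u
  pos[["PB"]] <- pos[["O3B"]] + 1.6 * u
  pos[["O1B"]] <- pos[["PB"]] + 1.45 * v
  pos[["O2B"]] <- pos[["PB"]] - 1.45 * v
  pos[["O3A"]] <- pos[["PB"]] + 1.6 * u
  pos[["PA"]] <- pos[["O3A"]] + 1.6 * u
  pos[["O1A"]] <- pos[["PA"]] + 1.45 * v
  pos[["O2A"]] <- pos[["PA"]] - 1.45 * v
  pos[["O5'"]] <- pos[["PA"]] + 1.6 * u
  pos[["C5'"]] <- pos[["O5'"]] + 1.4 * u
  pos[["C1'"]] <- pos[["C5'"]] + 2.4 * u
  pos[["N9"]] <- pos[["C1'"]] + 1.4 * u
  do.call(rbind, lapply(names(pos), function(nm) data.frame(
    name = nm, resid = "ATP", chain = chain, resno = resno,
    x = pos[[nm]][1L], y = pos[[nm]][2L], z = pos[[nm]][3L],
    elem = guessElement(nm), het = TRUE, stringsAsFactors = FALSE)))
}

# quasi-uniform points on a sphere (golden spiral)
.spherePoints <- function(center, radius, spacing) {
  nPts <- max(8L, ceiling(4 * pi * radius^2 / spacing^2))
  k <- seq_len(nPts)
  zu <- (2 * k - 1) / nPts - 1
  th <- k * pi * (3 - sqrt(5))
  r2 <- sqrt(pmax(0, 1 - zu^2))
  cbind(center[1L] + radius * r2 * cos(th),
        center[2L] + radius * r2 * sin(th),
        center[3L] + radius * zu)
}

#' Generate a synthetic fixture with ground truth
#'
#' Fixture kinds:
#' \describe{
#'   \item{ploop_peptide}{8-residue G-x-x-x-x-G-K-T peptide (default
#'     GMPGTGKT numbered from 649, the mouse DNA2 Walker A segment); ground
#'     truth holds sequence, numbering, and the lysine position from an
#'     independent regular-expression scan.}
#'   \item{displaced_pair}{peptide pair identical except a residue window
#'     rigidly shifted by a known vector; ground truth holds the window and
#'     shift magnitude.}
#'   \item{crowded_pocket}{central arginine caged by two concentric shells
#'     of carbon pseudo-atoms placed so every rotamer on the default chi
#'     grid clashes; verified at generation time by independent random-chi
#'     sampling.}
#'   \item{born_ion}{single spherical ion (radius \code{radius}, unit
#'     charge) with the analytic Born solvation energy.}
#'   \item{coulomb_pair}{two unit charges at a stated separation in uniform
#'     dielectric with the analytic interaction energy.}
#'   \item{titration_system}{random coupled-site system (n <= 20) whose
#'     exact per-site protonation probabilities are enumerated by an
#'     independent scalar double loop.}
#'   \item{variant_pair}{wild-type/mutant structure pair mimicking a
#'     Walker A x-position Thr-to-Arg substitution: shared helical scaffold
#'     (variant residue 652), bound ATP whose gamma-phosphate is displaced
#'     6 A (head group 1 A) in the mutant, a lysine-gamma-phosphate salt
#'     bridge lost and an inter-domain arginine-aspartate salt bridge
#'     gained, and a distant glutamate 50 A from the ATP.}
#' }
#'
#' @param kind fixture kind (see Details)
#' @param params named list of kind-specific parameters (all optional)
#' @param seed integer seed; identical (kind, params, seed) give identical
#'   output
#' @return a \code{\link{FixtureBundle}}
#' @export
makeFixture <- function(kind, params = list(), seed = 1L) {
  kinds <- c("ploop_peptide", "displaced_pair", "crowded_pocket",
             "born_ion", "coulomb_pair", "titration_system", "variant_pair",
             "clash_probe")
  if (!kind %in% kinds)
    stop("unknown fixture kind '", kind, "'; available: ",
         paste(kinds, collapse = ", "))
  set.seed(as.integer(seed))
  bundle <- switch(kind,
                   ploop_peptide = .fxPloop(params),
                   displaced_pair = .fxDisplaced(params),
                   crowded_pocket = .fxPocket(params),
                   born_ion = .fxBorn(params),
                   coulomb_pair = .fxCoulomb(params),
                   titration_system = .fxTitration(params),
                   variant_pair = .fxVariantPair(params),
                   clash_probe = .fxClashProbe(params))
  new("FixtureBundle", kind = kind, structures = bundle$structures,
      groundTruth = bundle$gt, seed = as.integer(seed))
}

.fxPloop <- function(params) {
  offset <- if (is.null(params$offset)) 649L else as.integer(params$offset)
  sequence <- if (is.null(params$sequence)) "GMPGTGKT" else params$sequence
  s <- buildPeptide(sequence, startRes = offset, chain = "A",
                    sideChains = FALSE)
  # independent oracle: regular-expression scan for the motif
  m <- gregexpr("(?=G....GK[TS])", sequence, perl = TRUE)[[1L]]
  starts <- if (m[1L] == -1L) integer() else as.integer(m)
  numbering <- offset + seq_len(nchar(sequence)) - 1L
  list(structures = list(s),
       gt = list(sequence = sequence, numbering = numbering,
                 motif_starts = numbering[starts],
                 k_resno = if (length(starts)) numbering[starts + 6L]
                           else integer(),
                 ts_resno = if (length(starts)) numbering[starts + 7L]
                            else integer()))
}

.fxDisplaced <- function(params) {
  nRes <- if (is.null(params$n_res)) 30L else as.integer(params$n_res)
  window <- if (is.null(params$window)) 10:13 else params$window
  shift <- if (is.null(params$shift)) c(3.5, 0, 0) else params$shift
  a <- buildPeptide(strrep("A", nRes), startRes = 1L, chain = "A",
                    sideChains = FALSE)
  at <- atoms(a)
  bt <- at
  idx <- bt$resno %in% window
  bt$x[idx] <- bt$x[idx] + shift[1L]
  bt$y[idx] <- bt$y[idx] + shift[2L]
  bt$z[idx] <- bt$z[idx] + shift[3L]
  b <- proteinStructure(bt, modelId = "displaced")
  list(structures = list(a, b),
       gt = list(window = window, shift = shift,
                 magnitude = .norm3(shift)))
}

.fxPocket <- function(params) {
  shells <- if (is.null(params$shells)) c(4.0, 6.5) else params$shells
  spacing <- if (is.null(params$spacing)) 2.0 else params$spacing
  s <- buildPeptide("GRG", startRes = 1L, chain = "A", sideChains = TRUE)
  at <- atoms(s)
  cb <- unlist(at[at$resno == 2L & at$name == "CB", c("x", "y", "z")])
  cage <- do.call(rbind, lapply(shells, function(r)
    .spherePoints(cb, r, spacing)))
  cageDf <- data.frame(name = "C", resid = "CAG", chain = "X",
                       resno = seq_len(nrow(cage)),
                       x = cage[, 1L], y = cage[, 2L], z = cage[, 3L],
                       elem = "C", het = TRUE, stringsAsFactors = FALSE)
  full <- proteinStructure(.bindAtoms(at, cageDf), modelId = "crowded-pocket")
  # independent oracle: random chi sampling must always find a clash
  # (carbon-carbon contact below vdw sum minus 0.4 A tolerance)
  argRows <- at[at$resno == 2L, , drop = FALSE]
  sampleClashes <- vapply(seq_len(200L), function(k) {
    chis <- stats::runif(4L, 0, 360)
    placed <- list(
      N = unlist(argRows[argRows$name == "N", c("x", "y", "z")]),
      CA = unlist(argRows[argRows$name == "CA", c("x", "y", "z")]),
      CB = cb)
    any(vapply(.SC_BUILD$ARG, function(step) {
      refs <- lapply(step[[2L]], function(nm) placed[[nm]])
      pos <- .placeAtom(refs[[1L]], refs[[2L]], refs[[3L]],
                        step[[3L]], step[[4L]],
                        .resolveDihedral(step[[5L]], chis))
      placed[[step[[1L]]]] <<- pos
      dmin <- min(sqrt(colSums((t(cage) - pos)^2)))
      dmin < (1.70 + ifelse(substr(step[[1L]], 1, 1) == "N", 1.55, 1.70) -
                0.4)
    }, logical(1L)))
  }, logical(1L))
  list(structures = list(full),
       gt = list(arg_resno = 2L, shells = shells,
                 n_cage = nrow(cage),
                 all_sampled_rotamers_clash = all(sampleClashes)))
}

.fxBorn <- function(params) {
  radius <- if (is.null(params$radius)) 4.0 else params$radius
  q <- if (is.null(params$q)) 1.0 else params$q
  epsIn <- if (is.null(params$eps_in)) 4.0 else params$eps_in
  epsOut <- if (is.null(params$eps_out)) 80.0 else params$eps_out
  s <- proteinStructure(
    data.frame(name = "ION", resid = "ION", chain = "A", resno = 1L,
               x = 0, y = 0, z = 0, elem = "X", het = TRUE,
               stringsAsFactors = FALSE),
    modelId = "born-ion")
  dgBorn <- (.COULOMB * q^2 / (2 * radius)) * (1 / epsOut - 1 / epsIn)
  list(structures = list(s),
       gt = list(radius = radius, q = q, eps_in = epsIn, eps_out = epsOut,
                 radii = c(X = radius),
                 charges = data.frame(x = 0, y = 0, z = 0, q = q),
                 dg_born = dgBorn))
}

.fxCoulomb <- function(params) {
  d <- if (is.null(params$distance)) 10.0 else params$distance
  eps <- if (is.null(params$eps)) 80.0 else params$eps
  s <- proteinStructure(data.frame(
    name = "NZ", resid = "LYS", chain = "A", resno = c(1L, 2L),
    x = c(-d / 2, d / 2), y = 0, z = 0, elem = "N", het = FALSE,
    stringsAsFactors = FALSE), modelId = "coulomb-pair")
  mkSite <- function(resno) list(
    siteId = paste0("LYS-", resno, "-A"), chain = "A", resno = resno,
    resid = "LYS", kind = "base", pkaRef = 10.4, qProt = 1, qDeprot = 0,
    atoms = data.frame(name = "NZ", qProt = 1, qDeprot = 0,
                       stringsAsFactors = FALSE),
    hisGroup = NA_character_)
  list(structures = list(s),
       gt = list(distance = d, eps = eps,
                 positions = rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0)),
                 sites = list(mkSite(1L), mkSite(2L)),
                 w_analytic = .COULOMB / (eps * d)))
}

.fxClashProbe <- function(params) {
  # an arginine whose guanidinium NH1 sits a stated distance from the
  # backbone carbonyl oxygen of a leucine (default 1.8 A, the contact the
  # mutant P-loop geometry forces against Leu824)
  d <- if (is.null(params$distance)) 1.8 else params$distance
  arg <- buildPeptide("R", startRes = 653L, chain = "A", sideChains = TRUE)
  aa <- atoms(arg)
  nh1 <- unlist(aa[aa$name == "NH1", c("x", "y", "z")])
  cz <- unlist(aa[aa$name == "CZ", c("x", "y", "z")])
  dir <- .unit(nh1 - cz)
  leu <- buildPeptide("L", startRes = 824L, chain = "A", sideChains = TRUE)
  la <- atoms(leu)
  oPos <- unlist(la[la$name == "O", c("x", "y", "z")])
  cPos <- unlist(la[la$name == "C", c("x", "y", "z")])
  # orient the leucine so its C=O bond points back toward the arginine
  R <- .alignVectors(.unit(oPos - cPos), -dir)
  laXYZ <- sweep(as.matrix(la[, c("x", "y", "z")]), 2L, oPos) %*% t(R)
  laXYZ <- sweep(laXYZ, 2L, -(nh1 + d * dir))
  la[, c("x", "y", "z")] <- laXYZ
  s <- proteinStructure(.bindAtoms(aa, la), modelId = "clash-probe")
  # ground truth from the bundled Bondi radii, stated independently
  list(structures = list(s),
       gt = list(distance = d, vdw_sum = 1.55 + 1.52,
                 overlap = 1.55 + 1.52 - d,
                 arg_resno = 653L, leu_resno = 824L))
}

.fxTitration <- function(params) {
  n <- if (is.null(params$n)) 5L else as.integer(params$n)
  pH <- if (is.null(params$pH)) 7.0 else params$pH
  temperature <- if (is.null(params$temperature)) 300 else params$temperature
  wMax <- if (is.null(params$w_max)) 1.5 else params$w_max
  if (n > 20L) stop("titration_system fixtures are limited to 20 sites")
  kind <- sample(c("acid", "base"), n, replace = TRUE)
  pka <- round(stats::runif(n, 3, 11), 2)
  W <- matrix(0, n, n)
  if (n > 1L) {
    vals <- round(stats::runif(n * (n - 1) / 2, 0, wMax), 3)
    W[upper.tri(W)] <- vals
    W <- W + t(W)
  }
  qd <- ifelse(kind == "acid", -1, 0)
  # independent oracle: scalar double-loop enumeration
  kT <- .RGAS * temperature
  beta <- 1 / kT
  g <- log(10) * kT * (pH - pka)
  Z <- 0
  num <- numeric(n)
  for (stateIdx in 0:(2^n - 1)) {
    x <- as.integer(intToBits(stateIdx))[1:n]
    E <- 0
    for (m in seq_len(n)) {
      E <- E + x[m] * g[m]
      if (m < n) for (v in (m + 1):n)
        E <- E + (qd[m] + x[m]) * (qd[v] + x[v]) * W[m, v]
    }
    w <- exp(-beta * E)
    Z <- Z + w
    num <- num + x * w
  }
  list(structures = list(),
       gt = list(sites = data.frame(siteId = paste0("S", seq_len(n)),
                                    kind = kind, pkaIntr = pka,
                                    stringsAsFactors = FALSE),
                 w_matrix = W, pH = pH, temperature = temperature,
                 probabilities = num / Z))
}

.fxVariantPair <- function(params) {
  # helical scaffold around the human-numbered Walker A segment:
  # G648 M649 P650 G651 T652 G653 K654 T655 inside a 640-660 helix
  scaffoldSeq <- "AAAAYAAAGMPGTGKTAAAAA"
  wtPep <- buildPeptide(scaffoldSeq, startRes = 640L, chain = "A",
                        sideChains = TRUE)
  at <- atoms(wtPep)
  getPos <- function(df, resno, name)
    unlist(df[df$resno == resno & df$name == name, c("x", "y", "z")])
  # ATP placed so O1G sits 2.8 A beyond Lys654 NZ (salt bridge in WT)
  nz <- getPos(at, 654L, "NZ")
  ce <- getPos(at, 654L, "CE")
  u <- .unit(nz - ce)
  atpWT <- .buildATP(nz + 2.8 * u, u, chain = "L", resno = 1L)
  # mutant: Thr652 -> Arg652 (extended side chain), same backbone
  mutAt <- at
  thrRows <- mutAt$resno == 652L & mutAt$name %in% c("OG1", "CG2")
  mutAt <- mutAt[!thrRows, , drop = FALSE]
  mutAt$resid[mutAt$resno == 652L] <- "ARG"
  placed <- list(N = getPos(at, 652L, "N"), CA = getPos(at, 652L, "CA"),
                 CB = getPos(at, 652L, "CB"))
  argRows <- list()
  for (step in .SC_BUILD$ARG) {
    refs <- lapply(step[[2L]], function(nm) placed[[nm]])
    pos <- .placeAtom(refs[[1L]], refs[[2L]], refs[[3L]],
                      step[[3L]], step[[4L]],
                      .resolveDihedral(step[[5L]], rep(180, 4L)))
    placed[[step[[1L]]]] <- pos
    argRows[[length(argRows) + 1L]] <- data.frame(
      name = step[[1L]], resid = "ARG", chain = "A", resno = 652L,
      x = pos[1L], y = pos[2L], z = pos[3L],
      elem = guessElement(step[[1L]]), het = FALSE,
      stringsAsFactors = FALSE)
  }
  mutAt <- .bindAtoms(mutAt, do.call(rbind, argRows))
  # Asp973 ("helicase 2A" partner): built locally, then rigidly moved so
  # OD1 lies 2.9 A beyond the mutant Arg652 NH1 along the CZ->NH1 axis
  asp <- buildPeptide("D", startRes = 973L, chain = "A", sideChains = TRUE)
  aspAt <- atoms(asp)
  od1 <- unlist(aspAt[aspAt$name == "OD1", c("x", "y", "z")])
  cg <- unlist(aspAt[aspAt$name == "CG", c("x", "y", "z")])
  nh1 <- placed$NH1
  cz <- placed$CZ
  dirA <- .unit(nh1 - cz)
  target <- nh1 + 2.9 * dirA
  # orient the aspartate so CG->OD1 points back toward the arginine
  R <- .alignVectors(.unit(od1 - cg), -dirA)
  aspXYZ <- as.matrix(aspAt[, c("x", "y", "z")])
  aspXYZ <- sweep(aspXYZ, 2L, od1) %*% t(R)
  aspXYZ <- sweep(aspXYZ, 2L, -target)
  aspAt[, c("x", "y", "z")] <- aspXYZ
  # distant glutamate ~50 A from the ATP centroid
  glu <- buildPeptide("E", startRes = 298L, chain = "A", sideChains = TRUE)
  gluAt <- atoms(glu)
  atpCen <- colMeans(as.matrix(atpWT[, c("x", "y", "z")]))
  gluCen <- colMeans(as.matrix(gluAt[, c("x", "y", "z")]))
  scafCen <- colMeans(as.matrix(at[, c("x", "y", "z")]))
  farDir <- .unit(atpCen - scafCen)
  gluAt[, c("x", "y", "z")] <-
    sweep(sweep(as.matrix(gluAt[, c("x", "y", "z")]), 2L, gluCen),
          2L, -(atpCen - 56.8 * farDir))
  # mutant ATP: gamma-phosphate 6 A toward bulk, head group 1 A
  mdir <- .unit(nz - getPos(at, 652L, "CA"))
  mdir <- .unit(mdir - sum(mdir * u) * u)  # perpendicular to the tail axis
  shiftTab <- c(O1G = 6, PG = 6, O2G = 6, O3G = 6,
                O3B = 4, PB = 4, O1B = 4, O2B = 4,
                O3A = 2.5, PA = 2, O1A = 2, O2A = 2,
                "O5'" = 1.2, "C5'" = 1.2, "C1'" = 1, N9 = 1)
  atpMut <- atpWT
  for (nm in names(shiftTab)) {
    i <- atpMut$name == nm
    atpMut[i, c("x", "y", "z")] <- atpMut[i, c("x", "y", "z")] +
      rep(shiftTab[[nm]], 3L) * mdir
  }
  wt <- proteinStructure(.bindAtoms(at, aspAt, gluAt, atpWT), modelId = "wt")
  mut <- proteinStructure(.bindAtoms(mutAt, aspAt, gluAt, atpMut),
                          modelId = "mut")
  # ground truth measured directly from the constructed coordinates
  dAspArg <- .norm3(target - nh1)
  dLysWT <- .norm3(getPos(atoms(wt), 1L, "O1G") - nz)
  dLysMut <- .norm3(getPos(atoms(mut), 1L, "O1G") - nz)
  gluXYZ <- as.matrix(gluAt[, c("x", "y", "z")])
  atpXYZ <- as.matrix(atpWT[, c("x", "y", "z")])
  minGluATP <- min(sqrt(outer(rowSums(gluXYZ^2), rowSums(atpXYZ^2), "+") -
                          2 * gluXYZ %*% t(atpXYZ)))
  regions <- regionTable(list(
    list(label = "helicase-1A", chain = "A", start = 600, end = 800),
    list(label = "helicase-2A", chain = "A", start = 900, end = 1100)))
  list(structures = list(wt, mut),
       gt = list(variant = list(chain_id = "A", residue_number = 652L,
                                from_aa = "T", to_aa = "R",
                                label = "T652R"),
                 regions = regions,
                 pg_displacement = 6.0, head_displacement = 1.0,
                 ploop_resno = 649:652, k_resno = 654L,
                 arg_asp_distance = dAspArg,
                 lys_o1g_wt = dLysWT, lys_o1g_mut = dLysMut,
                 glu_min_dist_atp = minGluATP,
                 glu_centroid_dist_atp = .norm3(atpCen -
                                                  colMeans(gluXYZ))))
}

# rotation matrix taking unit vector a onto unit vector b
.alignVectors <- function(a, b) {
  v <- c(a[2L] * b[3L] - a[3L] * b[2L],
         a[3L] * b[1L] - a[1L] * b[3L],
         a[1L] * b[2L] - a[2L] * b[1L])
  cth <- sum(a * b)
  if (.norm3(v) < 1e-12)
    return(if (cth > 0) diag(3) else diag(c(1, -1, -1)))
  vx <- matrix(c(0, -v[3L], v[2L], v[3L], 0, -v[1L], -v[2L], v[1L], 0),
               3L, 3L, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

#' Write a fixture bundle to disk
#'
#' Structures are serialised as PDB (so tests exercise the public reader)
#' and the ground truth as JSON, side by side.
#'
#' @param bundle a \code{\link{FixtureBundle}}
#' @param dir output directory (created if needed)
#' @return named list of written paths, invisibly
#' @export
writeFixture <- function(bundle, dir) {
  stopifnot(is(bundle, "FixtureBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (i in seq_along(bundle@structures)) {
    p <- file.path(dir, sprintf("%s_%d.pdb", bundle@kind, i))
    writeStructure(bundle@structures[[i]], p)
    paths[[length(paths) + 1L]] <- p
  }
  gtPath <- file.path(dir, paste0(bundle@kind, "_truth.json"))
  jsonlite::write_json(bundle@groundTruth, gtPath, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  paths$ground_truth <- gtPath
  invisible(paths)
}
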