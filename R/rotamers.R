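## Side-chain rotamer enumeration. Conformations are generated on a uniform
## chi-angle grid by rotating the existing side-chain atoms about each chi
## bond, and scored purely by summed van der Waals overlap against the rest
## of the structure. This clash score deliberately replaces force-field
## stability scoring: a rotamer whose every grid point clashes has no
## sterically acceptable conformation.

.CHI_DEFS <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  CYS = list(c("N", "CA", "CB", "SG")))

#' Enumerate side-chain rotamers and score them by steric clash
#'
#' Generates every combination of chi angles on a uniform grid (default
#' step 30 degrees, i.e. (360/step)^k conformations for k rotatable chi
#' angles) by rotating the residue's side-chain atoms about each chi bond,
#' and scores each conformation by the summed vdW overlap (over pairs whose
#' overlap exceeds the tolerance) of its side-chain atoms against all atoms
#' outside the residue.
#'
#' @param x a \code{ProteinStructure}
#' @param resno residue number of the residue to enumerate
#' @param chain chain identifier ("" auto-selects a single chain)
#' @param chiGrid grid step in degrees (must divide 360; default 30)
#' @param tolerance overlap threshold for counting a clash, Angstrom
#' @param radii vdW radius table (default \code{\link{defaultRadii}})
#' @return data.frame sorted by ascending clash score, one row per rotamer:
#'   chi1..chiK (degrees), clash_score (A, summed overlap), n_clashes
#' @examples
#' fx <- makeFixture("crowded_pocket", seed = 1, params = list())
#' rot <- enumerateRotamers(structures(fx)[[1]],
#'                          groundTruth(fx)$arg_resno, chiGrid = 120)
#' head(rot)
#' @export
enumerateRotamers <- function(x, resno, chain = "", chiGrid = 30,
                              tolerance = 0.4, radii = defaultRadii()) {
  stopifnot(is(x, "ProteinStructure"))
  if (360 %% chiGrid != 0) stop("chiGrid must divide 360")
  a <- atoms(x)
  a <- a[toupper(a$elem) != "H", , drop = FALSE]
  if (!nzchar(chain)) {
    ch <- unique(a$chain)
    if (length(ch) > 1L && sum(a$resno == resno & !a$het) == 0L)
      stop("chain must be given for multi-chain structures")
    chain <- unique(a$chain[a$resno == resno])[1L]
  }
  own <- a$chain == chain & a$resno == resno
  if (!any(own)) stop("residue not found: ", chain, ":", resno)
  res <- a[own, , drop = FALSE]
  resid <- res$resid[1L]
  defs <- .CHI_DEFS[[resid]]
  if (is.null(defs))
    stop("unsupported residue for rotamer enumeration: ", resid,
         " (no rotatable chi angles)")
  needed <- unique(unlist(defs))
  if (!all(needed %in% res$name))
    stop("missing side-chain atom(s) for ", resid, ": ",
         paste(setdiff(needed, res$name), collapse = ", "))
  nChi <- length(defs)
  P <- as.matrix(res[, c("x", "y", "z")])
  rownames(P) <- res$name
  adj <- .bondAdjacency(res)
  # moving set for each chi: connected component of a4 after cutting a2-a3
  movers <- lapply(defs, function(d) {
    i2 <- match(d[2L], res$name); i3 <- match(d[3L], res$name)
    i4 <- match(d[4L], res$name)
    adj2 <- adj
    adj2[[i2]] <- setdiff(adj2[[i2]], i3)
    adj2[[i3]] <- setdiff(adj2[[i3]], i2)
    comp <- i4; frontier <- i4
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj2[frontier])), comp)
      comp <- c(comp, nxt); frontier <- nxt
    }
    sort(comp)
  })
  # environment atoms within reach of CB
  cb <- P[match("CB", res$name), ]
  env <- a[!own, , drop = FALSE]
  if (nrow(env)) {
    reach <- 4 + max(sqrt(rowSums(sweep(P, 2L, cb)^2))) + 6
    dcb <- sqrt(colSums((t(as.matrix(env[, c("x", "y", "z")])) - cb)^2))
    env <- env[dcb < reach, , drop = FALSE]
  }
  envXYZ <- as.matrix(env[, c("x", "y", "z")])
  envR <- if (nrow(env)) .radiusFor(env$elem, radii) else numeric()
  scIdx <- which(!res$name %in% c("N", "CA", "C", "O", "OXT"))
  scR <- .radiusFor(res$elem[scIdx], radii)
  gridVals <- seq(0, 360 - chiGrid, by = chiGrid)
  combos <- as.matrix(expand.grid(rev(replicate(nChi, gridVals,
                                                simplify = FALSE))))
  combos <- combos[, rev(seq_len(nChi)), drop = FALSE]  # chi1 slowest
  colnames(combos) <- paste0("chi", seq_len(nChi))
  scoreOne <- function(Pcur) {
    if (!nrow(env)) return(c(0, 0))
    S <- Pcur[scIdx, , drop = FALSE]
    d <- sqrt(outer(rowSums(S^2), rowSums(envXYZ^2), "+") -
                2 * S %*% t(envXYZ))
    ov <- outer(scR, envR, "+") - d
    flag <- ov > tolerance
    c(sum(ov[flag]), sum(flag))
  }
  nCombo <- nrow(combos)
  scores <- matrix(0, nCombo, 2L)
  # recursive descent: reuse partial rotations of the slower chi angles
  desc <- function(level, Pcur, rowRange) {
    if (level > nChi) {
      scores[rowRange, ] <<- matrix(scoreOne(Pcur), 1L, 2L)
      return(invisible())
    }
    d <- defs[[level]]
    i1 <- match(d[1L], res$name); i2 <- match(d[2L], res$name)
    i3 <- match(d[3L], res$name); i4 <- match(d[4L], res$name)
    cur <- .dihedral(Pcur[i1, ], Pcur[i2, ], Pcur[i3, ], Pcur[i4, ])
    block <- length(rowRange) / length(gridVals)
    for (g in seq_along(gridVals)) {
      ang <- cur - gridVals[g]  # +rotation about the bond lowers the dihedral
      R <- .rotationAboutAxis(Pcur[i3, ] - Pcur[i2, ], ang)
      Pnew <- Pcur
      mv <- movers[[level]]
      Pnew[mv, ] <- sweep(sweep(Pcur[mv, , drop = FALSE], 2L, Pcur[i2, ]) %*%
                            t(R), 2L, -Pcur[i2, ])
      sub <- rowRange[((g - 1L) * block + 1L):(g * block)]
      desc(level + 1L, Pnew, sub)
    }
  }
  desc(1L, P, seq_len(nCombo))
  out <- as.data.frame(combos)
  out$clash_score <- scores[, 1L]
  out$n_clashes <- as.integer(scores[, 2L])
  ord <- do.call(order, c(list(out$clash_score),
                          as.list(as.data.frame(combos))))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
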