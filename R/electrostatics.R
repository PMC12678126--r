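## Finite-difference linear Poisson-Boltzmann electrostatics with grid
## focusing. The molecular volume is the union of atomic vdW spheres;
## dielectric values are assigned at edge midpoints; mobile-ion screening is
## zeroed inside an ion-exclusion layer; boundary potentials follow the
## screened (Debye-Hueckel) monopole of each source charge. Successive
## over-relaxation runs in compiled code.

# modified screening factor eps_s * kappa^2 in A^-2:
# 8 pi C (N_A/1e27) I / (R T), independent of eps_s
.kbar2 <- function(ionicStrength, temperature) {
  8 * pi * .COULOMB * 6.022e-4 * ionicStrength / (.RGAS * temperature)
}

# node coordinates along each axis
.gridAxes <- function(grid) {
  n <- grid@extent; h <- grid@spacing; c0 <- grid@center
  lapply(1:3, function(d) c0[d] + (seq_len(n[d]) - (n[d] + 1) / 2) * h)
}

#' Fit a grid around a bounding box
#'
#' @param bbox 2 x 3 matrix (min/max corners, Angstrom)
#' @param spacing grid spacing
#' @param margin absolute margin added on every side, Angstrom
#' @param minExtent minimum points per axis (default 33)
#' @return a \code{GridSpec} (odd extents, centred on the box)
#' @export
fitGrid <- function(bbox, spacing, margin = 0, minExtent = 33L) {
  span <- bbox[2L, ] - bbox[1L, ] + 2 * margin
  n <- pmax(minExtent, as.integer(ceiling(span / spacing)) + 1L)
  n <- ifelse(n %% 2L == 0L, n + 1L, n)
  gridSpec(spacing, n, colMeans(bbox))
}

.structureBBox <- function(s, radii = defaultRadii(), pad = 0) {
  xyz <- coords(s)
  if (!nrow(xyz)) return(rbind(c(-1, -1, -1), c(1, 1, 1)))
  r <- .radiusFor(atoms(s)$elem, radii) + pad
  rbind(apply(xyz - r, 2L, min), apply(xyz + r, 2L, max))
}

#' Build dielectric and ion-accessibility maps on a grid
#'
#' Edge midpoints inside the vdW-union volume (atom radii optionally
#' inflated by the solvent probe) get the protein dielectric; everything
#' else gets the solvent value. Ion accessibility is zero within the
#' ion-exclusion layer (atom radius + Stern thickness) around the solute.
#'
#' @param s a \code{ProteinStructure} (may be empty: uniform solvent)
#' @param model a \code{ContinuumModel}
#' @param grid a \code{GridSpec}
#' @param radii vdW radius table
#' @return list with 3-D arrays \code{epsNode}, \code{lambda} and
#'   edge-centred arrays \code{epsX}, \code{epsY}, \code{epsZ}
#' @export
buildDielectricMap <- function(s, model, grid, radii = defaultRadii()) {
  n <- grid@extent; h <- grid@spacing
  ax <- .gridAxes(grid)
  epsNode <- array(model@epsSolvent, n)
  lambda <- array(1, n)
  epsX <- array(model@epsSolvent, c(n[1] - 1L, n[2], n[3]))
  epsY <- array(model@epsSolvent, c(n[1], n[2] - 1L, n[3]))
  epsZ <- array(model@epsSolvent, c(n[1], n[2], n[3] - 1L))
  if (nAtoms(s) > 0L) {
    xyz <- coords(s)
    rv <- .radiusFor(atoms(s)$elem, radii) + model@solventProbeRadius
    lo <- sapply(1:3, function(d) min(ax[[d]]))
    hi <- sapply(1:3, function(d) max(ax[[d]]))
    if (any(apply(xyz - rv, 2L, min) < lo - h) ||
        any(apply(xyz + rv, 2L, max) > hi + h))
      stop("grid smaller than solute bounding box plus margin; enlarge ",
           "extent or use fitGrid()")
    mark <- function(target, axX, axY, axZ, radd) {
      for (i in seq_len(nrow(xyz))) {
        r <- rv[i] + radd
        ix <- which(abs(axX - xyz[i, 1]) <= r)
        iy <- which(abs(axY - xyz[i, 2]) <= r)
        iz <- which(abs(axZ - xyz[i, 3]) <= r)
        if (!length(ix) || !length(iy) || !length(iz)) next
        dx2 <- (axX[ix] - xyz[i, 1])^2
        dy2 <- (axY[iy] - xyz[i, 2])^2
        dz2 <- (axZ[iz] - xyz[i, 3])^2
        inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r * r
        target[ix, iy, iz][inside] <- 0
      }
      target
    }
    # node eps / lambda
    inP <- array(1, n)
    inP <- mark(inP, ax[[1]], ax[[2]], ax[[3]], 0)
    epsNode[inP == 0] <- model@epsProtein
    lambda <- mark(lambda, ax[[1]], ax[[2]], ax[[3]],
                   model@ionExclusionRadius)
    # edge-centred eps from midpoints
    mx <- ax[[1]][-n[1]] + h / 2
    my <- ax[[2]][-n[2]] + h / 2
    mz <- ax[[3]][-n[3]] + h / 2
    eX <- array(1, dim(epsX)); eX <- mark(eX, mx, ax[[2]], ax[[3]], 0)
    eY <- array(1, dim(epsY)); eY <- mark(eY, ax[[1]], my, ax[[3]], 0)
    eZ <- array(1, dim(epsZ)); eZ <- mark(eZ, ax[[1]], ax[[2]], mz, 0)
    epsX[eX == 0] <- model@epsProtein
    epsY[eY == 0] <- model@epsProtein
    epsZ[eZ == 0] <- model@epsProtein
  }
  list(epsNode = epsNode, epsX = epsX, epsY = epsY, epsZ = epsZ,
       lambda = lambda, grid = grid)
}

# trilinear spread of point charges onto grid nodes
.spreadCharges <- function(charges, grid) {
  n <- grid@extent; h <- grid@spacing
  ax <- .gridAxes(grid)
  q <- array(0, n)
  for (i in seq_len(nrow(charges))) {
    p <- c(charges$x[i], charges$y[i], charges$z[i])
    fi <- (p - c(ax[[1]][1], ax[[2]][1], ax[[3]][1])) / h + 1
    i0 <- floor(fi)
    if (any(i0 < 2) || any(i0 > n - 2))
      stop("charge outside (or too close to the boundary of) the grid")
    f <- fi - i0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[1] else 1 - f[1]) *
        (if (dy) f[2] else 1 - f[2]) *
        (if (dz) f[3] else 1 - f[3])
      q[i0[1] + dx, i0[2] + dy, i0[3] + dz] <-
        q[i0[1] + dx, i0[2] + dy, i0[3] + dz] + w * charges$q[i]
    }
  }
  q
}

# screened-monopole (Debye-Hueckel) potential of the source charges
.dhPotential <- function(pts, charges, model) {
  kb2 <- .kbar2(model@ionicStrength, model@temperature)
  kap <- sqrt(kb2 / model@epsSolvent)
  phi <- numeric(nrow(pts))
  for (i in seq_len(nrow(charges))) {
    r <- sqrt((pts[, 1] - charges$x[i])^2 + (pts[, 2] - charges$y[i])^2 +
                (pts[, 3] - charges$z[i])^2)
    r <- pmax(r, 0.5)
    phi <- phi + .COULOMB * charges$q[i] * exp(-kap * r) /
      (model@epsSolvent * r)
  }
  phi
}

# boundary node linear indices + coordinates of a grid
.boundaryNodes <- function(grid) {
  n <- grid@extent
  ax <- .gridAxes(grid)
  idx <- array(FALSE, n)
  idx[c(1, n[1]), , ] <- TRUE
  idx[, c(1, n[2]), ] <- TRUE
  idx[, , c(1, n[3])] <- TRUE
  which3 <- which(idx, arr.ind = TRUE)
  pts <- cbind(ax[[1]][which3[, 1]], ax[[2]][which3[, 2]],
               ax[[3]][which3[, 3]])
  list(lin = which(idx), pts = pts)
}

#' Solve the linear Poisson-Boltzmann equation on one grid
#'
#' Finite-difference solution of div(eps grad phi) - eps_s kappa^2 lambda
#' phi = -4 pi rho with trilinear charge assignment, Debye-Hueckel monopole
#' boundary values (or caller-supplied boundary potentials) and successive
#' over-relaxation.
#'
#' @param charges data.frame with columns x, y, z (Angstrom) and q
#'   (elementary charges)
#' @param dielMap output of \code{\link{buildDielectricMap}}
#' @param model a \code{ContinuumModel}
#' @param tolerance relative-residual convergence tolerance (default 1e-6)
#' @param maxIter maximum SOR sweeps (default 20000)
#' @param boundaryValues optional numeric vector of boundary potentials in
#'   the order of the grid's boundary nodes (used by grid focusing)
#' @return a \code{\link{PBSolution}}; potential in kcal/mol/e
#' @export
solveLPB <- function(charges, dielMap, model, tolerance = 1e-6,
                     maxIter = 20000L, boundaryValues = NULL) {
  grid <- dielMap$grid
  n <- grid@extent; h <- grid@spacing
  qGrid <- .spreadCharges(charges, grid)
  src <- 4 * pi * .COULOMB * qGrid / h
  phi <- array(0, n)
  bn <- .boundaryNodes(grid)
  if (is.null(boundaryValues)) {
    boundaryValues <- if (nrow(charges)) .dhPotential(bn$pts, charges, model)
    else numeric(length(bn$lin))
  }
  phi[bn$lin] <- boundaryValues
  kb2 <- .kbar2(model@ionicStrength, model@temperature)
  res <- .lpb_sor(as.numeric(phi), as.numeric(dielMap$epsX),
                  as.numeric(dielMap$epsY), as.numeric(dielMap$epsZ),
                  as.numeric(dielMap$lambda), as.numeric(src),
                  n, h, kb2, tolerance, as.integer(maxIter), -1)
  if (!res$converged)
    warning("LPB solver did not reach tolerance ", tolerance,
            " in ", maxIter, " sweeps (residual ",
            format(res$residual, digits = 3), ")")
  new("PBSolution", potential = array(res$phi, n), grid = grid,
      converged = res$converged, iterations = as.integer(res$iterations),
      residual = res$residual)
}

#' Evaluate a PB potential at arbitrary points
#'
#' Trilinear interpolation; points outside the grid return NA.
#'
#' @param sol a \code{PBSolution}
#' @param pts n x 3 matrix of coordinates
#' @return numeric vector, kcal/mol/e
#' @export
potentialAt <- function(sol, pts) {
  grid <- sol@grid
  n <- grid@extent; h <- grid@spacing
  ax <- .gridAxes(grid)
  pts <- matrix(pts, ncol = 3L)
  out <- rep(NA_real_, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    fi <- (pts[i, ] - c(ax[[1]][1], ax[[2]][1], ax[[3]][1])) / h + 1
    i0 <- floor(fi)
    if (any(i0 < 1) || any(i0 > n - 1)) next
    f <- fi - i0
    v <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[1] else 1 - f[1]) *
        (if (dy) f[2] else 1 - f[2]) *
        (if (dz) f[3] else 1 - f[3])
      v <- v + w * sol@potential[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
    out[i] <- v
  }
  out
}

#' Grid-focused LPB solution
#'
#' Solves on successively finer grids (default 2.5, 1.0, 0.3 Angstrom).
#' The coarsest grid covers the solute bounding box plus a 40 percent
#' margin; each finer grid covers the region of interest (by default the
#' charge bounding box plus 8 Angstrom) and takes its boundary values from
#' the previous solution (falling back to the screened monopole outside it).
#'
#' @param charges data.frame x, y, z, q
#' @param s \code{ProteinStructure} defining the dielectric volume
#' @param model a \code{ContinuumModel}
#' @param levels strictly decreasing grid spacings, Angstrom
#' @param tolerance,maxIter solver controls
#' @param focusBBox optional 2 x 3 matrix overriding the region of interest
#' @param radii vdW radius table
#' @return the \code{PBSolution} of the finest level
#' @export
focusSolve <- function(charges, s, model, levels = c(2.5, 1.0, 0.3),
                       tolerance = 1e-6, maxIter = 20000L,
                       focusBBox = NULL, radii = defaultRadii()) {
  if (any(diff(levels) >= 0)) stop("levels must be strictly decreasing")
  chM <- as.matrix(charges[, c("x", "y", "z")])
  solute <- .structureBBox(s, radii)
  outer_box <- rbind(pmin(solute[1L, ], apply(chM, 2L, min)),
                     pmax(solute[2L, ], apply(chM, 2L, max)))
  span <- max(outer_box[2L, ] - outer_box[1L, ], 1)
  if (is.null(focusBBox))
    focusBBox <- rbind(apply(chM, 2L, min) - 8, apply(chM, 2L, max) + 8)
  sol <- NULL
  for (lev in seq_along(levels)) {
    h <- levels[lev]
    grid <- if (lev == 1L)
      fitGrid(outer_box, h, margin = 0.2 * span)
    else fitGrid(focusBBox, h, margin = 0)
    dmap <- buildDielectricMap(s, model, grid, radii)
    bvals <- NULL
    if (!is.null(sol)) {
      bn <- .boundaryNodes(grid)
      bvals <- potentialAt(sol, bn$pts)
      if (anyNA(bvals)) {
        nai <- is.na(bvals)
        bvals[nai] <- .dhPotential(bn$pts[nai, , drop = FALSE], charges,
                                   model)
      }
    }
    sol <- solveLPB(charges, dmap, model, tolerance, maxIter, bvals)
  }
  sol
}

#' Electrostatic solvation (reaction-field) energy of a charge set
#'
#' Solves the focused LPB problem twice on identical grids -- once with the
#' heterogeneous dielectric map, once with the protein dielectric everywhere
#' and no salt -- and returns 0.5 * sum q (phi_het - phi_hom) evaluated at
#' the charge positions. The grid self-energy cancels in the subtraction,
#' leaving the reaction-field (Born) energy.
#'
#' @param charges data.frame x, y, z, q
#' @param s \code{ProteinStructure} defining the dielectric volume
#' @param model a \code{ContinuumModel}
#' @param levels focusing spacings
#' @param ... passed to \code{\link{focusSolve}}
#' @return energy in kcal/mol
#' @export
solvationEnergy <- function(charges, s, model, levels = c(2.5, 1.0, 0.3),
                            ...) {
  het <- focusSolve(charges, s, model, levels, ...)
  uni <- continuumModel(epsProtein = model@epsProtein,
                        epsSolvent = model@epsProtein,
                        ionicStrength = 0,
                        temperature = model@temperature,
                        ionExclusionRadius = model@ionExclusionRadius,
                        solventProbeRadius = model@solventProbeRadius)
  hom <- focusSolve(charges, s, uni, levels, ...)
  pts <- as.matrix(charges[, c("x", "y", "z")])
  0.5 * sum(charges$q * (potentialAt(het, pts) - potentialAt(hom, pts)))
}
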