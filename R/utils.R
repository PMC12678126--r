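## Small shared helpers: residue-code maps, element inference, vector
## geometry, and bundled parameter-table loaders.

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.AA1TO3 <- setNames(names(.AA3TO1), .AA3TO1)

#' Infer element symbols from PDB atom names
#'
#' Follows PDB conventions: two-letter elements (FE, MG, CL, ...) are
#' recognised; otherwise the first letter (after any leading digit) is the
#' element.
#'
#' @param name character vector of atom names
#' @return character vector of element symbols
#' @export
guessElement <- function(name) {
  nm <- toupper(trimws(name))
  nm <- sub("^[0-9']+", "", nm)
  two <- substr(nm, 1L, 2L)
  known2 <- c("FE", "MG", "CL", "BR", "ZN", "MN", "NA", "SE")
  elem <- ifelse(two %in% known2 & nchar(nm) == nchar(two),
                 two, substr(nm, 1L, 1L))
  # heteroatom metal names like 'FE1'
  elem[substr(nm, 1L, 2L) %in% c("FE", "MG", "ZN", "MN") &
         grepl("^[A-Z]{2}[0-9]*$", nm)] <- substr(nm, 1L, 2L)[
           substr(nm, 1L, 2L) %in% c("FE", "MG", "ZN", "MN") &
             grepl("^[A-Z]{2}[0-9]*$", nm)]
  elem
}

.norm3 <- function(v) sqrt(sum(v * v))

.unit <- function(v) v / .norm3(v)

#' Dihedral angle of four points
#' @param p1,p2,p3,p4 numeric(3) coordinates
#' @return angle in degrees, in (-180, 180]
#' @keywords internal
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / .norm3(b2)
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' Rotation matrix about an arbitrary axis
#' @param axis numeric(3), need not be normalised
#' @param angleDeg rotation angle, degrees
#' @return 3x3 rotation matrix
#' @keywords internal
.rotationAboutAxis <- function(axis, angleDeg) {
  u <- .unit(axis)
  th <- angleDeg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
           uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
           uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)),
         nrow = 3, byrow = TRUE)
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three placed atoms a-b-c, returns the position of atom d with the
#' given bond length c-d, angle b-c-d and dihedral a-b-c-d.
#'
#' @param a,b,c numeric(3) positions
#' @param length bond length c-d, Angstrom
#' @param angle angle b-c-d, degrees
#' @param dihedral dihedral a-b-c-d, degrees
#' @return numeric(3) position of d
#' @keywords internal
.placeAtom <- function(a, b, c, length, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  bc <- .unit(c - b)
  ab <- b - a
  nv <- c(ab[2] * bc[3] - ab[3] * bc[2],
          ab[3] * bc[1] - ab[1] * bc[3],
          ab[1] * bc[2] - ab[2] * bc[1])
  nv <- .unit(nv)
  mv <- c(nv[2] * bc[3] - nv[3] * bc[2],
          nv[3] * bc[1] - nv[1] * bc[3],
          nv[1] * bc[2] - nv[2] * bc[1])
  d2 <- c(-length * cos(th),
          length * sin(th) * cos(ph),
          -length * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * mv + d2[3] * nv
}

## ---- bundled parameter tables ---------------------------------------------

.paramCache <- new.env(parent = emptyenv())

.loadParam <- function(file) {
  if (!is.null(.paramCache[[file]])) return(.paramCache[[file]])
  path <- system.file("extdata", file, package = "VariantLens")
  if (!nzchar(path)) stop("bundled parameter file not found: ", file)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  .paramCache[[file]] <- obj
  obj
}

#' Bundled van der Waals radius table
#'
#' Bondi-style radii keyed by element symbol, used by the clash detector and
#' the dielectric-map builder.
#'
#' @return named numeric vector, Angstrom
#' @export
defaultRadii <- function() {
  tab <- .loadParam("vdw_radii.json")
  tab <- tab[names(tab) != "_comment"]
  unlist(tab)
}

#' Bundled hydrogen-bond donor/acceptor and charge-group table
#' @return list with components \code{backbone} and \code{residues}
#' @export
polarAtomTable <- function() {
  tab <- .loadParam("polar_atoms.json")
  tab[names(tab) != "_comment"]
}

#' Bundled titratable-site library
#'
#' Reference pKa values (Arg 12.0, Asp 4.0, Cys 9.5, Glu 4.4, Lys 10.4,
#' Tyr 9.6, His N-epsilon 7.0 / N-delta 6.6), per-state atomic charge sets,
#' and background formal charges for nucleotide/DNA phosphates.
#'
#' @return list with components \code{sites}, \code{imidazolate_penalty},
#'   \code{background_charges}
#' @export
siteDefinitions <- function() {
  tab <- .loadParam("site_definitions.json")
  tab[names(tab) != "_comment"]
}

#' Look up vdW radii for a vector of elements
#' @param elem character vector of element symbols
#' @param radii named radius table (default \code{defaultRadii()})
#' @return numeric vector
#' @keywords internal
.radiusFor <- function(elem, radii = defaultRadii()) {
  r <- radii[toupper(elem)]
  if (anyNA(r)) {
    bad <- unique(toupper(elem)[is.na(r)])
    stop("no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "))
  }
  unname(r)
}
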