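## Rigid-body superposition (Kabsch) and displacement profiling. Atoms are
## paired between structures by (chain, resno, insert, name); selections are
## predicate functions over the atom table.

#' Atom selection helpers
#'
#' Selections are functions taking an atom data.frame and returning a
#' logical vector. These constructors cover the common cases; arbitrary
#' predicates can be written directly.
#'
#' @param names atom names to keep
#' @param chain chain identifier(s)
#' @param resno residue numbers
#' @param exclude logical: invert the residue selection
#' @return a predicate \code{function(atoms) -> logical}
#' @export
selectCalpha <- function() function(a) a$name == "CA" & !a$het

#' @rdname selectCalpha
#' @export
selectAtomNames <- function(names) {
  force(names)
  function(a) a$name %in% names
}

#' @rdname selectCalpha
#' @export
selectChain <- function(chain) {
  force(chain)
  function(a) a$chain %in% chain
}

#' @rdname selectCalpha
#' @export
selectResidues <- function(resno, chain = NULL, exclude = FALSE) {
  force(resno); force(chain); force(exclude)
  function(a) {
    hit <- a$resno %in% resno
    if (!is.null(chain)) hit <- hit & a$chain %in% chain
    if (exclude) !hit else hit
  }
}

#' @rdname selectCalpha
#' @export
selectAll <- function() function(a) rep(TRUE, nrow(a))

.atomKey <- function(a) paste(a$chain, a$resno, a$insert, a$name, sep = "|")

# paired coordinate matrices for atoms selected in both structures
.pairAtoms <- function(reference, mobile, selection) {
  ra <- atoms(reference); ma <- atoms(mobile)
  rs <- ra[selection(ra), , drop = FALSE]
  ms <- ma[selection(ma), , drop = FALSE]
  rk <- .atomKey(rs); mk <- .atomKey(ms)
  common <- intersect(rk, mk)
  unmatched <- c(setdiff(rk, mk), setdiff(mk, rk))
  rs <- rs[match(common, rk), , drop = FALSE]
  ms <- ms[match(common, mk), , drop = FALSE]
  list(ref = rs, mob = ms, unmatched = unmatched)
}

#' Optimal rigid superposition of two structures (Kabsch)
#'
#' Computes the least-squares optimal rotation and translation mapping the
#' mobile structure onto the reference over a paired atom selection, by the
#' Kabsch/SVD method. Atoms are paired by (chain, residue number, insertion
#' code, atom name).
#'
#' @param reference,mobile \code{ProteinStructure} objects
#' @param selection predicate over the atom table (default: all C-alpha
#'   atoms)
#' @return a \code{\link{SuperpositionResult}}; apply it with
#'   \code{\link{applyTransform}}
#' @examples
#' fx <- makeFixture("displaced_pair", seed = 1)
#' sup <- superpose(structures(fx)[[1]], structures(fx)[[2]],
#'                  selectResidues(groundTruth(fx)$window, exclude = TRUE))
#' sup
#' @export
superpose <- function(reference, mobile, selection = selectCalpha()) {
  p <- .pairAtoms(reference, mobile, selection)
  n <- nrow(p$ref)
  if (n < 3L)
    stop("superposition needs >= 3 paired atoms, got ", n,
         if (length(p$unmatched))
           paste0(" (unmatched: ",
                  paste(head(p$unmatched, 5L), collapse = ", "), ")")
         else "")
  X <- as.matrix(p$mob[, c("x", "y", "z")])   # mobile
  Y <- as.matrix(p$ref[, c("x", "y", "z")])   # reference
  cx <- unname(colMeans(X)); cy <- unname(colMeans(Y))
  X0 <- sweep(X, 2L, cx); Y0 <- sweep(Y, 2L, cy)
  # collinearity guard: rank of the centred reference coordinates
  if (sum(svd(Y0)$d > 1e-8 * max(1, max(abs(Y0)))) < 2L)
    stop("selection atoms are collinear; superposition is degenerate")
  H <- crossprod(X0, Y0)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cy - as.vector(R %*% cx)
  fitted <- sweep(X %*% t(R), 2L, -tvec)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  new("SuperpositionResult", rotation = R, translation = tvec,
      rmsd = rmsd, nAtoms = as.integer(n))
}

#' Apply a rigid transform to a structure
#'
#' @param x a \code{ProteinStructure}
#' @param transform a \code{SuperpositionResult}
#' @return the transformed structure (y = R x + t per atom)
#' @export
applyTransform <- function(x, transform) {
  stopifnot(is(transform, "SuperpositionResult"))
  xyz <- coords(x)
  moved <- sweep(xyz %*% t(transform@rotation), 2L, -transform@translation)
  coords(x) <- moved
  x
}

#' Per-atom displacement profile between two structures
#'
#' Superposes \code{b} onto \code{a} over \code{fitSelection}, then reports
#' the Euclidean displacement of every atom in \code{reportSelection} that
#' is paired in both structures. Unpaired report atoms are skipped with a
#' warning. Entries follow chain/residue order of the reference.
#'
#' @param a reference \code{ProteinStructure}
#' @param b mobile \code{ProteinStructure}
#' @param fitSelection selection used for the rigid fit (default C-alpha)
#' @param reportSelection selection of atoms to report (default C-alpha)
#' @param selectionLabel label stored on the profile
#' @return a \code{\link{DisplacementProfile}}
#' @examples
#' fx <- makeFixture("displaced_pair", seed = 1)
#' pr <- displacementProfile(structures(fx)[[1]], structures(fx)[[2]],
#'         fitSelection = selectResidues(groundTruth(fx)$window,
#'                                       exclude = TRUE))
#' head(profileEntries(pr))
#' @export
displacementProfile <- function(a, b, fitSelection = selectCalpha(),
                                reportSelection = selectCalpha(),
                                selectionLabel = "C-alpha") {
  sup <- superpose(a, b, fitSelection)
  bFit <- applyTransform(b, sup)
  p <- .pairAtoms(a, bFit, reportSelection)
  if (length(p$unmatched))
    warning("skipping ", length(p$unmatched),
            " unpaired report atom(s): ",
            paste(head(p$unmatched, 5L), collapse = ", "))
  d <- sqrt(rowSums((as.matrix(p$ref[, c("x", "y", "z")]) -
                       as.matrix(p$mob[, c("x", "y", "z")]))^2))
  ord <- order(p$ref$chain, p$ref$resno, p$ref$insert)
  entries <- data.frame(chain = p$ref$chain[ord], resno = p$ref$resno[ord],
                        name = p$ref$name[ord], displacement = d[ord],
                        stringsAsFactors = FALSE)
  new("DisplacementProfile", entries = entries,
      selectionLabel = selectionLabel, superposition = sup)
}

#' Entries of a displacement profile
#' @param x a \code{DisplacementProfile}
#' @return data.frame with columns chain, resno, name, displacement
#' @export
profileEntries <- function(x) {
  stopifnot(is(x, "DisplacementProfile"))
  x@entries
}
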