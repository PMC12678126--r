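## Generics and accessors. Bioconductor-style: slots are reached through
## accessor generics, never with @ in user code.

#' Atom table of a structure
#' @param x a \code{ProteinStructure}
#' @return data.frame of atoms
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "ProteinStructure", function(x) x@atoms)

#' Number of atoms
#' @param x a \code{ProteinStructure}
#' @return integer
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "ProteinStructure", function(x) nrow(x@atoms))

#' Model identifier
#' @param x a \code{ProteinStructure}
#' @return character
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))

#' @rdname modelId
#' @export
setMethod("modelId", "ProteinStructure", function(x) x@modelId)

#' Atom coordinates as an n x 3 matrix
#' @param x a \code{ProteinStructure}
#' @return numeric matrix with columns x, y, z
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "ProteinStructure", function(x)
  as.matrix(x@atoms[, c("x", "y", "z")]))

#' Replace atom coordinates
#' @param x a \code{ProteinStructure}
#' @param value n x 3 matrix
#' @return the modified structure
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' @rdname coords-set
#' @export
setMethod("coords<-", "ProteinStructure", function(x, value) {
  stopifnot(nrow(value) == nrow(x@atoms), ncol(value) == 3L)
  x@atoms$x <- value[, 1L]
  x@atoms$y <- value[, 2L]
  x@atoms$z <- value[, 3L]
  validObject(x)
  x
})

#' Protonation probabilities
#' @param x a \code{ProtonationResult}
#' @return named numeric vector of per-site probabilities
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))

#' @rdname probabilities
#' @export
setMethod("probabilities", "ProtonationResult", function(x) x@probabilities)

#' Monte Carlo standard errors
#' @param x a \code{ProtonationResult}
#' @return named numeric vector (length 0 for exact enumeration)
#' @export
setGeneric("mcError", function(x) standardGeneric("mcError"))

#' @rdname mcError
#' @export
setMethod("mcError", "ProtonationResult", function(x) x@mcError)

#' Site-site interaction matrix
#' @param x a \code{TitrationSystem} or \code{SiteEnergies}
#' @return symmetric numeric matrix, kcal/mol
#' @export
setGeneric("wMatrix", function(x) standardGeneric("wMatrix"))

#' @rdname wMatrix
#' @export
setMethod("wMatrix", "TitrationSystem", function(x) x@wMatrix)

#' @rdname wMatrix
#' @export
setMethod("wMatrix", "SiteEnergies", function(x) x@wMatrix)

#' Titratable-site table
#' @param x a \code{TitrationSystem} or \code{SiteEnergies}
#' @return data.frame of sites
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @rdname siteTable
#' @export
setMethod("siteTable", "TitrationSystem", function(x) x@sites)

#' @rdname siteTable
#' @export
setMethod("siteTable", "SiteEnergies", function(x) x@sites)

#' Intrinsic charging free-energy shifts
#' @param x a \code{SiteEnergies}
#' @return numeric vector, kcal/mol
#' @export
setGeneric("deltaGIntr", function(x) standardGeneric("deltaGIntr"))

#' @rdname deltaGIntr
#' @export
setMethod("deltaGIntr", "SiteEnergies", function(x) x@deltaGIntr)

#' Conditions of a titration system
#' @param x a \code{TitrationSystem}
#' @return list(pH, temperature, ionicStrength)
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @rdname conditions
#' @export
setMethod("conditions", "TitrationSystem", function(x) x@conditions)

#' Ground truth of a synthetic fixture
#' @param x a \code{FixtureBundle}
#' @return list of expected quantities
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "FixtureBundle", function(x) x@groundTruth)

#' Structures held by a fixture bundle
#' @param x a \code{FixtureBundle}
#' @return list of \code{ProteinStructure} objects (may be empty for
#'   non-structural fixtures)
#' @export
setGeneric("structures", function(x) standardGeneric("structures"))

#' @rdname structures
#' @export
setMethod("structures", "FixtureBundle", function(x) x@structures)

## ---- show methods ----------------------------------------------------------

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  nres <- length(unique(paste(a$chain, a$resno, a$insert)))
  cat("ProteinStructure '", object@modelId, "': ", nrow(a), " atoms, ",
      nres, " residues, chains: ",
      paste(sort(unique(a$chain)), collapse = ","), "\n", sep = "")
})

setMethod("show", "MotifHit", function(object) {
  cat("Walker A motif hit on chain ", object@chain, ": ",
      object@sequence, " (", object@resno[1L], "-", object@resno[8L],
      "), K at ", object@resno[7L], "\n", sep = "")
})

setMethod("show", "SuperpositionResult", function(object) {
  cat("Superposition over", object@nAtoms, "atoms, RMSD",
      sprintf("%.3f", object@rmsd), "A\n")
})

setMethod("show", "PBSolution", function(object) {
  cat("PBSolution on ", paste(object@grid@extent, collapse = "x"),
      " grid, spacing ", object@grid@spacing, " A; ",
      if (object@converged) "converged" else "NOT converged",
      " after ", object@iterations, " sweeps (residual ",
      format(object@residual, digits = 3), ")\n", sep = "")
})

setMethod("show", "TitrationSystem", function(object) {
  cat("TitrationSystem: ", nrow(object@sites), " sites at pH ",
      object@conditions$pH, ", ", object@conditions$temperature, " K\n",
      sep = "")
})

setMethod("show", "ProtonationResult", function(object) {
  cat("ProtonationResult (", object@method, "): ",
      length(object@probabilities), " sites\n", sep = "")
  print(round(object@probabilities, 4))
})

setMethod("show", "FixtureBundle", function(object) {
  cat("FixtureBundle '", object@kind, "' (seed ", object@seed, "): ",
      length(object@structures), " structure(s), ground truth keys: ",
      paste(names(object@groundTruth), collapse = ", "), "\n", sep = "")
})

setMethod("show", "VariantReport", function(object) {
  v <- object@variant
  cat("VariantReport ", v$label, " (chain ", v$chain_id, ", residue ",
      v$residue_number, ")\n", sep = "")
  cat("  motif role: ", object@motifContext$variant_role, "\n", sep = "")
  cat("  clashes at variant residue: ", nrow(object@clashSummary),
      "\n", sep = "")
  cat("  interactions gained/lost: ",
      nrow(object@interactionDiff$gained), "/",
      nrow(object@interactionDiff$lost), "\n", sep = "")
})
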