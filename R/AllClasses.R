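## Central S4 classes. Atom tables are plain data.frames with a fixed set of
## columns (see .ATOM_COLS); the classes wrap them with validity checks so
## every downstream operation can rely on the invariants.

.ATOM_COLS <- c("serial", "name", "altloc", "resid", "chain", "resno",
                "insert", "x", "y", "z", "occ", "b", "elem", "het")

.MOTIF_ROLES <- c("G1", "x1", "x2", "x3", "x4", "G2", "K", "TS")

#' ProteinStructure: an atomic coordinate model
#'
#' Wraps a data.frame of atoms (one row per atom) with author numbering
#' preserved verbatim. Columns: \code{serial}, \code{name}, \code{altloc},
#' \code{resid} (3-letter residue code), \code{chain}, \code{resno},
#' \code{insert}, \code{x}, \code{y}, \code{z} (Angstrom), \code{occ},
#' \code{b}, \code{elem} (element symbol), \code{het} (logical, HETATM).
#'
#' @slot atoms data.frame of atoms in file order
#' @slot modelId character identifier
#' @slot metadata free-form list
#' @exportClass ProteinStructure
setClass("ProteinStructure",
         representation(atoms = "data.frame", modelId = "character",
                        metadata = "list"),
         prototype(modelId = "model", metadata = list()))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  missing_cols <- setdiff(.ATOM_COLS, names(a))
  if (length(missing_cols))
    return(paste("atom table lacks columns:",
                 paste(missing_cols, collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
      return("non-finite atom coordinates")
    if (any(is.na(a$elem) | a$elem == ""))
      return("empty element symbol")
    key <- paste(a$chain, a$resno, a$insert, a$name)
    if (anyDuplicated(key))
      return(paste("duplicate atom identifier:",
                   key[duplicated(key)][1L]))
  }
  TRUE
})

#' Construct a ProteinStructure
#'
#' @param atoms data.frame with at least \code{name}, \code{resid},
#'   \code{chain}, \code{resno}, \code{x}, \code{y}, \code{z}; remaining
#'   columns are filled with defaults (serial = row index, occupancy 1,
#'   B-factor 0, element inferred from the atom name, \code{het} from the
#'   residue code).
#' @param modelId character identifier carried into reports
#' @param metadata free-form list
#' @return a validated \code{ProteinStructure}
#' @export
proteinStructure <- function(atoms, modelId = "model", metadata = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$altloc)) atoms$altloc <- rep("", n)
  if (is.null(atoms$insert)) atoms$insert <- rep("", n)
  if (is.null(atoms$occ)) atoms$occ <- rep(1, n)
  if (is.null(atoms$b)) atoms$b <- rep(0, n)
  if (is.null(atoms$elem)) atoms$elem <- guessElement(atoms$name)
  if (is.null(atoms$het)) atoms$het <- !(atoms$resid %in% names(.AA3TO1))
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$resno <- as.integer(atoms$resno)
  atoms <- atoms[, .ATOM_COLS]
  rownames(atoms) <- NULL
  new("ProteinStructure", atoms = atoms, modelId = modelId,
      metadata = metadata)
}

#' MotifHit: a located Walker A motif instance
#'
#' @slot chain chain identifier
#' @slot resno integer(8) author residue numbers, aligned with \code{roles}
#' @slot roles character(8), always G1, x1..x4, G2, K, TS
#' @slot sequence the 8-letter matched sequence
#' @exportClass MotifHit
setClass("MotifHit",
         representation(chain = "character", resno = "integer",
                        roles = "character", sequence = "character"))

setValidity("MotifHit", function(object) {
  if (length(object@resno) != 8L) return("resno must have length 8")
  if (!identical(object@roles, .MOTIF_ROLES)) return("roles must be G1,x1..x4,G2,K,TS")
  if (!grepl("^G.{4}GK[TS]$", object@sequence)) return("sequence does not match G-x4-G-K-[TS]")
  TRUE
})

#' SuperpositionResult: an optimal rigid-body fit
#'
#' Transform convention: \code{y = rotation \%*\% x + translation} maps
#' mobile coordinates onto the reference frame.
#'
#' @slot rotation 3x3 proper rotation matrix
#' @slot translation numeric(3), Angstrom
#' @slot rmsd root-mean-square deviation over the fitted atoms, Angstrom
#' @slot nAtoms number of paired atoms used in the fit
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
         representation(rotation = "matrix", translation = "numeric",
                        rmsd = "numeric", nAtoms = "integer"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (abs(det(R) - 1) > 1e-6) return("rotation must be proper (det = +1)")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6) return("rotation not orthonormal")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})

#' DisplacementProfile: per-atom displacements after superposition
#'
#' @slot entries data.frame with columns chain, resno, name, displacement
#' @slot selectionLabel human-readable description of the reported atoms
#' @slot superposition the \code{SuperpositionResult} used for the fit
#' @exportClass DisplacementProfile
setClass("DisplacementProfile",
         representation(entries = "data.frame", selectionLabel = "character",
                        superposition = "SuperpositionResult"))

setValidity("DisplacementProfile", function(object) {
  e <- object@entries
  need <- c("chain", "resno", "name", "displacement")
  if (!all(need %in% names(e))) return("entries lacks required columns")
  if (nrow(e) && any(e$displacement < 0)) return("displacements must be >= 0")
  TRUE
})

#' GridSpec: a cubic finite-difference lattice
#'
#' @slot spacing grid spacing, Angstrom
#' @slot extent integer(3), points per axis
#' @slot center numeric(3), grid center, Angstrom
#' @exportClass GridSpec
setClass("GridSpec",
         representation(spacing = "numeric", extent = "integer",
                        center = "numeric"))

setValidity("GridSpec", function(object) {
  if (object@spacing <= 0) return("spacing must be > 0")
  if (length(object@extent) != 3L || any(object@extent < 33L))
    return("extent must be three integers >= 33")
  if (length(object@center) != 3L) return("center must be length 3")
  TRUE
})

#' Construct a GridSpec
#' @param spacing grid spacing (Angstrom)
#' @param extent points per axis (recycled to length 3); minimum 33
#' @param center grid center (Angstrom)
#' @return a \code{GridSpec}
#' @export
gridSpec <- function(spacing, extent, center = c(0, 0, 0)) {
  new("GridSpec", spacing = spacing,
      extent = as.integer(rep(extent, length.out = 3L)),
      center = as.numeric(center))
}

#' ContinuumModel: dielectric and ionic conditions
#'
#' Defaults follow common practice for protein continuum electrostatics:
#' protein interior dielectric 4, water 80, 0.1 M ionic strength, 300 K.
#'
#' @slot epsProtein protein interior dielectric constant
#' @slot epsSolvent solvent dielectric constant
#' @slot ionicStrength mol/L
#' @slot temperature Kelvin
#' @slot ionExclusionRadius Stern-layer thickness added to atomic radii (A)
#' @slot solventProbeRadius probe radius (A); 0 = plain vdW-union volume
#' @exportClass ContinuumModel
setClass("ContinuumModel",
         representation(epsProtein = "numeric", epsSolvent = "numeric",
                        ionicStrength = "numeric", temperature = "numeric",
                        ionExclusionRadius = "numeric",
                        solventProbeRadius = "numeric"))

setValidity("ContinuumModel", function(object) {
  if (object@epsProtein <= 0 || object@epsSolvent <= 0)
    return("dielectric constants must be > 0")
  if (object@ionicStrength < 0) return("ionic strength must be >= 0")
  if (object@temperature <= 0) return("temperature must be > 0")
  TRUE
})

#' Construct a ContinuumModel
#' @param epsProtein protein interior dielectric (default 4)
#' @param epsSolvent solvent dielectric (default 80)
#' @param ionicStrength mol/L (default 0.1)
#' @param temperature Kelvin (default 300)
#' @param ionExclusionRadius ion-exclusion (Stern) layer, Angstrom
#' @param solventProbeRadius solvent probe radius, Angstrom (default 0:
#'   molecular volume is the union of atomic vdW spheres)
#' @return a \code{ContinuumModel}
#' @export
continuumModel <- function(epsProtein = 4, epsSolvent = 80,
                           ionicStrength = 0.1, temperature = 300,
                           ionExclusionRadius = 2.0,
                           solventProbeRadius = 0) {
  new("ContinuumModel", epsProtein = epsProtein, epsSolvent = epsSolvent,
      ionicStrength = ionicStrength, temperature = temperature,
      ionExclusionRadius = ionExclusionRadius,
      solventProbeRadius = solventProbeRadius)
}

#' PBSolution: a finite-difference Poisson-Boltzmann potential
#'
#' @slot potential 3-D array, kcal/mol/e, dimensions = grid extent
#' @slot grid the \code{GridSpec} the potential lives on
#' @slot converged logical
#' @slot iterations SOR sweeps performed
#' @slot residual final relative residual
#' @exportClass PBSolution
setClass("PBSolution",
         representation(potential = "array", grid = "GridSpec",
                        converged = "logical", iterations = "integer",
                        residual = "numeric"))

#' SiteEnergies: intrinsic shifts and the site-site interaction matrix
#'
#' @slot sites data.frame: siteId, kind, pkaRef, pkaIntr, qProt, qDeprot
#' @slot deltaGIntr per-site charging free-energy shift, kcal/mol
#' @slot wMatrix symmetric site-by-site interaction energies between unit
#'   charge distributions, kcal/mol, zero diagonal
#' @exportClass SiteEnergies
setClass("SiteEnergies",
         representation(sites = "data.frame", deltaGIntr = "numeric",
                        wMatrix = "matrix"))

setValidity("SiteEnergies", function(object) {
  W <- object@wMatrix
  n <- nrow(object@sites)
  if (!all(dim(W) == c(n, n))) return("wMatrix dimension mismatch")
  if (n && max(abs(diag(W))) > 1e-9) return("wMatrix diagonal must be zero")
  if (n && max(abs(W - t(W))) > 0.05 * max(abs(W), 1e-12) + 1e-9)
    return("wMatrix not symmetric within 5% reciprocity tolerance")
  TRUE
})

#' TitrationSystem: coupled titratable sites under given conditions
#'
#' @slot sites data.frame: siteId, kind ("acid"/"base"), pkaRef, pkaIntr,
#'   qProt, qDeprot (formal charges of the two states; qProt - qDeprot = +1)
#' @slot wMatrix symmetric n x n site-site interaction energies (kcal/mol)
#'   between unit charge distributions, zero diagonal
#' @slot conditions list(pH, temperature, ionicStrength)
#' @slot statePenalties data.frame(i, j, xi, xj, energy): extra energy added
#'   when sites i and j are in protonation states (xi, xj); used for the
#'   histidine two-site model to exclude the imidazolate microstate
#' @exportClass TitrationSystem
setClass("TitrationSystem",
         representation(sites = "data.frame", wMatrix = "matrix",
                        conditions = "list", statePenalties = "data.frame"),
         prototype(statePenalties = data.frame(i = integer(), j = integer(),
                                               xi = integer(), xj = integer(),
                                               energy = numeric())))

setValidity("TitrationSystem", function(object) {
  s <- object@sites
  n <- nrow(s)
  if (n < 1L) return("at least one site required")
  need <- c("siteId", "kind", "pkaIntr", "qProt", "qDeprot")
  if (!all(need %in% names(s))) return("sites lacks required columns")
  if (any(abs((s$qProt - s$qDeprot) - 1) > 1e-9))
    return("qProt - qDeprot must equal +1 for every site")
  if (any(!is.finite(s$pkaIntr))) return("pkaIntr must be finite")
  W <- object@wMatrix
  if (!all(dim(W) == c(n, n))) return("wMatrix dimension mismatch")
  if (max(abs(diag(W))) > 1e-9) return("wMatrix diagonal must be zero")
  if (max(abs(W - t(W))) > 1e-9) return("wMatrix must be symmetric")
  cond <- object@conditions
  if (!all(c("pH", "temperature") %in% names(cond)))
    return("conditions must include pH and temperature")
  TRUE
})

#' Construct a TitrationSystem
#'
#' @param sites data.frame with columns \code{siteId}, \code{kind}
#'   ("acid" or "base"), \code{pkaIntr} (intrinsic pKa), and optionally
#'   \code{pkaRef}, \code{qProt}, \code{qDeprot} (defaults: acid 0/-1,
#'   base +1/0)
#' @param wMatrix symmetric interaction matrix, kcal/mol (default: all zero)
#' @param pH,temperature,ionicStrength conditions (defaults 7.0, 300 K, 0.1 M)
#' @param statePenalties optional data.frame(i, j, xi, xj, energy)
#' @return a \code{TitrationSystem}
#' @export
titrationSystem <- function(sites, wMatrix = NULL, pH = 7.0,
                            temperature = 300, ionicStrength = 0.1,
                            statePenalties = NULL) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  n <- nrow(sites)
  if (is.null(sites$siteId)) sites$siteId <- paste0("site", seq_len(n))
  if (is.null(sites$pkaRef)) sites$pkaRef <- sites$pkaIntr
  if (is.null(sites$pkaIntr)) sites$pkaIntr <- sites$pkaRef
  if (is.null(sites$qProt))
    sites$qProt <- ifelse(sites$kind == "acid", 0, 1)
  if (is.null(sites$qDeprot))
    sites$qDeprot <- ifelse(sites$kind == "acid", -1, 0)
  if (is.null(wMatrix)) wMatrix <- matrix(0, n, n)
  if (is.null(statePenalties))
    statePenalties <- data.frame(i = integer(), j = integer(),
                                 xi = integer(), xj = integer(),
                                 energy = numeric())
  new("TitrationSystem", sites = sites, wMatrix = as.matrix(wMatrix),
      conditions = list(pH = pH, temperature = temperature,
                        ionicStrength = ionicStrength),
      statePenalties = statePenalties)
}

#' ProtonationResult: equilibrium protonation probabilities
#'
#' @slot probabilities named numeric, one <x_i> in [0,1] per site
#' @slot method "exact" or "mc"
#' @slot mcError per-site standard error (Monte Carlo only; length 0 for
#'   exact enumeration)
#' @slot seed RNG seed (Monte Carlo only; NA for exact)
#' @exportClass ProtonationResult
setClass("ProtonationResult",
         representation(probabilities = "numeric", method = "character",
                        mcError = "numeric", seed = "integer"),
         prototype(mcError = numeric(), seed = NA_integer_))

setValidity("ProtonationResult", function(object) {
  p <- object@probabilities
  if (length(p) && (min(p) < -1e-12 || max(p) > 1 + 1e-12))
    return("probabilities must lie in [0,1]")
  if (!object@method %in% c("exact", "mc")) return("method must be exact or mc")
  if (object@method == "exact" && length(object@mcError))
    return("exact method must not carry mcError")
  TRUE
})

#' FixtureBundle: a synthetic structure (pair) with ground truth
#'
#' @slot kind fixture kind
#' @slot structures list of \code{ProteinStructure} (or numeric inputs for
#'   the non-structural kinds)
#' @slot groundTruth key/value list of expected quantities, computed by
#'   independent in-module oracles at generation time
#' @slot seed integer seed that reproduces the bundle bit-for-bit
#' @exportClass FixtureBundle
setClass("FixtureBundle",
         representation(kind = "character", structures = "list",
                        groundTruth = "list", seed = "integer"))

#' VariantReport: aggregated structural-impact report
#'
#' @slot variant list(chain_id, residue_number, from_aa, to_aa, label)
#' @slot motifContext list: hits and the variant's role
#' @slot clashSummary data.frame of mutant clashes at the variant residue
#' @slot rotamerSummary list: best/worst rotamer clash scores
#' @slot displacement list: fit RMSD, per-residue profile, named-atom shifts
#' @slot interactionDiff list(gained, lost) interaction tables
#' @slot protonation list or empty: pattern deviations for WT and mutant
#' @slot provenance list: config, seed, package version, stage log
#' @exportClass VariantReport
setClass("VariantReport",
         representation(variant = "list", motifContext = "list",
                        clashSummary = "data.frame", rotamerSummary = "list",
                        displacement = "list", interactionDiff = "list",
                        protonation = "list", provenance = "list"))
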