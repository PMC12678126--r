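## Steric-clash detection. A clash is a non-bonded heavy-atom pair whose
## distance falls short of the sum of van der Waals radii by more than a
## tolerance (default 0.4 A). Pairs connected by a short covalent path
## (<= 3 bonds, peptide links included) are excluded: bonded 1-2/1-3/1-4
## geometry is governed by covalent terms, not vdW contact.

.COV_RADII <- c(H = 0.32, C = 0.77, N = 0.70, O = 0.66, S = 1.04, P = 1.10,
                F = 0.64, CL = 0.99, BR = 1.14, I = 1.33, SE = 1.17,
                FE = 1.25, MG = 1.30, ZN = 1.25, MN = 1.35, "NA" = 1.54,
                K = 1.96, CA = 1.74)

# adjacency list of covalent bonds among the given atom rows.
# Bonds are inferred by distance (d <= rc_i + rc_j + 0.45) but only within
# one residue, plus the explicit backbone links between consecutive
# residues (peptide C-N, nucleotide O3'-P). Atoms of unrelated residues are
# never considered bonded, however close -- that is precisely the clash
# signal.
.bondAdjacency <- function(a) {
  n <- nrow(a)
  if (n < 2L) return(vector("list", n))
  rc <- .COV_RADII[toupper(a$elem)]
  rc[is.na(rc)] <- 0.77
  xyz <- as.matrix(a[, c("x", "y", "z")])
  adj <- vector("list", n)
  sameRes <- function(i, j) a$chain[i] == a$chain[j] &
    a$resno[i] == a$resno[j] & a$insert[i] == a$insert[j]
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    d <- sqrt(colSums((t(xyz[j, , drop = FALSE]) - xyz[i, ])^2))
    near <- d <= rc[i] + rc[j] + 0.45 & d > 0.4
    intra <- sameRes(rep.int(i, length(j)), j)
    linked <- a$chain[i] == a$chain[j] & abs(a$resno[i] - a$resno[j]) == 1L &
      ((a$name[i] == "C" & a$name[j] == "N") |
         (a$name[i] == "N" & a$name[j] == "C") |
         (a$name[i] == "O3'" & a$name[j] == "P") |
         (a$name[i] == "P" & a$name[j] == "O3'"))
    hit <- j[near & (intra | (linked & d <= 2.0))]
    if (length(hit)) {
      adj[[i]] <- c(adj[[i]], hit)
      for (h in hit) adj[[h]] <- c(adj[[h]], i)
    }
  }
  adj
}

# TRUE if a covalent path of length <= maxDepth links i and j
.bondPathLeq <- function(adj, i, j, maxDepth = 3L) {
  if (i == j) return(TRUE)
  frontier <- i
  seen <- i
  for (depth in seq_len(maxDepth)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- setdiff(nxt, seen)
    if (!length(nxt)) return(FALSE)
    if (j %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

#' Detect steric clashes
#'
#' Finds all non-bonded heavy-atom pairs with at least one atom in the
#' focus selection whose vdW overlap (radius sum minus distance) exceeds
#' the tolerance. Pairs joined by a covalent path of three bonds or fewer
#' (bonds inferred from covalent radii, peptide links included) are not
#' reported. Results are sorted by descending overlap.
#'
#' @param x a \code{ProteinStructure}
#' @param focus selection predicate; default considers every atom pair
#' @param tolerance overlap threshold, Angstrom (default 0.4)
#' @param radii named vdW radius table keyed by element (default
#'   \code{\link{defaultRadii}})
#' @return data.frame with one row per clash: atom_a, atom_b (identifier
#'   strings chain:resid resno:name), chain/resno/name/resid columns for
#'   both atoms, distance, vdw_sum, overlap (all Angstrom)
#' @examples
#' fx <- makeFixture("crowded_pocket", seed = 1)
#' head(findClashes(structures(fx)[[1]],
#'                  focus = selectResidues(groundTruth(fx)$arg_resno)))
#' @export
findClashes <- function(x, focus = selectAll(), tolerance = 0.4,
                        radii = defaultRadii()) {
  stopifnot(is(x, "ProteinStructure"))
  a <- atoms(x)
  a <- a[toupper(a$elem) != "H", , drop = FALSE]
  missing <- setdiff(unique(toupper(a$elem)), names(radii))
  if (length(missing))
    stop("radius table lacks element(s): ", paste(missing, collapse = ", "))
  n <- nrow(a)
  empty <- data.frame(atom_a = character(), atom_b = character(),
                      chain_a = character(), resno_a = integer(),
                      name_a = character(), resid_a = character(),
                      chain_b = character(), resno_b = integer(),
                      name_b = character(), resid_b = character(),
                      distance = numeric(), vdw_sum = numeric(),
                      overlap = numeric(), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  inFocus <- focus(a)
  if (!any(inFocus)) return(empty)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rv <- .radiusFor(a$elem, radii)
  fIdx <- which(inFocus)
  # candidate pairs: focus atom vs any atom, within vdw_sum - tolerance
  cand_i <- integer(); cand_j <- integer(); cand_d <- numeric()
  for (i in fIdx) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    lim <- rv[i] + rv - tolerance
    hit <- which(d < lim & d > 0 & seq_len(n) != i)
    if (length(hit)) {
      cand_i <- c(cand_i, rep.int(i, length(hit)))
      cand_j <- c(cand_j, hit)
      cand_d <- c(cand_d, d[hit])
    }
  }
  if (!length(cand_i)) return(empty)
  # dedupe unordered pairs
  lo <- pmin(cand_i, cand_j); hi <- pmax(cand_i, cand_j)
  keep <- !duplicated(paste(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]; cand_d <- cand_d[keep]
  # covalent-path exclusion on the local neighbourhood of the candidates
  local <- sort(unique(c(lo, hi)))
  near <- rep(FALSE, n)
  for (i in local)
    near <- near | sqrt(colSums((t(xyz) - xyz[i, ])^2)) < 5.5
  region <- which(near)
  adj <- .bondAdjacency(a[region, , drop = FALSE])
  rmap <- match(seq_len(n), region)
  bonded <- vapply(seq_along(lo), function(k) {
    .bondPathLeq(adj, rmap[lo[k]], rmap[hi[k]], 3L)
  }, logical(1L))
  lo <- lo[!bonded]; hi <- hi[!bonded]; cand_d <- cand_d[!bonded]
  if (!length(lo)) return(empty)
  # canonical pair order (independent of input atom order)
  keyOf <- function(i) paste(a$chain[i], sprintf("%08d", a$resno[i]),
                             a$insert[i], a$name[i])
  swap <- keyOf(lo) > keyOf(hi)
  tmp <- lo[swap]; lo[swap] <- hi[swap]; hi[swap] <- tmp
  vsum <- rv[lo] + rv[hi]
  out <- data.frame(
    atom_a = paste0(a$chain[lo], ":", a$resid[lo], a$resno[lo], ":", a$name[lo]),
    atom_b = paste0(a$chain[hi], ":", a$resid[hi], a$resno[hi], ":", a$name[hi]),
    chain_a = a$chain[lo], resno_a = a$resno[lo], name_a = a$name[lo],
    resid_a = a$resid[lo],
    chain_b = a$chain[hi], resno_b = a$resno[hi], name_b = a$name[hi],
    resid_b = a$resid[hi],
    distance = cand_d, vdw_sum = vsum, overlap = vsum - cand_d,
    stringsAsFactors = FALSE)
  out <- out[order(-out$overlap), , drop = FALSE]
  rownames(out) <- NULL
  out
}
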