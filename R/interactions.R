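## Polar-interaction inventory. Hydrogen bonds and salt bridges are detected
## from donor/acceptor heavy-atom distances only (hydrogens may be absent
## from the models, so no angular term is applied). Each contact is assigned
## a charge class at pH-7 formal charges and the corresponding energy scale:
## ~1 kcal/mol between uncharged polar groups, ~2 kcal/mol between a charged
## and an uncharged group, and ~4 kcal/mol between two charged groups.

.ENERGY_SCALE <- c("uncharged-uncharged" = 1, "charged-uncharged" = 2,
                   "charged-charged" = 4)

# per-atom donor/acceptor/charge typing; untyped residues dropped with warning
.typeAtoms <- function(a, table = polarAtomTable()) {
  std <- a$resid %in% names(.AA3TO1)
  known <- std | a$resid %in% names(table$residues)
  if (any(!known)) {
    skip <- unique(a$resid[!known])
    warning("untyped residue(s) skipped in interaction detection: ",
            paste(skip, collapse = ", "))
  }
  a <- a[known, , drop = FALSE]
  n <- nrow(a)
  donor <- acceptor <- logical(n)
  qsign <- integer(n)
  bb <- table$backbone
  donor[std[known] & a$name %in% bb$donors] <- TRUE
  acceptor[std[known] & a$name %in% bb$acceptors] <- TRUE
  qsign[std[known] & a$name %in% bb$charged_negative] <- -1L
  for (res in intersect(unique(a$resid), names(table$residues))) {
    e <- table$residues[[res]]
    sel <- a$resid == res
    donor[sel & a$name %in% unlist(e$donors)] <- TRUE
    acceptor[sel & a$name %in% unlist(e$acceptors)] <- TRUE
    qsign[sel & a$name %in% unlist(e$charged_positive)] <- 1L
    qsign[sel & a$name %in% unlist(e$charged_negative)] <- -1L
  }
  # N-terminal amine of each chain is positively charged
  for (ch in unique(a$chain[std[known]])) {
    sel <- a$chain == ch & std[known]
    if (!any(sel)) next
    firstRes <- min(a$resno[sel])
    qsign[sel & a$resno == firstRes & a$name == "N"] <- 1L
  }
  a$donor <- donor; a$acceptor <- acceptor; a$qsign <- qsign
  a
}

#' Inventory hydrogen bonds and salt bridges
#'
#' Every donor/acceptor heavy-atom pair within the distance cutoff becomes
#' one record (salt bridges, i.e. charged-charged pairs, are accepted up to
#' \code{saltBridgeCutoff}). Pairs within the same residue or joined by a
#' covalent path of three bonds or fewer are excluded. When region
#' annotations are supplied, contacts whose two atoms fall in different
#' annotated regions are flagged inter-region.
#'
#' @param x a \code{ProteinStructure}
#' @param regions optional region annotation data.frame (label, chain,
#'   start, end), see \code{\link{regionTable}}
#' @param distanceCutoff donor-acceptor heavy-atom cutoff for hydrogen
#'   bonds, Angstrom (default 3.5)
#' @param saltBridgeCutoff cutoff for charged-charged pairs (default 4.0)
#' @param table donor/acceptor typing table (default
#'   \code{\link{polarAtomTable}})
#' @return data.frame with one row per contact: donor_atom, acceptor_atom
#'   identifiers, their chain/resno/name/resid, distance, charge_class,
#'   energy_scale (kcal/mol, 1/2/4), kind ("h-bond"/"salt-bridge"),
#'   region_donor, region_acceptor, inter_region
#' @export
findPolarInteractions <- function(x, regions = NULL, distanceCutoff = 3.5,
                                  saltBridgeCutoff = 4.0,
                                  table = polarAtomTable()) {
  stopifnot(is(x, "ProteinStructure"))
  a <- atoms(x)
  a <- a[toupper(a$elem) != "H", , drop = FALSE]
  a <- .typeAtoms(a, table)
  empty <- data.frame(donor_atom = character(), acceptor_atom = character(),
                      chain_d = character(), resno_d = integer(),
                      name_d = character(), resid_d = character(),
                      chain_a = character(), resno_a = integer(),
                      name_a = character(), resid_a = character(),
                      distance = numeric(), charge_class = character(),
                      energy_scale = numeric(), kind = character(),
                      region_donor = character(),
                      region_acceptor = character(),
                      inter_region = logical(), stringsAsFactors = FALSE)
  di <- which(a$donor); ai <- which(a$acceptor)
  if (!length(di) || !length(ai)) return(empty)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  maxCut <- max(distanceCutoff, saltBridgeCutoff)
  pd <- integer(); pa <- integer(); dd <- numeric()
  for (i in di) {
    d <- sqrt(colSums((t(xyz[ai, , drop = FALSE]) - xyz[i, ])^2))
    hit <- which(d <= maxCut & ai != i)
    # different residues only
    hit <- hit[!(a$chain[ai[hit]] == a$chain[i] &
                   a$resno[ai[hit]] == a$resno[i] &
                   a$insert[ai[hit]] == a$insert[i])]
    if (length(hit)) {
      pd <- c(pd, rep.int(i, length(hit)))
      pa <- c(pa, ai[hit]); dd <- c(dd, d[hit])
    }
  }
  if (!length(pd)) return(empty)
  # covalent-path exclusion (<= 3 bonds), e.g. backbone O(i)..N(i+1)
  local <- sort(unique(c(pd, pa)))
  near <- rep(FALSE, nrow(a))
  for (i in local)
    near <- near | sqrt(colSums((t(xyz) - xyz[i, ])^2)) < 5.5
  region <- which(near)
  adj <- .bondAdjacency(a[region, , drop = FALSE])
  rmap <- match(seq_len(nrow(a)), region)
  bonded <- vapply(seq_along(pd), function(k)
    .bondPathLeq(adj, rmap[pd[k]], rmap[pa[k]], 3L), logical(1L))
  pd <- pd[!bonded]; pa <- pa[!bonded]; dd <- dd[!bonded]
  if (!length(pd)) return(empty)
  charged <- a$qsign[pd] > 0L & a$qsign[pa] < 0L
  nCharged <- (a$qsign[pd] != 0L) + (a$qsign[pa] != 0L)
  cls <- ifelse(charged, "charged-charged",
                ifelse(nCharged >= 1L, "charged-uncharged",
                       "uncharged-uncharged"))
  keep <- (cls == "charged-charged" & dd <= saltBridgeCutoff) |
    (dd <= distanceCutoff)
  pd <- pd[keep]; pa <- pa[keep]; dd <- dd[keep]; cls <- cls[keep]
  if (!length(pd)) return(empty)
  regD <- .regionOf(regions, a$chain[pd], a$resno[pd])
  regA <- .regionOf(regions, a$chain[pa], a$resno[pa])
  out <- data.frame(
    donor_atom = paste0(a$chain[pd], ":", a$resid[pd], a$resno[pd], ":",
                        a$name[pd]),
    acceptor_atom = paste0(a$chain[pa], ":", a$resid[pa], a$resno[pa], ":",
                           a$name[pa]),
    chain_d = a$chain[pd], resno_d = a$resno[pd], name_d = a$name[pd],
    resid_d = a$resid[pd],
    chain_a = a$chain[pa], resno_a = a$resno[pa], name_a = a$name[pa],
    resid_a = a$resid[pa],
    distance = dd, charge_class = cls,
    energy_scale = unname(.ENERGY_SCALE[cls]),
    kind = ifelse(cls == "charged-charged", "salt-bridge", "h-bond"),
    region_donor = regD, region_acceptor = regA,
    inter_region = !is.na(regD) & !is.na(regA) & regD != regA,
    stringsAsFactors = FALSE)
  out <- out[order(out$chain_d, out$resno_d, out$name_d, out$resno_a), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gained and lost interactions between two inventories
#'
#' Set difference keyed on (donor chain/residue number/atom, acceptor
#' chain/residue number/atom). Residue names are deliberately excluded from
#' the key so a mutated residue is matched by its number.
#'
#' @param wt interaction table of the wild type
#'   (\code{\link{findPolarInteractions}} output)
#' @param mut interaction table of the mutant
#' @return list with data.frames \code{gained} (in mut, not wt) and
#'   \code{lost} (in wt, not mut)
#' @export
diffInteractions <- function(wt, mut) {
  keyOf <- function(d) paste(d$chain_d, d$resno_d, d$name_d,
                             d$chain_a, d$resno_a, d$name_a, sep = "|")
  kw <- keyOf(wt); km <- keyOf(mut)
  gained <- mut[!(km %in% kw), , drop = FALSE]
  lost <- wt[!(kw %in% km), , drop = FALSE]
  rownames(gained) <- rownames(lost) <- NULL
  list(gained = gained, lost = lost)
}
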