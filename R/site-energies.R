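## Intrinsic pKa shifts and the site-site interaction matrix from continuum
## electrostatics. For every titratable site the standard two-environment
## thermodynamic cycle is evaluated: the charging free energy of the site in
## the protein (with every other titratable site in its neutral, zero-charge
## state, plus fixed background charges) minus the same charging free energy
## in the isolated model compound (the site's own residue, in its in-situ
## conformation, alone in solvent). Identical grids are used in the two
## environments so the grid self-energy cancels exactly. W is the
## interaction energy between unit charge-difference distributions of two
## sites in the protein environment, symmetrised by averaging the two
## one-sided estimates.

#' Define titratable sites present in a structure
#'
#' Scans the structure for titratable residues (Asp, Glu, Lys, Arg, Cys,
#' Tyr, His) with their required side-chain atoms present and builds site
#' definitions from the bundled library (\code{\link{siteDefinitions}}):
#' reference pKa, per-state atomic charges, and the histidine two-site
#' model (N-epsilon pKa 7.0, N-delta 6.6, half charges, imidazolate
#' penalty).
#'
#' @param x a \code{ProteinStructure}
#' @param residues optional data.frame(chain, resno) restricting which
#'   residues become sites (default: all titratable residues)
#' @return list of site definitions; each has siteId, chain, resno, resid,
#'   kind, pkaRef, qProt, qDeprot, atoms (data.frame name/qProt/qDeprot)
#'   and hisGroup (NA except for the paired His sites)
#' @export
defaultTitratableSites <- function(x, residues = NULL) {
  defs <- siteDefinitions()$sites
  a <- atoms(x)
  a <- a[!a$het | a$resid %in% names(.AA3TO1), , drop = FALSE]
  resKey <- paste(a$chain, a$resno, a$insert)
  first <- !duplicated(resKey)
  rl <- a[first, c("chain", "resno", "insert", "resid"), drop = FALSE]
  if (!is.null(residues))
    rl <- rl[paste(rl$chain, rl$resno) %in%
               paste(residues$chain, residues$resno), , drop = FALSE]
  sites <- list()
  for (k in seq_len(nrow(rl))) {
    resid <- rl$resid[k]
    keys <- if (resid == "HIS") c("HIS_NE2", "HIS_ND1")
            else if (resid %in% names(defs)) resid else character()
    for (key in keys) {
      d <- defs[[key]]
      atomNames <- union(names(d$atoms_prot), names(d$atoms_deprot))
      present <- a$chain == rl$chain[k] & a$resno == rl$resno[k] &
        a$insert == rl$insert[k]
      if (!all(atomNames %in% a$name[present])) {
        warning("site skipped (missing atoms): ", resid, rl$resno[k])
        next
      }
      qp <- sapply(atomNames, function(nm)
        if (!is.null(d$atoms_prot[[nm]])) d$atoms_prot[[nm]] else 0)
      qd <- sapply(atomNames, function(nm)
        if (!is.null(d$atoms_deprot[[nm]])) d$atoms_deprot[[nm]] else 0)
      sites[[length(sites) + 1L]] <- list(
        siteId = paste0(resid, "-", rl$resno[k], "-", rl$chain[k],
                        if (resid == "HIS") paste0("-", sub("HIS_", "", key))
                        else ""),
        chain = rl$chain[k], resno = rl$resno[k], resid = resid,
        kind = d$kind, pkaRef = d$pka_ref,
        qProt = d$q_prot, qDeprot = d$q_deprot,
        atoms = data.frame(name = atomNames, qProt = unname(qp),
                           qDeprot = unname(qd), stringsAsFactors = FALSE),
        hisGroup = if (resid == "HIS")
          paste0("HIS-", rl$resno[k], "-", rl$chain[k]) else NA_character_)
    }
  }
  sites
}

# charge data.frame (x,y,z,q) for one site in a given state
.siteCharges <- function(x, site, state = c("prot", "deprot")) {
  state <- match.arg(state)
  a <- atoms(x)
  col <- if (state == "prot") "qProt" else "qDeprot"
  sel <- a$chain == site$chain & a$resno == site$resno &
    a$name %in% site$atoms$name
  sub <- a[sel, , drop = FALSE]
  q <- site$atoms[[col]][match(sub$name, site$atoms$name)]
  data.frame(x = sub$x, y = sub$y, z = sub$z, q = q)
}

# fixed background charges: bundled formal charges on atoms that do not
# belong to any titratable site
.backgroundCharges <- function(x, sites) {
  bg <- siteDefinitions()$background_charges
  a <- atoms(x)
  siteAtomKey <- unlist(lapply(sites, function(s)
    paste(s$chain, s$resno, s$atoms$name)))
  q <- numeric(nrow(a))
  for (res in intersect(unique(a$resid), names(bg))) {
    tab <- bg[[res]]
    sel <- a$resid == res & a$name %in% names(tab)
    q[sel] <- unlist(tab)[a$name[sel]]
  }
  q[paste(a$chain, a$resno, a$name) %in% siteAtomKey] <- 0
  keep <- q != 0
  data.frame(x = a$x[keep], y = a$y[keep], z = a$z[keep], q = q[keep])
}

# structure containing only the residue of one site (model compound)
.modelCompound <- function(x, site) {
  a <- atoms(x)
  sel <- a$chain == site$chain & a$resno == site$resno
  proteinStructure(a[sel, , drop = FALSE], modelId = "model-compound")
}

#' Compute intrinsic pKa shifts and the interaction matrix
#'
#' Runs the two-environment charging cycle for every site and evaluates the
#' pairwise interaction matrix W (kcal/mol between unit charge-difference
#' distributions) in the protein environment. All solves for one structure
#' share the same focused grids, so grid self-energies cancel between the
#' protein and model-compound environments.
#'
#' @param x a \code{ProteinStructure}
#' @param sites list of site definitions
#'   (\code{\link{defaultTitratableSites}})
#' @param model a \code{ContinuumModel}
#' @param levels focusing spacings (default c(2.5, 1.0, 0.3))
#' @param tolerance,maxIter solver controls
#' @param radii vdW radius table
#' @return a \code{\link{SiteEnergies}}; \code{deltaGIntr} holds the
#'   protonation free-energy shift (kcal/mol, protein minus model
#'   compound), and the site table carries pkaIntr = pkaRef -
#'   deltaGIntr / (ln 10 kT)
#' @export
computeSiteEnergies <- function(x, sites, model = continuumModel(),
                                levels = c(2.5, 1.0, 0.3),
                                tolerance = 1e-6, maxIter = 20000L,
                                radii = defaultRadii()) {
  nS <- length(sites)
  if (!nS) stop("no titratable sites")
  # common focus region: all site atoms + 8 A
  siteXYZ <- do.call(rbind, lapply(sites, function(s)
    as.matrix(.siteCharges(x, s, "prot")[, 1:3, drop = FALSE])))
  allXYZ <- do.call(rbind, lapply(sites, function(s) {
    a <- atoms(x)
    sel <- a$chain == s$chain & a$resno == s$resno & a$name %in% s$atoms$name
    as.matrix(a[sel, c("x", "y", "z")])
  }))
  focusBBox <- rbind(apply(allXYZ, 2L, min) - 8, apply(allXYZ, 2L, max) + 8)
  bg <- .backgroundCharges(x, sites)
  lnTen_kT <- log(10) * .kT(model@temperature)

  dG <- numeric(nS)
  W <- matrix(0, nS, nS)
  for (m in seq_len(nS)) {
    s <- sites[[m]]
    chP <- .siteCharges(x, s, "prot")
    chD <- .siteCharges(x, s, "deprot")
    pts <- as.matrix(chP[, 1:3, drop = FALSE])
    energyIn <- function(env, charges) {
      if (!nrow(charges) || all(charges$q == 0)) return(list(E = 0, sol = NULL))
      sol <- focusSolve(charges, env, model, levels, tolerance, maxIter,
                        focusBBox = focusBBox, radii = radii)
      list(E = 0.5 * sum(charges$q *
                           potentialAt(sol, as.matrix(charges[, 1:3]))),
           sol = sol)
    }
    mc <- .modelCompound(x, s)
    protP <- energyIn(x, chP); protD <- energyIn(x, chD)
    modP <- energyIn(mc, chP); modD <- energyIn(mc, chD)
    # background interaction with the charging difference (protein only)
    backTerm <- 0
    if (nrow(bg)) {
      bgPts <- as.matrix(bg[, 1:3, drop = FALSE])
      phiP <- if (is.null(protP$sol)) 0 else potentialAt(protP$sol, bgPts)
      phiD <- if (is.null(protD$sol)) 0 else potentialAt(protD$sol, bgPts)
      phiDiff <- phiP - phiD
      phiDiff[is.na(phiDiff)] <- 0  # background atoms outside focus region
      backTerm <- sum(bg$q * phiDiff)
    }
    dG[m] <- (protP$E - protD$E) - (modP$E - modD$E) + backTerm
    # interaction of site m's unit charge difference with the others
    phiDelta <- function(ptsEval) {
      pP <- if (is.null(protP$sol)) 0 else potentialAt(protP$sol, ptsEval)
      pD <- if (is.null(protD$sol)) 0 else potentialAt(protD$sol, ptsEval)
      pP - pD
    }
    for (v in seq_len(nS)) {
      if (v == m) next
      sv <- sites[[v]]
      dv <- .siteCharges(x, sv, "prot")
      dv$q <- dv$q - .siteCharges(x, sv, "deprot")$q
      phis <- phiDelta(as.matrix(dv[, 1:3, drop = FALSE]))
      W[m, v] <- sum(dv$q * phis)
    }
  }
  reciprocity <- max(abs(W - t(W))) / max(max(abs(W)), 1e-12)
  if (nS > 1L && reciprocity > 0.05)
    warning("W-matrix reciprocity deviation ",
            sprintf("%.1f%%", 100 * reciprocity), " exceeds 5%")
  W <- (W + t(W)) / 2
  diag(W) <- 0
  tab <- data.frame(
    siteId = vapply(sites, `[[`, "", "siteId"),
    kind = vapply(sites, `[[`, "", "kind"),
    pkaRef = vapply(sites, `[[`, 0, "pkaRef"),
    qProt = vapply(sites, `[[`, 0, "qProt"),
    qDeprot = vapply(sites, `[[`, 0, "qDeprot"),
    hisGroup = vapply(sites, function(s)
      if (is.null(s$hisGroup)) NA_character_ else s$hisGroup, ""),
    stringsAsFactors = FALSE)
  tab$pkaIntr <- tab$pkaRef - dG / lnTen_kT
  new("SiteEnergies", sites = tab, deltaGIntr = dG, wMatrix = W)
}

#' Build a titration system from computed site energies
#'
#' @param se a \code{\link{SiteEnergies}}
#' @param pH,temperature,ionicStrength conditions (defaults 7.0, 300 K,
#'   0.1 M)
#' @param imidazolatePenalty energy (kcal/mol) added to the doubly
#'   deprotonated microstate of each histidine site pair (default from the
#'   bundled library, 10 kcal/mol)
#' @return a \code{\link{TitrationSystem}}
#' @export
titrationSystemFromEnergies <- function(se, pH = 7.0, temperature = 300,
                                        ionicStrength = 0.1,
                                        imidazolatePenalty = NULL) {
  if (is.null(imidazolatePenalty))
    imidazolatePenalty <- siteDefinitions()$imidazolate_penalty
  tab <- siteTable(se)
  pen <- data.frame(i = integer(), j = integer(), xi = integer(),
                    xj = integer(), energy = numeric())
  if ("hisGroup" %in% names(tab)) {
    for (g in unique(stats::na.omit(tab$hisGroup))) {
      idx <- which(!is.na(tab$hisGroup) & tab$hisGroup == g)
      if (length(idx) == 2L)
        pen <- rbind(pen, data.frame(i = idx[1L], j = idx[2L], xi = 0L,
                                     xj = 0L,
                                     energy = imidazolatePenalty))
    }
  }
  titrationSystem(tab, wMatrix = wMatrix(se), pH = pH,
                  temperature = temperature, ionicStrength = ionicStrength,
                  statePenalties = pen)
}
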