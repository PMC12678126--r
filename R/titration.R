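## Equilibrium multi-site protonation. The microstate energy is
##   E(x) = sum_mu x_mu dG_intr_mu(pH) + 1/2 sum_{mu != nu} q_mu q_nu W_munu
## with x_mu the protonation indicator, q_mu(x) the state formal charge and
## dG_intr_mu(pH) = ln(10) kT (pH - pKa_intr,mu) for every site kind; this
## sign convention makes an isolated site reproduce the
## Henderson-Hasselbalch curve <x> = 1/(1 + 10^(pH - pKa)) exactly.
## Averages over the 2^n microstates come from direct enumeration (n <= 20)
## or Metropolis Monte Carlo sampling.

# per-site intrinsic term at the system's (or an overridden) pH
.intrEnergies <- function(system, pH = NULL) {
  cond <- system@conditions
  if (is.null(pH)) pH <- cond$pH
  log(10) * .kT(cond$temperature) * (pH - system@sites$pkaIntr)
}

#' Energy of one protonation microstate
#'
#' @param system a \code{\link{TitrationSystem}}
#' @param x binary vector (1 = protonated), length = number of sites
#' @param pH optional pH overriding the system conditions
#' @return energy in kcal/mol
#' @export
stateEnergy <- function(system, x, pH = NULL) {
  stopifnot(is(system, "TitrationSystem"))
  n <- nrow(system@sites)
  if (length(x) != n)
    stop("state length ", length(x), " does not match ", n, " sites")
  g <- .intrEnergies(system, pH)
  q <- system@sites$qDeprot + x
  E <- sum(x * g) + 0.5 * sum((q %o% q) * system@wMatrix)
  pen <- system@statePenalties
  if (nrow(pen))
    E <- E + sum(pen$energy[x[pen$i] == pen$xi & x[pen$j] == pen$xj])
  E
}

# all 2^n states (rows), chunk-safe energies, and the partition average
.enumerate <- function(system, pH = NULL) {
  n <- nrow(system@sites)
  g <- .intrEnergies(system, pH)
  W <- system@wMatrix
  qd <- system@sites$qDeprot
  beta <- 1 / .kT(system@conditions$temperature)
  pen <- system@statePenalties
  nStates <- 2^n
  probs <- numeric(n)
  Z <- 0
  Emin <- NA_real_
  # two passes with a shared energy function, chunked to bound memory
  chunk <- 2^min(n, 14L)
  energies <- function(block) {
    X <- matrix(0L, length(block), n)
    for (b in seq_len(n)) X[, b] <- bitwAnd(bitwShiftR(block, b - 1L), 1L)
    Q <- sweep(X, 2L, qd, "+")
    E <- as.vector(X %*% g) + 0.5 * rowSums((Q %*% W) * Q)
    if (nrow(pen))
      for (r in seq_len(nrow(pen)))
        E <- E + pen$energy[r] * (X[, pen$i[r]] == pen$xi[r] &
                                    X[, pen$j[r]] == pen$xj[r])
    list(E = E, X = X)
  }
  for (start in seq(0L, nStates - 1L, by = chunk)) {
    block <- start:min(start + chunk - 1L, nStates - 1L)
    E <- energies(block)$E
    Emin <- min(Emin, min(E), na.rm = TRUE)
  }
  for (start in seq(0L, nStates - 1L, by = chunk)) {
    block <- start:min(start + chunk - 1L, nStates - 1L)
    en <- energies(block)
    w <- exp(-beta * (en$E - Emin))
    Z <- Z + sum(w)
    probs <- probs + as.vector(crossprod(en$X, w))
  }
  probs / Z
}

#' Exact protonation probabilities by enumeration
#'
#' Boltzmann-weighted average of every protonation indicator over all 2^n
#' microstates. Guarded at n <= 20; larger systems must use
#' \code{\link{mcTitrate}}.
#'
#' @param system a \code{\link{TitrationSystem}}
#' @return a \code{\link{ProtonationResult}} with method "exact"
#' @examples
#' sys <- titrationSystem(data.frame(kind = "acid", pkaIntr = 4.0), pH = 4.0)
#' probabilities(enumerateExact(sys))  # 0.5 at the midpoint
#' @export
enumerateExact <- function(system) {
  stopifnot(is(system, "TitrationSystem"))
  n <- nrow(system@sites)
  if (n > 20L)
    stop("exact enumeration is limited to 20 sites (2^n states); ",
         "use mcTitrate() for larger systems")
  p <- .enumerate(system)
  new("ProtonationResult",
      probabilities = setNames(p, system@sites$siteId),
      method = "exact")
}

#' Protonation probabilities by Metropolis Monte Carlo
#'
#' Samples microstates with single-site flips plus paired flips for site
#' pairs coupled more strongly than \code{pairThreshold}. Standard errors
#' come from batch means over the post-burn-in sweeps. Identical seed and
#' inputs give bitwise-identical output.
#'
#' @param system a \code{\link{TitrationSystem}}
#' @param sweeps total Monte Carlo sweeps (default 100000); one sweep is n
#'   single-site attempts plus one attempt per strongly coupled pair
#' @param burnIn discarded initial sweeps (default 10000)
#' @param seed integer RNG seed
#' @param pairThreshold |W| above which a pair gets joint flips, kcal/mol
#'   (default 2.0)
#' @param nBatch number of batches for the standard-error estimate
#' @return a \code{\link{ProtonationResult}} with method "mc". The per-site
#'   standard error is the batch-means estimate floored by a
#'   Laplace-smoothed binomial bound, so a site that never flips during the
#'   run still reports a non-zero uncertainty.
#' @export
mcTitrate <- function(system, sweeps = 100000L, burnIn = 10000L,
                      seed = 1L, pairThreshold = 2.0, nBatch = 50L) {
  stopifnot(is(system, "TitrationSystem"))
  if (burnIn < 0 || sweeps <= burnIn)
    stop("need sweeps > burnIn >= 0")
  n <- nrow(system@sites)
  g <- .intrEnergies(system)
  W <- system@wMatrix
  strong <- which(abs(W) > pairThreshold & upper.tri(W), arr.ind = TRUE)
  pen <- system@statePenalties
  # histidine-style state penalties also couple sites strongly
  if (nrow(pen))
    strong <- unique(rbind(strong, cbind(pen$i, pen$j)))
  beta <- 1 / .kT(system@conditions$temperature)
  set.seed(as.integer(seed))
  res <- .mc_titrate(g, W, system@sites$qDeprot, beta,
                     as.integer(sweeps), as.integer(burnIn),
                     matrix(as.integer(strong) - 1L, ncol = 2L),
                     matrix(as.integer(c(pen$i - 1L, pen$j - 1L,
                                         pen$xi, pen$xj)),
                            ncol = 4L),
                     as.numeric(pen$energy), as.integer(nBatch))
  nKept <- sweeps - burnIn
  p <- pmin(pmax(res$prob, 0), 1)
  pSmooth <- (p * nKept + 1) / (nKept + 2)
  seFloor <- sqrt(pSmooth * (1 - pSmooth) / nKept)
  new("ProtonationResult",
      probabilities = setNames(p, system@sites$siteId),
      method = "mc",
      mcError = setNames(pmax(res$se, seFloor), system@sites$siteId),
      seed = as.integer(seed))
}

#' Titration curve and half-protonation pKa of one site
#'
#' Evaluates the site's mean protonation across a pH grid (exact or Monte
#' Carlo backend) and locates the pH of half-protonation by linear
#' interpolation between the bracketing grid points.
#'
#' @param system a \code{\link{TitrationSystem}}
#' @param site site identifier (or index)
#' @param phGrid sorted pH grid (default 0 to 14 step 0.25)
#' @param method "exact" or "mc"
#' @param ... passed to \code{\link{mcTitrate}} when method = "mc"
#' @return list with \code{curve} (data.frame pH, probability),
#'   \code{pkaHalf} (NA with \code{crossed = FALSE} when the curve does not
#'   cross 0.5 in range) and \code{crossed}
#' @export
pkaCurve <- function(system, site = 1L, phGrid = seq(0, 14, by = 0.25),
                     method = c("exact", "mc"), ...) {
  stopifnot(is(system, "TitrationSystem"))
  method <- match.arg(method)
  if (is.character(site)) site <- match(site, system@sites$siteId)
  if (is.na(site)) stop("unknown site")
  if (is.unsorted(phGrid)) stop("phGrid must be sorted increasing")
  pr <- vapply(phGrid, function(ph) {
    sys2 <- system
    sys2@conditions$pH <- ph
    if (method == "exact") probabilities(enumerateExact(sys2))[site]
    else probabilities(mcTitrate(sys2, ...))[site]
  }, numeric(1L))
  curve <- data.frame(pH = phGrid, probability = unname(pr))
  cross <- which(diff(sign(pr - 0.5)) != 0)
  if (!length(cross)) {
    atHalf <- which(pr == 0.5)
    if (length(atHalf))
      return(list(curve = curve, pkaHalf = phGrid[atHalf[1L]],
                  crossed = TRUE))
    return(list(curve = curve, pkaHalf = NA_real_, crossed = FALSE))
  }
  i <- cross[1L]
  p1 <- pr[i]; p2 <- pr[i + 1L]
  pka <- phGrid[i] + (0.5 - p1) / (p2 - p1) * (phGrid[i + 1L] - phGrid[i])
  list(curve = curve, pkaHalf = pka, crossed = TRUE)
}

#' Report deviations from standard protonation states
#'
#' A site's standard state is the one its reference pKa implies at the
#' evaluation pH: the common acidic residues (Asp, Glu) are deprotonated at
#' pH 7 and the basic ones (Lys, Arg, His) protonated, while Cys/Tyr
#' (reference pKa above 7) are standardly protonated. A deviation is
#' reported whenever the probability of the non-standard state exceeds 0.5,
#' e.g. a glutamate held protonated by an adjacent phosphate group.
#'
#' @param result a \code{\link{ProtonationResult}}
#' @param system the \code{\link{TitrationSystem}} the result came from
#' @return data.frame with columns site_id, expected_state,
#'   observed_probability (of the protonated state), note; zero rows when
#'   every site is standard
#' @export
reportPattern <- function(result, system) {
  stopifnot(is(result, "ProtonationResult"), is(system, "TitrationSystem"))
  s <- system@sites
  p <- probabilities(result)
  pH <- system@conditions$pH
  pkaRef <- if (!is.null(s$pkaRef)) s$pkaRef else s$pkaIntr
  expected <- ifelse(pkaRef > pH, "protonated", "deprotonated")
  devProb <- ifelse(expected == "deprotonated", p, 1 - p)
  hit <- devProb > 0.5
  out <- data.frame(
    site_id = s$siteId[hit],
    expected_state = expected[hit],
    observed_probability = unname(p[hit]),
    note = sprintf("probability of the non-standard state %.3f at pH %s",
                   devProb[hit], format(system@conditions$pH)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
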