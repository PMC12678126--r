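## Variant structural-impact pipeline: runs motif annotation, clash and
## rotamer analysis, superposition/displacement profiling, interaction
## diffing and (optionally) the electrostatics + titration stage on a
## wild-type/mutant model pair, and aggregates everything into a
## VariantReport with full provenance. Stage failures are recorded and the
## report is still emitted for the stages that completed.

#' Specify a missense variant
#'
#' @param chain chain identifier
#' @param resno author residue number
#' @param from,to one-letter codes of the wild-type and mutant amino acid
#' @param label free label (default e.g. "T652R")
#' @return a validated variant-specification list
#' @export
variantSpec <- function(chain, resno, from, to,
                        label = paste0(from, resno, to)) {
  if (from == to)
    stop("from and to amino acids must differ (got ", from, " -> ", to, ")")
  if (!from %in% names(.AA1TO3) || !to %in% names(.AA1TO3))
    stop("unknown one-letter amino-acid code")
  list(chain_id = chain, residue_number = as.integer(resno),
       from_aa = from, to_aa = to, label = label)
}

#' Default pipeline configuration
#'
#' All thresholds of the analysis surface here: clash tolerance 0.4 A,
#' H-bond cutoff 3.5 A, salt-bridge cutoff 4.0 A, chi grid 30 degrees,
#' continuum conditions pH 7.0, 300 K, 100 mM, dielectrics 4/80, focusing
#' levels 2.5/1.0/0.3 A. \code{electrostatics = NA} enables the titration
#' stage automatically for structures up to 500 residues.
#'
#' @param ... overrides merged over the defaults
#' @return named list
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    clash_tolerance = 0.4,
    hbond_cutoff = 3.5,
    saltbridge_cutoff = 4.0,
    chi_grid = 30,
    flank = 2L,
    electrostatics = NA,
    levels = c(2.5, 1.0, 0.3),
    pH = 7.0, temperature = 300, ionic_strength = 0.1,
    eps_protein = 4, eps_solvent = 80,
    titration_method = "exact",
    mc_sweeps = 100000L, mc_burnin = 10000L,
    seed = 1L,
    ligand_resids = c("ATP", "ADP"))
  modifyList(cfg, list(...))
}

#' Run the full variant structural-impact analysis
#'
#' Executes, in order: Walker A motif scan and variant-position
#' classification; steric-clash detection focused on the variant residue of
#' the mutant; rotamer enumeration at the variant residue; superposition
#' (all shared C-alpha atoms excluding the P-loop and a two-residue flank)
#' with C-alpha and ligand-atom displacement profiling; polar-interaction
#' inventories of both structures and their difference with inter-region
#' tagging; and, when enabled, site-energy calculation plus titration and
#' protonation-pattern reporting for both structures.
#'
#' @param wt,mut wild-type and mutant \code{ProteinStructure}; numbering
#'   must agree except at the variant residue
#' @param variant a \code{\link{variantSpec}}
#' @param regions optional region annotations (\code{\link{regionTable}})
#' @param config a \code{\link{pipelineConfig}}
#' @return a \code{\link{VariantReport}}
#' @export
runVariantReport <- function(wt, mut, variant, regions = NULL,
                             config = pipelineConfig()) {
  stopifnot(is(wt, "ProteinStructure"), is(mut, "ProteinStructure"))
  # variant-identity validation
  wa <- atoms(wt); ma <- atoms(mut)
  wRes <- unique(wa$resid[wa$chain == variant$chain_id &
                            wa$resno == variant$residue_number & !wa$het])
  mRes <- unique(ma$resid[ma$chain == variant$chain_id &
                            ma$resno == variant$residue_number & !ma$het])
  if (length(wRes) != 1L || .AA3TO1[wRes] != variant$from_aa)
    stop("wild-type residue ", variant$chain_id, ":",
         variant$residue_number, " is not ", variant$from_aa)
  if (length(mRes) != 1L || .AA3TO1[mRes] != variant$to_aa)
    stop("mutant residue ", variant$chain_id, ":",
         variant$residue_number, " is not ", variant$to_aa)

  stages <- list()
  runStage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(list(ok = TRUE, value = expr),
                    error = function(e)
                      list(ok = FALSE, value = NULL,
                           error = conditionMessage(e)))
    stages[[length(stages) + 1L]] <<- list(
      stage = name, ok = out$ok,
      error = if (out$ok) NULL else out$error,
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      3))
    if (!out$ok) NULL else out$value
  }

  # 1. motif context
  motif <- runStage("motif_scan", {
    hits <- scanWalkerA(wt, variant$chain_id)
    role <- "outside"
    hitIdx <- NA_integer_
    for (i in seq_along(hits)) {
      r <- classifyPosition(hits[[i]], variant$residue_number)
      if (r != "outside") { role <- r; hitIdx <- i; break }
    }
    list(n_hits = length(hits), variant_role = role,
         hits = lapply(hits, function(h)
           list(chain = h@chain, sequence = h@sequence,
                resno = h@resno, roles = h@roles)),
         variant_hit = hitIdx)
  })

  # 2. clashes at the variant residue (mutant)
  clashes <- runStage("clashes", {
    findClashes(mut,
                focus = selectResidues(variant$residue_number,
                                       chain = variant$chain_id),
                tolerance = config$clash_tolerance)
  })
  if (is.null(clashes)) clashes <- data.frame()

  # 3. rotamer enumeration at the variant residue (mutant)
  rotamers <- runStage("rotamers", {
    rot <- enumerateRotamers(mut, variant$residue_number,
                             chain = variant$chain_id,
                             chiGrid = config$chi_grid,
                             tolerance = config$clash_tolerance)
    chiCols <- grep("^chi", names(rot))
    list(n_rotamers = nrow(rot),
         min_clash_score = min(rot$clash_score),
         max_clash_score = max(rot$clash_score),
         best_chi = as.numeric(rot[1L, chiCols]),
         n_clash_free = sum(rot$n_clashes == 0L))
  })

  # 4. displacement profile (fit: shared C-alpha minus P-loop +/- flank)
  displacement <- runStage("displacement", {
    excl <- integer()
    if (!is.null(motif) && !is.na(motif$variant_hit)) {
      h <- motif$hits[[motif$variant_hit]]
      ploop <- h$resno[2:5]
      excl <- (min(ploop) - config$flank):(max(ploop) + config$flank)
    }
    fitSel <- function(a) a$name == "CA" & !a$het & !(a$resno %in% excl)
    prof <- displacementProfile(wt, mut, fitSelection = fitSel,
                                selectionLabel = "C-alpha")
    ligSel <- function(a) a$resid %in% config$ligand_resids
    lig <- if (any(ligSel(atoms(wt)))) {
      profileEntries(displacementProfile(wt, mut, fitSelection = fitSel,
                                         reportSelection = ligSel,
                                         selectionLabel = "ligand"))
    } else data.frame()
    list(rmsd_fit = prof@superposition@rmsd,
         n_fit_atoms = prof@superposition@nAtoms,
         profile = profileEntries(prof), named_atoms = lig)
  })

  # 5. interaction inventories and their difference
  interactionDiff <- runStage("interactions", {
    iw <- findPolarInteractions(wt, regions, config$hbond_cutoff,
                                config$saltbridge_cutoff)
    im <- findPolarInteractions(mut, regions, config$hbond_cutoff,
                                config$saltbridge_cutoff)
    c(diffInteractions(iw, im), list(wt = iw, mut = im))
  })
  if (is.null(interactionDiff))
    interactionDiff <- list(gained = data.frame(), lost = data.frame())

  # 6. optional electrostatics + titration
  nRes <- length(unique(paste(wa$chain, wa$resno)[!wa$het]))
  doTitration <- isTRUE(config$electrostatics) ||
    (is.na(config$electrostatics) && nRes <= 500L)
  protonation <- if (doTitration) runStage("protonation", {
    model <- continuumModel(epsProtein = config$eps_protein,
                            epsSolvent = config$eps_solvent,
                            ionicStrength = config$ionic_strength,
                            temperature = config$temperature)
    analyse <- function(s) {
      sites <- defaultTitratableSites(s)
      if (!length(sites)) return(NULL)
      se <- computeSiteEnergies(s, sites, model, levels = config$levels)
      sys <- titrationSystemFromEnergies(
        se, pH = config$pH, temperature = config$temperature,
        ionicStrength = config$ionic_strength)
      res <- if (config$titration_method == "exact" &&
                 nrow(siteTable(sys)) <= 20L) enumerateExact(sys)
      else mcTitrate(sys, sweeps = config$mc_sweeps,
                     burnIn = config$mc_burnin, seed = config$seed)
      list(deviations = reportPattern(res, sys),
           probabilities = data.frame(site_id = siteTable(sys)$siteId,
                                      probability =
                                        unname(probabilities(res)),
                                      pka_intr = siteTable(sys)$pkaIntr))
    }
    list(wt = analyse(wt), mut = analyse(mut))
  }) else NULL
  if (is.null(protonation)) protonation <- list()

  prov <- list(package_version = as.character(packageVersion("VariantLens")),
               config = config, seed = config$seed,
               timestamp = format(Sys.time(), tz = "UTC"),
               models = c(wt = modelId(wt), mut = modelId(mut)),
               stages = stages)
  new("VariantReport", variant = variant,
      motifContext = if (is.null(motif))
        list(n_hits = 0L, variant_role = "outside", hits = list())
      else motif,
      clashSummary = clashes,
      rotamerSummary = if (is.null(rotamers)) list() else rotamers,
      displacement = if (is.null(displacement)) list() else displacement,
      interactionDiff = interactionDiff,
      protonation = protonation,
      provenance = prov)
}

#' Convert a VariantReport to a plain list (JSON-ready)
#' @param report a \code{VariantReport}
#' @return nested list matching the bundled report schema
#' @export
reportAsList <- function(report) {
  stopifnot(is(report, "VariantReport"))
  list(variant = report@variant,
       motif_context = report@motifContext[c("n_hits", "variant_role",
                                             "hits")],
       clash_summary = report@clashSummary,
       rotamer_summary = report@rotamerSummary,
       displacement = report@displacement,
       interaction_diff = report@interactionDiff[c("gained", "lost")],
       protonation = if (length(report@protonation)) report@protonation
       else NULL,
       provenance = report@provenance)
}

#' Write a VariantReport to disk
#'
#' Emits \code{report.json} (matching the bundled JSON schema),
#' \code{report.txt} (human-readable summary) and TSV tables for the
#' displacement profile and gained/lost interactions.
#'
#' @param report a \code{VariantReport}
#' @param dir output directory
#' @return named list of written paths, invisibly
#' @export
writeVariantReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(json = file.path(dir, "report.json"),
                txt = file.path(dir, "report.txt"))
  jsonlite::write_json(reportAsList(report), paths$json, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", null = "null")
  txt <- utils::capture.output(show(report))
  writeLines(txt, paths$txt)
  writeTSV <- function(df, name) {
    if (is.data.frame(df) && nrow(df)) {
      p <- file.path(dir, name)
      write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
      paths[[name]] <<- p
    }
  }
  writeTSV(report@displacement$profile, "displacement_profile.tsv")
  writeTSV(report@interactionDiff$gained, "interactions_gained.tsv")
  writeTSV(report@interactionDiff$lost, "interactions_lost.tsv")
  invisible(paths)
}

#' Check a report list against the bundled JSON schema
#'
#' Lightweight structural conformance check (required keys and basic
#' types) against \code{inst/extdata/variant-report.schema.json}.
#'
#' @param x nested list (\code{\link{reportAsList}}) or path to a report
#'   JSON file
#' @return TRUE if conformant, otherwise a character vector of problems
#' @export
validateReportSchema <- function(x) {
  if (is.character(x)) x <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  schema <- jsonlite::fromJSON(
    system.file("extdata", "variant-report.schema.json",
                package = "VariantLens"),
    simplifyVector = FALSE)
  problems <- character()
  for (key in unlist(schema$required))
    if (is.null(x[[key]]))
      problems <- c(problems, paste("missing required key:", key))
  if (!is.null(x$variant))
    for (key in unlist(schema$properties$variant$required))
      if (is.null(x$variant[[key]]))
        problems <- c(problems, paste("variant lacks:", key))
  if (!is.null(x$interaction_diff)) {
    for (key in c("gained", "lost"))
      if (is.null(x$interaction_diff[[key]]))
        problems <- c(problems, paste("interaction_diff lacks:", key))
  }
  if (!is.null(x$provenance))
    for (key in unlist(schema$properties$provenance$required))
      if (is.null(x$provenance[[key]]))
        problems <- c(problems, paste("provenance lacks:", key))
  if (length(problems)) problems else TRUE
}
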