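## Coordinate I/O. Parsing of PDB and mmCIF files is delegated to bio3d
## (read.pdb / read.cif); records are normalised into the package's atom
## table. Author numbering is always preserved verbatim; mapping between
## numbering schemes (e.g. the one-residue offset between the human and
## mouse DNA2 sequences) is done explicitly with shiftNumbering(), never
## inferred.

#' Read an atomic coordinate file
#'
#' Reads PDB or mmCIF (PDBx) coordinate files. Every ATOM/HETATM record
#' becomes one atom row; ligands (ATP, ADP, nucleotides, metal clusters) are
#' retained as hetero residues. Alternate locations are reduced to the
#' highest-occupancy conformer (ties: first encountered).
#'
#' @param path file path
#' @param format one of "auto", "pdb", "cif". "auto" decides from the file
#'   extension (.cif/.mmcif are mmCIF, everything else PDB).
#' @param modelId identifier stored on the returned object (default: file
#'   base name)
#' @return a \code{\link{ProteinStructure}}
#' @examples
#' fx <- makeFixture("ploop_peptide", seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(structures(fx)[[1]], f)
#' s <- readStructure(f)
#' nAtoms(s)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif"),
                          modelId = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  raw <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE,
                                         rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("parse error reading ", format, " file '",
                             path, "': ", conditionMessage(e)))
  a <- raw$atom
  if (is.null(a) || !nrow(a)) stop("parse error: no atom records in ", path)
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    # CIF readers may keep the quoting of primed atom names ("O5'")
    name   = gsub("^['\"]|['\"]$", "", trimws(a$elety)),
    altloc = ifelse(is.na(a$alt) | a$alt %in% c(".", "?"), "", a$alt),
    resid  = trimws(a$resid),
    chain  = ifelse(is.na(a$chain), "A", a$chain),
    resno  = as.integer(a$resno),
    insert = ifelse(is.na(a$insert) | a$insert %in% c(".", "?"), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    b   = ifelse(is.na(a$b), 0, a$b),
    elem = NA_character_,
    het  = a$type == "HETATM",
    stringsAsFactors = FALSE)
  elesy <- if (!is.null(a$elesy)) trimws(a$elesy) else rep("", nrow(a))
  atoms$elem <- ifelse(!is.na(elesy) & nzchar(elesy), toupper(elesy),
                       guessElement(atoms$name))
  atoms <- .reduceAltloc(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
  if (anyDuplicated(key))
    stop("parse error: duplicate atom record ",
         key[duplicated(key)][1L], " in ", path)
  if (is.null(modelId))
    modelId <- tools::file_path_sans_ext(basename(path))
  proteinStructure(atoms, modelId = modelId,
                   metadata = list(source = path, format = format))
}

# keep highest-occupancy altloc per atom identity; tie -> first encountered
.reduceAltloc <- function(atoms) {
  if (!any(nzchar(atoms$altloc))) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
  ord <- order(factor(key, levels = unique(key)), -atoms$occ,
               seq_len(nrow(atoms)))
  a2 <- atoms[ord, , drop = FALSE]
  keep <- !duplicated(paste(a2$chain, a2$resno, a2$insert, a2$name))
  a2 <- a2[keep, , drop = FALSE]
  a2 <- a2[order(match(paste(a2$chain, a2$resno, a2$insert, a2$name),
                       unique(key))), , drop = FALSE]
  a2$altloc <- ""
  rownames(a2) <- NULL
  a2
}

#' Write a structure to disk
#'
#' PDB records carry coordinates to 3 decimals; the minimal mmCIF writer
#' emits a standard \code{atom_site} loop at full precision.
#'
#' @param x a \code{ProteinStructure}
#' @param path output file path
#' @param format "auto" (from extension), "pdb" or "cif"
#' @return \code{path}, invisibly
#' @export
writeStructure <- function(x, path, format = c("auto", "pdb", "cif")) {
  stopifnot(is(x, "ProteinStructure"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  a <- atoms(x)
  if (format == "pdb") {
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = ifelse(a$het, "HETATM", "ATOM"),
                     resno = a$resno, resid = a$resid, eleno = a$serial,
                     elety = a$name, chain = a$chain, insert = a$insert,
                     o = a$occ, b = a$b, elesy = a$elem)
  } else {
    .writeCif(a, path, modelId(x))
  }
  invisible(path)
}

# minimal PDBx/mmCIF atom_site writer (full coordinate precision, canonical
# RCSB column order so generic readers accept it)
.writeCif <- function(a, path, dataName) {
  hdr <- c(paste0("data_", gsub("[^A-Za-z0-9_]", "_", dataName)),
           "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_entity_id",
           "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  # atom names containing primes (O5' etc.) need double quoting in CIF
  tok <- function(x) ifelse(grepl("'", x), paste0('"', x, '"'), x)
  rows <- sprintf(
    "%-6s %d %s %s %s %s %s 1 %d %s %.6f %.6f %.6f %.4f %.4f ? %d %s %s %s 1",
    ifelse(a$het, "HETATM", "ATOM"), a$serial, a$elem,
    tok(a$name), ".", a$resid, a$chain, a$resno,
    ifelse(nzchar(a$insert), a$insert, "?"),
    a$x, a$y, a$z, a$occ, a$b,
    a$resno, a$resid, a$chain, tok(a$name))
  writeLines(c(hdr, rows, "#"), path)
}

#' Extract the one-letter sequence of a chain
#'
#' Hetero residues are excluded. Non-standard amino-acid residues are
#' reported as \code{X} with a warning. Residues are ordered by residue
#' number (then insertion code) within the chain.
#'
#' @param x a \code{ProteinStructure}
#' @param chain chain identifier; \code{""} auto-selects when the structure
#'   has a single chain
#' @return list with components \code{sequence} (1-letter string) and
#'   \code{numbering} (integer vector, author numbering), aligned index-wise
#' @examples
#' fx <- makeFixture("ploop_peptide", seed = 1)
#' extractSequence(structures(fx)[[1]], "A")$sequence
#' @export
extractSequence <- function(x, chain = "") {
  stopifnot(is(x, "ProteinStructure"))
  a <- atoms(x)
  chains <- unique(a$chain[!a$het])
  if (!nzchar(chain)) {
    if (length(chains) != 1L)
      stop("chain must be given explicitly for multi-chain structures (",
           paste(chains, collapse = ","), ")")
    chain <- chains
  }
  if (!chain %in% a$chain) stop("chain not present: ", chain)
  a <- a[a$chain == chain & !a$het, , drop = FALSE]
  if (!nrow(a)) return(list(sequence = "", numbering = integer()))
  resKey <- paste(a$resno, a$insert)
  first <- !duplicated(resKey)
  res <- a[first, c("resid", "resno", "insert"), drop = FALSE]
  res <- res[order(res$resno, res$insert), , drop = FALSE]
  one <- .AA3TO1[res$resid]
  if (anyNA(one)) {
    warning("non-standard residue(s) reported as X: ",
            paste(unique(res$resid[is.na(one)]), collapse = ", "))
    one[is.na(one)] <- "X"
  }
  list(sequence = paste(one, collapse = ""), numbering = res$resno)
}

#' Shift author residue numbering by a fixed offset
#'
#' Used to map between numbering schemes of homologous structures, e.g. the
#' one-residue offset between the human and mouse DNA2 sequences (human
#' Thr652 corresponds to mouse Thr653). The offset is always explicit and
#' user-supplied.
#'
#' @param x a \code{ProteinStructure}
#' @param offset integer added to every residue number
#' @param chain optional chain to restrict the shift to (default all chains)
#' @return the renumbered structure
#' @export
shiftNumbering <- function(x, offset, chain = NULL) {
  stopifnot(is(x, "ProteinStructure"))
  a <- atoms(x)
  idx <- if (is.null(chain)) rep(TRUE, nrow(a)) else a$chain == chain
  a$resno[idx] <- a$resno[idx] + as.integer(offset)
  proteinStructure(a, modelId = modelId(x), metadata = x@metadata)
}

#' Read region annotations from a YAML or JSON file
#'
#' Expected content: a list of entries with fields \code{label},
#' \code{chain}, \code{start}, \code{end} (inclusive author numbering), e.g.
#' domain ranges such as helicase-1A / helicase-2A / nuclease.
#'
#' @param path YAML (.yml/.yaml) or JSON file
#' @return data.frame with columns label, chain, start, end
#' @export
readRegions <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = FALSE)
  regionTable(obj)
}

#' Build a region-annotation table
#'
#' @param regions list of lists with fields label, chain, start, end
#' @return validated data.frame with columns label, chain, start, end
#' @export
regionTable <- function(regions) {
  df <- do.call(rbind, lapply(regions, function(r) {
    data.frame(label = as.character(r$label), chain = as.character(r$chain),
               start = as.integer(r$start), end = as.integer(r$end),
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- data.frame(label = character(), chain = character(),
                                    start = integer(), end = integer())
  if (nrow(df) && any(df$start > df$end))
    stop("region start must be <= end")
  if (anyDuplicated(df[, c("chain", "start", "end")]))
    stop("duplicate region range")
  df
}

# region label for (chain, resno), or NA
.regionOf <- function(regions, chain, resno) {
  if (is.null(regions) || !nrow(regions)) return(rep(NA_character_, length(resno)))
  out <- rep(NA_character_, length(resno))
  for (k in seq_len(nrow(regions))) {
    hit <- chain == regions$chain[k] & resno >= regions$start[k] &
      resno <= regions$end[k]
    out[hit & is.na(out)] <- regions$label[k]
  }
  out
}
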