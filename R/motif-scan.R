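## Walker A (P-loop) motif annotation. The motif is the nucleotide-binding
## signature G-x-x-x-x-G-K-[T/S]: the four x positions form the phosphate-
## binding loop (P-loop) and the conserved lysine coordinates the ATP
## gamma-phosphate. The x positions are unrestricted -- an x may itself be
## glycine, as in the DNA2 instance (GMPGTGKT).

#' Locate Walker A motifs in a sequence
#'
#' Scans a one-letter sequence for every occurrence of the consensus
#' G-x-x-x-x-G-K-[T/S]. All maximal matches are reported; overlapping
#' matches are allowed (no greedy suppression).
#'
#' @param sequence one-letter amino-acid string
#' @param numbering integer vector of author residue numbers, same length
#'   as the sequence
#' @param chain chain identifier recorded on the hits
#' @return list of \code{\link{MotifHit}} objects (empty if none)
#' @examples
#' hits <- findWalkerA("GMPGTGKT", 649:656, "A")
#' hits[[1]]
#' @export
findWalkerA <- function(sequence, numbering, chain = "A") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seqChars <- strsplit(sequence, "")[[1]]
  if (length(seqChars) != length(numbering))
    stop("sequence length (", length(seqChars),
         ") does not match numbering length (", length(numbering), ")")
  n <- length(seqChars)
  hits <- list()
  if (n >= 8L) {
    for (i in seq_len(n - 7L)) {
      w <- seqChars[i:(i + 7L)]
      if (w[1L] == "G" && w[6L] == "G" && w[7L] == "K" &&
          (w[8L] == "T" || w[8L] == "S")) {
        hits[[length(hits) + 1L]] <- new(
          "MotifHit", chain = chain,
          resno = as.integer(numbering[i:(i + 7L)]),
          roles = .MOTIF_ROLES,
          sequence = paste(w, collapse = ""))
      }
    }
  }
  hits
}

#' Classify a residue's position within a Walker A motif
#'
#' @param hit a \code{\link{MotifHit}}
#' @param residueNumber author residue number to classify
#' @return the role label ("G1", "x1".."x4", "G2", "K", "TS") or
#'   \code{"outside"}; the x roles additionally carry the "(P-loop)" tag,
#'   e.g. \code{"x4 (P-loop)"}
#' @examples
#' hit <- findWalkerA("GMPGTGKT", 648:655, "A")[[1]]
#' classifyPosition(hit, 651)  # "x4 (P-loop)"
#' classifyPosition(hit, 653)  # "K"
#' @export
classifyPosition <- function(hit, residueNumber) {
  stopifnot(is(hit, "MotifHit"))
  idx <- match(as.integer(residueNumber), hit@resno)
  if (is.na(idx)) return("outside")
  role <- hit@roles[idx]
  if (role %in% c("x1", "x2", "x3", "x4"))
    role <- paste0(role, " (P-loop)")
  role
}

#' Scan a structure chain for Walker A motifs
#'
#' Convenience wrapper: extracts the chain sequence and runs
#' \code{\link{findWalkerA}} with author numbering.
#'
#' @param x a \code{ProteinStructure}
#' @param chain chain identifier ("" auto-selects a single chain)
#' @return list of \code{MotifHit}
#' @export
scanWalkerA <- function(x, chain = "") {
  sq <- extractSequence(x, chain)
  if (!nzchar(chain)) {
    ch <- unique(atoms(x)$chain[!atoms(x)$het])
    chain <- ch[1L]
  }
  findWalkerA(sq$sequence, sq$numbering, chain)
}
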