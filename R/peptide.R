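#' Parse and validate phosphopeptide sequence windows
#'
#' A phosphopeptide is represented as a 10-character sequence window with the
#' modified residue in the sixth position. The central residue must be an
#' uppercase `S`, `T` or `Y`. Other positions may hold any of the 20 standard
#' uppercase amino-acid letters, the lowercase phospho-priming residues `s`,
#' `t`, `y`, or `_` for an undefined position (e.g. beyond a protein
#' terminus). Lowercase letters mark prior phosphorylation at priming sites
#' and are therefore never accepted at the central position: a window centred
#' on a lowercase residue is rejected, not silently uppercased.
#'
#' Surrounding whitespace is stripped; everything else is taken verbatim.
#' Non-standard ambiguity letters (B, J, O, U, X, Z) are rejected — convert
#' them to `_` beforehand.
#'
#' @param x character vector of candidate 10-mer windows.
#' @return the validated character vector, invisibly identical to the
#'   (whitespace-trimmed) input.
#' @examples
#' parse_peptide("AAAAASAAAA")
#' parse_peptide("__MKKSARTY")   # '_' padding at the N-terminal positions
#' @export
parse_peptide <- function(x) {
  if (length(x) == 0L) stop("no peptide sequences given")
  x <- trimws(as.character(x))
  if (anyNA(x) || any(!nzchar(x))) stop("empty peptide sequence token")
  bad_len <- nchar(x) != PEPTIDE_WIDTH
  if (any(bad_len)) {
    stop(sprintf("peptide '%s' has length %d, expected %d",
                 x[bad_len][1L], nchar(x[bad_len][1L]), PEPTIDE_WIDTH))
  }
  ch <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
               nrow = PEPTIDE_WIDTH)
  centre <- ch[CENTER_INDEX, ]
  bad_centre <- !(centre %in% CENTER_RESIDUES)
  if (any(bad_centre)) {
    i <- which(bad_centre)[1L]
    stop(sprintf(
      "peptide '%s': central residue (position %d) is '%s', must be uppercase S, T or Y",
      x[i], CENTER_INDEX, centre[i]))
  }
  allowed <- c(RESIDUE_ALPHABET, "_")
  bad_sym <- matrix(!(ch %in% allowed), nrow = PEPTIDE_WIDTH)
  bad_sym[CENTER_INDEX, ] <- FALSE
  if (any(bad_sym)) {
    j <- which(bad_sym, arr.ind = TRUE)[1L, ]
    stop(sprintf("peptide '%s': illegal symbol '%s' at position %d",
                 x[j[2L]], ch[j[1L], j[2L]], j[1L]))
  }
  x
}

#' Extract a 10-mer phosphopeptide window from a protein sequence
#'
#' Returns the window covering positions `site_position - 5` to
#' `site_position + 4` of the protein, with positions falling outside the
#' protein filled by `_`, so that the phosphosite sits at window position 6.
#'
#' @param protein_sequence single protein sequence (character scalar,
#'   uppercase one-letter amino-acid codes).
#' @param site_position 1-based residue coordinate of the phosphosite.
#' @param expected_residue the expected central residue, one of `"S"`,
#'   `"T"`, `"Y"`; a mismatch with the protein sequence is an error.
#' @return a validated 10-character phosphopeptide window.
#' @examples
#' window_from_protein("MKKSARTY", 4, "S")  # "__MKKSARTY"
#' @export
window_from_protein <- function(protein_sequence, site_position,
                                expected_residue) {
  stopifnot(length(protein_sequence) == 1L, length(site_position) == 1L)
  expected_residue <- match.arg(toupper(expected_residue), CENTER_RESIDUES)
  len <- nchar(protein_sequence)
  site_position <- as.integer(site_position)
  if (is.na(site_position) || site_position < 1L || site_position > len) {
    stop(sprintf("site coordinate %s outside protein of length %d",
                 site_position, len))
  }
  found <- substr(protein_sequence, site_position, site_position)
  if (!identical(found, expected_residue)) {
    stop(sprintf(
      "site residue disagreement at position %d: protein has '%s', expected '%s'",
      site_position, found, expected_residue))
  }
  pos <- (site_position - 5L):(site_position + 4L)
  chars <- rep("_", PEPTIDE_WIDTH)
  ok <- pos >= 1L & pos <= len
  chars[ok] <- vapply(pos[ok], function(p) substr(protein_sequence, p, p), "")
  parse_peptide(paste0(chars, collapse = ""))
}

#' Build phosphopeptide windows from a FASTA-derived protein set
#'
#' Vectorized companion to [window_from_protein()] for a site table
#' of (accession, position, residue) triples resolved against a named set of
#' protein sequences, e.g. as returned by [read_protein_fasta()].
#'
#' @param proteins named character vector of protein sequences; names are
#'   accession keys.
#' @param accession,position,residue parallel vectors describing one
#'   phosphosite each.
#' @return character vector of validated 10-mer windows.
#' @export
site_windows <- function(proteins, accession, position, residue) {
  stopifnot(length(accession) == length(position),
            length(position) == length(residue))
  missing <- setdiff(unique(accession), names(proteins))
  if (length(missing)) {
    stop("accession(s) not found in protein set: ",
         paste(missing, collapse = ", "))
  }
  vapply(seq_along(accession), function(i) {
    window_from_protein(proteins[[accession[i]]], position[i], residue[i])
  }, "")
}

#' Read protein sequences from a FASTA file
#'
#' The header token up to the first whitespace is used as the accession key.
#'
#' @param path path to a (plain-text) FASTA file of amino-acid sequences.
#' @return named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}
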