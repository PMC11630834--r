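#' Construct and validate a kinase PSSM
#'
#' A kinase position-specific scoring matrix holds nonnegative amino-acid
#' affinity scores for the 10 window positions (-5..4, with 0 the modified
#' residue) over a 23-symbol residue alphabet: the 20 standard amino acids
#' followed by the phospho-priming residues `s`, `t`, `y`. The `_` symbol has
#' no column — an undefined window position contributes a constant factor 1
#' to the score product. The central row (position 0) may be nonzero only at
#' `S`/`T` for a Ser/Thr kinase and only at `Y` for a Tyr kinase.
#'
#' @param name kinase identifier.
#' @param kinase_class `"SerThr"` or `"Tyr"`.
#' @param matrix numeric 10 x 23 matrix; if dimnames are present the rows
#'   are matched to positions `-5..4` and the columns to the canonical
#'   residue order, otherwise that layout is assumed.
#' @return a validated `kinase_pssm` object (list with `name`,
#'   `kinase_class`, `matrix`).
#' @export
kinase_pssm <- function(name, kinase_class, matrix) {
  kinase_class <- match.arg(kinase_class, c("SerThr", "Tyr"))
  m <- as.matrix(matrix)
  if (!is.null(colnames(m))) {
    if ("_" %in% colnames(m)) {
      stop(sprintf("PSSM '%s': a '_' column is not allowed ('_' scores 1 by definition)", name))
    }
    if (!setequal(colnames(m), RESIDUE_ALPHABET)) {
      stop(sprintf("PSSM '%s': columns must be exactly the 23 residue symbols", name))
    }
    m <- m[, RESIDUE_ALPHABET, drop = FALSE]
  }
  if (!is.null(rownames(m))) {
    if (!setequal(rownames(m), POSITION_LABELS)) {
      stop(sprintf("PSSM '%s': rows must be labelled by positions -5..4", name))
    }
    m <- m[POSITION_LABELS, , drop = FALSE]
  }
  if (nrow(m) != PEPTIDE_WIDTH || ncol(m) != length(RESIDUE_ALPHABET)) {
    stop(sprintf("PSSM '%s': expected 10 position rows x 23 residue columns, got %d x %d",
                 name, nrow(m), ncol(m)))
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    stop(sprintf("PSSM '%s': entries must be finite and >= 0", name))
  }
  rownames(m) <- POSITION_LABELS
  colnames(m) <- RESIDUE_ALPHABET
  allowed <- if (kinase_class == "SerThr") c("S", "T") else "Y"
  centre <- m["0", ]
  if (any(centre[setdiff(RESIDUE_ALPHABET, allowed)] != 0)) {
    stop(sprintf(
      "PSSM '%s': class %s allows nonzero central-row entries only at %s",
      name, kinase_class, paste(allowed, collapse = "/")))
  }
  structure(list(name = name, kinase_class = kinase_class, matrix = m),
            class = "kinase_pssm")
}

#' @export
print.kinase_pssm <- function(x, ...) {
  cat(sprintf("Kinase PSSM '%s' (%s), 10 positions x 23 residues\n",
              x$name, x$kinase_class))
  invisible(x)
}

# Parse one PSSM block: a '#kinase <name> <class>' line, a residue header
# row, then 10 position-labelled data rows.
.parse_pssm_block <- function(lines, origin) {
  head_line <- lines[1L]
  if (!startsWith(head_line, "#kinase")) {
    stop("PSSM block in ", origin, " must start with '#kinase <name> <class>'")
  }
  fields <- strsplit(trimws(head_line), "\\s+")[[1L]]
  if (length(fields) != 3L) {
    stop("malformed PSSM block header in ", origin, ": ", head_line)
  }
  name <- fields[2L]; klass <- fields[3L]
  if (length(lines) != PEPTIDE_WIDTH + 2L) {
    stop(sprintf("PSSM '%s': expected %d data rows, found %d",
                 name, PEPTIDE_WIDTH, length(lines) - 2L))
  }
  header <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  symbols <- header[-1L]
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  ncols <- length(symbols) + 1L
  if (any(lengths(body) != ncols)) {
    stop(sprintf("PSSM '%s': ragged data rows", name))
  }
  m <- matrix(NA_real_, nrow = length(body), ncol = length(symbols),
              dimnames = list(vapply(body, `[`, "", 1L), symbols))
  for (r in seq_along(body)) m[r, ] <- as.numeric(body[[r]][-1L])
  if (anyNA(m)) stop(sprintf("PSSM '%s': non-numeric matrix entry", name))
  kinase_pssm(name, klass, m)
}

#' Read a set of kinase PSSMs
#'
#' Accepts either a single TSV file of blank-line-separated blocks, each
#' block being a `#kinase <name> <class>` header line, a residue-symbol
#' header row, and 10 position-labelled data rows; or a directory containing
#' one such file per kinase. Column order in the file is declared by its
#' header row and canonicalized on reading. Kinase names must be unique; the
#' returned list is sorted by name (C-locale order).
#'
#' @param path file or directory.
#' @return named list of [kinase_pssm()] objects.
#' @export
read_pssm_set <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    if (!length(files)) stop("no PSSM files in directory: ", path)
    lines <- unlist(lapply(files, function(f) c(readLines(f), "")))
  } else if (file.exists(path)) {
    lines <- readLines(path)
  } else {
    stop("PSSM path not found: ", path)
  }
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank)
  pssms <- lapply(split(lines[!blank], grp[!blank]), .parse_pssm_block,
                  origin = path)
  names(pssms) <- vapply(pssms, `[[`, "", "name")
  dup <- names(pssms)[duplicated(names(pssms))]
  if (length(dup)) stop("duplicate kinase name(s): ", paste(dup, collapse = ", "))
  pssms[sort(names(pssms), method = "radix")]
}

#' Write a set of kinase PSSMs in the block TSV dialect
#'
#' @param pssms named list of [kinase_pssm()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pssm_set <- function(pssms, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (p in pssms) {
    writeLines(sprintf("#kinase %s %s", p$name, p$kinase_class), con)
    writeLines(paste(c("pos", colnames(p$matrix)), collapse = "\t"), con)
    for (r in seq_len(nrow(p$matrix))) {
      writeLines(paste(c(rownames(p$matrix)[r],
                         sprintf("%.17g", p$matrix[r, ])), collapse = "\t"),
                 con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a background phosphopeptide list (one 10-mer per line)
#'
#' @param path text file with one peptide window per line; blank lines are
#'   ignored.
#' @param skip_invalid if `TRUE`, windows failing validation are dropped with
#'   a warning reporting their count instead of aborting.
#' @return character vector of validated windows.
#' @export
read_background <- function(path, skip_invalid = FALSE) {
  if (!file.exists(path)) stop("background file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("background file is empty: ", path)
  if (!skip_invalid) return(parse_peptide(lines))
  ok <- vapply(lines, function(x) {
    tryCatch({ parse_peptide(x); TRUE }, error = function(e) FALSE)
  }, NA)
  if (any(!ok)) {
    warning(sprintf("skipped %d invalid background peptide(s)", sum(!ok)))
  }
  if (!any(ok)) stop("no valid background peptides in ", path)
  lines[ok]
}
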