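#' Compute the background quantile table for one kinase
#'
#' Raw PSSM scores are computed for every background peptide; peptides with a
#' raw score of exactly 0 are discarded; the 10,000-quantiles of the
#' surviving score distribution are taken as calibration breakpoints.
#' Breakpoint `m` (m = 1..10000) is the nearest-rank empirical quantile at
#' probability m/10000, i.e. the sorted surviving score at index
#' `ceiling(m/10000 * n)`. Breakpoints are therefore members of the observed
#' score set, strictly positive, and non-decreasing.
#'
#' @param pssm a [kinase_pssm()].
#' @param background character vector of validated background peptide
#'   windows.
#' @return numeric vector of 10,000 sorted breakpoints.
#' @export
compute_quantile_table <- function(pssm, background) {
  if (!length(background)) stop("background peptide set is empty")
  raw <- raw_pssm_score(background, pssm)
  surv <- sort(raw[raw > 0])
  if (length(surv) < 2L) {
    stop(sprintf(
      "degenerate background for kinase '%s': %d peptide(s) with nonzero raw score (>= 2 required)",
      pssm$name, length(surv)))
  }
  n <- length(surv)
  idx <- ceiling(seq_len(N_QUANTILES) / N_QUANTILES * n)
  surv[pmin.int(pmax.int(idx, 1L), n)]
}

#' Compute quantile tables for a whole PSSM set
#'
#' @param pssms named list of [kinase_pssm()] objects.
#' @param background character vector of validated background windows.
#' @return named list of breakpoint vectors, parallel to `pssms`.
#' @export
compute_quantile_tables <- function(pssms, background) {
  out <- lapply(pssms, compute_quantile_table, background = background)
  names(out) <- names(pssms)
  out
}

#' Persist and reload per-kinase quantile tables
#'
#' The container is a single TSV with columns `kinase`, `m` (0..9999) and
#' `breakpoint`; a `.gz` path is compressed/decompressed transparently.
#' Breakpoints are written with 17 significant digits so that the round trip
#' is bit-exact.
#'
#' @param tables named list of 10,000-breakpoint vectors.
#' @param path output path (`.tsv` or `.tsv.gz`).
#' @return `path`, invisibly.
#' @export
write_quantile_tables <- function(tables, path) {
  kin <- rep(names(tables), each = N_QUANTILES)
  bp <- unlist(tables, use.names = FALSE)
  out <- data.frame(kinase = kin,
                    m = rep(0:(N_QUANTILES - 1L), times = length(tables)),
                    breakpoint = sprintf("%.17g", bp))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quantile_tables
#' @param kinases optional character vector restricting which kinases to
#'   load; requesting a kinase absent from the container is an error.
#' @return for `read_quantile_tables`: named list of breakpoint vectors.
#' @export
read_quantile_tables <- function(path, kinases = NULL) {
  if (!file.exists(path)) stop("quantile container not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer", "numeric"))
  if (!all(c("kinase", "m", "breakpoint") %in% names(tab))) {
    stop("quantile container must have columns kinase, m, breakpoint: ", path)
  }
  if (!is.null(kinases)) {
    missing <- setdiff(kinases, unique(tab$kinase))
    if (length(missing)) {
      stop("kinase(s) not present in quantile container: ",
           paste(missing, collapse = ", "))
    }
    tab <- tab[tab$kinase %in% kinases, , drop = FALSE]
  }
  ord <- order(tab$kinase, tab$m, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  tables <- split(tab$breakpoint, tab$kinase)
  for (k in names(tables)) {
    b <- tables[[k]]
    if (length(b) != N_QUANTILES) {
      stop(sprintf("truncated quantile table for kinase '%s': %d breakpoints (expected %d)",
                   k, length(b), N_QUANTILES))
    }
    if (anyNA(b) || any(b <= 0) || is.unsorted(b)) {
      stop(sprintf("corrupt quantile table for kinase '%s'", k))
    }
  }
  tables[sort(names(tables), method = "radix")]
}
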