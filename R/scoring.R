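#' Raw PSSM score of phosphopeptides against one kinase
#'
#' The raw score of a window is the product over its 10 positions of the
#' PSSM entry for the residue observed at that position. An undefined
#' position (`_`) contributes a factor of exactly 1; a lowercase priming
#' residue (`s`, `t`, `y`) selects its dedicated phospho-residue column. A
#' single zero entry annihilates the product, so any peptide carrying a
#' residue the kinase never accepts scores 0 — in particular, Ser/Thr
#' windows score 0 for Tyr kinases and vice versa.
#'
#' @param peptides character vector of validated 10-mer windows.
#' @param pssm a [kinase_pssm()].
#' @return numeric vector of nonnegative raw scores.
#' @export
raw_pssm_score <- function(peptides, pssm) {
  m <- pssm$matrix
  n <- length(peptides)
  ch <- matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
               nrow = PEPTIDE_WIDTH)
  sc <- rep(1, n)
  for (i in seq_len(PEPTIDE_WIDTH)) {
    j <- match(ch[i, ], RESIDUE_ALPHABET)  # NA for '_'
    f <- rep(1, n)
    def <- !is.na(j)
    f[def] <- m[i, j[def]]
    sc <- sc * f
  }
  sc
}

#' Quantile-calibrated PSSM score
#'
#' Maps a raw PSSM score onto `[0, 1]` as the fraction of the kinase's
#' 10,000 background breakpoints that are less than or equal to it. A raw
#' score of 0 maps to 0 (all breakpoints are positive); a raw score at or
#' above the largest breakpoint maps to 1.
#'
#' @param raw numeric vector of raw scores.
#' @param table breakpoint vector from [compute_quantile_table()].
#' @return numeric vector of scores in `[0, 1]`.
#' @export
quantile_score <- function(raw, table) {
  findInterval(raw, table) / length(table)
}

#' Assign each peptide of a profile to its top-scoring kinases
#'
#' For every peptide, kinases are ranked by quantile-calibrated score
#' (descending, ties broken by kinase name ascending); kinases for which the
#' peptide's raw score is 0 are excluded; the peptide's profile row index is
#' then added to the substrate set of the first `min(n, available)` kinases.
#' Ranking uses the calibrated rather than the raw score so that Ser/Thr and
#' Tyr kinases compete on a common `[0, 1]` scale.
#'
#' @param profile a [ranked_profile()].
#' @param pssms named list of [kinase_pssm()] objects.
#' @param tables named list of quantile tables covering every kinase in
#'   `pssms` (a missing table is a configuration error).
#' @param n number of top-scoring kinases each peptide is assigned to
#'   (default 10).
#' @return named list (one element per kinase, possibly empty) of 1-based
#'   row indices into `profile`; attribute `N` holds the profile size.
#' @export
assign_top_n <- function(profile, pssms, tables, n = 10L) {
  stopifnot(inherits(profile, "ranked_profile"), n >= 1L)
  kn <- sort(names(pssms), method = "radix")
  missing <- setdiff(kn, names(tables))
  if (length(missing)) {
    stop("no quantile table for kinase(s): ", paste(missing, collapse = ", "))
  }
  N <- nrow(profile)
  K <- length(kn)
  qs <- matrix(NA_real_, N, K)
  for (k in seq_len(K)) {
    raw <- raw_pssm_score(profile$peptide, pssms[[kn[k]]])
    qv <- quantile_score(raw, tables[[kn[k]]])
    qv[raw == 0] <- NA_real_  # ineligible: never a substrate
    qs[, k] <- qv
  }
  chosen <- vector("list", N)
  for (i in seq_len(N)) {
    v <- qs[i, ]
    ok <- which(!is.na(v))
    if (!length(ok)) next
    ord <- ok[order(-v[ok], ok)]  # score desc, then name asc (kn is sorted)
    chosen[[i]] <- ord[seq_len(min(n, length(ord)))]
  }
  ki <- unlist(chosen)
  ii <- rep.int(seq_len(N), lengths(chosen))
  asn <- split(ii, factor(ki, levels = seq_len(K)))
  names(asn) <- kn
  attr(asn, "N") <- N
  asn
}

#' Long-format peptide-by-kinase score table
#'
#' Diagnostic dump of raw scores, calibrated scores, and top-n assignment
#' membership for every peptide/kinase pair.
#'
#' @inheritParams assign_top_n
#' @return `data.frame` with columns `peptide`, `kinase`, `raw_score`,
#'   `quantile_score`, `assigned` (0/1).
#' @export
score_table <- function(profile, pssms, tables, n = 10L) {
  asn <- assign_top_n(profile, pssms, tables, n)
  kn <- names(asn)
  N <- nrow(profile)
  out <- vector("list", length(kn))
  for (k in seq_along(kn)) {
    raw <- raw_pssm_score(profile$peptide, pssms[[kn[k]]])
    out[[k]] <- data.frame(
      peptide = profile$peptide,
      kinase = kn[k],
      raw_score = raw,
      quantile_score = quantile_score(raw, tables[[kn[k]]]),
      assigned = as.integer(seq_len(N) %in% asn[[k]]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
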