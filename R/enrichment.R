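#' Weighted running-sum statistic over a ranked profile
#'
#' For a kinase with substrate set `C` (row indices into the ranked profile)
#' the running sum after rank `i` accumulates `|r_i| / N_R` when row `i` is
#' in `C` and `-1 / (N - N_h)` otherwise, where `N_R` is the sum of `|r|`
#' over the members, `N` the profile size and `N_h = |C|`. Because the
#' increments over the members total +1 and the decrements total -1, the
#' running sum always ends at 0; the enrichment signal is its maximum
#' excursion (see [enrichment_score()]).
#'
#' @param profile a [ranked_profile()].
#' @param members integer vector of 1-based member row indices; must satisfy
#'   `1 <= length(members) <= N - 1` and have positive total weight.
#' @return numeric vector of length `N`: the running sum after each rank.
#' @export
running_sum <- function(profile, members) {
  r <- profile$metric
  N <- length(r)
  members <- as.integer(members)
  if (anyNA(members) || any(members < 1L) || any(members > N) ||
      anyDuplicated(members)) {
    stop("members must be distinct row indices in 1..N")
  }
  n_h <- length(members)
  if (n_h < 1L || n_h > N - 1L) {
    stop(sprintf("need 1 <= N_h <= N-1; got N_h = %d with N = %d", n_h, N))
  }
  absr <- abs(r)
  NR <- sum(absr[members])
  if (NR <= 0) stop("all member metrics are zero (N_R = 0)")
  inc <- rep(-1 / (N - n_h), N)
  inc[members] <- absr[members] / NR
  # term-by-term accumulation in double precision (not cumsum's extended-
  # precision accumulator), so exact magnitude ties resolve reproducibly
  out <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- acc + inc[i]
    out[i] <- acc
  }
  out
}

#' Enrichment score: maximum deviation of the running sum from zero
#'
#' Returns the running-sum value of largest magnitude, sign preserved; when
#' several ranks tie in magnitude the earliest one wins.
#'
#' @param rs numeric running-sum vector (from [running_sum()]).
#' @return a single value in `[-1, 1]`.
#' @export
enrichment_score <- function(rs) {
  if (!length(rs)) stop("empty running sum")
  rs[which.max(abs(rs))]
}

# Enrichment scores for many member sets at once. idx is an n_h x B matrix
# of member indices, each column sorted ascending. Uses the fact that the
# extrema of the running sum occur at member ranks (after the increment) and
# immediately before member ranks (after the preceding decrement); the
# terminal value is always 0 and never exceeds those candidates in
# magnitude. The tie rule matches enrichment_score(): on equal magnitude the
# candidate at the earliest rank wins.
.es_for_member_sets <- function(absr, idx) {
  N <- length(absr)
  n_h <- nrow(idx)
  B <- ncol(idx)
  dec <- 1 / (N - n_h)
  A <- matrix(absr[idx], n_h, B)
  W <- A
  if (n_h > 1L) for (j in 2:n_h) W[j, ] <- W[j, ] + W[j - 1L, ]
  NR <- W[n_h, ]
  vmax <- rep(-Inf, B); imax <- rep(N + 1L, B)
  vmin <- rep(Inf, B); imin <- rep(N + 1L, B)
  for (j in seq_len(n_h)) {
    topj <- W[j, ] / NR - (idx[j, ] - j) * dec
    botj <- topj - A[j, ] / NR   # running sum at rank idx[j,] - 1
    bt <- topj > vmax            # strict: first maximal rank is kept
    vmax[bt] <- topj[bt]; imax[bt] <- idx[j, ][bt]
    bb <- botj < vmin
    vmin[bb] <- botj[bb]; imin[bb] <- idx[j, ][bb] - 1L
  }
  am <- abs(vmax); an <- abs(vmin)
  es <- ifelse(am > an, vmax,
               ifelse(an > am, vmin,
                      ifelse(imax <= imin, vmax, vmin)))
  es[NR == 0] <- 0  # all-zero-weight member set: no defined excursion
  es
}

#' Permutation null distribution of the enrichment score
#'
#' Draws `n_permutations` uniformly random substrate sets of size `n_h` from
#' the profile's ranks (metrics stay attached to their observed ranks, which
#' is equivalent to permuting the rank labels) and computes the enrichment
#' score of each. The null depends on the substrate set only through its
#' size, so kinases with equal `n_h` share a null; the RNG substream is
#' derived deterministically from `(seed, n_h)` so results are reproducible
#' and independent of the order in which kinases are processed. The caller's
#' RNG state is left untouched.
#'
#' @param profile a [ranked_profile()].
#' @param n_h substrate-set size, `1 <= n_h <= N - 1`.
#' @param n_permutations number of random sets to draw.
#' @param seed integer seed of the run.
#' @return numeric vector of `n_permutations` null enrichment scores.
#' @export
permutation_null <- function(profile, n_h, n_permutations, seed = 0L) {
  N <- nrow(profile)
  n_h <- as.integer(n_h)
  stopifnot(n_h >= 1L, n_h <= N - 1L, n_permutations >= 1L)
  absr <- abs(profile$metric)
  .with_seed(.substream(seed, n_h), {
    idx <- matrix(0L, n_h, n_permutations)
    for (b in seq_len(n_permutations)) {
      idx[, b] <- sort.int(sample.int(N, n_h))
    }
    .es_for_member_sets(absr, idx)
  })
}

#' Empirical permutation p-value of an observed enrichment score
#'
#' Two-sided on magnitude: the fraction of null enrichment scores whose
#' absolute value is at least `|es_observed|`, floored at
#' `1/n_permutations` — the smallest p-value the permutation scheme can
#' resolve.
#'
#' @param es_observed observed enrichment score.
#' @param null numeric vector of null enrichment scores.
#' @return p-value in `(0, 1]`.
#' @export
empirical_p <- function(es_observed, null) {
  if (!length(null)) stop("empty null distribution")
  max(sum(abs(null) >= abs(es_observed)), 1L) / length(null)
}

#' Bonferroni-corrected q-value
#'
#' @param p p-value in `(0, 1]`.
#' @param k_tested number of kinases independently tested.
#' @return `min(1, p * k_tested)`.
#' @export
bonferroni_q <- function(p, k_tested) {
  stopifnot(k_tested >= 1L)
  pmin(1, p * k_tested)
}

#' Signed kinase activity score
#'
#' `-log10(p)` carrying the sign of the enrichment score, capped at
#' `log10(n_permutations)` — the magnitude attained when the p-value sits at
#' the permutation floor. Positive values denote kinase activation, negative
#' values inhibition; a zero enrichment score gives activity 0.
#'
#' @param p empirical p-value in `(0, 1]`.
#' @param es observed enrichment score (sign carrier).
#' @param n_permutations permutation count that produced `p`.
#' @return signed activity score with `|activity| <= log10(n_permutations)`.
#' @export
activity_score <- function(p, es, n_permutations) {
  pmin(-log10(p), log10(n_permutations)) * sign(es)
}

#' Infer differential kinase activities from a ranked profile
#'
#' The full inference pipeline: peptides are assigned to their `n_top`
#' top-scoring kinases ([assign_top_n()]); each kinase's substrate set is
#' tested for enrichment at the extremes of the ranked profile via the
#' weighted running sum ([running_sum()], [enrichment_score()]); empirical
#' p-values come from a shared permutation null per substrate-set size
#' ([permutation_null()]); q-values are Bonferroni-corrected over the number
#' of kinases actually tested; activities are signed, capped `-log10(p)`
#' values ([activity_score()]).
#'
#' Kinases whose substrate set is degenerate (no substrates, all peptides as
#' substrates, or zero total member weight) are reported rather than
#' dropped, with `es = 0`, `p = 1`, `activity = 0` and a reason code, and do
#' not count towards the Bonferroni correction.
#'
#' @param profile a [ranked_profile()].
#' @param pssms named list of [kinase_pssm()] objects.
#' @param tables named list of quantile tables covering `pssms`.
#' @param n_top top-scoring kinases per peptide (default 10).
#' @param n_permutations permutation count (default 10,000; at least 10^4 is
#'   recommended so that Bonferroni-corrected values below 0.05 remain
#'   attainable for a few hundred kinases).
#' @param seed integer seed controlling every source of randomness.
#' @param verbose log a brief summary to standard error.
#' @return `data.frame` with one row per kinase: `kinase`, `n_substrates`,
#'   `es`, `p_value`, `q_value`, `activity`, `reason` (empty when tested),
#'   sorted by activity descending (ties by `es` descending, then kinase
#'   name). Attributes `n_permutations`, `seed`, `n_top` and `k_tested`
#'   record the run configuration.
#' @export
infer_activities <- function(profile, pssms, tables, n_top = 10L,
                             n_permutations = 10000L, seed = 0L,
                             verbose = FALSE) {
  stopifnot(inherits(profile, "ranked_profile"))
  if (nrow(profile) < 2L) stop("profile must contain at least 2 peptides")
  stopifnot(n_permutations >= 1L)
  asn <- assign_top_n(profile, pssms, tables, n_top)
  N <- nrow(profile)
  kn <- names(asn)
  K <- length(kn)
  n_h <- lengths(asn)
  absr <- abs(profile$metric)
  NR <- vapply(asn, function(m) sum(absr[m]), 0)

  reason <- character(K)
  reason[n_h == 0L] <- "no_substrates"
  reason[n_h == N] <- "all_substrates"
  reason[reason == "" & NR == 0] <- "zero_weight"
  tested <- which(reason == "")
  k_tested <- length(tested)

  es <- numeric(K)
  p <- rep(1, K)
  null_abs <- list()
  for (k in tested) {
    h <- as.character(n_h[k])
    if (is.null(null_abs[[h]])) {
      null_abs[[h]] <- abs(permutation_null(profile, n_h[k], n_permutations,
                                            seed))
    }
    es[k] <- enrichment_score(running_sum(profile, asn[[k]]))
    p[k] <- empirical_p(es[k], null_abs[[h]])
  }
  q <- rep(1, K)
  if (k_tested > 0L) q[tested] <- bonferroni_q(p[tested], k_tested)
  act <- activity_score(p, es, n_permutations)
  act[reason != ""] <- 0

  out <- data.frame(kinase = kn, n_substrates = as.integer(n_h), es = es,
                    p_value = p, q_value = q, activity = act,
                    reason = reason, stringsAsFactors = FALSE)
  ord <- order(-out$activity, -out$es, out$kinase, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_permutations") <- as.integer(n_permutations)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_top") <- as.integer(n_top)
  attr(out, "k_tested") <- k_tested
  if (verbose) {
    message(sprintf(
      "kinactive: N = %d peptides, %d/%d kinases tested (%d skipped), %d permutations, seed %d",
      N, k_tested, K, K - k_tested, n_permutations, seed))
    skipped <- out[out$reason != "", c("kinase", "reason")]
    if (nrow(skipped)) {
      message("skipped: ", paste(sprintf("%s (%s)", skipped$kinase,
                                         skipped$reason), collapse = ", "))
    }
  }
  out
}

#' Write / read a kinase result table as TSV
#'
#' Columns `kinase`, `n_substrates`, `es`, `p_value`, `q_value`, `activity`,
#' `reason`, sorted by activity descending; floating-point values are
#' printed with 6 significant digits.
#'
#' @param results result `data.frame` from [infer_activities()].
#' @param path output path.
#' @return `path` invisibly (write); the result `data.frame` (read).
#' @export
write_kinase_results <- function(results, path) {
  out <- results
  for (col in c("es", "p_value", "q_value", "activity")) {
    out[[col]] <- sprintf("%.6g", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinase_results
#' @export
read_kinase_results <- function(path) {
  if (!file.exists(path)) stop("result file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("kinase", "n_substrates", "es", "p_value", "q_value", "activity")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("result file lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"reason" %in% names(tab)) tab$reason <- ""
  tab$reason[is.na(tab$reason)] <- ""
  tab
}
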