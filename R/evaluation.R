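#' Min-max scale kinase activities to [0, 1]
#'
#' Subtracts the minimum activity and divides by the resulting maximum, so
#' the most inhibited kinase maps to 0 and the most activated to 1; the
#' ranking of kinases is preserved exactly. Used to compare activity values
#' across experiments on a common scale.
#'
#' @param results result `data.frame` from [infer_activities()] (or any
#'   frame with `kinase` and `activity` columns).
#' @return named numeric vector of scaled activities.
#' @export
scale_activities <- function(results) {
  a <- results$activity
  if (length(a) < 2L) stop("need at least 2 activity values to scale")
  rng <- max(a) - min(a)
  if (rng == 0) stop("degenerate scaling: all activity values are equal")
  stats::setNames((a - min(a)) / rng, results$kinase)
}

#' Linear separation of up- from down-regulated kinases
#'
#' AUROC via the rank (Mann-Whitney) formulation with ties counted one
#' half; AUPR via the non-interpolated step integral (average precision).
#' Up-regulated instances form the positive class.
#'
#' @param scores numeric vector of (scaled) activity scores, one per truth
#'   instance.
#' @param labels character vector of `"up"` / `"down"`, parallel to
#'   `scores`; both classes must be present.
#' @return list with elements `auroc` and `aupr`, both in `[0, 1]`.
#' @export
updown_separation <- function(scores, labels) {
  stopifnot(length(scores) == length(labels),
            all(labels %in% c("up", "down")))
  pos <- labels == "up"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both an up and a down instance are required")
  }
  rk <- rank(scores)  # average ranks: ties count 1/2
  auroc <- (sum(rk[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(-scores, seq_along(scores))  # stable, score descending
  hit <- pos[ord]
  prec <- cumsum(hit) / seq_along(hit)
  aupr <- sum(prec[hit]) / n_pos
  list(auroc = auroc, aupr = aupr)
}

#' Normalized rank of a truth kinase in the activity distribution
#'
#' Results are ordered by activity, descending for an up-regulated truth
#' kinase and ascending for a down-regulated one (ties broken by kinase
#' name for determinism); the truth kinase's zero-based rank is divided by
#' `K - 1`, so 0 is a perfect prediction and 1 the worst possible.
#'
#' @param results result `data.frame` with `kinase` and `activity` columns.
#' @param kinase truth kinase identifier (must be present).
#' @param direction `"up"` or `"down"`.
#' @return normalized rank in `[0, 1]`.
#' @export
normalized_rank <- function(results, kinase, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!kinase %in% results$kinase) stop("kinase not in results: ", kinase)
  K <- nrow(results)
  if (K < 2L) stop("need at least 2 kinases to rank")
  a <- if (direction == "up") -results$activity else results$activity
  ord <- order(a, results$kinase, method = "radix")
  (match(kinase, results$kinase[ord]) - 1) / (K - 1)
}

#' Recovery of truth kinases at the extremes of the activity distribution
#'
#' An up-regulated truth instance counts as recovered when its activity is
#' at or above the (1 - width) nearest-rank percentile of that experiment's
#' activity distribution (default: the 95th percentile, i.e. the top-5
#' percentile band); a down-regulated instance when it is at or below the
#' width percentile. Fractions are pooled over all truth instances of all
#' experiments.
#'
#' @param experiments list of experiments, each a list with `results` (a
#'   result `data.frame`) and `truth` (`data.frame` with `kinase`,
#'   `direction`).
#' @param width percentile band width as a fraction (default 0.05).
#' @return list with `up` and `down` recovery fractions (`NaN` when a
#'   direction has no truth instance).
#' @export
percentile_recovery <- function(experiments, width = 0.05) {
  stopifnot(length(experiments) >= 1L, width > 0, width < 1)
  n_up <- 0L; hit_up <- 0L; n_dn <- 0L; hit_dn <- 0L
  for (ex in experiments) {
    a <- ex$results$activity
    K <- length(a)
    s <- sort(a)
    hi <- s[min(K, max(1L, ceiling((1 - width) * K)))]
    lo <- s[min(K, max(1L, ceiling(width * K)))]
    for (j in seq_len(nrow(ex$truth))) {
      k <- ex$truth$kinase[j]
      av <- ex$results$activity[match(k, ex$results$kinase)]
      if (is.na(av)) stop("truth kinase not in results: ", k)
      if (ex$truth$direction[j] == "up") {
        n_up <- n_up + 1L
        if (av >= hi) hit_up <- hit_up + 1L
      } else {
        n_dn <- n_dn + 1L
        if (av <= lo) hit_dn <- hit_dn + 1L
      }
    }
  }
  list(up = if (n_up) hit_up / n_up else NaN,
       down = if (n_dn) hit_dn / n_dn else NaN)
}
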