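#' Construct a ranked phosphopeptide profile
#'
#' A ranked profile pairs validated phosphopeptide windows with a real-valued
#' ranking metric (typically the log2 fold change of the peptide's intensity)
#' and orders rows by the metric, descending, so that row 1 carries the
#' highest value. Ties keep their input order (stable sort), and duplicate
#' sequences are retained as independent quantifications — no aggregation is
#' performed.
#'
#' @param peptides character vector of 10-mer windows (validated via
#'   [parse_peptide()]).
#' @param metrics numeric vector of finite ranking-metric values, parallel to
#'   `peptides`.
#' @return a `ranked_profile`: a `data.frame` with columns `peptide` and
#'   `metric`, sorted by `metric` descending.
#' @export
ranked_profile <- function(peptides, metrics) {
  peptides <- parse_peptide(peptides)
  metrics <- as.numeric(metrics)
  if (length(peptides) != length(metrics)) {
    stop("peptides and metrics must have the same length")
  }
  if (length(metrics) < 1L) stop("empty profile")
  if (any(!is.finite(metrics))) stop("ranking metric must be finite")
  ord <- order(metrics, decreasing = TRUE, method = "radix")  # stable
  out <- data.frame(peptide = peptides[ord], metric = metrics[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_profile", "data.frame")
  out
}

#' Read a ranked phosphopeptide profile from a TSV file
#'
#' The file must be tab-separated with a header row; the decimal separator is
#' `.`. Rows are sorted by the metric, descending, after reading. A
#' non-numeric (including `NaN`/empty) metric entry is a parse error that
#' reports the offending line.
#'
#' @param path path to the TSV file.
#' @param sequence_column,metric_column column names holding the 10-mer
#'   window and the ranking metric (defaults `"peptide"` and `"log2fc"`).
#' @return a [ranked_profile()].
#' @export
read_ranked_profile <- function(path, sequence_column = "peptide",
                                metric_column = "log2fc") {
  if (!file.exists(path)) stop("profile file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  for (col in c(sequence_column, metric_column)) {
    if (!col %in% names(tab)) {
      stop(sprintf("column '%s' not found in %s", col, path))
    }
  }
  if (nrow(tab) == 0L) stop("profile file has zero data rows: ", path)
  raw <- tab[[metric_column]]
  val <- suppressWarnings(as.numeric(raw))
  bad <- !is.finite(val)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("non-numeric ranking metric '%s' at line %d of %s",
                 raw[i], i + 1L, path))
  }
  ranked_profile(tab[[sequence_column]], val)
}

#' Write a ranked profile to a TSV file
#'
#' @param profile a [ranked_profile()].
#' @param path output path.
#' @param sequence_column,metric_column column names to write.
#' @return `path`, invisibly.
#' @export
write_ranked_profile <- function(profile, path, sequence_column = "peptide",
                                 metric_column = "log2fc") {
  out <- data.frame(a = profile$peptide,
                    b = sprintf("%.17g", profile$metric))
  names(out) <- c(sequence_column, metric_column)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.ranked_profile <- function(x, ...) {
  cat(sprintf("Ranked phosphopeptide profile: %d peptides, metric in [%.4g, %.4g]\n",
              nrow(x), min(x$metric), max(x$metric)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
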