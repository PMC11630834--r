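#' Generate a synthetic set of kinase PSSMs
#'
#' Each non-central position row is drawn from a symmetric Dirichlet over
#' the 23 residue symbols and rescaled to mean 1, so that raw scores of
#' random peptides are centred on a common scale across kinases. The central
#' row is nonzero only at the class-allowed residues (S/T for Ser/Thr
#' kinases, Y for Tyr kinases), with the nonzero entries again Dirichlet
#' drawn and rescaled to mean 1 over the allowed set. Large `concentration`
#' values give near-uniform rows (weakly specific kinases); small values
#' give spiky, highly specific motifs.
#'
#' @param k_serthr,k_tyr number of Ser/Thr and Tyr kinases (named
#'   `STKnnn` / `TYRnnn`).
#' @param concentration Dirichlet concentration parameter (> 0, default 1).
#' @param seed integer seed; generation is a pure function of the arguments.
#' @return named list of [kinase_pssm()] objects, sorted by name.
#' @export
make_pssm_set <- function(k_serthr, k_tyr, concentration = 1, seed = 0L) {
  stopifnot(k_serthr >= 0L, k_tyr >= 0L, k_serthr + k_tyr >= 1L,
            concentration > 0)
  nsym <- length(RESIDUE_ALPHABET)
  draw_row <- function(d) {
    g <- stats::rgamma(d, shape = concentration)
    g / sum(g) * d  # Dirichlet rescaled to mean 1
  }
  make_one <- function(name, klass) {
    m <- matrix(0, PEPTIDE_WIDTH, nsym,
                dimnames = list(POSITION_LABELS, RESIDUE_ALPHABET))
    for (i in seq_len(PEPTIDE_WIDTH)) {
      if (i == CENTER_INDEX) {
        allowed <- if (klass == "SerThr") c("S", "T") else "Y"
        m[i, allowed] <- draw_row(length(allowed))
      } else {
        m[i, ] <- draw_row(nsym)
      }
    }
    kinase_pssm(name, klass, m)
  }
  .with_seed(.substream(seed, 1L), {
    pssms <- c(
      lapply(seq_len(k_serthr), function(i)
        make_one(sprintf("STK%03d", i), "SerThr")),
      lapply(seq_len(k_tyr), function(i)
        make_one(sprintf("TYR%03d", i), "Tyr")))
    names(pssms) <- vapply(pssms, `[[`, "", "name")
    pssms[sort(names(pssms), method = "radix")]
  })
}

#' Generate a synthetic background phosphopeptide set
#'
#' Windows have a uniformly random central residue among S/T/Y; the nine
#' flanking positions are uniform over the 20 standard amino acids, each
#' independently replaced by a uniformly chosen lowercase phospho-priming
#' residue (s/t/y) with probability `phospho_priming_rate`. No `_` symbols
#' are generated: the background emulates fully defined proteome-wide
#' windows.
#'
#' @param size number of peptides (>= 1).
#' @param seed integer seed.
#' @param phospho_priming_rate per-position probability of a priming
#'   residue, in `[0, 1)` (default 0.05).
#' @return character vector of `size` validated windows.
#' @export
make_background <- function(size, seed = 0L, phospho_priming_rate = 0.05) {
  stopifnot(size >= 1L, phospho_priming_rate >= 0,
            phospho_priming_rate < 1)
  .with_seed(.substream(seed, 2L), {
    ch <- matrix("", PEPTIDE_WIDTH, size)
    flank <- setdiff(seq_len(PEPTIDE_WIDTH), CENTER_INDEX)
    ch[flank, ] <- sample(AA_STANDARD, 9L * size, replace = TRUE)
    if (phospho_priming_rate > 0) {
      prim <- which(stats::runif(9L * size) < phospho_priming_rate)
      if (length(prim)) {
        sub <- sample(c("s", "t", "y"), length(prim), replace = TRUE)
        flat <- ch[flank, , drop = FALSE]
        flat[prim] <- sub
        ch[flank, ] <- flat
      }
    }
    ch[CENTER_INDEX, ] <- sample(CENTER_RESIDUES, size, replace = TRUE)
    parse_peptide(apply(ch, 2L, paste0, collapse = ""))
  })
}

#' Generate a synthetic experiment with planted kinase regulation
#'
#' Samples `n_peptides` windows as in [make_background()], assigns each an
#' i.i.d. Normal(0, `noise_sd`) baseline metric, then shifts the metric of
#' every peptide whose quantile score for a planted kinase is at least
#' `score_threshold` by `+effect_size` (direction `"up"`) or `-effect_size`
#' (direction `"down"`). Planting acts on quantile-score-selected peptides
#' rather than on the top-n assignment, so the planted signal is defined
#' independently of the inference parameter `n`. If a planted kinase has no
#' peptide above the threshold the sample is regenerated (with a warning) up
#' to `max_retries` times, then an error is raised.
#'
#' @param pssms named list of [kinase_pssm()] objects.
#' @param tables quantile tables covering `pssms`.
#' @param planted `data.frame` with columns `kinase` and `direction`
#'   (`"up"`/`"down"`); every kinase must exist in `pssms`.
#' @param n_peptides profile size (>= 20).
#' @param effect_size additive metric shift applied to planted-target
#'   peptides, in metric units.
#' @param noise_sd standard deviation of the baseline metric (default 1).
#' @param seed integer seed; the experiment is a pure function of its
#'   arguments.
#' @param score_threshold quantile-score cutoff defining a planted kinase's
#'   targets (default 0.95).
#' @param phospho_priming_rate passed to the peptide sampler.
#' @param max_retries resampling attempts when a planted kinase has no
#'   target in the sample.
#' @return a `synthetic_experiment`: list with `profile`
#'   (a [ranked_profile()]), `truth` (the `planted` table) and `params`.
#' @export
make_experiment <- function(pssms, tables, planted, n_peptides, effect_size,
                            noise_sd = 1, seed = 0L, score_threshold = 0.95,
                            phospho_priming_rate = 0.05, max_retries = 5L) {
  stopifnot(is.data.frame(planted),
            all(c("kinase", "direction") %in% names(planted)),
            all(planted$direction %in% c("up", "down")),
            n_peptides >= 20L, effect_size >= 0, noise_sd > 0)
  missing <- setdiff(planted$kinase, names(pssms))
  if (length(missing)) {
    stop("planted kinase(s) absent from PSSM set: ",
         paste(missing, collapse = ", "))
  }
  for (attempt in 0:max_retries) {
    pepseed <- .substream(seed, 100L + attempt)
    peps <- make_background(n_peptides, seed = pepseed,
                            phospho_priming_rate = phospho_priming_rate)
    hits <- lapply(planted$kinase, function(k) {
      raw <- raw_pssm_score(peps, pssms[[k]])
      which(quantile_score(raw, tables[[k]]) >= score_threshold)
    })
    if (all(lengths(hits) > 0L)) break
    if (attempt == max_retries) {
      stop("planted kinase(s) had no peptide above the score threshold ",
           "after ", max_retries + 1L, " sampling attempts")
    }
    warning("planted kinase without high-scoring peptides; resampling")
  }
  metric <- .with_seed(.substream(seed, 200L + attempt),
                       stats::rnorm(n_peptides, 0, noise_sd))
  for (j in seq_len(nrow(planted))) {
    shift <- if (planted$direction[j] == "up") effect_size else -effect_size
    metric[hits[[j]]] <- metric[hits[[j]]] + shift
  }
  structure(list(
    profile = ranked_profile(peps, metric),
    truth = planted,
    params = list(n_peptides = n_peptides, effect_size = effect_size,
                  noise_sd = noise_sd, seed = seed,
                  score_threshold = score_threshold,
                  phospho_priming_rate = phospho_priming_rate)),
    class = "synthetic_experiment")
}
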