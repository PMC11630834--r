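# Shared fixtures and independent oracles for the test suite.

ALPHA23 <- kinactive:::RESIDUE_ALPHABET
POSLAB <- kinactive:::POSITION_LABELS

# A PSSM with every usable entry equal to `value` (center row restricted to
# the class-allowed residues). Entries can then be overridden pointwise.
flat_pssm <- function(name = "KIN1", klass = "SerThr", value = 1,
                      overrides = list()) {
  m <- matrix(value, 10, 23, dimnames = list(POSLAB, ALPHA23))
  m["0", ] <- 0
  if (klass == "SerThr") m["0", c("S", "T")] <- value else m["0", "Y"] <- value
  for (ov in overrides) m[ov$pos, ov$res] <- ov$value  # ov: pos label, res, value
  kinase_pssm(name, klass, m)
}

# Term-by-term running-sum oracle: accumulates the statistic one rank at a
# time and tracks the first maximal deviation from zero.
oracle_es <- function(metrics, members) {
  N <- length(metrics)
  n_h <- length(members)
  NR <- sum(abs(metrics[members]))
  rs <- 0
  best <- 0
  best_abs <- -Inf
  for (i in seq_len(N)) {
    rs <- rs + if (i %in% members) abs(metrics[i]) / NR else -1 / (N - n_h)
    if (abs(rs) > best_abs) {
      best_abs <- abs(rs)
      best <- rs
    }
  }
  best
}

# Profile with prescribed (already descending) metrics over valid peptides.
metric_profile <- function(metrics, seed = 99) {
  ranked_profile(make_background(length(metrics), seed = seed), metrics)
}

# All member subsets of {1..N} with 1 <= size <= N-1.
proper_subsets <- function(N) {
  out <- list()
  for (h in 1:(N - 1)) {
    out <- c(out, combn(N, h, simplify = FALSE))
  }
  out
}
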