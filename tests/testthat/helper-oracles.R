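# Independent oracles and small fixture builders used across the suite.

# Brute-force mean-volume oracle: explicit substring schedule, per-substring
# mean, written independently of mv_spectrum's cumulative-sum path.
mv_oracle <- function(sequence, k) {
  n <- nchar(sequence)
  subs <- character(0)
  for (len in seq_len(k - 1)) subs <- c(subs, substr(sequence, 1, len))
  for (s in seq_len(n - k + 1)) subs <- c(subs, substr(sequence, s, s + k - 1))
  for (len in rev(seq_len(k - 1))) subs <- c(subs, substr(sequence, n - len + 1, n))
  vapply(subs, function(w) {
    r <- strsplit(w, "")[[1]]
    mean(aa_volume(r))
  }, numeric(1), USE.NAMES = FALSE)
}

# Independent coefficient-of-determination arithmetic.
r2_oracle <- function(obs, pred) {
  resid <- obs - pred
  dev <- obs - sum(obs) / length(obs)
  1 - crossprod(resid)[1, 1] / crossprod(dev)[1, 1]
}

# Four residues spanning the four volume groups, for exhaustive enumeration.
TEST_ALPHABET <- c("G", "D", "L", "W")

# All sequences of a given length over an alphabet.
all_sequences <- function(len, alphabet) {
  grid <- do.call(expand.grid, rep(list(alphabet), len))
  apply(as.matrix(grid), 1, paste, collapse = "")
}

# A nanospectrum carrying an explicit value series.
spec_of <- function(values, duration_ms = 5, id = "fix") {
  nanospectrum(values, duration_ms, source_id = id)
}

# Training pairs labelled by a known response function of the window.
labelled_pairs <- function(sequence, fn, k = 4) {
  wins <- protein_windows(sequence, k = k, pad = TRUE)
  data.frame(kmer = wins, signal = znormalize(vapply(wins, fn, numeric(1))),
             stringsAsFactors = FALSE)
}

# Mean volume / mean hydrophilicity of a (possibly padded) k-mer, averaged
# over the residues actually present (the MV edge convention).
window_mean_volume <- function(kmer) {
  r <- strsplit(kmer, "")[[1]]
  mean(aa_volume(r[r != "-"]))
}
window_mean_hydro <- function(kmer) {
  r <- strsplit(kmer, "")[[1]]
  mean(aa_hydrophilicity(r[r != "-"]))
}
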