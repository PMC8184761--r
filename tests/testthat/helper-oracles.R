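# Independent oracles used across tests. These deliberately avoid the
# package's fast paths: the brute-force annotator checks every peak against
# every theoretical ion, and the edit-distance oracle is a plain DP.

# O(peaks x ions) annotation: for each theoretical ion, scan all peaks.
brute_force_annotate <- function(spectrum, pep, tol_ppm = 25, tol_da = 0.4) {
  n <- nchar(pep$sequence)
  fm <- respectra:::empty_fragment_matrix(n, pep$charge)
  max_z <- min(3L, pep$charge)
  for (ion in c("b", "y")) {
    for (z in seq_len(max_z)) {
      for (pos in seq_len(min(n - 1L, 29L))) {
        mz <- fragment_mz(pep, ion, pos, z)
        tol <- if (spectrum$analyzer == "FTMS") mz * tol_ppm * 1e-6 else tol_da
        hits <- which(abs(spectrum$mz - mz) <= tol)
        if (length(hits) > 0) {
          err <- abs(spectrum$mz[hits] - mz)
          best <- hits[order(-spectrum$intensity[hits], err)][1]
          fm$values[pos, ion, z] <- spectrum$intensity[best]
        }
      }
    }
  }
  base_peak_normalize(fm)
}

# Classic O(nm) dynamic-programming edit distance.
dp_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  D <- matrix(0L, length(x) + 1L, length(y) + 1L)
  D[, 1] <- 0:length(x)
  D[1, ] <- 0:length(y)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      D[i + 1, j + 1] <- min(
        D[i, j + 1] + 1L, D[i + 1, j] + 1L,
        D[i, j] + (x[i] != y[j])
      )
    }
  }
  D[length(x) + 1L, length(y) + 1L]
}

# A quiet simulated dataset wrapper used by several files.
noiseless_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, ppm_sigma = 0, noise_rate = 0, intensity_sigma = 0, ...)
}

random_sequences <- function(n, len_range = c(7L, 15L), seed = 1L) {
  set.seed(seed)
  aa <- names(respectra::mass_constants$residues)
  vapply(seq_len(n), function(i) {
    len <- len_range[1] + sample.int(len_range[2] - len_range[1] + 1L, 1L) - 1L
    paste(sample(aa, len, replace = TRUE), collapse = "")
  }, "")
}
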