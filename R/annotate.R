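#' Annotate a spectrum with theoretical b/y ions
#'
#' Matches the theoretical b/y fragment ladder of a peptide (fragment charges
#' 1..3, capped at the precursor charge) against the observed peak list and
#' fills the masked fragment-intensity tensor. Matching tolerance is 25 ppm
#' for FTMS spectra and 0.4 Da for ITMS. When several peaks fall within
#' tolerance of one theoretical ion the most intense is taken, ties broken by
#' smallest mass error; one observed peak may serve several theoretical ions.
#' The result is base-peak normalized.
#'
#' @param spectrum A `raw_spectrum` (peaks sorted ascending).
#' @param peptide A `peptide`.
#' @param tol_ppm FTMS tolerance in ppm (default 25).
#' @param tol_da ITMS tolerance in Da (default 0.4).
#' @return A `fragment_matrix` with attribute `stats`: tibble with
#'   `n_matched`, `n_matched_b`, `n_matched_y`, `frac_tic_annotated`,
#'   `n_theoretical`.
#' @export
annotate <- function(spectrum, peptide, tol_ppm = 25, tol_da = 0.4) {
  n <- nchar(peptide$sequence)
  if (n > 30L) stop("peptide longer than 30 residues", call. = FALSE)
  fm <- empty_fragment_matrix(n, peptide$charge)
  theo <- theoretical_ions(peptide)

  matched_int <- numeric(nrow(theo))
  matched <- logical(nrow(theo))
  used_peaks <- integer()
  for (k in seq_len(nrow(theo))) {
    tol <- if (spectrum$analyzer == "FTMS") {
      theo$mz[k] * tol_ppm * 1e-6
    } else {
      tol_da
    }
    lo <- findInterval(theo$mz[k] - tol, spectrum$mz)
    hi <- findInterval(theo$mz[k] + tol, spectrum$mz)
    if (hi > lo) {
      idx <- (lo + 1L):hi
      err <- abs(spectrum$mz[idx] - theo$mz[k])
      best <- idx[order(-spectrum$intensity[idx], err)][1]
      matched[k] <- TRUE
      matched_int[k] <- spectrum$intensity[best]
      used_peaks <- c(used_peaks, best)
    }
  }
  for (k in which(matched)) {
    fm$values[theo$position[k], theo$ion[k], theo$charge[k]] <- matched_int[k]
  }
  fm <- base_peak_normalize(fm)
  tic <- sum(spectrum$intensity)
  attr(fm, "stats") <- tibble::tibble(
    n_matched = sum(matched),
    n_matched_b = sum(matched & theo$ion == "b"),
    n_matched_y = sum(matched & theo$ion == "y"),
    frac_tic_annotated = if (tic > 0) {
      sum(spectrum$intensity[unique(used_peaks)]) / tic
    } else {
      0
    },
    n_theoretical = nrow(theo)
  )
  fm
}

# All theoretical b/y ions of a peptide within the tensor domain.
theoretical_ions <- function(peptide) {
  n <- nchar(peptide$sequence)
  max_z <- min(3L, peptide$charge)
  grid <- expand.grid(
    position = seq_len(min(n - 1L, 29L)),
    ion = c("b", "y"),
    charge = seq_len(max_z),
    stringsAsFactors = FALSE
  )
  grid$mz <- NA_real_
  for (ion in c("b", "y")) {
    for (z in seq_len(max_z)) {
      sel <- grid$ion == ion & grid$charge == z
      grid$mz[sel] <- fragment_mz(peptide, ion, grid$position[sel], z)
    }
  }
  tibble::as_tibble(grid)
}
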