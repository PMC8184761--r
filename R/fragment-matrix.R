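#' The masked fragment-intensity tensor
#'
#' Fragment intensities live in a fixed 29 x 2 x 3 tensor indexed by fragment
#' position (1..29), ion series (b, y) and fragment charge (1..3). Entries that
#' cannot exist for a given peptide — positions at or beyond the peptide length,
#' or fragment charges above the precursor charge — are masked with the
#' sentinel value -1. Valid entries are relative intensities in [0, 1] after
#' base-peak normalization.
#'
#' The flattened 174-vector layout is position-major with ion b before y and
#' charge ascending fastest: (pos1 b1, pos1 b2, pos1 b3, pos1 y1, ..., pos29 y3).
#' This layout is part of the file contract for prediction vectors.
#'
#' @param values Numeric array `c(29, 2, 3)` or flat length-174 vector in the
#'   contract layout.
#' @param length Peptide length (7..30).
#' @param charge Precursor charge (1..6).
#' @return Object of class `fragment_matrix`.
#' @export
fragment_matrix <- function(values, length, charge) {
  if (is.null(dim(values))) {
    stopifnot(base::length(values) == 174L)
    values <- unflatten_fragment_values(values)
  }
  stopifnot(identical(dim(values), c(29L, 2L, 3L)))
  dimnames(values) <- list(NULL, c("b", "y"), NULL)
  structure(
    list(values = values, length = as.integer(length),
         charge = as.integer(charge)),
    class = "fragment_matrix"
  )
}

#' @export
print.fragment_matrix <- function(x, ...) {
  v <- valid_values(x)
  cat("<fragment_matrix> length ", x$length, ", precursor ", x$charge,
    "+, ", sum(fragment_mask(x$length, x$charge)), " valid dims, ",
    sum(v > 0), " nonzero\n",
    sep = ""
  )
  invisible(x)
}

# Logical 29 x 2 x 3 mask: TRUE where the dimension is valid for the peptide.
fragment_mask <- function(length, charge) {
  pos_ok <- seq_len(29L) < length
  chg_ok <- seq_len(3L) <= charge
  outer(outer(pos_ok, rep(TRUE, 2L), "&"), chg_ok, "&")
}

#' Number of valid (unmasked) tensor dimensions
#'
#' @param length Peptide length, 7..30.
#' @param precursor_charge Precursor charge.
#' @return `min(length - 1, 29) * 2 * min(3, precursor_charge)`.
#' @examples
#' valid_dimension_count(10, 2) # 36
#' @export
valid_dimension_count <- function(length, precursor_charge) {
  stopifnot(length >= 7L, length <= 30L)
  as.integer(min(length - 1L, 29L) * 2L * min(3L, precursor_charge))
}

# Build an empty (all-zero valid, -1 masked) tensor.
empty_fragment_matrix <- function(length, charge) {
  v <- array(-1, dim = c(29L, 2L, 3L))
  v[fragment_mask(length, charge)] <- 0
  fragment_matrix(v, length, charge)
}

valid_values <- function(fm) fm$values[fragment_mask(fm$length, fm$charge)]

#' Flatten a fragment matrix to the contract 174-vector
#' @param fm A `fragment_matrix`.
#' @return Numeric length-174 vector, masked entries -1.
#' @export
flatten_fragment_matrix <- function(fm) {
  # contract layout: position-major, ion b before y, charge fastest
  as.vector(aperm(fm$values, c(3L, 2L, 1L)))
}

unflatten_fragment_values <- function(flat) {
  aperm(array(flat, dim = c(3L, 2L, 29L)), c(3L, 2L, 1L))
}

#' Base-peak normalize a fragment matrix
#'
#' Divides all valid entries by the maximum valid entry so the base peak is 1.
#' An all-zero matrix is returned unchanged with attribute
#' `no_matched_fragments = TRUE`. Idempotent.
#'
#' @param fm A `fragment_matrix` with non-negative valid entries.
#' @return Normalized `fragment_matrix`.
#' @export
base_peak_normalize <- function(fm) {
  mask <- fragment_mask(fm$length, fm$charge)
  v <- fm$values[mask]
  top <- max(v)
  if (top <= 0) {
    attr(fm, "no_matched_fragments") <- TRUE
    return(fm)
  }
  fm$values[mask] <- v / top
  fm
}

#' Tidy a fragment matrix into a long tibble
#'
#' One row per valid dimension with its theoretical m/z; the TSV-dump format
#' of annotated or predicted matrices.
#'
#' @param x A `fragment_matrix`.
#' @param peptide Optional `peptide` used to add the theoretical `mz` column.
#' @param ... Unused.
#' @return Tibble with columns `position`, `ion`, `charge`, (`mz`,) `intensity`.
#' @export
tidy.fragment_matrix <- function(x, peptide = NULL, ...) {
  mask <- fragment_mask(x$length, x$charge)
  idx <- which(mask, arr.ind = TRUE)
  out <- tibble::tibble(
    position = as.integer(idx[, 1]),
    ion = c("b", "y")[idx[, 2]],
    charge = as.integer(idx[, 3]),
    intensity = x$values[mask]
  )
  out <- dplyr::arrange(out, .data$position, .data$ion, .data$charge)
  if (!is.null(peptide)) {
    out <- dplyr::mutate(out,
      mz = fragment_mz_rowwise(peptide, .data$ion, .data$position, .data$charge),
      .before = "intensity"
    )
  }
  out
}

fragment_mz_rowwise <- function(p, ion, index, charge) {
  purrr::pmap_dbl(
    list(ion, index, charge),
    function(i, x, z) fragment_mz(p, i, x, z)
  )
}
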