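#' Build a position weight matrix from equal-length peptides
#'
#' Column `j` holds the relative frequency of each amino acid at position
#' `j`: `(count + pseudocount) / (n + 20 * pseudocount)`. Every column sums
#' to 1.
#'
#' @param peptides Character vector of sequences, all the same length.
#' @param pseudocount Added to every cell before normalization (default 0 for
#'   motif display; emission scoring uses 0.5 to avoid hard zeros).
#' @return Object of class `pwm`: 20 x L column-stochastic `matrix`, `length`,
#'   `n_peptides`, `pseudocount`.
#' @export
build_pwm <- function(peptides, pseudocount = 0) {
  stopifnot(length(peptides) >= 1L)
  L <- unique(nchar(peptides))
  if (length(L) != 1L) {
    stop("peptides must all have the same length; got lengths ",
      paste(sort(L), collapse = ", "),
      call. = FALSE
    )
  }
  aa <- names(mass_constants$residues)
  chars <- do.call(rbind, strsplit(peptides, ""))
  M <- vapply(seq_len(L), function(j) {
    tab <- table(factor(chars[, j], levels = aa))
    (as.numeric(tab) + pseudocount) / (length(peptides) + 20 * pseudocount)
  }, numeric(20))
  rownames(M) <- aa
  structure(
    list(
      matrix = M, length = L, n_peptides = length(peptides),
      pseudocount = pseudocount
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  consensus <- paste(
    rownames(x$matrix)[apply(x$matrix, 2, which.max)],
    collapse = ""
  )
  cat("<pwm> length ", x$length, ", ", x$n_peptides,
    " peptides, consensus ", consensus, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.pwm <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$matrix,
    responseName = "frequency",
    stringsAsFactors = FALSE
  )) |>
    dplyr::transmute(
      residue = .data$Var1,
      position = as.integer(factor(.data$Var2, levels = unique(.data$Var2))),
      frequency = .data$frequency
    )
}

#' Motif emission probability of peptides
#'
#' Scores how well peptides fit length-matched motifs: positions of the PWM
#' are ranked by their maximum frequency in decreasing order (high maxima
#' mark anchor positions), and the peptide's residue frequencies at the
#' `top_k` top-ranked positions are summed. Peptides whose length has no PWM
#' are skipped and counted. Scores lie in `[0, top_k]`.
#'
#' @param peptides Character vector.
#' @param pwms_by_length Named list of `pwm` objects, names = lengths (e.g.
#'   `list("9" = pwm9)`).
#' @param top_k Number of most-diverging positions to sum (default 5).
#' @return Tibble with `peptide`, `length`, `emission`; skipped peptides get
#'   `NA` emission. The `n_skipped` attribute counts them.
#' @export
emission_probability <- function(peptides, pwms_by_length, top_k = 5L) {
  if (inherits(pwms_by_length, "pwm")) {
    pwms_by_length <- setNames(
      list(pwms_by_length),
      as.character(pwms_by_length$length)
    )
  }
  lens <- nchar(peptides)
  emission <- vapply(seq_along(peptides), function(i) {
    pwm <- pwms_by_length[[as.character(lens[i])]]
    if (is.null(pwm)) {
      return(NA_real_)
    }
    colmax <- apply(pwm$matrix, 2, max)
    top <- order(colmax, decreasing = TRUE)[seq_len(min(top_k, pwm$length))]
    res <- strsplit(peptides[i], "")[[1]]
    sum(pwm$matrix[cbind(match(res[top], rownames(pwm$matrix)), top)])
  }, numeric(1))
  out <- tibble::tibble(peptide = peptides, length = lens, emission = emission)
  attr(out, "n_skipped") <- sum(is.na(emission))
  out
}

#' Jensen-Shannon divergence between two motifs
#'
#' The mean over positions of the base-2 Jensen-Shannon divergence between
#' the corresponding PWM columns: 0 iff the motifs are identical, 1 when
#' every position pair has disjoint support. Symmetric.
#'
#' @param pwm_a,pwm_b `pwm` objects of equal length.
#' @return Divergence in `[0, 1]`.
#' @export
js_divergence <- function(pwm_a, pwm_b) {
  if (pwm_a$length != pwm_b$length) {
    stop("PWM lengths differ (", pwm_a$length, " vs ", pwm_b$length, ")",
      call. = FALSE
    )
  }
  per_pos <- vapply(seq_len(pwm_a$length), function(j) {
    jsd_base2(pwm_a$matrix[, j], pwm_b$matrix[, j])
  }, numeric(1))
  mean(per_pos)
}

jsd_base2 <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}
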