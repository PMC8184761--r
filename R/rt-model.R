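#' Fit an additive retention-time model
#'
#' Retention time is modeled as a linear function of residue composition
#' (counts of the 20 amino acids) plus an intercept. Because sequence length
#' equals the sum of the counts, an explicit length term is exactly collinear
#' with the composition design; it is therefore off by default and, when
#' requested, the fit switches to a ridge-regularized solve with a warning.
#' This composition-linear model plays the role of a learned hydrophobicity
#' predictor at desk scale: its absolute prediction error enters rescoring as
#' a feature exactly as a learned predictor's would.
#'
#' @param sequences Character vector of peptide sequences (>= 30).
#' @param observed_rt Observed retention times (iRT-like units or minutes).
#' @param include_length Add an explicit length column (ridge-regularized).
#' @param ridge Ridge penalty used when the design is rank-deficient.
#' @return Object of class `rt_model` with `coefficients` (named, per
#'   residue), `intercept`, `length_coef`, `residuals`.
#' @export
fit_rt <- function(sequences, observed_rt, include_length = FALSE,
                   ridge = 1e-6) {
  stopifnot(length(sequences) == length(observed_rt))
  if (length(sequences) < 30L) {
    stop("need at least 30 peptides to fit the RT model", call. = FALSE)
  }
  X <- composition_matrix(sequences)
  if (include_length) X <- cbind(X, length = nchar(sequences))
  Xd <- cbind(intercept = 1, X)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    warning("rank-deficient RT design; using ridge-regularized fit",
      call. = FALSE
    )
    beta <- solve(
      crossprod(Xd) + ridge * diag(ncol(Xd)),
      crossprod(Xd, observed_rt)
    )[, 1]
  } else {
    beta <- qr.coef(qrX, observed_rt)
  }
  fitted <- as.vector(Xd %*% beta)
  structure(
    list(
      coefficients = beta[colnames(composition_matrix(sequences[1]))],
      intercept = unname(beta["intercept"]),
      length_coef = if (include_length) unname(beta["length"]) else 0,
      residuals = observed_rt - fitted
    ),
    class = "rt_model"
  )
}

composition_matrix <- function(sequences) {
  aa <- names(mass_constants$residues)
  X <- vapply(aa, function(a) {
    stringr::str_count(sequences, stringr::fixed(a))
  }, numeric(length(sequences)))
  if (length(sequences) == 1L) X <- matrix(X, 1L, dimnames = list(NULL, aa))
  X
}

#' Predict retention times
#' @param object An `rt_model`.
#' @param sequences Peptide sequences.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.rt_model <- function(object, sequences, ...) {
  X <- composition_matrix(sequences)
  as.vector(X %*% object$coefficients) + object$intercept +
    object$length_coef * nchar(sequences)
}

#' @export
print.rt_model <- function(x, ...) {
  cat("<rt_model> composition-linear, residual sd ",
    signif(sd(x$residuals), 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.rt_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients), "length"),
    estimate = c(x$intercept, unname(x$coefficients), x$length_coef)
  )
}

#' @export
glance.rt_model <- function(x, ...) {
  tibble::tibble(
    n = length(x$residuals),
    residual_sd = sd(x$residuals),
    delta_rt95 = delta_irt95(x$residuals)
  )
}

#' Robustly align predicted to observed retention times
#'
#' Fits a Siegel repeated-median line from predicted to observed values on
#' the confident pairs (robust to gross outliers) and returns residuals
#' `observed - mapped` for all pairs.
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @param confident_mask Logical: pairs used to fit the map (default all).
#' @return List of class `rt_alignment`: `slope`, `intercept`, `residuals`.
#' @export
align_rt <- function(predicted, observed, confident_mask = NULL) {
  stopifnot(length(predicted) == length(observed))
  if (is.null(confident_mask)) confident_mask <- rep(TRUE, length(predicted))
  x <- predicted[confident_mask]
  y <- observed[confident_mask]
  if (length(x) < 10L) {
    stop("need at least 10 confident pairs for alignment", call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("degenerate alignment: all predicted values equal", call. = FALSE)
  }
  fit <- repeated_median_line(x, y)
  structure(
    list(
      slope = fit$slope, intercept = fit$intercept,
      residuals = observed - (fit$intercept + fit$slope * predicted)
    ),
    class = "rt_alignment"
  )
}

repeated_median_line <- function(x, y) {
  n <- length(x)
  slopes_i <- vapply(seq_len(n), function(i) {
    dx <- x[-i] - x[i]
    s <- (y[-i] - y[i])[dx != 0] / dx[dx != 0]
    if (length(s) == 0) NA_real_ else median(s)
  }, numeric(1))
  slope <- median(slopes_i, na.rm = TRUE)
  intercept <- median(y - slope * x)
  list(slope = slope, intercept = intercept)
}

#' @export
print.rt_alignment <- function(x, ...) {
  cat("<rt_alignment> observed ~ ", signif(x$intercept, 4), " + ",
    signif(x$slope, 4), " * predicted; delta_rt95 ",
    signif(delta_irt95(x$residuals), 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' 95th percentile of absolute RT residuals
#'
#' The chromatographic agreement metric: the linear-interpolation 95th
#' percentile of `|residuals|`. Scale-equivariant.
#'
#' @param residuals Non-empty numeric vector.
#' @return Scalar.
#' @export
delta_irt95 <- function(residuals) {
  stopifnot(length(residuals) > 0L)
  unname(quantile(abs(residuals), 0.95, type = 7))
}
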