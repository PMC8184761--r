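#' Target-decoy q-values
#'
#' For each score threshold `s`, `FDR(s) = (#decoys >= s + 1) / max(1,
#' #targets >= s)` (the +1 numerator keeps small samples conservative);
#' q-values are the running minimum of FDR from the lowest score upward, so
#' they are non-increasing in score. Target-decoy competition (best PSM per
#' spectrum) is applied upstream by the caller. Ties are handled
#' conservatively: a decoy at the threshold counts against it.
#'
#' @param scores Numeric PSM scores (higher is better).
#' @param is_decoy Logical, same length.
#' @return Numeric q-values in `[0, 1]`.
#' @examples
#' tdc_qvalues(c(10, 9, 8, 8.5), c(FALSE, FALSE, FALSE, TRUE))
#' @export
tdc_qvalues <- function(scores, is_decoy) {
  stopifnot(length(scores) == length(is_decoy))
  if (all(is_decoy)) stop("all-decoy input: no targets to estimate", call. = FALSE)
  if (!any(is_decoy)) warning("no decoys: FDR estimates degenerate", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  dec_sorted <- is_decoy[ord]
  n_dec <- cumsum(dec_sorted)
  n_tgt <- cumsum(!dec_sorted)
  s_sorted <- scores[ord]
  # threshold at each distinct score: counts at the last tied position
  last_of_tie <- c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  fdr_at <- (n_dec + 1) / pmax(1, n_tgt)
  fdr_thr <- fdr_at
  # propagate tie-group counts back over the whole tie
  idx_last <- cummax_rev(ifelse(last_of_tie, seq_along(s_sorted), NA_integer_))
  fdr_thr <- fdr_at[idx_last]
  q_sorted <- rev(cummin(rev(fdr_thr)))
  q <- numeric(length(scores))
  q[ord] <- pmin(q_sorted, 1)
  q
}

# fill NA with the next non-NA value below (vector is ordered)
cummax_rev <- function(x) {
  for (i in rev(seq_along(x))[-1]) {
    if (is.na(x[i])) x[i] <- x[i + 1L]
  }
  x
}

#' Semi-supervised target-decoy rescoring
#'
#' Re-implements the Percolator-style scheme on spectral features only. Per
#' cross-validation fold: the starting direction is the single feature (sign
#' included) that accepts the most targets at `q <= fdr`; then, for
#' `iterations` rounds, targets at `q <= fdr` become positives, all decoys
#' negatives, and an L2-regularized linear discriminant is refit. Each PSM's
#' final score comes from the fold whose model never saw it; per-fold scores
#' are standardized before pooling. A consolidated model refit on all PSMs is
#' stored for transfer to other engines (see [apply_pretrained()]).
#'
#' The search-engine score must not be part of `features`; a column named
#' `engine_score` is rejected.
#'
#' @param features Data frame of finite numeric features.
#' @param is_decoy Logical labels.
#' @param folds,iterations Cross-validation folds and refinement rounds.
#' @param fdr Working FDR threshold for positive selection (and reporting).
#' @param lambda Ridge penalty of the discriminant.
#' @param seed Seed for fold assignment.
#' @return Object of class `rescore_result`: tibble `psms` (score, model_score,
#'   qvalue, accepted), `weights` per fold, the consolidated `model`, and the
#'   feature names.
#' @export
semi_supervised_rescore <- function(features, is_decoy, folds = 3L,
                                    iterations = 10L, fdr = 0.01,
                                    lambda = 1, seed = 1L) {
  features <- tibble::as_tibble(features)
  if ("engine_score" %in% names(features)) {
    stop("engine_score must not be used as a rescoring feature", call. = FALSE)
  }
  X <- as.matrix(features)
  stopifnot(all(is.finite(X)), nrow(X) == length(is_decoy))
  n <- nrow(X)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  scores <- numeric(n)
  weights <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    w <- percolator_fold(X[tr, , drop = FALSE], is_decoy[tr], iterations, fdr, lambda)
    raw_tr <- as.vector(X[tr, , drop = FALSE] %*% w$w) + w$b
    mu <- mean(raw_tr)
    sdv <- sd(raw_tr)
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    raw_te <- as.vector(X[!tr, , drop = FALSE] %*% w$w) + w$b
    scores[!tr] <- (raw_te - mu) / sdv
    weights[[f]] <- c(w$w, intercept = w$b)
  }
  # consolidated model on all PSMs for cross-engine transfer
  wall <- percolator_fold(X, is_decoy, iterations, fdr, lambda)
  raw_all <- as.vector(X %*% wall$w) + wall$b
  mu_all <- mean(raw_all)
  sd_all <- sd(raw_all)
  if (!is.finite(sd_all) || sd_all == 0) sd_all <- 1
  model_score <- (raw_all - mu_all) / sd_all
  q <- tdc_qvalues(scores, is_decoy)
  structure(
    list(
      psms = tibble::tibble(
        score = scores, model_score = model_score, is_decoy = is_decoy,
        qvalue = q, accepted = !is_decoy & q <= fdr, fold = fold_id
      ),
      weights = weights,
      model = list(
        w = wall$w, b = wall$b, mu = mu_all, sd = sd_all,
        feature_names = colnames(X)
      ),
      fdr = fdr
    ),
    class = "rescore_result"
  )
}

# One semi-supervised refinement run on a training split.
percolator_fold <- function(X, is_decoy, iterations, fdr, lambda) {
  init <- best_single_feature(X, is_decoy, fdr)
  s <- X[, init$j] * init$sign
  best_w <- rep(0, ncol(X))
  best_w[init$j] <- init$sign
  best_b <- 0
  best_acc <- init$accepted
  w <- best_w
  b <- best_b
  for (it in seq_len(iterations)) {
    q <- tdc_qvalues(s, is_decoy)
    # relax the working threshold when the current direction yields no
    # positives yet (early iterations on weak single features)
    thr <- fdr
    pos <- !is_decoy & q <= thr
    while (sum(pos) < 2L && thr < 0.25) {
      thr <- thr * 5
      pos <- !is_decoy & q <= thr
    }
    if (sum(pos) < 2L) {
      if (it == 1L) {
        warning(
          "no positives at initialization; falling back to best raw feature",
          call. = FALSE
        )
      }
      break
    }
    fit <- ridge_lda(X, pos, is_decoy, lambda)
    s <- as.vector(X %*% fit$w) + fit$b
    acc <- sum(!is_decoy & tdc_qvalues(s, is_decoy) <= fdr)
    if (acc >= best_acc) {
      best_acc <- acc
      best_w <- fit$w
      best_b <- fit$b
    }
    w <- fit$w
    b <- fit$b
  }
  list(w = best_w, b = best_b)
}

best_single_feature <- function(X, is_decoy, fdr) {
  best <- list(j = 1L, sign = 1, accepted = -1L)
  for (j in seq_len(ncol(X))) {
    for (sg in c(1, -1)) {
      acc <- sum(!is_decoy & tdc_qvalues(sg * X[, j], is_decoy) <= fdr)
      if (acc > best$accepted) best <- list(j = j, sign = sg, accepted = acc)
    }
  }
  best
}

# L2-regularized linear discriminant between positives and negatives.
ridge_lda <- function(X, pos, is_decoy, lambda) {
  A <- X[pos, , drop = FALSE]
  B <- X[is_decoy, , drop = FALSE]
  mu1 <- colMeans(A)
  mu0 <- colMeans(B)
  S <- (crossprod(sweep(A, 2, mu1)) + crossprod(sweep(B, 2, mu0))) /
    max(1, nrow(A) + nrow(B) - 2)
  w <- as.vector(solve(S + lambda * diag(ncol(X)), mu1 - mu0))
  names(w) <- colnames(X)
  b <- -sum(w * (mu1 + mu0) / 2)
  list(w = w, b = b)
}

#' @export
print.rescore_result <- function(x, ...) {
  cat("<rescore_result> ", nrow(x$psms), " PSMs, ",
    sum(x$psms$accepted), " targets accepted at q <= ", x$fdr, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.rescore_result <- function(x, ...) x$psms

#' @export
glance.rescore_result <- function(x, ...) {
  tibble::tibble(
    n_psms = nrow(x$psms),
    n_targets = sum(!x$psms$is_decoy),
    n_decoys = sum(x$psms$is_decoy),
    accepted = sum(x$psms$accepted),
    fdr = x$fdr
  )
}

#' Apply a pre-trained rescoring model to another engine's features
#'
#' Scores arbitrary feature matrices with the consolidated model (weights and
#' standardization carried along), so PSMs from different search engines land
#' on one shared confidence scale and can be ranked against each other.
#' Feature names and order must match the training features exactly.
#'
#' @param result A `rescore_result`.
#' @param features Data frame with identical feature columns.
#' @param is_decoy Optional labels; when provided, q-values are computed on
#'   the new scores.
#' @return Tibble with `score` (and `qvalue` when labels are given).
#' @export
apply_pretrained <- function(result, features, is_decoy = NULL) {
  features <- tibble::as_tibble(features)
  if (!identical(names(features), result$model$feature_names)) {
    stop(
      "feature mismatch; expected [",
      paste(result$model$feature_names, collapse = ", "), "], got [",
      paste(names(features), collapse = ", "), "]",
      call. = FALSE
    )
  }
  X <- as.matrix(features)
  raw <- as.vector(X %*% result$model$w) + result$model$b
  score <- (raw - result$model$mu) / result$model$sd
  out <- tibble::tibble(score = score)
  if (!is.null(is_decoy)) out$qvalue <- tdc_qvalues(score, is_decoy)
  out
}

#' Peptide-level q-values
#'
#' Reduces to the best-scoring PSM per modified sequence (charge excluded
#' from the identity) and re-runs target-decoy estimation on the reduced set.
#'
#' @param psms Tibble with `modified_sequence`, `score`, `is_decoy`.
#' @param fdr Acceptance threshold for the `accepted` flag.
#' @return Tibble: one row per peptide with `score`, `qvalue`, `accepted`.
#' @export
peptide_qvalues <- function(psms, fdr = 0.01) {
  peps <- psms |>
    dplyr::group_by(.data$modified_sequence) |>
    dplyr::slice_max(.data$score, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  peps$qvalue <- tdc_qvalues(peps$score, peps$is_decoy)
  peps$accepted <- !peps$is_decoy & peps$qvalue <= fdr
  peps
}

#' Lost / shared / gained comparison of two peptide sets
#'
#' @param reference,new Character vectors of (modified) peptide sequences.
#' @return List of class `set_comparison`: `counts` tibble and the three
#'   sequence lists. `lost + shared = |reference|`, `shared + gained = |new|`.
#' @export
compare_sets <- function(reference, new) {
  reference <- unique(reference)
  new <- unique(new)
  lost <- setdiff(reference, new)
  shared <- intersect(reference, new)
  gained <- setdiff(new, reference)
  structure(
    list(
      counts = tibble::tibble(
        lost = length(lost), shared = length(shared), gained = length(gained)
      ),
      lost = lost, shared = shared, gained = gained
    ),
    class = "set_comparison"
  )
}

#' @export
print.set_comparison <- function(x, ...) {
  cat("<set_comparison> lost ", x$counts$lost, ", shared ", x$counts$shared,
    ", gained ", x$counts$gained, "\n",
    sep = ""
  )
  invisible(x)
}
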