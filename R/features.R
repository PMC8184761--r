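#' Normalized spectral contrast angle
#'
#' `SA = 1 - 2 * acos(<p, o>) / pi` with `p`, `o` the L2-normalized predicted
#' and observed intensity vectors over the dimensions valid in both matrices.
#' Negative predicted values are clipped to 0 before normalization. If either
#' vector is all-zero the angle is defined as 0 (an unmatchable PSM earns the
#' worst score). SA is 1 iff the vectors are positively proportional.
#'
#' @param pred,obs `fragment_matrix` objects with identical length/charge
#'   metadata, or plain numeric vectors of equal length (no masking).
#' @return Spectral angle in `[0, 1]`.
#' @export
spectral_angle <- function(pred, obs) {
  if (inherits(pred, "fragment_matrix") || inherits(obs, "fragment_matrix")) {
    if (pred$length != obs$length || pred$charge != obs$charge) {
      stop("mismatched fragment-matrix metadata (length/charge)", call. = FALSE)
    }
    mask <- fragment_mask(pred$length, pred$charge)
    p <- pred$values[mask]
    o <- obs$values[mask]
  } else {
    stopifnot(length(pred) == length(obs))
    p <- pred
    o <- obs
  }
  sa_from_vectors(p, o)
}

sa_from_vectors <- function(p, o) {
  p <- pmax(p, 0)
  o <- pmax(o, 0)
  np <- sqrt(sum(p^2))
  no <- sqrt(sum(o^2))
  if (np == 0 || no == 0) {
    return(0)
  }
  dot <- sum(p * o) / (np * no)
  dot <- min(max(dot, -1), 1)
  1 - 2 * acos(dot) / pi
}

#' Summarize spectral-angle distributions per group
#'
#' @param psms Tibble with a `spectral_angle` column.
#' @param group Column (tidy-eval) to group by; omit for one overall group.
#' @return Tibble with `n`, `median_sa`, `frac_below_0.5`, `frac_at_least_0.9`
#'   per group, deterministic order. Empty groups are absent, never zero rows.
#' @export
sa_distributions <- function(psms, group = NULL) {
  grp <- rlang::enquo(group)
  if (!rlang::quo_is_null(grp)) {
    psms <- dplyr::group_by(psms, !!grp)
  }
  out <- dplyr::summarise(
    psms,
    n = dplyr::n(),
    median_sa = median(.data$spectral_angle),
    frac_below_0.5 = mean(.data$spectral_angle < 0.5),
    frac_at_least_0.9 = mean(.data$spectral_angle >= 0.9),
    .groups = "drop"
  )
  if (!rlang::quo_is_null(grp)) out <- dplyr::arrange(out, !!grp)
  out
}

#' Build the rescoring feature vector for one PSM
#'
#' Only similarity and mass/chromatography features computable from the
#' prediction and the annotation enter the vector; the search-engine score is
#' deliberately never included, so the rescoring is engine-agnostic.
#'
#' @param psm One-row PSM tibble (needs `charge`, `retention_time`,
#'   `sequence`; optionally `precursor_mz_observed`).
#' @param pred Predicted `fragment_matrix`.
#' @param obs Observed (annotated) `fragment_matrix` with the `stats`
#'   attribute from [annotate()].
#' @param rt_pred Predicted retention time (minutes) or `NA` when no RT model
#'   is available; missingness is encoded as `abs_delta_rt = 0` plus the
#'   `rt_missing` indicator.
#' @return One-row tibble of finite numeric features.
#' @export
build_features <- function(psm, pred, obs, rt_pred = NA_real_) {
  mask <- fragment_mask(pred$length, pred$charge)
  p <- pmax(pred$values[mask], 0)
  o <- pmax(obs$values[mask], 0)
  st <- attr(obs, "stats")
  if (is.null(st)) {
    st <- tibble::tibble(
      n_matched_b = sum(obs$values[, "b", ][fragment_mask(obs$length, obs$charge)[, 1, ]] > 0),
      n_matched_y = sum(obs$values[, "y", ][fragment_mask(obs$length, obs$charge)[, 2, ]] > 0),
      frac_tic_annotated = 0
    )
  }
  two_valued <- function(x, y, method) {
    if (sd(x) == 0 || sd(y) == 0) {
      return(0)
    }
    v <- suppressWarnings(cor(x, y, method = method))
    if (!is.finite(v)) 0 else v
  }
  rt_missing <- as.numeric(is.na(rt_pred) || is.na(psm$retention_time))
  abs_delta_rt <- if (rt_missing == 1) 0 else abs(psm$retention_time - rt_pred)
  obs_ppm <- if ("precursor_mz_observed" %in% names(psm) &&
    !is.na(psm$precursor_mz_observed)) {
    pep <- peptide(psm$modified_sequence,
      charge = psm$charge,
      validate_domain = FALSE
    )
    theo <- (peptide_mass(pep) + psm$charge * mass_constants$proton) / psm$charge
    abs(psm$precursor_mz_observed - theo) / theo * 1e6
  } else {
    0
  }
  feats <- tibble::tibble(
    spectral_angle = sa_from_vectors(p, o),
    pearson = two_valued(p, o, "pearson"),
    spearman = two_valued(p, o, "spearman"),
    frac_pred_matched = if (sum(p > 0) > 0) {
      sum(p > 0 & o > 0) / sum(p > 0)
    } else {
      0
    },
    frac_intensity_annotated = st$frac_tic_annotated,
    n_matched_b = as.numeric(st$n_matched_b),
    n_matched_y = as.numeric(st$n_matched_y),
    abs_delta_rt = abs_delta_rt,
    rt_missing = rt_missing,
    abs_precursor_ppm = obs_ppm,
    length = nchar(psm$sequence)
  )
  charge_oh <- as.data.frame(as.list(setNames(
    as.numeric(seq_len(6) == psm$charge),
    paste0("charge_", 1:6)
  )))
  feats <- dplyr::bind_cols(feats, tibble::as_tibble(charge_oh))
  bad <- !vapply(feats, function(v) is.finite(v), logical(1))
  if (any(bad)) {
    stop("non-finite feature(s): ", paste(names(feats)[bad], collapse = ", "),
      call. = FALSE
    )
  }
  feats
}
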