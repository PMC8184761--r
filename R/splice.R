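#' Build an accounting report from per-stage rejection counts
#'
#' The bookkeeping object of the consecutive-filter re-assessment: stages are
#' applied in order, a candidate is charged to the first stage that rejects
#' it, and the counts always conserve the total.
#'
#' @param total Total number of candidates.
#' @param rejected Named integer vector of per-stage rejections, in stage
#'   order (e.g. `c(not_confident = 596, il_isomer = 90, better_canonical =
#'   315, insufficient_margin = 66)`).
#' @param non_assessable Candidates that could not be assessed (no rescore
#'   result); counted separately, never silently retained.
#' @return Object of class `accounting_report` with `retained`,
#'   `rejected_total`, `rejected_fraction` computed.
#' @examples
#' accounting_report(1230, c(
#'   not_confident = 596, il_isomer = 90,
#'   better_canonical = 315, insufficient_margin = 66
#' ))
#' @export
accounting_report <- function(total, rejected, non_assessable = 0L) {
  stopifnot(all(rejected >= 0), total >= sum(rejected) + non_assessable)
  rejected <- setNames(as.integer(rejected), names(rejected))
  retained <- total - sum(rejected) - non_assessable
  structure(
    list(
      total = as.integer(total),
      rejected = rejected,
      non_assessable = as.integer(non_assessable),
      retained = as.integer(retained),
      rejected_total = as.integer(sum(rejected)),
      rejected_fraction = sum(rejected) / total
    ),
    class = "accounting_report"
  )
}

#' @export
print.accounting_report <- function(x, ...) {
  cat("<accounting_report> ", x$total, " candidates: ",
    x$rejected_total, " rejected (",
    round(100 * x$rejected_fraction), "%), ",
    x$retained, " retained",
    if (x$non_assessable > 0) paste0(", ", x$non_assessable, " non-assessable"),
    "\n",
    sep = ""
  )
  for (nm in names(x$rejected)) {
    cat("  - ", nm, ": ", x$rejected[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.accounting_report <- function(x, ...) {
  tibble::tibble(
    stage = c(names(x$rejected), "retained", "non_assessable"),
    outcome = c(rep("rejected", length(x$rejected)), "retained", "non_assessable"),
    n = c(unname(x$rejected), x$retained, x$non_assessable)
  )
}

#' Re-assess proposed spliced peptides with consecutive filters
#'
#' Applies four filters in fixed order, charging each candidate to the first
#' stage that rejects it:
#' \describe{
#'   \item{i `not_confident`}{rescoring q-value above `q_threshold`;}
#'   \item{ii `il_isomer`}{the spliced sequence is an I/L isomer of a
#'     canonical competitor or of any peptide in `canonical_universe`;}
#'   \item{iii `better_canonical`}{a canonical competitor for the same
#'     spectrum has a shared-scale score at least as high;}
#'   \item{iv `insufficient_margin`}{the spliced score beats the best
#'     canonical competitor by no more than `margin`.}
#' }
#' Candidates without a rescore result are counted as non-assessable.
#'
#' @param candidates Tibble with columns `spliced` (sequence, optional pipe
#'   splice marker), `qvalue`, `score`, and a `competitors` list-column of
#'   tibbles with `sequence` and `score` (canonical competitors for the same
#'   spectrum; may be empty).
#' @param q_threshold Stage-i confidence threshold (default 0.01).
#' @param margin Stage-iv minimal score margin; the filter rejects a spliced
#'   candidate whose advantage over the canonical competitor is positive but
#'   no larger than this. With `margin = 0` stage iv rejects nothing.
#' @param canonical_universe Optional character vector of canonical peptide
#'   sequences for the stage-ii I/L check beyond same-spectrum competitors.
#' @return List: `report` (an `accounting_report`) and `verdicts` tibble with
#'   per-candidate `verdict` (`retained` or the rejecting stage).
#' @export
assess_spliced <- function(candidates, q_threshold = 0.01, margin = 1.0,
                           canonical_universe = character()) {
  stages <- c(
    "not_confident", "il_isomer", "better_canonical", "insufficient_margin"
  )
  universe_il <- unique(gsub("I", "L", canonical_universe, fixed = TRUE))
  verdicts <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    row <- candidates[i, ]
    plain <- gsub("|", "", row$spliced, fixed = TRUE)
    comp <- row$competitors[[1]]
    if (is.null(comp)) comp <- tibble::tibble(sequence = character(), score = numeric())
    if (is.na(row$qvalue) || is.na(row$score)) {
      verdicts[i] <- "non_assessable"
      next
    }
    if (row$qvalue > q_threshold) {
      verdicts[i] <- "not_confident"
    } else if (gsub("I", "L", plain, fixed = TRUE) %in%
      c(gsub("I", "L", comp$sequence, fixed = TRUE), universe_il)) {
      verdicts[i] <- "il_isomer"
    } else if (nrow(comp) > 0 && max(comp$score) >= row$score) {
      verdicts[i] <- "better_canonical"
    } else if (nrow(comp) > 0 && row$score - max(comp$score) <= margin) {
      verdicts[i] <- "insufficient_margin"
    } else {
      verdicts[i] <- "retained"
    }
  }
  rejected <- vapply(stages, function(s) sum(verdicts == s), integer(1))
  list(
    report = accounting_report(
      nrow(candidates), rejected,
      non_assessable = sum(verdicts == "non_assessable")
    ),
    verdicts = dplyr::mutate(
      dplyr::select(candidates, -dplyr::any_of("competitors")),
      verdict = verdicts
    )
  )
}

#' Control re-assessment of canonical peptides
#'
#' Mirrors [assess_spliced()] but applies only the rescoring-confidence
#' filter (stage i) and the better-competitor filter (stage iii); canonical
#' peptides are not screened for I/L isomery or a score margin against
#' themselves.
#'
#' @param candidates Tibble with `sequence`, `qvalue`, `score` and a
#'   `competitors` list-column (may be missing or empty).
#' @param q_threshold Confidence threshold.
#' @return List: `report` and `verdicts`, as in [assess_spliced()].
#' @export
assess_canonical <- function(candidates, q_threshold = 0.01) {
  verdicts <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    row <- candidates[i, ]
    comp <- if ("competitors" %in% names(candidates)) row$competitors[[1]] else NULL
    if (is.null(comp)) comp <- tibble::tibble(sequence = character(), score = numeric())
    if (is.na(row$qvalue) || is.na(row$score)) {
      verdicts[i] <- "non_assessable"
    } else if (row$qvalue > q_threshold) {
      verdicts[i] <- "not_confident"
    } else if (nrow(comp) > 0 && max(comp$score) >= row$score) {
      verdicts[i] <- "better_canonical"
    } else {
      verdicts[i] <- "retained"
    }
  }
  rejected <- vapply(
    c("not_confident", "better_canonical"),
    function(s) sum(verdicts == s), integer(1)
  )
  list(
    report = accounting_report(
      nrow(candidates), rejected,
      non_assessable = sum(verdicts == "non_assessable")
    ),
    verdicts = dplyr::mutate(
      dplyr::select(candidates, -dplyr::any_of("competitors")),
      verdict = verdicts
    )
  )
}

#' Best PSM per spectrum across search engines
#'
#' Given PSMs from several engines scored on one shared scale, returns the
#' best assignment per (rawfile, scan). Ties prefer canonical over spliced,
#' then the lexicographically smaller sequence.
#'
#' @param psms Tibble with `rawfile`, `scan`, `sequence`, `score` and logical
#'   `is_spliced`.
#' @return Tibble with one row per spectrum.
#' @export
rank_best_psm_per_spectrum <- function(psms) {
  psms |>
    dplyr::arrange(
      .data$rawfile, .data$scan, dplyr::desc(.data$score),
      .data$is_spliced, .data$sequence
    ) |>
    dplyr::distinct(.data$rawfile, .data$scan, .keep_all = TRUE)
}

#' End-to-end audit of spliced proposals on synthetic confusion pairs
#'
#' Generates isobaric spliced/canonical confusion pairs whose spectra come
#' from the canonical truth, annotates both explanations of every spectrum,
#' scores them (together with reversed decoys) by feature-only semi-supervised
#' rescoring, and runs the consecutive-filter assessment. With the spectra
#' generated from the canonical sequences, retained spliced candidates are
#' ground-truth false positives.
#'
#' @param n_pairs Number of confusion pairs.
#' @param seed Integer seed.
#' @param cfg A `sim_config` for spectrum rendering.
#' @param q_threshold,margin Assessment settings.
#' @return List: `report`, `verdicts`, `pairs`, `rescore` result.
#' @export
run_splice_audit <- function(n_pairs = 100L, seed = 1L,
                             cfg = sim_config(seed = seed),
                             q_threshold = 0.01, margin = 1.0) {
  pairs <- generate_confusion_pairs(n_pairs, seed = seed, cfg = cfg)
  pred <- oracle_predictor()
  feature_rows <- list()
  meta_rows <- list()
  k <- 0L
  for (i in seq_len(n_pairs)) {
    sp <- pairs$spectrum[[i]]
    seqs <- c(pairs$canonical[i], pairs$spliced_plain[i])
    kinds <- c("canonical", "spliced")
    decoyed <- c(FALSE, FALSE, TRUE)
    for (j in 1:2) {
      for (dec in if (j == 1) c(FALSE, TRUE) else FALSE) {
        s <- if (dec) generate_decoy(seqs[j]) else seqs[j]
        pep <- peptide(s, charge = sp$precursor_charge)
        obs <- annotate(sp, pep)
        pfm <- predict_fragments(
          pred,
          tibble::tibble(
            sequence = s, modified_sequence = s,
            charge = sp$precursor_charge, nce = cfg$nce
          )
        )[[1]]
        psm_row <- tibble::tibble(
          rawfile = sp$rawfile, scan = pairs$scan[i],
          modified_sequence = s, sequence = s,
          charge = sp$precursor_charge, retention_time = NA_real_
        )
        k <- k + 1L
        feature_rows[[k]] <- build_features(psm_row, pfm, obs)
        meta_rows[[k]] <- dplyr::mutate(psm_row,
          kind = if (dec) "decoy" else kinds[j], is_decoy = dec
        )
      }
    }
  }
  features <- dplyr::bind_rows(feature_rows)
  meta <- dplyr::bind_rows(meta_rows)
  res <- semi_supervised_rescore(features, meta$is_decoy, seed = seed)
  meta$score <- res$psms$score
  meta$qvalue <- res$psms$qvalue
  spl_psms <- meta[meta$kind == "spliced", ]
  canonical <- meta[meta$kind == "canonical", ]
  candidates <- tibble::tibble(
    spliced = pairs$spliced,
    qvalue = spl_psms$qvalue[match(pairs$scan, spl_psms$scan)],
    score = spl_psms$score[match(pairs$scan, spl_psms$scan)],
    competitors = purrr::map(pairs$scan, function(sc) {
      tibble::tibble(
        sequence = canonical$sequence[canonical$scan == sc],
        score = canonical$score[canonical$scan == sc]
      )
    })
  )
  out <- assess_spliced(candidates,
    q_threshold = q_threshold, margin = margin,
    canonical_universe = pairs$canonical
  )
  c(out, list(pairs = pairs, rescore = res))
}
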