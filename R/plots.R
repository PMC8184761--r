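#' Vennbar plot of lost / shared / gained peptides
#'
#' Barplot rendering of a two-set comparison: the shared area in blue flanked
#' by lost (red) and gained (green) segments.
#'
#' @param comparisons A `set_comparison` or a tibble with columns `label`,
#'   `lost`, `shared`, `gained` (one bar per row).
#' @return A ggplot.
#' @export
plot_vennbars <- function(comparisons) {
  if (inherits(comparisons, "set_comparison")) {
    comparisons <- dplyr::mutate(comparisons$counts, label = "comparison")
  }
  long <- tidyr::pivot_longer(comparisons, c("lost", "shared", "gained"),
    names_to = "segment", values_to = "n"
  )
  long$segment <- factor(long$segment, levels = c("lost", "shared", "gained"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$label, y = .data$n, fill = .data$segment
  )) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(
      lost = "#c0392b", shared = "#2980b9", gained = "#27ae60"
    )) +
    ggplot2::labs(x = NULL, y = "peptides", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn semi_supervised_rescore Score distributions of targets vs decoys.
#' @param object A `rescore_result`.
#' @param ... Unused.
#' @export
autoplot.rescore_result <- function(object, ...) {
  ggplot2::ggplot(object$psms, ggplot2::aes(
    x = .data$score,
    fill = ifelse(.data$is_decoy, "decoy", "target")
  )) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 50) +
    ggplot2::scale_fill_manual(values = c(decoy = "grey40", target = "#2980b9")) +
    ggplot2::labs(x = "rescoring score", y = "PSMs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn calibrate_ce Median spectral angle across the NCE grid.
#' @param object A `ce_calibration`.
#' @param ... Unused.
#' @export
autoplot.ce_calibration <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$nce, .data$median_sa)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_nce, linetype = 2) +
    ggplot2::labs(x = "NCE", y = "median spectral angle") +
    ggplot2::theme_minimal()
}

#' @describeIn build_pwm Heat-map rendering of a motif.
#' @param object A `pwm`.
#' @param ... Unused.
#' @export
autoplot.pwm <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
    x = .data$position, y = .data$residue, fill = .data$frequency
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c3e50") +
    ggplot2::labs(x = "position", y = NULL, fill = "freq") +
    ggplot2::theme_minimal()
}

#' @describeIn accounting_report Consecutive-filter accounting bars.
#' @param object An `accounting_report`.
#' @param ... Unused.
#' @export
autoplot.accounting_report <- function(object, ...) {
  df <- tidy(object)
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$stage, y = .data$n, fill = .data$outcome
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      rejected = "#c0392b", retained = "#2980b9", non_assessable = "grey60"
    )) +
    ggplot2::labs(x = NULL, y = "candidates", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @describeIn train_intensity_model Training and test loss curves.
#' @param object An `intensity_model`.
#' @param ... Unused.
#' @export
autoplot.intensity_model <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_loss", "test_loss"),
    names_to = "set", values_to = "loss"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    .data$epoch, .data$loss, colour = .data$set
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "spectral contrast loss", colour = NULL) +
    ggplot2::theme_minimal()
}
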