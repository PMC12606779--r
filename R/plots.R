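#' Plot the bootstrap expected-PPV calibration curve
#'
#' Expected PPV against candidate cut-point, with the PPV target and the
#' selected cut-point marked when present on the object.
#'
#' @param object A `ps_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ps_calibration
#' @export
autoplot.ps_calibration <- function(object, ...) {
  p <- ggplot(object$curve, aes(x = .data$threshold, y = .data$expected_ppv)) +
    geom_step(na.rm = TRUE) +
    labs(
      x = "Candidate Progression Score cut-point",
      y = "Bootstrap expected PPV",
      title = sprintf("Expected-PPV calibration (%s, B = %d)", object$model, object$B)
    ) +
    theme_minimal()
  if (!is.na(object$min_ppv)) {
    p <- p + geom_hline(yintercept = object$min_ppv, linetype = "dashed")
  }
  if (!is.na(object$selected_cutpoint)) {
    p <- p + geom_vline(xintercept = object$selected_cutpoint, linetype = "dotted")
  }
  p
}

#' Empirical ROC curve of a fitted progression model
#'
#' @param object A `ps_fit`.
#' @param ... Unused.
#' @return A ggplot of the training ROC curve with the AUC in the title.
#' @method autoplot ps_fit
#' @export
autoplot.ps_fit <- function(object, ...) {
  ord <- order(object$fitted_probabilities, decreasing = TRUE)
  y <- object$labels[ord]
  roc <- tibble(
    fpr = c(0, cumsum(!y) / sum(!y)),
    tpr = c(0, cumsum(y) / sum(y))
  )
  ggplot(roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    coord_equal() +
    labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%s (training AUC %.3f)", object$model, object$training_auc)
    ) +
    theme_minimal()
}

#' Scatter plot of Progression Scores by imaging outcome
#'
#' One point per patient, horizontally jittered within outcome group, with
#' the call cut-point drawn as a horizontal line — the at-a-glance view of
#' which patients the assay calls and whether any non-progressor sits above
#' the cut.
#'
#' @param calls Tibble with columns `ps` and `progressed` (e.g. the `calls`
#'   element of a [run_pipeline()] result).
#' @param cutpoint Optional cut-point to draw.
#' @return A ggplot.
#' @export
plot_ps_scores <- function(calls, cutpoint = NULL) {
  df <- calls |>
    mutate(outcome = dplyr::case_when(
      is.na(.data$progressed) ~ "unknown",
      .data$progressed ~ "progression by imaging",
      TRUE ~ "no progression by imaging"
    ))
  p <- ggplot(df, aes(x = .data$outcome, y = .data$ps, colour = .data$outcome)) +
    geom_jitter(width = 0.15, height = 0, alpha = 0.8, show.legend = FALSE) +
    labs(x = NULL, y = "Progression Score (0-100)") +
    ylim(0, 100) +
    theme_minimal()
  if (!is.null(cutpoint)) p <- p + geom_hline(yintercept = cutpoint, linetype = "dashed")
  p
}
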