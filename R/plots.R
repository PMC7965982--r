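#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_vline labs theme_minimal facet_wrap geom_abline
#' @export
ggplot2::autoplot

#' Plot a probability-velocity curve
#'
#' Shows the sweep with the plateau probability and the velocity at 95% of
#' the plateau.
#'
#' @param object a `velocity_curve`.
#' @param smooth isotonic smoothing before plateau detection.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.velocity_curve <- function(object, smooth = TRUE, ...) {
  pl <- plateau_and_velocity(object, smooth = smooth)
  g <- ggplot(object, aes(x = .data$velocity, y = .data$probability)) +
    geom_line(linewidth = 0.4) +
    geom_hline(yintercept = pl$P_f, linetype = "dashed", colour = "grey40") +
    labs(x = "impact velocity (m/s)",
         y = "P(damage proportion reached)",
         title = sprintf("plateau P_f = %.3f", pl$P_f)) +
    theme_minimal()
  if (pl$reached) {
    g <- g + geom_vline(xintercept = pl$v_at_95, linetype = "dotted",
                        colour = "firebrick")
  }
  g
}

#' ROC curve of pooled leave-one-out predictions
#'
#' @param object a `dmn_eval`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dmn_eval <- function(object, ...) {
  pr <- object$predictions
  ths <- sort(unique(c(-Inf, pr$probability, Inf)), decreasing = TRUE)
  roc <- purrr::map_dfr(ths, function(th) {
    pred <- pr$probability >= th
    tibble::tibble(
      fpr = sum(pred & pr$label == 0L) / sum(pr$label == 0L),
      tpr = sum(pred & pr$label == 1L) / sum(pr$label == 1L)
    )
  })
  ggplot(roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("LOO ROC (%s), AUC = %.3f", object$method,
                         object$metrics$auc)) +
    theme_minimal()
}

#' Damage-velocity overview of a scenario library
#'
#' DMN damage percentage against velocity, faceted by impact location,
#' coloured by impactor; fractured records are marked.
#'
#' @param library scenario-library tibble.
#' @return a ggplot.
#' @export
plot_library <- function(library) {
  ggplot(library, aes(x = .data$velocity, y = .data$damage_percent,
                      colour = .data$impactor, shape = .data$fractured)) +
    geom_point(alpha = 0.7, size = 1.4) +
    facet_wrap(~location) +
    labs(x = "impact velocity (m/s)", y = "DMN damage (%)") +
    theme_minimal()
}
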