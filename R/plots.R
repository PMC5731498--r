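#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline labs facet_wrap theme_minimal scale_fill_manual
#' @export
ggplot2::autoplot

#' Plot a threshold sweep
#'
#' MCC, precision, recall and F1 as a function of the decision threshold.
#'
#' @param object a `ppi_sweep` from [sweep_thresholds()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ppi_sweep
#' @export
autoplot.ppi_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("mcc", "precision", "recall", "f1"),
    names_to = "metric", values_to = "value"
  )
  ggplot(long, aes(x = .data$threshold, y = .data$value,
                   colour = .data$metric)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(x = "decision threshold on interface probability", y = NULL,
         colour = NULL) +
    theme_minimal()
}

#' Plot per-residue interface probabilities
#'
#' Probability along the sequence, one panel per chain, bars coloured by
#' the binary call; the decision threshold is drawn as a dashed line.
#'
#' @param object a `ppi_prediction` from [predict_structure()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ppi_prediction
#' @export
autoplot.ppi_prediction <- function(object, ...) {
  params <- attr(object, "params")
  tau <- if (!is.null(params)) params$threshold else NULL
  p <- ggplot(as_tibble(object),
              aes(x = .data$resno, y = .data$prob, fill = .data$call)) +
    geom_col() +
    facet_wrap(~chain, ncol = 1) +
    scale_fill_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "#7f8c8d"),
                      name = "interface call") +
    labs(x = "residue number", y = "interface probability |I| / |S|") +
    theme_minimal()
  if (!is.null(tau)) p <- p + geom_hline(yintercept = tau, linetype = 2)
  p
}
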