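# ggplot2 displays for the main result objects.

#' Elbow and silhouette curves of a k scan
#'
#' Two stacked panels over the candidate cluster counts: the SSE (elbow)
#' curve and the mean silhouette curve, with the chosen k marked.
#'
#' @param object A `k_scan` from [scan_k()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot k_scan
#' @export
autoplot.k_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, c("sse", "silhouette"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = "dashed") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = object$metrics$k) +
    ggplot2::labs(x = "number of clusters k", y = NULL,
                  title = sprintf("Cluster count selection (chosen k = %d)",
                                  object$chosen_k)) +
    ggplot2::theme_minimal()
}

#' Delta E per pair with perceptibility bands
#'
#' @param object A `similarity_report` from [evaluate_pairs()].
#' @param ... Unused.
#' @return A ggplot object: per-pair delta E bars with the band thresholds
#'   (1, 3, 6, 9, 12) as horizontal guides.
#' @method autoplot similarity_report
#' @export
autoplot.similarity_report <- function(object, ...) {
  df <- object$pairs
  df$pair_id <- if ("pair" %in% names(df)) factor(df$pair) else
    factor(seq_len(nrow(df)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair_id, y = .data$delta_e,
                                   fill = .data$band)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(1, 3, 6, 9, 12), linetype = "dotted") +
    ggplot2::labs(x = "pair", y = expression(Delta * E),
                  title = sprintf("Color difference per pair (mean %.4f)",
                                  object$summary$mean_delta_e)) +
    ggplot2::theme_minimal()
}

#' Channel-dominance plot of Shapley attributions
#'
#' Mean absolute Shapley contribution of each RGB channel to each pigment's
#' dose prediction, faceted by cluster — the global attribution picture.
#'
#' @param report Tibble from [dominance_report()].
#' @return A ggplot object.
#' @export
plot_dominance <- function(report) {
  long <- tidyr::pivot_longer(
    report, dplyr::starts_with("mean_abs_phi_"),
    names_to = "channel", values_to = "mean_abs_phi",
    names_prefix = "mean_abs_phi_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pigment,
                                     y = .data$mean_abs_phi,
                                     fill = .data$channel)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_manual(values = c(r = "#c0392b", g = "#27ae60",
                                          b = "#2980b9")) +
    ggplot2::labs(y = "mean |phi| (mg)", x = NULL,
                  title = "Channel contribution to pigment predictions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
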