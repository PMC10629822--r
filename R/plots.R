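#' Plot the event-type summary
#'
#' Bar chart of detected events per class, overall and among significant
#' events.
#'
#' @param summary Tibble from [summarize_event_types()].
#' @return A ggplot object.
#' @export
plot_event_types <- function(summary) {
  long <- tidyr::pivot_longer(summary, c("n_events", "n_significant"),
                              names_to = "set", values_to = "n")
  long$set <- ifelse(long$set == "n_events", "all", "significant")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$event_type, y = .data$n,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "events", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the cryptic-distance histogram on log2 bins
#'
#' @param histogram Tibble from [distance_histogram()].
#' @return A ggplot object.
#' @export
plot_distance_histogram <- function(histogram) {
  histogram$bin <- factor(histogram$bin, levels = histogram$bin)
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = .data$bin, y = .data$count,
                               fill = .data$is_mode)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey40")) +
    ggplot2::labs(x = "cryptic 3'ss distance (nt, log2 bins)", y = "events") +
    ggplot2::theme_minimal()
}

#' Sequence-logo style plot of a motif profile
#'
#' Stacked per-position bars whose total height is the position's
#' information content, split by base frequency.
#'
#' @param profile Tibble from [motif_profile()].
#' @return A ggplot object.
#' @export
plot_motif <- function(profile) {
  long <- tidyr::pivot_longer(
    profile[, c("offset", "freq_A", "freq_C", "freq_G", "freq_T", "ic")],
    dplyr::starts_with("freq_"), names_to = "base", values_to = "freq",
    names_prefix = "freq_"
  )
  long$height <- long$freq * long$ic
  ggplot2::ggplot(long, ggplot2::aes(x = .data$offset, y = .data$height,
                                     fill = .data$base)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255c99",
                                          G = "#f7b32b", T = "#d62839")) +
    ggplot2::labs(x = "offset from 3'ss (0 = last intronic base)",
                  y = "information (bits)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-splicing fit
#'
#' @param object A `cryptsplice_diff` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cryptsplice_diff <- function(object, ...) {
  res <- object$results
  ggplot2::ggplot(res, ggplot2::aes(x = .data$delta_psi,
                                    y = -log10(.data$p),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$config$delta_psi_min,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(object$config$p_max),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = expression(Delta * PSI ~ "(MUT - WT)"),
                  y = expression(-log[10] ~ p), colour = "significant") +
    ggplot2::theme_minimal()
}
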