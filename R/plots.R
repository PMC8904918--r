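#' Plot the annual reporting trend
#'
#' Bar chart of report counts per receipt year, optionally stacked by drug.
#'
#' @param x An [icsr_set()].
#' @param window Optional study window passed to [annual_trend()].
#' @param by_drug Stack bars by suspected-drug row label?
#' @return A ggplot object.
#' @export
plot_annual_trend <- function(x, window = NULL, by_drug = FALSE) {
  tr <- annual_trend(x, window = window, by_drug = by_drug)
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$year, y = .data$n))
  if (by_drug) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$drug))
  } else {
    p <- p + ggplot2::geom_col(fill = "steelblue")
  }
  p +
    ggplot2::scale_x_continuous(breaks = scales_breaks(tr$year)) +
    ggplot2::labs(x = "Year of receipt", y = "Reports",
                  title = "Annual ADR reporting trend") +
    ggplot2::theme_minimal()
}

# integer breaks without pulling in the scales package
scales_breaks <- function(years) {
  u <- sort(unique(years))
  if (length(u) > 10) u[seq(1, length(u), by = 2)] else u
}

#' Forest-style plot of a signal screen
#'
#' Log-scale point estimates with Woolf 95% intervals for the emitted
#' unexpected signals, ordered by ROR. The vertical line at 1 marks no
#' disproportionality.
#'
#' @param object A `pv_screen` from [screen_signals()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pv_screen <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (nrow(df) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No unexpected signals") +
             ggplot2::theme_minimal())
  }
  df$pair <- paste(df$drug, df$pt, sep = " — ")
  df$pair <- factor(df$pair, levels = rev(df$pair))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$pair)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Reporting odds ratio (log scale)", y = NULL,
                  title = "Unexpected disproportionality signals",
                  subtitle = "Woolf 95% confidence intervals") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot time-to-onset distributions per drug
#'
#' Box-and-whisker summary of per-reaction times to onset for each suspected
#' drug, on a log axis (onset times in spontaneous reports are heavily
#' right-skewed).
#'
#' @param x An [icsr_set()].
#' @param drug_dict Drug dictionary used for axis labels.
#' @return A ggplot object.
#' @export
plot_tto <- function(x, drug_dict = ms_drug_dictionary()) {
  tt <- compute_tto_ttr(x)
  tt <- tt[!is.na(tt$tto_days) & tt$tto_days > 0, , drop = FALSE]
  lab <- drug_dict$abbrev[match(tt$code, drug_dict$code)]
  tt$drug <- ifelse(is.na(lab), tt$code, lab)
  ggplot2::ggplot(tt, ggplot2::aes(x = .data$drug, y = .data$tto_days)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Time to onset (days, log scale)",
                  title = "Time to onset by suspected drug") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
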