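#' @import ggplot2
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

nerpe_base_colors <- c(A = "#4daf4a", C = "#377eb8", G = "#000000",
                       U = "#e41a1c")

#' Plot positional product base frequencies
#'
#' Stacked per-position base composition of products, the standard view of
#' product sequence bias (an unbiased experiment sits at 0.25 per base).
#'
#' @param freq_table Output of [positional_frequencies()].
#' @param max_position Trim the x axis (default: all positions with data).
#' @return A ggplot.
#' @export
plot_positional_frequencies <- function(freq_table, max_position = NULL) {
  d <- dplyr::filter(freq_table, !is.na(.data$freq))
  if (!is.null(max_position)) {
    d <- dplyr::filter(d, .data$position <= max_position)
  }
  ggplot(d, aes(x = factor(.data$position), y = .data$freq,
                fill = .data$base)) +
    geom_col(width = 0.8) +
    geom_hline(yintercept = 0.25, linetype = "dashed", linewidth = 0.3) +
    scale_fill_manual(values = nerpe_base_colors, name = NULL) +
    labs(x = "product position (+i)", y = "frequency") +
    theme_minimal()
}

#' Plot a trimer frequency table
#'
#' All 64 trimers ordered by identity (or by frequency), with the ideal
#' uniform frequency 1/64 marked.
#'
#' @param trimer_table Output of [trimer_frequencies()].
#' @param order `"identity"` (lexicographic) or `"frequency"`.
#' @return A ggplot.
#' @export
plot_trimer_frequencies <- function(trimer_table,
                                    order = c("identity", "frequency")) {
  order <- match.arg(order)
  d <- tibble::as_tibble(trimer_table)
  lev <- if (order == "identity") d$trimer else d$trimer[order(-d$freq)]
  d$trimer <- factor(d$trimer, levels = lev)
  ggplot(d, aes(x = .data$trimer, y = .data$freq)) +
    geom_col(fill = "grey25") +
    geom_hline(yintercept = 1 / 64, linetype = "dashed", colour = "red",
               linewidth = 0.3) +
    labs(x = "product trimer", y = "frequency") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1,
                                     size = 5))
}

#' Plot the mismatch spectrum
#'
#' Heatmap of the 12 template:product mismatch types by product position.
#'
#' @param spectrum Output of [mismatch_spectrum()].
#' @param max_position Trim the x axis.
#' @return A ggplot.
#' @export
plot_mismatch_spectrum <- function(spectrum, max_position = NULL) {
  d <- spectrum
  if (!is.null(max_position)) {
    d <- dplyr::filter(d, .data$position <= max_position)
  }
  ggplot(d, aes(x = factor(.data$position), y = .data$type,
                fill = .data$freq)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#b2182b", name = "frequency") +
    labs(x = "product position (+i)", y = "mismatch (template:product)") +
    theme_minimal()
}

#' Plot cumulative incorporation by position
#'
#' The fraction of all primers extended to at least each position, split into
#' correct and incorrect calls at that position.
#'
#' @param cumulative The `cumulative_incorporation` tibble from
#'   [yield_and_lengths()] or a `nerpe_stats` bundle.
#' @return A ggplot.
#' @export
plot_cumulative_incorporation <- function(cumulative) {
  d <- tidyr::pivot_longer(cumulative, c("correct", "incorrect"),
                           names_to = "call", values_to = "fraction_part")
  ggplot(d, aes(x = .data$position, y = .data$fraction_part,
                fill = .data$call)) +
    geom_col() +
    scale_fill_manual(values = c(correct = "grey30", incorrect = "#e41a1c"),
                      name = NULL) +
    labs(x = "product position (+i)", y = "fraction of primers") +
    theme_minimal()
}

#' Autoplot a statistics bundle
#'
#' @param object A `nerpe_stats` object.
#' @param which One of `"positional"`, `"trimer"`, `"spectrum"`,
#'   `"cumulative"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.nerpe_stats <- function(object, which = c("positional", "trimer",
                                                   "spectrum", "cumulative"),
                                 ...) {
  which <- match.arg(which)
  switch(which,
    positional = plot_positional_frequencies(object$positional_complementary),
    trimer = {
      if (is.null(object$trimer_123)) {
        abort("bundle has no trimer table", class = "nerpeseq_data_error")
      }
      plot_trimer_frequencies(object$trimer_123)
    },
    spectrum = plot_mismatch_spectrum(object$mismatch_spectrum),
    cumulative = plot_cumulative_incorporation(object$cumulative_incorporation)
  )
}
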