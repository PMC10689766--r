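# ggplot2 views of the main result types.

#' Plot a coverage profile with optional prophage calls
#'
#' Depth is binned (mean per bin) for plotting; called intervals are shaded.
#'
#' @param object A `vip_coverage`.
#' @param calls Optional call tibble to overlay.
#' @param bin_bp Bin width in bp (default 500).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vip_coverage <- function(object, calls = NULL, bin_bp = 500L, ...) {
  depth <- object$depth
  n <- length(depth)
  bin <- (seq_len(n) - 1L) %/% bin_bp
  df <- tibble(pos = tapply(seq_len(n) - 1L, bin, mean),
               depth = tapply(depth, bin, mean))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$background, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = paste0("position on ", object$genome_id, " (bp)"),
                  y = "depth", title = "virion read coverage") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls)) {
    p <- p + ggplot2::geom_rect(
      data = calls,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick",
      inherit.aes = FALSE)
  }
  p
}

#' @rdname autoplot.vip_coverage
#' @param x A `vip_detection`.
#' @export
autoplot.vip_detection <- function(x, bin_bp = 500L, ...) {
  autoplot.vip_coverage(x$profile, calls = x$calls, bin_bp = bin_bp, ...)
}

#' Bar plot of per-prophage titres
#'
#' @param titres Tibble from [quantify_prophages()].
#' @return A ggplot (log10 titre axis).
#' @export
plot_titres <- function(titres) {
  ggplot2::ggplot(titres,
                  ggplot2::aes(x = .data$label, y = .data$titre)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "titre (virions/mL)",
                  title = "induced prophage titres") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot prediction performance per active prophage
#'
#' Best base recall per active prophage, coloured by matched status, with
#' the match threshold marked.
#'
#' @param object A `vip_match`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vip_match <- function(object, ...) {
  ggplot2::ggplot(object$per_active,
                  ggplot2::aes(x = .data$active, y = .data$best_recall,
                               fill = .data$matched)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$recall_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "best base recall",
                  title = "prediction coverage of active prophages") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
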