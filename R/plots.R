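#' Plot a flexibility profile
#'
#' Per-residue deviation along each chain, with the conventional 0-10
#' Angstrom display window marked.
#'
#' @param object a `flex_profile` tibble
#' @param scale_max upper display reference line (default 10)
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.flex_profile <- function(object, scale_max = 10, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$resno, y = .data$deviation)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = scale_max, linetype = "dashed",
                        color = "grey50") +
    ggplot2::facet_wrap(~chain) +
    ggplot2::labs(x = "residue", y = "deviation (Å)",
                  title = paste0("flexibility profile (",
                                 attr(object, "mode"), ")")) +
    ggplot2::theme_minimal()
}

#' Plot validated crosslink distances
#'
#' One bar per mapped crosslink, sorted by distance, coloured by
#' satisfaction status, with the distance threshold marked — the
#' standard summary of a crosslink validation run.
#'
#' @param object an `xl_validation` object
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.xl_validation <- function(object, ...) {
  links <- object$links[object$links$status != "unmapped", ]
  links <- links[order(links$distance), ]
  links$idx <- seq_len(nrow(links))
  ggplot2::ggplot(links,
                  ggplot2::aes(x = .data$idx, y = .data$distance,
                               fill = .data$status)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = object$d_max, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(satisfied = "forestgreen",
                                          violated = "firebrick")) +
    ggplot2::labs(x = "crosslink (sorted)",
                  y = "Cα–Cα distance (Å)") +
    ggplot2::theme_minimal()
}

#' Bar plot of per-subunit-pair crosslink counts
#'
#' @param x an `xl_validation` object or mapped crosslink tibble
#' @param ... passed to [summarize_pairs()]
#' @return a ggplot
#' @export
plot_pair_counts <- function(x, ...) {
  pc <- summarize_pairs(x, ...)
  pc$pair <- paste(pc$sub_a, pc$sub_b, sep = "–")
  ggplot2::ggplot(pc, ggplot2::aes(x = stats::reorder(.data$pair, -.data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "subunit pair", y = "crosslinks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
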