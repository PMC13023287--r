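#' Plot a transcript accessibility profile
#'
#' Per-base unpaired probability along the transcript with the accessibility
#' threshold drawn as a dashed line.
#'
#' @param object An `accessibility_profile` from [unpaired_profile()].
#' @param threshold Threshold line to draw (default 0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot accessibility_profile
#' @export
autoplot.accessibility_profile <- function(object, threshold = 0.5, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data$p_unp)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "transcript position (nt)",
                  y = expression(P[unp]),
                  title = "RNA accessibility profile") +
    ggplot2::theme_minimal()
}

#' Plot screen results as TFO1 counts against their controls
#'
#' One panel row per pair: target count versus the shuffled and control
#' counts, coloured by tier.
#'
#' @param object A `triplex_screen` from [run_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot triplex_screen
#' @export
autoplot.triplex_screen <- function(object, ...) {
  ev <- object$evaluations
  if (nrow(ev) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "no evaluated pairs"))
  }
  ev$pair <- paste(ev$gene_id, ev$label, sep = "-")
  long <- tidyr::pivot_longer(
    ev, c("target", "shuffled_lncrna", "shuffled_target", "control"),
    names_to = "run", values_to = "count")
  long$run <- factor(long$run,
                     levels = c("target", "shuffled_lncrna",
                                "shuffled_target", "control"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$run, y = .data$count,
                                     fill = .data$tier)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~pair) +
    ggplot2::scale_fill_manual(values = c(high_confidence = "#1b9e77",
                                          partial = "#7570b3",
                                          rejected = "#d95f02"),
                               drop = FALSE) +
    ggplot2::labs(x = NULL, y = "TFO1 overlapping triplexes",
                  title = "Triplex density vs permutation and control runs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Coverage plot of triplex hits along the target
#'
#' Per-base overlap depth of hit TTS intervals, with the TFO1 peak shaded.
#'
#' @param hits Hit tibble from [scan_triplexes()].
#' @param cluster Optional [select_tfo1()] cluster to highlight.
#' @return A ggplot object.
#' @export
plot_triplex_density <- function(hits, cluster = NULL) {
  if (nrow(hits) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "no triplex hits"))
  }
  lo <- min(hits$tts_start); hi <- max(hits$tts_end)
  pos <- seq(lo, hi)
  depth <- vapply(pos, function(p) sum(hits$tts_start <= p & hits$tts_end >= p),
                  numeric(1))
  df <- tibble(pos = pos, depth = depth)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "#a6bddb") +
    ggplot2::geom_line(colour = "#2b8cbe") +
    ggplot2::labs(x = "target position (bp)", y = "overlapping triplexes",
                  title = "Triplex hit density on the target") +
    ggplot2::theme_minimal()
  if (!is.null(cluster) && cluster$hit_count > 0) {
    p <- p + ggplot2::annotate("rect", xmin = cluster$peak_start,
                               xmax = cluster$peak_end, ymin = 0,
                               ymax = max(depth), alpha = 0.25,
                               fill = "#fec44f")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
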