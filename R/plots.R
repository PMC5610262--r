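#' Ternary plot of color signatures
#'
#' Plots normalized color signatures inside the unit equilateral triangle
#' (red, green, blue vertices), the standard visual check of clonal
#' structure: cells of one clone form a tight cluster, singletons sit
#' apart.
#'
#' @param sig data.frame of signatures (`r_pct`, `g_pct`, `b_pct`);
#'   optional `clone_id` column colors points by clone.
#' @return A ggplot object.
#' @examples
#' sig <- normalizeSignature(data.frame(r_mean = c(2, 1), g_mean = c(1, 3),
#'                                      b_mean = c(1, 1)))
#' plotTernary(sig)
#' @export
plotTernary <- function(sig) {
  uv <- cbind(ternaryCoordinates(sig), sig)
  tri <- data.frame(u = c(0, 1, 0.5, 0), v = c(0, 0, sqrt(3) / 2, 0))
  lab <- data.frame(u = c(-0.03, 1.03, 0.5), v = c(-0.03, -0.03,
                                                   sqrt(3) / 2 + 0.05),
                    txt = c("R", "G", "B"))
  p <- ggplot2::ggplot(uv, ggplot2::aes(x = .data$u, y = .data$v)) +
    ggplot2::geom_path(data = tri, color = "grey40") +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(label = .data$txt), size = 4) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if ("clone_id" %in% names(uv))
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$clone_id),
                                 size = 2) +
      ggplot2::labs(color = "clone")
  else p <- p + ggplot2::geom_point(size = 2)
  p
}

#' Plot normalized calcium traces with the stimulus schedule
#'
#' Normalized fluorescence over time with the stimulation phases shaded,
#' the standard view of glucose-responsiveness recordings.
#'
#' @param traces either a [NormalizedTrace-class] or a list of them.
#' @param protocol the [StimulusProtocol-class].
#' @return A ggplot object.
#' @export
plotTraces <- function(traces, protocol) {
  stopifnot(is(protocol, "StimulusProtocol"))
  if (is(traces, "NormalizedTrace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(cell_id = tr@cellId, t = tr@t, f_norm = tr@fNorm)))
  ph <- phases(protocol)
  ph$label <- factor(ph$label, levels = unique(ph$label))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(data = ph,
                       ggplot2::aes(xmin = .data$t_start,
                                    xmax = .data$t_end,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$label),
                       alpha = 0.15, inherit.aes = FALSE) +
    ggplot2::geom_line(ggplot2::aes(x = .data$t, y = .data$f_norm,
                                    color = .data$cell_id)) +
    ggplot2::labs(x = "time (s)", y = "(F - F0) / (Fmax - F0)",
                  fill = "phase", color = "cell") +
    ggplot2::theme_minimal()
}
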