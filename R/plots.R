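## Evaluation charts: score gauge, Q-value chart, active/passive system
## grid. Values are ceiling-rounded at render time only ("rounded up" for
## presentability); stored results stay exact.

band_fill <- c(low = "#2c9c46", moderate = "#e0c000", high = "#e07b00",
               critical = "#c0392b")

plot_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    svg = grDevices::svg(path, width = width, height = height),
    png = grDevices::png(path, width = width * 96, height = height * 96,
                         res = 96, type = "cairo"),
    stop("unsupported chart format '", ext, "' (use .svg or .png): ", path)
  )
}

write_plot <- function(p, path, width, height) {
  plot_device(path, width, height)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}

band_palette <- function(labels) {
  known <- band_fill[labels]
  if (anyNA(known)) {
    known <- grDevices::hcl.colors(length(labels), "Temps")
  }
  setNames(unname(known), labels)
}

#' Render the total-score gauge
#'
#' A linear gauge over the achievable score range, shaded by risk band,
#' with the achieved score marked. The minimum (basic) and maximum possible
#' values anchor the scale; displayed numbers are rounded up.
#'
#' @param result a `rimeda_result`.
#' @param path output file, `.svg` (canonical) or `.png`.
#' @param scheme band scheme; defaults to four equal-width bands.
#' @param width,height device size in inches.
#' @return the path, invisibly.
#' @export
render_gauge <- function(result, path, scheme = risk_bands(),
                         width = 8, height = 2.4) {
  stopifnot(inherits(result, "rimeda_result"))
  edges <- band_edges(scheme, result$score_bounds)
  bands <- data.frame(xmin = edges[-length(edges)], xmax = edges[-1],
                      band = factor(scheme$labels, levels = scheme$labels))
  score <- ceiling(result$total_score)
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = 0, ymax = 1,
                   fill = .data$band),
      colour = "white", linewidth = 0.4) +
    ggplot2::annotate("segment", x = result$total_score,
                      xend = result$total_score, y = -0.12, yend = 1.12,
                      linewidth = 1.1) +
    ggplot2::annotate("label", x = result$total_score, y = 1.35,
                      label = sprintf("score %s (%s)", format(score),
                                      result$band), size = 3.4) +
    ggplot2::scale_x_continuous(breaks = round(edges, 1)) +
    ggplot2::scale_fill_manual(values = band_palette(scheme$labels),
                               name = "risk band") +
    ggplot2::coord_cartesian(ylim = c(-0.3, 1.6)) +
    ggplot2::labs(title = "Total re-identification risk score",
                  subtitle = sprintf("achievable range [%s, %s]",
                                     format(ceiling(result$score_bounds[["min"]])),
                                     format(ceiling(result$score_bounds[["max"]]))),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 11) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  write_plot(p, path, width, height)
}

#' Render the Q-value chart
#'
#' Signed bars of the per-entity Q-values ordered by decreasing |Q|;
#' risk-increasing (positive) and risk-reducing (negative) entities are
#' visually distinct. Bar heights are rounded up for display.
#'
#' @inheritParams render_gauge
#' @export
render_q_chart <- function(result, path, width = 7, height = 4.5) {
  stopifnot(inherits(result, "rimeda_result"))
  idx <- result$indices
  idx <- idx[order(-abs(idx$q_value), idx$entity), , drop = FALSE]
  idx$entity <- factor(idx$entity, levels = idx$entity)
  idx$direction <- factor(
    ifelse(idx$q_value >= 0, "risk-increasing", "risk-reducing"),
    levels = c("risk-increasing", "risk-reducing"))
  idx$q_display <- ceiling(idx$q_value)
  p <- ggplot2::ggplot(idx,
         ggplot2::aes(x = .data$entity, y = .data$q_display,
                      fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(
      values = c("risk-increasing" = "#c0392b", "risk-reducing" = "#2c7fb8"),
      drop = FALSE, name = NULL) +
    ggplot2::labs(title = "Q-values (cross-linkage) of the influencing factors",
                  subtitle = sprintf("convention '%s'; ordered by |Q|",
                                     result$q_convention),
                  x = NULL, y = "Q-value") +
    ggplot2::theme_minimal(base_size = 11)
  write_plot(p, path, width, height)
}

#' Render the active/passive system grid
#'
#' Each entity is plotted as the pair (active sum, passive sum) in a
#' Cartesian plane: abscissa = influence exerted on the system, ordinate =
#' influence received from it. The plane carries equal-size subdivisions
#' marking increasingly strong value pairs; axes include the origin, and
#' all four quadrants are shown whenever any sum is negative. Plotted
#' coordinates are rounded up; stored values stay exact.
#'
#' @inheritParams render_gauge
#' @param subdivisions number of equal-size subdivisions per axis side.
#' @export
render_system_grid <- function(result, path, subdivisions = 4,
                               width = 6.5, height = 6) {
  stopifnot(inherits(result, "rimeda_result"))
  idx <- result$indices
  idx$x <- ceiling(idx$active_sum)
  idx$y <- ceiling(idx$passive_sum)
  lim <- max(abs(c(idx$x, idx$y, 1)))
  any_negative <- any(idx$x < 0 | idx$y < 0)
  lims <- if (any_negative) c(-lim, lim) else c(0, lim)
  step <- diff(lims) / subdivisions
  grid_lines <- seq(lims[1], lims[2], by = step)
  p <- ggplot2::ggplot(idx, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = grid_lines, colour = "grey85",
                        linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = grid_lines, colour = "grey85",
                        linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.4) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$category), size = 2.4) +
    ggplot2::geom_text(ggplot2::aes(label = .data$entity),
                       nudge_y = diff(lims) / 45, size = 3.1) +
    ggplot2::scale_colour_manual(values = c(
      active = "#c0392b", reactive = "#2c7fb8",
      critical = "#7b3294", inert = "#5aae61"), drop = FALSE,
      name = "category") +
    ggplot2::coord_fixed(xlim = lims, ylim = lims, expand = TRUE) +
    ggplot2::labs(title = "System grid of the influencing factors",
                  subtitle = sprintf("%d equal subdivisions per axis",
                                     subdivisions),
                  x = "active sum (influence exerted)",
                  y = "passive sum (influence received)") +
    ggplot2::theme_minimal(base_size = 11) +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  write_plot(p, path, width, height)
}

#' @importFrom ggplot2 .data
NULL
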