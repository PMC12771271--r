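# ggplot2 rendering of the layered figures. Acceptance surfaces are the
# RenderReport counts and the layout artefacts, not pixels: image bytes are
# backend-dependent, the structural claims are not.

# 16 built-in palettes. Theme 1 ("classic") matches the described defaults:
# blue set points, alternating yellow/orange variants.
.arch_themes <- list(
  classic    = list(variant = c("#F2C14E", "#E07A2F"), set = "#2B6CB0", set2 = "#63B3ED",
                    edge = "#A0AEC0", threshold = "#C53030", background = "#FFFFFF"),
  ocean      = list(variant = c("#7FB3D5", "#2E86C1"), set = "#0B3C5D", set2 = "#66A5AD",
                    edge = "#B0C4DE", threshold = "#D64545", background = "#FFFFFF"),
  sunset     = list(variant = c("#F9A03F", "#D45113"), set = "#5D2A42", set2 = "#A26769",
                    edge = "#C9ADA7", threshold = "#861657", background = "#FFFFFF"),
  forest     = list(variant = c("#A3B18A", "#588157"), set = "#344E41", set2 = "#3A5A40",
                    edge = "#B7B7A4", threshold = "#BC4749", background = "#FFFFFF"),
  lagoon     = list(variant = c("#80CED7", "#007EA7"), set = "#003249", set2 = "#9AD1D4",
                    edge = "#CCDBDC", threshold = "#D1495B", background = "#FFFFFF"),
  ember      = list(variant = c("#F4A259", "#BC4B51"), set = "#5B8E7D", set2 = "#8CB369",
                    edge = "#C8BFC7", threshold = "#8C1C13", background = "#FFFFFF"),
  orchid     = list(variant = c("#C77DFF", "#7B2CBF"), set = "#10002B", set2 = "#9D4EDD",
                    edge = "#CDB4DB", threshold = "#E5383B", background = "#FFFFFF"),
  slate      = list(variant = c("#ADB5BD", "#495057"), set = "#212529", set2 = "#6C757D",
                    edge = "#CED4DA", threshold = "#D00000", background = "#FFFFFF"),
  citrus     = list(variant = c("#FFD166", "#EF8354"), set = "#118AB2", set2 = "#06D6A0",
                    edge = "#BFC0C0", threshold = "#EF476F", background = "#FFFFFF"),
  berry      = list(variant = c("#FF8FA3", "#C9184A"), set = "#590D22", set2 = "#FF4D6D",
                    edge = "#D8BFD8", threshold = "#343A40", background = "#FFFFFF"),
  tidepool   = list(variant = c("#90E0EF", "#0077B6"), set = "#03045E", set2 = "#00B4D8",
                    edge = "#CAF0F8", threshold = "#E63946", background = "#FFFFFF"),
  harvest    = list(variant = c("#E9C46A", "#E76F51"), set = "#264653", set2 = "#2A9D8F",
                    edge = "#C4C4B7", threshold = "#9B2226", background = "#FFFFFF"),
  glacier    = list(variant = c("#BDE0FE", "#5390D9"), set = "#1B4965", set2 = "#62B6CB",
                    edge = "#CAE9FF", threshold = "#FF5A5F", background = "#FFFFFF"),
  meadow     = list(variant = c("#B5E48C", "#52B69A"), set = "#184E77", set2 = "#34A0A4",
                    edge = "#D9ED92", threshold = "#BC4749", background = "#FFFFFF"),
  dusk       = list(variant = c("#FCBF49", "#F77F00"), set = "#003049", set2 = "#669BBC",
                    edge = "#BFC3C6", threshold = "#D62828", background = "#FFFFFF"),
  monochrome = list(variant = c("#BDBDBD", "#616161"), set = "#000000", set2 = "#424242",
                    edge = "#E0E0E0", threshold = "#9E9E9E", background = "#FFFFFF")
)

#' Built-in colour themes
#'
#' @return Named list of the 16 built-in palettes; each defines the
#'   alternating variant colour pair, set colour(s), edge colour,
#'   threshold-line colour and background, all as hex strings.
#' @export
arch_themes <- function() .arch_themes

get_theme <- function(name) {
  th <- .arch_themes[[name]]
  if (is.null(th)) {
    stop_config(sprintf("unknown theme '%s'; available: %s", name,
                        paste(names(.arch_themes), collapse = ", ")))
  }
  th
}

#' Plot options
#'
#' Customisation toggles for the rendered figures: title, subtitle, colours
#' and colour labels, the critical threshold line, genomic-coordinate axis
#' labels, legend visibility, edge highlighting, dual-colour significant
#' sets, and outlier trimming.
#'
#' @param title,subtitle Figure text.
#' @param show_title,show_subtitle,show_legend,show_threshold_line Toggles.
#' @param show_genomic_coordinate Label the x-axis in cumulative bp instead
#'   of chromosome names only.
#' @param colour_labels Named character vector overriding the legend labels
#'   for groups `variant`, `set`, `significant`.
#' @param theme Name of a built-in palette (see [arch_themes()]).
#' @param highlight_significant_edges_only Draw edges only for the
#'   significantly enriched sets (default); `FALSE` reveals all connections.
#' @param dual_colour_significant_sets Alternate two colours over the
#'   significant set points.
#' @param y_cap Optional `-log10(p)` cap: points above it are excluded from
#'   the figure and counted in the report's `trimmed` field (outlier
#'   trimming for distracting extreme signals).
#' @return A `plot_options` list.
#' @export
plot_options <- function(title = "Archipelago plot", subtitle = NULL,
                         show_title = TRUE, show_subtitle = TRUE,
                         show_legend = TRUE, show_threshold_line = TRUE,
                         show_genomic_coordinate = FALSE,
                         colour_labels = NULL, theme = "classic",
                         highlight_significant_edges_only = TRUE,
                         dual_colour_significant_sets = FALSE,
                         y_cap = NULL) {
  get_theme(theme)  # validates
  labs <- c(variant = "variant P value", set = "VSAT P value",
            significant = "significant set")
  if (!is.null(colour_labels)) labs[names(colour_labels)] <- colour_labels
  structure(list(title = title, subtitle = subtitle, show_title = show_title,
                 show_subtitle = show_subtitle, show_legend = show_legend,
                 show_threshold_line = show_threshold_line,
                 show_genomic_coordinate = show_genomic_coordinate,
                 colour_labels = labs, theme = theme,
                 highlight_significant_edges_only = highlight_significant_edges_only,
                 dual_colour_significant_sets = dual_colour_significant_sets,
                 y_cap = y_cap),
            class = "plot_options")
}

render_report <- function(path, points, variant_points, set_points, edges,
                          trimmed = 0L, layers = 2L, extra = list()) {
  structure(c(list(path = path, points = points,
                   variant_points = variant_points, set_points = set_points,
                   edges = edges, trimmed = trimmed, layers = layers),
              extra),
            class = "render_report")
}

#' @export
print.render_report <- function(x, ...) {
  cat("<render_report>\n")
  for (f in setdiff(names(x), "path")) {
    v <- x[[f]]
    if (is.numeric(v) && length(v) > 1L) v <- paste(signif(v, 6), collapse = ", ")
    cat(sprintf("  %s = %s\n", f, paste(v, collapse = ", ")))
  }
  cat(sprintf("  path = %s\n", x$path))
  invisible(x)
}

#' Serialise a render report as a key-value text block
#'
#' @param report A `render_report`.
#' @param path Optional file to write the block to.
#' @return The lines, invisibly when written to file.
#' @export
format_render_report <- function(report, path = NULL) {
  flat <- vapply(names(report), function(f) {
    paste0(f, "=", paste(format(report[[f]], digits = 15), collapse = ","))
  }, character(1))
  if (!is.null(path)) {
    writeLines(flat, path)
    return(invisible(flat))
  }
  flat
}

save_figure <- function(plot, out, width = 11, height = 5.5, dpi = 300) {
  ext <- tolower(tools::file_ext(out))
  dir <- dirname(out)
  if (!dir.exists(dir)) stop_config(sprintf("output directory does not exist: %s", dir))
  dev <- switch(ext,
                png = if (requireNamespace("ragg", quietly = TRUE)) ragg::agg_png else grDevices::png,
                pdf = grDevices::pdf,
                svg = grDevices::svg,
                stop_config(sprintf("unsupported image format '.%s' (use png, pdf or svg)", ext)))
  ggplot2::ggsave(out, plot = plot, device = dev, width = width,
                  height = height, dpi = dpi, units = "in")
  if (!file.exists(out) || file.size(out) == 0) {
    stop_config(sprintf("failed to write figure: %s", out))
  }
  invisible(out)
}

arch_plot_theme <- function(th, options) {
  ggplot2::theme_minimal(base_size = 12) +
    ggplot2::theme(
      panel.background = ggplot2::element_rect(fill = th$background, colour = NA),
      plot.background = ggplot2::element_rect(fill = th$background, colour = NA),
      panel.grid.major.x = ggplot2::element_blank(),
      panel.grid.minor = ggplot2::element_blank(),
      legend.position = if (isTRUE(options$show_legend)) "bottom" else "none",
      plot.title = if (isTRUE(options$show_title)) ggplot2::element_text(face = "bold")
                   else ggplot2::element_blank(),
      plot.subtitle = if (isTRUE(options$show_subtitle)) ggplot2::element_text()
                      else ggplot2::element_blank())
}

#' Render the archipelago figure
#'
#' Draws, in z-order: set-to-variant edges, variant points (alternating
#' colour by chromosome parity), set points (significant sets emphasised),
#' the significance threshold line, and the legend. Points above `y_cap`
#' are excluded and counted in the report. The returned report's counts
#' equal the layout's counts after the declared filtering - rendering never
#' silently drops data.
#'
#' @param layout An [assemble_layout()] result.
#' @param options A [plot_options()] list.
#' @param out Output image path; format by extension (`.png` default 300
#'   dpi, `.pdf`, `.svg`).
#' @return A `render_report` (point/edge/layer counts, trimmed count,
#'   output path).
#' @export
render_archipelago <- function(layout, options = plot_options(), out) {
  stopifnot(inherits(layout, "archipelago_layout"))
  th <- get_theme(options$theme)
  pts <- layout$points
  if (nrow(pts) == 0L) stop_input("cannot render an empty layout")

  trimmed <- 0L
  if (!is.null(options$y_cap)) {
    drop <- pts$y > options$y_cap
    trimmed <- sum(drop)
    pts <- pts[!drop, , drop = FALSE]
  }

  vp <- pts[pts$layer == "variant", , drop = FALSE]
  sp <- pts[pts$layer == "set", , drop = FALSE]

  edges <- layout$edges
  if (isTRUE(options$highlight_significant_edges_only) && nrow(edges) > 0L) {
    edges <- edges[edges$significant, , drop = FALSE]
  }
  # resolve edge endpoint coordinates; endpoints trimmed away drop the edge
  ex <- data.frame(
    x = sp$x[match(edges$set_id, sp$id)],
    y = sp$y[match(edges$set_id, sp$id)],
    xend = vp$x[match(edges$variant_id, vp$id)],
    yend = vp$y[match(edges$variant_id, vp$id)])
  ex <- ex[stats::complete.cases(ex), , drop = FALSE]

  sig_sets <- sp[sp$significant, , drop = FALSE]
  set_cols <- if (isTRUE(options$dual_colour_significant_sets)) {
    c(th$set, th$set2)
  } else {
    c(th$set, th$set)
  }

  g <- ggplot2::ggplot()
  if (nrow(ex) > 0L) {
    g <- g + ggplot2::geom_segment(
      data = ex,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = th$edge, linewidth = 0.3, alpha = 0.7)
  }
  g <- g +
    ggplot2::geom_point(
      data = vp,
      ggplot2::aes(x = .data$x, y = .data$y,
                   colour = factor(.data$colour_group, levels = c(1L, 2L))),
      size = 1.1) +
    ggplot2::scale_colour_manual(
      values = stats::setNames(th$variant, c("1", "2")),
      labels = rep(options$colour_labels[["variant"]], 2L),
      name = NULL, guide = if (isTRUE(options$show_legend)) "legend" else "none") +
    ggplot2::geom_point(
      data = sp,
      ggplot2::aes(x = .data$x, y = .data$y,
                   fill = factor(.data$colour_group, levels = c(1L, 2L))),
      shape = 21, colour = "grey20", size = 2.4, stroke = 0.2) +
    ggplot2::scale_fill_manual(
      values = stats::setNames(set_cols, c("1", "2")),
      labels = c(options$colour_labels[["set"]],
                 options$colour_labels[["significant"]]),
      name = NULL, guide = if (isTRUE(options$show_legend)) "legend" else "none")
  if (nrow(sig_sets) > 0L) {
    g <- g + ggplot2::geom_point(
      data = sig_sets, ggplot2::aes(x = .data$x, y = .data$y),
      shape = 21, fill = NA, colour = th$threshold, size = 3.4, stroke = 0.5)
  }
  if (isTRUE(options$show_threshold_line)) {
    g <- g + ggplot2::geom_hline(yintercept = -log10(layout$threshold),
                                 colour = th$threshold, linetype = "dashed",
                                 linewidth = 0.4)
  }

  ticks <- chrom_tick_positions(layout$axis)
  g <- g +
    ggplot2::scale_x_continuous(
      breaks = unname(ticks),
      labels = if (isTRUE(options$show_genomic_coordinate)) {
        sprintf("%s\n%.0f", names(ticks), ticks)
      } else {
        names(ticks)
      },
      expand = ggplot2::expansion(mult = 0.01)) +
    ggplot2::labs(
      title = if (isTRUE(options$show_title)) options$title else NULL,
      subtitle = if (isTRUE(options$show_subtitle)) options$subtitle else NULL,
      x = "chromosome", y = expression(-log[10](italic(p)))) +
    arch_plot_theme(th, options)

  save_figure(g, out)
  render_report(out, points = nrow(pts), variant_points = nrow(vp),
                set_points = nrow(sp), edges = nrow(ex), trimmed = trimmed,
                layers = 2L,
                extra = list(significant_sets = nrow(sig_sets),
                             theme = options$theme))
}

#' Render the raw ranked VSAT view
#'
#' The comparison panel without genomic anchoring: set-level P values have
#' no natural x-axis position, so they are plotted against their rank
#' (ascending P, strongest first) or the given input order.
#'
#' @param sets Set results data frame (`set_id`, `p`).
#' @param order `"p_rank"` or `"given"`.
#' @param out Output image path.
#' @param options A [plot_options()] list.
#' @param threshold Optional significance threshold for the dashed line.
#' @return A `render_report` with the plotted point count.
#' @export
render_raw_vsat <- function(sets, order = c("p_rank", "given"), out,
                            options = plot_options(title = "Raw VSAT P values"),
                            threshold = NULL) {
  order <- match.arg(order)
  th <- get_theme(options$theme)
  if (nrow(sets) == 0L) stop_input("no set results to render")
  df <- if (order == "p_rank") sets[order(sets$p, sets$set_id), , drop = FALSE] else sets
  df$x <- seq_len(nrow(df))
  df$y <- -log10(df$p)

  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(colour = th$set, size = 1.8) +
    ggplot2::labs(
      title = if (isTRUE(options$show_title)) options$title else NULL,
      subtitle = if (isTRUE(options$show_subtitle)) options$subtitle else NULL,
      x = if (order == "p_rank") "rank (ascending P)" else "input order",
      y = expression(-log[10](italic(p)))) +
    arch_plot_theme(th, options)
  if (!is.null(threshold) && isTRUE(options$show_threshold_line)) {
    g <- g + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 colour = th$threshold, linetype = "dashed")
  }
  save_figure(g, out, width = 7, height = 5)
  render_report(out, points = nrow(df), variant_points = 0L,
                set_points = nrow(df), edges = 0L, layers = 1L,
                extra = list(order = order))
}

#' Render the three-panel annotation (ACAT) drill-down
#'
#' Panel 1: the archipelago view restricted to the focus sets, with their
#' member variants in a distinct colour. Panel 2: per-variant annotation P
#' values for every layer, with horizontal per-layer mean lines (the
#' contribution hierarchy, [layer_means()]). Panel 3: panel 2 plus a
#' per-variant min-max spread overlay ([variant_spread()]).
#'
#' @param layout An [assemble_layout()] result.
#' @param m An [annotation_matrix()] covering the focus sets' members.
#' @param focus_sets Character vector of set IDs to drill into.
#' @param out Output image path.
#' @param options A [plot_options()] list.
#' @return A `render_report`; `panel2_points` is the variant x layer count
#'   and `layer_means` the per-layer means drawn in panel 2.
#' @export
render_acat_panels <- function(layout, m, focus_sets, out,
                               options = plot_options(title = "Annotation layer drill-down")) {
  stopifnot(inherits(layout, "archipelago_layout"),
            inherits(m, "annotation_matrix"))
  th <- get_theme(options$theme)
  all_edges <- layout$edges
  members <- unique(all_edges$variant_id[all_edges$set_id %in% focus_sets])
  if (length(members) == 0L) {
    stop_input(sprintf("no layout edges for focus set(s) %s; assemble the layout with significant_only = FALSE or pick significant sets",
                       paste(focus_sets, collapse = ", ")))
  }
  annotated <- intersect(members, rownames(m$p))
  if (length(annotated) == 0L) {
    stop_input(sprintf("focus set(s) have no annotated members: %s",
                       paste(focus_sets, collapse = ", ")))
  }

  pts <- layout$points
  vp <- pts[pts$layer == "variant" & pts$id %in% members, , drop = FALSE]
  sp <- pts[pts$layer == "set" & pts$id %in% focus_sets, , drop = FALSE]

  p1 <- ggplot2::ggplot() +
    ggplot2::geom_point(data = vp, ggplot2::aes(x = .data$x, y = .data$y),
                        colour = "black", size = 1.2) +
    ggplot2::geom_point(data = sp, ggplot2::aes(x = .data$x, y = .data$y),
                        colour = th$set, size = 2.8) +
    ggplot2::geom_hline(yintercept = -log10(layout$threshold),
                        colour = th$threshold, linetype = "dashed") +
    ggplot2::labs(title = "[1] Focus sets and contributing variants",
                  x = "cumulative position (bp)",
                  y = expression(-log[10](italic(p)))) +
    arch_plot_theme(th, options)

  xs <- stats::setNames(vp$x, vp$id)[annotated]
  sub <- m$p[annotated, , drop = FALSE]
  long <- data.frame(
    variant_id = rep(rownames(sub), times = ncol(sub)),
    layer = rep(colnames(sub), each = nrow(sub)),
    p = as.vector(sub), stringsAsFactors = FALSE)
  long$x <- xs[long$variant_id]
  lmeans <- layer_means(annotation_matrix(sub, weights = m$weights))

  layer_cols <- grDevices::hcl.colors(ncol(sub), palette = "Dark 3")
  p2 <- ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$p,
                                           colour = .data$layer)) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_hline(yintercept = unname(lmeans),
                        colour = layer_cols, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = stats::setNames(layer_cols, colnames(sub))) +
    ggplot2::labs(title = "[2] Annotation P values (per-layer mean lines)",
                  x = "cumulative position (bp)", y = "annotation P value") +
    arch_plot_theme(th, options)

  spread <- variant_spread(annotation_matrix(sub, weights = m$weights))
  spread$x <- xs[spread$variant_id]
  p3 <- p2 +
    ggplot2::geom_segment(
      data = spread,
      ggplot2::aes(x = .data$x, xend = .data$x, y = .data$p_min, yend = .data$p_max),
      inherit.aes = FALSE, colour = "grey40", linewidth = 0.3) +
    ggplot2::labs(title = "[3] Per-variant spread across layers")

  combined <- patchwork::wrap_plots(p1, p2, p3, ncol = 1L)
  save_figure(combined, out, width = 8, height = 11)
  render_report(out, points = nrow(vp) + nrow(sp) + nrow(long),
                variant_points = nrow(vp), set_points = nrow(sp),
                edges = 0L, layers = 3L,
                extra = list(panel2_points = nrow(long),
                             layer_means = unname(lmeans),
                             panels = 3L))
}
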