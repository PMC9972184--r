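# Figure generation: laying out the comparison tree and serializing it as
# deterministic SVG (optionally rasterized to PNG on a graphics device).

#' Options controlling figure rendering
#'
#' @param layout One of `"pie"`, `"bar"`, `"circle"`, `"rectangular"`.
#'   `pie` and `rectangular` place nodes on a left-to-right tree with pie-arc
#'   discs; `circle` places them radially; `bar` uses stacked bars instead of
#'   arcs.
#' @param scaling Radius scaling, one of `"linear"`, `"log"`, `"sqrt"`,
#'   `"power"` (see [scale_radius()]).
#' @param power_exponent Exponent used when `scaling = "power"`; default 0.5.
#' @param max_radius Disc radius (pixels) given to the most abundant clade.
#' @param width,height Figure dimensions in pixels (height grows with the
#'   leaf count when needed).
#' @param resolution Pixel width of the optional PNG export.
#' @param label_mode Which labels to draw: `"all"`, `"leaves"`, or
#'   `"highlighted"`.
#' @param label_font_size Label font size in points.
#' @param branch_vertical_margin Vertical margin (pixels) around the tree.
#' @param leaf_separation Vertical (or angular, for circular layouts) spacing
#'   between leaves, in pixels.
#' @param mode `"normal"` (discs split by per-source abundance share) or
#'   `"contrast"` (discs colored by TP/FP/FN classification against truth).
#' @param palette Ordered source colors; defaults to green, orange, purple
#'   (tools in order, then the truth takes the next color, so a single tool
#'   versus truth renders green versus orange).
#' @param contrast_green RGB endpoint (0-255) of the white-to-green error
#'   gradient in contrast mode; intensity is clamped at relative error 1.
#' @param fp_color,fn_color Fill colors for false positives / negatives.
#' @param highlight_label_color Label color for highlighted clades.
#' @param min_radius_frac Smallest drawn disc radius as a fraction of
#'   `max_radius` (keeps near-zero but drawable clades visible).
#' @return An object of class `render_options`.
#' @export
render_options <- function(layout = c("rectangular", "pie", "bar", "circle"),
                           scaling = c("linear", "log", "sqrt", "power"),
                           power_exponent = 0.5, max_radius = 30,
                           width = 900, height = 600, resolution = 900,
                           label_mode = c("all", "leaves", "highlighted"),
                           label_font_size = 11,
                           branch_vertical_margin = 40, leaf_separation = 70,
                           mode = c("normal", "contrast"),
                           palette = c("#228B22", "#FF8C00", "#800080", "#708090"),
                           contrast_green = c(0, 128, 0),
                           fp_color = "#FF0000", fn_color = "#0000FF",
                           highlight_label_color = "#0000FF",
                           min_radius_frac = 1 / 50) {
  layout <- match.arg(layout)
  scaling <- match.arg(scaling)
  label_mode <- match.arg(label_mode)
  mode <- match.arg(mode)
  stopifnot(max_radius > 0, width > 0, height > 0, power_exponent > 0,
            resolution > 0, length(contrast_green) == 3)
  structure(list(layout = layout, scaling = scaling,
                 power_exponent = power_exponent, max_radius = max_radius,
                 width = width, height = height, resolution = resolution,
                 label_mode = label_mode, label_font_size = label_font_size,
                 branch_vertical_margin = branch_vertical_margin,
                 leaf_separation = leaf_separation, mode = mode,
                 palette = palette, contrast_green = contrast_green,
                 fp_color = fp_color, fn_color = fn_color,
                 highlight_label_color = highlight_label_color,
                 min_radius_frac = min_radius_frac),
            class = "render_options")
}

#' Disc radius for an abundance value
#'
#' Maps a percentage abundance to a radius in pixels. With `m = max_radius`,
#' `a` the abundance and `A` the largest abundance drawn:
#' linear `m a/A`; sqrt `m sqrt(a/A)`; log `m log(1+a)/log(1+A)` (the +1
#' admits zero); power `m (a/A)^p`. Every mode is strictly increasing in `a`
#' and reaches `m` at `a = A`. Zero abundance maps to radius 0; callers that
#' must still draw the node (false negatives in contrast mode) substitute the
#' minimum visible radius `max_radius * min_radius_frac`.
#'
#' @param abundance Percentage abundance(s), `0 <= abundance <= total_max`.
#' @param total_max Largest abundance on the figure; must be positive.
#' @param opts A [render_options].
#' @return Radius (pixels), vectorized over `abundance`.
#' @export
scale_radius <- function(abundance, total_max, opts = render_options()) {
  if (total_max <= 0) stop("total_max must be positive")
  f <- switch(opts$scaling,
    linear = abundance / total_max,
    sqrt = sqrt(abundance / total_max),
    log = log1p(abundance) / log1p(total_max),
    power = (abundance / total_max)^opts$power_exponent)
  opts$max_radius * f
}

#' Per-source color fractions for a clade disc
#'
#' In normal mode a clade's disc is split among the sources in proportion to
#' their reported abundance there: equal predictions give equal halves, and
#' the split shifts with the disagreement. Sources with zero abundance are
#' omitted from the arc list.
#'
#' @param abundances Named (by source) or plain numeric vector of percentage
#'   abundances at the node; at least one must be positive.
#' @param colors Colors parallel to `abundances`.
#' @return A data frame with columns `source`, `fraction`, `color`;
#'   fractions sum to 1.
#' @export
color_split <- function(abundances, colors = NULL) {
  total <- sum(abundances)
  if (total <= 0) stop("color_split: all-zero abundance vector (node should have been pruned)")
  src <- names(abundances) %||% paste0("source", seq_along(abundances))
  if (is.null(colors)) colors <- render_options()$palette[seq_along(abundances)]
  keep <- abundances > 0
  data.frame(source = src[keep], fraction = abundances[keep] / total,
             color = colors[keep], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Contrast-mode fill color for a classified clade
#'
#' False positives are red, false negatives blue; true positives interpolate
#' linearly in RGB from white (zero relative error) toward the green endpoint,
#' with intensity `min(relative_error, 1)`. At relative error 0.5 the
#' documented midpoint color is `#80C080`.
#'
#' @param status One of `"TP"`, `"FP"`, `"FN"`.
#' @param relative_error Relative abundance error (TP only).
#' @param opts A [render_options].
#' @return A hex color string.
#' @export
contrast_fill <- function(status, relative_error = 0, opts = render_options()) {
  switch(status,
    FP = opts$fp_color,
    FN = opts$fn_color,
    TP = {
      t <- min(max(relative_error, 0), 1)
      ch <- round(255 + t * (opts$contrast_green - 255))
      grDevices::rgb(ch[1], ch[2], ch[3], maxColorValue = 255)
    },
    stop("contrast_fill: cannot color a '", status,
         "' node (unreachable for drawn nodes)"))
}

#' Lay out a comparison tree for rendering
#'
#' Resolves every visual attribute: deterministic node positions for the
#' chosen layout (rectangular/pie/bar: depth on x, leaves evenly spaced on
#' y; circle: depth on radius, leaves evenly spaced by angle; internal nodes
#' centered on their children), disc radii via [scale_radius()] on the
#' node's total abundance across sources, color splits ([color_split()]) in
#' normal mode or classification fills ([contrast_fill()]) in contrast mode,
#' label visibility per `label_mode`, and highlighted-label styling.
#'
#' @param tree A [build_comparison_tree()] result.
#' @param opts A [render_options].
#' @param assessments Result of [assess_nodes()]; required in contrast mode
#'   (computed with default [comparison_options()] when omitted and a truth
#'   source is present).
#' @param highlights Character vector of highlighted taxids; defaults to
#'   [highlight_pairwise()] with default options when the tree has at least
#'   two sources.
#' @param comparison_opts [comparison_options()] used for any internally
#'   computed assessments/highlights.
#' @return An object of class `render_spec`.
#' @export
layout_tree <- function(tree, opts = render_options(), assessments = NULL,
                        highlights = NULL,
                        comparison_opts = comparison_options()) {
  if (opts$mode == "contrast" && is.null(assessments)) {
    if (!tree$has_truth) stop("contrast mode requires a ground-truth source")
    assessments <- assess_nodes(tree, comparison_opts)
  }
  if (is.null(highlights)) {
    highlights <- if (!is.null(assessments)) {
      assessments$taxid[assessments$highlighted]
    } else if (length(tree$sources) >= 2) {
      highlight_pairwise(tree, comparison_opts)
    } else character()
  }

  nd <- tree$nodes
  taxids <- nd$taxid
  kids <- split(taxids[taxids != tree$root_id],
                factor(nd$parent_id[taxids != tree$root_id], levels = taxids))
  n_children <- vapply(kids, length, integer(1))
  is_leaf <- n_children[taxids] == 0 & taxids != tree$root_id

  # deterministic depth-first leaf order, children sorted by taxid
  leaf_order <- character(0)
  dfs <- function(tid) {
    ch <- sort(kids[[tid]])
    if (length(ch) == 0) {
      leaf_order <<- c(leaf_order, tid)
    } else {
      for (c in ch) dfs(c)
    }
  }
  dfs(tree$root_id)

  depth <- stats::setNames(nd$depth, taxids)
  max_depth <- max(depth)
  margin <- opts$branch_vertical_margin
  n_leaves <- length(leaf_order)

  ypos <- stats::setNames(rep(NA_real_, length(taxids)), taxids)
  if (opts$layout == "circle") {
    angle <- stats::setNames(rep(NA_real_, length(taxids)), taxids)
    angle[leaf_order] <- (seq_len(n_leaves) - 1) * 360 / max(n_leaves, 1)
    fill_internal <- function(tid) {
      ch <- kids[[tid]]
      if (length(ch) > 0) {
        for (c in ch) fill_internal(c)
        angle[tid] <<- mean(angle[ch])
      }
    }
    fill_internal(tree$root_id)
    width <- opts$width
    height <- opts$height
    cx <- width / 2; cy <- height / 2
    rmax <- min(width, height) / 2 - margin - opts$max_radius
    rad <- pmax(depth, 0) / max(max_depth, 1) * rmax
    x <- cx + rad * cospi(angle[taxids] / 180)
    y <- cy + rad * sinpi(angle[taxids] / 180)
  } else {
    ypos[leaf_order] <- margin + (seq_len(n_leaves) - 1) * opts$leaf_separation
    fill_internal <- function(tid) {
      ch <- kids[[tid]]
      if (length(ch) > 0) {
        for (c in ch) fill_internal(c)
        ypos[tid] <<- mean(ypos[ch])
      }
    }
    fill_internal(tree$root_id)
    width <- opts$width
    height <- max(opts$height, 2 * margin + (n_leaves - 1) * opts$leaf_separation)
    label_space <- 160
    x_step <- (width - 2 * margin - label_space) / max(max_depth, 1)
    x <- margin + depth[taxids] * x_step
    y <- ypos[taxids]
  }

  total <- rowSums(tree$abundance)[taxids]
  drawn <- taxids != tree$root_id & total > 0
  total_max <- if (any(drawn)) max(total[drawn]) else 1
  radius <- rep(0, length(taxids))
  radius[drawn] <- pmax(scale_radius(total[drawn], total_max, opts),
                        opts$max_radius * opts$min_radius_frac)

  src_colors <- stats::setNames(opts$palette[seq_along(tree$sources)],
                                tree$sources)
  fill <- rep(NA_character_, length(taxids))
  segments <- stats::setNames(vector("list", length(taxids)), taxids)
  for (i in seq_along(taxids)) {
    tid <- taxids[i]
    if (!drawn[i]) next
    if (opts$mode == "contrast") {
      st <- assessments[tid, "status"]
      if (is.na(st) || st == "both-absent") next
      re <- assessments[tid, "relative_error"]
      fill[i] <- contrast_fill(st, if (is.na(re)) 0 else re, opts)
    } else {
      segments[[tid]] <- color_split(tree$abundance[tid, ], src_colors)
    }
  }

  highlighted <- taxids %in% highlights
  label_visible <- switch(opts$label_mode,
    all = drawn,
    leaves = drawn & is_leaf[taxids],
    highlighted = drawn & highlighted)

  edges <- nd[nd$taxid != tree$root_id, c("taxid", "parent_id")]
  pos <- stats::setNames(seq_along(taxids), taxids)
  edges <- data.frame(
    x1 = x[pos[edges$parent_id]], y1 = y[pos[edges$parent_id]],
    x2 = x[pos[edges$taxid]], y2 = y[pos[edges$taxid]])

  legend <- if (opts$mode == "contrast") {
    data.frame(label = c("false positive", "false negative",
                         "true positive (error 0)"),
               color = c(opts$fp_color, opts$fn_color, "#FFFFFF"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(label = tree$sources, color = unname(src_colors),
               stringsAsFactors = FALSE)
  }

  nodes <- data.frame(taxid = taxids, name = nd$name, rank = nd$rank,
                      depth = unname(depth[taxids]),
                      x = unname(x), y = unname(y), radius = radius,
                      drawn = unname(drawn), fill = fill,
                      label = nd$name, label_visible = unname(label_visible),
                      highlighted = highlighted,
                      is_leaf = unname(is_leaf[taxids]),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- nodes$taxid
  structure(list(nodes = nodes, segments = segments, edges = edges,
                 legend = legend, width = width, height = height,
                 layout = opts$layout, mode = opts$mode),
            class = "render_spec")
}

# pie-slice path from fraction f0 to f1 (of a full turn, starting at 12
# o'clock, clockwise)
arc_path <- function(cx, cy, r, f0, f1) {
  a0 <- (f0 - 0.25) * 2 * pi
  a1 <- (f1 - 0.25) * 2 * pi
  x0 <- cx + r * cos(a0); y0 <- cy + r * sin(a0)
  x1 <- cx + r * cos(a1); y1 <- cy + r * sin(a1)
  large <- if ((f1 - f0) > 0.5) 1 else 0
  sprintf("M %s %s L %s %s A %s %s 0 %d 1 %s %s Z",
          fmt_num(cx), fmt_num(cy), fmt_num(x0), fmt_num(y0),
          fmt_num(r), fmt_num(r), large, fmt_num(x1), fmt_num(y1))
}

#' Serialize a render spec to SVG
#'
#' Writes deterministic SVG 1.1: same spec and options always produce
#' byte-identical output (fonts referenced by family name, fixed numeric
#' formatting, no timestamps). Each drawn clade becomes one element of class
#' `node`: a `circle` for single-color discs, a `g` of pie-arc `path`s for
#' split discs, or a `g` of stacked `rect`s in the bar layout.
#'
#' @param spec A [layout_tree()] result.
#' @param opts The [render_options] used for the layout.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
render_svg <- function(spec, opts = render_options(), file) {
  n <- spec$nodes
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt_num(spec$width, 0), fmt_num(spec$height, 0),
            fmt_num(spec$width, 0), fmt_num(spec$height, 0)),
    sprintf('<rect width="%s" height="%s" fill="#FFFFFF"/>',
            fmt_num(spec$width, 0), fmt_num(spec$height, 0)),
    '<g class="edges" stroke="#999999" stroke-width="1">')
  if (nrow(spec$edges) > 0) {
    out <- c(out, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s"/>',
                          fmt_num(spec$edges$x1), fmt_num(spec$edges$y1),
                          fmt_num(spec$edges$x2), fmt_num(spec$edges$y2)))
  }
  out <- c(out, '</g>', '<g class="discs">')
  for (i in seq_len(nrow(n))) {
    if (!n$drawn[i]) next
    tid <- n$taxid[i]
    cx <- n$x[i]; cy <- n$y[i]; r <- n$radius[i]
    seg <- spec$segments[[tid]]
    if (spec$mode == "contrast" || is.null(seg)) {
      if (is.na(n$fill[i])) next
      out <- c(out, sprintf(
        '<circle class="node" id="node-%s" cx="%s" cy="%s" r="%s" fill="%s" stroke="#333333" stroke-width="0.5"/>',
        xml_escape(tid), fmt_num(cx), fmt_num(cy), fmt_num(r), n$fill[i]))
    } else if (spec$layout == "bar") {
      cum <- c(0, cumsum(seg$fraction))
      rects <- sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
                       fmt_num(cx - r + 2 * r * cum[-length(cum)]),
                       fmt_num(cy - r / 2),
                       fmt_num(2 * r * seg$fraction), fmt_num(r),
                       seg$color)
      out <- c(out, sprintf('<g class="node" id="node-%s">', xml_escape(tid)),
               rects, '</g>')
    } else if (nrow(seg) == 1) {
      out <- c(out, sprintf(
        '<circle class="node" id="node-%s" cx="%s" cy="%s" r="%s" fill="%s" stroke="#333333" stroke-width="0.5"/>',
        xml_escape(tid), fmt_num(cx), fmt_num(cy), fmt_num(r), seg$color[1]))
    } else {
      cum <- c(0, cumsum(seg$fraction))
      paths <- sprintf('<path d="%s" fill="%s"/>',
                       mapply(arc_path, cx, cy, r,
                              cum[-length(cum)], cum[-1]),
                       seg$color)
      out <- c(out, sprintf('<g class="node" id="node-%s">', xml_escape(tid)),
               paths, '</g>')
    }
  }
  out <- c(out, '</g>',
           sprintf('<g class="labels" font-family="Helvetica, Arial, sans-serif" font-size="%s">',
                   fmt_num(opts$label_font_size, 0)))
  for (i in seq_len(nrow(n))) {
    if (!n$label_visible[i]) next
    col <- if (n$highlighted[i]) opts$highlight_label_color else "#000000"
    cls <- if (n$highlighted[i]) "label highlight" else "label"
    out <- c(out, sprintf('<text class="%s" x="%s" y="%s" fill="%s">%s</text>',
                          cls, fmt_num(n$x[i] + n$radius[i] + 4),
                          fmt_num(n$y[i] + 4), col, xml_escape(n$label[i])))
  }
  out <- c(out, '</g>', '<g class="legend" font-family="Helvetica, Arial, sans-serif" font-size="11">')
  for (i in seq_len(nrow(spec$legend))) {
    ly <- 16 + (i - 1) * 18
    out <- c(out,
      sprintf('<rect x="%s" y="%s" width="12" height="12" fill="%s" stroke="#333333" stroke-width="0.5"/>',
              fmt_num(spec$width - 170), fmt_num(ly), spec$legend$color[i]),
      sprintf('<text x="%s" y="%s" fill="#000000">%s</text>',
              fmt_num(spec$width - 152), fmt_num(ly + 10),
              xml_escape(spec$legend$label[i])))
  }
  out <- c(out, '</g>', '</svg>')
  con <- base::file(file, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(file)
}

#' Rasterize a render spec to PNG
#'
#' Draws the resolved spec directly on a `grDevices::png()` device at
#' `opts$resolution` pixels wide (aspect ratio preserved). Returns `NULL`
#' with a warning when no PNG device is available.
#'
#' @param spec A [layout_tree()] result.
#' @param opts The [render_options] used for the layout.
#' @param file Output path.
#' @return `file` invisibly, or `NULL` if PNG output is unavailable.
#' @export
render_png <- function(spec, opts = render_options(), file) {
  res <- tryCatch({
    w <- opts$resolution
    h <- round(opts$resolution * spec$height / spec$width)
    grDevices::png(file, width = w, height = h)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, spec$width), ylim = c(spec$height, 0),
                          xaxs = "i", yaxs = "i", asp = 1)
    e <- spec$edges
    if (nrow(e) > 0) graphics::segments(e$x1, e$y1, e$x2, e$y2, col = "grey40")
    n <- spec$nodes
    for (i in seq_len(nrow(n))) {
      if (!n$drawn[i]) next
      seg <- spec$segments[[n$taxid[i]]]
      if (spec$mode == "contrast" || is.null(seg)) {
        if (!is.na(n$fill[i])) {
          draw_disc(n$x[i], n$y[i], n$radius[i], n$fill[i])
        }
      } else {
        cum <- c(0, cumsum(seg$fraction))
        for (j in seq_len(nrow(seg))) {
          draw_slice(n$x[i], n$y[i], n$radius[i], cum[j], cum[j + 1],
                     seg$color[j])
        }
      }
      if (n$label_visible[i]) {
        graphics::text(n$x[i] + n$radius[i] + 4, n$y[i], n$label[i],
                       adj = 0, cex = 0.8,
                       col = if (n$highlighted[i]) opts$highlight_label_color
                             else "black")
      }
    }
    file
  }, error = function(e) {
    warning("PNG export unavailable: ", conditionMessage(e), call. = FALSE)
    NULL
  })
  invisible(res)
}

draw_disc <- function(cx, cy, r, col) {
  a <- seq(0, 2 * pi, length.out = 120)
  graphics::polygon(cx + r * cos(a), cy + r * sin(a), col = col,
                    border = "grey20")
}

draw_slice <- function(cx, cy, r, f0, f1, col) {
  a <- seq((f0 - 0.25) * 2 * pi, (f1 - 0.25) * 2 * pi, length.out = 60)
  graphics::polygon(c(cx, cx + r * cos(a)), c(cy, cy + r * sin(a)),
                    col = col, border = NA)
}
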