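# Deterministic SVG rendering of a nomogram layout. Pure string assembly:
# identical layout and options yield byte-identical output.

svg_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmt <- function(x) sprintf("%.3f", x)

#' Render a nomogram layout to SVG
#'
#' Draws one horizontal ruler per axis with the shared 0-100 points scale on
#' top and the total-points and response rulers at the bottom, in the classic
#' static-nomogram arrangement. Output is plain SVG 1.1 text and is
#' byte-identical for identical input and options.
#'
#' @param layout a [build_layout()] result.
#' @param options list: `width` (px, default 840), `row_height` (default 46),
#'   `margin_left` (default 170), `margin_right` (default 40), `title`.
#' @return a single character string containing the SVG document.
#' @export
render_svg <- function(layout, options = list()) {
  width <- options$width %||% 840
  rh <- options$row_height %||% 46
  ml <- options$margin_left %||% 170
  mr <- options$margin_right %||% 40
  title <- options$title %||% "Nomogram"
  plot_w <- width - ml - mr

  n_rows <- 1L + length(layout$axes) + 2L  # points scale + axes + total + response
  height <- 40 + n_rows * rh + 20
  px_per_point <- plot_w / 100

  out <- character(0)
  add <- function(...) out[[length(out) + 1L]] <<- sprintf(...)

  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
      round(width), round(height), round(width), round(height))
  add('<title>%s</title>', svg_esc(title))
  add('<style>text{font-family:sans-serif;font-size:11px;} .lab{font-size:12px;font-weight:bold;} .tick{stroke:#000;stroke-width:1;} .ruler{stroke:#000;stroke-width:1.2;}</style>')

  y <- 40
  ruler <- function(y, label, x0, x1) {
    add('<text class="lab" x="%s" y="%s">%s</text>', fmt(ml - 160), fmt(y + 4),
        svg_esc(label))
    add('<line class="ruler" x1="%s" y1="%s" x2="%s" y2="%s"/>',
        fmt(x0), fmt(y), fmt(x1), fmt(y))
  }
  tick <- function(x, y, lab, above = TRUE) {
    dy <- if (above) -6 else 6
    ty <- if (above) y - 9 else y + 16
    add('<line class="tick" x1="%s" y1="%s" x2="%s" y2="%s"/>',
        fmt(x), fmt(y), fmt(x), fmt(y + dy))
    add('<text x="%s" y="%s" text-anchor="middle">%s</text>',
        fmt(x), fmt(ty), svg_esc(lab))
  }

  # shared points scale, 0..100
  ruler(y, "Points", ml, ml + plot_w)
  for (p in seq(0, 100, by = 10))
    tick(ml + p * px_per_point, y, sprintf("%d", p))
  y <- y + rh

  for (ax in layout$axes) {
    ruler(y, ax$label, ml, ml + ax$max_points * px_per_point)
    tk <- ax$ticks
    below <- FALSE
    last_x <- -Inf
    for (i in seq_len(nrow(tk))) {
      x <- ml + tk$points[i] * px_per_point
      # alternate crowded labels above/below the ruler
      below <- if (x - last_x < 30) !below else FALSE
      tick(x, y, as.character(tk$value[i]), above = !below)
      last_x <- x
    }
    y <- y + rh
  }

  tp_max <- layout$total_points_range[2]
  px_total <- plot_w / max(tp_max, 1e-9)
  ruler(y, "Total points", ml, ml + plot_w)
  for (p in pretty(c(0, tp_max), 10)) {
    if (p < 0 || p > tp_max) next
    tick(ml + p * px_total, y, sprintf("%g", p))
  }
  y <- y + rh

  resp_lab <- switch(layout$family,
                     binomial = "Probability", poisson = "Predicted count",
                     gamma = "Predicted mean", cox = "Relative hazard",
                     "Predicted value")
  ruler(y, resp_lab, ml, ml + plot_w)
  rt <- layout$response_ticks
  for (i in seq_len(nrow(rt)))
    tick(ml + rt$points[i] * px_total, y, sprintf("%g", rt$response[i]))

  add('</svg>')
  paste(out, collapse = "\n")
}

#' Write a rendered nomogram to a file
#'
#' @param layout a [build_layout()] result.
#' @param path output `.svg` path.
#' @param options passed to [render_svg()].
#' @return `path`, invisibly.
#' @export
write_svg <- function(layout, path, options = list()) {
  writeLines(render_svg(layout, options), path, useBytes = TRUE)
  invisible(path)
}
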