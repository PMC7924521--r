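#' Render a score card
#'
#' Produces a static score-card document: one strip per main effect with
#' the thresholds at the interval boundaries and the points per
#' interval, interaction effects as grids, and a risk strip mapping
#' every achievable total score to its estimated risk.
#'
#' The `txt` format is a plain-text card holding every threshold, point
#' and risk value. The `svg` format draws the same card with a diverging
#' colour scale centred at zero points, shared across all effects (equal
#' points always get equal colours); the grayscale variant maps the
#' point magnitude instead.
#'
#' @param model an `ics_model`.
#' @param format `"txt"` or `"svg"`.
#' @param grayscale use the grayscale palette (svg only).
#' @param file optional path; when given the document is written there.
#' @return The document as a character scalar, invisibly when `file` is
#'   given.
#' @export
render_scorecard <- function(model, format = c("txt", "svg"),
                             grayscale = FALSE, file = NULL) {
  format <- match.arg(format)
  doc <- if (format == "txt") render_txt(model) else render_svg(model, grayscale)
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

interval_labels <- function(thresholds) {
  bounds <- c(-Inf, thresholds, Inf)
  vapply(seq_len(length(bounds) - 1), function(i) {
    sprintf("[%s, %s)", format(bounds[i], digits = 4),
            format(bounds[i + 1], digits = 4))
  }, "")
}

render_txt <- function(model) {
  out <- c(sprintf("=== score card (%sICS) ===", model$method), "")
  for (eff in model$effects) {
    out <- c(out, sprintf("-- %s --", eff$name))
    if (eff$kind == "main") {
      labs <- if (eff$type %in% c("binary", "categorical")) {
        as.character(eff$levels)
      } else interval_labels(eff$thresholds)
      out <- c(out, sprintf("  %-24s %+d points", labs, eff$points))
    } else {
      labs1 <- if (eff$type[1] %in% c("binary", "categorical"))
        as.character(eff$levels1) else interval_labels(eff$thresholds1)
      labs2 <- if (eff$type[2] %in% c("binary", "categorical"))
        as.character(eff$levels2) else interval_labels(eff$thresholds2)
      grid <- matrix(eff$points, length(labs1), length(labs2))
      for (k in seq_along(labs1))
        out <- c(out, sprintf("  %-24s %s", labs1[k],
                              paste(sprintf("%+d", grid[k, ]), collapse = " ")))
      out <- c(out, paste("  columns:", paste(labs2, collapse = " | ")))
    }
    out <- c(out, "")
  }
  out <- c(out, "-- risk profile --")
  out <- c(out, sprintf("  score %+d -> risk %.1f%%",
                        model$risk_table$score, 100 * model$risk_table$risk))
  out
}

## diverging palette centred at 0 points (blue = negative, red =
## positive); grayscale maps |points|
point_colour <- function(points, all_points, grayscale) {
  mx <- max(1, max(abs(all_points)))
  vapply(points, function(p) {
    if (grayscale) {
      g <- 1 - 0.8 * abs(p) / mx
      grDevices::rgb(g, g, g)
    } else if (p >= 0) {
      grDevices::rgb(1, 1 - 0.85 * p / mx, 1 - 0.85 * p / mx)
    } else {
      grDevices::rgb(1 + 0.85 * p / mx, 1 + 0.85 * p / mx, 1)
    }
  }, "")
}

svg_rect <- function(x, y, w, h, fill) {
  sprintf('<rect x="%.1f" y="%.1f" width="%.1f" height="%.1f" fill="%s" stroke="black"/>',
          x, y, w, h, fill)
}

svg_text <- function(x, y, s, size = 12, anchor = "middle") {
  sprintf('<text x="%.1f" y="%.1f" font-size="%d" text-anchor="%s" font-family="sans-serif">%s</text>',
          x, y, size, anchor, s)
}

render_svg <- function(model, grayscale = FALSE) {
  all_pts <- unlist(lapply(model$effects, `[[`, "points")) %||% 0
  cell_w <- 80; cell_h <- 32; left <- 140; row_gap <- 58
  body <- character(0)
  ypos <- 30
  for (eff in model$effects) {
    body <- c(body, svg_text(10, ypos + 20, eff$name, size = 13, anchor = "start"))
    if (eff$kind == "main") {
      labs <- if (eff$type %in% c("binary", "categorical"))
        as.character(eff$levels) else interval_labels(eff$thresholds)
      cols <- point_colour(eff$points, all_pts, grayscale)
      for (i in seq_along(eff$points)) {
        x0 <- left + (i - 1) * cell_w
        body <- c(body,
                  svg_rect(x0, ypos, cell_w, cell_h, cols[i]),
                  svg_text(x0 + cell_w / 2, ypos + 20, sprintf("%+d", eff$points[i])),
                  svg_text(x0 + cell_w / 2, ypos + cell_h + 14, labs[i], size = 9))
      }
      ypos <- ypos + row_gap
    } else {
      grid <- matrix(eff$points, eff$dims[1], eff$dims[2])
      cols <- matrix(point_colour(as.vector(grid), all_pts, grayscale),
                     eff$dims[1], eff$dims[2])
      for (k in seq_len(nrow(grid))) for (l in seq_len(ncol(grid))) {
        x0 <- left + (l - 1) * cell_w
        y0 <- ypos + (k - 1) * cell_h
        body <- c(body,
                  svg_rect(x0, y0, cell_w, cell_h, cols[k, l]),
                  svg_text(x0 + cell_w / 2, y0 + 20, sprintf("%+d", grid[k, l])))
      }
      ypos <- ypos + nrow(grid) * cell_h + row_gap - cell_h
    }
  }
  ## risk strip over every achievable score
  body <- c(body, svg_text(10, ypos + 20, "risk", size = 13, anchor = "start"))
  rt <- model$risk_table
  risk_cols <- point_colour(rt$score, c(all_pts, rt$score), grayscale)
  for (i in seq_len(nrow(rt))) {
    x0 <- left + (i - 1) * cell_w
    body <- c(body,
              svg_rect(x0, ypos, cell_w, cell_h, risk_cols[i]),
              svg_text(x0 + cell_w / 2, ypos + 13, sprintf("%+d", rt$score[i]), size = 10),
              svg_text(x0 + cell_w / 2, ypos + 27, sprintf("%.1f%%", 100 * rt$risk[i]), size = 10))
  }
  height <- ypos + cell_h + 30
  width <- left + cell_w * max(3, nrow(rt),
                               vapply(model$effects, function(e) length(e$points), 0)) + 20
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            ceiling(width), ceiling(height)),
    body, "</svg>")
}
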