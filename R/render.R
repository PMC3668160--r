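# ---------------------------------------------------------------------------
# Render: serialize a cpg_geometry to deterministic SVG 1.1.
#
# Determinism contract: byte-identical output for identical input. Fixed
# attribute order, fixed 3-decimal coordinate formatting, no timestamps,
# fonts referenced by generic family only. Every pie is a <g> carrying
# stable id and role attributes (data-complex, data-taxon) so the figure
# remains editable entity-by-entity in Inkscape/Illustrator.
# ---------------------------------------------------------------------------

# fixed 3-decimal formatting; "-0.000" normalized to "0.000"
.fmt <- function(x) {
  s <- sprintf("%.3f", x)
  sub("^-(0\\.000)$", "\\1", s)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# angle (degrees clockwise from 12 o'clock) -> point on circle;
# SVG y grows downward
.arc_point <- function(cx, cy, r, angle_deg) {
  th <- angle_deg * pi / 180
  c(x = cx + r * sin(th), y = cy - r * cos(th))
}

#' SVG path/element specification for one pie sector
#'
#' For a pie of two or more sectors the sector is a path: move to the
#' center, line to the arc start point, elliptical arc to the end point
#' (large-arc flag set iff the span exceeds 180 degrees, clockwise sweep),
#' close. A single-sector pie is emitted as a circle primitive instead.
#' Angles are degrees clockwise from 12 o'clock; the point mapping is
#' `x = cx + r*sin(theta)`, `y = cy - r*cos(theta)`. Coordinates use fixed
#' 3-decimal rounding.
#'
#' @param arc Sector record with `n`, `start_angle`, `end_angle` (e.g. from
#'   [sector_geometry()] plus `n`).
#' @param cx,cy Pie center.
#' @param r Pie radius.
#' @return List with `element` (`"path"` or `"circle"`) and either `d`
#'   (path data string) or `cx`/`cy`/`r` strings.
#' @examples
#' sector_path_data(list(n = 4, start_angle = 0, end_angle = 90), 0, 0, 10)
#' @export
sector_path_data <- function(arc, cx, cy, r) {
  if (arc$n == 1L)
    return(list(element = "circle", cx = .fmt(cx), cy = .fmt(cy), r = .fmt(r)))
  span <- arc$end_angle - arc$start_angle
  p1 <- .arc_point(cx, cy, r, arc$start_angle)
  p2 <- .arc_point(cx, cy, r, arc$end_angle)
  large <- if (span > 180) 1L else 0L
  d <- sprintf("M %s,%s L %s,%s A %s,%s 0 %d,1 %s,%s Z",
               .fmt(cx), .fmt(cy), .fmt(p1["x"]), .fmt(p1["y"]),
               .fmt(r), .fmt(r), large, .fmt(p2["x"]), .fmt(p2["y"]))
  list(element = "path", d = d)
}

.render_sector <- function(sec, pie, cfg) {
  spec <- sector_path_data(sec, pie$cx, pie$cy, pie$r)
  fill <- sec$color
  stroked <- pie$key || !sec$filled
  stroke_attr <- if (stroked)
    sprintf(' stroke="%s" stroke-width="0.5"', cfg$absent_stroke)
  else
    ' stroke="none"'
  if (spec$element == "circle")
    sprintf('    <circle class="sector" data-sector="%d" cx="%s" cy="%s" r="%s" fill="%s"%s/>',
            sec$index, spec$cx, spec$cy, spec$r, fill, stroke_attr)
  else
    sprintf('    <path class="sector" data-sector="%d" d="%s" fill="%s"%s/>',
            sec$index, spec$d, fill, stroke_attr)
}

.render_pie <- function(pie, cfg) {
  id <- if (pie$key) sprintf("pie-c%d-key", pie$complex)
        else sprintf("pie-c%d-t%d", pie$complex, pie$taxon)
  cls <- if (pie$key) "pie key" else "pie data"
  taxon_attr <- if (pie$key) "key" else as.character(pie$taxon)
  c(sprintf('  <g id="%s" class="%s" data-complex="%d" data-taxon="%s">',
            id, cls, pie$complex, taxon_attr),
    vapply(pie$sectors, .render_sector, "", pie = pie, cfg = cfg),
    "  </g>")
}

.render_label <- function(i, lab) {
  style_attr <- if (lab$style[i] == "italic") ' font-style="italic"' else ""
  rot_attr <- if (lab$rotation[i] != 0)
    sprintf(' transform="rotate(%s %s %s)"',
            .fmt(lab$rotation[i]), .fmt(lab$x[i]), .fmt(lab$y[i]))
  else ""
  sprintf('  <text class="label %s" x="%s" y="%s" font-family="sans-serif" font-size="%s" fill="%s" text-anchor="%s"%s%s>%s</text>',
          lab$role[i], .fmt(lab$x[i]), .fmt(lab$y[i]), .fmt(lab$size[i]),
          lab$color[i], lab$anchor[i], style_attr, rot_attr,
          .xml_escape(lab$text[i]))
}

#' Render a laid-out Coulson plot to SVG
#'
#' Serializes a `cpg_geometry` to a standards-compliant SVG 1.1 document.
#' The output is byte-identical across runs and platforms for identical
#' input. Width/height attributes carry a `pt` unit so downstream PDF
#' conversion preserves the canvas size numerically; the viewBox is in
#' user units equal to the canvas size.
#'
#' @param g A `cpg_geometry` from [layout_plot()].
#' @return A `cpg_svg` object: list with `text` (the complete XML
#'   document), `width` and `height`.
#' @export
render_svg <- function(g) {
  stopifnot(inherits(g, "cpg_geometry"))
  cfg <- g$config
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%spt" height="%spt" viewBox="0 0 %s %s">',
            .fmt(g$canvas_width), .fmt(g$canvas_height),
            .fmt(g$canvas_width), .fmt(g$canvas_height)),
    unlist(lapply(g$pies, .render_pie, cfg = cfg)))
  if (!is.null(g$leaders) && nrow(g$leaders) > 0)
    lines <- c(lines, vapply(seq_len(nrow(g$leaders)), function(i)
      sprintf('  <line class="leader" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="0.3"/>',
              .fmt(g$leaders$x1[i]), .fmt(g$leaders$y1[i]),
              .fmt(g$leaders$x2[i]), .fmt(g$leaders$y2[i])), ""))
  if (!is.null(g$labels) && nrow(g$labels) > 0)
    lines <- c(lines, vapply(seq_len(nrow(g$labels)), .render_label, "",
                             lab = g$labels))
  lines <- c(lines, "</svg>")
  structure(list(text = paste0(paste(lines, collapse = "\n"), "\n"),
                 width = g$canvas_width, height = g$canvas_height),
            class = "cpg_svg")
}

#' @export
print.cpg_svg <- function(x, ...) {
  cat(sprintf("SVG document, %.1f x %.1f pt, %d bytes\n",
              x$width, x$height, nchar(x$text, type = "bytes")))
  invisible(x)
}

#' Write an SVG document to a file
#'
#' Writes bytes exactly (no newline translation), so repeated runs produce
#' byte-identical files.
#'
#' @param doc A `cpg_svg`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(doc, path) {
  stopifnot(inherits(doc, "cpg_svg"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(doc$text)), con)
  invisible(path)
}

#' Locate an SVG-to-PDF converter on the PATH
#'
#' Looks for, in order, `rsvg-convert`, `cairosvg` and `inkscape`.
#'
#' @param candidates Command names to try, in preference order.
#' @return The first available command name, or `character(0)` when none
#'   is found.
#' @export
find_svg_converter <- function(candidates = c("rsvg-convert", "cairosvg",
                                              "inkscape")) {
  for (cmd in candidates)
    if (nzchar(Sys.which(cmd))) return(cmd)
  character(0)
}

#' Convert an SVG document to a vector PDF
#'
#' Delegates to an external SVG-to-PDF converter; SVG stays the single
#' source of truth for geometry and the PDF is a faithful vector
#' conversion, never a raster fallback. When no converter is available the
#' call fails with an actionable error.
#'
#' @param doc A `cpg_svg` (or a path to an SVG file).
#' @param path Output PDF path.
#' @param converter Converter command name; defaults to the first one
#'   found by [find_svg_converter()].
#' @return `path`, invisibly.
#' @export
convert_to_pdf <- function(doc, path, converter = find_svg_converter()) {
  if (length(converter) == 0L)
    stop("no SVG-to-PDF converter available: install one of ",
         "'rsvg-convert' (librsvg), 'cairosvg' or 'inkscape' and ensure ",
         "it is on the PATH", call. = FALSE)
  if (!nzchar(Sys.which(converter)))
    stop("SVG-to-PDF converter ", dQuote(converter, q = FALSE),
         " not found on the PATH", call. = FALSE)
  if (inherits(doc, "cpg_svg")) {
    svg_path <- tempfile(fileext = ".svg")
    on.exit(unlink(svg_path))
    write_svg(doc, svg_path)
  } else {
    svg_path <- doc
    if (!file.exists(svg_path)) stop("SVG file not found: ", svg_path)
  }
  args <- switch(basename(converter),
    "rsvg-convert" = c("-f", "pdf", "-o", shQuote(path), shQuote(svg_path)),
    "cairosvg" = c(shQuote(svg_path), "-f", "pdf", "-o", shQuote(path)),
    "inkscape" = c(shQuote(svg_path), "--export-type=pdf",
                   paste0("--export-filename=", shQuote(path))),
    c(shQuote(svg_path), "-o", shQuote(path)))
  status <- system2(converter, args, stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(path) || file.size(path) == 0)
    stop("SVG-to-PDF conversion with ", dQuote(converter, q = FALSE),
         " failed (exit status ", status, ")", call. = FALSE)
  invisible(path)
}
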