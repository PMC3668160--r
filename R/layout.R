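# ---------------------------------------------------------------------------
# Layout: Dataset + configuration -> fully positioned, colored scene.
# Pure in-memory transformation; no output format knowledge.
#
# Orientation follows the published plot: taxa are rows, complexes are
# columns. Above each complex column sits a smaller gray "key" pie whose
# sectors are labelled with the subunit names; the left band carries the
# supergroup labels (once per contiguous block) and species names, both
# colored by supergroup.
# ---------------------------------------------------------------------------

#' Layout configuration for a Coulson plot
#'
#' All lengths are in SVG user units (rendered as points). Sector order is
#' subunit input order, clockwise, starting at 12 o'clock; `start_angle`
#' rotates the whole convention.
#'
#' @param pie_radius Radius of a data pie (default 12).
#' @param key_pie_radius Radius of the gray key pie; defaults to
#'   0.75 x `pie_radius` and may not exceed `pie_radius`.
#' @param pie_gap_x,pie_gap_y Horizontal/vertical gap between neighbouring
#'   pies.
#' @param system_gap Extra horizontal gap between complex columns.
#' @param group_gap Extra vertical gap between supergroup blocks (default 0;
#'   extra supergroup spacing is traditionally added in post-editing, but is
#'   supported natively here).
#' @param font_size_labels Font size (points) for species, group and complex
#'   names.
#' @param font_size_key Font size (points) for subunit labels around the
#'   key pies.
#' @param margin Uniform canvas margin.
#' @param absent_fill Fill for absent sectors (default white).
#' @param absent_stroke Outline color for absent sectors and sector
#'   boundaries.
#' @param key_fill Fill for key-pie sectors (gray).
#' @param start_angle Degrees, clockwise from 12 o'clock, where sector 0
#'   starts.
#' @param italic_species Render species names in italic (default plain;
#'   italicisation is commonly applied during post-editing).
#' @return A `cpg_layout_config` list.
#' @export
layout_config <- function(pie_radius = 12,
                          key_pie_radius = 0.75 * pie_radius,
                          pie_gap_x = 8, pie_gap_y = 8,
                          system_gap = 10, group_gap = 0,
                          font_size_labels = 10, font_size_key = 7,
                          margin = 20,
                          absent_fill = "#FFFFFF",
                          absent_stroke = "#9E9E9E",
                          key_fill = "#BDBDBD",
                          start_angle = 0,
                          italic_species = FALSE) {
  lengths <- c(pie_radius = pie_radius, key_pie_radius = key_pie_radius,
               pie_gap_x = pie_gap_x, pie_gap_y = pie_gap_y,
               font_size_labels = font_size_labels,
               font_size_key = font_size_key, margin = margin)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all lengths and font sizes must be positive: ",
         paste(names(lengths)[!(is.finite(lengths) & lengths > 0)], collapse = ", "))
  if (system_gap < 0 || group_gap < 0)
    stop("system_gap and group_gap must be non-negative")
  if (key_pie_radius > pie_radius)
    stop("key_pie_radius must not exceed pie_radius")
  for (col in list(absent_fill, absent_stroke, key_fill))
    if (!grepl("^#[0-9A-Fa-f]{6}$", col))
      stop("colors must be 6-digit hex: ", col)
  structure(list(
    pie_radius = pie_radius, key_pie_radius = key_pie_radius,
    pie_gap_x = pie_gap_x, pie_gap_y = pie_gap_y,
    system_gap = system_gap, group_gap = group_gap,
    font_size_labels = font_size_labels, font_size_key = font_size_key,
    margin = margin, absent_fill = toupper(absent_fill),
    absent_stroke = toupper(absent_stroke), key_fill = toupper(key_fill),
    start_angle = start_angle, italic_species = isTRUE(italic_species)),
    class = "cpg_layout_config")
}

#' Map top-level groups to colors
#'
#' The i-th distinct top-level group (in order of first appearance among the
#' taxa) receives the i-th color of the set, cycling with a warning when
#' there are more groups than colors. When a color-set entry's label exactly
#' matches a group name, that color is used for the group in preference to
#' the positional assignment.
#'
#' @param ds A `cpg_dataset`.
#' @param cs A `cpg_color_set`.
#' @return Named character vector of `#RRGGBB` colors, one per distinct
#'   group, in first-appearance order.
#' @export
assign_group_colors <- function(ds, cs = default_color_set()) {
  stopifnot(inherits(ds, "cpg_dataset"), inherits(cs, "cpg_color_set"))
  groups <- unique(ds$taxa$group_top)
  n <- length(cs$colors)
  colors <- cs$colors[(seq_along(groups) - 1L) %% n + 1L]
  matched <- match(groups, cs$labels)
  colors[!is.na(matched)] <- cs$colors[matched[!is.na(matched)]]
  if (length(groups) > n)
    warning(sprintf("%d groups but only %d colors: colors are reused cyclically",
                    length(groups), n))
  stats::setNames(colors, groups)
}

#' Sector angles for one pie sector
#'
#' Sectors divide the disc equally: sector `index` of `n` spans
#' `index*360/n` to `(index+1)*360/n` degrees, measured clockwise from
#' 12 o'clock. A single-sector pie is the full disc (0 to 360). With
#' `start_angle` the whole fan is rotated; the start angle is normalized
#' to `[0, 360)`.
#'
#' @param n Total sectors in the pie (>= 1).
#' @param index 0-based sector ordinal, `0 <= index < n`.
#' @param start_angle Rotation of the convention, degrees clockwise.
#' @return List with `start_angle` and `end_angle` in degrees.
#' @examples
#' sector_geometry(4, 0)   # 12-to-3-o'clock quadrant
#' sector_geometry(12, 10) # the 10-to-11-o'clock sector
#' @export
sector_geometry <- function(n, index, start_angle = 0) {
  stopifnot(length(n) == 1L, length(index) == 1L, n >= 1, !is.na(index))
  if (index < 0 || index >= n)
    stop(sprintf("sector index %s out of range for n = %s", index, n))
  if (n == 1)
    return(list(start_angle = 0, end_angle = 360))
  span <- 360 / n
  start <- (start_angle + index * span) %% 360
  list(start_angle = start, end_angle = start + span)
}

# one sector record (a row of the pie's sector list)
.sector <- function(index, n, start_angle, filled, color) {
  ang <- sector_geometry(n, index, start_angle)
  list(index = index, n = n,
       start_angle = ang$start_angle, end_angle = ang$end_angle,
       filled = filled, color = color)
}

# crude deterministic text-width estimate (no font metrics by design:
# canvas sizing must be reproducible across platforms)
.text_width <- function(text, font_size) {
  nchar(text, type = "chars") * 0.6 * font_size
}

#' Lay out a Coulson plot
#'
#' Positions every pie, sector and label of the plot on a canvas sized to
#' its content. Taxa are rows in input order; complexes are columns in
#' input order. The header band holds each complex name above its gray key
#' pie, whose subunit names are placed outside each sector at its
#' mid-angle with a short leader line. The left band holds the top-level
#' group labels (once per contiguous block, vertically centred on the
#' block) and the species names, both colored by the group color map. A
#' data pie's sector is filled with its taxon's group color iff the
#' corresponding occupancy cell is present; absent sectors use
#' `absent_fill` with an `absent_stroke` outline.
#'
#' @param ds A `cpg_dataset`.
#' @param cfg A `cpg_layout_config`.
#' @param colors Group color map from [assign_group_colors()].
#' @return A `cpg_geometry` object: `canvas_width`, `canvas_height`,
#'   `pies` (list of pies, each with center, radius, complex/taxon indices
#'   and a sector list), `labels` (data frame), `leaders` (leader-line data
#'   frame), `legend` (subunit label placements) and `config`.
#' @export
layout_plot <- function(ds, cfg = layout_config(),
                        colors = assign_group_colors(ds)) {
  stopifnot(inherits(ds, "cpg_dataset"), inherits(cfg, "cpg_layout_config"))
  taxa <- ds$taxa
  n_t <- nrow(taxa)
  n_c <- length(ds$complexes)
  fs <- cfg$font_size_labels
  r <- cfg$pie_radius
  kr <- cfg$key_pie_radius

  # ---- left band: group label column + species column
  group_w <- max(.text_width(taxa$group_top, fs), 0) + 6
  species_w <- max(.text_width(taxa$species, fs), 0) + 6
  left_band <- group_w + species_w + 6

  # ---- header band: complex name line + key pie + radial label clearance
  name_h <- fs + 4
  label_clear <- cfg$font_size_key * 1.2 + 10
  key_zone <- 2 * (kr + label_clear)
  header_h <- name_h + key_zone + 4

  # ---- column geometry (complexes)
  name_w <- vapply(ds$complexes, function(cx) .text_width(cx$name, fs), 0)
  col_w <- pmax(2 * r, name_w) + cfg$pie_gap_x
  col_x0 <- cfg$margin + left_band +
    c(0, cumsum(col_w[-n_c] + cfg$system_gap))[seq_len(n_c)]
  col_cx <- col_x0 + col_w / 2

  # ---- row geometry (taxa), with group_gap between supergroup blocks
  row_h <- 2 * r + cfg$pie_gap_y
  new_block <- c(FALSE, taxa$group_top[-1] != taxa$group_top[-n_t])
  row_y0 <- cfg$margin + header_h +
    cumsum(c(0, rep(row_h, n_t - 1L))) + cumsum(new_block) * cfg$group_gap
  row_cy <- row_y0 + row_h / 2

  canvas_width <- left_band + sum(col_w) + (n_c - 1L) * cfg$system_gap +
    2 * cfg$margin
  canvas_height <- header_h + n_t * row_h + sum(new_block) * cfg$group_gap +
    2 * cfg$margin

  key_cy <- cfg$margin + name_h + label_clear + kr

  # subunit-global-row offset per complex
  n_sub <- vapply(ds$complexes, function(cx) length(cx$subunits), 1L)
  row_offset <- c(0L, cumsum(n_sub))[seq_len(n_c)]

  pies <- vector("list", n_c * (n_t + 1L))
  labels <- list()
  leaders <- list()
  legend <- list()
  pi_i <- 0L

  add_label <- function(text, x, y, size, color, style, anchor, role,
                        complex = NA_integer_, taxon = NA_integer_) {
    labels[[length(labels) + 1L]] <<- data.frame(
      text = text, x = x, y = y, size = size, color = color, style = style,
      rotation = 0, anchor = anchor, role = role, complex = complex,
      taxon = taxon, stringsAsFactors = FALSE)
  }

  for (ci in seq_len(n_c)) {
    cx <- ds$complexes[[ci]]
    ns <- length(cx$subunits)
    # complex name over the key pie
    add_label(cx$name, col_cx[ci], cfg$margin + fs, fs, "#000000",
              "plain", "middle", "complex-name", complex = ci)
    # key pie: all sectors gray
    sectors <- lapply(seq_len(ns) - 1L, function(s)
      .sector(s, ns, cfg$start_angle, TRUE, cfg$key_fill))
    pi_i <- pi_i + 1L
    pies[[pi_i]] <- list(cx = col_cx[ci], cy = key_cy, r = kr,
                         complex = ci, taxon = NA_integer_, key = TRUE,
                         sectors = sectors)
    # subunit labels radially outside the key pie, with a short leader
    for (s in seq_len(ns)) {
      ang <- sector_geometry(ns, s - 1L, cfg$start_angle)
      mid <- (ang$start_angle + ang$end_angle) / 2
      th <- mid * pi / 180
      sx <- sin(th); cyv <- cos(th)
      lx1 <- col_cx[ci] + kr * sx
      ly1 <- key_cy - kr * cyv
      lx2 <- col_cx[ci] + (kr + 3) * sx
      ly2 <- key_cy - (kr + 3) * cyv
      leaders[[length(leaders) + 1L]] <- data.frame(
        x1 = lx1, y1 = ly1, x2 = lx2, y2 = ly2, complex = ci,
        stringsAsFactors = FALSE)
      anchor <- if (sx > 0.1) "start" else if (sx < -0.1) "end" else "middle"
      tx <- col_cx[ci] + (kr + 5) * sx
      ty <- key_cy - (kr + 5) * cyv + 0.35 * cfg$font_size_key
      add_label(cx$subunits[s], tx, ty, cfg$font_size_key, "#000000",
                "plain", anchor, "subunit", complex = ci)
      legend[[length(legend) + 1L]] <- data.frame(
        complex = ci, subunit_index = s - 1L, text = cx$subunits[s],
        x = tx, y = ty, stringsAsFactors = FALSE)
    }
    # data pies down the column
    for (ti in seq_len(n_t)) {
      gcol <- unname(colors[taxa$group_top[ti]])
      sectors <- lapply(seq_len(ns) - 1L, function(s) {
        present <- ds$occupancy[row_offset[ci] + s + 1L, ti]
        .sector(s, ns, cfg$start_angle, present,
                if (present) gcol else cfg$absent_fill)
      })
      pi_i <- pi_i + 1L
      pies[[pi_i]] <- list(cx = col_cx[ci], cy = row_cy[ti], r = r,
                           complex = ci, taxon = ti, key = FALSE,
                           sectors = sectors)
    }
  }

  # left band labels: group blocks (centred) and species
  block_start <- which(c(TRUE, taxa$group_top[-1] != taxa$group_top[-n_t]))
  block_end <- c(block_start[-1] - 1L, n_t)
  for (b in seq_along(block_start)) {
    g <- taxa$group_top[block_start[b]]
    ymid <- (row_cy[block_start[b]] + row_cy[block_end[b]]) / 2
    add_label(g, cfg$margin + 2, ymid + 0.35 * fs, fs,
              unname(colors[g]), "plain", "start", "group")
  }
  for (ti in seq_len(n_t))
    add_label(taxa$species[ti], cfg$margin + group_w + species_w,
              row_cy[ti] + 0.35 * fs, fs,
              unname(colors[taxa$group_top[ti]]),
              if (cfg$italic_species) "italic" else "plain",
              "end", "species", taxon = ti)

  structure(list(
    canvas_width = canvas_width, canvas_height = canvas_height,
    pies = pies,
    labels = do.call(rbind, labels),
    leaders = if (length(leaders)) do.call(rbind, leaders) else NULL,
    legend = do.call(rbind, legend),
    config = cfg),
    class = "cpg_geometry")
}

#' Tally the drawable elements of a laid-out plot
#'
#' @param g A `cpg_geometry`.
#' @return List of exact integer counts: `pies` (data + key),
#'   `data_pies`, `key_pies`, `sectors` (all pies), `filled_sectors`
#'   (data pies only; equals the number of present occupancy cells) and
#'   `labels`.
#' @export
count_elements <- function(g) {
  stopifnot(inherits(g, "cpg_geometry"))
  key <- vapply(g$pies, function(p) p$key, TRUE)
  sectors <- vapply(g$pies, function(p) length(p$sectors), 1L)
  filled <- vapply(g$pies[!key], function(p)
    sum(vapply(p$sectors, function(s) s$filled, TRUE)), 1L)
  list(pies = length(g$pies),
       data_pies = sum(!key),
       key_pies = sum(key),
       sectors = sum(sectors),
       filled_sectors = sum(filled),
       labels = nrow(g$labels))
}

#' @export
print.cpg_geometry <- function(x, ...) {
  n <- count_elements(x)
  cat(sprintf("Coulson plot geometry: %.1f x %.1f units, %d pies (%d data + %d key), %d sectors, %d labels\n",
              x$canvas_width, x$canvas_height, n$pies, n$data_pies,
              n$key_pies, n$sectors, n$labels))
  invisible(x)
}
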