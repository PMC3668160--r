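# Scene construction: colors, sector angles, positions, tallies.

test_that("group colors: positional, label-matched, and cycling", {
  ds <- parse_text(cpg_example_text())$dataset  # groups GA, GB

  cs3 <- read_color_set("#111111\n#222222\n#333333\n")
  map <- assign_group_colors(ds, cs3)
  expect_identical(map, c(GA = "#111111", GB = "#222222"))

  # a label match wins over position, wherever it sits in the set
  cs_named <- read_color_set("GB\t#377EB8\n#111111\n")
  map2 <- assign_group_colors(ds, cs_named)
  expect_identical(unname(map2["GB"]), "#377EB8")

  # 5 groups, 3 colors: cycling with a warning
  ds5 <- generate_dataset(fixture_spec(n_groups = 5, species_per_group = 1,
                                       n_complexes = 1, seed = 2))
  expect_warning(map5 <- assign_group_colors(ds5, cs3), "reused")
  expect_identical(unname(map5), c("#111111", "#222222", "#333333",
                                   "#111111", "#222222"))
})

test_that("sector angles divide the disc clockwise from 12 o'clock", {
  expect_equal(sector_geometry(1, 0), list(start_angle = 0, end_angle = 360))
  expect_equal(sector_geometry(4, 0), list(start_angle = 0, end_angle = 90))
  # clock-position oracle: 11th sector of a 12-sector pie occupies the
  # 10-to-11-o'clock position
  expect_equal(sector_geometry(12, 10),
               list(start_angle = 300, end_angle = 330))
  expect_error(sector_geometry(4, 4), "out of range")
  expect_error(sector_geometry(4, -1), "out of range")
  # rotated convention normalizes the start into [0, 360)
  rot <- sector_geometry(4, 3, start_angle = 180)
  expect_equal(rot$start_angle, 90)
})

test_that("layout produces the expected pies, sectors and labels", {
  ds <- generate_dataset(fixture_spec(n_groups = 5, species_per_group = 2,
                                      n_complexes = 7, subunits_min = 2,
                                      subunits_max = 5, seed = 4))
  g <- layout_plot(ds)
  n <- count_elements(g)
  expect_identical(n$data_pies, 7L * 10L)
  expect_identical(n$key_pies, 7L)
  expect_identical(n$pies, 7L * 10L + 7L)
  # sectors per pie = subunits of its complex, key pies included
  n_sub <- vapply(ds$complexes, function(cx) length(cx$subunits), 1L)
  expect_identical(n$sectors, sum(n_sub) * 11L)
  for (p in g$pies)
    expect_identical(length(p$sectors), n_sub[p$complex])
  # 10 species labels, 5 group labels (one per contiguous block)
  expect_identical(sum(g$labels$role == "species"), 10L)
  expect_identical(sum(g$labels$role == "group"), 5L)
  expect_identical(sum(g$labels$role == "complex-name"), 7L)
  expect_identical(sum(g$labels$role == "subunit"), sum(n_sub))
})

test_that("angle conservation: sector spans sum to 360 per pie", {
  for (seed in c(1, 2, 3)) {
    ds <- generate_dataset(tiny_spec(seed))
    g <- layout_plot(ds, layout_config(start_angle = seed * 7))
    for (p in g$pies) {
      spans <- vapply(p$sectors, function(s) s$end_angle - s$start_angle, 0)
      expect_equal(sum(spans), 360, tolerance = 1e-9)
    }
  }
})

test_that("filled sectors mirror occupancy and use the taxon's group color", {
  ds <- generate_dataset(fixture_spec(n_groups = 2, species_per_group = 3,
                                      n_complexes = 4, subunits_min = 1,
                                      subunits_max = 6, presence_prob = 0.5,
                                      seed = 9))
  cfg <- layout_config()
  colors <- assign_group_colors(ds)
  g <- layout_plot(ds, cfg, colors)
  expect_identical(count_elements(g)$filled_sectors, sum(ds$occupancy))
  n_sub <- vapply(ds$complexes, function(cx) length(cx$subunits), 1L)
  offset <- c(0L, cumsum(n_sub))
  for (p in g$pies) {
    for (s in p$sectors) {
      if (p$key) {
        expect_identical(s$color, cfg$key_fill)
      } else {
        present <- ds$occupancy[offset[p$complex] + s$index + 1L, p$taxon]
        expect_identical(s$filled, present)
        expect_identical(
          s$color,
          if (present) unname(colors[ds$taxa$group_top[p$taxon]])
          else cfg$absent_fill)
      }
    }
  }
})

test_that("all-absent and all-present datasets hit the boundary counts", {
  ds0 <- generate_dataset(fixture_spec(n_groups = 2, species_per_group = 2,
                                       n_complexes = 3, presence_prob = 0,
                                       seed = 1))
  g0 <- layout_plot(ds0)
  expect_identical(count_elements(g0)$filled_sectors, 0L)
  for (p in g0$pies[!vapply(g0$pies, `[[`, TRUE, "key")])
    for (s in p$sectors)
      expect_identical(s$color, layout_config()$absent_fill)

  ds1 <- generate_dataset(fixture_spec(n_groups = 2, species_per_group = 2,
                                       n_complexes = 3, presence_prob = 1,
                                       seed = 1))
  g1 <- layout_plot(ds1)
  expect_identical(count_elements(g1)$filled_sectors,
                   length(ds1$occupancy))
})

test_that("single-subunit complexes render as single-sector discs", {
  ds <- generate_dataset(fixture_spec(n_groups = 2, species_per_group = 2,
                                      n_complexes = 5, subunits_min = 1,
                                      subunits_max = 1, seed = 6))
  g <- layout_plot(ds)
  n <- count_elements(g)
  expect_identical(n$pies, 5L * 4L + 5L)
  for (p in g$pies) {
    expect_identical(length(p$sectors), 1L)
    expect_equal(p$sectors[[1]]$end_angle - p$sectors[[1]]$start_angle, 360)
  }
})

test_that("pie bounding boxes never overlap", {
  ds <- generate_dataset(tiny_spec(5))
  g <- layout_plot(ds, layout_config(group_gap = 9))
  boxes <- t(vapply(g$pies, function(p)
    c(p$cx - p$r, p$cx + p$r, p$cy - p$r, p$cy + p$r), numeric(4)))
  n <- nrow(boxes)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sep <- boxes[i, 2] <= boxes[j, 1] || boxes[j, 2] <= boxes[i, 1] ||
        boxes[i, 4] <= boxes[j, 3] || boxes[j, 4] <= boxes[i, 3]
      expect_true(sep)
    }
  }
})

test_that("layout is monotone in gaps and translation-consistent in margin", {
  ds <- generate_dataset(tiny_spec(8))
  g1 <- layout_plot(ds, layout_config(pie_gap_x = 8))
  g2 <- layout_plot(ds, layout_config(pie_gap_x = 12))
  expect_true(g2$canvas_width > g1$canvas_width)

  # raising the margin shifts every coordinate by the same constant
  gm1 <- layout_plot(ds, layout_config(margin = 20))
  gm2 <- layout_plot(ds, layout_config(margin = 35))
  d <- 15
  expect_equal(gm2$canvas_width, gm1$canvas_width + 2 * d)
  expect_equal(gm2$canvas_height, gm1$canvas_height + 2 * d)
  for (k in seq_along(gm1$pies)) {
    expect_equal(gm2$pies[[k]]$cx, gm1$pies[[k]]$cx + d)
    expect_equal(gm2$pies[[k]]$cy, gm1$pies[[k]]$cy + d)
  }
  expect_equal(gm2$labels$x, gm1$labels$x + d)
  expect_equal(gm2$labels$y, gm1$labels$y + d)

  # group_gap inserts vertical space between supergroup blocks only
  gg <- layout_plot(ds, layout_config(group_gap = 10))
  g0 <- layout_plot(ds, layout_config(group_gap = 0))
  expect_equal(gg$canvas_height, g0$canvas_height + 10)
})

test_that("identical inputs give identical geometry", {
  ds <- generate_dataset(tiny_spec(3))
  cfg <- layout_config(system_gap = 14)
  expect_identical(layout_plot(ds, cfg), layout_plot(ds, cfg))
})

test_that("layout configuration validates its invariants", {
  expect_error(layout_config(pie_radius = 0), "positive")
  expect_error(layout_config(pie_radius = 10, key_pie_radius = 11),
               "key_pie_radius")
  expect_error(layout_config(absent_fill = "white"), "hex")
  expect_silent(layout_config(group_gap = 0))
})
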