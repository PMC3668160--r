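---
title: "Coulson plots: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coulson plots: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coulsonplot)
```

## What a Coulson plot encodes

Comparative genomics routinely reduces to a binary question asked many
times over: is an ortholog of subunit *s* of complex *c* predicted present
in genome *t*? The answers form a presence/absence ("occupancy") matrix
whose rows are subunits, grouped into complexes or pathways, and whose
columns are taxa. A Coulson plot renders this matrix as a grid of pie
charts: one pie per (complex, taxon) pair, divided into as many equal
sectors as the complex has subunits, each sector filled iff the
corresponding gene is called present. Filling uses the color of the
taxon's top-level group (its eukaryotic supergroup, in the plot's original
use), so blocks of rows share a color and losses stand out as white
wedges. Above each complex column sits a smaller gray *key pie* whose
sectors are labelled with the subunit names, making every wedge in the
column interpretable without a separate legend.

Relative to a dot plot, the format keeps the functional grouping: a
complex that is entirely missing reads as an empty circle, partial
retention as a partly filled one, and each retained sector is nameable.
When every complex has exactly one subunit the format degenerates to the
familiar dot-plot (filled/unfilled discs); the package renders that case
with circle primitives rather than one-sector arcs.

## The input dialect

Input is a comma- or tab-delimited table in the layout the original
desktop tool established. The four top rows carry taxonomy: rows 1 and 2
are group labels (row 1 drives coloring), row 3 the species names — which
must all be present, with no gaps — and row 4 optional annotation. The
first two columns carry labels: the complex name in column 1, written only
on the complex's first subunit row, and the subunit name in column 2.
Data cells accept `+`/`-` (including the typographic minus `−`) or
`1`/`0`, nothing else; empty data cells are errors. Validation reports
1-based row/column coordinates of the physical file, matching what a user
sees in their spreadsheet program.

Three points in the dialect are genuinely ambiguous, and the parser takes
a documented position on each:

* **Complex boundaries.** Both conventions found in the wild are
  accepted: a new complex starts at any row with a non-empty column-1
  cell, and fully blank rows also act as separators (they are consumed,
  never counted as subunits).
* **Row 4.** It may be annotation, absent, or the first data row. The
  parser reads it as data only when it is a *plausible* data row — every
  data cell a valid token **and** both label cells occupied — and records
  that classification as a warning so silent misreads cannot happen;
  `strict_row4 = TRUE` forces the annotation reading.
* **Group contiguity.** Colored group blocks presume that taxa of a
  group occupy adjacent columns. Nothing in the format enforces it, but a
  scattered group is almost always a column-ordering mistake, so it is an
  error by default, demotable to a warning
  (`noncontiguous_groups = "warn"`).

Blank cells in header rows 1–2 inherit the nearest non-empty label to
their left, which is how such tables are typically laid out in a
spreadsheet (the label written once per block). This is our reading of an
under-specified corner, not an attested behaviour of the original tool.

## Geometry conventions

Sectors are equal wedges in subunit input order, **clockwise from
12 o'clock**: sector $i$ of $n$ spans $[i \cdot 360/n, (i+1) \cdot 360/n)$
degrees. The angle-to-point mapping is $x = c_x + r\sin\theta$,
$y = c_y - r\cos\theta$ (SVG's y axis grows downward). The published
figures only hint at this convention (a 12-subunit pie whose 11th subunit
sits at the 10-to-11-o'clock position); it is configurable via
`start_angle` should data prepared under another convention arrive.

Layout is deterministic and font-metric-free: text width is estimated as
0.6 × font size per character, so identical inputs give identical
canvases on every platform, at the price of not micro-fitting long
labels. Long complex names widen their column rather than wrap. Key-pie
subunit labels sit radially outside their sector's mid-angle with a short
leader line; no further collision resolution is attempted, because the
output is explicitly meant to be polished in a vector editor afterwards.
For the same reason species names default to plain text
(`italic_species = TRUE` flips this) and `group_gap`, the extra space
between supergroup blocks, defaults to 0.

Tunable parameters (all lengths in SVG user units, rendered as points):
`pie_radius` (12), `key_pie_radius` (0.75 × pie radius), `pie_gap_x` /
`pie_gap_y` (8), `system_gap` between complex columns (10), `group_gap`
(0), `font_size_labels` (10 pt), `font_size_key` (7 pt), `margin` (20),
and the three colors `absent_fill` (white), `absent_stroke` (gray
outline of empty sectors) and `key_fill` (key-pie gray).

Group colors come from an ordered color set (`label<TAB>#RRGGBB` lines,
or bare hex colors). The i-th distinct top-level group, in order of first
appearance, takes the i-th color, cycling with a warning if groups
outnumber colors; an entry whose label exactly matches a group name
overrides the positional rule, so a curated set can pin, say,
Opisthokonta to its customary red regardless of column order. The
shipped default is an eight-color, colorblind-aware palette labelled
with the major eukaryotic supergroups.

## Rendering and determinism

SVG is the canonical backend. The serializer emits a fixed attribute
order, fixed 3-decimal coordinates (with negative zero normalized), no
timestamps, and generic `sans-serif` font references, so output is
byte-identical across runs and platforms — repeated builds of a figure
diff clean. Every pie is a `<g>` with a stable id (`pie-c3-t2`,
`pie-c7-key`) and `data-complex` / `data-taxon` role attributes, and every
sector, label and leader line is an addressable element, which is what
makes the downstream hand-editing workflow practical and which the test
suite uses to count elements.

A sector of a pie with $n \ge 2$ sectors is a path: move to the center,
line to the arc's start point, elliptical arc (large-arc flag set iff the
span exceeds 180°, clockwise sweep) to the end point, close. At exactly
180° — the two-subunit pie — the large-arc flag is 0 with the sweep flag
set, which renders the correct half-disc; the tests verify this by
reconstructing the arc from the path's endpoint parameterization and
integrating the sector area. $n = 1$ emits a circle primitive.

PDF output is a thin conversion of the SVG by an external tool
(`rsvg-convert`, `cairosvg` or `inkscape`, whichever is found first), not
a second renderer: one source of truth for geometry. The SVG's
width/height attributes carry a `pt` unit so the converted page box
equals the canvas numerically. When no converter is installed the
package fails with an instruction to install one — never a silent raster
fallback.

## The synthetic-data generator

`generate_dataset()` builds arbitrarily large valid datasets from six
knobs (groups, species per group, complexes, subunit-count range,
presence probability, seed). Its defaults — 5 groups × 5 species, 10
complexes with 2–8 subunits, presence probability 0.6 — mirror the scale
of a typical published membrane-trafficking comparison: a few dozen taxa,
tens of complexes, and majority presence with informative losses. All
randomness flows through one seed and the caller's RNG state is restored,
so fixtures are reproducible across test runs and machines.

Occupancy is i.i.d. Bernoulli. Real phylogenetic profiles are nothing of
the sort — absences are correlated along the species tree and within
complexes (whole-complex loss is common) — so passing tests demonstrate
the *plumbing* (parsing, validation, geometry, conservation of counts,
determinism) at realistic scale, not any biological claim. The generator
deliberately models no gene-loss process.

`make_malformed()` derives invalid inputs from valid ones by a single
seeded mutation per defect class (species-row gap, empty data cell, bad
token, subunit before any complex name, ragged row), paired with the file
coordinates where the validator must report the fault. Each fixture
therefore isolates exactly one validation rule. A ragged row is padded by
the parser, so its observable failure is the resulting empty cell in the
final column, and that is what the fixture announces.

## Numerical choices and edge cases

* Angle sums per pie are exact to 1e-9 by construction (spans are
  computed as differences of multiples of 360/n).
* Coordinates are rounded to 3 decimals only at serialization; layout
  arithmetic stays in doubles.
* The smallest representable dataset is one complex × one subunit × one
  taxon (two pies: one data, one key); empty datasets are rejected at
  validation.
* Degenerate probability values 0 and 1 produce exactly empty and
  exactly full matrices.
* Tokens are matched after whitespace stripping, byte-exactly otherwise;
  case variants and words are rejected so that a stray `O` (letter) in a
  `0` column cannot pass silently.

## Scale

The test suite and acceptance script exercise the pipeline end-to-end at
25 complexes × 10 taxa with 3–8 subunits per complex — 250 data pies and
roughly 1 400 sector elements in one SVG — and round-trip 100 random
fixtures; the whole suite runs in well under a minute. Canvas size grows
linearly in taxa and complexes, and nothing in the design caps it: the
practical limit is the user's patience with a very wide figure, not the
renderer.

## Limitations

* Two-state occupancy only; confidence grades (present / weak /
  absent) are not representable in the dialect.
* No automatic reordering or clustering of taxa or complexes; input
  order is authoritative, as in the original format.
* Label placement is estimate-based; unusually long subunit names may
  need a nudge in the vector editor, which is the intended workflow.
* No spreadsheet-binary input; export to CSV/TSV first.
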