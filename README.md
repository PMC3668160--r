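# coulsonplot

Deterministic Coulson plots — matrix-of-pie-chart figures for
comparative-genomics presence/absence data — from plain CSV/TSV tables,
rendered as editable SVG (optionally PDF).

## The problem and the plot

Comparative surveys of protein complexes and pathways reduce to an
occupancy matrix: for each subunit *s* of each complex *c* and each
genome *t*, a binary call of whether an ortholog is predicted present.
Spreadsheets hold this information but hide its patterns. A **Coulson
plot** shows it: a grid with one pie chart per (complex, taxon) pair,
divided into `n_subunits(c)` equal sectors, clockwise from 12 o'clock, in
subunit input order. Sector *i* is filled with the taxon's supergroup
color iff

    occupancy[subunit i of complex c, taxon t] = 1,

and left white otherwise. A smaller gray *key pie* above each column
labels which sector is which subunit. Complete losses read as empty
circles, partial retention as partly filled ones, and supergroup coloring
makes lineage-level patterns jump out. With one subunit per complex the
format degenerates to a classic dot plot.

This package is for anyone who has such a table — typically assembled in
a spreadsheet from BLAST/HMMer searches — and wants a publication-quality
figure without manual drawing. It reads the established table dialect
(two top label columns, four taxonomy header rows, `+`/`-` or `1`/`0`
cells), validates it with spreadsheet-style coordinates on every error,
and emits byte-deterministic SVG in which every pie, sector and label is
an addressable element for final polishing in Inkscape or Illustrator.

## Worked example

```r
library(coulsonplot)

ds <- generate_dataset(fixture_spec(n_groups = 3, species_per_group = 2,
                                    n_complexes = 4, subunits_min = 2,
                                    subunits_max = 6, seed = 42))
ds
#> Coulson plot dataset: 6 taxa in 3 groups, 4 complexes, 12 subunit rows (37 of 72 cells present)

geom <- layout_plot(ds)
geom
#> Coulson plot geometry: 264.0 x 304.8 units, 28 pies (24 data + 4 key), 84 sectors, 25 labels

doc <- render_svg(geom)
doc
#> SVG document, 264.0 x 304.8 pt, 20987 bytes
write_svg(doc, "demo.svg")
```

The dataset print shows the matrix dimensions: 6 taxa (3 supergroups of
2 species), 4 complexes totalling 12 subunit rows, of which 37 of the 72
occupancy cells are present. The geometry line confirms the accounting
the plot must obey: 4 × 6 = 24 data pies plus one key pie per complex,
and one sector per subunit per pie (12 × 7 = 84). `count_elements(geom)`
returns the same tallies programmatically, with `filled_sectors = 37`
matching the present cells exactly.

Real data enters through `read_cpg("table.csv")`, which returns the
validated dataset together with a report of every problem found
(1-based row/column, as in the spreadsheet). `write_dataset()` reverses
the parse exactly.

The same pipeline from the shell:

```sh
$ coulson example -o demo.csv --groups 3 --species 2 --complexes 4 --subunits 2:6 --seed 42
wrote demo.csv: 6 taxa, 4 complexes, 12 subunits
$ coulson validate demo.csv
OK: 6 taxa, 4 complexes, 12 subunits
$ coulson plot demo.csv -o demo.svg
wrote demo.svg: 28 pies, 84 sectors, canvas 264.0 x 304.8
```

(`coulson` is the Rscript at
`system.file("cli", "coulson", package = "coulsonplot")`; symlink it onto
your PATH or call it through `Rscript`.) Exit codes are scriptable:
0 success, 1 invalid data, 2 environment error. `coulson plot` refuses
invalid input and never leaves a partial output file. Pie size, gaps,
system spacing, fonts, colors and sector start angle are flags; see
`coulson` with no arguments.

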