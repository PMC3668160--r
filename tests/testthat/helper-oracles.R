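# Shared test utilities and independent oracles.

# --- SVG arc oracle ---------------------------------------------------------
# Parses a sector path ("M cx,cy L x1,y1 A r,r 0 large,sweep x2,y2 Z") and
# reconstructs the arc via the SVG 1.1 endpoint-to-center parameterization
# (spec appendix F.6.5), independently of how the path was generated.

parse_sector_path <- function(d) {
  num <- "(-?[0-9]+\\.?[0-9]*)"
  pat <- paste0("^M ", num, ",", num, " L ", num, ",", num,
                " A ", num, ",", num, " 0 ([01]),([01]) ",
                num, ",", num, " Z$")
  m <- regmatches(d, regexec(pat, d))[[1]]
  stopifnot(length(m) == 11L)
  v <- as.numeric(m[-1][-c(7, 8)])
  list(cx = v[1], cy = v[2], x1 = v[3], y1 = v[4], rx = v[5], ry = v[6],
       large = as.integer(m[8]), sweep = as.integer(m[9]),
       x2 = v[7], y2 = v[8])
}

# endpoint parameterization -> center, start angle, angular extent (radians)
arc_center_params <- function(p) {
  r <- p$rx
  x1p <- (p$x1 - p$x2) / 2
  y1p <- (p$y1 - p$y2) / 2
  num <- r^2 * r^2 - r^2 * y1p^2 - r^2 * x1p^2
  den <- r^2 * y1p^2 + r^2 * x1p^2
  co <- sqrt(max(num / den, 0))
  if (p$large == p$sweep) co <- -co
  cxp <- co * r * y1p / r
  cyp <- -co * r * x1p / r
  cx <- cxp + (p$x1 + p$x2) / 2
  cy <- cyp + (p$y1 + p$y2) / 2
  th1 <- atan2((y1p - cyp) / r, (x1p - cxp) / r)
  dth <- atan2((-y1p - cyp) / r, (-x1p - cxp) / r) - th1
  dth <- dth %% (2 * pi)
  if (p$sweep == 0 && dth > 0) dth <- dth - 2 * pi
  list(cx = cx, cy = cy, r = r, theta1 = th1, dtheta = dth)
}

# area of the circular sector described by a sector path, via the oracle
sector_path_area <- function(d) {
  p <- parse_sector_path(d)
  a <- arc_center_params(p)
  0.5 * a$r^2 * abs(a$dtheta)
}

# --- independent PDF page-box reader ---------------------------------------
# Scans a PDF for /MediaBox, inflating FlateDecode streams (where writers
# like librsvg keep the page dictionary) with memDecompress. Returns the
# four box numbers.

read_pdf_mediabox <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  # byte-aligned ASCII view: non-ASCII/NUL bytes become spaces so byte and
  # character offsets coincide and no encoding translation happens
  ascii_view <- function(r) {
    r[r == as.raw(0) | r > as.raw(127)] <- as.raw(32)
    rawToChar(r)
  }
  txt <- ascii_view(raw)
  hits <- regmatches(txt, gregexpr("/MediaBox\\s*\\[[^]]*\\]", txt))[[1]]
  # also look inside FlateDecode streams
  starts <- gregexpr("(?<!end)stream\r?\n", txt, perl = TRUE)[[1]]
  ends <- gregexpr("endstream", txt)[[1]]
  if (starts[1] != -1 && ends[1] != -1) {
    for (k in seq_along(starts)) {
      s_data <- starts[k] + attr(starts, "match.length")[k]
      e <- ends[ends > s_data]
      if (!length(e)) next
      e_data <- e[1] - 1L
      # drop the EOL that precedes "endstream"
      while (e_data > s_data && raw[e_data] %in% as.raw(c(10L, 13L)))
        e_data <- e_data - 1L
      seg <- raw[s_data:e_data]
      dec <- tryCatch(memDecompress(seg, type = "gzip"),
                      error = function(err) NULL)
      if (!is.null(dec)) {
        dtxt <- ascii_view(dec)
        hits <- c(hits,
                  regmatches(dtxt, gregexpr("/MediaBox\\s*\\[[^]]*\\]",
                                            dtxt))[[1]])
      }
    }
  }
  stopifnot(length(hits) >= 1)
  nums <- regmatches(hits[1], gregexpr("-?[0-9.]+", hits[1]))[[1]]
  as.numeric(nums)
}

# --- small fixture helpers --------------------------------------------------

tiny_spec <- function(seed = 1L, ...) {
  fixture_spec(n_groups = 2, species_per_group = 2, n_complexes = 3,
               subunits_min = 1, subunits_max = 4, presence_prob = 0.5,
               seed = seed, ...)
}

# a hand-built minimal CPG file: 2 complexes (3 + 2 subunits), 4 taxa
cpg_example_text <- function(fill = "+") {
  paste0(
    ",,GA,GA,GB,GB\n",
    ",,GAm,GAm,GBm,GBm\n",
    ",,sp1,sp2,sp3,sp4\n",
    ",,,,,\n",
    "CplxA,a1,", paste(rep(fill, 4), collapse = ","), "\n",
    ",a2,", paste(rep(fill, 4), collapse = ","), "\n",
    ",a3,", paste(rep(fill, 4), collapse = ","), "\n",
    "CplxB,b1,", paste(rep(fill, 4), collapse = ","), "\n",
    ",b2,", paste(rep(fill, 4), collapse = ","), "\n")
}

parse_text <- function(text, ...) build_dataset(parse_table(text), ...)

# run the installed CLI script through Rscript; returns list(status, stdout,
# stderr)
run_coulson <- function(...) {
  script <- system.file("cli", "coulson", package = "coulsonplot")
  stopifnot(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- tempfile(); err <- tempfile()
  on.exit(unlink(c(out, err)))
  status <- suppressWarnings(
    system2(rscript, c(script, vapply(list(...), as.character, "")),
            stdout = out, stderr = err))
  list(status = status,
       stdout = readLines(out, warn = FALSE),
       stderr = readLines(err, warn = FALSE))
}

svg_xml <- function(doc) xml2::read_xml(doc$text)

svg_ns_strip <- function(x) {
  xml2::xml_ns_strip(x)
  x
}

count_svg <- function(x, xpath) length(xml2::xml_find_all(x, xpath))
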