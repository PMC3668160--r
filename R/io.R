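# ---------------------------------------------------------------------------
# CPG table dialect
#
# Layout of a file (spreadsheet convention, 1-based):
#   row 1: supergroup labels (drives pie coloring)
#   row 2: second-level taxonomy labels
#   row 3: species names -- every data column must be occupied
#   row 4: optional annotation row, or the first data row
#   rows 5..: subunit rows; column 1 carries the complex name on the first
#             subunit row of each complex, column 2 the subunit name,
#             columns 3.. the occupancy tokens ('+'/'-' or '1'/'0')
# ---------------------------------------------------------------------------

#' Parse delimited text into a rectangular raw table
#'
#' Reads comma- or tab-delimited text (RFC-4180 style quoting) into a
#' rectangular character matrix. Ragged rows are padded with empty strings,
#' trailing blank lines are dropped, a leading byte-order mark is stripped,
#' and every cell is stripped of leading/trailing whitespace.
#'
#' @param text Character scalar: the raw file contents.
#' @param delimiter `"comma"`, `"tab"`, or `"auto"`. In auto mode the
#'   delimiter is inferred from the first line: tab wins if any tab is
#'   present, otherwise comma.
#' @return An object of class `cpg_raw_table`: a list with `cells`
#'   (character matrix) and `delimiter` (`"comma"` or `"tab"`).
#' @examples
#' tab <- parse_table("A,B\n1,0\n", delimiter = "comma")
#' tab$cells
#' @export
parse_table <- function(text, delimiter = c("auto", "comma", "tab")) {
  delimiter <- match.arg(delimiter)
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("`text` must be a single character string")
  if (!validUTF8(text))
    stop("input is not valid UTF-8 text")
  # strip UTF-8 BOM if present
  text <- sub("^﻿", "", text)
  if (!nzchar(gsub("[[:space:]]", "", text)))
    stop("input contains no data rows")

  first_line <- sub("\r?\n.*$", "", text)
  if (delimiter == "auto")
    delimiter <- if (grepl("\t", first_line, fixed = TRUE)) "tab" else "comma"
  sep <- if (delimiter == "tab") "\t" else ","

  ncol_max <- suppressWarnings(max(utils::count.fields(
    textConnection(text), sep = sep, quote = "\"",
    blank.lines.skip = FALSE), na.rm = TRUE))
  ncol_max <- max(ncol_max, 1L)
  df <- utils::read.table(
    text = text, sep = sep, quote = "\"", header = FALSE,
    colClasses = "character", col.names = paste0("V", seq_len(ncol_max)),
    fill = TRUE, blank.lines.skip = FALSE, na.strings = NULL,
    strip.white = FALSE, comment.char = "", stringsAsFactors = FALSE)
  cells <- as.matrix(df)
  dimnames(cells) <- NULL
  cells[] <- trimws(cells)

  # drop trailing all-blank rows (internal blank rows are meaningful:
  # they separate complexes)
  blank_row <- apply(cells == "", 1L, all)
  last_nonblank <- if (any(!blank_row)) max(which(!blank_row)) else 0L
  if (last_nonblank == 0L) stop("input contains no data rows")
  cells <- cells[seq_len(last_nonblank), , drop = FALSE]

  structure(list(cells = cells, delimiter = delimiter),
            class = "cpg_raw_table")
}

#' Read a CPG table file
#'
#' Convenience wrapper: reads a file as UTF-8 and runs [parse_table()] then
#' [build_dataset()].
#'
#' @param path Path to a CSV/TSV file in the CPG dialect.
#' @param delimiter Passed to [parse_table()].
#' @param ... Passed to [build_dataset()].
#' @return A list with elements `dataset` (a `cpg_dataset`, or `NULL` when
#'   validation failed) and `report` (a `cpg_report`).
#' @export
read_cpg <- function(path, delimiter = "auto", ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, what = "raw", n = file.size(path))
  text <- rawToChar(raw)
  Encoding(text) <- "UTF-8"
  build_dataset(parse_table(text, delimiter = delimiter), ...)
}

#' Parse one occupancy token
#'
#' The token set is closed: `"+"` or `"1"` mean present, `"-"`, the
#' typographic minus `"−"`, or `"0"` mean absent, after whitespace
#' stripping. Anything else is an error; no case-insensitive or wordy
#' variants are accepted, so parsing is bit-exact.
#'
#' @param token Character scalar.
#' @param row,col Optional 1-based file coordinates, used in the error
#'   message when the token is invalid.
#' @return `TRUE` (present) or `FALSE` (absent).
#' @examples
#' parse_occupancy_token("+")
#' parse_occupancy_token("0")
#' @export
parse_occupancy_token <- function(token, row = NULL, col = NULL) {
  v <- .occupancy_token(token)
  if (is.na(v)) {
    where <- if (!is.null(row) && !is.null(col))
      sprintf(" at row %d, column %d", row, col) else ""
    stop(sprintf("invalid occupancy token %s%s (expected '+', '-', '1' or '0')",
                 dQuote(token, q = FALSE), where), call. = FALSE)
  }
  v
}

# vectorized token classifier: TRUE/FALSE/NA (NA = invalid)
.occupancy_token <- function(tokens) {
  t <- trimws(tokens)
  out <- rep(NA, length(t))
  out[t %in% c("+", "1")] <- TRUE
  out[t %in% c("-", "−", "0")] <- FALSE
  out
}

# --- validation report ------------------------------------------------------

.new_report <- function() {
  structure(
    data.frame(severity = character(), row = integer(), col = integer(),
               message = character(), stringsAsFactors = FALSE),
    class = c("cpg_report", "data.frame"))
}

.add_issue <- function(report, severity, row, col, message) {
  rbind(report,
        data.frame(severity = severity, row = as.integer(row),
                   col = as.integer(col), message = message,
                   stringsAsFactors = FALSE))
}

#' @export
print.cpg_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No issues.\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x)))
    cat(sprintf("%s: row %d, column %d: %s\n",
                x$severity[i], x$row[i], x$col[i], x$message[i]))
  invisible(x)
}

#' Does a validation report contain errors?
#' @param report A `cpg_report`.
#' @return `TRUE` when no error-severity issue is present.
#' @export
report_ok <- function(report) {
  !any(report$severity == "error")
}

# --- dataset construction ---------------------------------------------------

#' Build a validated dataset from a raw table
#'
#' Interprets the CPG dialect: rows 1-2 are group labels (blank header cells
#' inherit the nearest non-empty label to their left), row 3 holds species
#' names (no gaps permitted), row 4 is annotation or the first data row, and
#' the remaining rows are subunit rows. A new complex starts at any row with
#' a non-empty column-1 cell; fully blank rows also act as separators and
#' are skipped. Every data cell must hold a valid occupancy token; empty
#' cells are not allowed.
#'
#' Row-4 classification: row 4 is taken as the first data row when all of
#' its data cells are valid occupancy tokens and its two label cells are
#' occupied, i.e. when it is a plausible first data row (the decision is
#' recorded as a warning in the report); otherwise it is annotation.
#' `strict_row4` forces the annotation interpretation.
#'
#' Taxa sharing a top-level group label must occupy contiguous columns
#' (colored blocks presume it); violations are errors by default, demotable
#' to warnings with `noncontiguous_groups = "warn"`.
#'
#' @param table A `cpg_raw_table` from [parse_table()].
#' @param strict_row4 Force row 4 to be read as annotation.
#' @param noncontiguous_groups `"error"` (default) or `"warn"`.
#' @return A list with `dataset` (a `cpg_dataset`, or `NULL` if any error
#'   was found) and `report` (a `cpg_report` with 1-based file coordinates).
#' @export
build_dataset <- function(table, strict_row4 = FALSE,
                          noncontiguous_groups = c("error", "warn")) {
  noncontiguous_groups <- match.arg(noncontiguous_groups)
  stopifnot(inherits(table, "cpg_raw_table"))
  cells <- table$cells
  report <- .new_report()

  if (nrow(cells) < 4L) {
    report <- .add_issue(report, "error", nrow(cells), 1L,
                         "table must have at least 4 rows (3 header rows and 1 data row)")
    return(list(dataset = NULL, report = report))
  }
  if (ncol(cells) < 3L) {
    report <- .add_issue(report, "error", 1L, ncol(cells),
                         "table must have at least 3 columns (2 label columns and 1 taxon)")
    return(list(dataset = NULL, report = report))
  }

  n_col <- ncol(cells)
  data_cols <- 3:n_col
  n_taxa <- length(data_cols)

  # header rows 1-2: blanks inherit nearest non-empty label to the left
  fill_left <- function(x) {
    for (j in seq_along(x)[-1]) if (x[j] == "") x[j] <- x[j - 1L]
    x
  }
  group_top <- fill_left(cells[1L, data_cols])
  group_mid <- fill_left(cells[2L, data_cols])

  species <- cells[3L, data_cols]
  for (j in which(species == ""))
    report <- .add_issue(report, "error", 3L, data_cols[j],
                         "species name missing: no gaps are permitted in row 3")

  # row-4 classification: data only when it is a plausible first data row
  # (all data cells valid tokens AND label columns occupied)
  row4_tokens <- .occupancy_token(cells[4L, data_cols])
  row4_is_data <- !strict_row4 && all(!is.na(row4_tokens)) &&
    cells[4L, 1L] != "" && cells[4L, 2L] != ""
  if (row4_is_data)
    report <- .add_issue(report, "warning", 4L, 3L,
                         "row 4 contains only occupancy tokens and was read as the first data row, not annotation")
  annotation <- if (row4_is_data) rep("", n_taxa) else cells[4L, data_cols]
  data_start <- if (row4_is_data) 4L else 5L

  # group contiguity on the top-level labels
  seen_groups <- character()
  prev <- NULL
  for (j in seq_len(n_taxa)) {
    g <- group_top[j]
    if (!identical(g, prev)) {
      if (g %in% seen_groups) {
        sev <- if (noncontiguous_groups == "error") "error" else "warning"
        report <- .add_issue(report, sev, 1L, data_cols[j],
                             sprintf("group '%s' reappears in non-contiguous columns", g))
      }
      seen_groups <- c(seen_groups, g)
      prev <- g
    }
  }

  # subunit rows
  complexes <- list()
  occ_rows <- list()
  cur_name <- NULL
  cur_subunits <- character()
  flush_complex <- function() {
    if (!is.null(cur_name))
      complexes[[length(complexes) + 1L]] <<-
        list(name = cur_name, subunits = cur_subunits)
    cur_name <<- NULL
    cur_subunits <<- character()
  }
  if (data_start <= nrow(cells)) {
    for (r in data_start:nrow(cells)) {
      rowc <- cells[r, ]
      if (all(rowc == "")) {       # blank separator row
        flush_complex()
        next
      }
      if (rowc[1L] != "") {        # new complex starts here
        flush_complex()
        cur_name <- rowc[1L]
      } else if (is.null(cur_name)) {
        report <- .add_issue(report, "error", r, 1L,
                             "subunit row appears before any complex name in column 1")
        next
      }
      if (rowc[2L] == "") {
        report <- .add_issue(report, "error", r, 2L, "subunit name is empty")
        next
      }
      cur_subunits <- c(cur_subunits, rowc[2L])
      vals <- .occupancy_token(rowc[data_cols])
      for (j in which(is.na(vals))) {
        tok <- rowc[data_cols[j]]
        msg <- if (tok == "")
          "empty cells are not allowed in the data matrix"
        else
          sprintf("invalid occupancy token %s (expected '+', '-', '1' or '0')",
                  dQuote(tok, q = FALSE))
        report <- .add_issue(report, "error", r, data_cols[j], msg)
      }
      occ_rows[[length(occ_rows) + 1L]] <- vals
    }
  }
  flush_complex()

  if (length(complexes) == 0L)
    report <- .add_issue(report, "error", data_start, 1L,
                         "no complexes found below the header rows")

  if (!report_ok(report))
    return(list(dataset = NULL, report = report))

  occupancy <- do.call(rbind, occ_rows)
  dimnames(occupancy) <- NULL
  taxa <- data.frame(
    group_top = group_top, group_mid = group_mid, species = species,
    annotation = annotation, column_index = seq_len(n_taxa) - 1L,
    stringsAsFactors = FALSE)
  ds <- structure(
    list(taxa = taxa, complexes = complexes, occupancy = occupancy,
         has_row4 = any(annotation != "")),
    class = "cpg_dataset")
  list(dataset = ds, report = report)
}

#' @export
print.cpg_dataset <- function(x, ...) {
  n_sub <- sum(vapply(x$complexes, function(cx) length(cx$subunits), 1L))
  cat(sprintf(
    "Coulson plot dataset: %d taxa in %d groups, %d complexes, %d subunit rows (%d of %d cells present)\n",
    nrow(x$taxa), length(unique(x$taxa$group_top)), length(x$complexes),
    n_sub, sum(x$occupancy), length(x$occupancy)))
  invisible(x)
}

#' Total subunit rows of a dataset
#' @param ds A `cpg_dataset`.
#' @return Integer: the summed subunit count over all complexes.
#' @export
n_subunits <- function(ds) {
  sum(vapply(ds$complexes, function(cx) length(cx$subunits), 1L))
}

# --- serialization ----------------------------------------------------------

# dataset -> cell matrix (header rows + subunit rows, no blank separators)
.dataset_cells <- function(ds) {
  n_taxa <- nrow(ds$taxa)
  n_col <- n_taxa + 2L
  header <- matrix("", nrow = 4L, ncol = n_col)
  header[1L, 3:n_col] <- ds$taxa$group_top
  header[2L, 3:n_col] <- ds$taxa$group_mid
  header[3L, 3:n_col] <- ds$taxa$species
  header[4L, 3:n_col] <- ds$taxa$annotation
  body <- NULL
  r <- 0L
  for (cx in ds$complexes) {
    for (s in seq_along(cx$subunits)) {
      r <- r + 1L
      row <- c(if (s == 1L) cx$name else "", cx$subunits[s],
               ifelse(ds$occupancy[r, ], "1", "0"))
      body <- rbind(body, row)
    }
  }
  dimnames(body) <- NULL
  rbind(header, body)
}

.serialize_cells <- function(cells, sep) {
  quote_field <- function(x) {
    needs <- grepl(sep, x, fixed = TRUE) | grepl("\"", x, fixed = TRUE) |
      grepl("\n", x, fixed = TRUE)
    x[needs] <- paste0("\"", gsub("\"", "\"\"", x[needs], fixed = TRUE), "\"")
    x
  }
  lines <- apply(cells, 1L, function(row) paste(quote_field(row), collapse = sep))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Serialize a dataset to the CPG dialect
#'
#' Emits four header rows followed by the subunit rows, occupancy written
#' as `'1'`/`'0'`, fields quoted when they contain the delimiter. The output
#' round-trips: parsing it back yields an identical dataset.
#'
#' @param ds A `cpg_dataset`.
#' @param delimiter `"comma"` or `"tab"`.
#' @return Character scalar: the file contents.
#' @export
write_dataset <- function(ds, delimiter = c("comma", "tab")) {
  delimiter <- match.arg(delimiter)
  stopifnot(inherits(ds, "cpg_dataset"))
  .serialize_cells(.dataset_cells(ds), if (delimiter == "tab") "\t" else ",")
}

#' Write a dataset to a file
#' @param ds A `cpg_dataset`.
#' @param path Output file path.
#' @param delimiter `"comma"` or `"tab"`.
#' @return `path`, invisibly.
#' @export
write_cpg <- function(ds, path, delimiter = c("comma", "tab")) {
  txt <- write_dataset(ds, delimiter)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(txt)), con)
  invisible(path)
}

# --- color sets -------------------------------------------------------------

#' Read a color set from text
#'
#' One entry per non-blank line, either `label<TAB>#RRGGBB` or a bare
#' `#RRGGBB` (the label then defaults to the entry's ordinal). Order is
#' preserved; colors must be 6-hex-digit sRGB.
#'
#' @param text Character scalar: file contents.
#' @return A `cpg_color_set`: list with character vectors `labels` and
#'   `colors`.
#' @examples
#' read_color_set("Excavata\t#E41A1C\nOpisthokonta\t#377EB8\n")
#' @export
read_color_set <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- sub("^﻿", "", text)
  lines <- strsplit(text, "\r?\n")[[1]]
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("color set is empty")
  labels <- character(0)
  colors <- character(0)
  for (i in keep) {
    fields <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    fields <- fields[nzchar(fields)]
    if (length(fields) == 1L) {
      label <- as.character(length(labels) + 1L)
      color <- fields[1L]
    } else if (length(fields) == 2L) {
      label <- fields[1L]
      color <- fields[2L]
    } else {
      stop(sprintf("line %d: malformed color-set line (expected 'label<TAB>#RRGGBB')", i))
    }
    if (!grepl("^#[0-9A-Fa-f]{6}$", color))
      stop(sprintf("line %d: %s is not a 6-digit hex color", i,
                   dQuote(color, q = FALSE)))
    labels <- c(labels, label)
    colors <- c(colors, toupper(color))
  }
  structure(list(labels = labels, colors = colors), class = "cpg_color_set")
}

#' Read a color set from a file
#' @param path Path to a color-set text file.
#' @return A `cpg_color_set`.
#' @export
read_color_set_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read_color_set(paste0(paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                              collapse = "\n"), "\n"))
}

#' The built-in default color set
#'
#' Eight colorblind-aware colors labelled with the major eukaryotic
#' supergroups; taxa whose top-level group matches a label get that color,
#' others are assigned positionally. The same set ships as a text file at
#' `system.file("extdata", "default_colors.txt", package = "coulsonplot")`.
#'
#' @return A `cpg_color_set`.
#' @export
default_color_set <- function() {
  structure(list(
    labels = c("Opisthokonta", "Amoebozoa", "Archaeplastida", "Excavata",
               "Stramenopila", "Alveolata", "Rhizaria", "Discoba"),
    colors = c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3",
               "#FF7F00", "#A65628", "#F781BF", "#17BECF")),
    class = "cpg_color_set")
}

#' @export
print.cpg_color_set <- function(x, ...) {
  cat(sprintf("Color set with %d entries:\n", length(x$colors)))
  cat(sprintf("  %s  %s\n", x$colors, x$labels), sep = "")
  invisible(x)
}
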