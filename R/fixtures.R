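# ---------------------------------------------------------------------------
# Synthetic fixtures: seeded valid datasets at arbitrary scale, and
# minimally mutated malformed inputs that each isolate one validation rule.
# All randomness flows from the single integer seed in the spec; the
# caller's RNG state is saved and restored.
# ---------------------------------------------------------------------------

#' Specification for a synthetic dataset
#'
#' @param n_groups Number of top-level taxonomic groups.
#' @param species_per_group Species (taxa) per group.
#' @param n_complexes Number of complexes (pies per taxon).
#' @param subunits_min,subunits_max Subunit counts are drawn uniformly in
#'   `[subunits_min, subunits_max]`; `subunits_min >= 1`.
#' @param presence_prob Probability that any occupancy cell is present,
#'   i.i.d. Bernoulli (no phylogenetic correlation is modelled).
#' @param seed Integer seed driving all randomness.
#' @return A `cpg_fixture_spec` list.
#' @export
fixture_spec <- function(n_groups = 5, species_per_group = 5,
                         n_complexes = 10, subunits_min = 2,
                         subunits_max = 8, presence_prob = 0.6,
                         seed = 1L) {
  stopifnot(n_groups >= 1, species_per_group >= 1, n_complexes >= 1,
            subunits_min >= 1, subunits_max >= subunits_min,
            presence_prob >= 0, presence_prob <= 1)
  structure(list(
    n_groups = as.integer(n_groups),
    species_per_group = as.integer(species_per_group),
    n_complexes = as.integer(n_complexes),
    subunits_min = as.integer(subunits_min),
    subunits_max = as.integer(subunits_max),
    presence_prob = presence_prob, seed = as.integer(seed)),
    class = "cpg_fixture_spec")
}

# run fn with a private RNG stream seeded from `seed`
.with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  fn()
}

#' Generate a synthetic valid dataset
#'
#' Deterministic for a fixed seed. Names are systematic: groups `G1..`,
#' species `G1_sp1..`, complexes `C1..`, subunits `C3_s4..`. Every
#' generated dataset passes [build_dataset()] validation after a
#' write/parse round trip.
#'
#' @param spec A `cpg_fixture_spec`.
#' @return A `cpg_dataset`.
#' @examples
#' ds <- generate_dataset(fixture_spec(n_groups = 2, species_per_group = 2,
#'                                     n_complexes = 3, seed = 7))
#' ds
#' @export
generate_dataset <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "cpg_fixture_spec"))
  .with_seed(spec$seed, function() {
    n_taxa <- spec$n_groups * spec$species_per_group
    groups <- paste0("G", seq_len(spec$n_groups))
    group_top <- rep(groups, each = spec$species_per_group)
    species <- paste0(group_top, "_sp",
                      rep(seq_len(spec$species_per_group), spec$n_groups))
    taxa <- data.frame(
      group_top = group_top,
      group_mid = paste0(group_top, "m"),
      species = species,
      annotation = rep("", n_taxa),
      column_index = seq_len(n_taxa) - 1L,
      stringsAsFactors = FALSE)
    n_sub <- spec$subunits_min +
      sample.int(spec$subunits_max - spec$subunits_min + 1L,
                 spec$n_complexes, replace = TRUE) - 1L
    complexes <- lapply(seq_len(spec$n_complexes), function(ci)
      list(name = paste0("C", ci),
           subunits = paste0("C", ci, "_s", seq_len(n_sub[ci]))))
    total <- sum(n_sub)
    occupancy <- matrix(stats::runif(total * n_taxa) < spec$presence_prob,
                        nrow = total, ncol = n_taxa)
    structure(list(taxa = taxa, complexes = complexes,
                   occupancy = occupancy, has_row4 = FALSE),
              class = "cpg_dataset")
  })
}

#' Derive a malformed input from a valid dataset
#'
#' Serializes the dataset and applies exactly one named defect at a
#' seed-chosen location, returning the mutated text together with the file
#' coordinates where [build_dataset()] is expected to report the error.
#' Each defect isolates one validation rule:
#' \describe{
#'   \item{gap_in_species_row}{blanks one species cell in row 3}
#'   \item{empty_data_cell}{blanks one occupancy cell}
#'   \item{bad_token}{replaces one occupancy cell with `"x"`}
#'   \item{subunit_before_complex}{blanks the first complex's name cell}
#'   \item{ragged_rows}{drops the last field of one data row (the parser
#'     pads it, so the observable failure is an empty cell in the last
#'     column)}
#' }
#'
#' @param ds A valid `cpg_dataset`.
#' @param defect One of the defect names above.
#' @param seed Integer seed choosing the mutation site.
#' @param delimiter `"comma"` or `"tab"`.
#' @return List with `text` (the malformed file contents), `defect`, and
#'   `expected` (data frame of 1-based `row`/`col` error coordinates).
#' @export
make_malformed <- function(ds,
                           defect = c("gap_in_species_row", "empty_data_cell",
                                      "bad_token", "subunit_before_complex",
                                      "ragged_rows"),
                           seed = 1L, delimiter = c("comma", "tab")) {
  defect <- match.arg(defect)
  delimiter <- match.arg(delimiter)
  stopifnot(inherits(ds, "cpg_dataset"))
  sep <- if (delimiter == "tab") "\t" else ","
  cells <- .dataset_cells(ds)
  n_row <- nrow(cells)
  n_col <- ncol(cells)
  .with_seed(seed, function() {
    pick_data_cell <- function() {
      r <- if (n_row == 5L) 5L else sample(5:n_row, 1L)
      j <- if (n_col == 3L) 3L else sample(3:n_col, 1L)
      c(r, j)
    }
    expected <- switch(defect,
      gap_in_species_row = {
        j <- if (n_col == 3L) 3L else sample(3:n_col, 1L)
        cells[3L, j] <- ""
        data.frame(row = 3L, col = j)
      },
      empty_data_cell = {
        rc <- pick_data_cell()
        cells[rc[1L], rc[2L]] <- ""
        data.frame(row = rc[1L], col = rc[2L])
      },
      bad_token = {
        rc <- pick_data_cell()
        cells[rc[1L], rc[2L]] <- "x"
        data.frame(row = rc[1L], col = rc[2L])
      },
      subunit_before_complex = {
        cells[5L, 1L] <- ""
        data.frame(row = 5L, col = 1L)
      },
      ragged_rows = {
        r <- if (n_row == 5L) 5L else sample(5:n_row, 1L)
        data.frame(row = r, col = n_col)
      })
    text <- if (defect == "ragged_rows") {
      lines <- vapply(seq_len(n_row), function(r) {
        row <- cells[r, ]
        if (r == expected$row[1L]) row <- row[-n_col]
        paste(row, collapse = sep)
      }, "")
      paste0(paste(lines, collapse = "\n"), "\n")
    } else {
      .serialize_cells(cells, sep)
    }
    list(text = text, defect = defect, expected = expected)
  })
}
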