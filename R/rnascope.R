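#' Segmented-cell table
#'
#' One row per segmented cell from a smFISH/immunofluorescence image
#' analysis export: the tissue section, the probe combination, the
#' phenotype call (`NA` for segmented-but-unlabeled nuclei), the
#' nuclear area in square microns, the puncta count of the total-RNA
#' probe, and optionally the cell radius in microns (derived from the
#' area assuming a circular nucleus when absent).
#'
#' @param data a data frame with columns `section_id`, `phenotype`,
#'   `nuclear_area`, `puncta`, and optionally `combination` and
#'   `radius`.
#' @return a tibble of class `cells_tbl`.
#' @export
cells_table <- function(data) {
  need <- c("section_id", "phenotype", "nuclear_area", "puncta")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("cells table missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  out <- as_tibble(data)
  if (any(is.na(out$section_id)) || any(out$section_id == "")) {
    abort("section_id must be non-empty.")
  }
  if (any(!is.finite(out$nuclear_area)) || any(out$nuclear_area < 0)) {
    abort("nuclear_area must be finite and non-negative.")
  }
  if (!"combination" %in% names(out)) out$combination <- NA_character_
  if (!"radius" %in% names(out)) out$radius <- NA_real_
  structure(out, class = c("cells_tbl", class(tibble())))
}

#' Read a HALO-style segmented-cell CSV
#'
#' Export schemas vary between image-analysis runs, so the mapping
#' from file columns to the canonical names is configurable (inline or
#' via a YAML file with a `columns:` block).
#'
#' @param path CSV path.
#' @param columns named character vector mapping canonical name
#'   (`section_id`, `phenotype`, `nuclear_area`, `puncta`,
#'   `combination`, `radius`) to the file's column name, or a YAML
#'   file path holding such a mapping under `columns`.
#' @return a [cells_table()].
#' @export
read_halo_cells <- function(path,
                            columns = c(section_id = "section_id",
                                        phenotype = "phenotype",
                                        nuclear_area = "nuclear_area",
                                        puncta = "puncta")) {
  if (is.character(columns) && length(columns) == 1 &&
      file.exists(columns)) {
    cfg <- yaml::read_yaml(columns)
    columns <- unlist(cfg$columns)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  absent <- setdiff(unname(columns), names(df))
  if (length(absent) > 0) {
    abort(paste0("columns absent from file: ",
                 paste(absent, collapse = ", ")))
  }
  out <- df[, unname(columns), drop = FALSE]
  names(out) <- names(columns)
  cells_table(out)
}

cell_radius <- function(cells) {
  ifelse(is.na(cells$radius), sqrt(cells$nuclear_area / pi), cells$radius)
}

#' Remove over-sized segmented cells
#'
#' Cells whose radius exceeds the plausible size of a single nucleus
#' are usually segmentation artefacts (merged nuclei). Removes rows
#' with radius strictly greater than `max_radius`; when the radius is
#' not recorded it is derived as `sqrt(nuclear_area / pi)`.
#'
#' @param cells a [cells_table()].
#' @param max_radius exclusion threshold in microns (default 5).
#' @return a list with `cells` (the filtered table) and `n_removed`.
#' @export
radius_filter <- function(cells, max_radius = 5) {
  if (!is.numeric(max_radius) || max_radius <= 0) {
    abort("`max_radius` must be positive.")
  }
  r <- cell_radius(cells)
  keep <- r <= max_radius
  list(cells = cells[keep, , drop = FALSE],
       n_removed = sum(!keep))
}

#' Drop low-quality tissue sections
#'
#' Sections are graded `Low < Okay < High` by expert review of tissue
#' morphology and staining; only sections at or above `min_grade` are
#' retained.
#'
#' @param cells a [cells_table()].
#' @param qc a data frame with `section_id` and `grade` columns
#'   covering every section in `cells`.
#' @param min_grade minimum acceptable grade (default `"Okay"`).
#' @return the filtered [cells_table()].
#' @export
qc_filter <- function(cells, qc, min_grade = c("Okay", "Low", "High")) {
  min_grade <- match.arg(min_grade)
  grades <- c(Low = 1, Okay = 2, High = 3)
  if (!all(qc$grade %in% names(grades))) {
    abort("grades must be Low, Okay, or High.")
  }
  ungraded <- setdiff(unique(cells$section_id), qc$section_id)
  if (length(ungraded) > 0) {
    abort(paste0("ungraded sections: ", paste(ungraded, collapse = ", ")))
  }
  section_grade <- setNames(grades[qc$grade], qc$section_id)
  keep <- section_grade[cells$section_id] >= grades[[min_grade]]
  cells[keep, , drop = FALSE]
}

#' Per-section cell-type proportions
#'
#' Divides the number of cells of each phenotype by the total number
#' of segmented cells in the section. Because the denominator counts
#' every segmented cell, labeled proportions alone need not sum to 1;
#' the explicit `other` column carries the unlabeled remainder so
#' each row sums to 1 exactly.
#'
#' @param cells a [cells_table()] (apply [radius_filter()] /
#'   [qc_filter()] first as appropriate).
#' @return a [proportion_tbl()] with one row per section, cell-type
#'   columns plus `other`, and unit ids equal to section ids.
#' @export
section_proportions <- function(cells) {
  if (nrow(cells) == 0) abort("empty cells table.")
  types <- sort(unique(cells$phenotype[!is.na(cells$phenotype)]))
  df <- tibble(section_id = cells$section_id,
               phenotype = ifelse(is.na(cells$phenotype), "other",
                                  cells$phenotype))
  counts <- df %>%
    group_by(.data$section_id, .data$phenotype) %>%
    summarise(n = dplyr::n(), .groups = "drop")
  wide <- tidyr::pivot_wider(counts, names_from = "phenotype",
                             values_from = "n", values_fill = 0)
  for (ct in c(types, "other")) {
    if (!ct %in% names(wide)) wide[[ct]] <- 0L
  }
  cols <- c(types, "other")
  m <- as.matrix(wide[, cols, drop = FALSE])
  m <- m / rowSums(m)
  out <- dplyr::bind_cols(tibble(unit_id = wide$section_id),
                          as_tibble(as.data.frame(m)))
  proportion_tbl(out, cols, method = "imaging")
}

#' Per-type cell-size metrics
#'
#' Three per-cell-type size summaries from labeled cells pooled across
#' sections (or per section first, then the median of section
#' medians): the median nuclear area, the median total-RNA puncta
#' count, and the median of the per-cell area x puncta product (the
#' median of products, not the product of medians).
#'
#' @param cells a [cells_table()] of retained, labeled cells.
#' @param pool `"cells"` pools all cells per type (default);
#'   `"sections"` takes per-section medians first.
#' @return a named list of three named numeric vectors (`area`,
#'   `puncta`, `area_x_puncta`), each cell type -> median. Types with
#'   no labeled cells are omitted with a warning.
#' @export
cell_size_metrics <- function(cells, pool = c("cells", "sections")) {
  pool <- match.arg(pool)
  labeled <- cells[!is.na(cells$phenotype), , drop = FALSE]
  if (nrow(labeled) == 0) {
    warn("no labeled cells; empty size metrics.")
    empty <- setNames(numeric(0), character(0))
    return(list(area = empty, puncta = empty, area_x_puncta = empty))
  }
  labeled$product <- labeled$nuclear_area * labeled$puncta
  per_type <- function(value_col) {
    if (pool == "cells") {
      agg <- labeled %>%
        group_by(.data$phenotype) %>%
        summarise(m = median(.data[[value_col]]), .groups = "drop")
    } else {
      agg <- labeled %>%
        group_by(.data$phenotype, .data$section_id) %>%
        summarise(m = median(.data[[value_col]]), .groups = "drop") %>%
        group_by(.data$phenotype) %>%
        summarise(m = median(.data$m), .groups = "drop")
    }
    setNames(agg$m, agg$phenotype)
  }
  list(area = per_type("nuclear_area"),
       puncta = per_type("puncta"),
       area_x_puncta = per_type("product"))
}
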