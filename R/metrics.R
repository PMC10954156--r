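# Emergent-behavior metrics: colony growth rate, symmetry, and mean cell
# cycle length, with 2D / 3D / center-slice (3DC) variants.

#' Colony growth rate
#'
#' The slope (sites/day) of a degree-1 least-squares fit of colony diameter
#' against time over the window starting at `start_day`. The fit requires at
#' least three time points at or after `start_day`.
#'
#' @param data A data frame with a time column (days) and a diameter column.
#' @param t,diameter Column names (unquoted) of time and diameter.
#' @param start_day Window start (days); 2 by default.
#' @return The fitted slope in sites/day.
#' @examples
#' growth_rate(tibble::tibble(t = 2:5, diameter = c(10, 12, 14, 16)))
#' @export
growth_rate <- function(data, t = t, diameter = diameter, start_day = 2) {
  tt <- dplyr::pull(data, {{ t }})
  dd <- dplyr::pull(data, {{ diameter }})
  keep <- tt >= start_day & !is.na(dd)
  tt <- tt[keep]; dd <- dd[keep]
  if (length(tt) < 3L) {
    stop("growth rate undefined: need at least 3 diameter observations at ",
         "or after day ", start_day, call. = FALSE)
  }
  unname(stats::lm.fit(cbind(1, tt), dd)$coefficients[2])
}

#' Colony symmetry
#'
#' The symmetry statistic `1 - (1/N) * sum_i n_i / lambda_i`, where N is the
#' number of unique occupied locations, `n_i` the number of unoccupied
#' symmetry-partner locations of location i (see [symmetry_partners()]), and
#' `lambda_i` the number of possible partners for its location class (5 for
#' hexagonal; 3 for generic rectangular locations, 7 on an axis or the
#' x = y diagonal). Values range from 0 (not symmetric) to 1 (perfectly
#' symmetric).
#'
#' If the occupancy set spans several z layers, symmetry is computed
#' separately for each slice and averaged over non-empty slices (the 3D
#' variant); pass `slice = "center"` to evaluate the z = 0 slice only (the
#' 3DC variant).
#'
#' @param occupied Coordinate tibble of occupied locations (duplicates are
#'   collapsed).
#' @param slice `"all"` (slice-wise average) or `"center"` (z = 0 only).
#' @return Symmetry value in `[0, 1]`.
#' @examples
#' ring <- grid_neighbors(hex_coord(0, 0), geometry_spec("hexagonal", "2D", 4))
#' colony_symmetry(dplyr::bind_rows(hex_coord(0, 0), ring[-1])) # 1
#' @export
colony_symmetry <- function(occupied, slice = c("all", "center")) {
  slice <- match.arg(slice)
  mode <- coord_mode(occupied)
  if (nrow(occupied) == 0L) {
    stop("symmetry undefined for an empty occupancy set", call. = FALSE)
  }
  m <- coord_matrix(occupied, mode)
  if (slice == "center") {
    m <- m[m[, 3] == 0L, , drop = FALSE]
    if (nrow(m) == 0L) {
      stop("symmetry undefined: center slice is empty", call. = FALSE)
    }
  }
  vals <- vapply(unique(m[, 3]), function(zk) {
    symmetry_ab(unique(m[m[, 3] == zk, 1:2, drop = FALSE]), mode)
  }, numeric(1))
  mean(vals)
}

#' Colony diameter
#'
#' The maximum per-axis occupied span. For multi-layer occupancy sets the 3D
#' diameter is the maximum across z slices; `slice = "center"` evaluates the
#' z = 0 slice only.
#'
#' @inheritParams colony_symmetry
#' @param spec A [geometry_spec()].
#' @return Diameter in lattice units.
#' @export
colony_diameter <- function(occupied, spec, slice = c("all", "center")) {
  slice <- match.arg(slice)
  mode <- coord_mode(occupied)
  m <- coord_matrix(occupied, mode)
  if (slice == "center") m <- m[m[, 3] == 0L, , drop = FALSE]
  if (nrow(m) == 0L) {
    stop("colony is extinct: cannot measure an empty occupancy set",
         call. = FALSE)
  }
  max(vapply(unique(m[, 3]), function(zk) {
    sl <- matrix_coords(m[m[, 3] == zk, , drop = FALSE], mode)
    axis_extents(sl, spec)$d
  }, numeric(1)))
}

#' Mean cell cycle length
#'
#' Cycle lengths (time from entering the proliferative state to a completed
#' division) are first averaged within each cell, then across all cancer
#' cells with at least one completed division; healthy tissue cells are
#' excluded. For 3D rosters, `slice = "center"` restricts to cells in the
#' z = 0 layer (the 3DC variant).
#'
#' @param records A data frame with one row per completed division:
#'   columns `cell` (cell id), `population`, `duration` (minutes), and
#'   optionally `z` (layer of the cell).
#' @param slice `"all"` or `"center"`.
#' @return Mean cycle length in minutes.
#' @examples
#' cycle_length(tibble::tibble(cell = c(1, 1, 2), population = "cancerous",
#'                             duration = c(1200, 1440, 1800)))
#' @export
cycle_length <- function(records, slice = c("all", "center")) {
  slice <- match.arg(slice)
  x <- dplyr::filter(records, .data$population == "cancerous")
  if (slice == "center" && "z" %in% names(x)) {
    x <- dplyr::filter(x, .data$z == 0L)
  }
  if (nrow(x) == 0L) {
    stop("cycle length undefined: no cancer cell has completed a division",
         call. = FALSE)
  }
  per_cell <- dplyr::summarise(dplyr::group_by(x, .data$cell),
                               m = mean(.data$duration), .groups = "drop")
  mean(per_cell$m)
}
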