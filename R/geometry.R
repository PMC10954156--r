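# Coordinate systems, neighbor topology, and grid-to-fine-lattice mapping for
# the rectangular and hexagonal lattice representations.
#
# Conventions:
#  * rectangular grid coordinates are (x, y, z); hexagonal are (u, v, w, z)
#    with u + v + w = 0. Only (u, v) are authoritative; w is derived.
#  * z = 0 is the center layer; layers run z = -(H-1)/2 .. (H-1)/2.
#  * 3D layer offset classes: rectangular layers alternate no-offset/offset
#    with class z mod 2; hexagonal layers cycle no-offset -> offset a ->
#    offset b with class z mod 3.

# -- same-layer neighbor offsets ---------------------------------------------
.HEX_SL <- matrix(c(0, 1, 0, -1, -1, 1, 1, -1, -1, 0, 1, 0),
                  ncol = 2, byrow = TRUE) # (du, dv)
.RECT_SL <- matrix(c(1, 0, -1, 0, 0, 1, 0, -1), ncol = 2, byrow = TRUE)

# -- vertical neighbor offsets by layer class --------------------------------
# Hexagonal: each layer sees the directly-stacked location plus one triple of
# in-plane offsets selected by its offset class; the below-triples are the
# negations of the above-triples of the layer underneath (reciprocity).
.HEX_T1 <- matrix(c(1, 0, -1, 1, 0, -1), ncol = 2, byrow = TRUE)
.HEX_T2 <- matrix(c(0, 1, -1, 0, 1, -1), ncol = 2, byrow = TRUE)
.hex_above <- list(rbind(c(0, 0), .HEX_T1),  # class 0: no offset
                   rbind(c(0, 0), .HEX_T2),  # class 1: offset a
                   rbind(c(0, 0), .HEX_T1))  # class 2: offset b
.hex_below <- list(rbind(c(0, 0), .HEX_T2),  # -above[[3]]
                   rbind(c(0, 0), .HEX_T2),  # -above[[1]]
                   rbind(c(0, 0), .HEX_T1))  # -above[[2]]
# Rectangular: class 0 (no offset) picks the first entry of each bracketed
# pair, class 1 (offset) the second; in-plane picks coincide above and below.
.rect_vert <- list(rbind(c(0, 0), c(-1, 0), c(0, -1), c(-1, -1)),
                   rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))

#' Define a lattice geometry
#'
#' A geometry specification fixes the coordinate mode (hexagonal or
#' rectangular), the dimensionality, the domain radius and, for 3D, the
#' number of stacked layers.
#'
#' @param mode `"hexagonal"` or `"rectangular"`.
#' @param dimension `"2D"` or `"3D"`.
#' @param radius Domain radius R in lattice units. The rectangular domain is
#'   the square `|x|, |y| <= R`; the hexagonal domain is the hexagon
#'   `max(|u|, |v|, |w|) <= R`.
#' @param layers Odd number of z layers H; must be 1 for 2D. Defaults to 1
#'   (2D) or 7 (3D).
#' @return An object of class `geometry_spec`.
#' @examples
#' geometry_spec("hexagonal", "2D", radius = 4)
#' @export
geometry_spec <- function(mode = c("hexagonal", "rectangular"),
                          dimension = c("2D", "3D"),
                          radius = 20, layers = NULL) {
  mode <- match.arg(mode)
  dimension <- match.arg(dimension)
  if (is.null(layers)) layers <- if (dimension == "2D") 1L else 7L
  layers <- as.integer(layers)
  radius <- as.integer(radius)
  stopifnot(radius >= 1L, layers >= 1L, layers %% 2L == 1L)
  if ((layers == 1L) != (dimension == "2D")) {
    stop("layers must be 1 exactly when dimension is \"2D\"", call. = FALSE)
  }
  structure(list(mode = mode, dimension = dimension,
                 radius = radius, layers = layers),
            class = "geometry_spec")
}

#' @export
print.geometry_spec <- function(x, ...) {
  cat(sprintf("<geometry_spec> %s %s, radius %d, %d layer%s\n",
              x$mode, x$dimension, x$radius, x$layers,
              if (x$layers > 1) "s" else ""))
  invisible(x)
}

#' Build coordinate tibbles
#'
#' Construct hexagonal `(u, v, w, z)` or rectangular `(x, y, z)` coordinate
#' tables. For hexagonal coordinates `w` is derived as `-u - v` so the
#' invariant `u + v + w = 0` holds by construction; supplying `w` explicitly
#' checks it instead.
#'
#' @param u,v,w Hexagonal axial coordinates (`w` optional).
#' @param x,y Rectangular coordinates.
#' @param z Layer coordinate (0 = center layer).
#' @return A tibble with columns `u, v, w, z` or `x, y, z`.
#' @examples
#' hex_coord(u = c(0, 1), v = c(0, -1))
#' rect_coord(x = 1, y = 2)
#' @export
hex_coord <- function(u, v, w = NULL, z = 0L) {
  u <- as.integer(u); v <- as.integer(v)
  if (!is.null(w) && any(u + v + as.integer(w) != 0L)) {
    stop("invalid hexagonal coordinate: u + v + w must equal 0", call. = FALSE)
  }
  tibble::tibble(u = u, v = v, w = -u - v,
                 z = recycle_int(z, length(u)))
}

#' @rdname hex_coord
#' @export
rect_coord <- function(x, y, z = 0L) {
  x <- as.integer(x)
  tibble::tibble(x = x, y = as.integer(y),
                 z = recycle_int(z, length(x)))
}

coord_mode <- function(coords) {
  if (all(c("u", "v", "z") %in% names(coords))) return("hexagonal")
  if (all(c("x", "y", "z") %in% names(coords))) return("rectangular")
  stop("coordinate table must have columns u,v[,w],z or x,y,z", call. = FALSE)
}

# internal: coords tibble -> integer matrix of axial columns (a, b, z)
coord_matrix <- function(coords, mode = coord_mode(coords)) {
  if (mode == "hexagonal") {
    if ("w" %in% names(coords) &&
        any(coords$u + coords$v + coords$w != 0L)) {
      stop("invalid hexagonal coordinate: u + v + w must equal 0",
           call. = FALSE)
    }
    cbind(a = as.integer(coords$u), b = as.integer(coords$v),
          z = as.integer(coords$z))
  } else {
    cbind(a = as.integer(coords$x), b = as.integer(coords$y),
          z = as.integer(coords$z))
  }
}

matrix_coords <- function(m, mode) {
  if (mode == "hexagonal") {
    tibble::tibble(u = m[, 1], v = m[, 2], w = -m[, 1] - m[, 2], z = m[, 3])
  } else {
    tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3])
  }
}

in_domain_matrix <- function(m, spec) {
  half <- (spec$layers - 1L) %/% 2L
  ok_z <- abs(m[, 3]) <= half
  if (spec$mode == "hexagonal") {
    ok_z & pmax(abs(m[, 1]), abs(m[, 2]), abs(m[, 1] + m[, 2])) <= spec$radius
  } else {
    ok_z & abs(m[, 1]) <= spec$radius & abs(m[, 2]) <= spec$radius
  }
}

#' Test whether coordinates lie inside the simulation domain
#'
#' @param coords A coordinate tibble (see [hex_coord()]).
#' @param spec A [geometry_spec()].
#' @return Logical vector, one element per row of `coords`.
#' @export
in_domain <- function(coords, spec) {
  mode <- coord_mode(coords)
  if (mode != spec$mode) stop("coordinate mode does not match geometry spec",
                              call. = FALSE)
  in_domain_matrix(coord_matrix(coords, mode), spec)
}

#' Enumerate every in-domain grid location
#'
#' @inheritParams in_domain
#' @return A coordinate tibble covering the full domain (all layers).
#' @export
domain_coords <- function(spec) {
  R <- spec$radius
  half <- (spec$layers - 1L) %/% 2L
  g <- expand.grid(a = -R:R, b = -R:R, z = -half:half)
  m <- as.matrix(g)
  matrix_coords(m[in_domain_matrix(m, spec), , drop = FALSE], spec$mode)
}

vertical_offsets <- function(mode, zclass, direction) {
  if (mode == "hexagonal") {
    if (direction > 0) .hex_above[[zclass + 1L]] else .hex_below[[zclass + 1L]]
  } else {
    .rect_vert[[zclass + 1L]]
  }
}

layer_class <- function(mode, z) {
  if (mode == "hexagonal") z %% 3L else z %% 2L
}

# internal: neighbor offsets (da, db, dz) for one layer class
neighbor_offsets <- function(mode, z, layers) {
  sl <- if (mode == "hexagonal") .HEX_SL else .RECT_SL
  out <- cbind(sl, 0L)
  if (layers > 1L) {
    cls <- layer_class(mode, z)
    out <- rbind(out,
                 cbind(vertical_offsets(mode, cls, +1L), 1L),
                 cbind(vertical_offsets(mode, cls, -1L), -1L))
  }
  out
}

#' Neighboring grid locations
#'
#' Returns the lattice neighbors of each input location: the 6 (hexagonal) or
#' 4 (rectangular) same-layer neighbors plus, in 3D, the vertical neighbors
#' selected by the layer's offset class. Rectangular layers alternate between
#' offset and no offset; hexagonal layers cycle no offset, offset a, offset b.
#' Neighbors falling outside the domain are dropped.
#'
#' @param coords Coordinate tibble of query locations.
#' @param spec A [geometry_spec()] whose mode matches `coords`.
#' @return A tibble of neighbor coordinates with a `.site` column giving the
#'   row of `coords` each neighbor belongs to.
#' @examples
#' spec <- geometry_spec("hexagonal", "2D", radius = 4)
#' grid_neighbors(hex_coord(0, 0), spec)
#' @export
grid_neighbors <- function(coords, spec) {
  mode <- coord_mode(coords)
  if (mode != spec$mode) stop("coordinate mode does not match geometry spec",
                              call. = FALSE)
  m <- coord_matrix(coords, mode)
  if (!all(in_domain_matrix(m, spec))) {
    stop("all query coordinates must lie inside the domain", call. = FALSE)
  }
  parts <- lapply(seq_len(nrow(m)), function(i) {
    off <- neighbor_offsets(mode, m[i, 3], spec$layers)
    nb <- sweep(off, 2L, m[i, ], "+")
    nb <- nb[in_domain_matrix(nb, spec), , drop = FALSE]
    cbind(.site = i, nb)
  })
  all <- do.call(rbind, parts)
  out <- matrix_coords(all[, -1, drop = FALSE], mode)
  out$.site <- all[, 1]
  out[, c(".site", setdiff(names(out), ".site"))]
}

# -- symmetry partners -------------------------------------------------------

#' Symmetry-partner locations
#'
#' For each location, the set of corresponding locations whose occupancy
#' defines perfect colony symmetry. Rectangular locations map to the three
#' partners (-y, x), (-x, -y), (y, -x); locations on an axis (x = 0 or
#' y = 0) or the diagonal x = y additionally check (x, -y), (y, x), (-x, y),
#' (-y, -x) (seven partners). Hexagonal locations map to the five partners
#' (-w, -u, -v), (v, w, u), (-u, -v, -w), (w, u, v), (-v, -w, -u). Partners
#' share the z layer of the query; duplicates and self-maps are collapsed.
#'
#' @param coords Coordinate tibble.
#' @return A tibble of partner coordinates with a `.site` column indexing the
#'   query row, and an `n_partners` attribute is not set; use
#'   [symmetry_partner_count()] for the per-class partner total.
#' @examples
#' symmetry_partners(hex_coord(1, -1))
#' symmetry_partners(rect_coord(1, 2))
#' @export
symmetry_partners <- function(coords) {
  mode <- coord_mode(coords)
  m <- coord_matrix(coords, mode)
  parts <- lapply(seq_len(nrow(m)), function(i) {
    p <- partner_matrix(m[i, 1], m[i, 2], mode)
    cbind(.site = i, p, z = m[i, 3])
  })
  all <- do.call(rbind, parts)
  out <- matrix_coords(all[, -1, drop = FALSE], mode)
  out$.site <- all[, 1]
  out[, c(".site", setdiff(names(out), ".site"))]
}

# internal: unique partner (a, b) pairs for a single 2D location
partner_matrix <- function(a, b, mode) {
  if (mode == "hexagonal") {
    u <- a; v <- b; w <- -u - v
    p <- rbind(c(-w, -u), c(v, w), c(-u, -v), c(w, u), c(-v, -w))
  } else {
    x <- a; y <- b
    p <- rbind(c(-y, x), c(-x, -y), c(y, -x))
    if (x == 0L || y == 0L || x == y) {
      p <- rbind(p, c(x, -y), c(y, x), c(-x, y), c(-y, -x))
    }
  }
  unique(p)
}

#' Number of possible corresponding locations for the symmetry metric
#'
#' The normalizer lambda of the symmetry statistic: 5 for hexagonal
#' locations; 3 for generic rectangular locations; 7 for rectangular
#' locations with x = 0, y = 0, or x = y.
#'
#' @inheritParams symmetry_partners
#' @return Integer vector, one element per row.
#' @export
symmetry_partner_count <- function(coords) {
  mode <- coord_mode(coords)
  m <- coord_matrix(coords, mode)
  if (mode == "hexagonal") return(rep(5L, nrow(m)))
  ifelse(m[, 1] == 0L | m[, 2] == 0L | m[, 1] == m[, 2], 7L, 3L)
}

# -- grid to fine (molecular) lattice ----------------------------------------

#' Map grid locations to fine-lattice sites
#'
#' Each rectangular grid location covers four rectangular fine-lattice sites
#' (sublocations indexed clockwise from top left); each hexagonal grid
#' location covers six triangular fine-lattice sites (indexed clockwise from
#' the upward-pointing triangle at the top of the hexagon). The union over
#' distinct grid locations tiles the fine lattice with no overlaps.
#'
#' @param coords Coordinate tibble.
#' @return A tibble with the coordinate columns, a `sub` sublocation index
#'   (0-based), and a `.site` column indexing the query row.
#' @export
grid_to_lattice <- function(coords) {
  mode <- coord_mode(coords)
  n_sub <- if (mode == "hexagonal") 6L else 4L
  out <- coords[rep(seq_len(nrow(coords)), each = n_sub), , drop = FALSE]
  out$sub <- rep(seq_len(n_sub) - 1L, nrow(coords))
  out$.site <- rep(seq_len(nrow(coords)), each = n_sub)
  tibble::as_tibble(out[, c(".site", setdiff(names(out), ".site"))])
}

# -- axis extents / colony diameter ------------------------------------------

#' Per-axis occupied spans of a colony
#'
#' The diameter along each lattice axis is the number of sites spanned by the
#' occupied set (max - min + 1 in lattice units), evaluated on the supplied
#' set regardless of layer. `d` is the maximum across axes:
#' `max(d_x, d_y)` for rectangular and `max(d_u, d_v, d_w)` for hexagonal
#' colonies.
#'
#' @param occupied Non-empty coordinate tibble of occupied locations.
#' @param spec A [geometry_spec()] (used for its mode).
#' @return A one-row tibble of per-axis spans and their maximum `d`.
#' @examples
#' spec <- geometry_spec("rectangular", "2D", radius = 4)
#' axis_extents(rect_coord(-2:2, 0), spec)
#' @export
axis_extents <- function(occupied, spec) {
  mode <- coord_mode(occupied)
  if (mode != spec$mode) stop("coordinate mode does not match geometry spec",
                              call. = FALSE)
  if (nrow(occupied) == 0L) {
    stop("colony is extinct: cannot measure an empty occupancy set",
         call. = FALSE)
  }
  span <- function(x) diff(range(x)) + 1L
  if (mode == "hexagonal") {
    out <- tibble::tibble(d_u = span(occupied$u), d_v = span(occupied$v),
                          d_w = span(-occupied$u - occupied$v))
    out$d <- max(out$d_u, out$d_v, out$d_w)
  } else {
    out <- tibble::tibble(d_x = span(occupied$x), d_y = span(occupied$y))
    out$d <- max(out$d_x, out$d_y)
  }
  out
}
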