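# Fine (molecular) lattice construction and nutrient diffusion.
#
# Diffusion of glucose, oxygen, and TGFa is solved on the fine lattice: a
# rectangular lattice at half the grid spacing (4 sites per grid location)
# or a triangular lattice (6 sites per hexagon). Each fine site has 4
# (rectangular) or 3 (triangular) in-plane neighbors and, in 3D, 2 vertical
# neighbors in the adjacent layers.
#
# Triangular adjacency: sublocation i of a hexagon (clockwise from the
# upward triangle at the top) shares edges with sublocations i+-1 (mod 6) of
# the same hexagon and with sublocation i+3 (mod 6) of the grid neighbor
# across side i.

.HEX_SIDE_DIRS <- matrix(c(0, 1, 1, 0, 1, -1, 0, -1, -1, 0, -1, 1),
                         ncol = 2, byrow = TRUE) # dir_i, with dir_{i+3} = -dir_i

#' Construct the fine (molecular) lattice for a geometry
#'
#' Precomputes the fine-lattice site table, grid-to-fine index maps,
#' in-plane and vertical adjacency, and the border (source ring) sites.
#' The result is reused by the diffusion operators and the simulation
#' engine.
#'
#' @param spec A [geometry_spec()].
#' @return An object of class `fine_lattice`.
#' @export
fine_lattice <- function(spec) {
  grid_tbl <- domain_coords(spec)
  gm <- coord_matrix(grid_tbl, spec$mode)
  n_grid <- nrow(gm)
  R <- spec$radius
  half <- (spec$layers - 1L) %/% 2L
  n_sub <- if (spec$mode == "hexagonal") 6L else 4L

  # grid lookup array: (a, b, z) -> grid index
  lookup <- array(NA_integer_,
                  dim = c(2L * R + 1L, 2L * R + 1L, spec$layers))
  lookup[cbind(gm[, 1] + R + 1L, gm[, 2] + R + 1L, gm[, 3] + half + 1L)] <-
    seq_len(n_grid)
  gidx <- function(a, b, z) {
    out <- rep(NA_integer_, length(a))
    ok <- abs(a) <= R & abs(b) <= R & abs(z) <= half
    out[ok] <- lookup[cbind(a[ok] + R + 1L, b[ok] + R + 1L, z[ok] + half + 1L)]
    out
  }

  fine_of_grid <- matrix(seq_len(n_grid * n_sub), nrow = n_grid,
                         ncol = n_sub, byrow = TRUE)
  n_fine <- n_grid * n_sub
  grid_of_fine <- rep(seq_len(n_grid), each = n_sub)
  sub_of_fine <- rep(seq_len(n_sub) - 1L, n_grid)

  if (spec$mode == "hexagonal") {
    nb <- matrix(NA_integer_, n_fine, 3L)
    sub <- sub_of_fine
    g <- grid_of_fine
    nb[, 1] <- fine_of_grid[cbind(g, ((sub + 1L) %% 6L) + 1L)]
    nb[, 2] <- fine_of_grid[cbind(g, ((sub - 1L) %% 6L) + 1L)]
    da <- .HEX_SIDE_DIRS[sub + 1L, 1L]
    db <- .HEX_SIDE_DIRS[sub + 1L, 2L]
    g2 <- gidx(gm[g, 1] + da, gm[g, 2] + db, gm[g, 3])
    ok <- !is.na(g2)
    nb[ok, 3] <- fine_of_grid[cbind(g2[ok], ((sub[ok] + 3L) %% 6L) + 1L)]
  } else {
    # fine coordinates: fx = 2a + dx, fy = 2b + dy with sublocations
    # clockwise from top left: 0 -> (0,1), 1 -> (1,1), 2 -> (1,0), 3 -> (0,0)
    dxy <- matrix(c(0L, 1L, 1L, 1L, 1L, 0L, 0L, 0L), ncol = 2, byrow = TRUE)
    fx <- 2L * gm[grid_of_fine, 1] + dxy[sub_of_fine + 1L, 1L]
    fy <- 2L * gm[grid_of_fine, 2] + dxy[sub_of_fine + 1L, 2L]
    fz <- gm[grid_of_fine, 3]
    flook <- array(NA_integer_,
                   dim = c(4L * R + 2L, 4L * R + 2L, spec$layers))
    flook[cbind(fx + 2L * R + 1L, fy + 2L * R + 1L, fz + half + 1L)] <-
      seq_len(n_fine)
    fidx <- function(x, y, z) {
      out <- rep(NA_integer_, length(x))
      ok <- x >= -2L * R & x <= 2L * R + 1L & y >= -2L * R &
        y <= 2L * R + 1L & abs(z) <= half
      out[ok] <- flook[cbind(x[ok] + 2L * R + 1L, y[ok] + 2L * R + 1L,
                             z[ok] + half + 1L)]
      out
    }
    nb <- cbind(fidx(fx + 1L, fy, fz), fidx(fx - 1L, fy, fz),
                fidx(fx, fy + 1L, fz), fidx(fx, fy - 1L, fz))
  }

  # vertical neighbors: same grid (a, b) and sublocation, adjacent layer
  if (spec$layers > 1L) {
    up_g <- gidx(gm[grid_of_fine, 1], gm[grid_of_fine, 2],
                 gm[grid_of_fine, 3] + 1L)
    dn_g <- gidx(gm[grid_of_fine, 1], gm[grid_of_fine, 2],
                 gm[grid_of_fine, 3] - 1L)
    up <- ifelse(is.na(up_g), NA_integer_,
                 fine_of_grid[cbind(up_g, sub_of_fine + 1L)])
    dn <- ifelse(is.na(dn_g), NA_integer_,
                 fine_of_grid[cbind(dn_g, sub_of_fine + 1L)])
  } else {
    up <- dn <- rep(NA_integer_, n_fine)
  }

  # lateral border ring: grid sites with a missing same-layer neighbor
  sl <- if (spec$mode == "hexagonal") .HEX_SL else .RECT_SL
  border_grid <- rep(FALSE, n_grid)
  for (k in seq_len(nrow(sl))) {
    border_grid <- border_grid |
      is.na(gidx(gm[, 1] + sl[k, 1], gm[, 2] + sl[k, 2], gm[, 3]))
  }

  structure(list(
    spec = spec, grid = grid_tbl, grid_matrix = gm,
    n_grid = n_grid, n_fine = n_fine, n_sub = n_sub,
    fine_of_grid = fine_of_grid, grid_of_fine = grid_of_fine,
    sub_of_fine = sub_of_fine,
    neighbors = nb, up = up, down = dn,
    border_grid = which(border_grid),
    border_fine = as.integer(t(fine_of_grid[border_grid, , drop = FALSE])),
    grid_index = gidx,
    cache = new.env(parent = emptyenv())
  ), class = "fine_lattice")
}

#' @export
print.fine_lattice <- function(x, ...) {
  cat(sprintf("<fine_lattice> %s, %d grid sites, %d fine sites\n",
              x$spec$mode, x$n_grid, x$n_fine))
  invisible(x)
}

#' Diffusion parameters
#'
#' @param D Diffusivity (um^2/s).
#' @param dt Diffusion time step (s); 1 s by default.
#' @param ds Spacing between adjacent fine-lattice sites (um); 15 um.
#' @param dz Spacing between layers (um); 8.7 um.
#' @param layers Number of z layers H; the vertical coupling switch `delta`
#'   is 0 when H = 1 and 1 otherwise.
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(D, dt = 1, ds = 15, dz = 8.7, layers = 1L) {
  stopifnot(D >= 0, dt > 0, ds > 0, dz > 0, layers >= 1)
  structure(list(D = D, dt = dt, ds = ds, dz = dz,
                 layers = as.integer(layers),
                 delta = if (layers > 1L) 1 else 0),
            class = "diffusion_params")
}

#' Von Neumann stability parameter
#'
#' `lambda = 4 D dt (1/ds^2 + delta/dz^2)`. The explicit finite-difference
#' scheme is stable when `0 <= lambda < 1`; otherwise the pseudo-steady-state
#' approximation is used.
#'
#' @param p A [diffusion_params()].
#' @return The dimensionless stability parameter.
#' @examples
#' stability_lambda(diffusion_params(D = 500)) # ~8.9: pseudo-steady regime
#' @export
stability_lambda <- function(p) {
  4 * p$D * p$dt * (1 / p$ds^2 + p$delta / p$dz^2)
}

# internal: memoized sparse operators -----------------------------------------

adjacency_weights <- function(lat, w_plane, w_vert) {
  i <- rep(seq_len(lat$n_fine), ncol(lat$neighbors))
  j <- as.vector(lat$neighbors)
  keep <- !is.na(j)
  ii <- i[keep]; jj <- j[keep]; ww <- rep(w_plane, length(ii))
  if (w_vert > 0) {
    for (v in list(lat$up, lat$down)) {
      keep <- !is.na(v)
      ii <- c(ii, which(keep)); jj <- c(jj, v[keep])
      ww <- c(ww, rep(w_vert, sum(keep)))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = ww,
                       dims = c(lat$n_fine, lat$n_fine))
}

operator_key <- function(kind, p) {
  paste(kind, p$D, p$dt, p$ds, p$dz, p$delta, sep = "|")
}

fd_operator <- function(lat, p) {
  key <- operator_key("fd", p)
  if (!is.null(lat$cache[[key]])) return(lat$cache[[key]])
  w_plane <- if (lat$spec$mode == "hexagonal") {
    4 * p$D * p$dt / (3 * p$ds^2)
  } else {
    p$D * p$dt / p$ds^2
  }
  w_vert <- p$delta * 2 * p$D * p$dt / p$dz^2
  W <- adjacency_weights(lat, w_plane, w_vert)
  L <- W - Matrix::Diagonal(x = Matrix::rowSums(W))
  lat$cache[[key]] <- L
  L
}

ps_operator <- function(lat, p) {
  key <- operator_key("ps", p)
  if (!is.null(lat$cache[[key]])) return(lat$cache[[key]])
  w_vert <- if (lat$spec$mode == "hexagonal") {
    p$delta * 3 * p$ds^2 / (2 * p$dz^2)
  } else {
    p$delta * 2 * p$ds^2 / p$dz^2
  }
  W <- adjacency_weights(lat, 1, w_vert)
  M <- Matrix::Diagonal(x = 1 / Matrix::rowSums(W)) %*% W
  lat$cache[[key]] <- M
  M
}

# -- molecule fields ----------------------------------------------------------

#' Create a molecule concentration field
#'
#' @param lattice A [fine_lattice()].
#' @param molecule Molecule name (e.g. `"glucose"`).
#' @param values Initial concentration, a scalar or a vector with one entry
#'   per fine-lattice site (fmol/um^3). Concentrations must be non-negative.
#' @return An object of class `molecule_field`.
#' @export
molecule_field <- function(lattice, molecule = "glucose", values = 0) {
  if (length(values) == 1L) values <- rep(as.numeric(values), lattice$n_fine)
  stopifnot(length(values) == lattice$n_fine, all(values >= 0))
  structure(list(lattice = lattice, molecule = molecule,
                 values = as.numeric(values)),
            class = "molecule_field")
}

#' @export
print.molecule_field <- function(x, ...) {
  cat(sprintf("<molecule_field> %s on %d fine sites; mean %.4g fmol/um^3\n",
              x$molecule, length(x$values), mean(x$values)))
  invisible(x)
}

#' Tidy a molecule field
#'
#' @param x A `molecule_field`.
#' @param ... Unused.
#' @return A tibble with the grid coordinates, sublocation index, and
#'   concentration of every fine-lattice site.
#' @export
tidy.molecule_field <- function(x, ...) {
  lat <- x$lattice
  out <- lat$grid[lat$grid_of_fine, , drop = FALSE]
  out$sub <- lat$sub_of_fine
  out$molecule <- x$molecule
  out$concentration <- x$values
  tibble::as_tibble(out)
}

#' One explicit finite-difference diffusion step
#'
#' Applies the explicit scheme on the fine lattice: in-plane neighbor sums
#' with coefficient `D dt / ds^2` (rectangular, 4 neighbors) or
#' `4 D dt / (3 ds^2)` (triangular, 3 neighbors) and, when `delta = 1`, a
#' vertical term with coefficient `2 D dt / dz^2` over the two adjacent
#' layers. Domain borders are zero-flux (missing neighbors drop out of the
#' sum), so total mass is conserved. Refuses to run when the scheme is
#' unstable (`lambda >= 1`); use [pseudo_steady_step()] there.
#'
#' @param field A [molecule_field()].
#' @param p A [diffusion_params()] consistent with the field's lattice.
#' @return The updated `molecule_field`.
#' @export
finite_difference_step <- function(field, p) {
  lam <- stability_lambda(p)
  if (lam >= 1) {
    stop(sprintf(paste0("finite-difference scheme is unstable here ",
                        "(lambda = %.3g >= 1); use pseudo_steady_step()"),
                 lam), call. = FALSE)
  }
  check_params_lattice(field$lattice, p)
  L <- fd_operator(field$lattice, p)
  field$values <- as.numeric(field$values + L %*% field$values)
  field
}

#' One pseudo-steady-state relaxation sweep
#'
#' Replaces each fine-lattice concentration by the weighted average of its
#' neighbors: in-plane weight 1 per neighbor with vertical weights
#' `2 ds^2 / dz^2` (rectangular) or `3 ds^2 / (2 dz^2)` (triangular) per
#' vertical neighbor, normalized by the total weight (at borders, by the
#' weight of the neighbors actually present, so a uniform field is a fixed
#' point everywhere). Valid as the stable fallback for any `lambda`.
#'
#' @inheritParams finite_difference_step
#' @return The updated `molecule_field`.
#' @export
pseudo_steady_step <- function(field, p) {
  check_params_lattice(field$lattice, p)
  M <- ps_operator(field$lattice, p)
  field$values <- as.numeric(M %*% field$values)
  field
}

check_params_lattice <- function(lat, p) {
  if ((p$delta == 1) != (lat$spec$layers > 1L)) {
    stop("diffusion params delta/layers inconsistent with lattice geometry",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Diffuse with automatic solver selection
#'
#' Computes [stability_lambda()] once and applies either the explicit
#' finite-difference scheme (`lambda < 1`) or `sweeps` pseudo-steady
#' relaxation sweeps.
#'
#' @inheritParams finite_difference_step
#' @param sweeps Number of pseudo-steady sweeps when that branch is taken.
#' @return The updated `molecule_field`.
#' @export
diffuse <- function(field, p, sweeps = 50L) {
  if (stability_lambda(p) < 1) return(finite_difference_step(field, p))
  for (k in seq_len(sweeps)) field <- pseudo_steady_step(field, p)
  field
}

#' Apply a generator component
#'
#' Adds the per-site generation array `G` (amount per generator tick) to the
#' field. Any concentration driven negative by a negative `G` (consumption
#' bookkeeping) is clamped to zero.
#'
#' @param field A [molecule_field()].
#' @param G Scalar or per-fine-site generation array.
#' @param sites Optional integer vector of fine sites to which `G` applies
#'   (default: all sites).
#' @return The updated `molecule_field`.
#' @export
apply_generator <- function(field, G, sites = NULL) {
  if (is.null(sites)) {
    field$values <- field$values + G
  } else {
    field$values[sites] <- field$values[sites] + G
  }
  field$values[field$values < 0] <- 0
  field
}

# -- source profiles ----------------------------------------------------------

#' Pulse-source concentration
#'
#' Media-change dynamics: the source concentration is reset to `c0` whenever
#' `t mod interval = 0` and otherwise tracks depletion of the media,
#' `(N - n) / volume`, where `N` is the molecule total before this tick and
#' `n` the amount consumed during it.
#'
#' @param t Time in days.
#' @param c0 Initial (reset) concentration.
#' @param interval Pulsing interval t* in days.
#' @param n_total Molecule total N before the current tick.
#' @param n_consumed Amount consumed during the current tick.
#' @param volume Media volume V.
#' @return The source concentration at `t`.
#' @export
pulse_concentration <- function(t, c0, interval, n_total = c0 * volume,
                                n_consumed = 0, volume) {
  stopifnot(t >= 0, volume > 0, interval > 0)
  phase <- t %% interval
  on_pulse <- phase < 1e-9 | interval - phase < 1e-9
  ifelse(on_pulse, c0, pmax(0, (n_total - n_consumed) / volume))
}

#' Cyclic-source concentration
#'
#' A smoothed sawtooth with three peaks per day:
#' `C(t) = c0 * (tanh((3t - floor(3t) - 0.5) * sigma) / (2 tanh(0.5 sigma))
#'   + floor(3t) + 1.5 - 3t)`.
#' The profile is periodic with period 1/3 day, equals `c0` exactly at
#' `t = 0` and at the midpoint of each period, and has daily mean `c0`.
#'
#' @param t Time in days.
#' @param c0 Initial concentration.
#' @param sigma Smoothing factor (default 15).
#' @return The source concentration at `t`.
#' @export
cycle_concentration <- function(t, c0, sigma = 15) {
  stopifnot(all(t >= 0), sigma > 0)
  f3 <- floor(3 * t)
  c0 * (tanh((3 * t - f3 - 0.5) * sigma) / (2 * tanh(0.5 * sigma)) +
          f3 + 1.5 - 3 * t)
}
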