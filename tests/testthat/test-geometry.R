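coord_key <- function(coords) {
  m <- latticetumor:::coord_matrix(coords)
  paste(m[, 1], m[, 2], m[, 3])
}

test_that("same-layer neighbor sets match the documented offset tables", {
  hex <- geometry_spec("hexagonal", "2D", radius = 4)
  nb <- grid_neighbors(hex_coord(0, 0), hex)
  expect_setequal(
    coord_key(nb),
    coord_key(hex_coord(c(0, 0, -1, 1, -1, 1), c(1, -1, 1, -1, 0, 0))))

  rect <- geometry_spec("rectangular", "2D", radius = 4)
  nb <- grid_neighbors(rect_coord(0, 0), rect)
  expect_setequal(
    coord_key(nb),
    coord_key(rect_coord(c(1, -1, 0, 0), c(0, 0, 1, -1))))
})

test_that("3D vertical neighbors follow the layer offset classes", {
  rect <- geometry_spec("rectangular", "3D", radius = 4, layers = 3)
  nb <- grid_neighbors(rect_coord(0, 0, 0), rect)
  expect_equal(nrow(nb), 12)
  above <- nb[nb$z == 1, ]
  expect_setequal(
    coord_key(above),
    coord_key(rect_coord(c(0, -1, 0, -1), c(0, 0, -1, -1), 1)))
  # offset layer (z = 1) picks the second bracket entries
  above1 <- grid_neighbors(rect_coord(0, 0, 1), rect)
  expect_setequal(
    coord_key(above1[above1$z == 2, ]),
    character(0)) # z = 2 is outside an H = 3 domain
  below1 <- above1[above1$z == 0, ]
  expect_setequal(
    coord_key(below1),
    coord_key(rect_coord(c(0, 1, 0, 1), c(0, 0, 1, 1), 0)))

  hex <- geometry_spec("hexagonal", "3D", radius = 4, layers = 3)
  nbh <- grid_neighbors(hex_coord(0, 0, z = 0), hex)
  expect_equal(nrow(nbh), 14)
  expect_equal(sum(nbh$z == 1), 4)
  expect_equal(sum(nbh$z == -1), 4)
  expect_true(all(nbh$u + nbh$v + nbh$w == 0))
})

test_that("neighbor relation is reciprocal over a radius-4, H=5 domain", {
  for (mode in c("hexagonal", "rectangular")) {
    spec <- geometry_spec(mode, "3D", radius = 4, layers = 5)
    dom <- domain_coords(spec)
    keys <- coord_key(dom)
    nb <- grid_neighbors(dom, spec)
    nb_keys <- split(coord_key(nb), nb$.site)
    adj <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(dom))) assign(keys[i], nb_keys[[as.character(i)]],
                                         envir = adj)
    for (i in seq_len(nrow(dom))) {
      for (k in nb_keys[[as.character(i)]]) {
        expect_true(keys[i] %in% get(k, envir = adj),
                    label = sprintf("%s reciprocal of %s (%s)", keys[i], k,
                                    mode))
      }
    }
    # interior neighbor counts: 6 + 4 + 4 (hex), 4 + 4 + 4 (rect)
    origin <- which(keys == "0 0 0")
    expect_equal(length(nb_keys[[as.character(origin)]]),
                 if (mode == "hexagonal") 14L else 12L)
  }
})

test_that("neighbor queries reject mode mismatches and invalid coordinates", {
  hex <- geometry_spec("hexagonal", "2D", radius = 4)
  expect_error(grid_neighbors(rect_coord(0, 0), hex), "mode")
  expect_error(hex_coord(1, 1, w = 1), "u \\+ v \\+ w")
  bad <- tibble::tibble(u = 1L, v = 1L, w = 1L, z = 0L)
  expect_error(grid_neighbors(bad, hex), "u \\+ v \\+ w")
})

test_that("symmetry partners match the documented templates", {
  p <- symmetry_partners(hex_coord(1, -1))
  expect_setequal(coord_key(p),
                  coord_key(hex_coord(c(0, -1, -1, 0, 1),
                                      c(-1, 0, 1, 1, 0))))
  p <- symmetry_partners(rect_coord(1, 2))
  expect_setequal(coord_key(p),
                  coord_key(rect_coord(c(-2, -1, 2), c(1, -2, -1))))
  # origin is a fixed point of every template
  p <- symmetry_partners(rect_coord(0, 0))
  expect_equal(coord_key(p), "0 0 0")
  # axis/diagonal rectangular locations get seven-partner treatment
  expect_equal(symmetry_partner_count(rect_coord(c(0, 3, 2, 1), c(5, 0, 2, 2))),
               c(7L, 7L, 7L, 3L))
  expect_equal(symmetry_partner_count(hex_coord(2, -1)), 5L)
})

test_that("symmetry partner orbits are closed", {
  for (mode in c("hexagonal", "rectangular")) {
    for (a in -5:5) for (b in -5:5) {
      c0 <- if (mode == "hexagonal") hex_coord(a, b) else rect_coord(a, b)
      orbit <- coord_key(symmetry_partners(c0))
      closure <- union(orbit, coord_key(c0))
      p <- symmetry_partners(c0)
      for (i in seq_len(nrow(p))) {
        p2 <- symmetry_partners(p[i, setdiff(names(p), ".site")])
        expect_true(all(coord_key(p2) %in% closure),
                    label = sprintf("orbit closure at (%d,%d) %s", a, b, mode))
      }
    }
  }
})

test_that("grid locations tile the fine lattice without overlap", {
  hex <- geometry_spec("hexagonal", "2D", radius = 3)
  sites <- grid_to_lattice(domain_coords(hex))
  expect_equal(nrow(sites), 6 * nrow(domain_coords(hex)))
  expect_equal(anyDuplicated(paste(sites$u, sites$v, sites$z, sites$sub)), 0L)

  rect <- geometry_spec("rectangular", "2D", radius = 3)
  dom <- domain_coords(rect)
  sites <- grid_to_lattice(dom)
  expect_equal(nrow(sites), 4 * nrow(dom))
  # explicit fine coordinates from the clockwise-from-top-left convention
  dxy <- rbind(c(0, 1), c(1, 1), c(1, 0), c(0, 0))
  fx <- 2 * sites$x + dxy[sites$sub + 1, 1]
  fy <- 2 * sites$y + dxy[sites$sub + 1, 2]
  expect_equal(anyDuplicated(paste(fx, fy, sites$z)), 0L)
  expect_equal(nrow(grid_to_lattice(hex_coord(2, -1))), 6)
  expect_equal(nrow(grid_to_lattice(rect_coord(2, 1))), 4)
})

test_that("axis extents report per-axis spans and their maximum", {
  rect <- geometry_spec("rectangular", "2D", radius = 4)
  expect_equal(axis_extents(rect_coord(0, 0), rect)$d, 1)
  e <- axis_extents(rect_coord(-2:2, 0), rect)
  expect_equal(e$d_x, 5)
  expect_equal(e$d_y, 1)
  expect_equal(e$d, 5)

  hex <- geometry_spec("hexagonal", "2D", radius = 4)
  flower <- dplyr::bind_rows(
    hex_coord(0, 0),
    grid_neighbors(hex_coord(0, 0), hex)[, c("u", "v", "w", "z")])
  e <- axis_extents(flower, hex)
  expect_equal(e$d_u, e$d_v)
  expect_equal(e$d_v, e$d_w)
  expect_equal(e$d, 3)
  expect_error(axis_extents(rect_coord(integer(0), integer(0)), rect),
               "extinct")
})

test_that("domain membership matches each geometry's natural ball", {
  hex <- geometry_spec("hexagonal", "2D", radius = 2)
  expect_equal(nrow(domain_coords(hex)), 3 * 4 + 3 * 2 + 1)
  expect_true(in_domain(hex_coord(2, 0), hex))
  expect_false(in_domain(hex_coord(2, 1), hex))
  rect <- geometry_spec("rectangular", "2D", radius = 2)
  expect_equal(nrow(domain_coords(rect)), 25)
  expect_true(in_domain(rect_coord(2, 2), rect))
})
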