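# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately re-derive everything from the documented
# conventions (coordinates, stencil weights, textbook ANOVA formulas)
# rather than reusing the package's adjacency structures.

# ---- dense finite-difference oracle (rectangular fine lattice) -------------
# Reconstructs fine-site coordinates from the grid table and the documented
# sublocation convention, then applies the explicit stencil with a plain
# double loop over coordinate lookups.
oracle_fd_rect <- function(lat, values, p) {
  g <- lat$grid_matrix[lat$grid_of_fine, , drop = FALSE]
  sub <- lat$sub_of_fine
  dxy <- rbind(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(0L, 0L))
  fx <- 2L * g[, 1] + dxy[sub + 1L, 1L]
  fy <- 2L * g[, 2] + dxy[sub + 1L, 2L]
  fz <- g[, 3]
  key <- paste(fx, fy, fz)
  idx <- new.env(parent = emptyenv())
  for (i in seq_along(key)) assign(key[i], i, envir = idx)
  get_i <- function(x, y, z) {
    k <- paste(x, y, z)
    if (exists(k, envir = idx, inherits = FALSE)) get(k, envir = idx) else NA
  }
  wp <- p$D * p$dt / p$ds^2
  wv <- p$delta * 2 * p$D * p$dt / p$dz^2
  out <- values
  for (i in seq_along(values)) {
    acc <- 0
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      j <- get_i(fx[i] + d[1], fy[i] + d[2], fz[i])
      if (!is.na(j)) acc <- acc + wp * (values[j] - values[i])
    }
    if (wv > 0) {
      for (dz in c(-1, 1)) {
        j <- get_i(fx[i], fy[i], fz[i] + dz)
        if (!is.na(j)) acc <- acc + wv * (values[j] - values[i])
      }
    }
    out[i] <- values[i] + acc
  }
  out
}

# ---- dense finite-difference oracle (triangular fine lattice) --------------
# Re-derives triangular adjacency from the (hexagon, sublocation) identity:
# triangles i +- 1 of the same hexagon, triangle i + 3 of the neighbor
# across side i, and the stacked triangle in adjacent layers.
oracle_fd_hex <- function(lat, values, p) {
  g <- lat$grid_matrix[lat$grid_of_fine, , drop = FALSE]
  sub <- lat$sub_of_fine
  dirs <- rbind(c(0, 1), c(1, 0), c(1, -1), c(0, -1), c(-1, 0), c(-1, 1))
  key <- paste(g[, 1], g[, 2], g[, 3], sub)
  idx <- new.env(parent = emptyenv())
  for (i in seq_along(key)) assign(key[i], i, envir = idx)
  get_i <- function(u, v, z, s) {
    k <- paste(u, v, z, s)
    if (exists(k, envir = idx, inherits = FALSE)) get(k, envir = idx) else NA
  }
  wp <- 4 * p$D * p$dt / (3 * p$ds^2)
  wv <- p$delta * 2 * p$D * p$dt / p$dz^2
  out <- values
  for (i in seq_along(values)) {
    s <- sub[i]
    js <- c(get_i(g[i, 1], g[i, 2], g[i, 3], (s + 1) %% 6),
            get_i(g[i, 1], g[i, 2], g[i, 3], (s - 1) %% 6),
            get_i(g[i, 1] + dirs[s + 1, 1], g[i, 2] + dirs[s + 1, 2],
                  g[i, 3], (s + 3) %% 6))
    acc <- 0
    for (j in js) if (!is.na(j)) acc <- acc + wp * (values[j] - values[i])
    if (wv > 0) {
      for (dz in c(-1, 1)) {
        j <- get_i(g[i, 1], g[i, 2], g[i, 3] + dz, s)
        if (!is.na(j)) acc <- acc + wv * (values[j] - values[i])
      }
    }
    out[i] <- values[i] + acc
  }
  out
}

# ---- whole-set symmetry oracle ---------------------------------------------
# Applies each symmetry template to the full occupancy set at once and
# counts, per location, the unique template images that are unoccupied.
oracle_symmetry <- function(occupied) {
  mode <- if ("u" %in% names(occupied)) "hexagonal" else "rectangular"
  if (mode == "hexagonal") {
    ab <- unique(cbind(occupied$u, occupied$v))
  } else {
    ab <- unique(cbind(occupied$x, occupied$y))
  }
  occ_key <- paste(ab[, 1], ab[, 2])
  n <- nrow(ab)
  fracs <- numeric(n)
  for (i in seq_len(n)) {
    if (mode == "hexagonal") {
      u <- ab[i, 1]; v <- ab[i, 2]; w <- -u - v
      imgs <- rbind(c(-w, -u), c(v, w), c(-u, -v), c(w, u), c(-v, -w))
      lam <- 5
    } else {
      x <- ab[i, 1]; y <- ab[i, 2]
      imgs <- rbind(c(-y, x), c(-x, -y), c(y, -x))
      special <- x == 0 || y == 0 || x == y
      if (special) imgs <- rbind(imgs, c(x, -y), c(y, x), c(-x, y), c(-y, -x))
      lam <- if (special) 7 else 3
    }
    imgs <- unique(imgs)
    miss <- sum(!(paste(imgs[, 1], imgs[, 2]) %in% occ_key))
    fracs[i] <- miss / lam
  }
  1 - mean(fracs)
}

# random colony occupancy within radius R (unique locations, origin seeded)
rand_colony <- function(mode, n, R = 6) {
  if (mode == "hexagonal") {
    u <- sample(-R:R, 3 * n, replace = TRUE)
    v <- sample(-R:R, 3 * n, replace = TRUE)
    ok <- pmax(abs(u), abs(v), abs(u + v)) <= R
    d <- unique(cbind(u[ok], v[ok]))
    d <- d[seq_len(min(n, nrow(d))), , drop = FALSE]
    hex_coord(c(0L, d[, 1]), c(0L, d[, 2]))
  } else {
    x <- sample(-R:R, 3 * n, replace = TRUE)
    y <- sample(-R:R, 3 * n, replace = TRUE)
    d <- unique(cbind(x, y))
    d <- d[seq_len(min(n, nrow(d))), , drop = FALSE]
    rect_coord(c(0L, d[, 1]), c(0L, d[, 2]))
  }
}

# ---- textbook balanced two-way ANOVA oracle --------------------------------
oracle_anova2 <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  a <- nlevels(A); b <- nlevels(B)
  n <- length(y) / (a * b)
  gm <- mean(y)
  am <- tapply(y, A, mean); bm <- tapply(y, B, mean)
  cm <- tapply(y, list(A, B), mean)
  ss_a <- n * b * sum((am - gm)^2)
  ss_b <- n * a * sum((bm - gm)^2)
  ss_ab <- n * sum((cm - outer(am, rep(1, b)) -
                      outer(rep(1, a), bm) + gm)^2)
  ss_t <- sum((y - gm)^2)
  ss_e <- ss_t - ss_a - ss_b - ss_ab
  df <- c(a - 1, b - 1, (a - 1) * (b - 1), a * b * (n - 1))
  ss <- c(ss_a, ss_b, ss_ab, ss_e)
  ms <- ss / df
  f <- c(ms[1:3] / ms[4], NA)
  p <- c(stats::pf(f[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
  list(sumsq = ss, df = df, statistic = f, p.value = p, ss_total = ss_t)
}

# ---- studentized-range (Tukey HSD) oracle ----------------------------------
oracle_tukey <- function(y, f) {
  f <- factor(f)
  k <- nlevels(f)
  ns <- tapply(y, f, length)
  ms <- tapply(y, f, mean)
  df_e <- length(y) - k
  mse <- sum(tapply(y, f, function(v) sum((v - mean(v))^2))) / df_e
  pairs <- utils::combn(levels(f), 2)
  out <- data.frame(contrast = paste(pairs[2, ], pairs[1, ], sep = "-"))
  out$estimate <- as.numeric(ms[pairs[2, ]] - ms[pairs[1, ]])
  se <- as.numeric(sqrt(mse / 2 * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]])))
  out$adj.p.value <- as.numeric(stats::ptukey(abs(out$estimate) / se, k,
                                              df_e, lower.tail = FALSE))
  out
}
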