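# Simulation engine: binds the lattice geometry, the nutrient environment,
# and the cell population into a tick-by-tick scheduler, and provides the
# factorial experiment presets (system representation, cell variability,
# nutrient dynamics).
#
# Clocking: agent tick 60 min; the nutrient field is relaxed to its
# pseudo-steady profile once per agent tick (the pseudo-steady operator is
# memoryless, so its fixed point does not depend on sweep cadence); source
# concentrations follow the configured profile evaluated at the tick time.

.ST <- c(undecided = 1L, quiescent = 2L, migratory = 3L, proliferative = 4L,
         apoptotic = 5L, necrotic = 6L, senescent = 7L)

#' Environment (nutrient) parameters
#'
#' Diffusivities, basal source concentrations, nutrient level multipliers,
#' and source-profile settings. Defaults are standard literature-range
#' values; low/basal/high glucose levels are 0.5x/1x/2x multipliers on the
#' basal source concentration.
#'
#' @param glucose_D,oxygen_D,tgfa_D Diffusivities (um^2/s).
#' @param glucose_basal,oxygen_basal Basal source concentrations
#'   (fmol/um^3); 0.005 fmol/um^3 of glucose corresponds to 5 mM.
#' @param level_multipliers Named multipliers for the low/basal/high glucose
#'   levels.
#' @param pulse_interval Pulse (media change) interval t* in days.
#' @param media_volume Pulse media volume V (um^3); defaults to the domain
#'   fine-lattice volume.
#' @param cycle_sigma Smoothing factor of the cyclic profile.
#' @param sweeps Pseudo-steady relaxation sweeps per agent tick.
#' @param ds,dz Fine-lattice site and layer spacing (um).
#' @return A list of class `env_params`.
#' @export
env_params <- function(glucose_D = 500, oxygen_D = 2000, tgfa_D = 100,
                       glucose_basal = 0.005, oxygen_basal = 0.005,
                       level_multipliers = c(low = 0.5, basal = 1, high = 2),
                       pulse_interval = 2, media_volume = NULL,
                       cycle_sigma = 15, sweeps = 50L, ds = 15, dz = 8.7) {
  structure(as.list(environment()), class = "env_params")
}

#' Simulation configuration
#'
#' Bundles every choice a run depends on: system representation (geometry
#' and dimension), context, nutrient profile and level, initial
#' cell-to-cell variability, duration, domain size, and seed.
#'
#' @param geometry `"hexagonal"` or `"rectangular"`.
#' @param dimension `"2D"` or `"3D"`.
#' @param context `"colony"` or `"tissue"`.
#' @param profile Glucose source profile: `"constant"`, `"pulse"`, or
#'   `"cyclic"`.
#' @param level Glucose level: `"low"`, `"basal"`, or `"high"`.
#' @param volume_mode,age_mode Initial variability modes (see
#'   [population_init()]).
#' @param days Simulated duration in days.
#' @param radius Domain radius (lattice units).
#' @param layers Layer count H (odd; 1 for 2D). Default 7 for 3D.
#' @param seed Integer seed; every stochastic draw of the run comes from
#'   this stream.
#' @param sample_hours Metric recording cadence (hours).
#' @param cells A [cell_params()].
#' @param env An [env_params()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(geometry = c("hexagonal", "rectangular"),
                       dimension = c("2D", "3D"),
                       context = c("colony", "tissue"),
                       profile = c("constant", "pulse", "cyclic"),
                       level = c("basal", "low", "high"),
                       volume_mode = c("normal", "constant"),
                       age_mode = c("uniform", "zero"),
                       days = 14, radius = 20, layers = NULL, seed = 1,
                       sample_hours = 12,
                       cells = cell_params(), env = env_params()) {
  geometry <- match.arg(geometry)
  dimension <- match.arg(dimension)
  spec <- geometry_spec(geometry, dimension, radius = radius, layers = layers)
  structure(list(
    spec = spec, context = match.arg(context),
    profile = match.arg(profile), level = match.arg(level),
    init = population_init(match.arg(volume_mode), match.arg(age_mode),
                           match.arg(context)),
    days = days, seed = as.integer(seed),
    sample_hours = sample_hours, cells = cells, env = env
  ), class = "sim_config")
}

# neighbor grid-index list (same layer + vertical classes in 3D)
grid_neighbor_list <- function(lat) {
  spec <- lat$spec
  gm <- lat$grid_matrix
  lapply(seq_len(lat$n_grid), function(g) {
    off <- neighbor_offsets(spec$mode, gm[g, 3], spec$layers)
    idx <- lat$grid_index(gm[g, 1] + off[, 1], gm[g, 2] + off[, 2],
                          gm[g, 3] + off[, 3])
    idx[!is.na(idx)]
  })
}

# internal fast symmetry on a unique (a, b) occupancy matrix
symmetry_ab <- function(ab, mode) {
  n <- nrow(ab)
  if (n == 0L) return(NA_real_)
  occ_key <- paste(ab[, 1], ab[, 2])
  frac <- numeric(n)
  for (i in seq_len(n)) {
    p <- partner_matrix(ab[i, 1], ab[i, 2], mode)
    lam <- if (mode == "hexagonal") 5L else {
      if (ab[i, 1] == 0L || ab[i, 2] == 0L || ab[i, 1] == ab[i, 2]) 7L else 3L
    }
    n_i <- sum(!(paste(p[, 1], p[, 2]) %in% occ_key))
    frac[i] <- n_i / lam
  }
  1 - mean(frac)
}

#' Run one simulation
#'
#' Advances the simulation tick by tick for the configured duration,
#' recording the emergent-behavior inputs (colony diameter, symmetry, mean
#' cell cycle length, population counts) at the configured cadence. A run
#' whose cancer population dies out terminates early with status
#' `"failed"` (failed to form a tumor).
#'
#' @param config A [sim_config()].
#' @return An object of class `tumor_sim` with elements `metrics` (a tibble
#'   of the recorded series), `cells` (final cell roster tibble), `config`,
#'   and `status`.
#' @export
run_simulation <- function(config) {
  set.seed(config$seed)
  spec <- config$spec
  prm <- config$cells
  ep <- config$env
  lat <- fine_lattice(spec)
  nb <- grid_neighbor_list(lat)
  n_grid <- lat$n_grid
  n_sub <- lat$n_sub
  gm_z <- lat$grid_matrix[, 3]
  gm_ab <- lat$grid_matrix[, 1:2, drop = FALSE]

  v_fine <- ep$ds^2 * ep$dz           # nominal fine-site volume (um^3)
  v_loc <- n_sub * v_fine
  mult <- ep$level_multipliers[[config$level]]
  glu_c0 <- ep$glucose_basal * mult
  oxy_c0 <- ep$oxygen_basal
  media_V <- ep$media_volume %||% (lat$n_fine * v_fine)
  pulse_N <- glu_c0 * media_V

  p_ps <- diffusion_params(D = ep$glucose_D, ds = ep$ds, dz = ep$dz,
                           layers = spec$layers)
  M <- ps_operator(lat, p_ps)
  B <- lat$border_fine

  # fields: columns glucose, oxygen, tgfa
  X <- cbind(rep(glu_c0, lat$n_fine), rep(oxy_c0, lat$n_fine),
             rep(0, lat$n_fine))

  # --- cell roster (indexed vectors, grown on demand) -----------------------
  cap <- max(64L, 4L * n_grid)
  roster0 <- initialize_population(spec, config$init, prm)
  n0 <- nrow(roster0)
  cap <- max(cap, 2L * n0)
  pop <- integer(cap); state <- integer(cap); loc <- integer(cap)
  vol <- numeric(cap); age <- numeric(cap); vcrit <- numeric(cap)
  meta <- numeric(cap); migra <- numeric(cap); crowd <- numeric(cap)
  starv <- numeric(cap); pentry <- rep(NA_real_, cap)
  cycsum <- numeric(cap); cycn <- integer(cap); ndiv <- integer(cap)
  parent <- rep(NA_integer_, cap); alive <- logical(cap)

  m0 <- coord_matrix(roster0, spec$mode)
  loc0 <- lat$grid_index(m0[, 1], m0[, 2], m0[, 3])
  is_cancer0 <- roster0$population == "cancerous"
  idx0 <- seq_len(n0)
  pop[idx0] <- ifelse(is_cancer0, 1L, 2L)
  state[idx0] <- .ST[["undecided"]]
  loc[idx0] <- loc0
  vol[idx0] <- roster0$volume
  age[idx0] <- roster0$age
  vcrit[idx0] <- roster0$v_crit
  meta[idx0] <- ifelse(is_cancer0, prm$meta_pref * prm$cancer_meta_pref,
                       prm$meta_pref)
  migra[idx0] <- ifelse(is_cancer0,
                        prm$migra_threshold * prm$cancer_migra_threshold,
                        prm$migra_threshold)
  crowd[idx0] <- ifelse(is_cancer0,
                        prm$max_height * prm$cancer_max_height,
                        prm$max_height) * 2 * prm$v_crit
  alive[idx0] <- TRUE
  n_cells <- n0
  site_vol <- numeric(n_grid)
  for (i in idx0) site_vol[loc[i]] <- site_vol[loc[i]] + vol[i]

  grow_cap <- function() {
    newcap <- 2L * cap
    length(pop) <<- newcap; length(state) <<- newcap
    length(loc) <<- newcap; length(vol) <<- newcap; length(age) <<- newcap
    length(vcrit) <<- newcap; length(meta) <<- newcap
    length(migra) <<- newcap; length(crowd) <<- newcap
    length(starv) <<- newcap
    pentry <<- c(pentry, rep(NA_real_, newcap - cap))
    length(cycsum) <<- newcap; length(cycn) <<- newcap
    length(ndiv) <<- newcap
    parent <<- c(parent, rep(NA_integer_, newcap - cap))
    alive <<- c(alive, rep(FALSE, newcap - cap))
    cap <<- newcap
  }

  # --- metric recording -----------------------------------------------------
  records <- list()
  record <- function(t_min) {
    ci <- which(alive[seq_len(n_cells)] & pop[seq_len(n_cells)] == 1L)
    if (length(ci) == 0L) return(invisible(NULL))
    gl <- loc[ci]
    zs <- gm_z[gl]
    d_slice <- s_slice <- rep(NA_real_, spec$layers)
    half <- (spec$layers - 1L) %/% 2L
    for (k in seq_len(spec$layers)) {
      zk <- k - 1L - half
      sel <- which(zs == zk)
      if (length(sel) == 0L) next
      ab <- unique(gm_ab[gl[sel], , drop = FALSE])
      d_slice[k] <- max(diff(range(ab[, 1])) + 1L, diff(range(ab[, 2])) + 1L,
                        if (spec$mode == "hexagonal")
                          diff(range(-ab[, 1] - ab[, 2])) + 1L else -Inf)
      s_slice[k] <- symmetry_ab(ab, spec$mode)
    }
    kc <- half + 1L
    cyc_mean <- function(sel) {
      has <- sel[cycn[sel] > 0L]
      if (length(has) == 0L) return(NA_real_)
      mean(cycsum[has] / cycn[has])
    }
    live_states <- state[ci]
    records[[length(records) + 1L]] <<- list(
      t = t_min / 1440,
      n_cancer = length(ci),
      n_healthy = sum(alive[seq_len(n_cells)] & pop[seq_len(n_cells)] == 2L),
      n_proliferative = sum(live_states == .ST[["proliferative"]]),
      n_quiescent = sum(live_states == .ST[["quiescent"]]),
      n_migratory = sum(live_states == .ST[["migratory"]]),
      n_necrotic = sum(live_states == .ST[["necrotic"]]),
      diameter = max(d_slice, na.rm = TRUE),
      diameter_center = d_slice[kc],
      symmetry = mean(s_slice, na.rm = TRUE),
      symmetry_center = s_slice[kc],
      cycle_length = cyc_mean(ci),
      cycle_length_center = cyc_mean(ci[zs == 0L]),
      glucose_center = mean(X[lat$fine_of_grid[
        lat$grid_index(0L, 0L, 0L), ], 1])
    )
    invisible(NULL)
  }

  n_ticks <- round(config$days * 24)
  sample_every <- round(config$sample_hours)
  record(0)
  status <- "completed"
  consumed_prev <- 0
  L_life <- prm$lifespan
  glu_starve <- prm$starvation_level * ep$glucose_basal
  ST_UND <- .ST[["undecided"]]; ST_QUI <- .ST[["quiescent"]]
  ST_MIG <- .ST[["migratory"]]; ST_PRO <- .ST[["proliferative"]]
  ST_APO <- .ST[["apoptotic"]]; ST_NEC <- .ST[["necrotic"]]
  ST_SEN <- .ST[["senescent"]]

  for (tick in seq_len(n_ticks)) {
    t_min <- tick * 60
    t_day <- tick / 24

    # source concentrations for this tick
    src_glu <- switch(config$profile,
      constant = glu_c0,
      pulse = {
        if ((t_day %% ep$pulse_interval) < 1e-9) {
          pulse_N <- glu_c0 * media_V
        } else {
          pulse_N <- max(0, pulse_N - consumed_prev)
        }
        pulse_N / media_V
      },
      cyclic = cycle_concentration(t_day, glu_c0, ep$cycle_sigma))

    # relax fields to pseudo-steady profile with Dirichlet border
    src <- c(src_glu, oxy_c0, 0)
    X[B, ] <- rep(src, each = length(B))
    for (s in seq_len(ep$sweeps)) {
      X <- as.matrix(M %*% X)
      X[B, ] <- rep(src, each = length(B))
    }

    # step cells in seeded-shuffled order
    live <- which(alive[seq_len(n_cells)])
    ord <- live[sample.int(length(live))]
    consumed_tick <- 0
    for (i in ord) {
      if (!alive[i]) next
      sti <- state[i]
      if (sti == ST_NEC) next
      age[i] <- age[i] + 60
      # lifespan / apoptosis hazard
      kill <- age[i] >= L_life
      if (!kill && age[i] > L_life / 2) {
        r <- prm$apoptosis_rate * (age[i] - L_life / 2) / (L_life / 2)
        kill <- stats::runif(1) < 1 - exp(-r / 24)
      }
      if (kill) {
        state[i] <- ST_APO
        alive[i] <- FALSE
        site_vol[loc[i]] <- site_vol[loc[i]] - vol[i]
        next
      }
      if (sti == ST_SEN) next
      g <- loc[i]
      fs <- lat$fine_of_grid[g, ]
      glu_local <- X[fs, 1]
      # starvation -> necrosis
      if (mean(glu_local) < glu_starve) {
        starv[i] <- starv[i] + 60
        if (starv[i] >= prm$starvation_window) {
          state[i] <- ST_NEC
          next
        }
      } else {
        starv[i] <- 0
      }
      # uptake and growth
      demand <- prm$uptake_rate * (vol[i] / prm$v_crit) * meta[i]
      avail <- sum(glu_local) * v_fine
      upt <- min(demand, prm$uptake_fraction * avail)
      if (upt > 0) {
        X[fs, 1] <- pmax(0, glu_local - upt / (n_sub * v_fine))
        consumed_tick <- consumed_tick + upt
      }
      oxy_local <- X[fs, 2]
      oupt <- min(demand, prm$uptake_fraction * sum(oxy_local) * v_fine)
      if (oupt > 0) X[fs, 2] <- pmax(0, oxy_local - oupt / (n_sub * v_fine))
      if (vol[i] < 2 * vcrit[i]) {
        vnew <- min(vol[i] + prm$growth_yield * upt, 2 * vcrit[i])
        site_vol[g] <- site_vol[g] + vnew - vol[i]
        vol[i] <- vnew
      }
      # TGFa surrogate secretion
      X[fs, 3] <- X[fs, 3] + prm$tgfa_secretion / (n_sub * v_fine)

      # state decision
      if (mean(X[fs, 3]) >= migra[i]) {
        # migratory: move toward the least-occupied admissible neighbor
        pentry[i] <- NA_real_
        nbs <- nb[[g]]
        occv <- site_vol[nbs]
        ok <- which(occv + vol[i] <= crowd[i] &
                      occv <= site_vol[g] - vol[i])
        if (length(ok) == 0L) {
          state[i] <- ST_QUI
        } else {
          state[i] <- ST_MIG
          best <- ok[occv[ok] == min(occv[ok])]
          tgt <- nbs[if (length(best) == 1L) best else
            best[sample.int(length(best), 1L)]]
          site_vol[g] <- site_vol[g] - vol[i]
          site_vol[tgt] <- site_vol[tgt] + vol[i]
          loc[i] <- tgt
        }
      } else {
        if (is.na(pentry[i])) pentry[i] <- t_min
        state[i] <- ST_PRO
        if (vol[i] >= 2 * vcrit[i] - 1e-9) {
          # attempt division
          f <- stats::rnorm(1, 0.5, 0.02)
          while (f < 0.4 || f > 0.6) f <- stats::rnorm(1, 0.5, 0.02)
          dvol <- f * vol[i]
          nbs <- nb[[g]]
          occv <- site_vol[nbs]
          ok <- which(occv + dvol <= crowd[i])
          if (length(ok) == 0L) {
            state[i] <- ST_QUI   # division deferred: no admissible target
          } else {
            best <- ok[occv[ok] == min(occv[ok])]
            tgt <- nbs[if (length(best) == 1L) best else
              best[sample.int(length(best), 1L)]]
            if (n_cells + 1L > cap) grow_cap()
            j <- n_cells + 1L
            n_cells <- j
            pop[j] <- pop[i]; state[j] <- ST_UND; loc[j] <- tgt
            vol[j] <- dvol; age[j] <- age[i]; vcrit[j] <- prm$v_crit
            meta[j] <- meta[i]; migra[j] <- migra[i]; crowd[j] <- crowd[i]
            starv[j] <- 0; pentry[j] <- NA_real_
            cycsum[j] <- 0; cycn[j] <- 0L; ndiv[j] <- 0L
            parent[j] <- i; alive[j] <- TRUE
            site_vol[tgt] <- site_vol[tgt] + dvol
            site_vol[g] <- site_vol[g] - dvol
            vol[i] <- vol[i] - dvol
            cycsum[i] <- cycsum[i] + (t_min - pentry[i])
            cycn[i] <- cycn[i] + 1L
            ndiv[i] <- ndiv[i] + 1L
            pentry[i] <- NA_real_
            if (ndiv[i] >= prm$division_cap) state[i] <- ST_SEN
          }
        }
      }
    }
    consumed_prev <- consumed_tick

    # extinction: no living, non-necrotic cancer cells left
    sq <- seq_len(n_cells)
    live_cancer <- alive[sq] & pop[sq] == 1L & state[sq] != ST_NEC
    if (!any(live_cancer)) {
      status <- "failed"
      record(t_min)
      break
    }
    if (t_min %% (sample_every * 60) == 0) record(t_min)
  }

  metrics <- dplyr::bind_rows(lapply(records, tibble::as_tibble))
  sq <- seq_len(n_cells)
  keep <- alive[sq]
  cells <- lat$grid[loc[sq][keep], , drop = FALSE]
  cells$id <- sq[keep]
  cells$parent <- parent[sq][keep]
  cells$population <- c("cancerous", "healthy")[pop[sq][keep]]
  cells$state <- names(.ST)[state[sq][keep]]
  cells$volume <- vol[sq][keep]
  cells$age <- age[sq][keep]
  cells$v_crit <- vcrit[sq][keep]
  cells$divisions <- ndiv[sq][keep]
  cells$cycle_mean <- ifelse(cycn[sq][keep] > 0L,
                             cycsum[sq][keep] / pmax(cycn[sq][keep], 1L),
                             NA_real_)
  cc <- c("id", "parent", "population", "state")
  cells <- tibble::as_tibble(
    cells[, c(cc, setdiff(names(cells), cc))])

  structure(list(config = config, status = status,
                 metrics = metrics, cells = cells),
            class = "tumor_sim")
}

#' @export
print.tumor_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<tumor_sim> %s %s %s, %s/%s glucose, %s days ",
                     "(status: %s)\n"),
              cfg$spec$mode, cfg$spec$dimension, cfg$context,
              cfg$profile, cfg$level, cfg$days, x$status))
  if (nrow(x$metrics) > 0) {
    last <- x$metrics[nrow(x$metrics), ]
    cat(sprintf("  day %.1f: %d cancer cells, diameter %d, symmetry %.3f\n",
                last$t, last$n_cancer, last$diameter, last$symmetry))
  }
  invisible(x)
}

#' Tidy a simulation's metric series
#'
#' @param x A `tumor_sim`.
#' @param ... Unused.
#' @return The recorded metric series in long form: `t` (days), `metric`,
#'   `value`.
#' @export
tidy.tumor_sim <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, -"t", names_to = "metric",
                      values_to = "value")
}

#' One-row summary of a run
#'
#' @param x A `tumor_sim`.
#' @param ... Unused.
#' @return A one-row tibble with the run status, final population counts,
#'   and the three emergent metrics in the run's native view.
#' @export
glance.tumor_sim <- function(x, ...) {
  view <- if (x$config$spec$dimension == "3D") "3D" else "2D"
  last <- x$metrics[nrow(x$metrics), ]
  dplyr::bind_cols(
    tibble::tibble(status = x$status, days = last$t,
                   n_cancer = last$n_cancer, n_healthy = last$n_healthy),
    sim_metrics(x, view))
}

#' Final emergent-behavior metrics of a run
#'
#' Extracts the three emergent-behavior metrics at the final recorded time
#' point. The `"3DC"` view evaluates all three metrics on the z = 0 center
#' slice of a 3D run; `"3D"` uses the maximum-diameter/averaged-symmetry
#' values across slices; `"2D"` is the plain series of a 2D run.
#'
#' @param sim A `tumor_sim`.
#' @param view `"2D"`, `"3D"`, or `"3DC"`.
#' @return A one-row tibble with `growth_rate` (sites/day), `symmetry`, and
#'   `cycle_length` (minutes), or NA columns for a failed run.
#' @export
sim_metrics <- function(sim, view = c("2D", "3D", "3DC")) {
  view <- match.arg(view)
  m <- sim$metrics
  if (sim$status != "completed" || nrow(m) < 2L) {
    return(tibble::tibble(growth_rate = NA_real_, symmetry = NA_real_,
                          cycle_length = NA_real_))
  }
  dia <- if (view == "3DC") m$diameter_center else m$diameter
  sym <- if (view == "3DC") m$symmetry_center else m$symmetry
  cyc <- if (view == "3DC") m$cycle_length_center else m$cycle_length
  gr <- tryCatch(
    growth_rate(tibble::tibble(t = m$t, diameter = dia)),
    error = function(e) NA_real_)
  tibble::tibble(growth_rate = gr,
                 symmetry = sym[length(sym)],
                 cycle_length = cyc[length(cyc)])
}

#' Factorial experiment designs
#'
#' The three factorial studies as runnable presets: `"system"` crosses
#' geometry (rectangular/hexagonal) with dimension (2D/3DC/3D); the 3DC
#' level is an analysis view of the 3D run's center slice, not a separate
#' simulation. `"variability"` crosses initial volume mode with initial age
#' mode (2D hexagonal, constant basal source). `"nutrient"` crosses glucose
#' profile (constant/pulse/cyclic) with level (low/basal/high)
#' (2D hexagonal, variable initial volumes and ages).
#'
#' @param design `"system"`, `"variability"`, or `"nutrient"`.
#' @param context `"colony"` or `"tissue"`.
#' @param replicates Replicates per condition.
#' @param base_seed Base seed; replicate seeds are derived from it and are
#'   pairwise distinct.
#' @param days,radius,layers Passed to [sim_config()].
#' @param cells,env Passed to [sim_config()].
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(design = c("system", "variability", "nutrient"),
                              context = c("colony", "tissue"),
                              replicates = 10, base_seed = 1,
                              days = 14, radius = 20, layers = NULL,
                              cells = cell_params(), env = env_params()) {
  design <- match.arg(design)
  context <- match.arg(context)
  conditions <- switch(design,
    system = tidyr::expand_grid(geometry = c("rectangular", "hexagonal"),
                                dimension = c("2D", "3DC", "3D")),
    variability = tidyr::expand_grid(volume_mode = c("constant", "normal"),
                                     age_mode = c("zero", "uniform")),
    nutrient = tidyr::expand_grid(profile = c("constant", "pulse", "cyclic"),
                                  level = c("low", "basal", "high")))
  structure(list(design = design, context = context,
                 conditions = conditions,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed),
                 days = days, radius = radius, layers = layers,
                 cells = cells, env = env),
            class = "experiment_design")
}

#' Run a factorial experiment
#'
#' Runs every condition of the design for the requested number of
#' replicates and returns one row per (condition, replicate) with the three
#' emergent-behavior metrics at the final time point. Failed runs (no tumor
#' formed) are kept with missing metric values.
#'
#' @param design An [experiment_design()].
#' @param progress Print a line per completed run.
#' @return A `factorial_table` tibble: the design's two factor columns,
#'   `context`, `replicate`, `seed`, `status`, `growth_rate`, `symmetry`,
#'   `cycle_length`.
#' @export
run_factorial <- function(design, progress = FALSE) {
  cond <- design$conditions
  # 3DC shares the 3D simulation: simulate unique runs, then emit views
  if (design$design == "system") {
    runs <- unique(tibble::tibble(
      geometry = cond$geometry,
      sim_dimension = ifelse(cond$dimension == "2D", "2D", "3D")))
  } else {
    runs <- cond
  }
  rows <- list()
  for (k in seq_len(nrow(runs))) {
    for (r in seq_len(design$replicates)) {
      seed <- design$base_seed + (k - 1L) * design$replicates + (r - 1L)
      args <- list(context = design$context, days = design$days,
                   radius = design$radius, layers = design$layers,
                   seed = seed, cells = design$cells, env = design$env)
      rk <- runs[k, ]
      if (design$design == "system") {
        args$geometry <- rk$geometry
        args$dimension <- rk$sim_dimension
      } else if (design$design == "variability") {
        args$volume_mode <- rk$volume_mode
        args$age_mode <- rk$age_mode
      } else {
        args$profile <- rk$profile
        args$level <- rk$level
      }
      args$layers <- if (identical(args$dimension, "3D")) design$layers
        else NULL
      sim <- run_simulation(do.call(sim_config, args))
      if (progress) {
        cat(sprintf("run %d/%d rep %d: %s\n", k, nrow(runs), r, sim$status))
      }
      if (design$design == "system") {
        views <- if (rk$sim_dimension == "2D") "2D" else c("3D", "3DC")
        for (v in views) {
          met <- sim_metrics(sim, v)
          rows[[length(rows) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(geometry = rk$geometry, dimension = v,
                           context = design$context, replicate = r,
                           seed = seed, status = sim$status), met)
        }
      } else {
        met <- sim_metrics(sim, "2D")
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          rk, tibble::tibble(context = design$context, replicate = r,
                             seed = seed, status = sim$status), met)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("factorial_table", class(out))
  out
}
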