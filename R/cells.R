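# Cell agents: population parameters, initialization with configurable
# initial variability, division, and migration-target selection.
#
# The cell state set is {quiescent, migratory, proliferative, apoptotic,
# necrotic, senescent, undecided}; "undecided" is the transient intra-tick
# state in which a cell evaluates its rules. The metabolism and signaling
# behaviors are deliberately simple, documented rules: uptake is capped by
# local availability and scales with volume and metabolic preference; growth
# is proportional to uptake; the proliferative/migratory decision compares
# the local TGFa surrogate against the cell's migratory threshold; cells
# starve to necrosis after a sustained glucose drought; the apoptosis hazard
# rises linearly from half-lifespan to lifespan.

CELL_STATES <- c("undecided", "quiescent", "migratory", "proliferative",
                 "apoptotic", "necrotic", "senescent")

#' Cell population parameters
#'
#' Baseline (healthy) cell parameters plus the cancer-cell modifications:
#' crowding tolerance +50%, metabolic preference +50%, migratory threshold
#' -50% of baseline, applied exactly once at cell construction.
#'
#' @param v_crit Critical volume v* (um^3); a cell divides on reaching twice
#'   its critical volume.
#' @param v_sd Standard deviation of the initial-volume normal distribution
#'   (um^3).
#' @param lifespan Maximum cell lifespan (minutes). Default 14 weeks: just
#'   above the 12-week initial-age maximum, so the oldest initialized cells
#'   reach end-of-life within a two-week run while the bulk of the age
#'   distribution is preserved with a cutoff at the lifespan.
#' @param apoptosis_rate Maximum apoptosis hazard rate (per day), reached at
#'   the lifespan; the hazard rises linearly from zero at half-lifespan.
#' @param max_height Baseline crowding tolerance multiplier; a location
#'   tolerates up to `max_height * 2 * v_crit` um^3 of cell volume.
#' @param meta_pref Baseline metabolic preference multiplier.
#' @param migra_threshold Baseline migratory threshold on the local TGFa
#'   surrogate concentration (fmol/um^3).
#' @param uptake_rate Glucose demand (fmol/hour) of a cell at its critical
#'   volume; demand scales linearly with volume.
#' @param growth_yield Volume grown per unit glucose taken up (um^3/fmol).
#' @param uptake_fraction Maximum fraction of the locally available molecule
#'   amount a cell may take up in one tick.
#' @param starvation_window Continuous time (minutes) below the starvation
#'   glucose level before a cell turns necrotic.
#' @param starvation_level Starvation glucose level as a fraction of the
#'   basal source concentration.
#' @param tgfa_secretion TGFa surrogate secretion rate (fmol/hour/cell).
#' @param division_cap Completed divisions after which a cell turns
#'   senescent (`Inf` disables senescence).
#' @param cancer_max_height,cancer_meta_pref,cancer_migra_threshold
#'   Multipliers applied to cancer cells (defaults +50%, +50%, -50%).
#' @return A list of class `cell_params`.
#' @export
cell_params <- function(v_crit = 2250, v_sd = 200,
                        lifespan = 14 * 7 * 24 * 60,
                        apoptosis_rate = 0.25,
                        max_height = 1.0, meta_pref = 1.0,
                        migra_threshold = 2e-4,
                        uptake_rate = 10, growth_yield = 10,
                        uptake_fraction = 0.5,
                        starvation_window = 36 * 60,
                        starvation_level = 0.1,
                        tgfa_secretion = 0.1,
                        division_cap = Inf,
                        cancer_max_height = 1.5,
                        cancer_meta_pref = 1.5,
                        cancer_migra_threshold = 0.5) {
  out <- as.list(environment())
  structure(out, class = "cell_params")
}

#' Population initialization settings
#'
#' @param volume_mode `"constant"` (all cells at v* = 2250 um^3) or
#'   `"normal"` (drawn from N(2250, 200) um^3, truncated positive). In
#'   normal mode the draw also sets the cell's critical volume.
#' @param age_mode `"zero"` or `"uniform"` (U(0, 12 weeks)).
#' @param context `"colony"` (cancer cells only, seeded at the center) or
#'   `"tissue"` (a background healthy cell fills every other location).
#' @param age_max Upper bound of the uniform age distribution (minutes).
#' @return A list of class `population_init`.
#' @export
population_init <- function(volume_mode = c("normal", "constant"),
                            age_mode = c("uniform", "zero"),
                            context = c("colony", "tissue"),
                            age_max = 12 * 7 * 24 * 60) {
  structure(list(volume_mode = match.arg(volume_mode),
                 age_mode = match.arg(age_mode),
                 context = match.arg(context),
                 age_max = age_max),
            class = "population_init")
}

draw_volumes <- function(n, init, params) {
  if (init$volume_mode == "constant") return(rep(params$v_crit, n))
  v <- stats::rnorm(n, params$v_crit, params$v_sd)
  while (any(v <= 0)) {
    bad <- v <= 0
    v[bad] <- stats::rnorm(sum(bad), params$v_crit, params$v_sd)
  }
  v
}

draw_ages <- function(n, init) {
  if (init$age_mode == "zero") rep(0, n) else stats::runif(n, 0, init$age_max)
}

#' Initialize a cell population
#'
#' Colony context seeds cancer cells at the center location (one per layer
#' in 3D); tissue context additionally fills every other in-domain location
#' with a healthy cell. Volumes and ages are drawn according to the
#' initialization modes from the current RNG stream.
#'
#' @param spec A [geometry_spec()].
#' @param init A [population_init()].
#' @param params A [cell_params()].
#' @return A tibble with one row per cell: `id`, `parent`, `population`,
#'   `state`, coordinate columns, `volume`, `age`, `v_crit`.
#' @examples
#' set.seed(1)
#' spec <- geometry_spec("hexagonal", "2D", radius = 3)
#' initialize_population(spec, population_init("constant", "zero", "colony"))
#' @export
initialize_population <- function(spec, init, params = cell_params()) {
  coords <- domain_coords(spec)
  m <- coord_matrix(coords, spec$mode)
  center <- which(m[, 1] == 0L & m[, 2] == 0L)
  if (init$context == "colony") {
    rows <- center
    pop <- rep("cancerous", length(rows))
  } else {
    others <- setdiff(seq_len(nrow(m)), center)
    rows <- c(center, others)
    pop <- c(rep("cancerous", length(center)), rep("healthy", length(others)))
  }
  n <- length(rows)
  vol <- draw_volumes(n, init, params)
  out <- coords[rows, , drop = FALSE]
  out$id <- seq_len(n)
  out$parent <- NA_integer_
  out$population <- pop
  out$state <- "undecided"
  out$volume <- vol
  out$age <- draw_ages(n, init)
  out$v_crit <- if (init$volume_mode == "normal") vol else
    rep(params$v_crit, n)
  tibble::as_tibble(out[, c("id", "parent", "population", "state",
                            setdiff(names(coords), character()),
                            "volume", "age", "v_crit")])
}

#' Divide a mother cell
#'
#' The volume split fraction f is drawn from N(0.5, 0.02) truncated to
#' [0.4, 0.6]; the daughter receives `f * volume`, the mother keeps
#' `(1 - f) * volume`, and the daughter inherits the mother's age.
#'
#' @param volume Mother volume before division (um^3).
#' @param age Mother age (minutes).
#' @param f Optional fixed split fraction (bypasses the draw).
#' @return A list with `mother_volume`, `daughter_volume`,
#'   `daughter_age`, and `f`.
#' @export
divide_cell <- function(volume, age, f = NULL) {
  if (is.null(f)) {
    f <- stats::rnorm(1, 0.5, 0.02)
    while (f < 0.4 || f > 0.6) f <- stats::rnorm(1, 0.5, 0.02)
  }
  list(mother_volume = (1 - f) * volume, daughter_volume = f * volume,
       daughter_age = age, f = f)
}

#' Select a migration or division target
#'
#' Among candidate neighbor locations, keeps those whose total cell volume
#' plus the added volume respects the crowding tolerance, then chooses
#' uniformly at random among the candidates of minimal occupied volume.
#'
#' @param occupied_volume Numeric vector: total cell volume currently at
#'   each candidate location.
#' @param add_volume Volume that would be added to the chosen location.
#' @param tolerance Crowding tolerance (maximum total volume) of the moving
#'   or dividing cell.
#' @return The index of the chosen candidate, or `NA_integer_` if every
#'   candidate violates the tolerance.
#' @export
select_move_target <- function(occupied_volume, add_volume, tolerance) {
  ok <- which(occupied_volume + add_volume <= tolerance)
  if (length(ok) == 0L) return(NA_integer_)
  best <- ok[occupied_volume[ok] == min(occupied_volume[ok])]
  if (length(best) == 1L) return(best)
  best[sample.int(length(best), 1L)]
}
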