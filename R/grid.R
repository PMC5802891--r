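#' Grid specification for a simulated landscape
#'
#' Defines the raster geometry and temporal conventions of a simulation:
#' cell counts, cell area (ha), calendar origin year, timestep (yr) and
#' horizon (yr). The default 6.25-ha cells correspond to a 250-m grid and
#' simulations advance in 5-yr steps over 100 yr.
#'
#' @param n_rows,n_cols grid dimensions (row 1 is the southern edge).
#' @param cell_area cell area in hectares.
#' @param origin_year calendar year of the initial state.
#' @param timestep step length in years; must divide \code{horizon}.
#' @param horizon simulated duration in years.
#' @return An object of class \code{grid_spec}.
#' @export
grid_spec <- function(n_rows, n_cols, cell_area = 6.25, origin_year = 2000,
                      timestep = 5, horizon = 100) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1, n_cols >= 1, cell_area > 0, timestep >= 1)
  if (horizon %% timestep != 0)
    stop("timestep (", timestep, ") must divide horizon (", horizon, ")")
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_area = cell_area,
                 origin_year = origin_year, timestep = as.integer(timestep),
                 horizon = as.integer(horizon)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells (%.2f ha each, %.0f ha total)\n",
              x$n_rows, x$n_cols, x$cell_area,
              x$n_rows * x$n_cols * x$cell_area))
  cat(sprintf("  years %d-%d, %d-yr steps\n", x$origin_year,
              x$origin_year + x$horizon, x$timestep))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Cell width in metres (cells are square)
#' @param grid a \code{grid_spec}.
#' @return numeric scalar, metres.
#' @export
cell_size_m <- function(grid) sqrt(grid$cell_area * 1e4)

# row-major cell indexing: cell = (row - 1) * n_cols + col
cell_row <- function(cell, grid) (cell - 1L) %/% grid$n_cols + 1L
cell_col <- function(cell, grid) (cell - 1L) %% grid$n_cols + 1L

#' Construct a landscape state
#'
#' The full per-cell simulation state: a cohort table (cell, species, age,
#' biomass), per-cell time-since-fire (NA until a cell first burns within
#' the simulation), the stand age and dominant composition recorded at the
#' moment of the last burn (needed to distinguish recently burned old vs
#' young habitat once the burn has reset the living cohorts), and static
#' zonation layers (landtype, fire region, management area, land tenure).
#'
#' @param grid a \code{grid_spec}.
#' @param cohorts a \code{data.frame}/\code{data.table} with columns
#'   \code{cell}, \code{species}, \code{age}, \code{biomass} (t/ha).
#' @param landtype,fire_region,management_area integer vectors, one value
#'   per cell.
#' @param tenure character vector per cell, \code{"public"} or
#'   \code{"private"}.
#' @param time_since_fire,pre_fire_age,pre_fire_conifer per-cell numeric
#'   vectors (NA where the cell has never burned in the simulation).
#' @param year calendar year of the state.
#' @return An object of class \code{landscape_state}.
#' @export
landscape_state <- function(grid, cohorts, landtype, fire_region,
                            management_area,
                            tenure = rep("public", n_cells(grid)),
                            time_since_fire = rep(NA_real_, n_cells(grid)),
                            pre_fire_age = rep(NA_real_, n_cells(grid)),
                            pre_fire_conifer = rep(NA_real_, n_cells(grid)),
                            year = grid$origin_year) {
  nc <- n_cells(grid)
  cohorts <- data.table::as.data.table(cohorts)
  if (nrow(cohorts) == 0)
    cohorts <- data.table::data.table(cell = integer(), species = character(),
                                      age = integer(), biomass = numeric())
  stopifnot(all(c("cell", "species", "age", "biomass") %in% names(cohorts)))
  check_len <- function(v, nm) {
    if (length(v) != nc) stop(nm, " must have one value per cell")
    v
  }
  st <- structure(list(
    grid = grid,
    cohorts = cohorts[, list(cell = as.integer(cell),
                             species = as.character(species),
                             age = as.integer(age),
                             biomass = as.numeric(biomass))],
    landtype = as.integer(check_len(landtype, "landtype")),
    fire_region = as.integer(check_len(fire_region, "fire_region")),
    management_area = as.integer(check_len(management_area, "management_area")),
    tenure = as.character(check_len(tenure, "tenure")),
    time_since_fire = as.numeric(check_len(time_since_fire, "time_since_fire")),
    pre_fire_age = as.numeric(check_len(pre_fire_age, "pre_fire_age")),
    pre_fire_conifer = as.numeric(check_len(pre_fire_conifer,
                                            "pre_fire_conifer")),
    year = year), class = "landscape_state")
  st
}

#' @export
print.landscape_state <- function(x, ...) {
  ages <- stand_age_map(x)
  cat(sprintf("<landscape_state> year %d, %d x %d cells\n", x$year,
              x$grid$n_rows, x$grid$n_cols))
  cat(sprintf("  %d cohorts, mean stand age %.1f yr, mean AGB %.1f t/ha\n",
              nrow(x$cohorts), mean(ages),
              sum(x$cohorts$biomass) / n_cells(x$grid)))
  cat(sprintf("  %d landtypes, %d fire regions, %d management areas\n",
              length(unique(x$landtype)), length(unique(x$fire_region)),
              length(unique(x$management_area))))
  invisible(x)
}

#' Stand age of one cell
#'
#' The stand age is the age of the oldest cohort; an empty cell has age 0.
#'
#' @param cell_cohorts a \code{data.frame} of cohorts for a single cell
#'   (columns \code{age}, and optionally others).
#' @return age in years.
#' @export
stand_age <- function(cell_cohorts) {
  if (is.null(cell_cohorts) || nrow(cell_cohorts) == 0) return(0)
  max(cell_cohorts$age)
}

#' Conifer biomass fraction of one cell
#'
#' Conifer biomass divided by total biomass; 0 by convention for an empty
#' cell (no biomass).
#'
#' @param cell_cohorts a \code{data.frame} of cohorts for a single cell
#'   (columns \code{species}, \code{biomass}).
#' @param traits species trait table (see [species_traits()]).
#' @return fraction in \[0, 1\].
#' @export
conifer_fraction <- function(cell_cohorts, traits = species_traits()) {
  if (is.null(cell_cohorts) || nrow(cell_cohorts) == 0) return(0)
  tot <- sum(cell_cohorts$biomass)
  if (tot <= 0) return(0)
  con <- traits$is_conifer[match(cell_cohorts$species, traits$code)]
  sum(cell_cohorts$biomass[con]) / tot
}

# Vectorized per-cell maps -------------------------------------------------

stand_age_map <- function(state) {
  out <- numeric(n_cells(state$grid))
  if (nrow(state$cohorts)) {
    agg <- state$cohorts[, list(a = max(age)), by = "cell"]
    out[agg$cell] <- agg$a
  }
  out
}

biomass_map <- function(state) {
  out <- numeric(n_cells(state$grid))
  if (nrow(state$cohorts)) {
    agg <- state$cohorts[, list(b = sum(biomass)), by = "cell"]
    out[agg$cell] <- agg$b
  }
  out
}

conifer_fraction_map <- function(state, traits = species_traits()) {
  nc <- n_cells(state$grid)
  out <- numeric(nc)
  if (nrow(state$cohorts)) {
    co <- state$cohorts
    isc <- traits$is_conifer[match(co$species, traits$code)]
    tot <- numeric(nc); con <- numeric(nc)
    agg <- co[, list(tot = sum(biomass)), by = "cell"]
    aggc <- co[isc, list(con = sum(biomass)), by = "cell"]
    tot[agg$cell] <- agg$tot
    con[aggc$cell] <- aggc$con
    ok <- tot > 0
    out[ok] <- con[ok] / tot[ok]
  }
  out
}
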