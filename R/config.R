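#' Default pipeline configuration
#'
#' Builds the full nested configuration used by the synthetic landscape
#' generator, the landscape simulator, the habitat classifier and the
#' factorial experiment. Every entry can be overridden from a YAML file
#' via [read_config()] or programmatically via \code{modifyList}-style
#' overrides here.
#'
#' Defaults encode the study conditions: 250-m cells (6.25 ha), 5-yr steps
#' over 2000-2100; an 8-species boreal pool on a south-to-north
#' conifer gradient; a negative-exponential stand-age structure with a
#' 100-yr fire-cycle surrogate mean; spruce budworm outbreaks lasting at
#' most 10 yr every 35 yr; harvesting of 0.5% of each management area per
#' year restricted to stands with cohorts older than 60 yr; and habitat
#' coefficients (home ranges and per-home-range productivities) for the
#' five woodpecker habitat types.
#'
#' @param ... named top-level sections to override (each a list merged
#'   into the default section), e.g. \code{grid = list(n_rows = 50)}.
#' @return A nested list of class \code{bbwo_config}.
#' @export
default_config <- function(...) {
  cfg <- list(
    grid = list(n_rows = 100L, n_cols = 100L, cell_area = 6.25,
                origin_year = 2000L, timestep = 5L, horizon = 100L),
    synthetic = list(
      n_landtypes = 5L,
      n_fire_regions = 2L,
      n_management_areas = 3L,   # last one private when private_fraction > 0
      private_fraction = 0.127,
      conifer_gradient = c(0.75, 0.95),  # (southern, northern) conifer prob.
      age_distribution_mean = 100,     # yr; fire-cycle surrogate
      correlation_range = 5,           # cells; patchiness of age/composition
      p_mixed = 0.35,                  # prob. of a secondary cohort
      secondary_biomass = c(0.10, 0.50),  # uniform bounds, x dominant biomass
      # conifer-dominated boreal pool: black spruce most abundant, balsam
      # fir and jack pine next, minor deciduous admixture
      species_pool = c(PICE.MAR = 0.40, ABIE.BAL = 0.18, PINU.BAN = 0.12,
                       PICE.GLA = 0.08, LARI.LAR = 0.04, POPU.TRE = 0.08,
                       BETU.PAP = 0.07, ACER.RUB = 0.03),
      initial_burns = TRUE,  # seed recent (<=10 yr) fire scars at start
      rng_seed = 1L),
    dynamics = list(
      # Desk-scale baseline calibration: carrying capacity (t/ha) and
      # free-growth productivity (kg/ha/yr) per species.
      maxAGB = c(ABIE.BAL = 110, ACER.RUB = 110, ACER.SAH = 120,
                 BETU.ALL = 110, BETU.PAP = 100, FAGU.GRA = 120,
                 LARI.LAR = 70, PICE.GLA = 100, PICE.MAR = 90,
                 PICE.RUB = 100, PINU.BAN = 80, PINU.RES = 100,
                 PINU.STR = 120, POPU.TRE = 120, QUER.RUB = 110,
                 THUJ.OCC = 90, TSUG.CAN = 110),
      maxANPP = c(ABIE.BAL = 3000, ACER.RUB = 3000, ACER.SAH = 2800,
                  BETU.ALL = 2800, BETU.PAP = 3000, FAGU.GRA = 2600,
                  LARI.LAR = 2500, PICE.GLA = 2600, PICE.MAR = 2200,
                  PICE.RUB = 2400, PINU.BAN = 2800, PINU.RES = 2600,
                  PINU.STR = 2800, POPU.TRE = 3500, QUER.RUB = 2600,
                  THUJ.OCC = 2000, TSUG.CAN = 2200),
      bias_scalars = NULL,  # optional named per-species multipliers
      landtype_range = c(0.85, 1.15),  # maxANPP/maxAGB spread over landtypes
      # Climate-trend strength by scenario: fractional change reached in the
      # 2071-2100 period (conifers decline, deciduous species rise).
      stand_strength = c(baseline = 0, rcp26 = 0.15, rcp45 = 0.30,
                         rcp85 = 0.50),
      establishment_biomass = 0.1,  # t/ha for a newly established cohort
      # Relative occupancy (biomass / maxAGB) below which a species of
      # shade tolerance 1..5 can still establish.
      light_thresholds = c(0.15, 0.30, 0.50, 0.70, 0.85)),
    fire = list(
      # Baseline regional regimes interpolated south -> north.
      annual_burn_rate = c(0.002, 0.010),  # fraction of region area / yr
      mean_fire_size = c(100, 500),        # ha
      size_cv = 1.0,                       # lognormal CV of fire size
      # Burn-rate multiplier reached by 2071-2100 is 1 + climate_strength.
      climate_strength = c(baseline = 0, rcp26 = 0.5, rcp45 = 1.5,
                           rcp85 = 3.0)),
    sbw = list(
      recurrence = 35, max_duration = 10, phase = 0,
      host_ranking = c("ABIE.BAL", "PICE.GLA", "PICE.RUB", "PICE.MAR"),
      susceptibility = c(0.9, 0.7, 0.5, 0.3),  # biomass loss / timestep
      young_factor = 0.5, young_age = 30),
    harvest = list(
      annual_rate = 0.005,        # fraction of each management area / yr
      eligibility_age = 60,       # must contain a cohort OLDER than this
      public_prescription = "clearcut",
      private_prescription = "partial_high",
      partial_low = c(0.01, 0.40),
      partial_high = c(0.41, 0.80)),
    habitat = list(
      conif_threshold = 0.75, mixed_lower = 0.25,
      old_age = 80, connectivity = 4L, count_mode = "patches",
      coefficients = habitat_coefficients()),
    species = species_traits()
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
  }
  cfg <- validate_config(cfg)
  class(cfg) <- "bbwo_config"
  cfg
}

scenario_names <- function() c("baseline", "rcp26", "rcp45", "rcp85")

climate_periods <- function() c("2000-2010", "2011-2040", "2041-2070",
                                "2071-2100")

# Fractional progression of the climate signal across periods.
period_ramp <- function(period) {
  ramp <- c("baseline" = 0, "2000-2010" = 0, "2011-2040" = 1 / 3,
            "2041-2070" = 2 / 3, "2071-2100" = 1)
  unname(ramp[period])
}

validate_config <- function(cfg) {
  g <- cfg$grid
  cfg$grid <- g <- utils::modifyList(
    list(cell_area = 6.25, origin_year = 2000L, timestep = 5L,
         horizon = 100L), g)
  stopifnot(g$n_rows >= 1, g$n_cols >= 1)
  if (g$cell_area <= 0) stop("grid$cell_area must be > 0")
  if (g$horizon %% g$timestep != 0) stop("timestep must divide horizon")
  s <- cfg$synthetic
  if (length(s$species_pool) == 0 || is.null(names(s$species_pool)))
    stop("synthetic$species_pool must be a non-empty named abundance vector")
  bad <- setdiff(names(s$species_pool), cfg$species$code)
  if (length(bad)) stop("species_pool references unknown species: ",
                        paste(bad, collapse = ", "))
  if (any(s$conifer_gradient < 0 | s$conifer_gradient > 1))
    stop("synthetic$conifer_gradient fractions must lie in [0, 1]")
  if (s$private_fraction < 0 || s$private_fraction > 1)
    stop("synthetic$private_fraction must lie in [0, 1]")
  if (s$age_distribution_mean <= 0)
    stop("synthetic$age_distribution_mean must be > 0")
  tr <- cfg$species
  if (any(tr$maturity_age <= 0 | tr$maturity_age >= tr$longevity))
    stop("species traits must satisfy 0 < maturity_age < longevity")
  if (any(tr$effective_dispersal > tr$maximum_dispersal))
    stop("effective_dispersal must not exceed maximum_dispersal")
  sep <- tr$sep_mean
  if (any(sep < 0 | sep > 1)) stop("SEP values must lie in [0, 1]")
  f <- cfg$fire
  if (any(f$annual_burn_rate < 0)) stop("fire$annual_burn_rate must be >= 0")
  if (any(f$mean_fire_size < g$cell_area))
    stop("fire$mean_fire_size must be >= cell_area")
  if (cfg$sbw$recurrence <= cfg$sbw$max_duration)
    stop("sbw$recurrence must exceed sbw$max_duration")
  if (any(cfg$sbw$susceptibility < 0 | cfg$sbw$susceptibility > 1))
    stop("sbw$susceptibility fractions must lie in [0, 1]")
  h <- cfg$harvest
  if (h$annual_rate < 0) stop("harvest$annual_rate must be >= 0")
  chk_band <- function(b, lo, hi, nm) {
    if (b[1] < lo || b[2] > hi || b[1] > b[2])
      stop("harvest$", nm, " bounds must lie within [", lo, ", ", hi, "]")
  }
  chk_band(h$partial_low, 0.01, 0.40, "partial_low")
  chk_band(h$partial_high, 0.41, 0.80, "partial_high")
  hb <- cfg$habitat
  if (!(hb$mixed_lower < hb$conif_threshold))
    stop("habitat$mixed_lower must be below habitat$conif_threshold")
  if (!hb$connectivity %in% c(4L, 8L))
    stop("habitat$connectivity must be 4 or 8")
  if (!hb$count_mode %in% c("patches", "home_ranges"))
    stop("habitat$count_mode must be 'patches' or 'home_ranges'")
  co <- hb$coefficients
  if (any(co$home_range <= 0) || any(co$productivity < 0))
    stop("habitat coefficients must have home_range > 0, productivity >= 0")
  cfg
}

#' Read and validate a configuration file
#'
#' Reads a YAML configuration, overlays it on the package defaults
#' (an empty file therefore yields the full default configuration) and
#' validates ranges and cross-references. Unknown top-level sections are
#' rejected.
#'
#' @param path path to a YAML file.
#' @return A validated \code{bbwo_config} list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- c("grid", "synthetic", "dynamics", "fire", "sbw", "harvest",
             "habitat", "species")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "))
  # vectors serialized as lists come back as lists; flatten numeric leaves
  y <- rapply(y, function(v) v, how = "replace")
  flatten <- function(x) {
    # scalar sequences and maps come back as lists; restore vectors
    if (is.list(x) && length(x) && all(vapply(x, function(e)
      is.atomic(e) && length(e) == 1, TRUE)))
      unlist(x) else x
  }
  y <- lapply(y, function(sec) if (is.list(sec)) lapply(sec, flatten) else sec)
  if (!is.null(y$species)) {
    y$species <- as.data.frame(do.call(rbind, lapply(y$species, as.data.frame)))
  }
  args <- y[setdiff(names(y), "species")]
  cfg <- do.call(default_config, args)
  if (!is.null(y$species)) {
    cfg$species <- y$species
    cfg <- validate_config(cfg)
    class(cfg) <- "bbwo_config"
  }
  cfg
}

#' Write a configuration to YAML
#'
#' @param cfg a \code{bbwo_config}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$habitat$coefficients <- NULL  # table defaults live in code
  out$species <- NULL
  # yaml drops names of atomic vectors; write them as maps instead
  as_maps <- function(x) {
    if (is.list(x)) lapply(x, as_maps)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(as_maps(out), path)
  invisible(path)
}

config_grid <- function(cfg) {
  do.call(grid_spec, cfg$grid[c("n_rows", "n_cols", "cell_area",
                                "origin_year", "timestep", "horizon")])
}
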