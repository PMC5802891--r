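# The simulation driver: per 5-yr step, look up the climate period for the
# stand-scale and fire parameter tables (honouring the factorial toggles),
# then apply succession, fire, spruce budworm (always on, as a background
# disturbance) and harvest. Each stochastic process draws from its own
# seed stream derived from the master seed, so toggling one process does
# not perturb another's draws.

#' Map a calendar year to a climate period
#'
#' Climate-sensitive parameters switch in 2010, 2040 and 2070: years map to
#' the periods 2000-2010, 2011-2040, 2041-2070 and 2071-2100. The baseline
#' scenario always maps to \code{"baseline"} (period-constant parameters).
#'
#' @param year calendar year.
#' @param scenario forcing scenario name.
#' @return period key string.
#' @export
update_climate_period <- function(year, scenario) {
  if (!scenario %in% scenario_names()) stop("unknown scenario: ", scenario)
  if (scenario == "baseline") return("baseline")
  if (year <= 2010) "2000-2010"
  else if (year <= 2040) "2011-2040"
  else if (year <= 2070) "2041-2070"
  else "2071-2100"
}

# Deterministic per-step, per-process seed stream (31-bit).
stream_seed <- function(master, step, process) {
  procs <- c(establishment = 1, fire = 2, sbw = 3, harvest = 4)
  as.integer((as.numeric(master) * 48271 + step * 1299709 +
                procs[[process]] * 15485863) %% 2147483647)
}

default_toggles <- function() {
  list(harvest = TRUE, fire_climate = TRUE, stand_climate = TRUE)
}

#' Run a full landscape simulation
#'
#' Runs the landscape forward from the initial state over the grid's
#' horizon at its timestep, applying per step: climate-period lookup
#' (respecting the factorial toggles), succession, fire, spruce budworm
#' (always active as a background disturbance) and harvesting (if
#' toggled on). With \code{stand_climate} (or \code{fire_climate}) off,
#' the stand-scale dynamic inputs (or the fire regime) are held at their
#' baseline calibration for the whole run. Snapshots of the
#' habitat-relevant layers are retained at every step. Fully reproducible
#' from \code{seed}.
#'
#' @param initial a [landscape_state()].
#' @param scenario forcing scenario name.
#' @param toggles list with logical elements \code{harvest},
#'   \code{fire_climate}, \code{stand_climate}.
#' @param seed master integer seed.
#' @param config a \code{bbwo_config}.
#' @param dyn,regime optional pre-built dynamic-input / fire-regime tables
#'   (both scenarios' tables are generated from \code{config} otherwise).
#' @param prescriptions optional harvest prescription table
#'   (default [build_prescriptions()]).
#' @param fire_boost optional \code{list(from_year =, factor =)} applying a
#'   burn-rate multiplier from a given calendar year onward (stress tests).
#' @return An object of class \code{bbwo_sim}: per-step layer snapshots,
#'   a disturbance log and per-species mean AGB series.
#' @export
run_simulation <- function(initial, scenario = "baseline",
                           toggles = default_toggles(), seed = 1,
                           config = default_config(), dyn = NULL,
                           regime = NULL, prescriptions = NULL,
                           fire_boost = NULL) {
  toggles <- utils::modifyList(default_toggles(), toggles)
  grid <- initial$grid
  traits <- config$species
  stand_scn <- if (toggles$stand_climate) scenario else "baseline"
  fire_scn <- if (toggles$fire_climate) scenario else "baseline"
  if (is.null(dyn)) dyn <- generate_dynamic_inputs(config, stand_scn)
  if (is.null(regime)) regime <- generate_fire_regime(config, fire_scn)
  if (is.null(prescriptions)) prescriptions <- build_prescriptions(config,
                                                                   initial)
  state <- initial
  n_steps <- grid$horizon %/% grid$timestep
  snapshots <- vector("list", n_steps + 1)
  log_rows <- vector("list", n_steps)
  agb_rows <- vector("list", n_steps + 1)

  take_snapshot <- function(state) {
    list(year = state$year,
         stand_age = stand_age_map(state),
         conifer_fraction = conifer_fraction_map(state, traits),
         time_since_fire = state$time_since_fire,
         pre_fire_age = state$pre_fire_age,
         pre_fire_conifer = state$pre_fire_conifer)
  }
  agb_series <- function(state) {
    if (!nrow(state$cohorts))
      return(data.table::data.table(year = state$year, species = character(),
                                    agb = numeric()))
    a <- state$cohorts[, list(agb = sum(biomass) / n_cells(grid)),
                       by = "species"]
    a$year <- state$year
    a[, c("year", "species", "agb")]
  }
  snapshots[[1]] <- take_snapshot(state)
  agb_rows[[1]] <- agb_series(state)

  for (step in seq_len(n_steps)) {
    state$year <- state$year + grid$timestep
    burned_prev <- !is.na(state$time_since_fire)
    state$time_since_fire[burned_prev] <-
      state$time_since_fire[burned_prev] + grid$timestep

    sp_period <- update_climate_period(state$year, stand_scn)
    fr_period <- update_climate_period(state$year, fire_scn)

    set.seed(stream_seed(seed, step, "establishment"))
    state <- step_succession(state, dyn[dyn$period == sp_period, ], traits,
                             config)

    set.seed(stream_seed(seed, step, "fire"))
    mult <- 1
    if (!is.null(fire_boost) && state$year >= fire_boost$from_year)
      mult <- fire_boost$factor
    fr <- simulate_fire(state, regime, fr_period, config, traits,
                        rate_multiplier = mult)
    state <- fr$state

    set.seed(stream_seed(seed, step, "sbw"))
    state <- apply_sbw(state, config$sbw)

    h_area <- 0; h_short <- 0
    if (toggles$harvest) {
      set.seed(stream_seed(seed, step, "harvest"))
      hv <- apply_harvest(state, prescriptions, config)
      state <- hv$state
      h_area <- sum(hv$report$harvested_area)
      h_short <- sum(hv$report$shortfall)
    }

    snapshots[[step + 1]] <- take_snapshot(state)
    agb_rows[[step + 1]] <- agb_series(state)
    log_rows[[step]] <- data.table::data.table(
      year = state$year, burned_area = sum(fr$burned) * grid$cell_area,
      harvested_area = h_area, harvest_shortfall = h_short)
  }

  structure(list(
    grid = grid, scenario = scenario, toggles = toggles, seed = seed,
    years = vapply(snapshots, `[[`, 0, "year"),
    snapshots = snapshots,
    log = data.table::rbindlist(log_rows),
    agb = data.table::rbindlist(agb_rows),
    final_state = state), class = "bbwo_sim")
}

#' @export
print.bbwo_sim <- function(x, ...) {
  cat(sprintf("<bbwo_sim> scenario %s, years %d-%d (%d snapshots)\n",
              x$scenario, min(x$years), max(x$years), length(x$years)))
  cat(sprintf("  toggles: harvest=%s fire_climate=%s stand_climate=%s, seed %s\n",
              x$toggles$harvest, x$toggles$fire_climate,
              x$toggles$stand_climate, format(x$seed)))
  cat(sprintf("  burned %0.f ha, harvested %0.f ha over the run\n",
              sum(x$log$burned_area), sum(x$log$harvested_area)))
  invisible(x)
}
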