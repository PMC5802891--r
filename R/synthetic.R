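# Synthetic boreal landscape and dynamic-input generation.
#
# The generator stands in for initialization from inventory/remote-sensing
# data: it reproduces the statistical structure the downstream analysis
# relies on (a south-to-north conifer gradient, a negative-exponential
# stand-age distribution consistent with a stand-replacing fire cycle, and
# zonation into fire regions and management areas), not any real landscape.

# Inverse CDF of an exponential(mean) truncated at upper bound.
qtrunc_exp <- function(u, mean, upper) {
  -mean * log(1 - u * (1 - exp(-upper / mean)))
}

# Spatially correlated field with uniform(0,1) marginals: Gaussian noise
# smoothed to the requested correlation range (cells) by iterated
# 5-point averaging (edge-replicated), then rank-transformed. Gives forest
# attributes the patchiness of real landscapes while leaving each cell's
# marginal distribution exactly uniform.
corr_unif_field <- function(grid, range_cells) {
  z <- matrix(stats::rnorm(n_cells(grid)), grid$n_rows, grid$n_cols)
  iters <- round(range_cells^2)
  if (iters > 0) {
    nr <- nrow(z); nc <- ncol(z)
    up <- function(m) m[c(1, seq_len(nr - 1)), , drop = FALSE]
    dn <- function(m) m[c(seq_len(nr - 1) + 1, nr), , drop = FALSE]
    lf <- function(m) m[, c(1, seq_len(nc - 1)), drop = FALSE]
    rt <- function(m) m[, c(seq_len(nc - 1) + 1, nc), drop = FALSE]
    for (i in seq_len(iters))
      z <- (z + up(z) + dn(z) + lf(z) + rt(z)) / 5
  }
  v <- as.numeric(t(z))  # row-major cell order
  (rank(v, ties.method = "first") - 0.5) / length(v)
}

# Closed-form mean of an exponential(mean) truncated at upper; used as the
# oracle for the generated age structure.
trunc_exp_mean <- function(mean, upper) {
  p <- 1 - exp(-upper / mean)
  mean - upper * exp(-upper / mean) / p
}

#' Generate a synthetic initial landscape
#'
#' Draws per-cell stand ages from a negative-exponential distribution
#' (the stationary age structure under a constant-rate stand-replacing
#' fire regime) with mean \code{synthetic$age_distribution_mean}, truncated
#' at each species' longevity and rounded to the timestep grid; assigns a
#' dominant species per cell with conifer probability interpolated linearly
#' by row between the southern and northern endpoints of
#' \code{synthetic$conifer_gradient}; optionally adds a secondary cohort of
#' the opposite type to create a composition spectrum; and zones the grid
#' into horizontal bands of fire regions and management areas (the last
#' management area is private land when \code{private_fraction > 0}).
#' Age and composition are driven by spatially correlated uniform fields
#' (range \code{synthetic$correlation_range} cells), so old coniferous
#' stands form contiguous patches while every cell's marginal distribution
#' stays exactly the configured one. When \code{synthetic$initial_burns}
#' is set (the default), two historic fire timesteps under the baseline
#' regime leave the start-year landscape with 5- and 10-yr-old burn scars,
#' as a landscape with an ongoing fire regime must have.
#' Cohort biomasses are initialized below the cell's carrying capacity with
#' an age-dependent saturating fill. Fully reproducible from the seed.
#'
#' @param config a \code{bbwo_config} (see [default_config()]).
#' @param seed integer RNG seed; defaults to \code{synthetic$rng_seed}.
#' @return A [landscape_state()].
#' @examples
#' cfg <- default_config(grid = list(n_rows = 20, n_cols = 20))
#' st <- generate_initial_landscape(cfg, seed = 1)
#' st
#' @export
generate_initial_landscape <- function(config, seed = NULL) {
  syn <- config$synthetic
  if (length(syn$species_pool) == 0) stop("empty species pool")
  if (is.null(seed)) seed <- syn$rng_seed
  set.seed(seed)
  grid <- config_grid(config)
  nc <- n_cells(grid)
  traits <- config$species
  pool <- names(syn$species_pool)
  ab <- syn$species_pool / sum(syn$species_pool)
  isc <- traits$is_conifer[match(pool, traits$code)]
  con_pool <- pool[isc]; dec_pool <- pool[!isc]

  rows <- cell_row(seq_len(nc), grid)
  # row 1 = southern edge
  frac <- if (grid$n_rows == 1) 0.5 else (rows - 1) / (grid$n_rows - 1)
  p_con <- syn$conifer_gradient[1] +
    frac * (syn$conifer_gradient[2] - syn$conifer_gradient[1])

  pick <- function(codes, n) {
    if (length(codes) == 0) return(character(n))
    if (length(codes) == 1) return(rep(codes, n))
    sample(codes, n, replace = TRUE, prob = ab[codes])
  }
  rng <- syn$correlation_range
  if (is.null(rng)) rng <- 5
  is_con_cell <- corr_unif_field(grid, rng) < p_con
  if (length(con_pool) == 0) is_con_cell[] <- FALSE
  if (length(dec_pool) == 0) is_con_cell[] <- TRUE
  dom <- character(nc)
  dom[is_con_cell] <- pick(con_pool, sum(is_con_cell))
  dom[!is_con_cell] <- pick(dec_pool, sum(!is_con_cell))

  longv <- traits$longevity[match(dom, traits$code)]
  age_raw <- qtrunc_exp(corr_unif_field(grid, rng),
                        syn$age_distribution_mean, longv)
  age <- round(age_raw / grid$timestep) * grid$timestep

  dynb <- generate_dynamic_inputs(config, "baseline")
  landtype <- sample.int(syn$n_landtypes, nc, replace = TRUE)
  key <- paste(dynb$species, dynb$landtype)
  magb <- dynb$maxAGB[match(paste(dom, landtype), key)]

  fill <- 0.85 * (1 - exp(-2.5 * age / longv))
  biomass <- magb * fill

  keep <- age > 0
  cohorts <- data.table::data.table(
    cell = which(keep), species = dom[keep], age = as.integer(age[keep]),
    biomass = biomass[keep])

  # secondary cohorts: opposite type, smaller and no older than the dominant
  both <- length(con_pool) > 0 && length(dec_pool) > 0
  if (both && syn$p_mixed > 0) {
    sec_cells <- which(keep & stats::runif(nc) < syn$p_mixed)
    if (length(sec_cells)) {
      sec_sp <- ifelse(is_con_cell[sec_cells],
                       pick(dec_pool, length(sec_cells)),
                       pick(con_pool, length(sec_cells)))
      sec_long <- traits$longevity[match(sec_sp, traits$code)]
      sec_age <- pmin(age[sec_cells], round(sec_long / grid$timestep) *
                        grid$timestep)
      u <- stats::runif(length(sec_cells), syn$secondary_biomass[1],
                        syn$secondary_biomass[2])
      sec <- data.table::data.table(
        cell = sec_cells, species = sec_sp, age = as.integer(sec_age),
        biomass = biomass[sec_cells] * u)
      sec <- sec[sec$age > 0 & sec$biomass > 0, ]
      cohorts <- rbind(cohorts, sec)
    }
  }
  data.table::setkeyv(cohorts, "cell")

  band <- function(k) {
    # horizontal bands, contiguous, south (row 1) to north
    idx <- ceiling(rows / grid$n_rows * k)
    pmin(pmax(idx, 1L), as.integer(k))
  }
  fire_region <- band(syn$n_fire_regions)
  n_ma <- syn$n_management_areas
  if (syn$private_fraction > 0 && n_ma >= 2) {
    priv_rows <- max(1L, round(syn$private_fraction * grid$n_rows))
    is_priv <- rows > grid$n_rows - priv_rows
    pub_idx <- ceiling(pmin(rows, grid$n_rows - priv_rows) /
                         (grid$n_rows - priv_rows) * (n_ma - 1L))
    management_area <- ifelse(is_priv, n_ma, pmin(pmax(pub_idx, 1L),
                                                  n_ma - 1L))
    tenure <- ifelse(is_priv, "private", "public")
  } else {
    management_area <- band(n_ma)
    tenure <- rep("public", nc)
  }

  st <- landscape_state(grid, cohorts, landtype, fire_region,
                        as.integer(management_area), tenure)

  # Recent fire scars: the real landscape enters the simulation with burns
  # from the previous decade (they feed the recently-burned habitat
  # classes). Two historic fire timesteps under the baseline regime leave
  # cells 5 and 10 yr post-fire at the start year.
  if (isTRUE(syn$initial_burns)) {
    regime <- generate_fire_regime(config, "baseline")
    for (k in 1:2) {
      st <- simulate_fire(st, regime, "baseline", config, traits)$state
      seen <- !is.na(st$time_since_fire)
      st$time_since_fire[seen] <- st$time_since_fire[seen] + grid$timestep
    }
  }
  st
}

#' Generate dynamic growth and establishment inputs
#'
#' Produces the table of species establishment probability (SEP, per 5-yr
#' timestep), maximum annual net primary productivity (maxANPP, kg/ha/yr)
#' and maximum aboveground biomass (maxAGB, t/ha) per species x landtype x
#' climate period for one forcing scenario. Baseline values come from the
#' configured per-species calibration spread across landtypes; under an
#' RCP scenario, multiplicative trends ramp up over the climate periods so
#' that conifer values decline and deciduous values rise, with magnitude
#' increasing with forcing strength (rcp26 < rcp45 < rcp85). The baseline
#' scenario returns period-constant values. SEP is clamped to \[0, 1\].
#'
#' @param config a \code{bbwo_config}.
#' @param scenario one of \code{"baseline"}, \code{"rcp26"},
#'   \code{"rcp45"}, \code{"rcp85"}.
#' @return A \code{data.table} with columns \code{scenario}, \code{period},
#'   \code{species}, \code{landtype}, \code{SEP}, \code{maxANPP},
#'   \code{maxAGB}.
#' @export
generate_dynamic_inputs <- function(config, scenario = "baseline") {
  if (!scenario %in% scenario_names())
    stop("unknown scenario: ", scenario)
  dyn <- config$dynamics
  traits <- config$species
  nlt <- config$synthetic$n_landtypes
  ltm <- if (nlt == 1) 1 else seq(dyn$landtype_range[1],
                                  dyn$landtype_range[2], length.out = nlt)
  sp <- traits$code
  bias <- rep(1, length(sp)); names(bias) <- sp
  if (!is.null(dyn$bias_scalars))
    bias[names(dyn$bias_scalars)] <- dyn$bias_scalars

  base <- data.table::CJ(species = sp, landtype = seq_len(nlt))
  i <- match(base$species, sp)
  base$SEP <- traits$sep_mean[i]
  base$maxANPP <- unname(dyn$maxANPP[base$species]) * ltm[base$landtype] *
    bias[base$species]
  base$maxAGB <- unname(dyn$maxAGB[base$species]) * ltm[base$landtype] *
    bias[base$species]

  periods <- if (scenario == "baseline") "baseline" else climate_periods()
  strength <- dyn$stand_strength[[scenario]]
  out <- data.table::rbindlist(lapply(periods, function(p) {
    d <- data.table::copy(base)
    dir <- ifelse(traits$is_conifer[match(d$species, sp)], -1, 1)
    m <- 1 + dir * strength * period_ramp(p)
    d$SEP <- pmin(1, pmax(0, d$SEP * m))
    d$maxANPP <- pmax(0, d$maxANPP * m)
    d$maxAGB <- pmax(0, d$maxAGB * m)
    d$period <- p
    d
  }))
  out$scenario <- scenario
  data.table::setcolorder(out, c("scenario", "period", "species", "landtype",
                                 "SEP", "maxANPP", "maxAGB"))
  data.table::setkeyv(out, c("period", "species", "landtype"))
  out[]
}

#' Generate fire-regime parameters per fire region and climate period
#'
#' Baseline annual burn rates and mean fire sizes are interpolated linearly
#' from the southern to the northern fire region (fire activity increases
#' northward). Under an RCP scenario the burn rate is multiplied by
#' \code{1 + climate_strength[scenario] * ramp(period)}, ramping to its
#' full value in 2071-2100; mean fire size grows with half that signal.
#'
#' @param config a \code{bbwo_config}.
#' @param scenario forcing scenario name.
#' @return A \code{data.table} with columns \code{scenario}, \code{period},
#'   \code{region}, \code{annual_burn_rate}, \code{mean_fire_size}.
#' @export
generate_fire_regime <- function(config, scenario = "baseline") {
  if (!scenario %in% scenario_names()) stop("unknown scenario: ", scenario)
  f <- config$fire
  k <- config$synthetic$n_fire_regions
  rate <- if (k == 1) mean(f$annual_burn_rate) else
    seq(f$annual_burn_rate[1], f$annual_burn_rate[2], length.out = k)
  size <- if (k == 1) mean(f$mean_fire_size) else
    seq(f$mean_fire_size[1], f$mean_fire_size[2], length.out = k)
  periods <- if (scenario == "baseline") "baseline" else climate_periods()
  strength <- f$climate_strength[[scenario]]
  out <- data.table::rbindlist(lapply(periods, function(p) {
    r <- period_ramp(p)
    data.table::data.table(
      scenario = scenario, period = p, region = seq_len(k),
      annual_burn_rate = rate * (1 + strength * r),
      mean_fire_size = size * (1 + 0.5 * strength * r))
  }))
  data.table::setkeyv(out, c("period", "region"))
  out[]
}

#' Build harvest prescriptions for a landscape
#'
#' One prescription per management area: a constant target area per
#' timestep (\code{annual_rate * area * timestep}), clearcutting on public
#' land and the configured partial-harvest class on private land, with
#' eligibility restricted to cells containing a cohort older than
#' \code{eligibility_age}.
#'
#' @param config a \code{bbwo_config}.
#' @param state a [landscape_state()] (supplies management-area areas and
#'   tenure).
#' @return A \code{data.frame} with one row per management area.
#' @export
build_prescriptions <- function(config, state) {
  h <- config$harvest
  mas <- sort(unique(state$management_area))
  area <- vapply(mas, function(m)
    sum(state$management_area == m) * state$grid$cell_area, 0)
  ten <- vapply(mas, function(m)
    state$tenure[match(m, state$management_area)], "")
  data.frame(
    management_area = mas,
    tenure = ten,
    target_area = h$annual_rate * area * state$grid$timestep,
    prescription = ifelse(ten == "private", h$private_prescription,
                          h$public_prescription),
    eligibility_age = h$eligibility_age,
    stringsAsFactors = FALSE)
}
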