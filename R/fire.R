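# Stochastic fire regime: Poisson fire counts per region, lognormal fire
# sizes, and stochastic 4-neighbour spread from a random ignition cell.
# Fires may cross management areas but not fire regions, and stop at the
# grid edge or when no unburned neighbours remain.

# lognormal with arithmetic mean m and coefficient of variation cv
rlnorm_mean_cv <- function(n, m, cv) {
  sdlog2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# 4-neighbours of cells (row-major indexing), NA-free
cell_neighbours4 <- function(cells, grid) {
  r <- cell_row(cells, grid); cc <- cell_col(cells, grid)
  nb <- c(ifelse(r > 1, cells - grid$n_cols, NA),
          ifelse(r < grid$n_rows, cells + grid$n_cols, NA),
          ifelse(cc > 1, cells - 1L, NA),
          ifelse(cc < grid$n_cols, cells + 1L, NA))
  nb[!is.na(nb)]
}

# Grow one fire to (up to) target_cells cells by stochastic accretion.
spread_fire <- function(ignition, target_cells, allowed, burned, grid) {
  fire <- integer(0)
  cand <- ignition
  while (length(fire) < target_cells && length(cand)) {
    i <- if (length(cand) == 1) 1L else sample.int(length(cand), 1L)
    cell <- cand[i]
    cand <- cand[-i]
    if (burned[cell] || !allowed[cell]) next
    burned[cell] <- TRUE
    fire <- c(fire, cell)
    nb <- cell_neighbours4(cell, grid)
    nb <- nb[allowed[nb] & !burned[nb]]
    cand <- c(cand, nb)
  }
  list(fire = fire, burned = burned)
}

#' Simulate one timestep of the fire regime
#'
#' Per fire region: the number of fires is Poisson with mean
#' \code{timestep * fire_occurrence}, where the expected fire occurrence
#' (fires/yr) is \code{annual_burn_rate * region_area / mean_fire_size};
#' each fire's target size is lognormal with the regional mean size and the
#' configured coefficient of variation, and the fire grows from a random
#' ignition cell by stochastic 4-neighbour accretion within the region
#' until it reaches its target size or runs out of unburned neighbours.
#'
#' On burned cells all cohorts are killed except post-fire regeneration:
#' serotinous species re-establish a fresh cohort where a mature cohort was
#' present before the fire, resprouting species where any cohort was
#' present. Time-since-fire is reset to 0 and the pre-fire stand age and
#' conifer fraction are recorded (they drive the burned-habitat classes).
#'
#' @param state a [landscape_state()].
#' @param regime fire-regime table from [generate_fire_regime()].
#' @param period climate period key to look up in \code{regime}.
#' @param config a \code{bbwo_config}.
#' @param traits trait table.
#' @param rate_multiplier scalar multiplier on the annual burn rate
#'   (stress-testing knob; default 1).
#' @return \code{list(state = updated state, burned = logical per-cell
#'   mask)}.
#' @export
simulate_fire <- function(state, regime, period = "baseline",
                          config = default_config(),
                          traits = species_traits(), rate_multiplier = 1) {
  grid <- state$grid
  nc <- n_cells(grid)
  regime <- as.data.frame(regime)  # plain subsetting; period is also a column
  rows <- regime[regime$period == period, ]
  burned <- logical(nc)
  for (reg in sort(unique(state$fire_region))) {
    pr <- rows[rows$region == reg, ]
    if (nrow(pr) != 1)
      stop("fire regime missing for region ", reg, ", period ", period)
    rate <- pr$annual_burn_rate * rate_multiplier
    if (rate <= 0) next
    region_cells <- state$fire_region == reg
    area <- sum(region_cells) * grid$cell_area
    occurrence <- rate * area / pr$mean_fire_size
    n_fires <- stats::rpois(1, grid$timestep * occurrence)
    if (n_fires == 0) next
    sizes <- pmax(grid$cell_area,
                  rlnorm_mean_cv(n_fires, pr$mean_fire_size, config$fire$size_cv))
    for (s in sizes) {
      open <- which(region_cells & !burned)
      if (!length(open)) break
      ign <- if (length(open) == 1) open else sample(open, 1)
      res <- spread_fire(ign, max(1L, round(s / grid$cell_area)),
                         region_cells, burned, grid)
      burned <- res$burned
    }
  }
  if (any(burned)) {
    age_now <- stand_age_map(state)
    cf_now <- conifer_fraction_map(state, traits)
    bc <- which(burned)
    state$pre_fire_age[bc] <- age_now[bc]
    state$pre_fire_conifer[bc] <- cf_now[bc]
    state$time_since_fire[bc] <- 0

    co <- state$cohorts
    inb <- co$cell %in% bc
    pre <- co[inb, ]
    ti <- match(pre$species, traits$code)
    regen_mode <- traits$post_fire_regen[ti]
    sero_ok <- regen_mode == "serotiny" & pre$age >= traits$maturity_age[ti]
    resp_ok <- regen_mode == "resprout"
    regen <- unique(pre[sero_ok | resp_ok, c("cell", "species")])
    co <- co[!inb, ]
    if (nrow(regen)) {
      co <- rbind(co, data.table::data.table(
        cell = regen$cell, species = regen$species,
        age = as.integer(grid$timestep),
        biomass = config$dynamics$establishment_biomass))
    }
    data.table::setkeyv(co, "cell")
    state$cohorts <- co
  }
  list(state = state, burned = burned)
}
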