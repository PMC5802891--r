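# Cohort succession: establishment probability, seed dispersal, growth,
# senescence and recruitment. A stated simplification of biomass-based
# cohort succession: logistic-style, competition-limited growth with
# species shape-parameter modifiers; recruitment gated by seed availability
# (dispersal kernel), light (relative occupancy vs shade tolerance) and the
# per-timestep establishment probability.

#' Establishment probability from a mean establishment time
#'
#' A species needing on average \code{t} years for stems to begin
#' accumulating biomass is treated as a Bernoulli process with annual
#' success probability \code{1/t}; the per-timestep establishment
#' probability is the probability of at least one success in
#' \code{timestep} consecutive annual trials:
#' \deqn{SEP = 1 - (1 - 1/t)^{timestep}}
#'
#' @param t mean establishment time in years (>= 1).
#' @param timestep timestep length in years.
#' @return probability in \[0, 1\].
#' @examples
#' sep_from_establishment_time(5)    # 1 - 0.8^5
#' @export
sep_from_establishment_time <- function(t, timestep = 5) {
  if (any(t < 1)) stop("t must be >= 1")
  1 - (1 - 1 / t)^timestep
}

# Dispersal kernel ---------------------------------------------------------
# Exponential-decay distance kernel truncated at the species' maximum
# dispersal distance, with the decay rate solved so that 95% of dispersal
# falls within the effective dispersal distance.

kernel_rate <- function(effective, maximum, q = 0.95) {
  if (effective >= maximum) return(Inf)
  if (effective / maximum >= q)  # truncation alone already concentrates mass
    return(.Machine$double.eps)
  f <- function(lam) (1 - exp(-lam * effective)) /
    (1 - exp(-lam * maximum)) - q
  stats::uniroot(f, lower = 1e-8, upper = 10, tol = 1e-12)$root
}

# P(dispersal distance <= d) under the truncated kernel
kernel_cdf <- function(d, effective, maximum, q = 0.95) {
  lam <- kernel_rate(effective, maximum, q)
  out <- (1 - exp(-lam * pmin(d, maximum))) / (1 - exp(-lam * maximum))
  out[d < 0] <- 0
  out
}

#' Sample seed dispersal distances for a species
#'
#' Draws from the truncated exponential-decay kernel whose 95% quantile is
#' the species' effective dispersal distance and whose support ends at its
#' maximum dispersal distance.
#'
#' @param n number of draws.
#' @param traits_row one row of [species_traits()].
#' @return numeric vector of distances (m).
#' @export
sample_dispersal_distance <- function(n, traits_row) {
  eff <- traits_row$effective_dispersal
  mx <- traits_row$maximum_dispersal
  lam <- kernel_rate(eff, mx)
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-lam * mx))) / lam
}

# Probability that seed from a source at distance d reaches a cell:
# 1 at d = 0, 0.05 at the effective distance, 0 beyond the maximum.
dispersal_reach_prob <- function(d, traits_row) {
  p <- 1 - kernel_cdf(d, traits_row$effective_dispersal,
                      traits_row$maximum_dispersal)
  p[d <= 0] <- 1
  p[d > traits_row$maximum_dispersal] <- 0
  p
}

# Euclidean distance (m) from every cell to the nearest TRUE cell of mask.
source_distance_m <- function(mask, grid) {
  m <- matrix(0, grid$n_rows, grid$n_cols)
  m[cbind(cell_row(which(mask), grid), cell_col(which(mask), grid))] <- 1
  d <- EBImage::distmap(1 - m)  # distance to nearest source, in cells
  as.numeric(t(d)) * cell_size_m(grid)  # back to row-major cell order
}

#' Per-cell seed-source indicator for one species
#'
#' A cell containing a mature cohort of the species (or any cohort, for
#' vegetatively regenerating species) is always a source for itself. Other
#' cells receive seed stochastically with probability decreasing with
#' Euclidean distance to the nearest mature cohort under the species'
#' dispersal kernel: probability 1 at distance 0, 5% at the effective
#' dispersal distance and 0 beyond the maximum dispersal distance.
#'
#' @param state a [landscape_state()].
#' @param species species code.
#' @param traits trait table.
#' @param stochastic if \code{FALSE}, return the per-cell seed-arrival
#'   probabilities instead of Bernoulli draws.
#' @return logical vector per cell (or numeric probabilities).
#' @export
disperse_seeds <- function(state, species, traits = species_traits(),
                           stochastic = TRUE) {
  tr <- traits[traits$code == species, ]
  if (nrow(tr) != 1) stop("unknown species: ", species)
  nc <- n_cells(state$grid)
  co <- state$cohorts[state$cohorts$species == species, ]
  mature <- logical(nc)
  mature[unique(co$cell[co$age >= tr$maturity_age])] <- TRUE
  self_src <- mature
  if (tr$vegetative_regen) self_src[unique(co$cell)] <- TRUE
  if (!any(mature)) {
    if (stochastic) return(self_src)
    return(as.numeric(self_src))
  }
  d <- source_distance_m(mature, state$grid)
  p <- dispersal_reach_prob(d, tr)
  p[self_src] <- 1
  if (!stochastic) return(p)
  stats::runif(nc) < p
}

# Growth-shape modifier: species with shape 0 grow at full rate at any age;
# shape 1 species slow linearly as cohorts approach longevity.
growth_factor <- function(age, longevity, shape) {
  pmax(0, 1 - shape * age / longevity)
}

# Senescence: negligible biomass loss until cohorts near longevity, then a
# steep rise; the mortality shape parameter (15-25) sets how late and how
# abruptly senescence begins.
senescence_loss <- function(age, longevity, shape) {
  pmin(1, (age / longevity)^shape)
}

#' Advance succession by one timestep
#'
#' Applies, per cell: (1) cohort ages advance by one timestep; (2) cohorts
#' past their species' longevity die, with senescent biomass loss ramping
#' up beforehand according to the mortality shape parameter; (3) each
#' surviving cohort gains biomass
#' \code{timestep * maxANPP * growth_factor * (1 - B_cell / maxAGB)}
#' (kg converted to t/ha), floored at zero, and cell biomass never exceeds
#' the largest applicable maxAGB; (4) each species with a seed source
#' (see [disperse_seeds()]) and adequate light establishes a new
#' timestep-aged cohort with probability SEP.
#'
#' Light adequacy: a species of shade tolerance s establishes only where
#' relative occupancy (cell biomass / its maxAGB) is at or below the
#' configured threshold for s (higher tolerance admits establishment under
#' denser canopies). Establishment is skipped where an immature cohort of
#' the same species is already present.
#'
#' @param state a [landscape_state()].
#' @param dyn dynamic inputs for the current period (rows of
#'   [generate_dynamic_inputs()] with a single \code{period}).
#' @param traits trait table.
#' @param config a \code{bbwo_config} (light thresholds, establishment
#'   biomass).
#' @return The advanced \code{landscape_state} (year unchanged; the run
#'   loop manages calendar time).
#' @export
step_succession <- function(state, dyn, traits = species_traits(),
                            config = default_config()) {
  grid <- state$grid
  ts <- grid$timestep
  co <- data.table::copy(state$cohorts)
  dyn <- data.table::as.data.table(dyn)
  if (length(unique(dyn$period)) > 1)
    stop("dyn must contain a single climate period")

  present <- unique(data.frame(species = co$species,
                               landtype = state$landtype[co$cell]))
  have <- paste(dyn$species, dyn$landtype)
  missing <- setdiff(paste(present$species, present$landtype), have)
  if (length(missing))
    stop("missing dynamic inputs for: ", paste(missing, collapse = "; "))

  ti <- match(co$species, traits$code)
  if (anyNA(ti)) stop("unknown species in cohort table")
  longv <- traits$longevity[ti]

  # (1) aging
  co$age <- co$age + as.integer(ts)

  # (2) senescence and longevity mortality
  loss <- senescence_loss(co$age, longv, traits$mortality_shape[ti])
  co$biomass <- co$biomass * (1 - loss)
  keep <- co$age <= longv
  co <- co[keep, ]; ti <- ti[keep]; longv <- longv[keep]

  # (3) competition-limited growth
  if (nrow(co)) {
    di <- match(paste(co$species, state$landtype[co$cell]), have)
    btot <- numeric(n_cells(grid))
    agg <- co[, list(b = sum(biomass)), by = "cell"]
    btot[agg$cell] <- agg$b
    gf <- growth_factor(co$age, longv, traits$growth_shape[ti])
    room <- pmax(0, 1 - btot[co$cell] / dyn$maxAGB[di])
    incr <- pmax(0, ts * dyn$maxANPP[di] / 1000 * gf * room)
    co$biomass <- co$biomass + incr
    # cap: cell biomass must not exceed the largest applicable maxAGB
    agg2 <- co[, list(b = sum(biomass)), by = "cell"]
    cap <- co[, list(cap = max(dyn$maxAGB[di[.I]])), by = "cell"]
    over <- agg2$b > cap$cap
    if (any(over)) {
      sc <- rep(1, n_cells(grid))
      sc[agg2$cell[over]] <- cap$cap[over] / agg2$b[over]
      co$biomass <- co$biomass * sc[co$cell]
    }
  }

  # (4) establishment
  btot <- numeric(n_cells(grid))
  if (nrow(co)) {
    agg <- co[, list(b = sum(biomass)), by = "cell"]
    btot[agg$cell] <- agg$b
  }
  state2 <- state; state2$cohorts <- co
  lth <- config$dynamics$light_thresholds
  new_list <- list()
  for (sp in intersect(unique(dyn$species), traits$code)) {
    tr <- traits[traits$code == sp, ]
    spco <- co[co$species == sp, ]
    has_mature <- any(spco$age >= tr$maturity_age)
    if (!has_mature && !(tr$vegetative_regen && nrow(spco))) next
    seeded <- disperse_seeds(state2, sp, traits)
    if (!any(seeded)) next
    di <- match(paste(sp, state$landtype), have)
    light_ok <- btot / dyn$maxAGB[di] <= lth[tr$shade_tolerance]
    blocked <- logical(n_cells(grid))
    blocked[unique(spco$cell[spco$age < tr$maturity_age])] <- TRUE
    cand <- which(seeded & light_ok & !blocked)
    if (!length(cand)) next
    est <- cand[stats::runif(length(cand)) < dyn$SEP[di[cand]]]
    if (length(est))
      new_list[[sp]] <- data.table::data.table(
        cell = est, species = sp, age = as.integer(ts),
        biomass = config$dynamics$establishment_biomass)
  }
  if (length(new_list))
    co <- rbind(co, data.table::rbindlist(new_list))
  co <- co[co$biomass > 1e-9, ]  # senescent/defoliated remnants die out
  data.table::setkeyv(co, "cell")
  state$cohorts <- co
  state
}
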