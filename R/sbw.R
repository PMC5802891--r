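# Spruce budworm outbreaks: a background disturbance on a fixed recurrence
# cycle. Outbreaks defoliate host conifers, with mortality decreasing along
# the host-vulnerability ranking (balsam fir > white spruce > red spruce >
# black spruce) and reduced in young cohorts.

#' Is a budworm outbreak active in a given simulation year?
#'
#' Outbreaks recur every \code{recurrence} years (measured from
#' \code{phase}) and last at most \code{max_duration} years: with the
#' default phase 0 and 35-yr recurrence, simulation years \[35, 45) and
#' \[70, 80) of a 100-yr run are outbreak-active.
#'
#' @param year_rel years since the simulation origin.
#' @param params the \code{sbw} section of a \code{bbwo_config}.
#' @return logical.
#' @export
sbw_active <- function(year_rel, params) {
  t <- year_rel - params$phase
  t >= params$recurrence & (t %% params$recurrence) < params$max_duration
}

#' Apply one timestep of spruce budworm disturbance
#'
#' Outside outbreak-active timesteps the state is returned unchanged.
#' During an outbreak, each host cohort loses the fraction of biomass
#' configured for its species in the vulnerability ranking, halved (by
#' default) for cohorts at or below the young-age threshold; non-host
#' species are untouched. Cohorts reduced to negligible biomass die.
#'
#' @param state a [landscape_state()].
#' @param params the \code{sbw} section of a \code{bbwo_config}.
#' @param year_rel years since the simulation origin (defaults to the
#'   state's own clock).
#' @return The updated \code{landscape_state}.
#' @export
apply_sbw <- function(state, params,
                      year_rel = state$year - state$grid$origin_year) {
  if (!sbw_active(year_rel, params)) return(state)
  co <- data.table::copy(state$cohorts)
  hi <- match(co$species, params$host_ranking)
  hosts <- !is.na(hi)
  if (!any(hosts)) return(state)
  frac <- params$susceptibility[hi[hosts]]
  frac <- frac * ifelse(co$age[hosts] <= params$young_age,
                        params$young_factor, 1)
  co$biomass[hosts] <- co$biomass[hosts] * (1 - frac)
  co <- co[co$biomass > 1e-9, ]
  state$cohorts <- co
  state
}
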