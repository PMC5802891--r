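# Harvesting: constant-area targets per management area, restricted to
# stands containing cohorts older than the eligibility age. Clearcutting
# removes all cohorts except the youngest (0-5 yr) age class; partial
# prescriptions remove a biomass fraction drawn uniformly within the
# prescription class bounds, applied proportionally across cohorts.

#' Apply one timestep of harvesting
#'
#' Per management area: cells containing a cohort older than the
#' eligibility age are eligible; cells are drawn at random among them until
#' the constant area target is reached or eligible cells run out (the
#' shortfall is reported). \code{clearcut} removes all cohorts older than
#' one timestep; \code{partial_low} (1-40% of biomass) and
#' \code{partial_high} (41-80%) remove a fraction drawn uniformly within
#' the class bounds per event.
#'
#' @param state a [landscape_state()].
#' @param prescriptions table from [build_prescriptions()].
#' @param config a \code{bbwo_config} (partial-class bounds).
#' @return \code{list(state = updated state, harvested = logical per-cell
#'   mask, report = data.frame per management area with target, harvested
#'   and shortfall areas in ha)}.
#' @export
apply_harvest <- function(state, prescriptions, config = default_config()) {
  grid <- state$grid
  nc <- n_cells(grid)
  harvested <- logical(nc)
  co <- data.table::copy(state$cohorts)
  reports <- list()
  bounds <- list(partial_low = config$harvest$partial_low,
                 partial_high = config$harvest$partial_high)
  for (i in seq_len(nrow(prescriptions))) {
    p <- prescriptions[i, ]
    ma_cells <- state$management_area == p$management_area
    elig_cells <- unique(co$cell[co$age > p$eligibility_age])
    elig <- elig_cells[ma_cells[elig_cells]]
    n_target <- round(p$target_area / grid$cell_area)
    n_cut <- min(n_target, length(elig))
    cut <- if (n_cut == 0) integer(0)
    else if (length(elig) == 1) elig
    else sample(elig, n_cut)
    harvested[cut] <- TRUE
    if (length(cut)) {
      incut <- co$cell %in% cut
      if (p$prescription == "clearcut") {
        co <- co[!(incut & co$age > grid$timestep), ]
      } else if (p$prescription %in% names(bounds)) {
        b <- bounds[[p$prescription]]
        frac <- stats::runif(1, b[1], b[2])
        co$biomass[incut] <- co$biomass[incut] * (1 - frac)
      } else stop("unknown prescription: ", p$prescription)
    }
    reports[[i]] <- data.frame(
      management_area = p$management_area,
      prescription = p$prescription,
      target_area = n_target * grid$cell_area,
      eligible_area = length(elig) * grid$cell_area,
      harvested_area = n_cut * grid$cell_area,
      shortfall = max(0, n_target - n_cut) * grid$cell_area)
  }
  co <- co[co$biomass > 1e-9, ]
  data.table::setkeyv(co, "cell")
  state$cohorts <- co
  list(state = state, harvested = harvested,
       report = do.call(rbind, reports))
}
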