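# Black-backed Woodpecker habitat: rule-based reclassification of the
# simulated layers into six habitat types, aggregation of same-type cells
# into contiguous patches, home-range eligibility thresholds, and potential
# productivity (fledglings/yr) with per-type relative contributions.

snapshot_layers <- function(x, traits) {
  if (inherits(x, "landscape_state")) {
    list(year = x$year,
         stand_age = stand_age_map(x),
         conifer_fraction = conifer_fraction_map(x, traits),
         time_since_fire = x$time_since_fire,
         pre_fire_age = x$pre_fire_age,
         pre_fire_conifer = x$pre_fire_conifer,
         grid = x$grid)
  } else x
}

#' Classify cells into woodpecker habitat types
#'
#' Applies the habitat rules in precedence order: (1) cells 1-5 yr
#' post-fire are "recently burned old coniferous" when the pre-fire stand
#' was at least 80 yr old and coniferous, "recently burned young
#' coniferous" when younger and coniferous, and non-habitat otherwise;
#' (2) cells 6-10 yr post-fire with an old coniferous pre-fire stand are
#' "older burned coniferous"; (3) unburned cells (including > 10 yr
#' post-fire) at least 80 yr old are "old coniferous unburned" when
#' coniferous and "old mixed unburned" when mixed; (4) everything else is
#' non-habitat. "Coniferous" means a conifer biomass fraction at or above
#' \code{conif_threshold} (default 0.75); "mixed" means between
#' \code{mixed_lower} (default 0.25) and the coniferous threshold. Burned
#' cells are judged on the composition recorded at burn time, since live
#' post-fire biomass is near zero.
#'
#' @param state a [landscape_state()] or a \code{bbwo_sim} snapshot.
#' @param config a \code{bbwo_config} (thresholds).
#' @param grid the \code{grid_spec} (required when \code{state} is a bare
#'   snapshot without one).
#' @return An object of class \code{habitat_map}: a per-cell factor of the
#'   six labels plus the year and grid.
#' @export
classify_habitat <- function(state, config = default_config(), grid = NULL) {
  sl <- snapshot_layers(state, config$species)
  if (is.null(grid)) grid <- sl$grid
  if (is.null(grid)) stop("grid must be supplied for bare snapshots")
  for (nm in c("stand_age", "conifer_fraction", "time_since_fire",
               "pre_fire_age", "pre_fire_conifer"))
    if (is.null(sl[[nm]])) stop("missing layer: ", nm)
  hb <- config$habitat
  age <- sl$stand_age
  cf <- sl$conifer_fraction
  tsf <- sl$time_since_fire
  pfa <- sl$pre_fire_age
  pfc <- sl$pre_fire_conifer
  nc <- length(age)

  lab <- rep("NON_HABITAT", nc)
  w15 <- !is.na(tsf) & tsf >= 1 & tsf <= 5
  w610 <- !is.na(tsf) & tsf >= 6 & tsf <= 10
  unb <- is.na(tsf) | tsf > 10  # a cell burned this very step is neither

  pre_con <- !is.na(pfc) & pfc >= hb$conif_threshold
  pre_old <- !is.na(pfa) & pfa >= hb$old_age

  lab[w15 & pre_con & pre_old] <- "BURNED_OLD_CONIF_1_5"
  lab[w15 & pre_con & !pre_old] <- "BURNED_YOUNG_CONIF_1_5"
  lab[w610 & pre_con & pre_old] <- "BURNED_OLD_CONIF_6_10"

  old_unb <- unb & age >= hb$old_age
  # the burn-window rules above take precedence over the unburned rules
  lab[old_unb & cf >= hb$conif_threshold] <- "OLD_CONIF_UNBURNED"
  lab[old_unb & cf >= hb$mixed_lower & cf < hb$conif_threshold] <-
    "OLD_MIXED_UNBURNED"

  structure(list(labels = factor(lab, levels = habitat_labels()),
                 year = sl$year, grid = grid), class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat(sprintf("<habitat_map> year %s, %d x %d cells\n", format(x$year),
              x$grid$n_rows, x$grid$n_cols))
  print(table(x$labels))
  invisible(x)
}

# Connected-component labelling by union-find over same-label neighbours.
# Returns an integer component id per cell (0 for cells to be ignored).
label_components <- function(labels, grid, connectivity = 4L,
                             ignore = "NON_HABITAT") {
  nc <- n_cells(grid)
  lab <- as.character(labels)
  active <- !(lab %in% ignore)
  parent <- seq_len(nc)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }
  cells <- which(active)
  r <- cell_row(cells, grid); cc <- cell_col(cells, grid)
  link <- function(nb_ok, nb) {
    nb <- ifelse(nb_ok, nb, 1L)  # clamp invalid indices; masked out below
    same <- nb_ok & active[nb] & lab[nb] == lab[cells]
    for (k in which(same)) union(cells[k], nb[k])
  }
  # look only "backwards" (left, up, and the two upper diagonals for
  # 8-connectivity) so every adjacency is visited once
  link(cc > 1, cells - 1L)
  link(r > 1, cells - grid$n_cols)
  if (connectivity == 8L) {
    link(r > 1 & cc > 1, cells - grid$n_cols - 1L)
    link(r > 1 & cc < grid$n_cols, cells - grid$n_cols + 1L)
  } else if (connectivity != 4L) stop("connectivity must be 4 or 8")
  comp <- integer(nc)
  roots <- vapply(cells, find, 0L)
  comp[cells] <- as.integer(factor(roots))
  comp
}

#' Aggregate a habitat map into contiguous patches
#'
#' Groups spatially contiguous cells of the same habitat type into patches
#' (rook 4-neighbour contiguity by default, queen 8-neighbour optional),
#' computes each patch's area, and flags patches at least as large as the
#' mean home range of their habitat type as eligible to support breeding.
#'
#' @param habitat a \code{habitat_map} from [classify_habitat()].
#' @param connectivity 4 or 8.
#' @param coefficients habitat coefficient table (home ranges).
#' @return An object of class \code{habitat_patches}: a patch table
#'   (\code{patch}, \code{type}, \code{n_cells}, \code{area},
#'   \code{eligible}) plus the per-cell patch ids.
#' @export
aggregate_patches <- function(habitat, connectivity = 4L,
                              coefficients = habitat_coefficients()) {
  grid <- habitat$grid
  comp <- label_components(habitat$labels, grid, as.integer(connectivity))
  idx <- which(comp > 0)
  if (!length(idx)) {
    tab <- data.frame(patch = integer(), type = character(),
                      n_cells = integer(), area = numeric(),
                      eligible = logical())
  } else {
    dt <- data.table::data.table(patch = comp[idx],
                                 type = as.character(habitat$labels[idx]))
    tab <- dt[, list(type = type[1], n_cells = .N), by = "patch"]
    data.table::setorderv(tab, "patch")
    tab <- as.data.frame(tab)
    tab$area <- tab$n_cells * grid$cell_area
    hr <- coefficients$home_range[match(tab$type, coefficients$type)]
    tab$eligible <- tab$area >= hr
  }
  structure(list(patches = tab, cell_patch = comp, year = habitat$year,
                 grid = grid), class = "habitat_patches")
}

#' @export
print.habitat_patches <- function(x, ...) {
  cat(sprintf("<habitat_patches> %d patches (%d eligible), year %s\n",
              nrow(x$patches), sum(x$patches$eligible), format(x$year)))
  invisible(x)
}

#' Potential woodpecker productivity of a patch set
#'
#' Per habitat type, potential productivity is the number of eligible
#' patches multiplied by the mean productivity per home range
#' (fledglings/yr); an alternative reading
#' (\code{count_mode = "home_ranges"}) counts whole home ranges fitting in
#' each patch instead. Densities are normalized per 100 km2 (10,000 ha)
#' of landscape, and each type's relative contribution is its share of
#' total productivity (reported as 0, with \code{undefined = TRUE}, when
#' total productivity is zero).
#'
#' @param patches a \code{habitat_patches} object.
#' @param coefficients habitat coefficient table.
#' @param landscape_area landscape area in hectares (defaults to the full
#'   grid area).
#' @param count_mode \code{"patches"} (eligible patch count) or
#'   \code{"home_ranges"} (floor(area / home range) summed over patches).
#' @return An object of class \code{productivity_report} with a per-type
#'   table and totals.
#' @export
compute_productivity <- function(patches,
                                 coefficients = habitat_coefficients(),
                                 landscape_area = NULL,
                                 count_mode = "patches") {
  grid <- patches$grid
  if (is.null(landscape_area))
    landscape_area <- n_cells(grid) * grid$cell_area
  tab <- patches$patches
  per <- coefficients[, c("type", "home_range", "productivity")]
  names(per)[3] <- "per_home_range"
  if (count_mode == "patches") {
    cnt <- vapply(per$type, function(ty)
      sum(tab$eligible & tab$type == ty), 0)
  } else if (count_mode == "home_ranges") {
    cnt <- vapply(seq_len(nrow(per)), function(i)
      sum(floor(tab$area[tab$type == per$type[i]] / per$home_range[i])), 0)
  } else stop("count_mode must be 'patches' or 'home_ranges'")
  per$eligible_patches <- unname(cnt)
  per$productivity <- per$eligible_patches * per$per_home_range
  total <- sum(per$productivity)
  undefined <- total <= 0
  per$contribution <- if (undefined) 0 else per$productivity / total
  per$density <- per$productivity * 1e4 / landscape_area
  structure(list(table = per, total = total,
                 density = total * 1e4 / landscape_area,
                 landscape_area = landscape_area,
                 undefined = undefined, year = patches$year),
            class = "productivity_report")
}

#' @export
print.productivity_report <- function(x, ...) {
  cat(sprintf("<productivity_report> year %s\n", format(x$year)))
  print(x$table[, c("type", "eligible_patches", "productivity",
                    "density", "contribution")], row.names = FALSE)
  cat(sprintf("total %.2f fledglings/yr (%.2f per 100 km2)%s\n", x$total,
              x$density,
              if (x$undefined) " [no eligible habitat: contributions undefined]"
              else ""))
  invisible(x)
}

#' Productivity time series of a simulation
#'
#' Classifies every retained snapshot of a simulation, aggregates patches
#' and computes potential productivity, returning one row per year and
#' habitat type plus a \code{TOTAL} row per year.
#'
#' @param sim a \code{bbwo_sim} from [run_simulation()].
#' @param config a \code{bbwo_config}.
#' @return A \code{data.table} with columns \code{year}, \code{type},
#'   \code{eligible_patches}, \code{productivity}, \code{density},
#'   \code{contribution}.
#' @export
productivity_series <- function(sim, config = default_config()) {
  hb <- config$habitat
  rows <- lapply(sim$snapshots, function(sn) {
    hm <- classify_habitat(sn, config, grid = sim$grid)
    pr <- compute_productivity(
      aggregate_patches(hm, hb$connectivity, hb$coefficients),
      hb$coefficients, count_mode = hb$count_mode)
    t1 <- data.table::as.data.table(
      pr$table[, c("type", "eligible_patches", "productivity", "density",
                   "contribution")])
    t1 <- rbind(t1, data.table::data.table(
      type = "TOTAL", eligible_patches = sum(t1$eligible_patches),
      productivity = pr$total, density = pr$density,
      contribution = if (pr$undefined) 0 else 1))
    t1$year <- sn$year
    t1
  })
  out <- data.table::rbindlist(rows)
  data.table::setcolorder(out, c("year", "type"))
  out[]
}
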