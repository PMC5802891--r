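# Factorial simulation design and sensitivity statistics: three drivers of
# change (harvesting, climate-induced fire-regime change, climate-induced
# stand-scale change) crossed 2x2x2 within each forcing scenario, with
# paired seeds across toggle combinations; effect sizes by omega-squared
# from a three-way factorial ANOVA; percentage differences in productivity
# (delta-Prod) and per-species biomass (delta-B) between the full model and
# reduced models omitting one driver.

#' Run the full factorial simulation experiment
#'
#' For each scenario, replicate and combination of the three driver
#' toggles (harvest on/off, fire-regime climate update on/off, stand-scale
#' climate update on/off), runs one simulation. Replicate r uses the same
#' initial landscape and the same master seed across all toggle
#' combinations and scenarios (a paired design), so factor contrasts are
#' not confounded by landscape or draw differences. With the study design
#' (5 replicates, 3 scenarios) this is 120 runs.
#'
#' @param config a \code{bbwo_config}.
#' @param scenarios character vector of RCP scenario names.
#' @param replicates number of replicates.
#' @param seed_base integer; replicate r uses \code{seed_base + r}.
#' @return An object of class \code{bbwo_factorial}:
#'   \code{$productivity} (one row per run x timestep: total potential
#'   productivity and density) and \code{$agb} (one row per run x
#'   timestep x species: landscape-mean AGB, t/ha).
#' @export
run_factorial <- function(config, scenarios = c("rcp26", "rcp45", "rcp85"),
                          replicates = 5, seed_base = 100) {
  bad <- setdiff(scenarios, setdiff(scenario_names(), "baseline"))
  if (length(bad)) stop("unknown scenario(s): ", paste(bad, collapse = ", "))
  combos <- expand.grid(harvest = c(TRUE, FALSE), fire_climate = c(TRUE, FALSE),
                        stand_climate = c(TRUE, FALSE))
  prod_rows <- list(); agb_rows <- list()
  run_id <- 0L
  for (r in seq_len(replicates)) {
    init <- generate_initial_landscape(config, seed = seed_base + r)
    for (scn in scenarios) {
      for (i in seq_len(nrow(combos))) {
        run_id <- run_id + 1L
        tg <- as.list(combos[i, ])
        sim <- run_simulation(init, scn, toggles = tg, seed = seed_base + r,
                              config = config)
        ps <- productivity_series(sim, config)
        tot <- ps[ps$type == "TOTAL", ]
        meta <- data.table::data.table(
          run_id = run_id, scenario = scn, replicate = r,
          harvest = tg$harvest, fire_climate = tg$fire_climate,
          stand_climate = tg$stand_climate)
        prod_rows[[run_id]] <- cbind(meta[rep(1, nrow(tot)), ],
                                     tot[, c("year", "productivity",
                                             "density")])
        agb <- sim$agb
        agb_rows[[run_id]] <- cbind(meta[rep(1, nrow(agb)), ], agb)
      }
    }
  }
  structure(list(productivity = data.table::rbindlist(prod_rows),
                 agb = data.table::rbindlist(agb_rows),
                 scenarios = scenarios, replicates = replicates,
                 seed_base = seed_base),
            class = "bbwo_factorial")
}

#' @export
print.bbwo_factorial <- function(x, ...) {
  n_runs <- length(unique(x$productivity$run_id))
  cat(sprintf("<bbwo_factorial> %d runs (%d replicates x 8 toggle combinations x %d scenarios)\n",
              n_runs, x$replicates, length(x$scenarios)))
  invisible(x)
}

#' Three-way factorial ANOVA decomposition
#'
#' Balanced-design type-I sums of squares for the three driver main
#' effects, the three two-way interactions and the three-way interaction,
#' with the error term estimated from within-cell replication. The input
#' must be a balanced 2x2x2 design with at least two replicates per cell.
#'
#' @param df data.frame with logical/factor columns \code{harvest},
#'   \code{fire_climate}, \code{stand_climate} and a numeric
#'   \code{response} column.
#' @param response name of the response column.
#' @return An object of class \code{anova_decomp}: an effect table
#'   (\code{effect}, \code{SS}, \code{df}), \code{MS_error},
#'   \code{SS_error}, \code{df_error} and \code{SS_tot}.
#' @export
compute_anova <- function(df, response = "response") {
  df <- as.data.frame(df)
  need <- c("harvest", "fire_climate", "stand_climate", response)
  if (!all(need %in% names(df)))
    stop("df must have columns ", paste(need, collapse = ", "))
  H <- factor(df$harvest); F_ <- factor(df$fire_climate)
  S <- factor(df$stand_climate)
  if (nlevels(H) != 2 || nlevels(F_) != 2 || nlevels(S) != 2)
    stop("each factor must have exactly two levels")
  counts <- table(H, F_, S)
  if (length(unique(as.vector(counts))) != 1)
    stop("unbalanced design: unequal cell counts")
  if (counts[1] < 2) stop("at least two replicates per cell are required")
  y <- df[[response]]
  fit <- stats::aov(y ~ H * F_ * S)
  an <- suppressWarnings(stats::anova(fit))
  terms <- rownames(an)
  name_map <- c("H" = "harvest", "F_" = "fire", "S" = "stand",
                "H:F_" = "harvest:fire", "H:S" = "harvest:stand",
                "F_:S" = "fire:stand", "H:F_:S" = "harvest:fire:stand")
  eff <- terms != "Residuals"
  tab <- data.frame(effect = unname(name_map[terms[eff]]),
                    SS = an$`Sum Sq`[eff], df = an$Df[eff],
                    stringsAsFactors = FALSE)
  SS_error <- an$`Sum Sq`[!eff]; df_error <- an$Df[!eff]
  structure(list(effects = tab, SS_error = SS_error, df_error = df_error,
                 MS_error = SS_error / df_error,
                 SS_tot = sum(an$`Sum Sq`), n = length(y),
                 response_scale = mean(y^2)),
            class = "anova_decomp")
}

#' @export
print.anova_decomp <- function(x, ...) {
  cat("<anova_decomp>\n")
  print(x$effects, row.names = FALSE)
  cat(sprintf("SS_error %.4g (df %d), SS_tot %.4g\n", x$SS_error,
              x$df_error, x$SS_tot))
  invisible(x)
}

#' Omega-squared effect size
#'
#' The share of response variance attributable to an effect:
#' \deqn{\omega^2 = \frac{SS_{effect} - df_{effect} \, MS_{error}}
#'                       {MS_{error} + SS_{tot}}}
#' Values can be negative when the effect sum of squares falls below its
#' error expectation; they are reported as computed, not clamped.
#'
#' @param decomp an \code{anova_decomp}, or a list with elements
#'   \code{SS_effect}, \code{df_effect}, \code{MS_error}, \code{SS_tot}.
#' @param effect effect name (e.g. \code{"harvest"}) when \code{decomp}
#'   is an \code{anova_decomp}.
#' @return numeric omega-squared.
#' @examples
#' omega_squared(list(SS_effect = 80, df_effect = 1, MS_error = 2,
#'                    SS_tot = 100))  # 78/102
#' @export
omega_squared <- function(decomp, effect = NULL) {
  if (inherits(decomp, "anova_decomp")) {
    if (is.null(effect)) stop("effect must be named")
    i <- match(effect, decomp$effects$effect)
    if (is.na(i)) stop("unknown effect: ", effect)
    ss <- decomp$effects$SS[i]; dfe <- decomp$effects$df[i]
    mse <- decomp$MS_error; sst <- decomp$SS_tot
    # an (essentially) constant response carries no variance to attribute
    if (sst <= 1e-12 * max(decomp$n * decomp$response_scale, 1e-300))
      stop("degenerate data: all responses identical (zero variance)")
  } else {
    ss <- decomp$SS_effect; dfe <- decomp$df_effect
    mse <- decomp$MS_error; sst <- decomp$SS_tot
  }
  den <- mse + sst
  if (!is.finite(den) || den <= 0)
    stop("degenerate data: all responses identical (zero variance)")
  (ss - dfe * mse) / den
}

#' Omega-squared for every effect of a decomposition
#' @param decomp an \code{anova_decomp}.
#' @return named numeric vector over the seven effects.
#' @export
omega_squared_all <- function(decomp) {
  out <- vapply(decomp$effects$effect, function(e)
    omega_squared(decomp, e), 0)
  names(out) <- decomp$effects$effect
  out
}

# core percentage difference; flags an undefined denominator
pct_difference <- function(full, reduced) {
  mf <- mean(full); mr <- mean(reduced)
  if (!is.finite(mr) || mr == 0)
    return(structure(NA_real_, undefined = TRUE))
  structure(100 * (mf - mr) / mr, undefined = FALSE)
}

#' Percentage productivity difference between full and reduced models
#'
#' \code{100 * (mean(full) - mean(reduced)) / mean(reduced)} over paired
#' replicate values at one timestep: the full model includes all drivers,
#' the reduced model omits the driver of interest (harvesting omitted, or
#' fire regime / stand-scale parameters held at baseline calibration). A
#' negative value means the driver lowers productivity. Undefined (NA,
#' with attribute \code{undefined}) when the reduced-model mean is zero.
#'
#' @param full,reduced numeric vectors of replicate responses.
#' @return percentage, with attribute \code{undefined}.
#' @export
delta_prod <- function(full, reduced) pct_difference(full, reduced)

#' Percentage species-biomass difference between full and reduced models
#'
#' The [delta_prod()] contract applied to landscape-mean aboveground
#' biomass of a single species. Undefined (NA) when the species is absent
#' from the reduced runs.
#'
#' @param full,reduced numeric vectors of replicate mean AGB values.
#' @return percentage, with attribute \code{undefined}.
#' @export
delta_biomass <- function(full, reduced) pct_difference(full, reduced)

driver_cols <- function() c(harvest = "harvest", fire = "fire_climate",
                            stand = "stand_climate")

# split a factorial table into full-model rows and reduced-model rows for
# one driver (the driver's toggle FALSE, the other two TRUE)
full_reduced <- function(tab, driver) {
  cols <- driver_cols()
  if (!driver %in% names(cols)) stop("unknown driver: ", driver)
  on <- tab[[cols[["harvest"]]]] & tab[[cols[["fire"]]]] &
    tab[[cols[["stand"]]]]
  off <- !tab[[cols[[driver]]]]
  for (d in setdiff(names(cols), driver)) off <- off & tab[[cols[[d]]]]
  list(full = tab[on, ], reduced = tab[off, ])
}

#' Sensitivity analysis of a factorial experiment
#'
#' For each scenario and timestep, decomposes total potential productivity
#' by three-way factorial ANOVA and reports omega-squared per driver
#' together with delta-Prod (full vs reduced model, paired replicates).
#' Interaction omega-squared values are computed (see
#' [omega_squared_all()]) but only the three driver main effects are
#' reported here.
#'
#' @param fact a \code{bbwo_factorial} from [run_factorial()].
#' @return An object of class \code{sensitivity_result}: a
#'   \code{data.table} with columns \code{scenario}, \code{year},
#'   \code{driver}, \code{omega2}, \code{delta_prod}, plus the list of
#'   per-(scenario, year) ANOVA decompositions.
#' @export
sensitivity_analysis <- function(fact) {
  tab <- fact$productivity
  rows <- list(); decomps <- list()
  for (scn in unique(tab$scenario)) {
    for (yr in sort(unique(tab$year))) {
      sl <- tab[tab$scenario == scn & tab$year == yr, ]
      dec <- tryCatch(compute_anova(sl, response = "productivity"),
                      error = function(e) NULL)
      key <- paste(scn, yr, sep = "_")
      decomps[[key]] <- dec
      for (drv in names(driver_cols())) {
        om <- if (is.null(dec)) NA_real_ else
          tryCatch(omega_squared(dec, drv), error = function(e) NA_real_)
        fr <- full_reduced(sl, drv)
        dp <- delta_prod(fr$full$productivity, fr$reduced$productivity)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          scenario = scn, year = yr, driver = drv, omega2 = om,
          delta_prod = as.numeric(dp))
      }
    }
  }
  structure(list(table = data.table::rbindlist(rows), decomps = decomps),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result>\n")
  tb <- x$table
  last <- tb[tb$year == max(tb$year), ]
  cat("final-year summary:\n")
  print(as.data.frame(last), row.names = FALSE)
  invisible(x)
}

#' Per-species biomass sensitivity (delta-B)
#'
#' [delta_biomass()] applied per scenario, timestep, driver and species to
#' the factorial AGB table.
#'
#' @param fact a \code{bbwo_factorial}.
#' @return \code{data.table} with columns \code{scenario}, \code{year},
#'   \code{driver}, \code{species}, \code{delta_b}, \code{undefined}.
#' @export
biomass_sensitivity <- function(fact) {
  tab <- fact$agb
  rows <- list()
  for (scn in unique(tab$scenario)) {
    for (drv in names(driver_cols())) {
      fr <- full_reduced(tab[tab$scenario == scn, ], drv)
      yrs <- sort(unique(tab$year))
      for (yr in yrs) {
        f <- fr$full[fr$full$year == yr, ]
        rd <- fr$reduced[fr$reduced$year == yr, ]
        per_run <- function(d, sp) {
          # one AGB value per run, zero where the species is absent
          ids <- unique(d$run_id)
          v <- d$agb[match(paste(ids, sp), paste(d$run_id, d$species))]
          v[is.na(v)] <- 0
          v
        }
        for (sp in unique(c(f$species, rd$species))) {
          db <- delta_biomass(per_run(f, sp), per_run(rd, sp))
          rows[[length(rows) + 1L]] <- data.table::data.table(
            scenario = scn, year = yr, driver = drv, species = sp,
            delta_b = as.numeric(db),
            undefined = isTRUE(attr(db, "undefined")))
        }
      }
    }
  }
  data.table::rbindlist(rows)
}
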