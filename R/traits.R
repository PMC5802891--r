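#' Life-history traits of boreal and northern temperate tree species
#'
#' Returns the species trait table used by the succession, dispersal and
#' disturbance routines: longevity, age at sexual maturity, shade tolerance
#' (ordinal 1 = least to 5 = most tolerant), effective seed dispersal distance
#' (metres, the distance within which 95% of seeds fall), maximum seed
#' dispersal distance (metres), whether the species regenerates vegetatively,
#' its post-fire regeneration mode (\code{"none"}, \code{"resprout"} or
#' \code{"serotiny"}), shape parameters controlling the growth and senescence
#' curves, the mean landscape-level establishment probability per 5-yr
#' timestep under baseline climate, and a conifer/deciduous flag.
#'
#' @param species optional character vector of species codes to subset to.
#' @return A \code{data.frame} with one row per species, keyed by \code{code}.
#' @examples
#' traits <- species_traits()
#' traits[traits$code == "PICE.MAR", ]
#' @export
species_traits <- function(species = NULL) {
  tr <- data.frame(
    code = c("ABIE.BAL", "ACER.RUB", "ACER.SAH", "BETU.ALL", "BETU.PAP",
             "FAGU.GRA", "LARI.LAR", "PICE.GLA", "PICE.MAR", "PICE.RUB",
             "PINU.BAN", "PINU.RES", "PINU.STR", "POPU.TRE", "QUER.RUB",
             "THUJ.OCC", "TSUG.CAN"),
    longevity = c(150L, 150L, 300L, 300L, 150L, 250L, 150L, 200L, 200L,
                  300L, 150L, 200L, 300L, 150L, 250L, 300L, 300L),
    maturity_age = c(30L, 10L, 40L, 40L, 20L, 40L, 40L, 30L, 30L, 30L,
                     20L, 40L, 20L, 20L, 30L, 30L, 60L),
    shade_tolerance = c(5L, 3L, 5L, 3L, 2L, 5L, 1L, 3L, 4L, 4L, 1L, 2L,
                        3L, 1L, 3L, 5L, 5L),
    effective_dispersal = c(25, 100, 100, 100, 200, 30, 50, 100, 80, 100,
                            30, 12, 100, 1000, 30, 45, 30),
    maximum_dispersal = c(160, 200, 200, 400, 5000, 3000, 200, 303, 200,
                          303, 100, 275, 250, 5000, 3000, 60, 100),
    vegetative_regen = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                         FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                         FALSE, FALSE),
    post_fire_regen = c("none", "resprout", "resprout", "resprout",
                        "resprout", "none", "none", "none", "serotiny",
                        "none", "serotiny", "none", "none", "resprout",
                        "resprout", "none", "none"),
    growth_shape = c(0, 0, 1, 1, 0, 1, 0, 1, 1, 1, 0, 1, 1, 0, 1, 1, 1),
    mortality_shape = c(25, 25, 15, 15, 25, 15, 25, 15, 15, 15, 25, 15,
                        15, 25, 15, 15, 15),
    sep_mean = c(0.48, 0.31, 0.30, 0.29, 0.55, 0.27, 0.54, 0.43, 0.36,
                 0.25, 0.54, 0.32, 0.30, 0.59, 0.28, 0.26, 0.21),
    stringsAsFactors = FALSE
  )
  # Standard taxonomy split; drives the coniferous/mixed habitat rules.
  conifer_genera <- c("ABIE", "LARI", "PICE", "PINU", "THUJ", "TSUG")
  tr$is_conifer <- sub("\\..*$", "", tr$code) %in% conifer_genera
  if (!is.null(species)) {
    missing <- setdiff(species, tr$code)
    if (length(missing))
      stop("unknown species code(s): ", paste(missing, collapse = ", "))
    tr <- tr[match(species, tr$code), , drop = FALSE]
    rownames(tr) <- NULL
  }
  tr
}

#' Habitat coefficients for Black-backed Woodpecker habitat types
#'
#' The five parameterized habitat types with their stand-characteristic
#' rules, mean home-range size (ha) and mean potential productivity
#' (fledglings per home range per year). A sixth implicit class,
#' \code{NON_HABITAT}, has zero productivity. Patches smaller than the
#' home-range size of their type contribute no productivity.
#'
#' @return A \code{data.frame} with columns \code{type}, \code{age_rule},
#'   \code{post_fire_window}, \code{composition}, \code{home_range} and
#'   \code{productivity}.
#' @export
habitat_coefficients <- function() {
  data.frame(
    type = c("OLD_CONIF_UNBURNED", "OLD_MIXED_UNBURNED",
             "BURNED_OLD_CONIF_1_5", "BURNED_YOUNG_CONIF_1_5",
             "BURNED_OLD_CONIF_6_10"),
    age_rule = c(">=80", ">=80", ">=80", "<80", ">=80"),
    post_fire_window = c("unburned", "unburned", "1-5", "1-5", "6-10"),
    composition = c("coniferous", "mixed", "coniferous", "coniferous",
                    "coniferous"),
    home_range = c(150, 300, 40, 100, 200),
    productivity = c(1.5, 1.0, 1.4, 0.25, 0.4),
    stringsAsFactors = FALSE
  )
}

#' All habitat labels, including the non-habitat class
#' @return Character vector of the six habitat labels.
#' @export
habitat_labels <- function() {
  c(habitat_coefficients()$type, "NON_HABITAT")
}
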