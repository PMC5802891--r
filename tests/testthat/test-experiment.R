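test_that("omega-squared evaluates the printed formula", {
  expect_equal(omega_squared(list(SS_effect = 80, df_effect = 1,
                                  MS_error = 2, SS_tot = 100)),
               78 / 102, tolerance = 1e-12)
  expect_equal(round(omega_squared(list(SS_effect = 80, df_effect = 1,
                                        MS_error = 2, SS_tot = 100)), 5),
               0.76471)
  # formula zero when SS_effect equals its error expectation
  expect_equal(omega_squared(list(SS_effect = 6, df_effect = 3,
                                  MS_error = 2, SS_tot = 100)), 0)
  # negative values are reported as computed
  expect_lt(omega_squared(list(SS_effect = 1, df_effect = 1,
                               MS_error = 2, SS_tot = 100)), 0)
  expect_error(omega_squared(list(SS_effect = 0, df_effect = 1,
                                  MS_error = 0, SS_tot = 0)), "degenerate")
})

test_that("the ANOVA decomposition matches the mean-based oracle", {
  set.seed(101)
  for (i in 1:20) {
    d <- random_factorial_table(r = 5)
    dec <- compute_anova(d)
    ora <- anova_oracle(d)
    for (e in dec$effects$effect) {
      expect_equal(dec$effects$SS[dec$effects$effect == e], ora[[e]],
                   tolerance = 1e-10)
    }
    expect_equal(dec$SS_error, ora$SS_err, tolerance = 1e-10)
    expect_equal(dec$MS_error, ora$MS_err, tolerance = 1e-10)
    expect_equal(dec$SS_tot, ora$SS_tot, tolerance = 1e-10)
    # SS decomposition is exhaustive
    expect_equal(sum(dec$effects$SS) + dec$SS_error, dec$SS_tot,
                 tolerance = 1e-8)
    # effect-size sanity: all seven omega-squared sum below 1
    expect_lt(sum(omega_squared_all(dec)), 1)
  }
})

test_that("single-factor signal loads only on that factor", {
  set.seed(5)
  d <- random_factorial_table(r = 5, effects = list(harvest = 10, fire = 0,
                                                    stand = 0))
  d$response <- round(d$response - d$response %% 0.001, 6)
  dec <- compute_anova(d)
  ss <- setNames(dec$effects$SS, dec$effects$effect)
  expect_gt(ss["harvest"], 100)
  expect_lt(ss["fire"], ss["harvest"] / 10)
  expect_lt(ss["stand"], ss["harvest"] / 10)
})

test_that("degenerate and malformed designs are rejected", {
  d <- random_factorial_table(r = 5)
  d$response <- 1
  dec <- compute_anova(d)
  expect_error(omega_squared(dec, "harvest"), "degenerate")
  expect_error(compute_anova(d[-1, ]), "unbalanced")
  d1 <- random_factorial_table(r = 1)
  expect_error(compute_anova(d1), "two replicates")
  expect_error(omega_squared(compute_anova(random_factorial_table(5)),
                             "nope"), "unknown effect")
})

test_that("delta statistics implement the percentage-difference contract", {
  expect_equal(as.numeric(delta_prod(c(40, 40), c(50, 50))), -20)
  expect_equal(as.numeric(delta_prod(1:5, 1:5)), 0)
  und <- delta_prod(c(1, 2), c(0, 0))
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
  expect_equal(as.numeric(delta_biomass(c(30), c(60))), -50)
  both_absent <- delta_biomass(0, 0)
  expect_true(attr(both_absent, "undefined"))
})

test_that("a small factorial experiment has the designed run structure", {
  cfg <- tiny_cfg(15)
  fact <- run_factorial(cfg, scenarios = "rcp85", replicates = 1,
                        seed_base = 7)
  tab <- fact$productivity
  expect_equal(length(unique(tab$run_id)), 8)   # 2^3 toggle combinations
  expect_equal(nrow(unique(tab[, c("harvest", "fire_climate",
                                   "stand_climate")])), 8)
  expect_equal(nrow(tab), 8 * 21)               # every timestep recorded
  # determinism: rerunning reproduces the table exactly
  fact2 <- run_factorial(cfg, scenarios = "rcp85", replicates = 1,
                         seed_base = 7)
  expect_equal(as.data.frame(fact$productivity),
               as.data.frame(fact2$productivity))
  expect_error(run_factorial(cfg, scenarios = "rcpX"), "unknown scenario")
})

test_that("sensitivity analysis extracts paired full/reduced contrasts", {
  # hand-built factorial table: productivity depends only on harvest
  d <- expand.grid(harvest = c(TRUE, FALSE), fire_climate = c(TRUE, FALSE),
                   stand_climate = c(TRUE, FALSE), replicate = 1:3)
  d$run_id <- seq_len(nrow(d))
  d$scenario <- "rcp45"; d$year <- 2100
  d$productivity <- ifelse(d$harvest, 40, 50)
  d$density <- d$productivity
  fact <- structure(list(productivity = data.table::as.data.table(d)),
                    class = "bbwo_factorial")
  sens <- sensitivity_analysis(fact)
  tb <- sens$table
  expect_equal(tb$delta_prod[tb$driver == "harvest"], -20)
  expect_equal(tb$delta_prod[tb$driver == "fire"], 0)
  expect_equal(tb$delta_prod[tb$driver == "stand"], 0)
  # with zero replicate noise the ANOVA is exact: harvest explains all
  expect_gt(tb$omega2[tb$driver == "harvest"], 0.9)
  expect_lt(abs(tb$omega2[tb$driver == "fire"]), 0.05)
})

test_that("planted harvest signals are recovered as the top-ranked driver", {
  set.seed(202)
  wins <- 0
  for (i in 1:100) {
    d <- random_factorial_table(r = 5, effects = list(harvest = 8, fire = 1,
                                                      stand = 1))
    dec <- compute_anova(d)
    om <- omega_squared_all(dec)[c("harvest", "fire", "stand")]
    if (which.max(om) == 1) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("per-species biomass sensitivity handles presence, absence and sign", {
  d <- expand.grid(harvest = c(TRUE, FALSE), fire_climate = c(TRUE, FALSE),
                   stand_climate = c(TRUE, FALSE), replicate = 1:2)
  d$run_id <- seq_len(nrow(d))
  d$scenario <- "rcp85"; d$year <- 2100
  # black spruce AGB halves when harvesting is on; aspen absent everywhere
  agb <- data.frame(d, species = "PICE.MAR",
                    agb = ifelse(d$harvest, 20, 40))
  fact <- structure(list(agb = data.table::as.data.table(agb)),
                    class = "bbwo_factorial")
  db <- biomass_sensitivity(fact)
  hv <- db[db$driver == "harvest" & db$species == "PICE.MAR", ]
  expect_equal(hv$delta_b, -50)
  expect_false(hv$undefined)
  expect_equal(db$delta_b[db$driver == "fire" & db$species == "PICE.MAR"], 0)
})
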