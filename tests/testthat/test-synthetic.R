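test_that("landscape generation is reproducible and validates its inputs", {
  cfg <- tiny_cfg(15)
  a <- generate_initial_landscape(cfg, seed = 3)
  b <- generate_initial_landscape(cfg, seed = 3)
  expect_equal(as.data.frame(a$cohorts), as.data.frame(b$cohorts))
  expect_identical(a$landtype, b$landtype)
  expect_identical(a$fire_region, b$fire_region)
  c2 <- generate_initial_landscape(cfg, seed = 4)
  expect_false(identical(as.data.frame(a$cohorts), as.data.frame(c2$cohorts)))
  cfg_bad <- cfg
  cfg_bad$synthetic$species_pool <- numeric(0)
  expect_error(generate_initial_landscape(cfg_bad), "species pool")
})

test_that("a degenerate all-conifer gradient yields conifer-dominated cells everywhere", {
  cfg <- tiny_cfg(15, synthetic = list(conifer_gradient = c(1, 1),
                                       initial_burns = FALSE))
  st <- generate_initial_landscape(cfg, seed = 5)
  cf <- conifer_fraction_map(st, cfg$species)
  occupied <- stand_age_map(st) > 0
  expect_true(all(cf[occupied] > 0.5))
})

test_that("stand ages follow the truncated negative-exponential distribution", {
  # single-species pool so the truncation point is a single longevity
  cfg <- default_config(
    grid = list(n_rows = 100L, n_cols = 100L),
    synthetic = list(age_distribution_mean = 100,
                     species_pool = c(PICE.MAR = 1), p_mixed = 0,
                     initial_burns = FALSE))
  st <- generate_initial_landscape(cfg, seed = 11)
  ages <- stand_age_map(st)
  # closed-form mean of an exponential(100) truncated at longevity 200
  m <- 100; Tl <- 200
  p <- 1 - exp(-Tl / m)
  oracle <- m - Tl * exp(-Tl / m) / p
  se <- sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - oracle), 3 * se)
  expect_true(all(ages <= Tl))
  expect_true(all(ages %% 5 == 0))
})

test_that("the conifer gradient rises from the southern to the northern band", {
  cfg <- tiny_cfg(40)
  st <- generate_initial_landscape(cfg, seed = 2)
  cf <- conifer_fraction_map(st, cfg$species)
  rows <- (seq_len(1600) - 1) %/% 40 + 1
  south <- mean(cf[rows <= 10]); north <- mean(cf[rows > 30])
  expect_gte(north, south)
})

test_that("zonation bands are contiguous and tenure follows the private fraction", {
  cfg <- tiny_cfg(30)
  st <- generate_initial_landscape(cfg, seed = 2)
  rows <- (seq_len(900) - 1) %/% 30 + 1
  for (lab in list(st$fire_region, st$management_area)) {
    per_row <- tapply(lab, rows, function(x) length(unique(x)))
    expect_true(all(per_row == 1))       # horizontal bands
    expect_true(all(diff(lab[seq(1, 900, by = 30)]) >= 0))  # ordered
  }
  expect_setequal(unique(st$tenure[st$management_area == 3]), "private")
  expect_setequal(unique(st$tenure[st$management_area != 3]), "public")
  pf <- mean(st$tenure == "private")
  expect_lt(abs(pf - cfg$synthetic$private_fraction), 0.05)
})

test_that("dynamic inputs are period-constant under baseline and trend under forcing", {
  cfg <- tiny_cfg()
  base <- generate_dynamic_inputs(cfg, "baseline")
  expect_equal(unique(base$period), "baseline")
  expect_error(generate_dynamic_inputs(cfg, "rcp99"), "unknown scenario")

  r26 <- generate_dynamic_inputs(cfg, "rcp26")
  r85 <- generate_dynamic_inputs(cfg, "rcp85")
  # first period equals baseline calibration
  p0 <- r85[r85$period == "2000-2010", ]
  expect_equal(p0$maxANPP, base$maxANPP)
  expect_equal(p0$SEP, base$SEP)
  # conifer declines monotonically with forcing strength by end of century
  pick <- function(d, sp) d[d$period == "2071-2100" & d$species == sp &
                              d$landtype == 1, ]
  expect_lt(pick(r85, "PICE.MAR")$maxANPP, pick(r26, "PICE.MAR")$maxANPP)
  expect_lt(pick(r26, "PICE.MAR")$maxANPP,
            base[base$species == "PICE.MAR" & base$landtype == 1, ]$maxANPP)
  # deciduous rises
  expect_gt(pick(r85, "POPU.TRE")$maxANPP, pick(r26, "POPU.TRE")$maxANPP)
  expect_true(all(r85$SEP >= 0 & r85$SEP <= 1))
})

test_that("zero trend strength reproduces baseline values under any scenario", {
  cfg <- tiny_cfg(10, dynamics = list(stand_strength = c(
    baseline = 0, rcp26 = 0, rcp45 = 0, rcp85 = 0)))
  base <- generate_dynamic_inputs(cfg, "baseline")
  r85 <- generate_dynamic_inputs(cfg, "rcp85")
  for (p in unique(r85$period)) {
    sl <- r85[r85$period == p, ]
    expect_equal(sl$SEP, base$SEP)
    expect_equal(sl$maxAGB, base$maxAGB)
  }
})

test_that("fire regimes intensify northward and with forcing", {
  cfg <- tiny_cfg()
  base <- generate_fire_regime(cfg, "baseline")
  expect_true(all(diff(base$annual_burn_rate) > 0))  # region 1 south
  r85 <- generate_fire_regime(cfg, "rcp85")
  last <- r85[r85$period == "2071-2100", ]
  first <- r85[r85$period == "2000-2010", ]
  expect_true(all(last$annual_burn_rate > first$annual_burn_rate))
  expect_equal(first$annual_burn_rate, base$annual_burn_rate)
})
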