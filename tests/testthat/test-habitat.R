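snapshot_of <- function(age, cf, tsf, pfa, pfc, n = 1) {
  list(year = 2050,
       stand_age = rep(age, n * n), conifer_fraction = rep(cf, n * n),
       time_since_fire = rep(tsf, n * n), pre_fire_age = rep(pfa, n * n),
       pre_fire_conifer = rep(pfc, n * n))
}

classify_one <- function(age, comp, window, cfg = default_config()) {
  cf <- c(conifer = 0.9, mixed = 0.5, deciduous = 0.1)[[comp]]
  grid <- grid_spec(1, 1)
  sn <- if (window == "unburned") {
    snapshot_of(age, cf, NA, NA, NA)
  } else {
    tsf <- if (window == "1-5") 5 else 10
    # the burn reset the stand: live age/composition reflect regrowth
    snapshot_of(tsf, 0, tsf, age, cf)
  }
  as.character(classify_habitat(sn, cfg, grid = grid)$labels)
}

test_that("the classifier reproduces the full habitat truth table", {
  expected <- list(
    c(90, "conifer", "unburned", "OLD_CONIF_UNBURNED"),
    c(90, "mixed", "unburned", "OLD_MIXED_UNBURNED"),
    c(90, "deciduous", "unburned", "NON_HABITAT"),
    c(40, "conifer", "unburned", "NON_HABITAT"),
    c(40, "mixed", "unburned", "NON_HABITAT"),
    c(40, "deciduous", "unburned", "NON_HABITAT"),
    c(90, "conifer", "1-5", "BURNED_OLD_CONIF_1_5"),
    c(90, "mixed", "1-5", "NON_HABITAT"),
    c(90, "deciduous", "1-5", "NON_HABITAT"),
    c(40, "conifer", "1-5", "BURNED_YOUNG_CONIF_1_5"),
    c(40, "mixed", "1-5", "NON_HABITAT"),
    c(40, "deciduous", "1-5", "NON_HABITAT"),
    c(90, "conifer", "6-10", "BURNED_OLD_CONIF_6_10"),
    c(90, "mixed", "6-10", "NON_HABITAT"),
    c(90, "deciduous", "6-10", "NON_HABITAT"),
    c(40, "conifer", "6-10", "NON_HABITAT"),
    c(40, "mixed", "6-10", "NON_HABITAT"),
    c(40, "deciduous", "6-10", "NON_HABITAT"))
  for (e in expected) {
    got <- classify_one(as.numeric(e[1]), e[2], e[3])
    expect_equal(got, e[4],
                 label = paste("age", e[1], e[2], e[3], "->", got))
  }
})

test_that("boundary ages and thresholds classify as documented", {
  expect_equal(classify_one(80, "conifer", "unburned"), "OLD_CONIF_UNBURNED")
  expect_equal(classify_one(79, "conifer", "unburned"), "NON_HABITAT")
  expect_equal(classify_one(80, "conifer", "1-5"), "BURNED_OLD_CONIF_1_5")
  expect_equal(classify_one(79, "conifer", "1-5"), "BURNED_YOUNG_CONIF_1_5")
  # exact composition thresholds: 0.75 is coniferous, 0.25 is mixed
  grid <- grid_spec(1, 1)
  lab <- function(cf) as.character(classify_habitat(
    snapshot_of(100, cf, NA, NA, NA), default_config(), grid = grid)$labels)
  expect_equal(lab(0.75), "OLD_CONIF_UNBURNED")
  expect_equal(lab(0.7499), "OLD_MIXED_UNBURNED")
  expect_equal(lab(0.25), "OLD_MIXED_UNBURNED")
  expect_equal(lab(0.2499), "NON_HABITAT")
  # a cell burned this very step (tsf 0) is not yet burned habitat
  sn0 <- snapshot_of(0, 0, 0, 100, 0.9)
  expect_equal(as.character(classify_habitat(sn0, default_config(),
                                             grid = grid)$labels),
               "NON_HABITAT")
  # beyond the 10-yr window the cell is judged as unburned regrowth
  sn11 <- snapshot_of(15, 0.9, 15, 100, 0.9)
  expect_equal(as.character(classify_habitat(sn11, default_config(),
                                             grid = grid)$labels),
               "NON_HABITAT")
})

test_that("a 24-cell block forms a single eligible old-conifer patch", {
  # 4x6 block of old conifer = 24 x 6.25 ha = 150 ha, the home-range size
  grid <- grid_spec(10, 10)
  age <- rep(0, 100); cf <- rep(0, 100)
  rows <- (seq_len(100) - 1) %/% 10 + 1; cols <- (seq_len(100) - 1) %% 10 + 1
  block <- rows %in% 3:6 & cols %in% 2:7
  age[block] <- 120; cf[block] <- 0.9
  sn <- list(year = 2000, stand_age = age, conifer_fraction = cf,
             time_since_fire = rep(NA_real_, 100),
             pre_fire_age = rep(NA_real_, 100),
             pre_fire_conifer = rep(NA_real_, 100))
  hm <- classify_habitat(sn, default_config(), grid = grid)
  ps <- aggregate_patches(hm)
  expect_equal(nrow(ps$patches), 1)
  expect_equal(ps$patches$area, 150)
  expect_true(ps$patches$eligible)
  # one cell less falls below the home range and is ineligible
  age[which(block)[1]] <- 0
  sn$stand_age <- age
  ps2 <- aggregate_patches(classify_habitat(sn, default_config(),
                                            grid = grid))
  expect_equal(ps2$patches$area, 150 - 6.25)
  expect_false(ps2$patches$eligible)
})

test_that("diagonal blocks merge under 8- but not 4-connectivity", {
  grid <- grid_spec(6, 6)
  age <- rep(0, 36); cf <- rep(0, 36)
  rows <- (seq_len(36) - 1) %/% 6 + 1; cols <- (seq_len(36) - 1) %% 6 + 1
  blk <- (rows %in% 1:2 & cols %in% 1:2) | (rows %in% 3:4 & cols %in% 3:4)
  age[blk] <- 100; cf[blk] <- 1
  sn <- list(year = 2000, stand_age = age, conifer_fraction = cf,
             time_since_fire = rep(NA_real_, 36),
             pre_fire_age = rep(NA_real_, 36),
             pre_fire_conifer = rep(NA_real_, 36))
  hm <- classify_habitat(sn, default_config(), grid = grid)
  expect_equal(nrow(aggregate_patches(hm, 4)$patches), 2)
  expect_equal(nrow(aggregate_patches(hm, 8)$patches), 1)
})

test_that("patch aggregation matches a brute-force flood fill", {
  cfg <- default_config()
  labs <- habitat_labels()
  set.seed(77)
  for (i in 1:25) {
    grid <- grid_spec(12, 12)
    lab <- sample(labs, 144, replace = TRUE,
                  prob = c(rep(0.12, 5), 0.4))
    hm <- structure(list(labels = factor(lab, levels = labs), year = 2000,
                         grid = grid), class = "habitat_map")
    for (conn in c(4L, 8L)) {
      got <- aggregate_patches(hm, conn)
      want <- flood_fill_labels(lab, 12, 12, conn)
      expect_true(same_partition(got$cell_patch, want))
      # conservation: per-label patch areas sum to the label's cell count
      for (ty in setdiff(labs, "NON_HABITAT")) {
        expect_equal(sum(got$patches$n_cells[got$patches$type == ty]),
                     sum(lab == ty))
      }
    }
  }
})

test_that("productivity multiplies eligible patch counts by the coefficients", {
  co <- habitat_coefficients()
  fake_patches <- function(df) {
    structure(list(patches = df, cell_patch = integer(0), year = 2000,
                   grid = grid_spec(40, 40)), class = "habitat_patches")
  }
  p1 <- fake_patches(data.frame(
    patch = 1:3, type = c("OLD_CONIF_UNBURNED", "OLD_CONIF_UNBURNED",
                          "OLD_CONIF_UNBURNED"),
    n_cells = c(30, 40, 10), area = c(187.5, 250, 62.5),
    eligible = c(TRUE, TRUE, FALSE)))
  r1 <- compute_productivity(p1, co)
  expect_equal(r1$total, 3.0)  # 2 eligible patches x 1.5
  expect_equal(r1$density, 3.0 * 1e4 / (1600 * 6.25))
  expect_false(r1$undefined)

  # contributions from two burned classes: 1.4 vs 0.4
  p2 <- fake_patches(data.frame(
    patch = 1:2, type = c("BURNED_OLD_CONIF_1_5", "BURNED_OLD_CONIF_6_10"),
    n_cells = c(10, 40), area = c(62.5, 250), eligible = c(TRUE, TRUE)))
  r2 <- compute_productivity(p2, co)
  tab <- r2$table
  expect_equal(tab$contribution[tab$type == "BURNED_OLD_CONIF_1_5"],
               1.4 / 1.8, tolerance = 1e-4)
  expect_equal(tab$contribution[tab$type == "BURNED_OLD_CONIF_6_10"],
               0.4 / 1.8, tolerance = 1e-4)
  expect_equal(round(tab$contribution[tab$type == "BURNED_OLD_CONIF_1_5"], 4),
               0.7778)

  # no eligible patches: zero productivity, flagged undefined
  p3 <- fake_patches(data.frame(patch = integer(), type = character(),
                                n_cells = integer(), area = numeric(),
                                eligible = logical()))
  r3 <- compute_productivity(p3, co)
  expect_equal(r3$total, 0)
  expect_true(r3$undefined)
  expect_true(all(r3$table$contribution == 0))

  # productivity is monotone in eligible patch count
  expect_gt(r1$total,
            compute_productivity(fake_patches(p1$patches[1, ]), co)$total)
})

test_that("the home-range counting mode implements the alternative reading", {
  co <- habitat_coefficients()
  df <- data.frame(patch = 1L, type = "BURNED_OLD_CONIF_1_5",
                   n_cells = 20, area = 125, eligible = TRUE)
  ps <- structure(list(patches = df, cell_patch = integer(0), year = 2000,
                       grid = grid_spec(10, 10)), class = "habitat_patches")
  # one 125-ha patch holds three whole 40-ha home ranges
  expect_equal(compute_productivity(ps, co)$total, 1.4)
  expect_equal(compute_productivity(ps, co,
                                    count_mode = "home_ranges")$total,
               3 * 1.4)
})

test_that("an all-non-habitat map yields an empty patch set", {
  grid <- grid_spec(5, 5)
  sn <- snapshot_of(40, 0.2, NA, NA, NA, n = 5)
  hm <- classify_habitat(sn, default_config(), grid = grid)
  ps <- aggregate_patches(hm)
  expect_equal(nrow(ps$patches), 0)
})
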