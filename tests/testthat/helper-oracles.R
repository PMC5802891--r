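# Independent oracles and small fixtures, kept deliberately separate from
# the package implementations they check.

# Brute-force connected-component labelling by BFS flood fill.
flood_fill_labels <- function(labels, n_rows, n_cols, connectivity = 4,
                              ignore = "NON_HABITAT") {
  lab <- matrix(as.character(labels), n_rows, n_cols, byrow = TRUE)
  comp <- matrix(0L, n_rows, n_cols)
  next_id <- 0L
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  for (r0 in seq_len(n_rows)) for (c0 in seq_len(n_cols)) {
    if (lab[r0, c0] %in% ignore || comp[r0, c0] != 0L) next
    next_id <- next_id + 1L
    queue <- list(c(r0, c0))
    comp[r0, c0] <- next_id
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        rr <- cur[1] + o[1]; cc <- cur[2] + o[2]
        if (rr < 1 || rr > n_rows || cc < 1 || cc > n_cols) next
        if (comp[rr, cc] == 0L && !(lab[rr, cc] %in% ignore) &&
            lab[rr, cc] == lab[cur[1], cur[2]]) {
          comp[rr, cc] <- next_id
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  as.integer(t(comp))  # row-major cell order
}

# Partition equality of two component labellings (ids may differ).
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  on <- a > 0
  length(unique(paste(a[on], b[on]))) == length(unique(a[on])) &&
    length(unique(paste(a[on], b[on]))) == length(unique(b[on]))
}

# Mean-based balanced three-way ANOVA decomposition (2x2x2 x r).
anova_oracle <- function(df, response = "response") {
  y <- df[[response]]
  A <- factor(df$harvest); B <- factor(df$fire_climate)
  C <- factor(df$stand_climate)
  r <- length(y) / 8
  g <- mean(y)
  m1 <- function(f) tapply(y, f, mean)
  m2 <- function(f1, f2) tapply(y, list(f1, f2), mean)
  m3 <- tapply(y, list(A, B, C), mean)
  mA <- m1(A); mB <- m1(B); mC <- m1(C)
  mAB <- m2(A, B); mAC <- m2(A, C); mBC <- m2(B, C)
  SS_A <- 4 * r * sum((mA - g)^2)
  SS_B <- 4 * r * sum((mB - g)^2)
  SS_C <- 4 * r * sum((mC - g)^2)
  SS_AB <- 2 * r * sum((sweep(sweep(mAB, 1, mA), 2, mB) + g)^2)
  SS_AC <- 2 * r * sum((sweep(sweep(mAC, 1, mA), 2, mC) + g)^2)
  SS_BC <- 2 * r * sum((sweep(sweep(mBC, 1, mB), 2, mC) + g)^2)
  dev3 <- m3
  for (a in 1:2) for (b in 1:2) for (cc in 1:2)
    dev3[a, b, cc] <- m3[a, b, cc] - mAB[a, b] - mAC[a, cc] - mBC[b, cc] +
      mA[a] + mB[b] + mC[cc] - g
  SS_ABC <- r * sum(dev3^2)
  cellm <- m3[cbind(as.integer(A), as.integer(B), as.integer(C))]
  SS_err <- sum((y - cellm)^2)
  list(harvest = SS_A, fire = SS_B, stand = SS_C,
       `harvest:fire` = SS_AB, `harvest:stand` = SS_AC,
       `fire:stand` = SS_BC, `harvest:fire:stand` = SS_ABC,
       SS_err = SS_err, SS_tot = sum((y - g)^2),
       MS_err = SS_err / (8 * (r - 1)))
}

# random balanced 2x2x2 factorial table
random_factorial_table <- function(r = 5, effects = NULL) {
  d <- expand.grid(harvest = c(TRUE, FALSE), fire_climate = c(TRUE, FALSE),
                   stand_climate = c(TRUE, FALSE),
                   replicate = seq_len(r))
  mu <- rnorm(1, 50, 10)
  y <- rep(mu, nrow(d))
  if (!is.null(effects)) {
    y <- y + effects$harvest * d$harvest + effects$fire * d$fire_climate +
      effects$stand * d$stand_climate
  } else {
    y <- y + rnorm(1, 0, 5) * d$harvest + rnorm(1, 0, 5) * d$fire_climate +
      rnorm(1, 0, 5) * d$stand_climate +
      rnorm(1, 0, 3) * (d$harvest & d$fire_climate)
  }
  d$response <- y + rnorm(nrow(d), 0, 2)
  d
}

# compact configuration for fast tests
tiny_cfg <- function(n = 20, ...) {
  default_config(grid = list(n_rows = as.integer(n), n_cols = as.integer(n)),
                 ...)
}

# a minimal hand-built landscape state: every cell empty unless given
bare_state <- function(n = 4, cohorts = NULL, cell_area = 6.25, ...) {
  grid <- grid_spec(n, n, cell_area = cell_area)
  if (is.null(cohorts))
    cohorts <- data.frame(cell = integer(), species = character(),
                          age = integer(), biomass = numeric())
  landscape_state(grid, cohorts,
                  landtype = rep(1L, n * n), fire_region = rep(1L, n * n),
                  management_area = rep(1L, n * n), ...)
}

# uniform single-period dynamic inputs for hand-built tests
flat_dyn <- function(species, sep = 1, maxanpp = 1000, maxagb = 1e6,
                     landtypes = 1, period = "baseline") {
  d <- expand.grid(species = species, landtype = seq_len(landtypes),
                   stringsAsFactors = FALSE)
  data.table::data.table(scenario = "baseline", period = period,
                         species = d$species, landtype = d$landtype,
                         SEP = sep, maxANPP = maxanpp, maxAGB = maxagb)
}
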