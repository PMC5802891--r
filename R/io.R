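# Text raster I/O (ESRI ASCII grid), cohort-table I/O and run manifests.
# The ASCII grid dialect is used for every per-cell scalar layer because it
# is plain text and dependency-free; values are written with full double
# precision so a write/read round trip is bit-exact.

#' Write a per-cell layer as an ESRI ASCII grid
#'
#' @param values numeric vector in row-major cell order (row 1 = south) or
#'   a matrix with \code{n_rows} rows.
#' @param grid a \code{grid_spec}.
#' @param path output file.
#' @param na_value NODATA sentinel.
#' @return \code{path}, invisibly.
#' @export
write_ascii_grid <- function(values, grid, path, na_value = -9999) {
  m <- if (is.matrix(values)) values else
    matrix(values, grid$n_rows, grid$n_cols, byrow = TRUE)
  cellsize <- cell_size_m(grid)
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           "xllcorner 0", "yllcorner 0",
           sprintf("cellsize %.17g", cellsize),
           sprintf("NODATA_value %.17g", na_value))
  m[is.na(m)] <- na_value
  # ASCII grids list rows from north to south; row n_rows is our north edge
  body <- vapply(rev(seq_len(nrow(m))), function(r)
    paste(sprintf("%.17g", m[r, ]), collapse = " "), "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] (or any ESRI ASCII
#'   grid).
#' @return \code{list(values = row-major numeric vector (row 1 = south),
#'   n_rows =, n_cols =, cellsize =)}.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  n_rows <- as.integer(hdr$nrows); n_cols <- as.integer(hdr$ncols)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != n_rows * n_cols) stop("corrupt ASCII grid: ", path)
  m <- matrix(vals, n_rows, n_cols, byrow = TRUE)
  m <- m[rev(seq_len(n_rows)), , drop = FALSE]  # back to south-first rows
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  list(values = as.numeric(t(m)), n_rows = n_rows, n_cols = n_cols,
       cellsize = hdr$cellsize)
}

#' Write all layers of a landscape state to a directory
#'
#' Emits the scalar layers (stand age, time since fire, conifer fraction,
#' pre-fire age and composition, landtype, fire region, management area,
#' tenure) as ASCII grids, the full cohort table as CSV, and a JSON
#' manifest listing every file with the grid/temporal metadata needed to
#' reproduce the state bit-for-bit via [read_layers()].
#'
#' @param state a [landscape_state()].
#' @param dir output directory (created if needed).
#' @param traits trait table (for the conifer-fraction layer).
#' @return The file registry (named character vector), invisibly.
#' @export
write_layers <- function(state, dir, traits = species_traits()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- state$grid
  layers <- list(
    stand_age = stand_age_map(state),
    conifer_fraction = conifer_fraction_map(state, traits),
    time_since_fire = state$time_since_fire,
    pre_fire_age = state$pre_fire_age,
    pre_fire_conifer = state$pre_fire_conifer,
    landtype = state$landtype,
    fire_region = state$fire_region,
    management_area = state$management_area,
    tenure = as.numeric(state$tenure == "private"))
  registry <- character(0)
  for (nm in names(layers)) {
    f <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(layers[[nm]], grid, f)
    registry[nm] <- basename(f)
  }
  cf <- file.path(dir, "cohorts.csv")
  codf <- as.data.frame(state$cohorts)
  codf$biomass <- sprintf("%.17g", codf$biomass)  # bit-exact round trip
  utils::write.csv(codf, cf, row.names = FALSE, quote = FALSE)
  registry["cohorts"] <- basename(cf)
  manifest <- list(
    package_version = as.character(utils::packageVersion("bbwohab")),
    year = state$year,
    grid = state$grid[c("n_rows", "n_cols", "cell_area", "origin_year",
                        "timestep", "horizon")],
    files = as.list(registry))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  registry["manifest"] <- "manifest.json"
  invisible(registry)
}

#' Read a landscape state written by [write_layers()]
#'
#' @param dir directory containing a manifest and layer files.
#' @return A [landscape_state()].
#' @export
read_layers <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  grid <- do.call(grid_spec, mf$grid)
  rd <- function(nm) read_ascii_grid(file.path(dir, mf$files[[nm]]))$values
  cohorts <- utils::read.csv(file.path(dir, mf$files$cohorts),
                             stringsAsFactors = FALSE)
  landscape_state(
    grid, cohorts,
    landtype = rd("landtype"), fire_region = rd("fire_region"),
    management_area = rd("management_area"),
    tenure = ifelse(rd("tenure") > 0, "private", "public"),
    time_since_fire = rd("time_since_fire"),
    pre_fire_age = rd("pre_fire_age"),
    pre_fire_conifer = rd("pre_fire_conifer"),
    year = mf$year)
}

#' Write a habitat map as an ASCII grid of integer codes
#'
#' Codes follow the order of [habitat_labels()] (1-based;
#' \code{NON_HABITAT} is 6).
#'
#' @param habitat a \code{habitat_map}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_habitat_map <- function(habitat, path) {
  write_ascii_grid(as.integer(habitat$labels), habitat$grid, path)
}

#' Read a habitat map written by [write_habitat_map()]
#' @param path file path.
#' @param year optional year to attach.
#' @return A \code{habitat_map}.
#' @export
read_habitat_map <- function(path, year = NA) {
  g <- read_ascii_grid(path)
  grid <- grid_spec(g$n_rows, g$n_cols, cell_area = (g$cellsize / 100)^2)
  structure(list(labels = factor(habitat_labels()[g$values],
                                 levels = habitat_labels()),
                 year = year, grid = grid), class = "habitat_map")
}
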