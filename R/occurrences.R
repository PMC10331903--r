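#' Read occurrence records for one species from CSV
#'
#' The file must have a header with columns `species`, `longitude`,
#' `latitude`. Rows are matched to `species` by exact string equality after
#' trimming surrounding whitespace (curated binomials; no fuzzy matching).
#' Malformed rows — non-numeric or out-of-world-bounds coordinates — are
#' skipped with a message giving the count. Duplicate rows are retained;
#' thinning deals with them.
#'
#' @param path CSV file path.
#' @param species Species name to select.
#' @return An object of class `sdm_occurrences`: fields `species`, `points`
#'   (data frame `longitude`, `latitude` in file order), `source`.
#' @export
read_occurrences <- function(path, species) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "longitude", "latitude")
  if (!all(need %in% names(df)))
    stop("occurrence CSV must have columns species, longitude, latitude")
  df$species <- trimws(df$species)
  df <- df[df$species == trimws(species), , drop = FALSE]
  if (nrow(df) == 0) stop("no rows for species '", species, "'")
  lon <- suppressWarnings(as.numeric(df$longitude))
  lat <- suppressWarnings(as.numeric(df$latitude))
  ok <- is.finite(lon) & is.finite(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  if (any(!ok))
    message(sum(!ok), " malformed occurrence row(s) skipped for ", species)
  occurrence_set(species = trimws(species),
                 points = data.frame(longitude = lon[ok], latitude = lat[ok]),
                 source = path)
}

#' Construct an occurrence set
#'
#' @param species Species name.
#' @param points Data frame with columns `longitude`, `latitude`.
#' @param source Free-text provenance.
#' @return An `sdm_occurrences` object.
#' @export
occurrence_set <- function(species, points, source = "") {
  stopifnot(is.data.frame(points),
            all(c("longitude", "latitude") %in% names(points)))
  if (any(points$longitude < -180 | points$longitude > 180 |
          points$latitude < -90 | points$latitude > 90))
    stop("coordinates outside world bounds")
  structure(list(species = species,
                 points = points[, c("longitude", "latitude")],
                 source = source),
            class = "sdm_occurrences")
}

# point -> (row, col); half-open cells, west/north edges inclusive
points_to_cells <- function(grid, lon, lat) {
  delta <- grid_delta(grid)
  col <- floor((lon - grid$west) / delta + 1e-12) + 1
  row <- floor((grid_north(grid) - lat) / delta + 1e-12) + 1
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Thin occurrences to one presence per grid cell
#'
#' Each point is assigned to the grid cell containing it (half-open cell
#' boxes, west/north edges inclusive); occupied cells are deduplicated.
#' Points outside the grid are dropped with a message.
#'
#' @param occ An `sdm_occurrences` object.
#' @param grid An `sdm_grid`.
#' @return An object of class `sdm_presences`: fields `grid`, `cells`
#'   (matrix of unique `row`, `col`), `n_raw` (in-grid point count),
#'   `species`.
#' @export
thin_to_grid <- function(occ, grid) {
  pts <- occ$points
  cells <- points_to_cells(grid, pts$longitude, pts$latitude)
  inside <- cells[, 1] >= 1 & cells[, 1] <= grid$n_rows &
    cells[, 2] >= 1 & cells[, 2] <= grid$n_cols
  if (!any(inside)) stop("all points fall outside the grid")
  if (any(!inside))
    message(sum(!inside), " point(s) outside the grid dropped for ",
            occ$species)
  cells <- cells[inside, , drop = FALSE]
  key <- paste(cells[, 1], cells[, 2])
  uniq <- cells[!duplicated(key), , drop = FALSE]
  # deterministic order: north to south, west to east
  uniq <- uniq[order(uniq[, 1], uniq[, 2]), , drop = FALSE]
  structure(list(grid = grid, cells = uniq, n_raw = sum(inside),
                 species = occ$species),
            class = "sdm_presences")
}

#' @export
print.sdm_presences <- function(x, ...) {
  cat(sprintf("sdm_presences: %s, %d cells (from %d in-grid records)\n",
              x$species, nrow(x$cells), x$n_raw))
  invisible(x)
}

#' Write thinned presences to CSV
#'
#' One row per presence cell with its grid indices and cell-centre
#' coordinates.
#'
#' @param presences An `sdm_presences` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_presences <- function(presences, path) {
  ctr <- cell_centers(presences$grid, presences$cells)
  df <- data.frame(species = presences$species,
                   row = presences$cells[, 1], col = presences$cells[, 2],
                   longitude = ctr[, 1], latitude = ctr[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
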