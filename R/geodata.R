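EARTH_RADIUS_KM <- 6371.0088  # IUGG mean Earth radius, spherical model

#' Build a geographic grid
#'
#' Defines a regular lattice of square (in degrees) cells on the WGS84
#' lon/lat graticule. Cells are anchored so that -180 and -90 fall on cell
#' edges (the WorldClim registration): the requested west/south corner is
#' snapped outward to the nearest anchored edge, and the extent is expanded
#' to an integer number of cells. Row 1 is the northernmost row; each cell
#' is a half-open box whose west and north edges are inclusive.
#'
#' @param west,south,east,north Extent in decimal degrees.
#' @param resolution_arcmin Angular cell size in arcminutes (default 2.5,
#'   i.e. roughly 5 km at the equator).
#' @return An object of class `sdm_grid` with fields `resolution_arcmin`,
#'   `west`, `south`, `n_rows`, `n_cols`.
#' @examples
#' g <- build_grid(0, 0, 1, 1, resolution_arcmin = 30)
#' g$n_rows  # 2
#' @export
build_grid <- function(west, south, east, north, resolution_arcmin = 2.5) {
  if (!is.finite(resolution_arcmin) || resolution_arcmin <= 0)
    stop("resolution_arcmin must be positive")
  if (east <= west || north <= south)
    stop("extent must have east > west and north > south")
  if (west < -180 - 1e-9 || east > 180 + 1e-9 ||
      south < -90 - 1e-9 || north > 90 + 1e-9)
    stop("extent outside world bounds [-180,180] x [-90,90]")
  delta <- resolution_arcmin / 60
  # snap origin outward onto the -180/-90 anchored lattice
  west_s <- -180 + floor((west + 180) / delta + 1e-9) * delta
  south_s <- -90 + floor((south + 90) / delta + 1e-9) * delta
  n_cols <- as.integer(ceiling((east - west_s) / delta - 1e-9))
  n_rows <- as.integer(ceiling((north - south_s) / delta - 1e-9))
  structure(
    list(resolution_arcmin = resolution_arcmin,
         west = west_s, south = south_s,
         n_rows = n_rows, n_cols = n_cols),
    class = "sdm_grid")
}

#' @export
print.sdm_grid <- function(x, ...) {
  cat(sprintf("sdm_grid: %d rows x %d cols at %.4g arcmin\n",
              x$n_rows, x$n_cols, x$resolution_arcmin))
  cat(sprintf("  extent: lon [%.6g, %.6g], lat [%.6g, %.6g]\n",
              x$west, grid_east(x), x$south, grid_north(x)))
  invisible(x)
}

grid_delta <- function(grid) grid$resolution_arcmin / 60
grid_north <- function(grid) grid$south + grid$n_rows * grid_delta(grid)
grid_east <- function(grid) grid$west + grid$n_cols * grid_delta(grid)

grids_identical <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$resolution_arcmin - b$resolution_arcmin) < tol * 60 &&
    abs(a$west - b$west) < tol && abs(a$south - b$south) < tol
}

#' Spherical area of the cells in one grid row
#'
#' Cells in the same row share a latitude band and hence an area. Uses the
#' spherical-zone formula A = R^2 * d_lambda * (sin(phi_top) - sin(phi_bottom))
#' with the IUGG mean Earth radius R = 6371.0088 km.
#'
#' @param grid An `sdm_grid`.
#' @param row Row index (1 = northernmost row).
#' @return Cell area in square kilometres.
#' @examples
#' g <- build_grid(0, 0, 1, 1, 2.5)
#' cell_area_km2(g, g$n_rows)  # cell touching the equator: ~21.47 km2
#' @export
cell_area_km2 <- function(grid, row) {
  if (any(row < 1L) || any(row > grid$n_rows)) stop("row out of range")
  delta <- grid_delta(grid)
  phi_top <- (grid_north(grid) - (row - 1) * delta) * pi / 180
  phi_bot <- (grid_north(grid) - row * delta) * pi / 180
  EARTH_RADIUS_KM^2 * (delta * pi / 180) * (sin(phi_top) - sin(phi_bot))
}

#' Construct a raster layer on a grid
#'
#' @param grid An `sdm_grid`.
#' @param values Numeric matrix `n_rows x n_cols` (row 1 = north) or a
#'   single value to fill with.
#' @param kind `"continuous"` or `"categorical"` (integer codes).
#' @param valid_mask Logical matrix of the same shape; defaults to
#'   `is.finite(values)`.
#' @return An object of class `sdm_raster`.
#' @export
new_raster <- function(grid, values, kind = c("continuous", "categorical"),
                       valid_mask = NULL) {
  kind <- match.arg(kind)
  if (length(values) == 1)
    values <- matrix(values, grid$n_rows, grid$n_cols)
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("values must be an n_rows x n_cols matrix")
  if (is.null(valid_mask)) valid_mask <- is.finite(values)
  storage.mode(values) <- "double"
  values[!valid_mask] <- NA_real_
  if (kind == "categorical") {
    v <- values[valid_mask]
    if (any(abs(v - round(v)) > 1e-9))
      stop("categorical layers must hold integer codes")
  }
  structure(list(grid = grid, values = values, valid_mask = valid_mask,
                 kind = kind),
            class = "sdm_raster")
}

#' @export
print.sdm_raster <- function(x, ...) {
  cat(sprintf("sdm_raster (%s): %d x %d, %d valid cells\n", x$kind,
              x$grid$n_rows, x$grid$n_cols, sum(x$valid_mask)))
  invisible(x)
}

#' Read a raster layer from an ESRI ASCII grid file
#'
#' The plain-text `.asc` format carries a single band plus the geographic
#' registration (`xllcorner`, `yllcorner`, `cellsize`) and a nodata value.
#' Nodata pixels become invalid cells; the grid is inferred from the header.
#'
#' @param path Path to an `.asc` file.
#' @param kind `"continuous"` or `"categorical"`.
#' @return An `sdm_raster`.
#' @export
read_layer <- function(path, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2 || grepl("^[-0-9.]", parts[1]) ||
        is.na(suppressWarnings(as.numeric(parts[2]))))
      break
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    n_hdr <- n_hdr + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header incomplete in ", path)
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  n_rows <- as.integer(hdr$nrows)
  n_cols <- as.integer(hdr$ncols)
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != n_rows * n_cols)
    stop("ASCII grid payload has wrong length in ", path)
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  grid <- structure(
    list(resolution_arcmin = hdr$cellsize * 60,
         west = hdr$xllcorner, south = hdr$yllcorner,
         n_rows = n_rows, n_cols = n_cols),
    class = "sdm_grid")
  mask <- is.finite(m) & m != nodata
  new_raster(grid, m, kind = kind, valid_mask = mask)
}

#' Write a raster layer to an ESRI ASCII grid file
#'
#' Invalid cells are written as -9999. Values are serialized with 17
#' significant digits so that a read/write round trip reproduces doubles
#' bit-exactly.
#'
#' @param layer An `sdm_raster`.
#' @param path Output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_layer <- function(layer, path) {
  g <- layer$grid
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.17g", g$west),
    sprintf("yllcorner %.17g", g$south),
    sprintf("cellsize %.17g", grid_delta(g)),
    "NODATA_value -9999")
  m <- layer$values
  m[!layer$valid_mask] <- -9999
  rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Assemble aligned raster layers into a covariate stack
#'
#' All layers must sit on the identical grid (origin and resolution within
#' 1e-9 degrees). At most one categorical layer is allowed and it must be
#' named `"biome"`. The stack records layer order (which fixes the model
#' matrix column order) and the shared validity mask (cells valid in every
#' layer).
#'
#' @param layers Named list of `sdm_raster` objects.
#' @return An object of class `sdm_stack` with fields `grid`, `layers`,
#'   `shared_mask`.
#' @export
assemble_stack <- function(layers) {
  if (length(layers) == 0 || is.null(names(layers)) ||
      any(!nzchar(names(layers))))
    stop("layers must be a non-empty named list")
  grid <- layers[[1]]$grid
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "sdm_raster"))
      stop("layer '", nm, "' is not an sdm_raster")
    if (!grids_identical(grid, layers[[nm]]$grid))
      stop("layer '", nm, "' is not aligned with the first layer's grid")
  }
  cat_layers <- names(layers)[vapply(layers, function(l) l$kind, "") ==
                                "categorical"]
  if (length(cat_layers) > 1)
    stop("at most one categorical layer is allowed")
  if (length(cat_layers) == 1 && cat_layers != "biome")
    stop("the categorical layer must be named 'biome'")
  shared <- Reduce(`&`, lapply(layers, function(l) l$valid_mask))
  structure(list(grid = grid, layers = layers, shared_mask = shared),
            class = "sdm_stack")
}

#' @export
print.sdm_stack <- function(x, ...) {
  cat(sprintf("sdm_stack: %d layers (%s) on %d x %d grid, %d shared cells\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$grid$n_rows, x$grid$n_cols, sum(x$shared_mask)))
  invisible(x)
}

#' Covariate matrix for a set of cells
#'
#' Extracts the stack's layer values at the given cells, one column per
#' layer in the stack's recorded order.
#'
#' @param stack An `sdm_stack`.
#' @param cells Matrix with columns `row`, `col`.
#' @return Numeric matrix, one row per cell.
#' @export
stack_matrix <- function(stack, cells) {
  idx <- cbind(cells[, 1], cells[, 2])
  out <- vapply(stack$layers, function(l) l$values[idx],
                numeric(nrow(cells)))
  if (nrow(cells) == 1) out <- matrix(out, nrow = 1,
                                      dimnames = list(NULL, names(stack$layers)))
  out
}

#' Cells of a logical mask
#'
#' Row/column indices of all TRUE entries, in row-major (north-to-south)
#' order.
#'
#' @param mask Logical matrix.
#' @return Matrix with columns `row`, `col`.
#' @export
mask_cells <- function(mask) {
  w <- which(t(mask))
  n_cols <- ncol(mask)
  cbind(row = (w - 1) %/% n_cols + 1, col = (w - 1) %% n_cols + 1)
}

#' Cell-centre coordinates
#'
#' @param grid An `sdm_grid`.
#' @param cells Matrix with columns `row`, `col`.
#' @return Matrix with columns `longitude`, `latitude`.
#' @export
cell_centers <- function(grid, cells) {
  delta <- grid_delta(grid)
  cbind(longitude = grid$west + (cells[, 2] - 0.5) * delta,
        latitude = grid_north(grid) - (cells[, 1] - 0.5) * delta)
}

# total area of the TRUE cells of a boolean raster, in km^2
mask_area_km2 <- function(mask_raster) {
  m <- mask_raster$values > 0 & mask_raster$valid_mask
  counts <- rowSums(m)
  rows <- which(counts > 0)
  if (length(rows) == 0) return(0)
  sum(counts[rows] * cell_area_km2(mask_raster$grid, rows))
}
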