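#' Build an analysis grid
#'
#' Defines a rectangular lat/lon lattice of square cells with an optional
#' land mask. Cells are half-open boxes `[lon, lon + cell_size) x
#' (lat - cell_size, lat]`; row 1 is the northernmost row, and the centre of
#' cell `(r, c)` (1-based) sits at
#' `lat_max - (r - 0.5) * cell_size`, `lon_min + (c - 0.5) * cell_size`.
#' Land cells are indexed row-major (west to east within a row, north to
#' south across rows); that ordering is the single cell convention used by
#' every other function in the package.
#'
#' @param lat_max northern edge of the grid, decimal degrees.
#' @param lon_min western edge of the grid, decimal degrees.
#' @param n_rows,n_cols lattice dimensions (>= 1).
#' @param cell_size cell edge length in degrees (> 0).
#' @param land_mask logical `n_rows x n_cols` matrix, `TRUE` for land.
#'   Defaults to all-land.
#' @return An object of class `bs_grid`.
#' @examples
#' g <- build_grid(lat_max = 0, lon_min = 0, n_rows = 2, n_cols = 2,
#'                 cell_size = 0.5)
#' grid_centers(g)[1, ]  # (-0.25, 0.25)
#' @export
build_grid <- function(lat_max, lon_min, n_rows, n_cols, cell_size,
                       land_mask = NULL) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != round(n_rows) || n_cols != round(n_cols))
    stop("n_rows and n_cols must be positive integers")
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop("cell_size must be > 0")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.null(land_mask)) {
    land_mask <- matrix(TRUE, n_rows, n_cols)
  } else {
    if (!is.logical(land_mask)) stop("land_mask must be logical")
    if (!is.matrix(land_mask) ||
        nrow(land_mask) != n_rows || ncol(land_mask) != n_cols)
      stop(sprintf("land_mask must be a %d x %d logical matrix", n_rows, n_cols))
  }
  # row-major enumeration of land cells
  k <- which(t(land_mask))
  land_rc <- cbind(row = (k - 1L) %/% n_cols + 1L,
                   col = (k - 1L) %% n_cols + 1L)
  cell_index <- matrix(NA_integer_, n_rows, n_cols)
  cell_index[land_rc] <- seq_len(nrow(land_rc))
  structure(list(lat_max = lat_max, lon_min = lon_min,
                 n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 land_mask = land_mask, land_rc = land_rc,
                 cell_index = cell_index, n_land = nrow(land_rc)),
            class = "bs_grid")
}

#' @export
print.bs_grid <- function(x, ...) {
  cat(sprintf("<bs_grid> %d x %d cells of %g deg, %d land cells\n",
              x$n_rows, x$n_cols, x$cell_size, x$n_land))
  cat(sprintf("  lat in (%g, %g], lon in [%g, %g)\n",
              x$lat_max - x$n_rows * x$cell_size, x$lat_max,
              x$lon_min, x$lon_min + x$n_cols * x$cell_size))
  invisible(x)
}

#' Land-cell centre coordinates
#'
#' @param grid a `bs_grid`.
#' @return data.frame with columns `lat`, `lon`, one row per land cell in
#'   row-major order.
#' @export
grid_centers <- function(grid) {
  stopifnot(inherits(grid, "bs_grid"))
  data.frame(
    lat = grid$lat_max - (grid$land_rc[, "row"] - 0.5) * grid$cell_size,
    lon = grid$lon_min + (grid$land_rc[, "col"] - 0.5) * grid$cell_size)
}

# Directed adjacency pairs between land cells.
# scheme "queen" = 8 neighbours (edge or corner), "rook" = 4.
# Returns a 2-column integer matrix (focal, neighbor) of land-cell indices;
# every undirected link appears in both directions.
adjacency_pairs <- function(grid, scheme = c("queen", "rook")) {
  scheme <- match.arg(scheme)
  off <- if (scheme == "queen") {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
          dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  rc <- grid$land_rc
  out_i <- vector("list", nrow(off)); out_j <- out_i
  for (k in seq_len(nrow(off))) {
    r2 <- rc[, "row"] + off[k, "dr"]
    c2 <- rc[, "col"] + off[k, "dc"]
    ok <- r2 >= 1 & r2 <= grid$n_rows & c2 >= 1 & c2 <= grid$n_cols
    j <- rep(NA_integer_, nrow(rc))
    j[ok] <- grid$cell_index[cbind(r2[ok], c2[ok])]
    keep <- !is.na(j)
    out_i[[k]] <- which(keep)
    out_j[[k]] <- j[keep]
  }
  cbind(focal = unlist(out_i), neighbor = unlist(out_j))
}

#' Cell field: one value per land cell
#'
#' A `cell_field` carries one real value per land cell of a grid, in the
#' grid's row-major land-cell order, with `NA` marking missing cells
#' (missing is never encoded as 0).
#'
#' @param grid a `bs_grid`.
#' @param values numeric vector of length `grid$n_land`; `NA` = missing.
#' @param name,units labels carried along into outputs.
#' @return An object of class `cell_field`.
#' @export
cell_field <- function(grid, values, name = "field", units = "") {
  stopifnot(inherits(grid, "bs_grid"))
  if (length(values) != grid$n_land)
    stop(sprintf("values must have length %d (one per land cell)", grid$n_land))
  structure(list(grid = grid, values = as.numeric(values),
                 name = name, units = units),
            class = "cell_field")
}

#' @export
print.cell_field <- function(x, ...) {
  v <- x$values
  cat(sprintf("<cell_field> '%s'%s: %d cells (%d missing)\n", x$name,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              length(v), sum(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  range %.4g .. %.4g, mean %.4g\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE),
                mean(v, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.cell_field <- function(object, ...) {
  summary(object$values, ...)
}

#' Plot a cell field as a raster image
#'
#' @param x a `cell_field`.
#' @param ... passed to [graphics::image()].
#' @export
plot.cell_field <- function(x, ...) {
  g <- x$grid
  m <- matrix(NA_real_, g$n_rows, g$n_cols)
  m[g$land_rc] <- x$values
  lon <- g$lon_min + (seq_len(g$n_cols) - 0.5) * g$cell_size
  lat_asc <- rev(g$lat_max - (seq_len(g$n_rows) - 0.5) * g$cell_size)
  # image() wants ascending axes; flip rows so north is up
  graphics::image(lon, lat_asc, t(m[g$n_rows:1, , drop = FALSE]),
                  xlab = "longitude", ylab = "latitude", main = x$name, ...)
  invisible(x)
}

# Great-circle (km, spherical Earth R = 6371 km) or planar-degree distance
# matrix between land-cell centres.
cell_distances <- function(grid, method = c("greatcircle", "planar")) {
  method <- match.arg(method)
  ctr <- grid_centers(grid)
  if (method == "greatcircle") {
    d <- geosphere::distm(cbind(ctr$lon, ctr$lat),
                          fun = function(p1, p2)
                            geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  } else {
    d <- as.matrix(stats::dist(cbind(ctr$lon, ctr$lat)))
  }
  attr(d, "units") <- if (method == "greatcircle") "km" else "degrees"
  d
}
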