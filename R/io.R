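# Plain-text readers and writers: grid JSON, gridded CSV fields, PAM CSV,
# GeoJSON ranges, YAML pipeline configuration. Row/col indices in files
# are 0-based (row 0 = northernmost row); in-memory indices are 1-based.

#' Write / read a grid definition (JSON)
#'
#' The JSON grid file is the single source of truth for geometry; every
#' raster read is validated against it.
#'
#' @param grid a `bs_grid`.
#' @param path file path.
#' @return `read_grid` returns a `bs_grid`; `write_grid` returns `path`
#'   invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "bs_grid"))
  obj <- list(lat_max = grid$lat_max, lon_min = grid$lon_min,
              n_rows = grid$n_rows, n_cols = grid$n_cols,
              cell_size = grid$cell_size,
              land_mask = as.integer(t(grid$land_mask)))  # row-major
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mask <- matrix(as.logical(obj$land_mask), obj$n_rows, obj$n_cols,
                 byrow = TRUE)
  build_grid(obj$lat_max, obj$lon_min, obj$n_rows, obj$n_cols,
             obj$cell_size, mask)
}

grid_congruent <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$lat_max - b$lat_max) <= tol &&
    abs(a$lon_min - b$lon_min) <= tol &&
    abs(a$cell_size - b$cell_size) <= tol &&
    identical(a$land_mask, b$land_mask)
}

stop_grid_mismatch <- function(file_grid, grid) {
  stop(sprintf(paste0(
    "grid mismatch: file has %dx%d cells of %g deg at (%.9g, %.9g), ",
    "expected %dx%d cells of %g deg at (%.9g, %.9g)"),
    file_grid$n_rows, file_grid$n_cols, file_grid$cell_size,
    file_grid$lat_max, file_grid$lon_min,
    grid$n_rows, grid$n_cols, grid$cell_size, grid$lat_max, grid$lon_min))
}

#' Write / read a cell field (gridded CSV)
#'
#' Columns `row,col,value` (plus `neighbor_count` for neighborhood
#' fields), one line per land cell in row-major order, 0-based indices,
#' 17 significant digits (lossless round trip for doubles). Missing cells
#' are written as empty values.
#'
#' @param field a [cell_field()].
#' @param path file path.
#' @param grid the `bs_grid` the file must conform to.
#' @return `read_field` returns a [cell_field()] (a `nbhd_field` when the
#'   file has a `neighbor_count` column).
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "cell_field"))
  g <- field$grid
  df <- data.frame(row = g$land_rc[, "row"] - 1L,
                   col = g$land_rc[, "col"] - 1L,
                   value = formatC(field$values, format = "g", digits = 17))
  df$value[is.na(field$values)] <- ""
  if (!is.null(field$neighbor_count)) df$neighbor_count <- field$neighbor_count
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @param name,units labels for the field read back.
#' @export
read_field <- function(path, grid, name = basename(path), units = "") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("row", "col", "value")
  if (!all(need %in% names(df))) stop("field CSV needs columns row,col,value")
  rc <- cbind(row = as.integer(df$row) + 1L, col = as.integer(df$col) + 1L)
  if (nrow(rc) != grid$n_land ||
      !all(rc == grid$land_rc))
    stop_grid_mismatch(list(n_rows = max(rc[, 1]), n_cols = max(rc[, 2]),
                            cell_size = NA, lat_max = NA, lon_min = NA), grid)
  vals <- suppressWarnings(as.numeric(df$value))
  f <- cell_field(grid, vals, name = name, units = units)
  if ("neighbor_count" %in% names(df)) {
    f$neighbor_count <- as.integer(df$neighbor_count)
    f$transform <- "none"
    class(f) <- c("nbhd_field", class(f))
  }
  f
}

#' Write / read a presence/absence matrix (CSV)
#'
#' First two columns `row,col` (0-based), then one 0/1 column per
#' species. Any entry other than 0 or 1 is a validation error.
#'
#' @param pam a `pa_matrix`.
#' @param path file path.
#' @param grid grid the file must conform to.
#' @param species_meta optional data.frame with `species_id` and
#'   `clade_path` to attach on read.
#' @return `read_pam` returns a `pa_matrix`.
#' @export
write_pam <- function(pam, path) {
  stopifnot(inherits(pam, "pa_matrix"))
  g <- pam$grid
  df <- data.frame(row = g$land_rc[, "row"] - 1L,
                   col = g$land_rc[, "col"] - 1L)
  inc <- pam$incidence * 1L
  df <- cbind(df, as.data.frame(inc))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pam
#' @export
read_pam <- function(path, grid, species_meta = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("row", "col") %in% names(df)))
    stop("PAM CSV needs leading columns row,col")
  rc <- cbind(row = as.integer(df$row) + 1L, col = as.integer(df$col) + 1L)
  if (nrow(rc) != grid$n_land || !all(rc == grid$land_rc))
    stop_grid_mismatch(list(n_rows = max(rc[, 1]), n_cols = max(rc[, 2]),
                            cell_size = NA, lat_max = NA, lon_min = NA), grid)
  sp_cols <- setdiff(names(df), c("row", "col"))
  if (length(sp_cols) == 0) stop("PAM CSV has no species columns")
  inc <- as.matrix(df[sp_cols])
  bad <- which(!(inc %in% c(0, 1)), arr.ind = FALSE)
  if (length(bad) > 0) {
    rcb <- arrayInd(bad[1], dim(inc))
    stop(sprintf("non-boolean PAM entry '%s' at data row %d, species '%s'",
                 inc[bad[1]], rcb[1], sp_cols[rcb[2]]))
  }
  inc <- matrix(as.logical(as.numeric(inc)), nrow(inc), ncol(inc),
                dimnames = list(NULL, sp_cols))
  clade <- rep("", length(sp_cols))
  if (!is.null(species_meta)) {
    m <- match(sp_cols, species_meta$species_id)
    clade[!is.na(m)] <- species_meta$clade_path[m[!is.na(m)]]
  }
  meta <- data.frame(species_id = sp_cols, clade_path = clade,
                     range_size_cells = colSums(inc),
                     stringsAsFactors = FALSE)
  structure(list(grid = grid, species_ids = sp_cols, incidence = inc,
                 species_meta = meta,
                 empty_species = sp_cols[colSums(inc) == 0]),
            class = "pa_matrix")
}

#' Read species ranges from GeoJSON
#'
#' Expects a FeatureCollection of Polygon/MultiPolygon features with
#' properties `species` (or `species_id`) and optionally `clade_path`
#' (`"A/B/C"`). Coordinates are lon/lat degrees.
#'
#' @param path file path.
#' @return list of ranges suitable for [build_pam()].
#' @export
read_ranges_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  lapply(gj$features, function(f) {
    pr <- f$properties
    sid <- if (!is.null(pr$species)) pr$species else pr$species_id
    if (is.null(sid)) stop("feature without a species property")
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(lapply(geom$coordinates, ring_mat)),
      MultiPolygon = lapply(geom$coordinates, function(p) lapply(p, ring_mat)),
      stop(sprintf("unsupported geometry type '%s' for species '%s'",
                   geom$type, sid)))
    list(species_id = sid,
         clade_path = if (!is.null(pr$clade_path)) pr$clade_path else "",
         geometry = polys)
  })
}

#' Write species ranges as GeoJSON cell-union polygons
#'
#' Each species becomes a MultiPolygon of its occupied cells (one square
#' per cell; adjacent cells are not dissolved).
#'
#' @param ranges named list of integer land-cell index vectors.
#' @param grid the `bs_grid`.
#' @param path file path.
#' @param species_meta optional data.frame with `species_id`,
#'   `clade_path`.
#' @export
write_ranges_geojson <- function(ranges, grid, path, species_meta = NULL) {
  cs <- grid$cell_size
  feats <- lapply(seq_along(ranges), function(i) {
    cells <- ranges[[i]]
    rc <- grid$land_rc[cells, , drop = FALSE]
    polys <- lapply(seq_len(nrow(rc)), function(k) {
      x0 <- grid$lon_min + (rc[k, "col"] - 1) * cs
      y1 <- grid$lat_max - (rc[k, "row"] - 1) * cs
      list(list(list(x0, y1 - cs), list(x0 + cs, y1 - cs),
                list(x0 + cs, y1), list(x0, y1), list(x0, y1 - cs)))
    })
    sid <- names(ranges)[i]
    clade <- ""
    if (!is.null(species_meta)) {
      m <- match(sid, species_meta$species_id)
      if (!is.na(m)) clade <- species_meta$clade_path[m]
    }
    list(type = "Feature",
         properties = list(species = sid, clade_path = clade),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# FNV-1a 64-bit-ish hash (on doubles mod 2^53) of a character scalar;
# stable across platforms, used to fingerprint configurations.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 14695981039346656037 %% 9007199254740992
  for (b in bytes) {
    h <- bitwXor(h %% 2^31, b) + (h %/% 2^31) * 2^31
    h <- (h * 1099511628211) %% 9007199254740992
  }
  sprintf("%.0f", h)
}

pipeline_defaults <- function() {
  list(
    grid_file = NULL,            # JSON grid definition
    input_mode = "polygons",     # "polygons" | "pam"
    ranges_file = NULL,          # GeoJSON (input_mode = polygons)
    pam_file = NULL,             # PAM CSV (input_mode = pam)
    env_files = NULL,            # named list of gridded CSV layer paths
    clades = NULL,               # clade labels to analyse separately
    restricted_quantile = 0.25,
    coverage_threshold = 0.5,
    adjacency = "queen",         # "queen" | "rook"
    diff_mode = "absolute",      # "absolute" | "signed"
    dist_method = "greatcircle", # "greatcircle" | "planar"
    pcnm_alpha = 0.05,
    pcnm_permutations = 99,
    pcnm_max_filters = 60,
    pcnm_i_stop = 0.05,
    select_on = "raw",           # filter selection on the raw response
    out_dir = NULL,
    seed = 1L,
    verbose = FALSE)
}

#' Pipeline configuration
#'
#' Builds a validated configuration for [run_pipeline()]. Every field has
#' a documented default (see the source of `pipeline_defaults`); unknown
#' keys are rejected before any computation. Configurations round-trip
#' through YAML: `read_config(write_config(x)) = x`.
#'
#' @param ... configuration fields overriding the defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  defs <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defs))
  if (length(unknown) > 0)
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defs, user, keep.null = TRUE)
  if (!cfg$input_mode %in% c("polygons", "pam"))
    stop("input_mode must be 'polygons' or 'pam'")
  if (!cfg$adjacency %in% c("queen", "rook")) stop("bad adjacency")
  if (!cfg$diff_mode %in% c("absolute", "signed")) stop("bad diff_mode")
  if (!cfg$dist_method %in% c("greatcircle", "planar")) stop("bad dist_method")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
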