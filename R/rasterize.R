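# Polygon-on-grid rasterization with a coverage rule, presence/absence
# assembly, richness, and range-size / clade subsets.

# Sutherland-Hodgman clip of a single ring (2-col matrix, not necessarily
# closed) against the half-plane a*x + b*y <= c. Returns the clipped ring.
clip_halfplane <- function(ring, a, b, cc) {
  n <- nrow(ring)
  if (n == 0) return(ring)
  vx <- ring[, 1]; vy <- ring[, 2]
  inside <- a * vx + b * vy <= cc + 1e-300
  px <- vx[c(n, seq_len(n - 1))]; py <- vy[c(n, seq_len(n - 1))]
  pin <- inside[c(n, seq_len(n - 1))]
  outx <- numeric(0); outy <- numeric(0)
  for (k in seq_len(n)) {
    if (inside[k]) {
      if (!pin[k]) {  # entering: add intersection
        t <- (cc - a * px[k] - b * py[k]) /
             (a * (vx[k] - px[k]) + b * (vy[k] - py[k]))
        outx <- c(outx, px[k] + t * (vx[k] - px[k]))
        outy <- c(outy, py[k] + t * (vy[k] - py[k]))
      }
      outx <- c(outx, vx[k]); outy <- c(outy, vy[k])
    } else if (pin[k]) {  # leaving: add intersection only
      t <- (cc - a * px[k] - b * py[k]) /
           (a * (vx[k] - px[k]) + b * (vy[k] - py[k]))
      outx <- c(outx, px[k] + t * (vx[k] - px[k]))
      outy <- c(outy, py[k] + t * (vy[k] - py[k]))
    }
  }
  cbind(outx, outy)
}

# Area of ring clipped to rectangle [x0,x1] x [y0,y1] (shoelace, absolute).
clipped_ring_area <- function(ring, x0, x1, y0, y1) {
  r <- clip_halfplane(ring, -1, 0, -x0)   # x >= x0
  r <- clip_halfplane(r, 1, 0, x1)        # x <= x1
  r <- clip_halfplane(r, 0, -1, -y0)      # y >= y0
  r <- clip_halfplane(r, 0, 1, y1)        # y <= y1
  n <- nrow(r)
  if (n < 3) return(0)
  x <- r[, 1]; y <- r[, 2]
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Normalize geometry input into a list of "polygons", each a list of rings
# (first ring outer, the rest holes), each ring a 2-col matrix (lon, lat).
as_polys <- function(geometry, species_id = "<unknown>") {
  fail <- function() stop(sprintf(
    "invalid or empty geometry for species '%s'", species_id))
  clean_ring <- function(r) {
    r <- as.matrix(r)
    if (!is.numeric(r) || ncol(r) != 2 || anyNA(r)) fail()
    # drop duplicated closing vertex
    if (nrow(r) > 1 && all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(r) < 3) fail()
    r
  }
  if (is.matrix(geometry) || is.data.frame(geometry))
    return(list(list(clean_ring(geometry))))
  if (is.list(geometry) && length(geometry) > 0) {
    if (is.matrix(geometry[[1]]) || is.data.frame(geometry[[1]]))
      return(list(lapply(geometry, clean_ring)))          # one polygon + holes
    if (is.list(geometry[[1]]))
      return(lapply(geometry, function(p) lapply(p, clean_ring)))  # multipolygon
  }
  fail()
}

#' Rasterize a species range onto the grid
#'
#' A species is scored present in a cell when its range polygon covers at
#' least `coverage_threshold` of the cell's area (default one half,
#' inclusive: exactly 50% coverage admits the cell). Coverage is computed
#' by exact polygon-rectangle clipping in planar lon/lat degrees.
#'
#' @param range a species range: a list with `species_id`, optional
#'   `clade_path`, and either `geometry` (a 2-column lon/lat matrix, a
#'   list of rings where the first is the outer boundary and later rings
#'   are holes, or a list of such polygons) or `cells` (an explicit
#'   integer vector of land-cell indices, which bypasses clipping).
#' @param grid a `bs_grid`.
#' @param coverage_threshold minimum covered fraction of a cell, in
#'   `(0, 1]`.
#' @return Sorted integer vector of land-cell indices. A range whose
#'   polygon never reaches the threshold yields an empty set with a
#'   warning.
#' @export
rasterize_range <- function(range, grid, coverage_threshold = 0.5) {
  stopifnot(inherits(grid, "bs_grid"))
  if (!is.numeric(coverage_threshold) || coverage_threshold <= 0 ||
      coverage_threshold > 1)
    stop("coverage_threshold must lie in (0, 1]")
  sid <- if (!is.null(range$species_id)) range$species_id else "<unknown>"
  if (!is.null(range$cells)) {
    cells <- as.integer(range$cells)
    if (length(cells) == 0 || anyNA(cells) ||
        any(cells < 1) || any(cells > grid$n_land))
      stop(sprintf("invalid explicit cell set for species '%s'", sid))
    return(sort(unique(cells)))
  }
  polys <- as_polys(range$geometry, sid)
  cs <- grid$cell_size
  cell_area <- cs * cs

  # candidate cells: bounding box of all rings
  allv <- do.call(rbind, unlist(polys, recursive = FALSE))
  if (max(apply(allv, 2, function(v) diff(range(v)))) == 0 ||
      nrow(allv) < 3)
    stop(sprintf("invalid or empty geometry for species '%s'", sid))
  c_lo <- max(1L, 1L + floor((min(allv[, 1]) - grid$lon_min) / cs))
  c_hi <- min(grid$n_cols, 1L + floor((max(allv[, 1]) - grid$lon_min) / cs + 1e-12))
  r_lo <- max(1L, 1L + floor((grid$lat_max - max(allv[, 2])) / cs))
  r_hi <- min(grid$n_rows, 1L + floor((grid$lat_max - min(allv[, 2])) / cs + 1e-12))
  hits <- integer(0)
  if (c_lo <= c_hi && r_lo <= r_hi) {
    for (r in r_lo:r_hi) for (ccol in c_lo:c_hi) {
      idx <- grid$cell_index[r, ccol]
      if (is.na(idx)) next
      x0 <- grid$lon_min + (ccol - 1) * cs; x1 <- x0 + cs
      y1 <- grid$lat_max - (r - 1) * cs;   y0 <- y1 - cs
      cov <- 0
      for (p in polys) {
        cov <- cov + clipped_ring_area(p[[1]], x0, x1, y0, y1)
        if (length(p) > 1)
          for (h in p[-1]) cov <- cov - clipped_ring_area(h, x0, x1, y0, y1)
      }
      if (cov / cell_area >= coverage_threshold - 1e-12)
        hits <- c(hits, idx)
    }
  }
  if (length(hits) == 0)
    warning(sprintf("species '%s' occupies no cell at threshold %g",
                    sid, coverage_threshold))
  sort(hits)
}

#' Build a presence/absence matrix
#'
#' Rasterizes every range with [rasterize_range()] and assembles the
#' boolean land-cells x species incidence matrix. Species that occupy no
#' cell are retained as all-`FALSE` columns and listed in the
#' `empty_species` attribute so counts stay auditable.
#'
#' @param ranges list of species ranges (see [rasterize_range()]); names
#'   or `species_id` entries must be unique. A bare integer vector element
#'   is taken as an explicit cell set.
#' @param grid a `bs_grid`.
#' @param coverage_threshold passed to [rasterize_range()].
#' @param species_meta optional data.frame with columns `species_id`,
#'   `clade_path` (and optionally others) overriding per-range metadata.
#' @return An object of class `pa_matrix`: list with `grid`,
#'   `species_ids`, `incidence` (logical matrix, land cells x species),
#'   and `species_meta` (species_id, clade_path, range_size_cells).
#' @export
build_pam <- function(ranges, grid, coverage_threshold = 0.5,
                      species_meta = NULL) {
  stopifnot(inherits(grid, "bs_grid"))
  if (length(ranges) < 1) stop("need at least one species range")
  norm <- lapply(seq_along(ranges), function(i) {
    r <- ranges[[i]]
    if (is.numeric(r) && is.null(dim(r))) r <- list(cells = r)
    if (is.null(r$species_id))
      r$species_id <- if (!is.null(names(ranges)) && nzchar(names(ranges)[i]))
        names(ranges)[i] else sprintf("sp%04d", i)
    r
  })
  ids <- vapply(norm, function(r) as.character(r$species_id), "")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate species_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  inc <- matrix(FALSE, grid$n_land, length(ids),
                dimnames = list(NULL, ids))
  for (i in seq_along(norm)) {
    cells <- withCallingHandlers(
      rasterize_range(norm[[i]], grid, coverage_threshold),
      warning = function(w) invokeRestart("muffleWarning"))
    inc[cells, i] <- TRUE
  }
  clade <- vapply(norm, function(r)
    if (!is.null(r$clade_path)) as.character(r$clade_path) else "", "")
  meta <- data.frame(species_id = ids, clade_path = clade,
                     range_size_cells = colSums(inc),
                     stringsAsFactors = FALSE)
  if (!is.null(species_meta)) {
    m <- match(meta$species_id, species_meta$species_id)
    ok <- !is.na(m)
    if ("clade_path" %in% names(species_meta))
      meta$clade_path[ok] <- species_meta$clade_path[m[ok]]
  }
  empty <- ids[colSums(inc) == 0]
  if (length(empty) > 0)
    message(sprintf("%d species occupy no cell: %s", length(empty),
                    paste(utils::head(empty, 5), collapse = ", ")))
  structure(list(grid = grid, species_ids = ids, incidence = inc,
                 species_meta = meta, empty_species = empty),
            class = "pa_matrix")
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf("<pa_matrix> %d land cells x %d species (%d empty columns)\n",
              nrow(x$incidence), ncol(x$incidence), length(x$empty_species)))
  cat(sprintf("  occupancy: %d presences, mean range %0.1f cells\n",
              sum(x$incidence), mean(colSums(x$incidence))))
  invisible(x)
}

#' Species richness per cell
#'
#' Sums the species present in each cell. Richness is defined for every
#' land cell (an empty cell has richness 0, not missing).
#'
#' @param pam a `pa_matrix`.
#' @return A [cell_field()] of integer counts.
#' @export
richness <- function(pam) {
  stopifnot(inherits(pam, "pa_matrix"))
  cell_field(pam$grid, as.numeric(rowSums(pam$incidence)),
             name = "richness", units = "species")
}

#' Subset to restricted-range species
#'
#' Keeps the `ceiling(quantile * S)` species with the smallest occupied
#' range (in cells). Ties at the cutoff are broken deterministically by
#' species_id order, so the subset size is exactly `ceiling(quantile * S)`.
#'
#' @param pam a `pa_matrix`.
#' @param quantile fraction of species to keep, in `(0, 1)`; default the
#'   smallest-range quartile.
#' @return A `pa_matrix` restricted to the selected species.
#' @export
restricted_range_subset <- function(pam, quantile = 0.25) {
  stopifnot(inherits(pam, "pa_matrix"))
  if (!is.numeric(quantile) || quantile <= 0 || quantile >= 1)
    stop("quantile must lie in (0, 1)")
  sizes <- pam$species_meta$range_size_cells
  if (any(sizes < 1))
    stop("every species must occupy at least one cell")
  S <- length(pam$species_ids)
  k <- as.integer(ceiling(quantile * S))
  keep <- order(sizes, seq_len(S))[seq_len(k)]  # stable: ties by id order
  subset_pam(pam, sort(keep))
}

#' Subset to a clade
#'
#' Keeps species whose `clade_path` (a `/`-separated lineage string such
#' as `"Sigmodontinae/Akodontini"`) contains `clade_label` as one of its
#' components.
#'
#' @param pam a `pa_matrix`.
#' @param clade_label label to match.
#' @return A `pa_matrix` restricted to the clade.
#' @export
clade_subset <- function(pam, clade_label) {
  stopifnot(inherits(pam, "pa_matrix"))
  parts <- strsplit(pam$species_meta$clade_path, "/", fixed = TRUE)
  keep <- which(vapply(parts, function(p) clade_label %in% p, TRUE))
  if (length(keep) == 0) {
    known <- sort(unique(unlist(parts)))
    stop(sprintf("unknown clade label '%s'; known labels: %s",
                 clade_label, paste(known, collapse = ", ")))
  }
  subset_pam(pam, keep)
}

subset_pam <- function(pam, keep) {
  inc <- pam$incidence[, keep, drop = FALSE]
  structure(list(grid = pam$grid, species_ids = pam$species_ids[keep],
                 incidence = inc,
                 species_meta = pam$species_meta[keep, , drop = FALSE],
                 empty_species = intersect(pam$empty_species,
                                           pam$species_ids[keep])),
            class = "pa_matrix")
}
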