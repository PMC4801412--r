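#' Specification of a synthetic continent
#'
#' Parameter container for [make_continent()]. The virtual continent is a
#' rectangular all-land lattice carrying four environmental layers:
#'
#' * **elevation** (m): a Gaussian ridge running north-south near one
#'   margin (an Andes stand-in), plus smooth regional undulation
#'   (`elevation_noise_sd`) and rough local relief
#'   (`elevation_relief_sd`);
#' * **temperature** (deg C):
#'   `temp_equator - temp_latitude_slope * |lat - lat_equator| -
#'   temp_lapse * regional_elevation / 1000`, plus (when
#'   `temp_noise_sd > 0`) a smooth anomaly field emulating
#'   maritime/continental departures from the lapse + latitude model.
#'   The lapse acts on the regional (ridge + smooth undulation) part of
#'   elevation only: interpolated climate surfaces follow smoothed
#'   topography, not cell-scale rough relief. Without the anomaly,
#'   temperature would be an exact linear combination of elevation and
#'   latitude and the predictor set would be singular (infinite VIF),
#'   unlike any real climate surface. With `elevation_relief_sd = 0` and
#'   `temp_noise_sd = 0` the formula above is exact in elevation;
#' * **precipitation** (mm): a smooth monotone (increasing) function of
#'   latitude plus smooth noise;
#' * **seasonality** (index): a smooth monotone (decreasing, i.e. more
#'   seasonal southward) function of latitude plus smooth noise.
#'
#' All randomness derives from `seed`; identical spec + seed gives
#' bit-identical layers.
#'
#' @param n_rows,n_cols lattice dimensions (>= 3).
#' @param cell_size cell edge, degrees.
#' @param lat_max,lon_min northern / western grid edge, degrees.
#' @param lat_equator latitude treated as the thermal equator.
#' @param ridge_position ridge centre as a fraction of the column span,
#'   in `[0, 1]` (0 = western margin).
#' @param ridge_height ridge crest height, m (>= 0).
#' @param ridge_width Gaussian ridge width (standard deviation), columns (>= 1).
#' @param elevation_noise_sd standard deviation of the smooth regional
#'   elevation undulation, m.
#' @param elevation_relief_sd standard deviation of the rough local
#'   relief (not mirrored in temperature), m.
#' @param temp_equator mean temperature at the equator at sea level, deg C.
#' @param temp_lapse lapse rate, deg C per 1000 m.
#' @param temp_latitude_slope cooling per degree of latitude away from the
#'   equator, deg C.
#' @param temp_noise_sd standard deviation of the smooth temperature
#'   anomaly, deg C.
#' @param precip_base precipitation at the equator, mm.
#' @param precip_latitude_slope change in precipitation per degree of
#'   (signed) latitude, mm.
#' @param precip_noise_sd smooth precipitation noise sd, mm.
#' @param seasonality_base seasonality index at the equator.
#' @param seasonality_latitude_slope increase in seasonality per degree of
#'   latitude away from the equator.
#' @param seasonality_noise_sd smooth seasonality noise sd.
#' @param seed integer RNG seed.
#' @return A validated list of class `continent_spec`.
#' @export
continent_spec <- function(n_rows = 40, n_cols = 60, cell_size = 0.5,
                           lat_max = 5, lon_min = -80, lat_equator = 0,
                           ridge_position = 0.15, ridge_height = 2500,
                           ridge_width = 3, elevation_noise_sd = 180,
                           elevation_relief_sd = 450,
                           temp_equator = 27, temp_lapse = 6.5,
                           temp_latitude_slope = 0.6,
                           temp_noise_sd = 1.5,
                           precip_base = 2200, precip_latitude_slope = 45,
                           precip_noise_sd = 120,
                           seasonality_base = 1,
                           seasonality_latitude_slope = 0.15,
                           seasonality_noise_sd = 0.25,
                           seed = 1L) {
  if (n_rows < 3 || n_cols < 3) stop("invalid continent spec: n_rows and n_cols must be >= 3")
  if (cell_size <= 0) stop("invalid continent spec: cell_size must be > 0")
  if (ridge_position < 0 || ridge_position > 1)
    stop("invalid continent spec: ridge_position must lie in [0, 1]")
  if (ridge_height < 0) stop("invalid continent spec: ridge_height must be >= 0")
  if (ridge_width < 1) stop("invalid continent spec: ridge_width must be >= 1")
  if (elevation_noise_sd < 0 || elevation_relief_sd < 0 || temp_noise_sd < 0 ||
      precip_noise_sd < 0 || seasonality_noise_sd < 0)
    stop("invalid continent spec: noise sd must be >= 0")
  spec <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
               cell_size = cell_size, lat_max = lat_max, lon_min = lon_min,
               lat_equator = lat_equator,
               ridge_position = ridge_position, ridge_height = ridge_height,
               ridge_width = ridge_width,
               elevation_noise_sd = elevation_noise_sd,
               elevation_relief_sd = elevation_relief_sd,
               temp_equator = temp_equator, temp_lapse = temp_lapse,
               temp_latitude_slope = temp_latitude_slope,
               temp_noise_sd = temp_noise_sd,
               precip_base = precip_base,
               precip_latitude_slope = precip_latitude_slope,
               precip_noise_sd = precip_noise_sd,
               seasonality_base = seasonality_base,
               seasonality_latitude_slope = seasonality_latitude_slope,
               seasonality_noise_sd = seasonality_noise_sd,
               seed = as.integer(seed))
  class(spec) <- "continent_spec"
  spec
}

# Smooth Gaussian noise on the lattice: iid normals passed through a 3x3
# moving average (`passes` times; more passes = longer correlation
# length), rescaled to the requested sd. Deterministic given the seed.
smooth_noise <- function(n_rows, n_cols, sd, seed, passes = 2) {
  if (sd == 0) return(matrix(0, n_rows, n_cols))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  for (pass in seq_len(passes)) {
    zp <- rbind(z[1, ], z, z[n_rows, ])
    zp <- cbind(zp[, 1], zp, zp[, n_cols])
    z <- (zp[1:n_rows, 1:n_cols] + zp[1:n_rows, 2:(n_cols + 1)] + zp[1:n_rows, 3:(n_cols + 2)] +
          zp[2:(n_rows + 1), 1:n_cols] + zp[2:(n_rows + 1), 2:(n_cols + 1)] + zp[2:(n_rows + 1), 3:(n_cols + 2)] +
          zp[3:(n_rows + 2), 1:n_cols] + zp[3:(n_rows + 2), 2:(n_cols + 1)] + zp[3:(n_rows + 2), 3:(n_cols + 2)]) / 9
  }
  z <- z - mean(z)
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z * (sd / s)
  z
}

#' Generate a virtual continent
#'
#' Builds the grid and the four environmental layers described in
#' [continent_spec()].
#'
#' @param spec a `continent_spec`.
#' @param land_mask optional logical mask; defaults to all-land.
#' @return list with elements `grid` (a `bs_grid`) and `env`, a named list
#'   of four [cell_field()] layers: `elevation`, `temperature`,
#'   `precipitation`, `seasonality`.
#' @examples
#' ct <- make_continent(continent_spec(n_rows = 10, n_cols = 12, seed = 7))
#' range(ct$env$elevation$values)
#' @export
make_continent <- function(spec, land_mask = NULL) {
  stopifnot(inherits(spec, "continent_spec"))
  grid <- build_grid(spec$lat_max, spec$lon_min, spec$n_rows, spec$n_cols,
                     spec$cell_size, land_mask)
  if (grid$n_land == 0) stop("continent has no land cells")
  rc <- grid$land_rc
  ctr <- grid_centers(grid)
  dlat <- abs(ctr$lat - spec$lat_equator)

  ridge_col <- 0.5 + spec$ridge_position * (spec$n_cols - 1)  # in column units
  elev_regional <- spec$ridge_height *
    exp(-0.5 * ((rc[, "col"] - ridge_col) / spec$ridge_width)^2) +
    smooth_noise(spec$n_rows, spec$n_cols, spec$elevation_noise_sd,
                 spec$seed + 101L, passes = 5)[rc]
  elev <- elev_regional +
    smooth_noise(spec$n_rows, spec$n_cols, spec$elevation_relief_sd,
                 spec$seed + 505L, passes = 1)[rc]

  # the lapse follows the regional elevation surface; climatic anomalies
  # are regional too, so the anomaly gets a long correlation length
  temp_noise <- smooth_noise(spec$n_rows, spec$n_cols, spec$temp_noise_sd,
                             spec$seed + 404L, passes = 8)
  temp <- spec$temp_equator - spec$temp_latitude_slope * dlat -
    spec$temp_lapse * elev_regional / 1000 + temp_noise[rc]

  prec_noise <- smooth_noise(spec$n_rows, spec$n_cols, spec$precip_noise_sd,
                             spec$seed + 202L)
  prec <- spec$precip_base + spec$precip_latitude_slope *
    (ctr$lat - spec$lat_equator) + prec_noise[rc]

  seas_noise <- smooth_noise(spec$n_rows, spec$n_cols, spec$seasonality_noise_sd,
                             spec$seed + 303L)
  seas <- spec$seasonality_base + spec$seasonality_latitude_slope *
    (spec$lat_equator - ctr$lat) + seas_noise[rc]

  env <- list(
    elevation     = cell_field(grid, elev, "elevation", "m"),
    temperature   = cell_field(grid, temp, "temperature", "degC"),
    precipitation = cell_field(grid, prec, "precipitation", "mm"),
    seasonality   = cell_field(grid, seas, "seasonality", "index"))
  list(grid = grid, env = env)
}

#' Specification of a virtual clade
#'
#' Parameters for [simulate_ranges()]. Each species in the clade gets a
#' niche optimum drawn from the environment at a seed cell; the clade's
#' `niche_axis_weights` say which environmental axes structure its
#' distribution (order: elevation, temperature, precipitation,
#' seasonality). The sign of a weight sets the preferred direction along
#' the axis (positive = species concentrate where the axis is high), its
#' magnitude the selectivity of the niche on that axis.
#'
#' @param clade_id label.
#' @param n_species number of species (>= 1).
#' @param niche_axis_weights numeric length-4 vector; at least one nonzero.
#' @param niche_breadth Gaussian niche breadth in per-axis standard
#'   deviations of the environment (> 0).
#' @param range_size_log_mean,range_size_log_sd log-normal parameters for
#'   target range size in cells (right-skewed sizes; `log_sd` >= 0).
#' @param seed_bias strength of the preference with which species seed
#'   cells scoring high on the clade's weighted environmental axes
#'   (0 = uniform seeding).
#' @param seed integer RNG seed.
#' @return A validated list of class `clade_spec`.
#' @export
clade_spec <- function(clade_id, n_species,
                       niche_axis_weights,
                       niche_breadth = 0.8,
                       range_size_log_mean = log(50),
                       range_size_log_sd = 0.8,
                       seed_bias = 1.2,
                       seed = 1L) {
  if (n_species < 1) stop("invalid clade spec: n_species must be >= 1")
  if (length(niche_axis_weights) != 4 || all(niche_axis_weights == 0))
    stop("invalid clade spec: niche_axis_weights must be length 4 with a nonzero entry")
  if (niche_breadth <= 0) stop("invalid clade spec: niche_breadth must be > 0")
  if (range_size_log_sd < 0) stop("invalid clade spec: range_size_log_sd must be >= 0")
  structure(list(clade_id = as.character(clade_id),
                 n_species = as.integer(n_species),
                 niche_axis_weights = as.numeric(niche_axis_weights),
                 niche_breadth = niche_breadth,
                 range_size_log_mean = range_size_log_mean,
                 range_size_log_sd = range_size_log_sd,
                 seed_bias = seed_bias,
                 seed = as.integer(seed)),
            class = "clade_spec")
}

# Per-species subseed: a fixed counter scheme so adding species never
# perturbs the draws of earlier ones.
species_subseed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + 7919 * as.double(i)) %% 2147483647)
}

#' Simulate niche-structured species ranges
#'
#' For each species: a seed cell is drawn with probability proportional to
#' `exp(seed_bias * weighted environmental score)` (so the clade
#' concentrates where its favoured axes score high); the niche optimum is
#' the standardized environment at that cell; habitat suitability is a
#' Gaussian kernel of the weighted environmental distance from the
#' optimum; and the range grows from the seed cell by repeatedly annexing
#' the most-suitable adjacent land cell (queen adjacency, ties broken by
#' row-major cell order) until a log-normal target size is reached. Ranges
#' are therefore always single connected components. If growth exhausts
#' the reachable landmass before the target size, the range is truncated
#' and flagged in the truth record.
#'
#' @param grid a `bs_grid` with at least one land cell.
#' @param env named list of the four environmental [cell_field()] layers
#'   (as from [make_continent()]), aligned with `grid`.
#' @param clade a `clade_spec`.
#' @return list with
#'   `ranges`: named list of integer land-cell index vectors, one per
#'   species;
#'   `species_meta`: data.frame (species_id, clade_path, range_size_cells);
#'   `truth`: ground-truth record (class `synthetic_truth`) with the clade
#'   weights, the expected ranking of predictors by `|weight|`, per-species
#'   niche optima in environmental units, realized sizes and truncation
#'   flags, and the seed.
#' @export
simulate_ranges <- function(grid, env, clade) {
  stopifnot(inherits(grid, "bs_grid"), inherits(clade, "clade_spec"))
  if (grid$n_land == 0) stop("grid has no land cells")
  lay <- c("elevation", "temperature", "precipitation", "seasonality")
  if (!all(lay %in% names(env))) stop("env must contain the four standard layers")
  for (nm in lay)
    if (length(env[[nm]]$values) != grid$n_land)
      stop("environmental layers are not aligned with the grid")

  E <- sapply(lay, function(nm) env[[nm]]$values)   # n_land x 4
  mu <- colMeans(E); sg <- apply(E, 2, stats::sd)
  sg[sg == 0] <- 1
  Z <- sweep(sweep(E, 2, mu), 2, sg, "/")

  w <- clade$niche_axis_weights
  score <- as.vector(Z %*% w)
  ssd <- stats::sd(score)
  seed_prob <- if (ssd > 0) exp(clade$seed_bias * (score - max(score)) / ssd) else
    rep(1, grid$n_land)

  # adjacency list (queen) for growth
  ap <- adjacency_pairs(grid, "queen")
  nbr <- split(ap[, "neighbor"], ap[, "focal"])
  nbr_of <- vector("list", grid$n_land)
  nbr_of[as.integer(names(nbr))] <- nbr

  aw <- abs(w)
  two_b2 <- 2 * clade$niche_breadth^2

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  n <- clade$n_species
  ranges <- vector("list", n)
  opt_env <- matrix(NA_real_, n, 4, dimnames = list(NULL, lay))
  sizes <- integer(n); truncated <- logical(n)
  ids <- sprintf("%s_sp%04d", clade$clade_id, seq_len(n))

  for (i in seq_len(n)) {
    set.seed(species_subseed(clade$seed, i))
    seed_cell <- sample.int(grid$n_land, 1, prob = seed_prob)
    opt <- Z[seed_cell, ]
    opt_env[i, ] <- mu + sg * opt
    target <- max(1L, as.integer(ceiling(stats::rlnorm(
      1, clade$range_size_log_mean, clade$range_size_log_sd))))

    # suitability of every cell for this species
    d2 <- as.vector((sweep(Z, 2, opt))^2 %*% aw)
    suit <- exp(-d2 / two_b2)

    in_range <- logical(grid$n_land)
    in_range[seed_cell] <- TRUE
    members <- integer(target); members[1] <- seed_cell
    m <- 1L
    frontier <- nbr_of[[seed_cell]]
    while (m < target && length(frontier) > 0) {
      # most suitable frontier cell; ties -> smallest row-major index
      best <- frontier[which.max(suit[frontier])]
      cand <- frontier[suit[frontier] == suit[best]]
      best <- min(cand)
      m <- m + 1L
      members[m] <- best
      in_range[best] <- TRUE
      frontier <- frontier[frontier != best]
      new_nb <- nbr_of[[best]]
      new_nb <- new_nb[!in_range[new_nb]]
      frontier <- unique(c(frontier, new_nb))
    }
    ranges[[i]] <- sort(members[seq_len(m)])
    sizes[i] <- m
    truncated[i] <- m < target
  }
  names(ranges) <- ids

  truth <- structure(list(
    clade_id = clade$clade_id,
    niche_axis_weights = stats::setNames(w, lay),
    expected_predictor_ranking = lay[order(-abs(w))],
    niche_optimum = opt_env,
    range_size_cells = sizes,
    truncated = truncated,
    seed = clade$seed), class = "synthetic_truth")

  list(ranges = ranges,
       species_meta = data.frame(species_id = ids,
                                 clade_path = clade$clade_id,
                                 range_size_cells = sizes,
                                 stringsAsFactors = FALSE),
       truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> clade '%s': %d species, seed %d\n",
              x$clade_id, length(x$range_size_cells), x$seed))
  cat("  weights:", paste(sprintf("%s=%g", names(x$niche_axis_weights),
                                  x$niche_axis_weights), collapse = ", "), "\n")
  cat("  expected predictor ranking:",
      paste(x$expected_predictor_ranking, collapse = " > "), "\n")
  invisible(x)
}
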