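# Baselga beta-diversity components and neighborhood (focal cell vs its
# adjacent cells) turnover and environmental-difference fields.

#' Pairwise composition counts between two cells
#'
#' @param pam a `pa_matrix`.
#' @param cell_i,cell_j land-cell indices (focal = `cell_i`).
#' @return Named integer vector `c(a, b, c)`: species shared, exclusive to
#'   the focal cell, and exclusive to the other cell.
#' @export
pair_components <- function(pam, cell_i, cell_j) {
  stopifnot(inherits(pam, "pa_matrix"))
  n <- nrow(pam$incidence)
  for (cc in c(cell_i, cell_j))
    if (!is.numeric(cc) || cc < 1 || cc > n || cc != round(cc))
      stop("cell index out of range: not a land cell")
  si <- pam$incidence[cell_i, ]
  sj <- pam$incidence[cell_j, ]
  c(a = sum(si & sj), b = sum(si & !sj), c = sum(!si & sj))
}

check_abc <- function(a, b, c) {
  if (any(c(a, b, c) < 0)) stop("component counts must be non-negative")
}

#' Simpson-based turnover component
#'
#' `beta_sim = min(b, c) / (a + min(b, c))`: the turnover component of
#' beta diversity, insensitive to richness differences between the two
#' cells (a nested pair, `min(b, c) = 0` with `a > 0`, scores 0 no matter
#' how unequal the richnesses are). Undefined — returned as `NA` — when
#' `a + min(b, c) = 0`, i.e. when at least one of the two communities is
#' effectively empty.
#'
#' @param a,b,c non-negative counts (vectorized).
#' @return numeric in `[0, 1]`, or `NA` where undefined.
#' @export
beta_sim <- function(a, b, c) {
  check_abc(a, b, c)
  m <- pmin(b, c)
  den <- a + m
  out <- ifelse(den == 0, NA_real_, m / den)
  as.numeric(out)
}

#' Sorensen dissimilarity and its nestedness component
#'
#' `beta_sor = (b + c) / (2a + b + c)` and
#' `beta_sne = beta_sor - beta_sim`, completing the Baselga decomposition
#' `beta_sor = beta_sim + beta_sne`. Undefined (`NA`) when
#' `2a + b + c = 0`; `beta_sne` additionally inherits `beta_sim`'s
#' undefined cases.
#'
#' @inheritParams beta_sim
#' @return list with numeric components `beta_sor` and `beta_sne`.
#' @export
beta_sor_sne <- function(a, b, c) {
  check_abc(a, b, c)
  den <- 2 * a + b + c
  bsor <- ifelse(den == 0, NA_real_, (b + c) / den)
  bsne <- bsor - beta_sim(a, b, c)
  list(beta_sor = as.numeric(bsor), beta_sne = as.numeric(bsne))
}

# a-counts for a list of directed cell pairs, vectorized over pairs.
pair_shared_counts <- function(inc, ii, jj) {
  if (length(ii) == 0) return(integer(0))
  rowSums(inc[ii, , drop = FALSE] & inc[jj, , drop = FALSE])
}

#' Neighborhood turnover field
#'
#' For each land cell, the mean Simpson turnover ([beta_sim()]) between
#' the focal cell and each of its (up to eight) adjacent land cells.
#' Pairs where `beta_sim` is undefined are skipped; the number of pairs
#' actually used is recorded per cell, and cells with no usable pair are
#' missing. Coastal and grid-edge cells simply average over the adjacent
#' land cells that exist.
#'
#' @param pam a `pa_matrix`.
#' @param adjacency `"queen"` (default, 8 neighbours) or `"rook"` (4;
#'   offered for sensitivity analysis).
#' @return A `nbhd_field` (a [cell_field()] with extra elements
#'   `neighbor_count` and `transform`).
#' @export
neighborhood_turnover <- function(pam, adjacency = c("queen", "rook")) {
  stopifnot(inherits(pam, "pa_matrix"))
  adjacency <- match.arg(adjacency)
  grid <- pam$grid
  ap <- adjacency_pairs(grid, adjacency)
  ii <- ap[, "focal"]; jj <- ap[, "neighbor"]
  rich <- rowSums(pam$incidence)
  a <- pair_shared_counts(pam$incidence, ii, jj)
  b <- rich[ii] - a
  c_ <- rich[jj] - a
  bs <- beta_sim(a, b, c_)
  ok <- !is.na(bs)
  used <- tabulate(ii[ok], nbins = grid$n_land)
  tot <- numeric(grid$n_land)
  if (any(ok)) {
    agg <- rowsum(bs[ok], ii[ok])
    tot[as.integer(rownames(agg))] <- agg[, 1]
  }
  vals <- ifelse(used > 0, tot / pmax(used, 1L), NA_real_)
  nbhd_field(grid, vals, used, name = "turnover", units = "beta_sim",
             transform = "none")
}

nbhd_field <- function(grid, values, neighbor_count, name, units, transform) {
  f <- cell_field(grid, values, name, units)
  f$neighbor_count <- as.integer(neighbor_count)
  f$transform <- transform
  class(f) <- c("nbhd_field", class(f))
  f
}

#' Square-root transform of a neighborhood field
#'
#' Turnover values are right-skewed; the square root symmetrizes them
#' before regression. Missing cells are preserved; negative values are an
#' error.
#'
#' @param field a `nbhd_field` (or any `cell_field`).
#' @return The transformed field with its `transform` tag set to
#'   `"sqrt"`.
#' @export
sqrt_transform <- function(field) {
  stopifnot(inherits(field, "cell_field"))
  v <- field$values
  if (any(v < 0, na.rm = TRUE))
    stop("square-root transform needs non-negative values")
  field$values <- sqrt(v)
  field$transform <- "sqrt"
  field$name <- paste0("sqrt_", field$name)
  if (!inherits(field, "nbhd_field")) class(field) <- c("nbhd_field", class(field))
  field
}

#' Neighborhood environmental difference (".dif" predictor)
#'
#' For each land cell, the mean difference between the focal cell's value
#' and each adjacent land cell's value, matching the spatial scale of the
#' turnover statistic. The default takes mean *absolute* differences
#' (signed differences cancel on monotone gradients, which would erase
#' exactly the relief signal this predictor exists to capture);
#' `mode = "signed"` is available for sensitivity analysis. Pairs with a
#' missing neighbour value are skipped; a focal cell that is itself
#' missing, or has no valid pair, is missing.
#'
#' @param layer a [cell_field()] environmental layer.
#' @param adjacency `"queen"` (default) or `"rook"`.
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return A `nbhd_field` named `<layer>.dif`.
#' @export
neighborhood_env_diff <- function(layer, adjacency = c("queen", "rook"),
                                  mode = c("absolute", "signed")) {
  stopifnot(inherits(layer, "cell_field"))
  adjacency <- match.arg(adjacency)
  mode <- match.arg(mode)
  grid <- layer$grid
  ap <- adjacency_pairs(grid, adjacency)
  ii <- ap[, "focal"]; jj <- ap[, "neighbor"]
  d <- layer$values[ii] - layer$values[jj]
  if (mode == "absolute") d <- abs(d)
  ok <- !is.na(d)
  used <- tabulate(ii[ok], nbins = grid$n_land)
  tot <- numeric(grid$n_land)
  if (any(ok)) {
    agg <- rowsum(d[ok], ii[ok])
    tot[as.integer(rownames(agg))] <- agg[, 1]
  }
  vals <- ifelse(used > 0, tot / pmax(used, 1L), NA_real_)
  nbhd_field(grid, vals, used, name = paste0(layer$name, ".dif"),
             units = layer$units, transform = "none")
}
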