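# Spatial weights, Moran's I, correlograms, PCNM eigenvector filters and
# residual-autocorrelation filter selection.

#' Queen contiguity weights
#'
#' Binary symmetric weights: `w_ij = 1` iff land cells i and j share an
#' edge or a corner.
#'
#' @param grid a `bs_grid` with at least two land cells.
#' @param scheme `"queen"` (default) or `"rook"`.
#' @return An object of class `spatial_weights`: list with `n`, a sparse
#'   symmetric `Matrix::sparseMatrix` `w` with zero diagonal, and a
#'   `scheme` tag.
#' @export
queen_weights <- function(grid, scheme = c("queen", "rook")) {
  stopifnot(inherits(grid, "bs_grid"))
  scheme <- match.arg(scheme)
  if (grid$n_land < 2) stop("need at least two land cells")
  ap <- adjacency_pairs(grid, scheme)
  w <- Matrix::sparseMatrix(i = ap[, "focal"], j = ap[, "neighbor"],
                            x = 1, dims = c(grid$n_land, grid$n_land))
  structure(list(n = grid$n_land, w = w, scheme = scheme),
            class = "spatial_weights")
}

# Arbitrary-weight constructor (used by correlogram distance classes).
weights_from_matrix <- function(w, scheme) {
  structure(list(n = nrow(w), w = w, scheme = scheme),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> n = %d, scheme = %s, %d nonzero links\n",
              x$n, x$scheme, Matrix::nnzero(x$w)))
  invisible(x)
}

#' Moran's I
#'
#' Global spatial autocorrelation:
#' `I = (n / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `W = sum_ij w_ij` over `i != j`. Cells with missing values are
#' dropped together with their weights. Needs at least three defined
#' values with nonzero variance.
#'
#' @param values a [cell_field()] or plain numeric vector.
#' @param w a `spatial_weights` on the same cells.
#' @return numeric scalar.
#' @export
morans_i <- function(values, w) {
  x <- if (inherits(values, "cell_field")) values$values else as.numeric(values)
  stopifnot(inherits(w, "spatial_weights"))
  if (length(x) != w$n) stop("values and weights have different lengths")
  ok <- !is.na(x)
  if (sum(ok) < 3) stop("need at least 3 defined values")
  x <- x[ok]
  wm <- w$w[ok, ok, drop = FALSE]
  xc <- x - mean(x)
  ss <- sum(xc^2)
  if (ss == 0) stop("undefined statistic: values have zero variance")
  W <- sum(wm)
  if (W == 0) stop("no weights among defined cells")
  (length(x) / W) * sum(xc * as.vector(wm %*% xc)) / ss
}

# Vectorized Moran's I over the columns of X (already restricted to
# defined cells). Returns a numeric vector, one I per column.
morans_i_cols <- function(X, wm, W) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  num <- colSums(Xc * as.matrix(wm %*% Xc))
  den <- colSums(Xc^2)
  (n / W) * num / den
}

#' Moran's I correlogram
#'
#' Computes Moran's I in equal-width distance classes spanning `(0, dmax/2]`
#' where `dmax` is the maximum inter-cell distance, with a two-sided
#' permutation test per class (values permuted across cells; deviations
#' measured from the null expectation `-1/(n-1)`).
#'
#' @param values a [cell_field()].
#' @param grid a `bs_grid` (defaults to the field's grid).
#' @param n_classes number of distance classes (>= 2).
#' @param n_permutations permutations for the p-value.
#' @param seed integer seed for the permutations.
#' @param dist_method `"greatcircle"` (km; default) or `"planar"`
#'   (degrees).
#' @return data.frame of class `bs_correlogram` with columns
#'   `class_index`, `d_lo`, `d_hi`, `n_pairs`, `morans_i`, `p_value`.
#'   Classes with no pairs are dropped with a warning.
#' @export
correlogram <- function(values, grid = values$grid, n_classes = 10,
                        n_permutations = 999, seed = 1L,
                        dist_method = c("greatcircle", "planar")) {
  stopifnot(inherits(values, "cell_field"))
  dist_method <- match.arg(dist_method)
  if (n_classes < 2) stop("n_classes must be >= 2")
  x <- values$values
  ok <- !is.na(x)
  if (sum(ok) < 3) stop("need at least 3 defined values")
  x <- x[ok]
  n <- length(x)
  D <- cell_distances(grid, dist_method)[ok, ok, drop = FALSE]
  d_max <- max(D) / 2
  if (d_max <= 0) stop("degenerate geometry: all cells coincide")
  breaks <- seq(0, d_max, length.out = n_classes + 1)

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  P <- matrix(0, n, n_permutations)
  for (b in seq_len(n_permutations)) P[, b] <- x[sample.int(n)]

  e_i <- -1 / (n - 1)
  rows <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    inb <- D > breaks[k] & D <= breaks[k + 1]
    diag(inb) <- FALSE
    n_pairs <- sum(inb) / 2
    if (n_pairs < 1) {
      warning(sprintf("distance class %d (%.3g, %.3g] has no pairs; dropped",
                      k, breaks[k], breaks[k + 1]))
      next
    }
    wm <- Matrix::Matrix(inb * 1, sparse = TRUE)
    W <- sum(wm)
    i_obs <- morans_i_cols(matrix(x, ncol = 1), wm, W)
    i_perm <- morans_i_cols(P, wm, W)
    p <- (sum(abs(i_perm - e_i) >= abs(i_obs - e_i)) + 1) / (n_permutations + 1)
    rows[[k]] <- data.frame(class_index = k, d_lo = breaks[k],
                            d_hi = breaks[k + 1], n_pairs = n_pairs,
                            morans_i = i_obs, p_value = p)
  }
  out <- do.call(rbind, rows)
  attr(out, "dist_units") <- if (dist_method == "greatcircle") "km" else "degrees"
  class(out) <- c("bs_correlogram", class(out))
  out
}

#' @export
plot.bs_correlogram <- function(x, ...) {
  mid <- (x$d_lo + x$d_hi) / 2
  graphics::plot(mid, x$morans_i, type = "b", pch = ifelse(x$p_value < 0.05, 19, 1),
                 xlab = sprintf("distance (%s)", attr(x, "dist_units")),
                 ylab = "Moran's I", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Minimum-spanning-tree truncation distance
#'
#' The longest edge of the minimum spanning tree over the complete
#' inter-cell distance graph: the smallest threshold at which the cell
#' network is fully connected, used to truncate the PCNM distance matrix.
#'
#' @param coords 2-column matrix/data.frame of coordinates, or a
#'   `bs_grid` (cell centres are used).
#' @param dist_method `"greatcircle"` or `"planar"` (only used when
#'   `coords` is a grid; a plain coordinate matrix is treated as planar).
#' @return numeric scalar `t` in the distance units used, with a `units`
#'   attribute.
#' @export
mst_truncation <- function(coords, dist_method = c("greatcircle", "planar")) {
  dist_method <- match.arg(dist_method)
  D <- resolve_distances(coords, dist_method)
  if (nrow(D) < 2) stop("need at least two cells")
  sp <- vegan::spantree(stats::as.dist(D))
  t_ <- max(sp$dist)
  attr(t_, "units") <- attr(D, "units")
  t_
}

resolve_distances <- function(coords, dist_method) {
  if (inherits(coords, "bs_grid")) return(cell_distances(coords, dist_method))
  D <- as.matrix(stats::dist(as.matrix(coords)))
  attr(D, "units") <- "planar"
  D
}

#' PCNM spatial eigenvector filters
#'
#' Principal coordinates of neighbour matrices: inter-cell distances
#' beyond the truncation distance `t` are replaced by `4 t`, the matrix is
#' Gower double-centred (`-D^2/2`, centred by rows and columns) and
#' eigendecomposed; eigenvectors with positive eigenvalues (above
#' `1e-9 * max eigenvalue`) are kept as unit-norm columns. Eigenvectors
#' with large eigenvalues describe broad-scale spatial gradients, small
#' eigenvalues fine-scale structure; they serve as spatial covariates
#' ("filters") in the regressions.
#'
#' @param coords coordinates or a `bs_grid` (see [mst_truncation()]).
#' @param t truncation distance; defaults to the MST criterion.
#' @param dist_method `"greatcircle"` or `"planar"`.
#' @return An object of class `pcnm_filters`: list with `truncation_t`,
#'   `eigenvalues` (decreasing), `vectors` (cells x k, unit-norm centred
#'   columns) and `kept_rule`.
#' @export
pcnm <- function(coords, t = NULL, dist_method = c("greatcircle", "planar")) {
  dist_method <- match.arg(dist_method)
  D <- resolve_distances(coords, dist_method)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 cells")
  if (is.null(t)) t <- as.numeric(mst_truncation(coords, dist_method))
  if (t <= 0) stop("truncation distance must be > 0")
  D2 <- D
  D2[D2 > t] <- 4 * t
  diag(D2) <- 0
  A <- -0.5 * D2^2
  A <- sweep(A, 1, rowMeans(A))
  A <- sweep(A, 2, colMeans(A))
  e <- eigen(A, symmetric = TRUE)
  keep <- e$values > 1e-9 * max(e$values)
  if (!any(keep)) stop("no positive eigenvectors: degenerate geometry")
  V <- e$vectors[, keep, drop = FALSE]
  # eigen() returns unit-norm columns already; enforce explicitly
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  colnames(V) <- sprintf("V%d", seq_len(ncol(V)))
  structure(list(truncation_t = t, eigenvalues = e$values[keep],
                 vectors = V, kept_rule = "eigenvalue > 1e-9 * max",
                 dist_units = attr(D, "units")),
            class = "pcnm_filters")
}

#' @export
print.pcnm_filters <- function(x, ...) {
  cat(sprintf("<pcnm_filters> %d eigenvectors on %d cells, t = %.4g %s\n",
              ncol(x$vectors), nrow(x$vectors), x$truncation_t,
              x$dist_units))
  cat(sprintf("  eigenvalues %.4g .. %.4g\n",
              max(x$eigenvalues), min(x$eigenvalues)))
  invisible(x)
}

#' Select spatial filters by minimizing residual Moran's I
#'
#' Greedy forward selection: starting from the raw response, at each step
#' the candidate eigenvector whose inclusion most reduces the absolute
#' Moran's I of the least-squares residuals is added. Selection stops as
#' soon as the residual autocorrelation is negligible — below the
#' absolute magnitude `i_stop`, the conventional target in
#' eigenvector-based spatial filtering — or no longer significant under
#' a two-sided permutation test at `alpha`, or when no candidate reduces
#' `|I|` or `max_k` filters have been taken. Without an absolute target
#' the permutation test alone over-selects at large n (tiny residual
#' autocorrelation stays statistically significant), stripping the very
#' structure the covariates of interest should explain. The residual
#' `|I|` is non-increasing along the selection path by construction.
#'
#' @param response a [cell_field()] or numeric vector (may contain `NA`;
#'   those cells are dropped from response and filters alike).
#' @param filters a `pcnm_filters` object or a numeric matrix of filter
#'   columns.
#' @param w a `spatial_weights` over the same cells (typically queen
#'   contiguity).
#' @param alpha stopping significance level.
#' @param n_permutations permutations for the stopping test (99 resolves
#'   p down to 0.01, enough for the default `alpha`).
#' @param seed integer seed.
#' @param max_k optional cap on the number of selected filters.
#' @param i_stop absolute residual-autocorrelation target; selection
#'   stops once `|I|` of the residuals is at or below it.
#' @return list with `selected` (integer indices into the filter columns,
#'   in selection order), `residual_i` (Moran's I of the final
#'   residuals), `p_value` (its permutation p), `path` (data.frame of the
#'   residual `|I|` after each step) and `cells_used` (logical vector).
#' @export
select_filters <- function(response, filters, w, alpha = 0.05,
                           n_permutations = 99, seed = 1L, max_k = NULL,
                           i_stop = 0.05) {
  y <- if (inherits(response, "cell_field")) response$values else as.numeric(response)
  V <- if (inherits(filters, "pcnm_filters")) filters$vectors else as.matrix(filters)
  stopifnot(inherits(w, "spatial_weights"))
  if (length(y) != nrow(V) || length(y) != w$n)
    stop("response, filters and weights are not aligned")
  ok <- !is.na(y)
  y <- y[ok]
  n <- length(y)
  if (n < 4) stop("need at least 4 defined cells")
  Vs <- V[ok, , drop = FALSE]
  # the update rule below needs centred orthonormal columns; rebuild an
  # orthonormal basis for the filter column space (restriction to a cell
  # subset breaks centring/orthogonality), keeping the column index map.
  # For already-orthonormal PCNM columns on the full cell set this is the
  # identity up to per-column sign.
  Vc <- sweep(Vs, 2, colMeans(Vs))
  qr_ <- qr(Vc)
  col_map <- qr_$pivot[seq_len(qr_$rank)]
  Vs <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
  wm <- w$w[ok, ok, drop = FALSE]
  W <- sum(wm)
  if (W == 0) stop("no weights among defined cells")
  if (is.null(max_k)) max_k <- ncol(Vs)

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  moran_of <- function(r) {
    rc <- r - mean(r)
    ss <- sum(rc^2)
    if (ss == 0) return(0)
    (n / W) * sum(rc * as.vector(wm %*% rc)) / ss
  }
  # one fixed set of permutations, reused for every sequential test
  IDX <- matrix(0L, n, n_permutations)
  for (b in seq_len(n_permutations)) IDX[, b] <- sample.int(n)
  e_i <- -1 / (n - 1)
  perm_p <- function(r) {
    i_obs <- moran_of(r)
    rc <- r - mean(r)
    ss <- sum(rc^2)
    Pm <- matrix(rc[IDX], n, n_permutations)
    i_perm <- (n / W) * colSums(Pm * as.matrix(wm %*% Pm)) / ss
    list(i = i_obs,
         p = (sum(abs(i_perm - e_i) >= abs(i_obs - e_i)) + 1) /
             (n_permutations + 1))
  }

  WV <- as.matrix(wm %*% Vs)
  qv <- colSums(Vs * WV)          # v' W v per candidate
  r <- y - mean(y)                # residual of y on the intercept
  selected <- integer(0)
  avail <- rep(TRUE, ncol(Vs))
  path <- list()
  pp <- perm_p(r)
  path[[1]] <- data.frame(step = 0L, filter = NA_integer_,
                          residual_abs_i = abs(pp$i), p_value = pp$p)
  step <- 0L
  # projections of r on the candidates; with an orthonormal basis these
  # admit rank-one updates after each selection, so the O(n k) crossprods
  # are paid once, not per step
  a_k <- as.vector(crossprod(Vs, r))
  vWr <- as.vector(crossprod(Vs, as.vector(wm %*% r)))
  while (abs(pp$i) > i_stop && pp$p <= alpha && any(avail) &&
         length(selected) < max_k) {
    rWr <- sum(r * as.vector(wm %*% r))
    rr <- sum(r^2)
    # residual after removing candidate k: r - a_k v_k (v_k centred, unit)
    num <- rWr - 2 * a_k * vWr + a_k^2 * qv
    den <- rr - a_k^2
    i_k <- ifelse(den > 1e-300, (n / W) * num / den, 0)
    i_k[!avail] <- Inf
    cur <- (n / W) * rWr / rr
    kk <- which.min(abs(i_k))
    if (abs(i_k[kk]) >= abs(cur) - 1e-15) break  # no candidate reduces |I|
    delta <- a_k[kk]
    r <- r - delta * Vs[, kk]
    vWr <- vWr - delta * as.vector(crossprod(Vs, WV[, kk]))
    a_k[kk] <- 0
    selected <- c(selected, kk)
    avail[kk] <- FALSE
    step <- step + 1L
    pp <- perm_p(r)
    path[[step + 1L]] <- data.frame(step = step, filter = col_map[kk],
                                    residual_abs_i = abs(pp$i),
                                    p_value = pp$p)
  }
  list(selected = col_map[selected],
       residual_i = pp$i, p_value = pp$p,
       path = do.call(rbind, path), cells_used = ok)
}
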