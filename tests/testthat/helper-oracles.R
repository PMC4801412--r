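# Independent brute-force oracles used across the test files. These are
# deliberately naive (loops, dense algebra) so they share no code path
# with the package implementations they check.

# Moran's I by the dense double sum.
oracle_morans_i <- function(x, wm) {
  n <- length(x)
  xc <- x - mean(x)
  num <- 0; W <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- num + wm[i, j] * xc[i] * xc[j]
    W <- W + wm[i, j]
  }
  (n / W) * num / sum(xc^2)
}

# queen/rook neighbour offsets
offsets <- function(scheme) {
  if (scheme == "queen")
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else
    list(c(-1,0), c(0,-1), c(0,1), c(1,0))
}

# Mean beta_sim between each focal land cell and its adjacent land cells,
# by direct per-pair set algebra.
oracle_turnover <- function(pam, scheme = "queen") {
  g <- pam$grid
  vals <- rep(NA_real_, g$n_land)
  used <- integer(g$n_land)
  for (k in seq_len(g$n_land)) {
    r <- g$land_rc[k, "row"]; cc <- g$land_rc[k, "col"]
    si <- which(pam$incidence[k, ])
    bs <- c()
    for (d in offsets(scheme)) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (r2 < 1 || r2 > g$n_rows || c2 < 1 || c2 > g$n_cols) next
      j <- g$cell_index[r2, c2]
      if (is.na(j)) next
      sj <- which(pam$incidence[j, ])
      a <- length(intersect(si, sj))
      b <- length(setdiff(si, sj)); c_ <- length(setdiff(sj, si))
      if (a + min(b, c_) == 0) next
      bs <- c(bs, min(b, c_) / (a + min(b, c_)))
    }
    if (length(bs) > 0) { vals[k] <- mean(bs); used[k] <- length(bs) }
  }
  list(values = vals, neighbor_count = used)
}

# Mean |focal - neighbour| of a layer over adjacent land cells.
oracle_env_diff <- function(grid, v, scheme = "queen") {
  vals <- rep(NA_real_, grid$n_land)
  for (k in seq_len(grid$n_land)) {
    if (is.na(v[k])) next
    r <- grid$land_rc[k, "row"]; cc <- grid$land_rc[k, "col"]
    ds <- c()
    for (d in offsets(scheme)) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (r2 < 1 || r2 > grid$n_rows || c2 < 1 || c2 > grid$n_cols) next
      j <- grid$cell_index[r2, c2]
      if (is.na(j) || is.na(v[j])) next
      ds <- c(ds, abs(v[k] - v[j]))
    }
    if (length(ds) > 0) vals[k] <- mean(ds)
  }
  vals
}

# Longest edge of the minimum spanning tree, O(n^2) Prim.
oracle_mst_longest_edge <- function(D) {
  n <- nrow(D)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]
  longest <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    longest <- max(longest, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, D[j, ])
  }
  longest
}

# VIF by explicit normal equations.
oracle_vif <- function(X) {
  p <- ncol(X)
  out <- numeric(p)
  for (j in seq_len(p)) {
    y <- X[, j]
    M <- cbind(1, X[, -j, drop = FALSE])
    beta <- solve(t(M) %*% M, t(M) %*% y)
    res <- y - M %*% beta
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    out[j] <- 1 / (1 - r2)
  }
  out
}

# Semipartial R^2 of each predictor by two independent QR-based lm fits.
oracle_semipartial <- function(y, X, Fm = NULL) {
  r2 <- function(M) summary(stats::lm(y ~ M))$r.squared
  full <- r2(cbind(Fm, X))
  vapply(seq_len(ncol(X)), function(j)
    full - r2(cbind(Fm, X[, -j, drop = FALSE])), 0)
}

# Fraction of a cell covered by a polygon, by dense point sampling
# (res x res points per cell); point-in-polygon via mgcv::in.out.
oracle_coverage <- function(poly, grid, cell, res = 100) {
  cs <- grid$cell_size
  r <- grid$land_rc[cell, "row"]; cc <- grid$land_rc[cell, "col"]
  x0 <- grid$lon_min + (cc - 1) * cs
  y1 <- grid$lat_max - (r - 1) * cs
  xs <- x0 + (seq_len(res) - 0.5) * cs / res
  ys <- y1 - (seq_len(res) - 0.5) * cs / res
  pts <- as.matrix(expand.grid(x = xs, y = ys))
  bnd <- rbind(poly, poly[1, ], c(NA, NA))
  mean(mgcv::in.out(bnd[-nrow(bnd), , drop = FALSE], pts))
}

# A random simple (convex-hull) polygon inside the given bounding box.
random_polygon <- function(xlim, ylim, n_pts = 8) {
  x <- stats::runif(n_pts, xlim[1], xlim[2])
  y <- stats::runif(n_pts, ylim[1], ylim[2])
  h <- grDevices::chull(x, y)
  cbind(x[h], y[h])
}

# Random pa_matrix on a small all-land grid.
random_pam <- function(n_rows, n_cols, n_species, p = 0.3, seed = 1) {
  set.seed(seed)
  g <- build_grid(0, 0, n_rows, n_cols, 0.5)
  inc <- matrix(stats::runif(g$n_land * n_species) < p, g$n_land, n_species)
  colnames(inc) <- sprintf("sp%03d", seq_len(n_species))
  ranges <- lapply(seq_len(n_species), function(j) which(inc[, j]))
  names(ranges) <- colnames(inc)
  keep <- lengths(ranges) > 0
  build_pam(ranges[keep], g)
}
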