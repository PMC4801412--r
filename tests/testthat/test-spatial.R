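test_that("Moran's I reproduces closed-form and brute-force values", {
  # 2x2 rook checkerboard: I = -1 by hand evaluation of the double sum
  g <- build_grid(0, 0, 2, 2, 1)
  w <- queen_weights(g, scheme = "rook")
  chk <- cell_field(g, c(1, -1, -1, 1))
  expect_equal(morans_i(chk, w), -1)

  # constant field -> undefined-statistic error
  expect_error(morans_i(cell_field(g, rep(2, 4)), w), "zero variance")

  # random fields match the dense double-sum oracle
  set.seed(31)
  gg <- build_grid(0, 0, 5, 5, 1)
  ww <- queen_weights(gg)
  dense <- as.matrix(ww$w)
  for (rep in 1:10) {
    x <- stats::rnorm(gg$n_land)
    expect_equal(morans_i(cell_field(gg, x), ww), oracle_morans_i(x, dense),
                 tolerance = 1e-12)
  }

  # missing cells are dropped with their weights
  x <- stats::rnorm(gg$n_land); x[c(2, 9)] <- NA
  ok <- !is.na(x)
  expect_equal(morans_i(cell_field(gg, x), ww),
               oracle_morans_i(x[ok], dense[ok, ok]), tolerance = 1e-12)
})

test_that("MST truncation distance matches Prim on arbitrary point sets", {
  # regular 1D transect with spacing d -> t = d
  tr <- cbind(x = seq(0, 9) * 2.5, y = 0)
  expect_equal(as.numeric(mst_truncation(tr)), 2.5)

  # two clusters separated by a gap -> t = the bridge
  pts <- rbind(cbind(stats::runif(10, 0, 1), stats::runif(10, 0, 1)),
               cbind(stats::runif(10, 50, 51), stats::runif(10, 0, 1)))
  D <- as.matrix(stats::dist(pts))
  expect_equal(as.numeric(mst_truncation(pts)), oracle_mst_longest_edge(D))
  expect_gt(as.numeric(mst_truncation(pts)), 45)

  set.seed(13)
  for (rep in 1:10) {
    p <- cbind(stats::runif(15), stats::runif(15))
    expect_equal(as.numeric(mst_truncation(p)),
                 oracle_mst_longest_edge(as.matrix(stats::dist(p))),
                 tolerance = 1e-12)
  }
})

test_that("PCNM eigenvectors are centred, orthogonal and reconstruct Gower", {
  set.seed(17)
  pts <- cbind(stats::runif(20, 0, 10), stats::runif(20, 0, 10))
  f <- pcnm(pts)
  V <- f$vectors
  expect_true(all(abs(colMeans(V)) < 1e-10))
  G <- crossprod(V)
  expect_true(all(abs(G - diag(ncol(V))) < 1e-8))
  expect_true(all(diff(f$eigenvalues) <= 1e-9))
  expect_true(all(f$eigenvalues > 0))

  # reconstruction: double-centred truncated matrix = V L V' on kept part
  t_ <- f$truncation_t
  D <- as.matrix(stats::dist(pts)); D[D > t_] <- 4 * t_
  A <- -0.5 * D^2
  A <- sweep(A, 1, rowMeans(A)); A <- sweep(A, 2, colMeans(A))
  R <- V %*% diag(f$eigenvalues) %*% t(V)
  e_full <- eigen(A, symmetric = TRUE)
  keep <- e_full$values > 1e-9 * max(e_full$values)
  Rfull <- e_full$vectors[, keep] %*% diag(e_full$values[keep]) %*%
    t(e_full$vectors[, keep])
  expect_lt(max(abs(R - Rfull)) / max(abs(Rfull)), 1e-6)
})

test_that("PCNM matches the independent vegan implementation", {
  set.seed(19)
  pts <- cbind(stats::runif(12, 0, 5), stats::runif(12, 0, 5))
  ours <- pcnm(pts)
  ref <- vegan::pcnm(stats::dist(pts))
  expect_equal(ours$eigenvalues, ref$values[seq_along(ours$eigenvalues)],
               tolerance = 1e-8)
  for (j in seq_len(ncol(ours$vectors)))
    expect_gt(abs(stats::cor(ours$vectors[, j], ref$vectors[, j])), 1 - 1e-6)
})

test_that("PCNM eigenvectors on a transect are broad-scale sinusoids", {
  n <- 50
  tr <- cbind(x = seq_len(n), y = 0)
  f <- pcnm(tr)
  # with MST truncation the leading eigenvector is a one-period sinusoid
  x <- seq_len(n) - 0.5
  basis <- cbind(sin(2 * pi * x / n), cos(2 * pi * x / n))
  r2 <- summary(stats::lm(f$vectors[, 1] ~ basis))$r.squared
  expect_gt(sqrt(r2), 0.99)
  # and untruncated principal coordinates of a line recover position,
  # which is a half-period cosine to high accuracy
  D <- as.matrix(stats::dist(tr))
  A <- -0.5 * D^2
  A <- sweep(A, 1, rowMeans(A)); A <- sweep(A, 2, colMeans(A))
  e1 <- eigen(A, symmetric = TRUE)$vectors[, 1]
  expect_gt(abs(stats::cor(e1, cos(pi * x / n))), 0.95)
})

test_that("correlogram bins pairs by distance and flags gradient structure", {
  # 1x3 strip, planar distances, two classes: d=1 pairs then the d=2 pair
  g <- build_grid(0, 0, 1, 3, 1)
  f <- cell_field(g, c(1, 5, 2))
  # classes partition (0, dmax/2] = (0, 1]; the empty first class is
  # dropped with a warning, the d = 1 pairs land in the second
  expect_warning(cg <- correlogram(f, n_classes = 2, n_permutations = 49,
                                   dist_method = "planar"), "no pairs")
  expect_equal(nrow(cg), 1L)
  expect_equal(cg$n_pairs, 2)
  expect_equal(cg$d_lo, 0.5)

  # strong gradient: positive I at short range, negative at the longest
  gg <- build_grid(0, 0, 10, 10, 1)
  grad <- cell_field(gg, as.numeric(gg$land_rc[, "col"]))
  cg2 <- correlogram(grad, n_classes = 6, n_permutations = 99, seed = 2,
                     dist_method = "planar")
  expect_gt(cg2$morans_i[1], 0)
  expect_lt(cg2$morans_i[nrow(cg2)], 0)
  expect_lt(cg2$p_value[1], 0.05)
})

test_that("filter selection recovers a constructed eigenvector signal", {
  g <- build_grid(0, 0, 8, 8, 1)
  w <- queen_weights(g)
  f <- pcnm(g, dist_method = "planar")
  set.seed(23)
  y <- 3 * f$vectors[, 1] + stats::rnorm(g$n_land, sd = 0.3)
  sel <- select_filters(y, f, w, seed = 5)
  expect_equal(sel$selected[1], 1L)                 # first eigenvector first
  expect_true(sel$p_value > 0.05 || abs(sel$residual_i) <= 0.05)
  # residual |I| non-increasing along the path
  expect_true(all(diff(sel$path$residual_abs_i) <= 1e-8))

  # white noise: nothing to remove
  y0 <- stats::rnorm(g$n_land)
  sel0 <- select_filters(y0, f, w, seed = 5)
  expect_lte(length(sel0$selected), 2)
})

test_that("filter selection is deterministic given a seed and honours max_k", {
  g <- build_grid(0, 0, 7, 7, 1)
  w <- queen_weights(g)
  f <- pcnm(g, dist_method = "planar")
  set.seed(29)
  y <- as.numeric(scale(g$land_rc[, "row"])) + stats::rnorm(g$n_land, sd = 0.5)
  s1 <- select_filters(y, f, w, seed = 11)
  s2 <- select_filters(y, f, w, seed = 11)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$p_value, s2$p_value)
  s3 <- select_filters(y, f, w, seed = 11, max_k = 2)
  expect_lte(length(s3$selected), 2)

  # missing cells are dropped consistently
  y[c(3, 10)] <- NA
  s4 <- select_filters(y, f, w, seed = 11)
  expect_equal(sum(s4$cells_used), g$n_land - 2L)
})
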