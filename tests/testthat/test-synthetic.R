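test_that("continent layers follow the stated formulas in the noiseless limit", {
  spec0 <- continent_spec(n_rows = 8, n_cols = 10, ridge_height = 0,
                          elevation_noise_sd = 0, elevation_relief_sd = 0,
                          temp_noise_sd = 0, precip_noise_sd = 0,
                          seasonality_noise_sd = 0, seed = 1)
  ct <- make_continent(spec0)
  expect_equal(ct$env$elevation$values, rep(0, 80))

  # lapse rate: same-latitude cells differing by 1000 m differ by -6.5 C
  spec1 <- continent_spec(n_rows = 8, n_cols = 10, ridge_height = 2000,
                          elevation_noise_sd = 0, elevation_relief_sd = 0,
                          temp_noise_sd = 0, temp_lapse = 6.5, seed = 1)
  ct1 <- make_continent(spec1)
  rw <- ct1$grid$land_rc[, "row"]
  same_row <- which(rw == 4)
  e <- ct1$env$elevation$values[same_row]
  tp <- ct1$env$temperature$values[same_row]
  expect_equal(diff(tp), -6.5 * diff(e) / 1000, tolerance = 1e-12)

  # precipitation and seasonality are monotone in latitude without noise
  spec2 <- continent_spec(n_rows = 8, n_cols = 4, precip_noise_sd = 0,
                          seasonality_noise_sd = 0, seed = 1)
  ct2 <- make_continent(spec2)
  col1 <- ct2$grid$land_rc[, "col"] == 1
  expect_true(all(diff(ct2$env$precipitation$values[col1]) < 0))  # drier south
  expect_true(all(diff(ct2$env$seasonality$values[col1]) > 0))    # more seasonal
})

test_that("continent generation is bit-identical under the same spec and seed", {
  spec <- continent_spec(n_rows = 10, n_cols = 12, seed = 77)
  a <- make_continent(spec)
  b <- make_continent(spec)
  for (nm in names(a$env)) expect_identical(a$env[[nm]]$values, b$env[[nm]]$values)
  c_ <- make_continent(continent_spec(n_rows = 10, n_cols = 12, seed = 78))
  expect_false(identical(a$env$elevation$values, c_$env$elevation$values))
})

test_that("continent and clade specs validate their invariants", {
  expect_error(continent_spec(n_rows = 2), "n_rows")
  expect_error(continent_spec(cell_size = 0), "cell_size")
  expect_error(continent_spec(ridge_height = -5), "ridge_height")
  expect_error(continent_spec(ridge_width = 0.5), "ridge_width")
  expect_error(clade_spec("x", 0, c(1, 0, 0, 0)), "n_species")
  expect_error(clade_spec("x", 5, c(0, 0, 0, 0)), "nonzero")
  expect_error(clade_spec("x", 5, c(1, 0, 0, 0), niche_breadth = 0), "breadth")
})

test_that("simulated ranges are contiguous, sized and reproducible", {
  ct <- make_continent(continent_spec(n_rows = 12, n_cols = 15, seed = 5))
  cl <- clade_spec("test", 25, c(1, 0, 0, 0), seed = 9)
  sim <- simulate_ranges(ct$grid, ct$env, cl)
  expect_length(sim$ranges, 25)
  expect_true(all(lengths(sim$ranges) >= 1))
  expect_equal(sim$species_meta$range_size_cells, unname(lengths(sim$ranges)))

  # contiguity under queen adjacency: breadth-first search spans each range
  ap <- betascape:::adjacency_pairs(ct$grid, "queen")
  for (cells in sim$ranges) {
    if (length(cells) == 1) next
    reached <- cells[1]
    repeat {
      nb <- ap[ap[, "focal"] %in% reached, "neighbor"]
      nxt <- union(reached, intersect(nb, cells))
      if (length(nxt) == length(reached)) break
      reached <- nxt
    }
    expect_setequal(reached, cells)
  }

  # determinism and per-species counter seeding: earlier species unchanged
  sim2 <- simulate_ranges(ct$grid, ct$env, cl)
  expect_identical(sim$ranges, sim2$ranges)
  cl30 <- clade_spec("test", 30, c(1, 0, 0, 0), seed = 9)
  sim3 <- simulate_ranges(ct$grid, ct$env, cl30)
  expect_identical(sim3$ranges[1:25], sim$ranges)
})

test_that("degenerate size distribution gives exact range sizes", {
  ct <- make_continent(continent_spec(n_rows = 8, n_cols = 8, seed = 3))
  cl <- clade_spec("four", 10, c(0, 1, 0, 0), range_size_log_mean = log(4),
                   range_size_log_sd = 0, seed = 2)
  sim <- simulate_ranges(ct$grid, ct$env, cl)
  expect_true(all(lengths(sim$ranges) == 4))
  expect_false(any(sim$truth$truncated))

  # single species -> one column with at least one presence
  cl1 <- clade_spec("solo", 1, c(1, 0, 0, 0), seed = 4)
  sim1 <- simulate_ranges(ct$grid, ct$env, cl1)
  pam <- build_pam(sim1$ranges, ct$grid)
  expect_equal(ncol(pam$incidence), 1L)
  expect_gte(sum(pam$incidence), 1)
})

test_that("ranges larger than the landmass are truncated and flagged", {
  mask <- matrix(FALSE, 4, 4); mask[1:2, 1:2] <- TRUE  # 4-cell island
  ct <- make_continent(continent_spec(n_rows = 4, n_cols = 4, seed = 1),
                       land_mask = mask)
  cl <- clade_spec("big", 3, c(1, 0, 0, 0), range_size_log_mean = log(50),
                   range_size_log_sd = 0, seed = 6)
  sim <- simulate_ranges(ct$grid, ct$env, cl)
  expect_true(all(lengths(sim$ranges) == 4))
  expect_true(all(sim$truth$truncated))
})

test_that("elevation-weighted clades concentrate on high ground", {
  # across seeded replicates, mean richness in the top elevation quartile
  # exceeds the bottom quartile
  wins <- 0
  for (rep in 1:20) {
    ct <- make_continent(continent_spec(n_rows = 15, n_cols = 20,
                                        seed = 100 + rep))
    cl <- clade_spec("mont", 30, c(1, 0, 0, 0), seed = 200 + rep)
    sim <- simulate_ranges(ct$grid, ct$env, cl)
    rich <- richness(build_pam(sim$ranges, ct$grid))$values
    e <- ct$env$elevation$values
    hi <- e >= stats::quantile(e, 0.75)
    lo <- e <= stats::quantile(e, 0.25)
    if (mean(rich[hi]) > mean(rich[lo])) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("clade-specific drivers imprint on richness correlations", {
  # clade weighted on elevation correlates more with elevation than
  # temperature, and vice versa, in most replicates (construction check
  # at reduced scale)
  ok_a <- 0; ok_b <- 0; n_rep <- 10
  for (rep in 1:n_rep) {
    ct <- make_continent(continent_spec(n_rows = 20, n_cols = 30,
                                        seed = 300 + rep))
    sa <- simulate_ranges(ct$grid, ct$env,
                          clade_spec("A", 100, c(1, 0, 0, 0), seed = 400 + rep))
    sb <- simulate_ranges(ct$grid, ct$env,
                          clade_spec("B", 100, c(0, 1, 0, 0), seed = 500 + rep))
    ra <- richness(build_pam(sa$ranges, ct$grid))$values
    rb <- richness(build_pam(sb$ranges, ct$grid))$values
    e <- ct$env$elevation$values; tp <- ct$env$temperature$values
    if (abs(stats::cor(ra, e)) > abs(stats::cor(ra, tp))) ok_a <- ok_a + 1
    if (abs(stats::cor(rb, tp)) > abs(stats::cor(rb, e))) ok_b <- ok_b + 1
  }
  expect_gte(ok_a, 0.9 * n_rep)
  expect_gte(ok_b, 0.9 * n_rep)
})

test_that("the truth record states the expected predictor ranking", {
  ct <- make_continent(continent_spec(n_rows = 8, n_cols = 8, seed = 2))
  cl <- clade_spec("mix", 5, c(0.2, -1, 0, 0.5), seed = 3)
  sim <- simulate_ranges(ct$grid, ct$env, cl)
  expect_equal(sim$truth$expected_predictor_ranking,
               c("temperature", "seasonality", "elevation", "precipitation"))
  expect_equal(nrow(sim$truth$niche_optimum), 5L)
  expect_false(any(is.na(sim$truth$niche_optimum)))
})
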