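test_that("coverage rule admits a cell at exactly 50% and rejects 49%", {
  g <- build_grid(1, 0, 2, 2, 1)
  # square congruent with cell (row 1, col 1): lon [0,1], lat [0,1]
  full <- list(species_id = "full",
               geometry = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(rasterize_range(full, g), 1L)

  # rectangle covering exactly half of that cell
  half <- list(species_id = "half",
               geometry = rbind(c(0, 0), c(0.5, 0), c(0.5, 1), c(0, 1)))
  expect_equal(rasterize_range(half, g), 1L)

  # 49% of every cell it touches -> empty set with a warning
  under <- list(species_id = "under",
                geometry = rbind(c(0, 0), c(0.49, 0), c(0.49, 1), c(0, 1)))
  expect_warning(out <- rasterize_range(under, g), "no cell")
  expect_length(out, 0)
})

test_that("rasterization is monotone in the coverage threshold", {
  g <- build_grid(2, 0, 4, 4, 0.5)
  set.seed(7)
  for (rep in 1:10) {
    poly <- random_polygon(c(0.1, 1.9), c(0.1, 1.9))
    rg <- list(species_id = "s", geometry = poly)
    prev <- NULL
    for (th in c(0.9, 0.5, 0.2, 0.05)) {
      cells <- suppressWarnings(rasterize_range(rg, g, th))
      if (!is.null(prev)) expect_true(all(prev %in% cells))
      prev <- cells
    }
  }
})

test_that("rasterization agrees with a subcell point-sampling oracle", {
  skip_if_not_installed("mgcv")
  g <- build_grid(2, 0, 4, 4, 0.5)
  set.seed(42)
  n_bad <- 0
  for (rep in 1:100) {
    poly <- random_polygon(c(0.05, 1.95), c(0.05, 1.95), n_pts = 7)
    cells <- suppressWarnings(
      rasterize_range(list(species_id = "s", geometry = poly), g))
    cov <- vapply(seq_len(g$n_land), function(k)
      oracle_coverage(poly, g, k, res = 10), 0)
    oracle_cells <- which(cov >= 0.5)
    n_bad <- n_bad + length(union(setdiff(cells, oracle_cells),
                                  setdiff(oracle_cells, cells)))
  }
  # sampling-resolution discretization allows at most ~1 cell per fixture
  expect_lte(n_bad, 100)
})

test_that("holes reduce coverage and invalid geometry errors name the species", {
  g <- build_grid(1, 0, 1, 1, 1)
  outer <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  hole <- rbind(c(0.1, 0.1), c(0.9, 0.1), c(0.9, 0.9), c(0.1, 0.9))
  # outer covers 100%, hole removes 64% -> 36% < 50%
  expect_warning(
    out <- rasterize_range(list(species_id = "ring",
                                geometry = list(outer, hole)), g),
    "no cell")
  expect_length(out, 0)
  expect_error(rasterize_range(list(species_id = "bad",
                                    geometry = rbind(c(0, 0), c(1, 1))), g),
               "bad")
})

test_that("build_pam assembles incidence, keeps empty species, rejects duplicates", {
  g <- build_grid(1.5, 0, 3, 3, 0.5)
  ranges <- list(
    list(species_id = "a", clade_path = "X/P", cells = 1L),
    list(species_id = "b", clade_path = "X/Q", cells = 5L),
    list(species_id = "c", clade_path = "Y", cells = 9L))
  pam <- build_pam(ranges, g)
  expect_equal(richness(pam)$values, as.numeric(seq_len(9) %in% c(1, 5, 9)))
  expect_equal(pam$species_meta$range_size_cells, c(1, 1, 1))

  # explicit cell set bypasses polygon clipping
  pam2 <- build_pam(list(list(species_id = "a", cells = c(3, 7))), g)
  expect_equal(which(pam2$incidence[, 1]), c(3L, 7L))

  # a never-present species stays as an all-false column, reported
  never <- list(species_id = "ghost",
                geometry = rbind(c(10, 10), c(10.1, 10), c(10.1, 10.1), c(10, 10.1)))
  expect_message(pam3 <- build_pam(list(never, ranges[[1]]), g), "no cell")
  expect_equal(pam3$empty_species, "ghost")
  expect_equal(ncol(pam3$incidence), 2L)

  expect_error(build_pam(list(list(species_id = "a", cells = 1L),
                              list(species_id = "a", cells = 2L)), g),
               "duplicate")
})

test_that("richness equals the row-sum oracle and adds over disjoint clades", {
  pam <- random_pam(5, 6, 25, seed = 3)
  expect_equal(richness(pam)$values, as.numeric(rowSums(pam$incidence)))

  g <- build_grid(0, 0, 3, 3, 1)
  rngs <- c(lapply(1:3, function(j) list(species_id = paste0("a", j),
                                         clade_path = "A", cells = j)),
            lapply(1:3, function(j) list(species_id = paste0("b", j),
                                         clade_path = "B", cells = c(j, j + 3L))))
  pam2 <- build_pam(rngs, g)
  rA <- richness(clade_subset(pam2, "A"))$values
  rB <- richness(clade_subset(pam2, "B"))$values
  expect_equal(rA + rB, richness(pam2)$values)
})

test_that("restricted-range subset takes exactly ceiling(q S) smallest species", {
  g <- build_grid(0, 0, 2, 2, 1)
  rngs <- list(list(species_id = "s1", cells = 1L),
               list(species_id = "s2", cells = 1:2),
               list(species_id = "s3", cells = 1:3),
               list(species_id = "s4", cells = 1:4))
  sub <- restricted_range_subset(build_pam(rngs, g))
  expect_equal(sub$species_ids, "s1")   # ceiling(0.25 * 4) = 1

  # ties broken by species order, subset size exact
  ties <- lapply(1:8, function(j) list(species_id = sprintf("t%02d", j),
                                       cells = 1:2))
  sub2 <- restricted_range_subset(build_pam(ties, g))
  expect_equal(sub2$species_ids, c("t01", "t02"))

  # the count rule at the study's scale: 653 species -> 164
  expect_equal(as.integer(ceiling(0.25 * 653)), 164L)
  expect_error(restricted_range_subset(build_pam(rngs, g), quantile = 1.2),
               "quantile")
})

test_that("clade subsets match labels along the clade path and compose", {
  g <- build_grid(0, 0, 2, 2, 1)
  rngs <- list(
    list(species_id = "s1", clade_path = "Rodentia/Sig/Akodontini", cells = 1L),
    list(species_id = "s2", clade_path = "Rodentia/Sig/Oryzomyini", cells = 2L),
    list(species_id = "s3", clade_path = "Rodentia/Cav", cells = 3L))
  pam <- build_pam(rngs, g)
  expect_equal(clade_subset(pam, "Rodentia")$species_ids, pam$species_ids)
  expect_equal(clade_subset(pam, "Sig")$species_ids, c("s1", "s2"))
  # nested subset equals direct subset
  expect_equal(clade_subset(clade_subset(pam, "Sig"), "Akodontini")$species_ids,
               clade_subset(pam, "Akodontini")$species_ids)
  expect_error(clade_subset(pam, "Primates"), "known labels")
})
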